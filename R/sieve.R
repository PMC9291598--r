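#' Monotone B-spline sieve specification
#'
#' Builds the B-spline sieve space over which each baseline transform
#' \eqn{\phi_j} is estimated: a clamped B-spline of order `m` on
#' \eqn{[a, b]} with `n_interior` internal knots placed at empirical
#' percentiles of the pooled finite observation times \eqn{\{V_i, U_i\}}
#' (left-censoring zeros and right-censoring sentinels excluded). The
#' number of internal knots defaults to \eqn{N_n = \lceil n^\nu \rceil}
#' with \eqn{\nu = 1/(1+2p)}; the basis dimension is \eqn{N_n + m}.
#'
#' @param times Numeric vector of observation times used for knot placement;
#'   zeros and non-finite values are dropped.
#' @param n Sample size used in the knot-count rule (defaults to
#'   `length(times)` which is appropriate when `times` pools U and V from n
#'   subjects only approximately; pass the true n for the asymptotic rule).
#' @param order B-spline order `m` (4 = cubic).
#' @param n_interior Number of internal knots; overrides the `n^nu` rule.
#' @param nu Rate exponent for the knot-count rule; the default 1/5
#'   corresponds to smoothness p = 2.
#' @return An object of class `sieve_spec`: list with `knots` (full knot
#'   vector with boundary multiplicity `m`), `order`, `a`, `b`, `df`
#'   (= basis dimension), `n_interior`.
#' @examples
#' sp <- sieve_spec(c(1, 2, 3, 4, 5), n = 5, order = 4, n_interior = 1)
#' sp$knots  # clamped at 0 and 5, interior knot at the median 3
#' @export
sieve_spec <- function(times, n = length(times), order = 4L, n_interior = NULL,
                       nu = 1 / 5) {
  stopifnot(order >= 1L, nu > 0, nu < 1)
  times <- times[is.finite(times) & times > 0]
  if (length(times) == 0L) {
    stop("no finite positive observation times to place knots on", call. = FALSE)
  }
  a <- 0
  b <- max(times)
  if (is.null(n_interior)) n_interior <- as.integer(ceiling(n^nu))
  n_distinct_inner <- length(unique(times[times < b]))
  if (n_interior > n_distinct_inner) {
    warning(sprintf(
      "reducing number of interior knots from %d to %d (too few distinct times)",
      n_interior, n_distinct_inner
    ), call. = FALSE)
    n_interior <- n_distinct_inner
  }
  interior <- numeric(0)
  if (n_interior > 0) {
    probs <- seq_len(n_interior) / (n_interior + 1)
    interior <- unname(stats::quantile(times, probs = probs))
    interior <- interior[interior > a & interior < b]
    interior <- unique(interior)
    if (length(interior) < n_interior) {
      warning("dropped tied/boundary interior knots", call. = FALSE)
      n_interior <- length(interior)
    }
  }
  structure(
    list(
      knots = c(rep(a, order), interior, rep(b, order)),
      order = as.integer(order),
      a = a, b = b,
      n_interior = as.integer(n_interior),
      df = as.integer(n_interior + order)
    ),
    class = "sieve_spec"
  )
}

#' @export
print.sieve_spec <- function(x, ...) {
  cat(sprintf(
    "Monotone B-spline sieve: order %d, %d interior knot(s), df %d on [%g, %g]\n",
    x$order, x$n_interior, x$df, x$a, x$b
  ))
  invisible(x)
}

#' Evaluate the B-spline basis of a sieve specification
#'
#' Returns the matrix of B-spline basis functions \eqn{B_{s,m}(t)}. The basis
#' is a partition of unity: rows are nonnegative and sum to 1.
#'
#' @param spec A [sieve_spec()] object.
#' @param t Times in `[spec$a, spec$b]`.
#' @return Matrix with `length(t)` rows and `spec$df` columns.
#' @export
sieve_basis <- function(spec, t) {
  stopifnot(inherits(spec, "sieve_spec"))
  if (any(t < spec$a | t > spec$b)) {
    stop(sprintf("times outside the sieve domain [%g, %g]", spec$a, spec$b),
         call. = FALSE)
  }
  splines::splineDesign(spec$knots, x = t, ord = spec$order)
}

#' Evaluate a monotone sieve baseline transform
#'
#' \eqn{\phi(t; \gamma) = \sum_s \gamma_s B_{s,m}(t)}; nondecreasing in `t`
#' whenever `gamma` is increasing. With clamped boundary knots,
#' `phi(a) = gamma[1]` and `phi(b) = gamma[df]`.
#'
#' @inheritParams sieve_basis
#' @param gamma Increasing coefficient vector of length `spec$df`.
#' @export
sieve_phi <- function(spec, gamma, t) {
  stopifnot(length(gamma) == spec$df)
  drop(sieve_basis(spec, t) %*% gamma)
}

#' Baseline transform as a function of time
#'
#' Convenience closure wrapping [sieve_phi()], suitable as the `phi`
#' argument of [cif_eval()].
#'
#' @inheritParams sieve_phi
#' @return A function of `t`.
#' @export
sieve_phi_fun <- function(spec, gamma) {
  force(spec); force(gamma)
  function(t) sieve_phi(spec, gamma, t)
}

#' Unconstrained parameterization of increasing spline coefficients
#'
#' The monotonicity restriction \eqn{\gamma_1 < \dots < \gamma_{N_n+m}} is
#' enforced by optimizing over an unconstrained vector `raw` with
#' \eqn{\gamma_1 = raw_1} and
#' \eqn{\gamma_{s+1} = \gamma_s + \exp(raw_{s+1}) + \delta}. The minimum gap
#' `delta` keeps strict inequality numerically meaningful.
#'
#' @param raw Unconstrained numeric vector.
#' @param delta Minimum gap between consecutive coefficients.
#' @return Strictly increasing `gamma` of the same length.
#' @seealso [gamma_to_raw()] for the inverse map.
#' @export
raw_to_gamma <- function(raw, delta = 1e-6) {
  if (length(raw) == 1L) return(raw)
  cumsum(c(raw[1], exp(raw[-1]) + delta))
}

#' @rdname raw_to_gamma
#' @param gamma Strictly increasing vector with consecutive gaps > `delta`.
#' @export
gamma_to_raw <- function(gamma, delta = 1e-6) {
  if (length(gamma) == 1L) return(gamma)
  gaps <- diff(gamma)
  if (any(gaps <= delta)) {
    stop("`gamma` must be strictly increasing with gaps > delta", call. = FALSE)
  }
  c(gamma[1], log(gaps - delta))
}
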