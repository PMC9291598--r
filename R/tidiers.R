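#' Tidy a sieve fit
#'
#' One row per regression coefficient with bootstrap standard error, 95%
#' Wald limits, and normal-theory p-value when a bootstrap was run.
#'
#' @param x A `cif_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `cause`, `covariate`, `estimate`,
#'   and (if available) `std.error`, `conf.low`, `conf.high`, `p.value`.
#' @method tidy cif_fit
#' @export
tidy.cif_fit <- function(x, ...) {
  k <- nrow(x$beta); d <- ncol(x$beta)
  out <- tibble::tibble(
    term = paste0("beta", rep(seq_len(k), times = d),
                  rep(seq_len(d), each = k)),
    cause = rep(seq_len(k), times = d),
    covariate = rep(colnames(x$beta), each = k),
    estimate = as.vector(x$beta)
  )
  if (!is.null(x$se_beta)) {
    out$std.error <- as.vector(x$se_beta)
    out$conf.low <- as.vector(x$ci_lower)
    out$conf.high <- as.vector(x$ci_upper)
    out$p.value <- 2 * stats::pnorm(-abs(out$estimate / out$std.error))
  }
  out
}

#' Glance at a sieve fit
#'
#' @param x A `cif_fit`.
#' @param ... Unused.
#' @return A one-row tibble: method, sample sizes, objective value at the
#'   optimum, sieve dimension, convergence flag, bootstrap replicates used.
#' @method glance cif_fit
#' @export
glance.cif_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method, n = x$n, n_events = x$n_events,
    n_missing = x$n_missing, objective = x$objective,
    sieve_df = if (is.null(x$spec)) NA_integer_ else x$spec$df,
    converged = x$converged, n_bootstrap_used = x$n_bootstrap_used
  )
}

#' Plot fitted cumulative incidence curves
#'
#' Fitted CIFs per cause at a covariate value (default: the baseline,
#' `z = 0`), with bootstrap-free point curves.
#'
#' @param object A `cif_fit` with baseline coefficients (not an MI pool).
#' @param z Covariate vector at which to evaluate.
#' @param times Optional time grid.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cif_fit
#' @export
autoplot.cif_fit <- function(object, z = NULL, times = NULL, ...) {
  if (is.null(object$gamma)) {
    stop("this fit carries no baseline (MI pools coefficients only)",
         call. = FALSE)
  }
  pc <- predict_cif(object, z = z, times = times)
  ggplot2::ggplot(pc, ggplot2::aes(.data$time, .data$cif,
                                   colour = factor(.data$cause))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "cumulative incidence", colour = "cause") +
    ggplot2::theme_minimal()
}
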