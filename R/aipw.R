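#' Control parameters for the sieve fit
#'
#' @param order B-spline order (4 = cubic).
#' @param nu Knot-count rate exponent (interior knots \eqn{\lceil n^\nu\rceil}).
#' @param n_interior Fixed interior-knot count, overriding the rate rule.
#' @param eps_clip Clip for fitted response probabilities used as inverse
#'   weights.
#' @param barrier_mu Decreasing sequence of log-barrier weights for the
#'   feasibility constraint \eqn{\max_z \sum_j F_j(b; z) < 1}; the optimizer
#'   is run once per value, warm-starting each stage.
#' @param restarts Number of jittered re-initializations tried on
#'   nonconvergence.
#' @param rel_tol,maxit Passed to [stats::nlminb()].
#' @param delta_gap Minimum gap enforced between consecutive spline
#'   coefficients (see [raw_to_gamma()]).
#' @return A list of class `aipw_control`.
#' @export
aipw_control <- function(order = 4L, nu = 1 / 5, n_interior = NULL,
                         eps_clip = 1e-3, barrier_mu = c(1e-2, 1e-4),
                         restarts = 3L, rel_tol = 1e-10, maxit = 1000L,
                         delta_gap = 1e-6) {
  structure(list(order = order, nu = nu, n_interior = n_interior,
                 eps_clip = eps_clip, barrier_mu = barrier_mu,
                 restarts = restarts, rel_tol = rel_tol, maxit = maxit,
                 delta_gap = delta_gap), class = "aipw_control")
}

#' AIPW pseudo-indicators for one event record
#'
#' The augmented inverse-probability weights that replace the unobservable
#' event-type indicators in the weighted log-likelihood:
#' \deqn{\tilde\Delta_{ij}^{(l)} = \frac{R_i}{\rho_i}\Delta_{ij}^{(l)} -
#'   \frac{R_i - \rho_i}{\rho_i}\,\Delta_i^{(l)}\,\pi_j(O_i),}
#' where the augmentation \eqn{\pi_j} is applied to the record's observed
#' censoring class \eqn{l} (the class indicator \eqn{\Delta_i^{(l)}} is
#' always observed, only the type may be missing). Summed over causes and
#' classes the weights conserve mass: \eqn{\sum_{j,l}\tilde\Delta_{ij}^{(l)} = 1}
#' whenever \eqn{\sum_j \pi_j = 1}.
#'
#' @param cause Observed event type (1..k) or `NA` if missing.
#' @param delta1,delta2 Interval- and left-censoring indicators (0/1; must
#'   sum to 1: the record must be an event).
#' @param r Response indicator (0/1).
#' @param rho Fitted response probability in (0, 1).
#' @param pi Fitted event-type probability vector (length k, sums to 1).
#' @return A k-by-2 matrix; column `l` holds \eqn{\tilde\Delta_{ij}^{(l)}}.
#' @examples
#' tilde_weights(cause = 1, delta1 = 1, delta2 = 0, r = 1,
#'               rho = 0.5, pi = c(0.3, 0.7))
#' @export
tilde_weights <- function(cause, delta1, delta2, r, rho, pi) {
  if (delta1 + delta2 != 1L) {
    stop("tilde_weights() applies to event records only (delta = 1)",
         call. = FALSE)
  }
  stopifnot(rho > 0, rho < 1)
  k <- length(pi)
  ind <- numeric(k)
  if (r == 1) {
    stopifnot(!is.na(cause), cause >= 1, cause <= k)
    ind[cause] <- 1
  }
  w <- (r / rho) * ind - ((r - rho) / rho) * pi
  cbind(`1` = delta1 * w, `2` = delta2 * w)
}

# vectorized tilde weights for the event rows of a dataset: returns the two
# n_event x k weight matrices (interval / left classes)
tilde_weight_matrices <- function(ev, rho, pi) {
  k <- ncol(pi)
  ind <- matrix(0, nrow(ev), k)
  obs <- ev$r == 1L
  ind[cbind(which(obs), ev$cause[obs])] <- 1
  core <- (ev$r / rho) * ind - ((ev$r - rho) / rho) * pi
  list(w1 = ev$delta1 * core, w2 = ev$delta2 * core)
}

# ---- internal model frame -------------------------------------------------

make_frame <- function(data, spec, alpha) {
  z_cols <- ic_z_cols(data)
  Z <- as.matrix(data[, z_cols, drop = FALSE])
  i1 <- which(data$delta1 == 1L)
  i2 <- which(data$delta2 == 1L)
  i0 <- which(data$delta == 0L)
  list(
    n = nrow(data), k = ic_k(data), d = length(z_cols), spec = spec,
    alpha = alpha, z_cols = z_cols,
    i1 = i1, i2 = i2, i0 = i0,
    BU1 = sieve_basis(spec, data$u[i1]), BV1 = sieve_basis(spec, data$v[i1]),
    BU2 = sieve_basis(spec, data$u[i2]), BV0 = sieve_basis(spec, data$v[i0]),
    Z1 = Z[i1, , drop = FALSE], Z2 = Z[i2, , drop = FALSE],
    Z0 = Z[i0, , drop = FALSE],
    Zb = unique(Z)
  )
}

# pack/unpack: x = c(raw_1, beta_1, ..., raw_k, beta_k)
unpack_theta <- function(x, q, d, k, delta_gap) {
  per <- q + d
  lapply(seq_len(k), function(j) {
    block <- x[((j - 1) * per + 1):(j * per)]
    list(raw = block[1:q],
         gamma = raw_to_gamma(block[1:q], delta_gap),
         beta = block[(q + 1):(q + d)])
  })
}

# negative penalized objective and gradient; weights W1 (|i1| x k), W2 (|i2| x k)
make_engine <- function(frame, W1, W2, delta_gap) {
  q <- frame$spec$df; d <- frame$d; k <- frame$k; n <- frame$n
  tiny <- 1e-300

  links <- lapply(frame$alpha, gor_fns)

  eval_all <- function(x) {
    th <- unpack_theta(x, q, d, k, delta_gap)
    FU1 <- FV1 <- matrix(0, length(frame$i1), k)
    dU1 <- dV1 <- FU1
    FU2 <- dU2 <- matrix(0, length(frame$i2), k)
    FV0 <- dV0 <- matrix(0, length(frame$i0), k)
    Fb <- dFb <- matrix(0, nrow(frame$Zb), k)
    for (j in seq_len(k)) {
      lk <- links[[j]]
      bz1 <- drop(frame$Z1 %*% th[[j]]$beta)
      bz2 <- drop(frame$Z2 %*% th[[j]]$beta)
      bz0 <- drop(frame$Z0 %*% th[[j]]$beta)
      eU1 <- drop(frame$BU1 %*% th[[j]]$gamma) + bz1
      eV1 <- drop(frame$BV1 %*% th[[j]]$gamma) + bz1
      eU2 <- drop(frame$BU2 %*% th[[j]]$gamma) + bz2
      eV0 <- drop(frame$BV0 %*% th[[j]]$gamma) + bz0
      eb <- th[[j]]$gamma[q] + drop(frame$Zb %*% th[[j]]$beta)
      FU1[, j] <- lk$F(eU1); dU1[, j] <- lk$dF(eU1)
      FV1[, j] <- lk$F(eV1); dV1[, j] <- lk$dF(eV1)
      FU2[, j] <- lk$F(eU2); dU2[, j] <- lk$dF(eU2)
      FV0[, j] <- lk$F(eV0); dV0[, j] <- lk$dF(eV0)
      Fb[, j] <- lk$F(eb); dFb[, j] <- lk$dF(eb)
    }
    list(th = th, FU1 = FU1, FV1 = FV1, dU1 = dU1, dV1 = dV1,
         FU2 = FU2, dU2 = dU2, FV0 = FV0, dV0 = dV0, Fb = Fb, dFb = dFb)
  }

  # log-sum-exp upper bound on the per-row CIF totals at b: keeps the
  # log-barrier differentiable where the argmax row would switch, and
  # dominates the hard max (over-shoot at most temp*log(#rows)), so a
  # feasible smoothed margin implies the hard constraint holds. The hard
  # margin is still re-checked at the returned solution.
  soft_temp <- 0.005

  loglik_parts <- function(ev) {
    diff1 <- pmax(ev$FU1 - ev$FV1, tiny)
    denom0 <- 1 - rowSums(ev$FV0)
    s <- rowSums(ev$Fb)
    m <- max(s)
    wsoft <- exp((s - m) / soft_temp)
    feas <- 1 - (m + soft_temp * log(sum(wsoft)))
    ok <- all(denom0 > 0)
    ll <- if (!ok) -Inf else {
      (sum(W1 * log(diff1)) + sum(W2 * log(pmax(ev$FU2, tiny))) +
         sum(log(denom0))) / n
    }
    list(ll = ll, diff1 = diff1, denom0 = denom0, feas = feas,
         wsoft = wsoft / sum(wsoft), hard_feas = 1 - m)
  }

  # nlminb evaluates f and grad at the same point back to back: cache
  cache <- new.env(parent = emptyenv())
  eval_cached <- function(x) {
    if (!is.null(cache$x) && identical(cache$x, x)) return(cache$val)
    ev <- eval_all(x)
    val <- list(ev = ev, p = loglik_parts(ev))
    cache$x <- x
    cache$val <- val
    val
  }

  objective <- function(x, mu) {
    p <- eval_cached(x)$p
    if (!is.finite(p$ll) || p$feas <= 0) return(Inf)
    -p$ll - mu * log(p$feas)
  }

  gradient <- function(x, mu) {
    cv <- eval_cached(x)
    ev <- cv$ev
    p <- cv$p
    if (!is.finite(p$ll) || p$feas <= 0) return(rep(0, length(x)))
    g <- numeric(length(x))
    per <- q + d
    for (j in seq_len(k)) {
      c1 <- W1[, j] / p$diff1[, j]
      c2 <- W2[, j] / pmax(ev$FU2[, j], tiny)
      c0 <- 1 / p$denom0
      ggam <- drop(crossprod(frame$BU1, c1 * ev$dU1[, j])) -
        drop(crossprod(frame$BV1, c1 * ev$dV1[, j])) +
        drop(crossprod(frame$BU2, c2 * ev$dU2[, j])) -
        drop(crossprod(frame$BV0, c0 * ev$dV0[, j]))
      gbet <- drop(crossprod(frame$Z1, c1 * (ev$dU1[, j] - ev$dV1[, j]))) +
        drop(crossprod(frame$Z2, c2 * ev$dU2[, j])) -
        drop(crossprod(frame$Z0, c0 * ev$dV0[, j]))
      ggam <- ggam / n
      gbet <- gbet / n
      # barrier: d(-mu log feas)/dtheta with softmax weights over the rows
      dsoft <- sum(p$wsoft * ev$dFb[, j])
      ggam[q] <- ggam[q] - (mu / p$feas) * dsoft
      gbet <- gbet - (mu / p$feas) *
        drop(crossprod(frame$Zb, p$wsoft * ev$dFb[, j]))
      # chain through the monotone reparameterization
      raw <- ev$th[[j]]$raw
      tails <- rev(cumsum(rev(ggam)))
      graw <- c(tails[1], if (q > 1) exp(raw[-1]) * tails[-1])
      g[((j - 1) * per + 1):(j * per)] <- c(-graw, -gbet)
    }
    g
  }

  list(objective = objective, gradient = gradient, eval_all = eval_all,
       loglik_parts = loglik_parts)
}

default_init <- function(q, d, k, alpha, delta_gap) {
  # baseline CIFs rising from ~0.01 at a to 0.3/k at b: always feasible
  x <- numeric(0)
  for (j in seq_len(k)) {
    gam <- gor_link(seq(0.01, 0.3 / k, length.out = q), alpha[j])
    x <- c(x, gamma_to_raw(gam, delta_gap), rep(0, d))
  }
  x
}

fit_sieve_engine <- function(data, W1, W2, alpha, control, spec = NULL,
                             init = NULL, seed = NULL) {
  if (is.null(spec)) {
    times <- c(data$v[data$v > 0], data$u[is.finite(data$u)])
    spec <- sieve_spec(times, n = nrow(data), order = control$order,
                       n_interior = control$n_interior, nu = control$nu)
  }
  frame <- make_frame(data, spec, alpha)
  eng <- make_engine(frame, W1, W2, control$delta_gap)
  q <- spec$df; d <- frame$d; k <- frame$k

  x0 <- if (is.null(init)) default_init(q, d, k, alpha, control$delta_gap) else init
  if (!is.finite(eng$objective(x0, control$barrier_mu[1]))) {
    x0 <- default_init(q, d, k, alpha, control$delta_gap)
  }

  # compact sieve space: box constraints on the working parameters. The
  # weighted objective can carry negative weights, under which a probability
  # driven to zero increases the objective without bound; the consistency
  # theory assumes a bounded parameter space, and these generous boxes make
  # that operational (|gamma_1|, |beta| well beyond any plausible scale).
  lower <- rep(c(-15, rep(-25, q - 1), rep(-10, d)), k)
  upper <- rep(c(15, rep(3.5, q - 1), rep(10, d)), k)
  x0 <- pmin(pmax(x0, lower), upper)

  run_once <- function(x_start) {
    x <- pmin(pmax(x_start, lower), upper)
    res <- NULL
    for (mu in control$barrier_mu) {
      res <- stats::nlminb(
        x, objective = eng$objective, gradient = eng$gradient, mu = mu,
        lower = lower, upper = upper,
        control = list(rel.tol = control$rel_tol, iter.max = control$maxit,
                       eval.max = 2L * control$maxit)
      )
      x <- res$par
    }
    g <- eng$gradient(res$par, control$barrier_mu[length(control$barrier_mu)])
    # projected gradient: components pressing against an active bound are
    # KKT-consistent and do not count as nonconvergence
    g[res$par <= lower + 1e-8 & g > 0] <- 0
    g[res$par >= upper - 1e-8 & g < 0] <- 0
    gnorm <- max(abs(g))
    res$grad_norm <- gnorm
    res$hard_feas <- eng$loglik_parts(eng$eval_all(res$par))$hard_feas
    res$ok <- (res$convergence == 0 || gnorm < 1e-3) && res$hard_feas > 0
    res
  }

  best <- run_once(x0)
  tries <- 0L
  if (!best$ok && !is.null(seed)) set.seed(seed)
  while (!best$ok && tries < control$restarts) {
    tries <- tries + 1L
    res <- run_once(x0 + stats::rnorm(length(x0), sd = 0.3))
    if (res$ok || res$objective < best$objective) best <- res
  }
  if (!best$ok) {
    cond <- structure(
      class = c("aipwcif_nonconvergence", "error", "condition"),
      list(message = sprintf(
        "sieve optimizer failed to converge (grad norm %.2e); best iterate attached",
        best$grad_norm
      ), call = NULL, best = best)
    )
    stop(cond)
  }

  th <- unpack_theta(best$par, q, d, k, control$delta_gap)
  ll <- eng$loglik_parts(eng$eval_all(best$par))$ll
  list(
    spec = spec, alpha = alpha,
    gamma = lapply(th, `[[`, "gamma"),
    beta = do.call(rbind, lapply(th, `[[`, "beta")),
    par = best$par, objective = ll, converged = TRUE,
    grad_norm = best$grad_norm, restarts_used = tries
  )
}

# ---- exported objective-layer functions (test / diagnostic surface) --------

theta_matrices <- function(theta, data) {
  # theta: list(spec, gamma = list per cause, beta = k x d matrix, alpha)
  stopifnot(inherits(theta$spec, "sieve_spec"))
  k <- length(theta$gamma)
  beta <- theta$beta
  if (is.null(dim(beta))) beta <- matrix(beta, nrow = k, byrow = TRUE)
  Z <- as.matrix(data[, ic_z_cols(data), drop = FALSE])
  FU <- FV <- matrix(NA_real_, nrow(data), k)
  ev <- data$delta == 1L
  for (j in seq_len(k)) {
    bz <- drop(Z %*% beta[j, ])
    if (any(ev)) {
      FU[ev, j] <- gor_inverse(
        sieve_phi(theta$spec, theta$gamma[[j]], data$u[ev]) + bz[ev],
        theta$alpha[j])
    }
    FV[, j] <- gor_inverse(
      sieve_phi(theta$spec, theta$gamma[[j]], data$v) + bz, theta$alpha[j])
  }
  list(FU = FU, FV = FV, k = k, beta = beta)
}

#' Complete-data weighted sieve log-likelihood
#'
#' The (1/n-scaled) log-likelihood of interval-censored competing-risks data
#' with fully observed event types:
#' \deqn{\frac1n \sum_i \Big[\sum_j \Delta_{ij}^{(1)}
#'   \log\{F_j(U_i) - F_j(V_i)\} + \sum_j \Delta_{ij}^{(2)} \log F_j(U_i)
#'   + (1 - \Delta_i)\log\{1 - \sum_j F_j(V_i)\}\Big].}
#' Returns `-Inf` when any log argument is nonpositive.
#'
#' @param theta List with elements `spec` (a [sieve_spec()]), `gamma`
#'   (list of per-cause coefficient vectors), `beta` (k-by-d matrix), and
#'   `alpha` (length-k vector of link exponents).
#' @param data An `ic_data` tibble with all event types observed.
#' @return Scalar log-likelihood value.
#' @export
complete_loglik <- function(theta, data) {
  if (any(data$r == 0L)) {
    stop("complete_loglik() requires fully observed event types", call. = FALSE)
  }
  ev <- data$delta == 1L
  ind <- matrix(0, nrow(data), length(theta$gamma))
  ind[cbind(which(ev), data$cause[ev])] <- 1
  aipw_loglik_core(theta, data, W = ind)
}

#' AIPW objective function
#'
#' The augmented inverse-probability-weighted version of the complete-data
#' log-likelihood: event terms carry the pseudo-indicators
#' \eqn{\tilde\Delta_{ij}^{(l)}} built from the fitted response probability
#' `rho` and event-type probabilities `pi`; right-censored terms are
#' unweighted. Reduces exactly to [complete_loglik()] when every type is
#' observed and `rho` is identically 1.
#'
#' @inheritParams complete_loglik
#' @param data An `ic_data` tibble.
#' @param rho Numeric vector (length `nrow(data)`) of response
#'   probabilities; only event rows are used.
#' @param pi Matrix (`nrow(data)` by k) of event-type probabilities.
#' @return Scalar objective value.
#' @export
aipw_objective <- function(theta, data, rho, pi) {
  ev <- data$delta == 1L
  k <- length(theta$gamma)
  pi <- matrix(pi, nrow(data), k)
  tw <- tilde_weight_matrices(data[ev, , drop = FALSE], rho[ev],
                              pi[ev, , drop = FALSE])
  W <- matrix(0, nrow(data), k)
  W[ev, ] <- tw$w1 + tw$w2   # each event row is in exactly one class
  aipw_loglik_core(theta, data, W)
}

aipw_loglik_core <- function(theta, data, W) {
  tm <- theta_matrices(theta, data)
  ev <- data$delta == 1L
  i1 <- data$delta1 == 1L
  i2 <- data$delta2 == 1L
  i0 <- !ev
  diff1 <- tm$FU[i1, , drop = FALSE] - tm$FV[i1, , drop = FALSE]
  fu2 <- tm$FU[i2, , drop = FALSE]
  denom0 <- 1 - rowSums(tm$FV[i0, , drop = FALSE])
  active1 <- W[i1, , drop = FALSE] != 0
  active2 <- W[i2, , drop = FALSE] != 0
  if (any(diff1[active1] <= 0) || any(fu2[active2] <= 0) || any(denom0 <= 0)) {
    return(-Inf)
  }
  l1 <- sum((W[i1, , drop = FALSE] * log(pmax(diff1, 1e-300)))[active1])
  l2 <- sum((W[i2, , drop = FALSE] * log(pmax(fu2, 1e-300)))[active2])
  (l1 + l2 + sum(log(denom0))) / nrow(data)
}

#' Feasibility margin of the joint CIF constraint
#'
#' The fitted model must satisfy \eqn{\max_z \sum_j F_j(b; z) < 1}, with the
#' maximum taken over the observed covariate rows of the data (for
#' continuous covariates an unrestricted maximum would be unbounded).
#' Returns \eqn{1 - \max_z \sum_j F_j(b; z)}: positive iff feasible.
#'
#' @inheritParams complete_loglik
#' @param data An `ic_data` tibble supplying the observed covariate rows.
#' @return Scalar margin.
#' @export
feasibility_constraint <- function(theta, data) {
  Z <- unique(as.matrix(data[, ic_z_cols(data), drop = FALSE]))
  k <- length(theta$gamma)
  beta <- theta$beta
  if (is.null(dim(beta))) beta <- matrix(beta, nrow = k, byrow = TRUE)
  q <- theta$spec$df
  s <- rep(0, nrow(Z))
  for (j in seq_len(k)) {
    s <- s + gor_inverse(theta$gamma[[j]][q] + drop(Z %*% beta[j, ]),
                         theta$alpha[j])
  }
  1 - max(s)
}
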