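#' Complete-case sieve fit
#'
#' The naive benchmark: drops every event whose type is missing (`r == 0`;
#' right-censored subjects are always kept since their status is observed)
#' and runs the complete-data sieve MLE on the remainder. Because
#' missingness occurs selectively among events, this estimator is subject
#' to selection bias under missing event types.
#'
#' @inheritParams fit_sieve
#' @return An object of class `c("cc_fit", "cif_fit")`.
#' @export
fit_cc <- function(data, alpha = NULL, control = aipw_control(),
                   nboot = 0L, stratified = FALSE, seed = NULL,
                   init = NULL, spec = NULL) {
  kept <- ic_subset(data, which(data$r == 1L))
  fit <- fit_sieve(kept, alpha = alpha, control = control, seed = seed,
                   init = init, spec = spec)
  fit$method <- "cc"
  class(fit) <- c("cc_fit", "cif_fit")
  fit$n <- nrow(data)
  fit$n_missing <- sum(data$r == 0L)
  if (nboot > 0L) {
    fit <- add_bootstrap(fit, data, nboot, stratified, seed,
                         refit = function(d) fit_cc(
                           d, alpha = fit$alpha, control = control,
                           init = fit$par))
  }
  fit
}

#' Impute missing event types from the fitted event-type model
#'
#' Produces one completed dataset: for every record with a missing type,
#' the cause is drawn from the event-type distribution \eqn{\pi(O; \psi^*)}.
#' Under proper imputation (`proper = TRUE`) \eqn{\psi^*} is first drawn
#' from the asymptotic normal of \eqn{\hat\psi}, so that imputation
#' uncertainty about the model parameters propagates into the
#' between-imputation variance; with `proper = FALSE` the MLE
#' \eqn{\hat\psi} is used as is.
#'
#' @param data An `ic_data` tibble.
#' @param pi_fit A fitted [fit_pi()] model (k = 2 for proper draws).
#' @param proper Draw \eqn{\psi^*} from \eqn{N(\hat\psi, \widehat{cov})}?
#' @param seed Optional integer seed.
#' @return An `ic_data` tibble with `r == 1` everywhere.
#' @export
impute_types <- function(data, pi_fit, proper = TRUE, seed = NULL) {
  stopifnot(inherits(pi_fit, "pi_fit"))
  if (!is.null(seed)) set.seed(seed)
  miss <- which(data$r == 0L)
  if (length(miss) == 0L) return(data)
  coef <- NULL
  if (proper) {
    if (pi_fit$k != 2L) stop("proper draws are implemented for k = 2")
    coef <- drop(MASS::mvrnorm(1, mu = pi_fit$coef, Sigma = pi_fit$vcov))
  }
  p <- predict_pi(pi_fit, ic_subset(data, miss), coef = coef)
  out <- data
  if (pi_fit$k == 2L) {
    out$cause[miss] <- ifelse(stats::runif(length(miss)) < p[, 1], 1L, 2L)
  } else {
    out$cause[miss] <- vapply(seq_len(nrow(p)), function(i) {
      sample.int(pi_fit$k, 1L, prob = p[i, ])
    }, integer(1))
  }
  out$r[miss] <- 1L
  out
}

#' Pool multiply imputed estimates by Rubin's rules
#'
#' Combines M complete-data estimates: pooled mean, within-imputation
#' variance \eqn{\bar W}, between-imputation variance \eqn{B}, total
#' variance \eqn{T = \bar W + (1 + 1/M) B}, and \eqn{SE = \sqrt T}.
#'
#' @param estimates List of M numeric vectors (or matrices) of estimates.
#' @param variances Optional list of M per-imputation variance vectors of
#'   the same shape (e.g. squared bootstrap SEs). When omitted, only the
#'   pooled point estimate and between-imputation variance are returned.
#' @return List with `m`, `beta_bar`, `within`, `between`, `total`, `se`.
#' @examples
#' rubin_pool(list(0.4, 0.6), list(0.01, 0.01))
#' @export
rubin_pool <- function(estimates, variances = NULL) {
  m <- length(estimates)
  stopifnot(m >= 2L)
  if (!is.null(variances) && length(variances) != m) {
    stop("`estimates` and `variances` must have equal length", call. = FALSE)
  }
  est <- lapply(estimates, function(e) as.numeric(e))
  p <- length(est[[1]])
  stopifnot(all(vapply(est, length, integer(1)) == p))
  emat <- do.call(rbind, est)
  beta_bar <- colMeans(emat)
  between <- apply(emat, 2, stats::var)
  out <- list(m = m, beta_bar = beta_bar, between = between,
              within = NULL, total = NULL, se = NULL)
  if (!is.null(variances)) {
    vmat <- do.call(rbind, lapply(variances, as.numeric))
    stopifnot(ncol(vmat) == p)
    out$within <- colMeans(vmat)
    out$total <- out$within + (1 + 1 / m) * between
    out$se <- sqrt(out$total)
  }
  out
}

#' Multiple-imputation sieve fit
#'
#' The MI benchmark: M completed datasets are produced by [impute_types()]
#' under the fitted event-type model, each is analyzed with the
#' complete-data sieve MLE, and results are pooled by Rubin's rules
#' ([rubin_pool()]). Within-imputation variances come from a nonparametric
#' bootstrap of each completed-data fit (`nboot_within` replicates);
#' set `nboot_within = 0` for point estimation only.
#'
#' @inheritParams fit_aipw
#' @param m Number of imputations.
#' @param nboot_within Bootstrap replications per imputation for the
#'   within-imputation variance (0 = point estimates only).
#' @param proper Propagate imputation-model parameter uncertainty
#'   (see [impute_types()]).
#' @return An object of class `c("mi_fit", "cif_fit")`; `se_beta` and the
#'   Wald limits are Rubin-pooled when `nboot_within > 0`.
#' @export
fit_mi <- function(data, m = 5L, alpha = NULL, pi_formula = NULL,
                   control = aipw_control(), nboot_within = 0L,
                   proper = TRUE, seed = NULL) {
  check_fit_inputs(data)
  if (all(data$r == 1L)) {
    fit <- fit_sieve(data, alpha = alpha, control = control, seed = seed)
    fit$method <- "mi"
    class(fit) <- c("mi_fit", "cif_fit")
    fit$m <- 1L
    return(fit)
  }
  if (!is.null(seed)) set.seed(seed)
  pi_fit <- fit_pi(data, pi_formula)
  fits <- vector("list", m)
  init <- NULL
  for (i in seq_len(m)) {
    imp <- impute_types(data, pi_fit, proper = proper)
    fits[[i]] <- fit_sieve(imp, alpha = alpha, control = control, init = init,
                           nboot = nboot_within)
    init <- fits[[i]]$par
  }
  est <- lapply(fits, `[[`, "beta")
  vars <- if (nboot_within > 0L) lapply(fits, function(f) f$se_beta^2) else NULL
  pooled <- rubin_pool(est, vars)

  fit <- fits[[1]]
  shape <- dim(fit$beta)
  dn <- dimnames(fit$beta)
  fit$beta <- matrix(pooled$beta_bar, shape[1], shape[2], dimnames = dn)
  fit$method <- "mi"
  class(fit) <- c("mi_fit", "cif_fit")
  fit$m <- m
  fit$pooled <- pooled
  fit$gamma <- NULL  # per-imputation baselines are not pooled
  fit$nuisance <- list(pi = pi_fit)
  fit$n <- nrow(data)
  fit$n_missing <- sum(data$r == 0L)
  if (!is.null(pooled$se)) {
    fit$se_beta <- matrix(pooled$se, shape[1], shape[2], dimnames = dn)
    fit$ci_lower <- fit$beta - 1.96 * fit$se_beta
    fit$ci_upper <- fit$beta + 1.96 * fit$se_beta
  } else {
    fit$se_beta <- NULL
    fit$ci_lower <- fit$ci_upper <- NULL
  }
  fit
}
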