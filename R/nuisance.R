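default_nuisance_formula <- function(data) {
  rhs <- c("u", ic_z_cols(data), ic_a_cols(data))
  stats::as.formula(paste("~", paste(rhs, collapse = " + ")))
}

nuisance_design <- function(formula, data) {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.pass)
  stats::model.matrix(formula, mf)
}

check_logistic_fit <- function(fit, label) {
  if (!fit$converged) {
    stop(sprintf("%s model did not converge (possible separation); %s",
                 label, "inspect the design or simplify the formula"),
         call. = FALSE)
  }
  p <- stats::fitted(fit)
  if ((any(p < 1e-8) || any(p > 1 - 1e-8)) && max(abs(stats::coef(fit))) > 15) {
    stop(sprintf("quasi-complete separation in the %s model: fitted %s",
                 label, "probabilities numerically 0/1 with diverging coefficients"),
         call. = FALSE)
  }
  invisible(fit)
}

#' Fit the missingness (response) model
#'
#' Stage 1a of the two-stage AIPW analysis: a binary logistic model for the
#' response indicator \eqn{R} given \eqn{O = (U, Z, A)}, fitted by maximum
#' likelihood on the event cases (\eqn{\Delta = 1}) only. The default design
#' is intercept + `u` + all covariates + all auxiliaries (linear).
#'
#' If no event case is missing its type, the estimator needs no weighting;
#' this is signalled by a fit with `no_missingness = TRUE` and callers short
#' circuit to the complete-data sieve MLE.
#'
#' @param data An `ic_data` tibble.
#' @param formula Right-hand-side formula over columns of `data`
#'   (default: `~ u + z... + a...`).
#' @return An object of class `rho_fit`: list with `coef`, `vcov`,
#'   `formula`, `no_missingness`, `glm` (the underlying fit).
#' @export
fit_rho <- function(data, formula = NULL) {
  stopifnot(inherits(data, "ic_data"))
  ev <- data[data$delta == 1L, , drop = FALSE]
  if (nrow(ev) == 0L) stop("no event cases to fit the missingness model on",
                           call. = FALSE)
  if (is.null(formula)) formula <- default_nuisance_formula(data)
  if (all(ev$r == 1L)) {
    return(structure(list(coef = NULL, vcov = NULL, formula = formula,
                          no_missingness = TRUE, glm = NULL),
                     class = "rho_fit"))
  }
  if (all(ev$r == 0L)) {
    stop("all event types are missing; the missingness model is degenerate",
         call. = FALSE)
  }
  X <- nuisance_design(formula, ev)
  fit <- suppressWarnings(stats::glm.fit(
    X, ev$r, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-12, maxit = 100)
  ))
  fit$formula <- formula
  check_logistic_fit(fit, "missingness")
  # observed-information covariance
  w <- fit$weights
  xtwx <- crossprod(X * sqrt(w))
  structure(
    list(coef = stats::coef(fit), vcov = solve(xtwx), formula = formula,
         no_missingness = FALSE, glm = fit),
    class = "rho_fit"
  )
}

#' Fit the event-type model
#'
#' Stage 1b: a binary (k = 2) or multinomial (k > 2) logistic model for the
#' event type \eqn{\epsilon} given \eqn{O = (U, Z, A)}, fitted on the
#' complete event cases (\eqn{R = 1, \Delta = 1}). For k = 2 the model is
#' for \eqn{\pi_1 = \Pr(\epsilon = 1 | \Delta = 1, O)}.
#'
#' @inheritParams fit_rho
#' @return An object of class `pi_fit`: list with `coef`, `vcov`, `formula`,
#'   `k`, and the underlying fit.
#' @export
fit_pi <- function(data, formula = NULL) {
  stopifnot(inherits(data, "ic_data"))
  k <- ic_k(data)
  cc <- data[data$delta == 1L & data$r == 1L, , drop = FALSE]
  causes <- sort(unique(cc$cause))
  if (length(causes) < 2L) {
    stop("fewer than two distinct observed event types; the event-type ",
         "model is degenerate", call. = FALSE)
  }
  if (is.null(formula)) formula <- default_nuisance_formula(data)
  X <- nuisance_design(formula, cc)
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient event-type design (a term is constant on the ",
         "complete cases)", call. = FALSE)
  }
  if (k == 2L) {
    fit <- suppressWarnings(stats::glm.fit(
      X, as.integer(cc$cause == 1L), family = stats::binomial(),
      control = stats::glm.control(epsilon = 1e-12, maxit = 100)
    ))
    check_logistic_fit(fit, "event-type")
    w <- fit$weights
    vc <- solve(crossprod(X * sqrt(w)))
    coefs <- stats::coef(fit)
  } else {
    df <- as.data.frame(X[, -1, drop = FALSE])
    df$.cause <- factor(cc$cause, levels = seq_len(k))
    fit <- nnet::multinom(.cause ~ ., data = df, trace = FALSE, maxit = 500)
    coefs <- stats::coef(fit)
    vc <- stats::vcov(fit)
  }
  structure(
    list(coef = coefs, vcov = vc, formula = formula, k = k, fit = fit),
    class = "pi_fit"
  )
}

#' Predict missingness and event-type probabilities
#'
#' `predict_rho()` returns \eqn{\hat\rho(O)} clipped to
#' `[eps_clip, 1 - eps_clip]` (the clipped value is used as an inverse
#' weight; a clip is logged via a message when active). `predict_pi()`
#' returns the n-by-k matrix of event-type probabilities, rows summing to 1.
#'
#' @param fit A `rho_fit` or `pi_fit`.
#' @param data An `ic_data` tibble (rows need not be restricted to events).
#' @param eps_clip Weight-stabilizing clip for \eqn{\hat\rho}.
#' @param coef Optional coefficient override (used by proper multiple
#'   imputation, which draws event-type parameters from their asymptotic
#'   normal).
#' @return `predict_rho()`: numeric vector. `predict_pi()`: matrix.
#' @export
predict_rho <- function(fit, data, eps_clip = 1e-3) {
  stopifnot(inherits(fit, "rho_fit"))
  if (fit$no_missingness) return(rep(1, nrow(data)))
  X <- nuisance_design(fit$formula, data)
  p <- unname(stats::plogis(drop(X %*% fit$coef)))
  n_clip <- sum(p < eps_clip | p > 1 - eps_clip)
  if (n_clip > 0) {
    message(sprintf("clipping %d fitted response probabilities to [%g, %g]",
                    n_clip, eps_clip, 1 - eps_clip))
  }
  pmin(pmax(p, eps_clip), 1 - eps_clip)
}

#' @rdname predict_rho
#' @export
predict_pi <- function(fit, data, coef = NULL, eps_clip = 1e-6) {
  stopifnot(inherits(fit, "pi_fit"))
  X <- nuisance_design(fit$formula, data)
  if (fit$k == 2L) {
    cf <- if (is.null(coef)) fit$coef else coef
    p1 <- unname(stats::plogis(drop(X %*% cf)))
    p1 <- pmin(pmax(p1, eps_clip), 1 - eps_clip)
    out <- cbind(p1, 1 - p1)
  } else {
    if (!is.null(coef)) stop("coefficient override is only supported for k = 2")
    out <- stats::predict(fit$fit,
                          newdata = as.data.frame(X[, -1, drop = FALSE]),
                          type = "probs")
    out <- pmin(pmax(out, eps_clip), 1)
    out <- out / rowSums(out)
  }
  dimnames(out) <- list(NULL, paste0("cause", seq_len(fit$k)))
  out
}
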