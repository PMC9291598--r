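#' Gompertz baseline transform
#'
#' The improper-Gompertz baseline used by the synthetic-data generator:
#' \eqn{\exp\{\phi(t)\} = -(\tau/\rho)\{1 - \exp(\rho t)\}} with
#' \eqn{\tau > 0, \rho < 0}, so that \eqn{\phi} is nondecreasing,
#' \eqn{\phi(0) = -\infty} (the CIF starts at 0) and
#' \eqn{\exp\{\phi(\infty)\} = -\tau/\rho} (the subdistribution plateau on
#' the odds scale).
#'
#' @param t Times (\eqn{\ge 0}).
#' @param tau Positive scale \eqn{\tau}.
#' @param rho Negative shape \eqn{\rho}.
#' @return \eqn{\phi(t)} values.
#' @export
gompertz_phi <- function(t, tau, rho) {
  stopifnot(tau > 0, rho < 0)
  log(tau) - log(-rho) + log(-expm1(rho * t))
}

#' Simulation scenario for the synthetic-data generator
#'
#' Encodes the full generative design emulated by [simulate_crdata()]:
#' two competing causes with proportional-odds CIFs
#' \eqn{F_j(t; z) = \mathrm{expit}\{\phi_j(t) + \beta_j^\top z\}} under
#' improper Gompertz baselines; a binary covariate `z1` (Bernoulli
#' `p_z1`) and optionally a standard-normal `z2`; an auxiliary variable
#' \eqn{A = I(\epsilon = 1) + N(0,1)}; a visit process with exponential
#' gaps (`visit_rate`) or a fixed grid (`visit_grid`), administratively
#' ended at `c_admin`; and a logistic missing-at-random response model
#' \eqn{\mathrm{logit}\Pr(R = 1 | O) = \xi_0 + \xi_u U + \xi_{z1} Z_1 +
#' \xi_{z2} Z_2 + \xi_4 A} applied to events only (right-censoring is
#' always observed).
#'
#' Defaults are the study conditions of the Monte Carlo design this
#' package reproduces: \eqn{(\tau_1,\rho_1)=(0.40,-0.60)},
#' \eqn{(\tau_2,\rho_2)=(0.75,-0.50)},
#' \eqn{\beta = (0.5, -0.3, -0.5, 0.3)}, visit rate 3/year (one visit
#' every four months on average), 3-year administrative end (13.6%
#' right censoring), and \eqn{(\xi_0,\xi_4)=(0.60, 0)} giving a 30%
#' missingness rate among events.
#'
#' Under these parameters the cause-1 and cause-2 subdistribution plateaus
#' are exactly complementary, \eqn{F_1(\infty;z)+F_2(\infty;z)=1} for every
#' z. For user-supplied parameters with total plateau mass below 1 the
#' remainder is treated as a cured (never-event) fraction, right-censored
#' at study end; total mass above 1 is a configuration error.
#'
#' @param tau,rho_g Per-cause Gompertz parameters (length 2; `rho_g` is the
#'   Gompertz shape, distinct from the missingness-model \eqn{\rho}).
#' @param beta True coefficient matrix, one row per cause (columns: `z1`
#'   and, if `z2 = TRUE`, `z2`).
#' @param p_z1 Bernoulli probability of `z1`.
#' @param z2 Include the standard-normal covariate `z2`?
#' @param visit_rate Exponential visit-gap rate (visits/year).
#' @param visit_grid Optional fixed visit-time grid replacing the
#'   exponential process.
#' @param c_admin Administrative study end (years).
#' @param xi0,xi_u,xi_z1,xi_z2,xi4 Missingness-model coefficients.
#' @return A list of class `sim_scenario`.
#' @export
sim_scenario <- function(tau = c(0.40, 0.75), rho_g = c(-0.60, -0.50),
                         beta = matrix(c(0.5, -0.3, -0.5, 0.3), 2,
                                       byrow = TRUE),
                         p_z1 = 0.4, z2 = TRUE,
                         visit_rate = 3, visit_grid = NULL, c_admin = 3,
                         xi0 = 0.60, xi_u = 0.5, xi_z1 = -0.5, xi_z2 = 0.6,
                         xi4 = 0) {
  stopifnot(length(tau) == 2, length(rho_g) == 2, all(tau > 0),
            all(rho_g < 0), c_admin > 0,
            is.null(visit_grid) || all(visit_grid > 0))
  if (is.null(visit_grid)) stopifnot(visit_rate > 0)
  beta <- matrix(beta, nrow = 2)
  d_expected <- 1L + as.integer(z2)
  if (ncol(beta) != d_expected) {
    stop(sprintf("`beta` must have %d column(s) for this covariate set",
                 d_expected), call. = FALSE)
  }
  structure(
    list(tau = tau, rho_g = rho_g, beta = beta, p_z1 = p_z1, z2 = z2,
         visit_rate = visit_rate, visit_grid = visit_grid, c_admin = c_admin,
         xi0 = xi0, xi_u = xi_u, xi_z1 = xi_z1, xi_z2 = xi_z2, xi4 = xi4),
    class = "sim_scenario"
  )
}

# analytic CIF of the generator: F_j(t; z) = expit(phi_j(t) + beta_j' z)
scenario_cif <- function(t, z, cause, scenario) {
  bz <- sum(scenario$beta[cause, ] * z)
  stats::plogis(gompertz_phi(t, scenario$tau[cause], scenario$rho_g[cause]) + bz)
}

scenario_plateau <- function(z, cause, scenario) {
  bz <- sum(scenario$beta[cause, ] * z)
  stats::plogis(log(scenario$tau[cause] / -scenario$rho_g[cause]) + bz)
}

#' Invert a Gompertz proportional-odds CIF
#'
#' Closed-form solution of \eqn{F_j(T; z) = q} for the generator's
#' subdistributions: \eqn{T = \rho^{-1}\log(1 + \rho c/\tau)} with
#' \eqn{c = \exp\{\mathrm{logit}(q) - \beta^\top z\}}. Valid for
#' \eqn{0 < q < F_j(\infty; z)}, the plateau of the (improper)
#' subdistribution.
#'
#' @param q Target CIF value.
#' @param z Covariate vector.
#' @param cause Cause index (1 or 2).
#' @param scenario A [sim_scenario()].
#' @return The time \eqn{T} with \eqn{F_j(T; z) = q}.
#' @export
invert_cif_gompertz <- function(q, z, cause, scenario) {
  plateau <- scenario_plateau(z, cause, scenario)
  if (any(q <= 0 | q >= plateau)) {
    stop("`q` must lie in (0, F_j(Inf; z)): the subdistribution never ",
         "reaches that mass", call. = FALSE)
  }
  bz <- sum(scenario$beta[cause, ] * z)
  cc <- exp(stats::qlogis(q) - bz)
  log1p(scenario$rho_g[cause] * cc / scenario$tau[cause]) / scenario$rho_g[cause]
}

# number of uniforms consumed per subject (fixed layout: extending n leaves
# earlier subjects' draws unchanged)
SIM_NGAPS <- 40L
SIM_DRAWS <- 6L + SIM_NGAPS

#' Simulate an interval-censored competing-risks dataset
#'
#' Draws `n` independent subjects under a [sim_scenario()]: covariates,
#' latent event type and time (by closed-form inversion of the conditional
#' subdistribution at a uniform quantile), the auxiliary variable, the
#' visit process truncated at the administrative end, censoring-class
#' classification (event before the first visit: left-censored; between
#' visits: interval-censored; undetected by the last visit, or no visits
#' at all: right-censored), and the missing-at-random blanking of event
#' types.
#'
#' Randomness is consumed from a fixed per-subject block of uniforms, so a
#' given `seed` yields a bit-identical dataset and extending `n` preserves
#' the earlier subjects.
#'
#' @param n Number of subjects.
#' @param scenario A [sim_scenario()].
#' @param seed Integer seed.
#' @param keep_latent Keep the latent `t_true` and `eps_true` columns
#'   (useful for generator diagnostics)?
#' @return An `ic_data` tibble (validates cleanly); the scenario is
#'   attached as attribute `scenario`.
#' @examples
#' dat <- simulate_crdata(500, sim_scenario(), seed = 7)
#' table(delta = dat$delta, missing = is.na(dat$cause))
#' @export
simulate_crdata <- function(n, scenario = sim_scenario(), seed = NULL,
                            keep_latent = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  U <- matrix(stats::runif(n * SIM_DRAWS), nrow = n, byrow = TRUE)

  z1 <- as.numeric(U[, 1] < scenario$p_z1)
  z2 <- if (scenario$z2) stats::qnorm(U[, 2]) else NULL
  Z <- if (scenario$z2) cbind(z1, z2) else cbind(z1)

  p1 <- stats::plogis(log(scenario$tau[1] / -scenario$rho_g[1]) +
                        drop(Z %*% scenario$beta[1, ]))
  p2 <- stats::plogis(log(scenario$tau[2] / -scenario$rho_g[2]) +
                        drop(Z %*% scenario$beta[2, ]))
  if (any(p1 + p2 > 1 + 1e-8)) {
    stop("scenario is inconsistent: subdistribution plateaus exceed total ",
         "mass 1 for some covariate values", call. = FALSE)
  }
  eps <- ifelse(U[, 4] < p1, 1L, ifelse(U[, 4] < p1 + p2, 2L, 0L))

  # latent event time: conditional-quantile inversion, cause by cause
  t_true <- rep(Inf, n)
  for (j in 1:2) {
    sel <- eps == j
    if (!any(sel)) next
    pj <- if (j == 1) p1[sel] else p2[sel]
    bz <- drop(Z[sel, , drop = FALSE] %*% scenario$beta[j, ])
    cc <- exp(stats::qlogis(U[sel, 5] * pj) - bz)
    t_true[sel] <- log1p(scenario$rho_g[j] * cc / scenario$tau[j]) /
      scenario$rho_g[j]
  }

  a_aux <- as.numeric(eps == 1L) + stats::qnorm(U[, 3])

  # visit process
  if (is.null(scenario$visit_grid)) {
    gaps <- matrix(stats::qexp(U[, 7:(6 + SIM_NGAPS)], rate = scenario$visit_rate),
                   nrow = n)
    tri <- upper.tri(diag(SIM_NGAPS), diag = TRUE)
    visits <- gaps %*% (tri * 1)  # row-wise cumulative sums
  } else {
    visits <- matrix(rep(scenario$visit_grid, each = n), nrow = n)
  }
  inwin <- visits <= scenario$c_admin
  if (is.null(scenario$visit_grid) && any(rowSums(inwin) == ncol(visits))) {
    # with 40 exponential gaps this has probability ~ pgamma(c_admin, 40, rate),
    # i.e. ~1e-15 under the defaults
    stop("visit-gap budget exhausted (administrative end far beyond the ",
         "visit process); increase the visit rate or shorten c_admin",
         call. = FALSE)
  }
  nvisit <- rowSums(inwin)
  masked <- ifelse(inwin, visits, -Inf)
  n_before <- rowSums(inwin & visits < t_true)  # visits strictly before T

  right <- n_before == nvisit            # undetected (incl. no visits, cures)
  v <- numeric(n); u <- numeric(n)
  v[right] <- ifelse(nvisit[right] > 0,
                     do.call(pmax, as.data.frame(masked))[right], 0)
  u[right] <- Inf
  det <- !right
  u[det] <- visits[cbind(which(det), n_before[det] + 1L)]
  v[det] <- ifelse(n_before[det] > 0,
                   visits[cbind(which(det), pmax(n_before[det], 1L))], 0)

  delta <- as.integer(det)
  lp <- scenario$xi0 + scenario$xi_u * u + scenario$xi_z1 * z1 +
    (if (scenario$z2) scenario$xi_z2 * z2 else 0) + scenario$xi4 * a_aux
  r <- ifelse(delta == 1L, as.integer(U[, 6] < stats::plogis(lp)), 1L)

  cause <- ifelse(delta == 0L, 0L, ifelse(r == 1L, eps, NA_integer_))

  df <- tibble::tibble(id = seq_len(n), v = v, u = u, cause = cause, z1 = z1)
  if (scenario$z2) df$z2 <- z2
  df$a <- a_aux
  if (keep_latent) {
    df$t_true <- t_true
    df$eps_true <- eps
    df$n_visits <- nvisit
  }
  out <- as_ic_data(df, z = if (scenario$z2) c("z1", "z2") else "z1",
                    a = "a", k = 2L)
  if (keep_latent) {
    out$t_true <- df$t_true
    out$eps_true <- df$eps_true
    out$n_visits <- df$n_visits
  }
  attr(out, "scenario") <- scenario
  out
}

#' Calibrate the missingness intercept to a target rate
#'
#' Solves for the intercept \eqn{\xi_0} of the logistic response model so
#' that the expected missingness rate among events equals `target`,
#' holding the slope coefficients fixed. The expectation is taken over a
#' large calibration sample from the scenario (the fixed parts of the
#' linear predictor do not depend on \eqn{\xi_0}, so the root is exact for
#' that sample).
#'
#' @param scenario A [sim_scenario()].
#' @param target Target missingness proportion among events (e.g. 0.5).
#' @param n_cal Calibration sample size.
#' @param seed Seed for the calibration sample.
#' @return The scenario with `xi0` replaced by the calibrated value.
#' @export
calibrate_missingness <- function(scenario, target, n_cal = 2e4, seed = 1L) {
  stopifnot(target > 0, target < 1)
  dat <- simulate_crdata(n_cal, scenario, seed = seed)
  ev <- dat[dat$delta == 1L, , drop = FALSE]
  fixed <- scenario$xi_u * ev$u + scenario$xi_z1 * ev$z1 +
    (if (scenario$z2) scenario$xi_z2 * ev$z2 else 0) + scenario$xi4 * ev$a
  f <- function(x0) mean(stats::plogis(x0 + fixed)) - (1 - target)
  scenario$xi0 <- stats::uniroot(f, c(-20, 20), tol = 1e-10)$root
  scenario
}
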