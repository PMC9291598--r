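toy_theta <- function(g1, g2) {
  # two-level step baselines on [0, 1] (see helper), beta = 0, logit links
  list(spec = step_spec(), gamma = list(g1, g2),
       beta = matrix(0, 2, 1), alpha = c(1, 1))
}

test_that("complete-data log-likelihood matches hand-computed toy values", {
  # right-censored record with F1(V) = 0.2, F2(V) = 0.3 -> log 0.5
  th <- toy_theta(c(qlogis(0.2), qlogis(0.5)), c(qlogis(0.3), qlogis(0.4)))
  d_rc <- make_ic(v = 0.25, u = Inf, cause = 0)
  expect_equal(complete_loglik(th, d_rc), log(0.5), tolerance = 1e-12)

  # interval-censored cause-1 record, F1(U) = 0.5, F1(V) = 0.2 -> log 0.3
  d_ic <- make_ic(v = 0.25, u = 0.75, cause = 1)
  expect_equal(complete_loglik(th, d_ic), log(0.3), tolerance = 1e-12)

  # left-censored cause-2 record with F2(U) = 0.25 -> log 0.25
  th2 <- toy_theta(c(qlogis(0.1), qlogis(0.5)), c(qlogis(0.1), qlogis(0.25)))
  d_lc <- make_ic(v = 0, u = 0.75, cause = 2)
  expect_equal(complete_loglik(th2, d_lc), log(0.25), tolerance = 1e-12)

  expect_error(complete_loglik(th, make_ic(v = 0.25, u = 0.75, cause = 1,
                                           r_missing = 1)),
               "fully observed")
})

test_that("tilde weights follow the AIPW formula and conserve mass", {
  # rho = 1 reduces the weights to the observed indicators
  w <- tilde_weights(cause = 1, delta1 = 1, delta2 = 0, r = 1,
                     rho = 1 - 1e-12, pi = c(0.3, 0.7))
  expect_equal(w, cbind(`1` = c(1, 0), `2` = c(0, 0)), tolerance = 1e-9)

  # unobserved type: the event-type probabilities, on the observed class
  w0 <- tilde_weights(cause = NA, delta1 = 1, delta2 = 0, r = 0,
                      rho = 0.6, pi = c(0.3, 0.7))
  expect_equal(w0[, 1], c(0.3, 0.7))
  expect_equal(w0[, 2], c(0, 0))

  # observed type with rho = 0.5: plug-in arithmetic
  w1 <- tilde_weights(cause = 1, delta1 = 1, delta2 = 0, r = 1,
                      rho = 0.5, pi = c(0.3, 0.7))
  expect_equal(w1[, 1], c(1.7, -0.7), tolerance = 1e-12)

  # mass conservation across random configurations, to 1e-12
  set.seed(8)
  for (i in 1:200) {
    k <- sample(2:4, 1)
    pi <- as.vector(stats::rgamma(k, 1)); pi <- pi / sum(pi)
    r <- rbinom(1, 1, 0.5)
    d1 <- rbinom(1, 1, 0.5)
    w <- tilde_weights(cause = if (r == 1) sample(k, 1) else NA,
                       delta1 = d1, delta2 = 1 - d1, r = r,
                       rho = runif(1, 0.05, 0.95), pi = pi)
    expect_equal(sum(w), 1, tolerance = 1e-12)
  }

  expect_error(tilde_weights(cause = 0, delta1 = 0, delta2 = 0, r = 1,
                             rho = 0.5, pi = c(0.5, 0.5)), "event records")
})

test_that("AIPW objective reduces to the complete-data likelihood and matches a hand sum", {
  th <- toy_theta(c(qlogis(0.2), qlogis(0.5)), c(qlogis(0.1), qlogis(0.3)))
  # one record of each censoring class, all observed
  d <- make_ic(v = c(0.25, 0, 0.25), u = c(0.75, 0.75, Inf),
               cause = c(1, 2, 0))
  rho1 <- rep(1 - 1e-13, 3)
  pihat <- matrix(c(0.4, 0.6), 3, 2, byrow = TRUE)
  expect_equal(aipw_objective(th, d, rho1, pihat), complete_loglik(th, d),
               tolerance = 1e-12)

  # unobserved interval-censored record: pi-weighted mixture of cause terms
  dm <- make_ic(v = 0.25, u = 0.75, cause = 1, r_missing = 1)
  got <- aipw_objective(dm, theta = th, rho = 0.6,
                        pi = matrix(c(0.3, 0.7), 1))
  want <- 0.3 * log(0.5 - 0.2) + 0.7 * log(0.3 - 0.1)
  expect_equal(got, want, tolerance = 1e-12)

  # three-record mixed dataset against a spreadsheet-style oracle
  d3 <- make_ic(v = c(0.25, 0, 0.25), u = c(0.75, 0.75, Inf),
                cause = c(1, 2, 0), r_missing = 1)
  rho3 <- c(0.8, 0.9, 1)
  pi3 <- matrix(c(0.25, 0.75, 0.4, 0.6, 0.5, 0.5), 3, 2, byrow = TRUE)
  # record 1 (interval, R = 0): weights = pi, log of the interval masses
  o1 <- 0.25 * log(0.5 - 0.2) + 0.75 * log(0.3 - 0.1)
  # record 2 (left, R = 1, cause 2): (1/.9) on cause 2, -(0.1/0.9) pi,
  # log of F_j(U) with U past the step knot
  w2 <- c(0 - (0.1 / 0.9) * 0.4, 1 / 0.9 - (0.1 / 0.9) * 0.6)
  o2 <- w2[1] * log(0.5) + w2[2] * log(0.3)
  # record 3 (right-censored): log(1 - F1(V) - F2(V))
  o3 <- log(1 - 0.2 - 0.1)
  expect_equal(aipw_objective(th, d3, rho3, pi3), (o1 + o2 + o3) / 3,
               tolerance = 1e-12)
})

test_that("feasibility margin is 1 minus the worst observed-row CIF total", {
  th <- toy_theta(c(qlogis(0.2), qlogis(0.5)), c(qlogis(0.1), qlogis(0.4)))
  d <- make_ic(v = c(0.25, 0.3), u = c(0.75, 0.8), cause = c(1, 2))
  expect_equal(feasibility_constraint(th, d), 1 - 0.9, tolerance = 1e-12)

  # infeasible parameter point: negative margin
  th_bad <- toy_theta(c(qlogis(0.2), qlogis(0.7)), c(qlogis(0.1), qlogis(0.4)))
  expect_lt(feasibility_constraint(th_bad, d), 0)
})

test_that("analytic gradient agrees with finite differences at random feasible points", {
  dat <- simulate_crdata(120, sim_scenario(), seed = 3)
  spec <- sieve_spec(c(dat$v[dat$v > 0], dat$u[is.finite(dat$u)]),
                     n = nrow(dat))
  frame <- aipwcif:::make_frame(dat, spec, c(1, 1))
  ev <- dat$delta == 1L
  ind <- matrix(0, nrow(dat), 2)
  ind[cbind(which(ev), dat$cause[ev])] <- 1
  eng <- aipwcif:::make_engine(frame, ind[dat$delta1 == 1, ],
                               ind[dat$delta2 == 1, ], 1e-6)
  set.seed(5)
  npts <- 0
  for (r in 1:20) {
    x <- aipwcif:::default_init(spec$df, 2, 2, c(1, 1), 1e-6) +
      rnorm(2 * (spec$df + 2), sd = 0.2)
    if (!is.finite(eng$objective(x, 1e-4))) next
    npts <- npts + 1
    g <- eng$gradient(x, 1e-4)
    gn <- vapply(seq_along(x), function(i) {
      h <- 1e-6 * max(1, abs(x[i]))
      xp <- x; xp[i] <- x[i] + h
      xm <- x; xm[i] <- x[i] - h
      (eng$objective(xp, 1e-4) - eng$objective(xm, 1e-4)) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(g - gn)), 1e-4)
    if (npts >= 10) break
  }
  expect_gte(npts, 10)
})

test_that("with no missingness the AIPW fit equals the complete-data sieve MLE", {
  dat <- simulate_crdata(150, sim_scenario(xi0 = 50), seed = 21)  # all observed
  expect_true(all(dat$r == 1))
  f_complete <- fit_sieve(dat, seed = 1)
  # force the AIPW optimizer route with rho = 1 and an arbitrary pi model
  f_aipw <- fit_aipw(dat, nuisance = list(rho = rep(1 - 1e-12, nrow(dat)),
                                          pi = rep(0.5, 2 * nrow(dat))),
                     seed = 1)
  expect_lt(max(abs(f_aipw$beta - f_complete$beta)), 1e-6)
  # and the short-circuit route reports the same coefficients
  f_short <- suppressMessages(fit_aipw(dat, seed = 1))
  expect_lt(max(abs(f_short$beta - f_complete$beta)), 1e-8)
})

test_that("fitted CIFs are monotone and jointly feasible", {
  dat <- simulate_crdata(150, sim_scenario(), seed = 33)
  fit <- fit_aipw(dat, seed = 33)
  expect_true(fit$converged)
  pc <- predict_cif(fit, z = c(1, 0.5))
  for (j in 1:2) {
    expect_true(all(diff(pc$cif[pc$cause == j]) >= -1e-10))
  }
  th <- list(spec = fit$spec, gamma = fit$gamma, beta = fit$beta,
             alpha = fit$alpha)
  expect_gt(feasibility_constraint(th, dat), 0)
  expect_true(all(diff(fit$gamma[[1]]) > 0))
  expect_true(all(diff(fit$gamma[[2]]) > 0))
  expect_error(predict_cif(fit, times = fit$spec$b + 1), "domain")
})

test_that("bootstrap machinery respects its contracts", {
  dat <- simulate_crdata(120, sim_scenario(), seed = 55)
  fit <- fit_aipw(dat, seed = 55)
  expect_null(fit$se_beta)           # nboot = 0: no SEs
  expect_equal(fit$n_bootstrap_used, 0L)

  # stratified resampling preserves stratum sizes by construction
  set.seed(1)
  for (i in 1:20) {
    idx <- aipwcif:::boot_indices(dat, stratified = TRUE)
    expect_equal(sum(dat$delta[idx] == 1 & dat$r[idx] == 1),
                 sum(dat$delta == 1 & dat$r == 1))
    expect_equal(sum(dat$delta[idx] == 1 & dat$r[idx] == 0),
                 sum(dat$delta == 1 & dat$r == 0))
    expect_equal(sum(dat$delta[idx] == 0), sum(dat$delta == 0))
  }

  fit_b <- bootstrap_variance(fit, dat, nboot = 8, seed = 2)
  expect_equal(dim(fit_b$se_beta), dim(fit$beta))
  expect_true(all(fit_b$se_beta > 0))
  expect_equal(fit_b$n_bootstrap_used, 8L)
  expect_true(all(fit_b$ci_lower < fit_b$ci_upper))
})

test_that("degenerate event-type data is rejected", {
  dat <- simulate_crdata(100, sim_scenario(), seed = 4)
  dat$cause[dat$delta == 1L & dat$r == 1L] <- 1L  # single observed cause
  expect_error(fit_aipw(dat), "distinct observed")
})
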