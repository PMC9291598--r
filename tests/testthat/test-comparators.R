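test_that("complete-case analysis drops exactly the missing-type events", {
  dat <- simulate_crdata(150, sim_scenario(xi0 = 50), seed = 12)  # no missing
  f_cc <- fit_cc(dat, seed = 1)
  f_full <- fit_sieve(dat, seed = 1)
  expect_equal(f_cc$beta, f_full$beta, tolerance = 1e-10)

  dat2 <- simulate_crdata(300, sim_scenario(), seed = 12)
  f_cc2 <- fit_cc(dat2, seed = 1)
  expect_equal(f_cc2$n_missing, sum(dat2$r == 0))
  # the same fit on the manually reduced data
  f_red <- fit_sieve(aipwcif:::ic_subset(dat2, which(dat2$r == 1)), seed = 1)
  expect_equal(f_cc2$beta, f_red$beta, tolerance = 1e-10)
})

test_that("selective missingness of one cause shifts the CC estimate", {
  # blank only cause-1 events: CC then underrepresents cause 1
  dat <- simulate_crdata(400, sim_scenario(xi0 = 50), seed = 42)
  miss <- which(dat$delta == 1L & dat$cause == 1L)[1:40]
  dat$cause[miss] <- NA
  dat$r[miss] <- 0L
  f_cc <- fit_cc(dat, seed = 2)
  f_aipw <- fit_aipw(dat, seed = 2)
  # direction check: estimates differ materially between the two strategies
  expect_gt(max(abs(f_cc$beta - f_aipw$beta)), 0.01)
})

test_that("Rubin pooling matches hand computation and the textbook oracle", {
  p <- rubin_pool(list(0.4, 0.6), list(0.01, 0.01))
  expect_equal(p$beta_bar, 0.5)
  expect_equal(p$between, 0.02)
  expect_equal(p$total, 0.01 + 1.5 * 0.02)
  expect_equal(p$se, sqrt(0.04))

  # identical imputations: B = 0, T = W
  p2 <- rubin_pool(list(c(1, 2), c(1, 2), c(1, 2)), list(c(4, 1), c(4, 1), c(4, 1)))
  expect_equal(p2$between, c(0, 0))
  expect_equal(p2$total, c(4, 1))
  expect_equal(p2$se, c(2, 1))

  set.seed(99)
  for (i in 1:100) {
    m <- sample(2:8, 1)
    p <- sample(1:4, 1)
    est <- replicate(m, rnorm(p), simplify = FALSE)
    vars <- replicate(m, rgamma(p, 2), simplify = FALSE)
    got <- rubin_pool(est, vars)
    want <- oracle_rubin(est, vars)
    expect_equal(got$beta_bar, want$qbar, tolerance = 1e-12)
    expect_equal(got$within, want$ubar, tolerance = 1e-12)
    expect_equal(got$between, want$b, tolerance = 1e-12)
    expect_equal(got$total, want$t, tolerance = 1e-12)
  }
  expect_error(rubin_pool(list(1, 2), list(1)), "equal length")

  # pooled point estimate is invariant to imputation order
  est <- list(c(0.1, 0.4), c(0.3, 0.2), c(0.2, 0.5))
  vars <- list(c(1, 1), c(2, 2), c(3, 3))
  perm <- c(3, 1, 2)
  expect_equal(rubin_pool(est, vars)$beta_bar,
               rubin_pool(est[perm], vars[perm])$beta_bar)
  expect_equal(rubin_pool(est, vars)$total,
               rubin_pool(est[perm], vars[perm])$total)
})

test_that("imputation draws types from the fitted event-type distribution", {
  # fixed pi1 = 0.3 with no parameter uncertainty: binomial sampling oracle
  n <- 1e4
  dat <- make_ic(v = rep(0.3, n), u = rep(0.8, n), cause = rep(c(1, 2), n / 2),
                 r_missing = seq_len(n))
  # a fit_pi-shaped object with intercept logit(0.3) and zero covariance
  pf <- structure(list(coef = qlogis(0.3), vcov = matrix(0, 1, 1),
                       formula = ~1, k = 2L), class = "pi_fit")
  imp <- impute_types(dat, pf, proper = TRUE, seed = 123)
  expect_true(all(imp$r == 1))
  frac1 <- mean(imp$cause == 1)
  expect_lt(abs(frac1 - 0.3), 3 * sqrt(0.3 * 0.7 / n))

  # nothing to impute: dataset unchanged
  clean <- make_ic(v = c(0.3, 0.4), u = c(0.8, 0.9), cause = c(1, 2))
  expect_identical(impute_types(clean, pf, seed = 1), clean)
})

test_that("multiple imputation pools m complete-data fits", {
  dat <- simulate_crdata(200, sim_scenario(), seed = 31)
  fit <- fit_mi(dat, m = 3, seed = 31)
  expect_s3_class(fit, "mi_fit")
  expect_equal(fit$m, 3L)
  expect_null(fit$se_beta)  # point estimation only without within-bootstrap
  expect_equal(dim(fit$beta), c(2L, 2L))
  expect_true(all(is.finite(fit$beta)))

  # no missingness: reduces to a single complete-data fit
  datc <- simulate_crdata(150, sim_scenario(xi0 = 50), seed = 31)
  fitc <- fit_mi(datc, m = 5, seed = 1)
  expect_equal(fitc$m, 1L)
  expect_equal(fitc$beta, fit_sieve(datc, seed = 1)$beta, tolerance = 1e-10)
})
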