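test_that("Gompertz baseline transform matches its closed form", {
  # F(0) = 0
  expect_equal(exp(gompertz_phi(0, 0.40, -0.60)), 0)
  # plateau: exp(phi) -> tau/(-rho) = 2/3
  expect_equal(exp(gompertz_phi(1e9, 0.40, -0.60)), 2 / 3, tolerance = 1e-12)
  # finite-time value against independent arithmetic
  expect_equal(exp(gompertz_phi(3, 0.40, -0.60)),
               (0.40 / 0.60) * (1 - exp(-1.8)), tolerance = 1e-12)
  tt <- seq(0, 10, by = 0.1)
  expect_true(all(diff(gompertz_phi(tt, 0.75, -0.50)) > 0))
})

test_that("closed-form CIF inversion agrees with forward evaluation", {
  sc <- sim_scenario()
  T1 <- invert_cif_gompertz(0.2, z = c(0, 0), cause = 1, sc)
  expect_equal(T1, 0.78334, tolerance = 1e-4)
  # forward-evaluation oracle: F_1(T; 0) = 0.2
  f_fwd <- plogis(gompertz_phi(T1, sc$tau[1], sc$rho_g[1]))
  expect_equal(f_fwd, 0.2, tolerance = 1e-10)

  set.seed(2)
  for (i in 1:50) {
    z <- c(rbinom(1, 1, 0.5), rnorm(1))
    j <- sample(1:2, 1)
    plateau <- plogis(log(sc$tau[j] / -sc$rho_g[j]) + sum(sc$beta[j, ] * z))
    q <- runif(1, 1e-4, plateau - 1e-6)
    tq <- invert_cif_gompertz(q, z, j, sc)
    f <- plogis(gompertz_phi(tq, sc$tau[j], sc$rho_g[j]) + sum(sc$beta[j, ] * z))
    expect_equal(f, q, tolerance = 1e-10)
  }
  # small quantiles give small times; masses at the plateau are unreachable
  expect_lt(invert_cif_gompertz(1e-8, c(0, 0), 1, sc), 1e-6)
  expect_error(invert_cif_gompertz(0.45, c(0, 0), 1, sc), "never")
})

test_that("subdistribution plateaus are complementary under the study design", {
  sc <- sim_scenario()
  set.seed(3)
  for (i in 1:1000) {
    z <- c(rbinom(1, 1, 0.4), rnorm(1))
    p1 <- plogis(log(sc$tau[1] / -sc$rho_g[1]) + sum(sc$beta[1, ] * z))
    p2 <- plogis(log(sc$tau[2] / -sc$rho_g[2]) + sum(sc$beta[2, ] * z))
    expect_equal(p1 + p2, 1, tolerance = 1e-12)
  }
})

test_that("inconsistent plateau masses are rejected; deficits become cures", {
  # total mass > 1 for some covariate value
  expect_error(
    simulate_crdata(50, sim_scenario(tau = c(0.9, 0.9), rho_g = c(-0.5, -0.5),
                                     beta = matrix(0, 2, 2)), seed = 1),
    "exceed"
  )
  # total mass < 1: remainder is a never-event fraction, right-censored
  sc_cure <- sim_scenario(tau = c(0.2, 0.2), rho_g = c(-0.5, -0.5),
                          beta = matrix(0, 2, 2))
  dat <- simulate_crdata(4000, sc_cure, seed = 1, keep_latent = TRUE)
  expect_true(all(dat$delta[dat$eps_true == 0] == 0))
  # cure fraction: 1 - p1 - p2 = 1 - 2*expit(log(0.4)) ~ 0.43
  expect_lt(abs(mean(dat$eps_true == 0) - (1 - 2 * plogis(log(0.4)))), 0.03)
})

test_that("censoring classification is consistent and validates cleanly", {
  dat <- simulate_crdata(5000, sim_scenario(), seed = 6, keep_latent = TRUE)
  expect_true(all(validate_ic_data(dat)$violations == 0))
  # latent time inside (V, U] for events; after the last visit otherwise
  ev <- dat$delta == 1L
  expect_true(all(dat$t_true[ev] > dat$v[ev] & dat$t_true[ev] <= dat$u[ev]))
  expect_true(all(dat$t_true[!ev] > dat$v[!ev]))
  # left-censored = detected at the first visit
  expect_true(all(dat$v[dat$delta2 == 1L] == 0))
})

test_that("generated data match the analytic CIFs (fixed covariate values)", {
  n <- 1e5
  for (z1val in c(0, 1)) {
    sc <- sim_scenario(z2 = FALSE, beta = matrix(c(0.5, -0.5), 2),
                       p_z1 = z1val)
    dat <- simulate_crdata(n, sc, seed = 10 + z1val, keep_latent = TRUE)
    for (tt in c(0.5, 1, 2)) {
      for (j in 1:2) {
        emp <- mean(dat$t_true <= tt & dat$eps_true == j)
        truth <- plogis(gompertz_phi(tt, sc$tau[j], sc$rho_g[j]) +
                          sc$beta[j, 1] * z1val)
        se <- sqrt(truth * (1 - truth) / n)
        expect_lt(abs(emp - truth), 3 * se)
      }
    }
  }
})

test_that("visit process has the intended intensity", {
  # exponential gaps at rate 3 over 3 years: mean visit count 9
  dat <- simulate_crdata(2e4, sim_scenario(), seed = 14, keep_latent = TRUE)
  expect_lt(abs(mean(dat$n_visits) - 9), 3 * 3 / sqrt(2e4))
})

test_that("generation is reproducible and extension-stable", {
  a <- simulate_crdata(100, sim_scenario(), seed = 99)
  b <- simulate_crdata(100, sim_scenario(), seed = 99)
  expect_identical(a, b)
  big <- simulate_crdata(200, sim_scenario(), seed = 99)
  expect_equal(as.data.frame(big[1:100, ]), as.data.frame(a),
               tolerance = 1e-15)
})

test_that("missingness intercept calibration hits the target rate", {
  sc50 <- calibrate_missingness(sim_scenario(), target = 0.5, n_cal = 2e4,
                                seed = 1)
  dat <- simulate_crdata(4e4, sc50, seed = 2)
  miss <- mean(dat$r[dat$delta == 1L] == 0)
  expect_lt(abs(miss - 0.5), 0.02)
})
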