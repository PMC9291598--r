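#' Percent bias of a set of estimates
#'
#' \eqn{100\,\{\bar{\hat\beta} - \beta_0\}/\beta_0}. Undefined for a zero
#' truth (use absolute bias there).
#'
#' @param estimates Numeric vector of replicate estimates.
#' @param truth Nonzero true value.
#' @return Scalar percent bias.
#' @export
percent_bias <- function(estimates, truth) {
  if (truth == 0) stop("percent bias is undefined for a zero truth; ",
                       "use absolute bias", call. = FALSE)
  100 * (mean(estimates) - truth) / truth
}

#' Empirical coverage probability
#'
#' Fraction of confidence intervals containing the truth.
#'
#' @param lower,upper Interval limits (equal-length vectors).
#' @param truth True value.
#' @return Proportion in \[0, 1\].
#' @export
ecp <- function(lower, upper, truth) {
  stopifnot(length(lower) == length(upper), length(lower) > 0)
  mean(lower <= truth & truth <= upper)
}

derive_seed <- function(master, i) {
  as.integer((as.numeric(master) %% 2147483629 * 1000003 + i * 7919) %%
               2147483629) + 1L
}

fit_one_method <- function(method, data, args) {
  switch(
    method,
    aipw = fit_aipw(data, rho_formula = args$rho_formula,
                    pi_formula = args$pi_formula, control = args$control,
                    nboot = args$nboot, stratified = args$stratified),
    cc = fit_cc(data, control = args$control, nboot = args$nboot,
                stratified = args$stratified),
    mi = fit_mi(data, m = args$mi_m, pi_formula = args$pi_formula,
                control = args$control, nboot_within = args$nboot_within),
    stop("unknown method: ", method)
  )
}

#' Run a Monte Carlo simulation study
#'
#' Replicates the full pipeline `reps` times: simulate a dataset of size
#' `n` from `scenario`, fit each requested method (complete-case `cc`,
#' multiple imputation `mi`, doubly robust `aipw`), and collect the
#' coefficient estimates (plus bootstrap SEs and 95% Wald intervals when
#' `nboot > 0`) and the fitted baseline CIFs on `cif_times`. Replicates
#' whose fit fails to converge are dropped per method and counted.
#'
#' Per-replicate seeds are derived from `seed` by a counter scheme, so
#' results are reproducible and independent of `workers`.
#'
#' @param scenario A [sim_scenario()].
#' @param n Sample size per replicate.
#' @param reps Number of Monte Carlo replicates.
#' @param methods Subset of `c("cc", "mi", "aipw")`.
#' @param nboot Bootstrap replications per fit for SEs and coverage
#'   (0 = point estimation only; ASE/ECP then unavailable).
#' @param nboot_within Within-imputation bootstrap size for MI SEs.
#' @param mi_m Number of imputations for MI.
#' @param stratified Stratified bootstrap resampling.
#' @param rho_formula,pi_formula Nuisance designs passed to [fit_aipw()] /
#'   [fit_mi()].
#' @param control An [aipw_control()].
#' @param cif_times Times at which fitted baseline CIFs are recorded
#'   (`NULL` to skip).
#' @param seed Master seed.
#' @param workers Parallel workers (forked; results identical for any
#'   worker count).
#' @return An object of class `sim_study`: list with `estimates` (long
#'   tibble: rep, method, term, cause, covariate, estimate, se, lower,
#'   upper), `cif` (rep, method, cause, time, cif), `truth`, `failures`,
#'   `scenario`, `n`, `reps`. Summarize with [generics::tidy()]
#'   (percent bias, MCSD, ASE, ECP per method and coefficient).
#' @export
run_sim_study <- function(scenario, n, reps, methods = c("cc", "mi", "aipw"),
                          nboot = 0L, nboot_within = nboot, mi_m = 5L,
                          stratified = FALSE, rho_formula = NULL,
                          pi_formula = NULL, control = aipw_control(),
                          cif_times = c(0.5, 1, 2), seed = 1L, workers = 1L) {
  stopifnot(reps >= 1)
  methods <- match.arg(methods, c("cc", "mi", "aipw"), several.ok = TRUE)
  args <- list(rho_formula = rho_formula, pi_formula = pi_formula,
               control = control, nboot = nboot, nboot_within = nboot_within,
               mi_m = mi_m, stratified = stratified)

  one_rep <- function(i) {
    s <- derive_seed(seed, i)
    dat <- simulate_crdata(n, scenario, seed = s)
    set.seed(s + 1L)
    est <- list(); cif <- list()
    for (m in methods) {
      fit <- tryCatch(suppressMessages(fit_one_method(m, dat, args)),
                      error = function(e) NULL)
      if (is.null(fit)) next
      k <- nrow(fit$beta); d <- ncol(fit$beta)
      est[[m]] <- tibble::tibble(
        rep = i, method = m,
        cause = rep(seq_len(k), times = d),
        covariate = rep(colnames(fit$beta), each = k),
        term = paste0("beta", rep(seq_len(k), times = d),
                      rep(seq_len(d), each = k)),
        estimate = as.vector(fit$beta),
        se = if (is.null(fit$se_beta)) NA_real_ else as.vector(fit$se_beta),
        lower = if (is.null(fit$ci_lower)) NA_real_ else as.vector(fit$ci_lower),
        upper = if (is.null(fit$ci_upper)) NA_real_ else as.vector(fit$ci_upper)
      )
      if (!is.null(cif_times) && !is.null(fit$gamma)) {
        tt <- cif_times[cif_times <= fit$spec$b & cif_times >= fit$spec$a]
        if (length(tt)) {
          pc <- predict_cif(fit, times = tt)
          cif[[m]] <- tibble::tibble(rep = i, method = m, cause = pc$cause,
                                     time = pc$time, cif = pc$cif)
        }
      }
    }
    list(est = dplyr::bind_rows(est), cif = dplyr::bind_rows(cif))
  }

  res <- if (workers > 1L) {
    parallel::mclapply(seq_len(reps), one_rep, mc.cores = workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(seq_len(reps), one_rep)
  }

  estimates <- dplyr::bind_rows(lapply(res, `[[`, "est"))
  cif <- dplyr::bind_rows(lapply(res, `[[`, "cif"))
  failures <- vapply(methods, function(m) {
    as.integer(reps - length(unique(estimates$rep[estimates$method == m])))
  }, integer(1))
  if (any(failures / reps > 0.05)) {
    warning("more than 5% of replicates failed for: ",
            paste(methods[failures / reps > 0.05], collapse = ", "),
            call. = FALSE)
  }

  truth <- scenario$beta
  dimnames(truth) <- list(paste0("cause", 1:2),
                          if (scenario$z2) c("z1", "z2") else "z1")
  structure(
    list(estimates = estimates, cif = cif, truth = truth, scenario = scenario,
         n = n, reps = reps, failures = failures, methods = methods,
         nboot = nboot, seed = seed),
    class = "sim_study"
  )
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("Monte Carlo study: %d replicates, n = %d, methods: %s\n",
              x$reps, x$n, paste(x$methods, collapse = ", ")))
  print(generics::tidy(x))
  invisible(x)
}

#' Summarize a simulation study
#'
#' One row per method and coefficient with the standard Monte Carlo
#' metrics: percent bias, Monte Carlo standard deviation of the estimates
#' (MCSD), average estimated standard error (ASE), and empirical coverage
#' probability of the nominal 95% intervals (ECP). ASE and ECP are `NA`
#' when the study was run without bootstrap SEs.
#'
#' @param x A `sim_study` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy sim_study
#' @export
tidy.sim_study <- function(x, ...) {
  truth_tbl <- tibble::tibble(
    cause = rep(1:2, times = ncol(x$truth)),
    covariate = rep(colnames(x$truth), each = 2),
    truth = as.vector(x$truth)
  )
  x$estimates |>
    dplyr::left_join(truth_tbl, by = c("cause", "covariate")) |>
    dplyr::group_by(.data$method, .data$term, .data$cause, .data$covariate) |>
    dplyr::summarise(
      truth = .data$truth[1],
      reps_used = dplyr::n(),
      percent_bias = percent_bias(.data$estimate, .data$truth[1]),
      mcsd = stats::sd(.data$estimate),
      ase = mean(.data$se),
      ecp = if (all(is.na(.data$lower))) NA_real_ else
        ecp(.data$lower, .data$upper, .data$truth[1]),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$method, .data$term)
}

#' Baseline-CIF overlay for a simulation study
#'
#' Plots the Monte Carlo mean of the fitted baseline CIFs against the
#' generator's true Gompertz baselines.
#'
#' @param object A `sim_study` run with `cif_times` set.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sim_study
#' @export
autoplot.sim_study <- function(object, ...) {
  stopifnot(nrow(object$cif) > 0)
  avg <- object$cif |>
    dplyr::group_by(.data$method, .data$cause, .data$time) |>
    dplyr::summarise(cif = mean(.data$cif), .groups = "drop") |>
    dplyr::mutate(curve = paste0("estimated (", .data$method, ")"))
  grid <- seq(0.01, object$scenario$c_admin, length.out = 100)
  truth <- purrr::map_dfr(1:2, function(j) {
    tibble::tibble(cause = j, time = grid,
                   cif = scenario_cif(grid, rep(0, ncol(object$truth)), j,
                                      object$scenario),
                   curve = "true")
  })
  ggplot2::ggplot(dplyr::bind_rows(avg, truth),
                  ggplot2::aes(.data$time, .data$cif,
                               colour = .data$curve,
                               linetype = .data$curve)) +
    ggplot2::geom_line(data = truth) +
    ggplot2::geom_point(data = avg) +
    ggplot2::facet_wrap(~cause, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time", y = "baseline cumulative incidence",
                  colour = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
}
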