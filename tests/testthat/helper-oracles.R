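# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Newton-Raphson binary-logistic MLE (hand-rolled IRLS oracle)
oracle_logistic <- function(X, y, iter = 50) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(iter)) {
    p <- 1 / (1 + exp(-drop(X %*% beta)))
    w <- p * (1 - p)
    step <- solve(crossprod(X, X * w), crossprod(X, y - p))
    beta <- beta + drop(step)
    if (max(abs(step)) < 1e-12) break
  }
  unname(beta)
}

# textbook Rubin's-rules pooling
oracle_rubin <- function(est, vars) {
  m <- length(est)
  emat <- do.call(rbind, lapply(est, as.numeric))
  qbar <- colMeans(emat)
  ubar <- colMeans(do.call(rbind, lapply(vars, as.numeric)))
  b <- apply(emat, 2, function(x) sum((x - mean(x))^2) / (m - 1))
  tt <- ubar + (1 + 1 / m) * b
  list(qbar = qbar, ubar = ubar, b = b, t = tt, se = sqrt(tt))
}

# tiny ic_data builder for hand-constructed records
make_ic <- function(v, u, cause, z1 = 0, r_missing = NULL, k = 2) {
  df <- tibble::tibble(v = v, u = u, cause = cause, z1 = z1)
  if (!is.null(r_missing)) df$cause[r_missing] <- NA
  as_ic_data(df, z = "z1", k = k)
}

# piecewise-constant two-level sieve on [0, 1] with a knot at 0.5:
# phi = gamma[1] on [0, 0.5), gamma[2] on [0.5, 1]
step_spec <- function() {
  structure(list(knots = c(0, 0.5, 1), order = 1L, a = 0, b = 1,
                 n_interior = 1L, df = 2L), class = "sieve_spec")
}
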