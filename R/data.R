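#' Construct an interval-censored competing-risks dataset
#'
#' Normalizes a per-subject data frame into the observed-data structure used
#' by all fitting functions: last visit before the event `v` (\eqn{V_i}; 0 if
#' left-censored), first visit after the event `u` (\eqn{U_i}; `Inf` if
#' right-censored), event type `cause` (1..k; 0 = right-censored; the missing
#' code when the type was not ascertained), covariates of interest `z` and
#' optional auxiliary covariates `a`. Censoring-class indicators
#' (`delta`, `delta1`, `delta2`) and the response indicator `r` are derived:
#'
#' * `u = Inf` or `cause = 0`: right-censored (`delta = 0`, `r = 1`);
#' * `v = 0` with finite `u` and an event: left-censored (`delta2 = 1`);
#' * otherwise interval-censored (`delta1 = 1`);
#' * `cause` equal to `missing_code`: `r = 0`, `cause` stored as `NA`.
#'
#' Validation errors name the offending rows. Right-censored records must
#' have an observed (non-missing) status: censoring is always observed.
#'
#' @param data A data frame with one row per subject.
#' @param v,u,cause Column names (strings) for the observation times and the
#'   event-type code.
#' @param z Character vector of covariate column names.
#' @param a Character vector of auxiliary covariate column names (may be
#'   empty).
#' @param id Optional subject-identifier column; created if absent.
#' @param k Number of event types (default: max observed cause code, at
#'   least 2).
#' @param missing_code Code marking a missing event type (default `NA`).
#' @return A tibble of class `ic_data` with columns
#'   `id, v, u, cause, delta, delta1, delta2, r`, the `z` columns and the
#'   `a` columns, and attributes `z_cols`, `a_cols`, `k`.
#' @examples
#' df <- tibble::tibble(v = c(0.3, 0, 2.5), u = c(0.7, 0.3, Inf),
#'                      cause = c(1, 2, 0), z1 = c(1, 0, 1))
#' as_ic_data(df, z = "z1")
#' @export
as_ic_data <- function(data, v = "v", u = "u", cause = "cause",
                       z = NULL, a = character(0), id = "id",
                       k = NULL, missing_code = NA) {
  stopifnot(is.data.frame(data))
  need <- c(v, u, cause, z, a)
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (is.null(z)) stop("`z` must name at least one covariate column", call. = FALSE)

  out <- tibble::tibble(
    id = if (id %in% names(data)) data[[id]] else seq_len(nrow(data)),
    v = as.numeric(data[[v]]),
    u = as.numeric(data[[u]]),
    cause = data[[cause]]
  )
  # missing-code handling: map to NA before coercion
  if (is.na(missing_code)) {
    out$cause[is.na(out$cause) | out$cause %in% ""] <- NA
  } else {
    out$cause[!is.na(out$cause) & out$cause == missing_code] <- NA
  }
  out$cause <- suppressWarnings(as.integer(out$cause))
  out$u[is.na(out$u)] <- Inf  # empty u field = right-censoring dialect

  bad <- which(out$v < 0 | (is.finite(out$u) & out$u < 0))
  if (length(bad)) {
    stop("negative observation times in rows: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }

  right <- !is.finite(out$u) | (!is.na(out$cause) & out$cause == 0L)
  bad <- which(right & is.na(out$cause) )
  if (length(bad)) {
    stop("right-censored rows with a missing event-type code (censoring is ",
         "always observed) in rows: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  out$u[right] <- Inf
  out$cause[right] <- 0L

  bad <- which(!right & out$v >= out$u)
  if (length(bad)) {
    stop("event rows with v >= u: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }

  out$delta <- as.integer(!right)
  out$delta2 <- as.integer(!right & out$v == 0)
  out$delta1 <- out$delta - out$delta2
  out$r <- as.integer(right | !is.na(out$cause))

  for (col in c(z, a)) out[[col]] <- as.numeric(data[[col]])

  if (is.null(k)) {
    obs <- out$cause[!is.na(out$cause)]
    k <- if (length(obs)) max(2L, max(obs)) else 2L
  }
  obs_causes <- out$cause[out$delta == 1L & out$r == 1L]
  if (any(obs_causes < 1L | obs_causes > k)) {
    stop("event-type codes outside 1..k", call. = FALSE)
  }

  structure(
    out[, c("id", "v", "u", "cause", "delta", "delta1", "delta2", "r", z, a)],
    z_cols = z, a_cols = a, k = as.integer(k),
    class = c("ic_data", class(tibble::tibble()))
  )
}

ic_z_cols <- function(data) attr(data, "z_cols", exact = TRUE)
ic_a_cols <- function(data) attr(data, "a_cols", exact = TRUE)
ic_k <- function(data) attr(data, "k", exact = TRUE)

# rebuild an ic_data after row subsetting/resampling (attributes survive,
# indicator columns are already present and still valid)
ic_subset <- function(data, idx) {
  out <- data[idx, , drop = FALSE]
  attr(out, "z_cols") <- ic_z_cols(data)
  attr(out, "a_cols") <- ic_a_cols(data)
  attr(out, "k") <- ic_k(data)
  class(out) <- class(data)
  out
}

#' Read / write interval-censored competing-risks data
#'
#' `read_ic_data()` reads a delimited text file (CSV by default) and passes
#' it through [as_ic_data()]. Right censoring may be encoded as `cause = 0`
#' with `u` empty or the literal `Inf`; both dialects are accepted.
#' `write_ic_data()` writes the reverse dialect (`Inf` spelled out, missing
#' causes as empty fields).
#'
#' @param path File path.
#' @param delim Field delimiter.
#' @inheritParams as_ic_data
#' @param ... Passed to [as_ic_data()].
#' @return `read_ic_data()`: an `ic_data` tibble. `write_ic_data()`: `path`,
#'   invisibly.
#' @export
read_ic_data <- function(path, delim = ",", ...) {
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  as_ic_data(raw, ...)
}

#' @rdname read_ic_data
#' @param data An `ic_data` tibble.
#' @export
write_ic_data <- function(data, path, delim = ",") {
  stopifnot(inherits(data, "ic_data"))
  out <- as.data.frame(data)
  out$u <- ifelse(is.finite(out$u), format(out$u, digits = 17), "Inf")
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(path)
}

#' Validate an interval-censored competing-risks dataset
#'
#' Checks every record-level invariant of the observed-data structure and
#' returns per-rule violation counts. A dataset must validate cleanly (zero
#' violations) before fitting.
#'
#' @param data An `ic_data` tibble.
#' @return A tibble with columns `rule`, `violations`, `rows` (list-column
#'   of offending row indices).
#' @export
validate_ic_data <- function(data) {
  stopifnot(inherits(data, "ic_data"))
  rules <- list(
    "delta = delta1 + delta2" = data$delta != data$delta1 + data$delta2,
    "delta2 = 1 => v = 0" = data$delta2 == 1L & data$v != 0,
    "delta = 0 => u = Inf" = data$delta == 0L & is.finite(data$u),
    "delta = 0 => r = 1" = data$delta == 0L & data$r != 1L,
    "delta = 1 => v < u < Inf" =
      data$delta == 1L & !(data$v < data$u & is.finite(data$u)),
    "r = 1 & delta = 1 => cause observed" =
      data$r == 1L & data$delta == 1L & is.na(data$cause),
    "r = 0 => cause missing" = data$r == 0L & !is.na(data$cause),
    "times nonnegative" = data$v < 0 | (is.finite(data$u) & data$u < 0)
  )
  tibble::tibble(
    rule = names(rules),
    violations = unname(vapply(rules, function(x) sum(x, na.rm = TRUE),
                               integer(1))),
    rows = unname(lapply(rules, function(x) which(x)))
  )
}
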