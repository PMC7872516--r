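#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

# Fail with a consistent message when required columns are missing.
.require_columns <- function(data, cols, where) {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0L) {
    stop(sprintf("%s: missing required column(s): %s", where,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

# Error if any value in the named columns is NA, naming the field and the
# first offending participant. Missing raw fields are contract violations,
# not something to impute.
.fail_on_missing <- function(data, cols, id_col = "participant_id") {
  for (col in cols) {
    bad <- which(is.na(data[[col]]))
    if (length(bad) > 0L) {
      id <- if (id_col %in% names(data)) data[[id_col]][bad[1L]] else bad[1L]
      stop(sprintf("field '%s' is missing for participant '%s' (and %d other row(s))",
                   col, id, length(bad) - 1L), call. = FALSE)
    }
  }
  invisible(TRUE)
}

# Derive independent per-stage substreams from one user-facing seed.
# Offsets keep every derived seed a valid 32-bit integer.
.substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  offsets <- c(
    covariates = 11L, lifestyle = 23L, metabolites = 37L, genotypes = 53L,
    outcome = 71L, sampling = 97L, duplicates = 113L, ldlc = 131L,
    truth = 149L, experiment = 211L
  )
  if (!stage %in% names(offsets)) stop("unknown seed stage: ", stage)
  (as.integer(seed) %% 1000000L) * 2011L + offsets[[stage]]
}

# Truncated-normal draws by inverse-CDF; vectorised over n.
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, pl, pu), mean, sd)
}

# Central finite-difference gradient; used as the numerical cross-check for
# the analytic delta-method gradients.
.numeric_gradient <- function(f, x, eps = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    h <- eps * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# Delta-method variance g' Sigma g for one estimand.
.delta_var <- function(grad, sigma) {
  as.numeric(t(grad) %*% sigma %*% grad)
}

.wald_ci <- function(estimate, se, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(low = estimate - z * se, high = estimate + z * se)
}
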