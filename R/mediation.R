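# Parametric causal mediation for a continuous mediator and a rare binary
# outcome in a nested case-control design: a linear model for the mediator
# (controls only) and a logistic model for the outcome (CHD cases +
# controls), optionally with an exposure-mediator product term. Natural
# effects use the standard rare-outcome (OR ~ RR) closed forms; the four-way
# decomposition is evaluated exactly under the rare-outcome risk model via
# Gaussian moment-generating-function integrals. Uncertainty comes from the
# delta method over the stacked parameter vector of the two fits, treated as
# independent (block-diagonal covariance), with the residual variance's own
# sampling variability included.

.default_mediation_covariates <- c("age", "sex", "fasting_ge_8h", "area",
                                   "education")

#' Fit the mediator model (controls only)
#'
#' Ordinary least squares of a transformed metabolite on the continuous HLF
#' count plus covariates, fit in control participants only. Presence of any
#' case rows is a contract violation and an error.
#'
#' @param data Control rows only (`status == "control"`).
#' @param mediator Transformed metabolite column name.
#' @param exposure Exposure column name (default `hlf_count`).
#' @param covariates Covariate column names.
#' @return Object of class `mediator_model`: coefficients, their covariance,
#'   the residual variance `sigma2` and its sampling variance, and the
#'   control-sample mean of each covariate design column (the default
#'   covariate reference vector for the mediation formulas).
#' @export
fit_mediator_model <- function(data, mediator, exposure = "hlf_count",
                               covariates = .default_mediation_covariates) {
  .require_columns(data, c(mediator, exposure, covariates, "status"),
                   "fit_mediator_model")
  if (any(data$status != "control")) {
    stop("fit_mediator_model: input must contain control participants only",
         call. = FALSE)
  }
  df <- data
  df$.exposure <- df[[exposure]]
  fit <- stats::lm(.build_formula(mediator, c(".exposure", covariates)),
                   data = df)
  .check_aliased(fit, "fit_mediator_model")
  X <- stats::model.matrix(fit)
  n <- nrow(X)
  p <- ncol(X)
  sigma2 <- sum(stats::residuals(fit)^2) / (n - p)
  cov_cols <- setdiff(colnames(X), c("(Intercept)", ".exposure"))
  structure(list(
    coef = stats::coef(fit),
    vcov = stats::vcov(fit),
    sigma2 = sigma2,
    var_sigma2 = 2 * sigma2^2 / (n - p),
    n = n,
    exposure = ".exposure",
    exposure_name = exposure,
    mediator_name = mediator,
    cov_cols = cov_cols,
    cov_reference = colMeans(X[, cov_cols, drop = FALSE]),
    fit = fit
  ), class = "mediator_model")
}

#' Fit the outcome model (CHD cases and controls)
#'
#' Maximum-likelihood logistic regression of CHD status on exposure, the
#' mediator, covariates, and optionally the exposure-by-mediator product
#' term. Stroke cases must be excluded before calling.
#'
#' @param data Rows with `status` in control / chd_case only.
#' @param mediator,exposure,covariates As in [fit_mediator_model()].
#' @param interaction Logical; include the exposure x mediator term.
#' @return Object of class `outcome_model` with coefficients, covariance,
#'   and the design column names of the exposure, mediator and (if present)
#'   interaction terms.
#' @export
fit_outcome_model <- function(data, mediator, exposure = "hlf_count",
                              covariates = .default_mediation_covariates,
                              interaction = FALSE) {
  .require_columns(data, c(mediator, exposure, covariates, "status"),
                   "fit_outcome_model")
  extra <- setdiff(unique(data$status), c("control", "chd_case"))
  if (length(extra) > 0L) {
    stop("fit_outcome_model: stroke/other cases must be excluded; found: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  df <- data
  df$.y <- as.integer(df$status == "chd_case")
  df$.exposure <- df[[exposure]]
  df$.mediator <- df[[mediator]]
  terms <- c(".exposure", ".mediator", covariates)
  if (interaction) terms <- c(terms, ".exposure:.mediator")
  fit <- stats::glm(.build_formula(".y", terms), family = stats::binomial(),
                    data = df)
  .check_aliased(fit, "fit_outcome_model")
  if (!fit$converged) {
    stop("fit_outcome_model: logistic fit did not converge", call. = FALSE)
  }
  mu <- stats::fitted(fit)
  if (any(mu < 1e-10 | mu > 1 - 1e-10)) {
    stop("fit_outcome_model: perfect or quasi-perfect separation detected",
         call. = FALSE)
  }
  X <- stats::model.matrix(fit)
  int_col <- if (interaction) ".exposure:.mediator" else NA_character_
  cov_cols <- setdiff(colnames(X),
                      c("(Intercept)", ".exposure", ".mediator", int_col))
  structure(list(
    coef = stats::coef(fit),
    vcov = stats::vcov(fit),
    n = nrow(X),
    exposure = ".exposure",
    exposure_name = exposure,
    mediator = ".mediator",
    mediator_name = mediator,
    interaction = interaction,
    interaction_col = int_col,
    cov_cols = cov_cols,
    cov_reference = colMeans(X[, cov_cols, drop = FALSE]),
    marginal_risk = mean(df$.y),
    fit = fit
  ), class = "outcome_model")
}

# ---- parameter stacking -----------------------------------------------------

.stack_params <- function(mm, om) {
  par <- c(stats::setNames(mm$coef, paste0("m:", names(mm$coef))),
           "m:sigma2" = mm$sigma2,
           stats::setNames(om$coef, paste0("o:", names(om$coef))))
  par
}

.stack_vcov <- function(mm, om, include_sigma2_var = TRUE) {
  k1 <- length(mm$coef)
  k2 <- length(om$coef)
  n <- k1 + 1L + k2
  sigma <- matrix(0, n, n)
  sigma[seq_len(k1), seq_len(k1)] <- mm$vcov
  sigma[k1 + 1L, k1 + 1L] <- if (include_sigma2_var) mm$var_sigma2 else 0
  sigma[(k1 + 2L):n, (k1 + 2L):n] <- om$vcov
  rownames(sigma) <- colnames(sigma) <- names(.stack_params(mm, om))
  sigma
}

# Extract the scalar structural parameters from a stacked vector.
.unpack <- function(par, mm, om) {
  beta0 <- par[["m:(Intercept)"]]
  beta1 <- par[[paste0("m:", mm$exposure)]]
  beta2 <- par[paste0("m:", mm$cov_cols)]
  sigma2 <- par[["m:sigma2"]]
  theta1 <- par[[paste0("o:", om$exposure)]]
  theta2 <- par[[paste0("o:", om$mediator)]]
  theta3 <- if (om$interaction) par[[paste0("o:", om$interaction_col)]] else 0
  list(beta0 = beta0, beta1 = beta1, beta2 = unname(beta2), sigma2 = sigma2,
       theta1 = theta1, theta2 = theta2, theta3 = theta3)
}

# Point estimates of nde / nie / te on the log-OR scale from structural
# parameters (rare-outcome closed forms).
.ne_point <- function(ps, a, a_star, cvec) {
  d <- a - a_star
  mu_star <- ps$beta0 + ps$beta1 * a_star +
    (if (length(cvec)) sum(ps$beta2 * cvec) else 0)
  nie <- (ps$theta2 * ps$beta1 + ps$theta3 * ps$beta1 * a) * d
  nde <- (ps$theta1 + ps$theta3 * (mu_star + ps$theta2 * ps$sigma2)) * d +
    0.5 * ps$theta3^2 * ps$sigma2 * (a^2 - a_star^2)
  c(nde = nde, nie = nie, te = nde + nie)
}

# Analytic gradients of (nde, nie, te) with respect to the stacked vector.
.ne_gradients <- function(par, mm, om, a, a_star, cvec) {
  ps <- .unpack(par, mm, om)
  d <- a - a_star
  mu_star <- ps$beta0 + ps$beta1 * a_star +
    (if (length(cvec)) sum(ps$beta2 * cvec) else 0)
  g_nie <- g_nde <- stats::setNames(numeric(length(par)), names(par))

  g_nie[paste0("m:", mm$exposure)] <- (ps$theta2 + ps$theta3 * a) * d
  g_nie[paste0("o:", om$mediator)] <- ps$beta1 * d
  g_nde[paste0("o:", om$exposure)] <- d
  if (om$interaction) {
    ic <- paste0("o:", om$interaction_col)
    g_nie[ic] <- a * ps$beta1 * d
    g_nde[ic] <- d * (mu_star + ps$theta2 * ps$sigma2) +
      ps$theta3 * ps$sigma2 * (a^2 - a_star^2)
    g_nde["m:(Intercept)"] <- d * ps$theta3
    g_nde[paste0("m:", mm$exposure)] <- d * ps$theta3 * a_star
    if (length(cvec)) {
      g_nde[paste0("m:", mm$cov_cols)] <- d * ps$theta3 * cvec
    }
    g_nde[paste0("o:", om$mediator)] <- d * ps$theta3 * ps$sigma2
    g_nde["m:sigma2"] <- d * ps$theta3 * ps$theta2 +
      0.5 * ps$theta3^2 * (a^2 - a_star^2)
  }
  list(nde = g_nde, nie = g_nie, te = g_nde + g_nie)
}

.resolve_cvec <- function(mm, c_vals) {
  if (is.null(c_vals)) return(mm$cov_reference)
  if (length(mm$cov_cols) == 0L) return(numeric(0))
  if (is.null(names(c_vals)) && length(c_vals) == length(mm$cov_cols)) {
    return(stats::setNames(as.numeric(c_vals), mm$cov_cols))
  }
  if (!all(mm$cov_cols %in% names(c_vals))) {
    stop("covariate reference vector must name every mediator-model ",
         "covariate design column", call. = FALSE)
  }
  c_vals[mm$cov_cols]
}

#' Natural direct, indirect, and total effects (log-OR scale)
#'
#' Closed-form natural effects for the linear-mediator / logistic-outcome
#' system under the rare-outcome approximation, for the exposure contrast
#' `a` vs `a_star` at covariate reference `c_vals`:
#' \deqn{NIE = (\theta_2\beta_1 + \theta_3\beta_1 a)(a - a^*)}
#' \deqn{NDE = [\theta_1 + \theta_3(\beta_0 + \beta_1 a^* + \beta_2'c +
#'   \theta_2\sigma^2)](a - a^*) + \tfrac12\theta_3^2\sigma^2(a^2 - a^{*2})}
#' with `TE = NDE + NIE` exactly. Standard errors are delta-method with
#' analytic gradients over the stacked parameters of the two fits.
#'
#' @param mm A `mediator_model`.
#' @param om An `outcome_model` (same exposure and mediator).
#' @param a,a_star Exposure contrast values (`a != a_star`); defaults: one
#'   additional healthy lifestyle factor above the control-sample mean is
#'   supplied by [mediate()].
#' @param c_vals Covariate reference vector aligned to the mediator-model
#'   covariate design columns; default: control-sample means.
#' @param level Confidence level.
#' @return Data frame with one row per estimand (`nde`, `nie`, `te`):
#'   log-OR estimate, se, CI, p, and the exponentiated (OR-scale) columns.
#' @export
natural_effects <- function(mm, om, a, a_star, c_vals = NULL, level = 0.95) {
  stopifnot(inherits(mm, "mediator_model"), inherits(om, "outcome_model"))
  if (a == a_star) stop("natural_effects: a must differ from a_star",
                        call. = FALSE)
  if (mm$exposure_name != om$exposure_name ||
      mm$mediator_name != om$mediator_name) {
    stop("natural_effects: mediator and outcome models disagree on ",
         "exposure/mediator", call. = FALSE)
  }
  cvec <- .resolve_cvec(mm, c_vals)
  par <- .stack_params(mm, om)
  sigma <- .stack_vcov(mm, om)
  est <- .ne_point(.unpack(par, mm, om), a, a_star, unname(cvec))
  grads <- .ne_gradients(par, mm, om, a, a_star, unname(cvec))
  se <- vapply(grads, function(g) sqrt(.delta_var(g, sigma)), numeric(1))
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(
    estimand = c("nde", "nie", "te"),
    estimate = unname(est),
    se = unname(se[c("nde", "nie", "te")]),
    ci_low = unname(est - z * se[c("nde", "nie", "te")]),
    ci_high = unname(est + z * se[c("nde", "nie", "te")]),
    p = 2 * stats::pnorm(-abs(unname(est) / unname(se[c("nde", "nie", "te")]))),
    or = exp(unname(est)),
    or_low = exp(unname(est - z * se[c("nde", "nie", "te")])),
    or_high = exp(unname(est + z * se[c("nde", "nie", "te")])),
    row.names = NULL
  )
}

# Expected counterfactual risk under the rare-outcome (log-linear) model,
# up to the factor exp(theta0 + theta4'c) which cancels in every ratio:
# Q(x, z) = E[exp((theta2 + theta3 x) M(z))] * exp(theta1 x) with
# M(z) ~ N(mu(z), sigma2).
.qfun <- function(ps, x, z, cvec) {
  mu_z <- ps$beta0 + ps$beta1 * z +
    (if (length(cvec)) sum(ps$beta2 * cvec) else 0)
  s <- ps$theta2 + ps$theta3 * x
  exp(ps$theta1 * x + s * mu_z + 0.5 * s^2 * ps$sigma2)
}

.fourway_point <- function(ps, a, a_star, cvec, m_star) {
  d <- a - a_star
  mu_star <- ps$beta0 + ps$beta1 * a_star +
    (if (length(cvec)) sum(ps$beta2 * cvec) else 0)
  if (is.null(m_star)) m_star <- mu_star
  q_aa <- .qfun(ps, a, a, cvec)
  q_as <- .qfun(ps, a, a_star, cvec)
  q_sa <- .qfun(ps, a_star, a, cvec)
  q_ss <- .qfun(ps, a_star, a_star, cvec)
  y_am <- exp(ps$theta1 * a + (ps$theta2 + ps$theta3 * a) * m_star)
  y_sm <- exp(ps$theta1 * a_star + (ps$theta2 + ps$theta3 * a_star) * m_star)
  ne <- .ne_point(ps, a, a_star, cvec)
  c(
    err_cde = (y_am - y_sm) / q_ss,
    err_intref = (q_as - q_ss - y_am + y_sm) / q_ss,
    err_intmed = (q_aa - q_sa - q_as + q_ss) / q_ss,
    err_pie = (q_sa - q_ss) / q_ss,
    err_total = (q_aa - q_ss) / q_ss,
    # multiplicative (log-OR-scale) split: interaction parts proportional to
    # theta3, so they vanish exactly when no product term is fitted
    log_cde = (ps$theta1 + ps$theta3 * m_star) * d,
    log_intref = ne[["nde"]] - (ps$theta1 + ps$theta3 * m_star) * d,
    log_intmed = ps$theta3 * ps$beta1 * d^2,
    log_pie = (ps$theta2 + ps$theta3 * a_star) * ps$beta1 * d,
    m_star = m_star
  )
}

#' Four-way decomposition of the total effect
#'
#' Splits the total excess relative risk into the controlled direct effect,
#' reference interaction, mediated interaction, and pure indirect effect,
#' evaluated exactly under the rare-outcome risk model by analytic Gaussian
#' integration of the counterfactual definitions. The four excess-RR
#' components sum to `exp(te) - 1` identically. A multiplicative (log-OR
#' scale) split is reported alongside: there `cde = (theta1 + theta3 m*)(a -
#' a*)`, the two interaction parts are proportional to the product-term
#' coefficient (hence exactly zero when no interaction is fitted), and the
#' four parts sum to the total effect on the log scale.
#'
#' @inheritParams natural_effects
#' @param m_star Reference mediator level for the controlled direct effect;
#'   default: the model-implied mediator mean at `a_star` and `c_vals`.
#' @return List with `err` (named excess-RR components, their delta-method
#'   ses via numerical gradients, proportions of the total excess RR),
#'   `log` (the multiplicative split), `m_star`, and `te`.
#' @export
four_way_decomposition <- function(mm, om, a, a_star, c_vals = NULL,
                                   m_star = NULL) {
  stopifnot(inherits(mm, "mediator_model"), inherits(om, "outcome_model"))
  if (a == a_star) stop("four_way_decomposition: a must differ from a_star",
                        call. = FALSE)
  cvec <- unname(.resolve_cvec(mm, c_vals))
  par <- .stack_params(mm, om)
  sigma <- .stack_vcov(mm, om)
  ps <- .unpack(par, mm, om)
  mu_star <- ps$beta0 + ps$beta1 * a_star +
    (if (length(cvec)) sum(ps$beta2 * cvec) else 0)
  m_star_fixed <- if (is.null(m_star)) mu_star else m_star
  point <- .fourway_point(ps, a, a_star, cvec, m_star_fixed)
  comp <- c("err_cde", "err_intref", "err_intmed", "err_pie")
  # delta-method ses by central finite differences over the stacked params
  ses <- vapply(comp, function(nm) {
    g <- .numeric_gradient(function(p) {
      .fourway_point(.unpack(p, mm, om), a, a_star, cvec, m_star_fixed)[[nm]]
    }, par)
    sqrt(.delta_var(g, sigma))
  }, numeric(1))
  total <- point[["err_total"]]
  props <- if (abs(total) < 1e-12) {
    warning("four_way_decomposition: total excess RR ~ 0; proportions undefined")
    stats::setNames(rep(NA_real_, 4L), comp)
  } else {
    point[comp] / total
  }
  list(
    err = list(components = point[comp], se = ses, total = total,
               proportions = props),
    log = point[c("log_cde", "log_intref", "log_intmed", "log_pie")],
    m_star = m_star_fixed,
    te = .ne_point(ps, a, a_star, cvec)[["te"]]
  )
}

#' Delta-method standard error for an arbitrary estimand of the two fits
#'
#' Computes `sqrt(g' Sigma g)` where `Sigma` is the block-diagonal covariance
#' of the stacked parameter vector (mediator coefficients, residual variance,
#' outcome coefficients) and `g` is the gradient of the estimand, supplied
#' analytically or obtained by central finite differences.
#'
#' @param mm,om Fitted mediator and outcome models.
#' @param estimand Function of the named stacked parameter vector returning a
#'   scalar.
#' @param gradient Optional analytic gradient function (same signature,
#'   returns a vector aligned to the stacked parameters).
#' @param include_sigma2_var Include the sampling variability of the residual
#'   variance (default TRUE).
#' @param level Confidence level.
#' @return List with `estimate`, `se`, `ci_low`, `ci_high`.
#' @export
delta_method_ci <- function(mm, om, estimand, gradient = NULL,
                            include_sigma2_var = TRUE, level = 0.95) {
  par <- .stack_params(mm, om)
  sigma <- .stack_vcov(mm, om, include_sigma2_var = include_sigma2_var)
  if (any(!is.finite(sigma))) stop("delta_method_ci: singular covariance",
                                   call. = FALSE)
  est <- estimand(par)
  g <- if (is.null(gradient)) .numeric_gradient(estimand, par) else gradient(par)
  se <- sqrt(.delta_var(g, sigma))
  ci <- .wald_ci(est, se, level)
  list(estimate = est, se = se, ci_low = ci[["low"]], ci_high = ci[["high"]])
}

#' Proportion mediated
#'
#' `pm = nie / (nde + nie)` on the log odds-ratio scale, with 0 indicating no
#' mediation. Flagged inconsistent when the direct and indirect effects have
#' opposite signs (the ratio is then not a proportion in the usual sense);
#' undefined when the total effect is zero.
#'
#' @param nde,nie Natural direct and indirect effects (log-OR scale).
#' @return List with `pm` (proportion; multiply by 100 for percent),
#'   `inconsistent` and `undefined` flags.
#' @export
proportion_mediated <- function(nde, nie) {
  te <- nde + nie
  if (te == 0) {
    warning("proportion_mediated: total effect is zero; pm undefined")
    return(list(pm = NA_real_, inconsistent = FALSE, undefined = TRUE))
  }
  list(pm = nie / te,
       inconsistent = (nde != 0 && nie != 0 && sign(nde) != sign(nie)),
       undefined = FALSE)
}

#' Monte-Carlo counterfactual integration of the natural effects
#'
#' Independent numerical oracle for the closed forms: simulates the mediator
#' under each exposure level from the fitted mediator model (shared normal
#' draws across counterfactual worlds) and averages the counterfactual risk.
#' With `risk = "loglinear"` the risk is the rare-outcome exponential form on
#' which the closed-form estimands are defined, so agreement is limited only
#' by Monte-Carlo error; with `risk = "logistic"` the fitted inverse-logit
#' risk is averaged, which additionally carries the (documented) rare-outcome
#' approximation difference.
#'
#' @inheritParams natural_effects
#' @param n_draws Number of Monte-Carlo draws.
#' @param seed Integer seed.
#' @param risk "loglinear" or "logistic".
#' @return List with `nde`, `nie`, `te` and `se` (named Monte-Carlo standard
#'   errors accounting for shared draws).
#' @export
mc_natural_effects <- function(mm, om, a, a_star, c_vals = NULL,
                               n_draws = 1e6, seed = 1,
                               risk = c("loglinear", "logistic")) {
  risk <- match.arg(risk)
  cvec <- unname(.resolve_cvec(mm, c_vals))
  ps <- .unpack(.stack_params(mm, om), mm, om)
  theta0 <- om$coef[["(Intercept)"]]
  theta4c <- if (length(om$cov_cols)) {
    sum(om$coef[om$cov_cols] * om$cov_reference)
  } else 0
  mu <- function(z) ps$beta0 + ps$beta1 * z +
    (if (length(cvec)) sum(ps$beta2 * cvec) else 0)
  set.seed(seed)
  zdraw <- stats::rnorm(n_draws)
  m_a <- mu(a) + sqrt(ps$sigma2) * zdraw
  m_s <- mu(a_star) + sqrt(ps$sigma2) * zdraw
  lp <- function(x, m) theta0 + theta4c + ps$theta1 * x +
    (ps$theta2 + ps$theta3 * x) * m
  rf <- if (risk == "loglinear") exp else stats::plogis
  w_aa <- rf(lp(a, m_a))       # E[Y_{a, M(a)}]
  w_as <- rf(lp(a, m_s))       # E[Y_{a, M(a*)}]
  w_ss <- rf(lp(a_star, m_s))  # E[Y_{a*, M(a*)}]
  log_ratio_se <- function(x, y) {
    mx <- mean(x); my <- mean(y)
    v <- stats::var(x) / mx^2 + stats::var(y) / my^2 -
      2 * stats::cov(x, y) / (mx * my)
    sqrt(max(v, 0) / length(x))
  }
  list(
    nde = log(mean(w_as)) - log(mean(w_ss)),
    nie = log(mean(w_aa)) - log(mean(w_as)),
    te = log(mean(w_aa)) - log(mean(w_ss)),
    se = c(nde = log_ratio_se(w_as, w_ss),
           nie = log_ratio_se(w_aa, w_as),
           te = log_ratio_se(w_aa, w_ss))
  )
}

#' Full mediation analysis for one metabolite
#'
#' Fits the mediator model on controls and the outcome model on CHD cases
#' plus controls, screens for exposure-mediator interaction by likelihood
#' ratio test (policy "auto" reports the no-interaction decomposition when
#' the product term is not significant at 0.05, the interaction-allowing
#' decomposition otherwise), and returns the natural effects, proportion
#' mediated, and four-way components with delta-method uncertainty.
#'
#' @param data Data frame containing controls and CHD cases (stroke cases,
#'   if present, are dropped with a message), the transformed `marker`
#'   column, `hlf_count`, `status`, and covariates.
#' @param marker Transformed metabolite column name.
#' @param exposure Exposure column (default `hlf_count`).
#' @param covariates Covariate column names (both models).
#' @param interaction "auto", "on", or "off".
#' @param a,a_star Exposure contrast; default `a_star` is the mean exposure
#'   among controls and `a = a_star + 1` (one additional HLF).
#' @param level Confidence level.
#' @return One-row data frame: marker, contrast endpoints, nde/nie/te with
#'   se, CI and p (p for the NIE is the mediation test), pm (as a
#'   proportion), pm flags, interaction p-value and whether the product term
#'   was retained, and the excess-RR four-way components.
#' @export
mediate <- function(data, marker, exposure = "hlf_count",
                    covariates = .default_mediation_covariates,
                    interaction = c("auto", "on", "off"),
                    a = NULL, a_star = NULL, level = 0.95) {
  interaction <- match.arg(interaction)
  .require_columns(data, c(marker, exposure, covariates, "status"), "mediate")
  keep <- data$status %in% c("control", "chd_case")
  if (!all(keep)) {
    message(sprintf("mediate: dropping %d non-CHD case row(s)", sum(!keep)))
    data <- data[keep, , drop = FALSE]
  }
  controls <- data[data$status == "control", , drop = FALSE]
  if (nrow(controls) == 0L || !any(data$status == "chd_case")) {
    stop("mediate: need both controls and CHD cases", call. = FALSE)
  }
  if (is.null(a_star)) a_star <- mean(controls[[exposure]])
  if (is.null(a)) a <- a_star + 1

  mm <- fit_mediator_model(controls, marker, exposure, covariates)
  df <- data
  df$.y <- as.integer(df$status == "chd_case")
  lrt <- interaction_lrt(df, ".y", exposure, marker, covariates,
                         family = "binomial")
  use_interaction <- switch(interaction,
                            on = TRUE, off = FALSE,
                            auto = lrt$p_value <= 0.05)
  om <- fit_outcome_model(data, marker, exposure, covariates,
                          interaction = use_interaction)
  ne <- natural_effects(mm, om, a, a_star, level = level)
  fw <- four_way_decomposition(mm, om, a, a_star)
  pm <- proportion_mediated(ne$estimate[ne$estimand == "nde"],
                            ne$estimate[ne$estimand == "nie"])
  # delta-method se for pm via quotient rule over the analytic gradients
  par <- .stack_params(mm, om)
  sigma <- .stack_vcov(mm, om)
  cvec <- unname(.resolve_cvec(mm, NULL))
  grads <- .ne_gradients(par, mm, om, a, a_star, cvec)
  est <- .ne_point(.unpack(par, mm, om), a, a_star, cvec)
  pm_se <- if (!pm$undefined) {
    g_pm <- (est[["te"]] * grads$nie - est[["nie"]] * grads$te) / est[["te"]]^2
    sqrt(.delta_var(g_pm, sigma))
  } else NA_real_

  row <- data.frame(
    marker = marker, a = a, a_star = a_star,
    nde = est[["nde"]], nde_se = ne$se[ne$estimand == "nde"],
    nie = est[["nie"]], nie_se = ne$se[ne$estimand == "nie"],
    nie_ci_low = ne$ci_low[ne$estimand == "nie"],
    nie_ci_high = ne$ci_high[ne$estimand == "nie"],
    te = est[["te"]], te_se = ne$se[ne$estimand == "te"],
    p_nie = ne$p[ne$estimand == "nie"],
    pm = pm$pm, pm_se = pm_se,
    pm_inconsistent = pm$inconsistent,
    p_interaction = lrt$p_value,
    interaction_used = use_interaction,
    cde_err = fw$err$components[["err_cde"]],
    intref_err = fw$err$components[["err_intref"]],
    intmed_err = fw$err$components[["err_intmed"]],
    pie_err = fw$err$components[["err_pie"]],
    m_star = fw$m_star,
    row.names = NULL
  )
  attr(row, "models") <- list(mediator = mm, outcome = om)
  row
}

#' Mediation analysis across a metabolite panel
#'
#' Runs [mediate()] per marker and appends BH-FDR adjusted p-values for the
#' natural indirect effects across the panel.
#'
#' @inheritParams mediate
#' @param markers Character vector of transformed metabolite column names.
#' @return Data frame, one row per marker, with `p_nie_fdr`.
#' @export
mediate_panel <- function(data, markers, exposure = "hlf_count",
                          covariates = .default_mediation_covariates,
                          interaction = c("auto", "on", "off"),
                          a = NULL, a_star = NULL) {
  interaction <- match.arg(interaction)
  res <- do.call(rbind, lapply(markers, function(mk) {
    r <- mediate(data, mk, exposure, covariates, interaction, a, a_star)
    attr(r, "models") <- NULL
    r
  }))
  res$p_nie_fdr <- bh_fdr(res$p_nie)
  res
}

#' Joint mediation through the top principal components
#'
#' Multi-mediator extension used to estimate the joint mediating effect of
#' the whole lipid panel: one mediator model per principal component (fit in
#' controls), a single outcome model containing all components (no
#' interaction terms), joint `NIE = sum_k theta_2k beta_1k (a - a*)`, total
#' effect `TE = theta_1 (a - a*) + NIE`, and joint proportion mediated
#' `NIE / TE`, with delta-method uncertainty over all stacked fits.
#'
#' @param data Controls + CHD cases with PC score columns, exposure,
#'   covariates and `status`.
#' @param pc_cols Names of the principal-component score columns.
#' @param exposure,covariates,a,a_star As in [mediate()].
#' @return List: `nie`, `nde`, `te`, `pm`, `se` (named, for nie and pm),
#'   `p_nie`, and the per-component `beta1` / `theta2`.
#' @export
joint_mediation_via_pcs <- function(data, pc_cols, exposure = "hlf_count",
                                    covariates = .default_mediation_covariates,
                                    a = NULL, a_star = NULL) {
  .require_columns(data, c(pc_cols, exposure, covariates, "status"),
                   "joint_mediation_via_pcs")
  data <- data[data$status %in% c("control", "chd_case"), , drop = FALSE]
  controls <- data[data$status == "control", , drop = FALSE]
  if (is.null(a_star)) a_star <- mean(controls[[exposure]])
  if (is.null(a)) a <- a_star + 1
  d <- a - a_star

  mms <- lapply(pc_cols, function(pc) {
    fit_mediator_model(controls, pc, exposure, covariates)
  })
  df <- data
  df$.y <- as.integer(df$status == "chd_case")
  fit <- stats::glm(.build_formula(".y", c(exposure, pc_cols, covariates)),
                    family = stats::binomial(), data = df)
  .check_aliased(fit, "joint_mediation_via_pcs")
  theta <- stats::coef(fit)
  vtheta <- stats::vcov(fit)
  beta1 <- vapply(mms, function(m) m$coef[[m$exposure]], numeric(1))
  theta2 <- theta[pc_cols]
  theta1 <- theta[[exposure]]
  nie <- sum(theta2 * beta1) * d
  te <- theta1 * d + nie
  nde <- theta1 * d

  # stacked parameters: (beta1_k)_k then (theta1, theta2_k); block-diagonal
  k <- length(pc_cols)
  par_len <- k + 1L + k
  sigma <- matrix(0, par_len, par_len)
  for (i in seq_len(k)) {
    sigma[i, i] <- mms[[i]]$vcov[mms[[i]]$exposure, mms[[i]]$exposure]
  }
  o_idx <- c(exposure, pc_cols)
  sigma[(k + 1L):par_len, (k + 1L):par_len] <- vtheta[o_idx, o_idx]
  g_nie <- c(theta2 * d, 0, beta1 * d)
  g_te <- c(theta2 * d, d, beta1 * d)
  se_nie <- sqrt(.delta_var(g_nie, sigma))
  se_te <- sqrt(.delta_var(g_te, sigma))
  g_pm <- (te * g_nie - nie * g_te) / te^2
  se_pm <- sqrt(.delta_var(g_pm, sigma))
  list(
    nie = nie, nde = nde, te = te, pm = nie / te,
    se = c(nie = se_nie, te = se_te, pm = se_pm),
    p_nie = 2 * stats::pnorm(-abs(nie / se_nie)),
    beta1 = stats::setNames(beta1, pc_cols), theta2 = theta2
  )
}

#' Bias from dichotomizing a continuous exposure in mediation analysis
#'
#' Simulation experiment: data are generated with a continuous standard
#' normal exposure, a linear mediator (`M = beta1 A + N(0, 1)`), and a rare
#' logistic outcome with direct and mediated effects. For each
#' exposure-mediator effect size in `beta1_grid`, the proportion mediated is
#' estimated twice per replicate - with the exposure entered continuously
#' and with the exposure dichotomized at its median - and the mean deviation
#' of each estimator from the generative proportion mediated is reported
#' with its Monte-Carlo standard error.
#'
#' @param beta1_grid Numeric vector of exposure-mediator effects (SD units).
#' @param n Participants per simulated dataset.
#' @param n_sim Replicates per grid point.
#' @param seed Integer seed (deterministic output for fixed inputs).
#' @param theta_direct Direct exposure log-OR.
#' @param theta2 Mediator log-OR per SD.
#' @param marginal_risk Target outcome prevalence (rare).
#' @return Data frame: `beta1`, `true_pm`, `bias_continuous`,
#'   `bias_dichotomized`, `mc_se_continuous`, `mc_se_dichotomized`.
#' @export
dichotomization_bias_experiment <- function(beta1_grid, n = 1500, n_sim = 200,
                                            seed = 1, theta_direct = 0.3,
                                            theta2 = 0.4,
                                            marginal_risk = 0.03) {
  stopifnot(length(beta1_grid) >= 1L, n_sim >= 1L)
  set.seed(.substream_seed(seed, "experiment"))
  one_pm <- function(a_col, m, y) {
    b1 <- stats::coef(stats::lm(m ~ a_col))[[2L]]
    cf <- stats::coef(stats::glm(y ~ a_col + m, family = stats::binomial()))
    nie <- cf[[3L]] * b1
    te <- cf[[2L]] + nie
    nie / te
  }
  rows <- lapply(beta1_grid, function(b1) {
    true_pm <- theta2 * b1 / (theta_direct + theta2 * b1)
    est_c <- est_d <- numeric(n_sim)
    for (s in seq_len(n_sim)) {
      a_cont <- stats::rnorm(n)
      m <- b1 * a_cont + stats::rnorm(n)
      lp <- theta_direct * a_cont + theta2 * m
      theta0 <- stats::uniroot(function(t0) {
        mean(stats::plogis(t0 + lp)) - marginal_risk
      }, c(-30, 5))$root
      y <- stats::rbinom(n, 1L, stats::plogis(theta0 + lp))
      if (sum(y) < 5L) { # degenerate rare draw; resample deterministic path
        est_c[s] <- NA; est_d[s] <- NA; next
      }
      a_dich <- as.integer(a_cont > stats::median(a_cont))
      est_c[s] <- one_pm(a_cont, m, y)
      est_d[s] <- one_pm(a_dich, m, y)
    }
    ok <- is.finite(est_c) & is.finite(est_d)
    data.frame(
      beta1 = b1, true_pm = true_pm,
      bias_continuous = mean(est_c[ok]) - true_pm,
      bias_dichotomized = mean(est_d[ok]) - true_pm,
      mc_se_continuous = stats::sd(est_c[ok]) / sqrt(sum(ok)),
      mc_se_dichotomized = stats::sd(est_d[ok]) / sqrt(sum(ok)),
      n_used = sum(ok)
    )
  })
  do.call(rbind, rows)
}
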