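# Shared fixtures, all generated in code.

# Small full-featured generative setup for structural tests.
small_params <- function(seed = 42L, ...) {
  generative_params(
    n_source = 12000L,
    n_cases_chd = 180L,
    n_cases_stroke = c(ischemic = 200L, ich = 200L),
    n_controls = 320L,
    n_selection = 2000L,
    n_duplicates = 40L,
    seed = seed,
    ...
  )
}

# Single-marker panel with no factor structure: the single-mediator model
# assumptions hold exactly, so true pm is in closed form.
single_marker_params <- function(beta_per_hlf, theta2, theta_direct = -0.18,
                                 seed = 1L, n_source = 58000L,
                                 n_cases_chd = 900L, n_controls = 1500L,
                                 risk = 0.02) {
  mk <- "M1"
  generative_params(
    n_source = n_source,
    marker_names = mk,
    lifestyle_effect_matrix = matrix(beta_per_hlf, 1L, 5L,
                                     dimnames = list(mk, NULL)),
    metabolite_loading_matrix = matrix(0, 1L, 1L, dimnames = list(mk, "f1")),
    variant_spec = data.frame(id = "v1", chrom = "chr1", pos = 1000L,
                              ref = "A", alt = "G", allele_freq = 0.3,
                              ldl_effect = 0, ld_block_id = "b1",
                              gene_window = "G1"),
    metabolite_genetic_scale = 0,
    outcome_model = list(intercept = NA_real_,
                         direct_hlf_log_or = theta_direct,
                         metabolite_log_ors = stats::setNames(theta2, mk),
                         covariate_log_ors = c(age_z = 0.35, sex_male = 0.4)),
    chd_marginal_risk = risk,
    stroke_marginal_risks = c(ischemic = 0.002, ich = 0.002),
    n_cases_chd = n_cases_chd,
    n_cases_stroke = c(ischemic = 10L, ich = 10L),
    n_controls = n_controls,
    n_selection = 0L,
    n_duplicates = 0L,
    seed = seed
  )
}

# Analysis data frame: transformed markers + cohort columns.
make_analysis_df <- function(sim, markers = colnames(sim$metabolites)) {
  tm <- transform_metabolites(sim$metabolites[, markers, drop = FALSE])
  adf <- sim$cohort
  for (mk in markers) adf[[mk]] <- tm[, mk]
  attr(adf, "transformed_matrix") <- tm
  adf
}

chd_subset <- function(adf) {
  adf[adf$status %in% c("control", "chd_case"), , drop = FALSE]
}

# Minimal covariate-free mediation fixture: population draw with a rare
# logistic outcome; returns a data frame ready for the two mediation fits.
gen_med_fixture <- function(n = 2000, beta0 = 0, beta1 = 0.4, sigma = 1,
                            theta1 = 0.3, theta2 = 0.5, theta3 = 0,
                            base_risk = 0.08, seed = 1) {
  set.seed(seed)
  a <- stats::rbinom(n, 5L, 0.45)
  m <- beta0 + beta1 * a + stats::rnorm(n, 0, sigma)
  lp <- theta1 * a + theta2 * m + theta3 * a * m
  t0 <- stats::uniroot(function(x) mean(stats::plogis(x + lp)) - base_risk,
                       c(-30, 5))$root
  y <- stats::rbinom(n, 1L, stats::plogis(t0 + lp))
  data.frame(hlf_count = a, med = m,
             status = ifelse(y == 1L, "chd_case", "control"))
}

fit_both <- function(df, interaction = FALSE, covariates = character(0)) {
  mm <- fit_mediator_model(df[df$status == "control", , drop = FALSE],
                           "med", "hlf_count", covariates)
  om <- fit_outcome_model(df, "med", "hlf_count", covariates,
                          interaction = interaction)
  list(mm = mm, om = om)
}

# Hand-built model objects for closed-form arithmetic checks (no fitting).
fake_models <- function(beta0 = 0, beta1 = 0.5, sigma2 = 1,
                        theta1 = 0.2, theta2 = 0.3, theta3 = 0) {
  k1 <- 2L
  mm <- structure(list(
    coef = c("(Intercept)" = beta0, ".exposure" = beta1),
    vcov = diag(1e-4, k1, k1) |>
      (\(m) { dimnames(m) <- list(c("(Intercept)", ".exposure"),
                                  c("(Intercept)", ".exposure")); m })(),
    sigma2 = sigma2, var_sigma2 = 1e-6, n = 1000L,
    exposure = ".exposure", exposure_name = "hlf_count",
    mediator_name = "med", cov_cols = character(0),
    cov_reference = numeric(0)
  ), class = "mediator_model")
  interaction <- theta3 != 0
  cn <- c("(Intercept)", ".exposure", ".mediator",
          if (interaction) ".exposure:.mediator")
  coefs <- c(-4, theta1, theta2, if (interaction) theta3)
  names(coefs) <- cn
  om <- structure(list(
    coef = coefs,
    vcov = diag(1e-4, length(cn)) |>
      (\(m) { dimnames(m) <- list(cn, cn); m })(),
    n = 1000L, exposure = ".exposure", exposure_name = "hlf_count",
    mediator = ".mediator", mediator_name = "med",
    interaction = interaction,
    interaction_col = if (interaction) ".exposure:.mediator" else NA_character_,
    cov_cols = character(0), cov_reference = numeric(0),
    marginal_risk = 0.02
  ), class = "outcome_model")
  list(mm = mm, om = om)
}

# Raw lifestyle rows for classification tests.
raw_row <- function(sex = "female", smoking = "never", freq = "never",
                    g_day = 0, diet_n = 5, met = 20, bmi = 23, wc = 78) {
  comps <- c("veg_daily", "fruit_daily", "red_meat_lt7", "soybean_ge4",
             "fish_ge1", "coarse_grain_ge4")
  out <- data.frame(sex = sex, smoking_status = smoking, alcohol_freq = freq,
                    alcohol_g_day = g_day, activity_met_h = met,
                    bmi = bmi, wc = wc)
  for (i in seq_along(comps)) out[[comps[i]]] <- i <= diet_n
  out
}
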