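test_that("closed-form natural effects reproduce the product formula", {
  # theta3 = 0, theta2 = 0.3, beta1 = 0.5, contrast 1 -> nie = 0.15
  fm <- fake_models(beta1 = 0.5, theta1 = 0.2, theta2 = 0.3, theta3 = 0)
  ne <- natural_effects(fm$mm, fm$om, a = 1, a_star = 0)
  expect_equal(ne$estimate[ne$estimand == "nie"], 0.15, tolerance = 1e-12)
  expect_equal(ne$estimate[ne$estimand == "nde"], 0.2, tolerance = 1e-12)
  expect_equal(ne$estimate[ne$estimand == "te"], 0.35, tolerance = 1e-12)

  # no exposure-mediator path: nie = 0 regardless of the outcome model
  fm0 <- fake_models(beta1 = 0, theta2 = 0.8, theta3 = 0.3)
  ne0 <- natural_effects(fm0$mm, fm0$om, a = 1, a_star = 0)
  expect_equal(ne0$estimate[ne0$estimand == "nie"], 0)

  # with interaction the closed-form expressions hold term by term
  fm3 <- fake_models(beta0 = 0.1, beta1 = 0.5, sigma2 = 1.3,
                     theta1 = 0.2, theta2 = 0.3, theta3 = 0.15)
  a <- 3.2; as <- 2.2
  ne3 <- natural_effects(fm3$mm, fm3$om, a, as)
  nie_expect <- (0.3 * 0.5 + 0.15 * 0.5 * a) * (a - as)
  nde_expect <- (0.2 + 0.15 * (0.1 + 0.5 * as + 0.3 * 1.3)) * (a - as) +
    0.5 * 0.15^2 * 1.3 * (a^2 - as^2)
  expect_equal(ne3$estimate[ne3$estimand == "nie"], nie_expect, tolerance = 1e-12)
  expect_equal(ne3$estimate[ne3$estimand == "nde"], nde_expect, tolerance = 1e-12)

  expect_error(natural_effects(fm$mm, fm$om, 1, 1), "differ")
})

test_that("fitted models satisfy te = nde + nie and the no-interaction product", {
  df <- gen_med_fixture(n = 3000, beta1 = 0.4, theta1 = 0.25, theta2 = 0.5,
                        seed = 2)
  fits <- fit_both(df)
  a_star <- mean(df$hlf_count[df$status == "control"]); a <- a_star + 1
  ne <- natural_effects(fits$mm, fits$om, a, a_star)
  expect_equal(ne$estimate[3], ne$estimate[1] + ne$estimate[2], tolerance = 1e-12)
  # classic product of coefficients, exactly
  expect_equal(ne$estimate[ne$estimand == "nie"],
               fits$mm$coef[[".exposure"]] * fits$om$coef[[".mediator"]],
               tolerance = 1e-12)
  # parameter recovery within sampling error
  expect_lt(abs(fits$om$coef[[".mediator"]] - 0.5),
            3 * sqrt(fits$om$vcov[".mediator", ".mediator"]))
})

test_that("mediator and outcome model contracts are enforced", {
  df <- gen_med_fixture(seed = 3)
  expect_error(fit_mediator_model(df, "med", "hlf_count", character(0)),
               "control participants only")
  df2 <- df
  df2$status[1:5] <- "ischemic_stroke_case"
  expect_error(fit_outcome_model(df2, "med", "hlf_count", character(0)),
               "stroke")
  # residual variance equals an independent normal-equations solve
  controls <- df[df$status == "control", ]
  mm <- fit_mediator_model(controls, "med", "hlf_count", character(0))
  X <- cbind(1, controls$hlf_count)
  b <- solve(t(X) %*% X, t(X) %*% controls$med)
  r <- controls$med - X %*% b
  expect_equal(mm$sigma2, sum(r^2) / (nrow(X) - 2), tolerance = 1e-10)

  # shifting the mediator by a constant only moves the outcome intercept
  om1 <- fit_outcome_model(df, "med", "hlf_count", character(0))
  df3 <- df; df3$med <- df3$med + 5
  om2 <- fit_outcome_model(df3, "med", "hlf_count", character(0))
  expect_equal(om1$coef[[".mediator"]], om2$coef[[".mediator"]], tolerance = 1e-8)
  expect_equal(om1$coef[[".exposure"]], om2$coef[[".exposure"]], tolerance = 1e-8)
  expect_equal(om2$coef[["(Intercept)"]],
               om1$coef[["(Intercept)"]] - 5 * om1$coef[[".mediator"]],
               tolerance = 1e-6)
})

test_that("delta-method machinery: identity gradient and analytic-vs-numeric", {
  df <- gen_med_fixture(n = 2500, beta1 = 0.4, theta2 = 0.5, seed = 7)
  fits <- fit_both(df, interaction = TRUE)
  # estimand = theta2 alone reproduces the logistic fit's reported se
  out <- delta_method_ci(fits$mm, fits$om,
                         estimand = function(p) p[["o:.mediator"]],
                         gradient = function(p) {
                           g <- numeric(length(p)); names(g) <- names(p)
                           g[["o:.mediator"]] <- 1; g
                         })
  expect_equal(out$se, sqrt(fits$om$vcov[".mediator", ".mediator"]),
               tolerance = 1e-12)

  # analytic gradients of nde/nie/te vs central finite differences
  a_star <- mean(df$hlf_count); a <- a_star + 1
  par <- lipidmed:::.stack_params(fits$mm, fits$om)
  grads <- lipidmed:::.ne_gradients(par, fits$mm, fits$om, a, a_star, numeric(0))
  for (nm in c("nde", "nie", "te")) {
    gn <- lipidmed:::.numeric_gradient(function(p) {
      lipidmed:::.ne_point(lipidmed:::.unpack(p, fits$mm, fits$om),
                           a, a_star, numeric(0))[[nm]]
    }, par)
    expect_lt(max(abs(grads[[nm]] - gn)), 1e-6)
  }
})

test_that("four-way decomposition: exact identities on both scales", {
  df <- gen_med_fixture(n = 3000, beta1 = 0.5, theta1 = 0.3, theta2 = 0.5,
                        theta3 = 0.1, base_risk = 0.1, seed = 11)
  fits <- fit_both(df, interaction = TRUE)
  a_star <- 2; a <- 3
  ne <- natural_effects(fits$mm, fits$om, a, a_star)
  fw <- four_way_decomposition(fits$mm, fits$om, a, a_star)
  te <- ne$estimate[ne$estimand == "te"]
  # excess-RR components sum to exp(te) - 1
  expect_equal(sum(fw$err$components), exp(te) - 1, tolerance = 1e-10)
  expect_equal(fw$err$total, exp(te) - 1, tolerance = 1e-10)
  expect_equal(sum(fw$err$proportions), 1, tolerance = 1e-10)
  # multiplicative split sums to te
  expect_equal(sum(unlist(fw$log)), te, tolerance = 1e-10)

  # no-interaction degeneracy on the multiplicative scale
  fits0 <- fit_both(df, interaction = FALSE)
  ne0 <- natural_effects(fits0$mm, fits0$om, a, a_star)
  fw0 <- four_way_decomposition(fits0$mm, fits0$om, a, a_star)
  expect_equal(fw0$log[["log_intref"]], 0)
  expect_equal(fw0$log[["log_intmed"]], 0)
  expect_equal(fw0$log[["log_cde"]], ne0$estimate[ne0$estimand == "nde"])
  expect_equal(fw0$log[["log_pie"]], ne0$estimate[ne0$estimand == "nie"])
  expect_equal(sum(fw0$err$components), exp(ne0$estimate[3]) - 1,
               tolerance = 1e-10)
})

test_that("closed forms agree with Monte-Carlo counterfactual integration", {
  df <- gen_med_fixture(n = 2500, beta1 = 0.45, theta1 = 0.25, theta2 = 0.4,
                        theta3 = 0.12, base_risk = 0.06, seed = 13)
  fits <- fit_both(df, interaction = TRUE)
  a_star <- mean(df$hlf_count); a <- a_star + 1
  ne <- natural_effects(fits$mm, fits$om, a, a_star)
  mc <- mc_natural_effects(fits$mm, fits$om, a, a_star, n_draws = 2e5,
                           seed = 5, risk = "loglinear")
  for (nm in c("nde", "nie", "te")) {
    diff <- abs(mc[[nm]] - ne$estimate[ne$estimand == nm])
    expect_lt(diff, 3 * mc$se[[nm]] + 1e-9)
  }
  # the four ERR components match the same draws integrated component-wise
  fw <- four_way_decomposition(fits$mm, fits$om, a, a_star)
  ps <- lipidmed:::.unpack(lipidmed:::.stack_params(fits$mm, fits$om),
                           fits$mm, fits$om)
  set.seed(5)
  z <- rnorm(2e5)
  mu <- function(x) ps$beta0 + ps$beta1 * x
  m_a <- mu(a) + sqrt(ps$sigma2) * z
  m_s <- mu(a_star) + sqrt(ps$sigma2) * z
  w <- function(x, m) exp(ps$theta1 * x + (ps$theta2 + ps$theta3 * x) * m)
  m_star <- fw$m_star
  p0 <- mean(w(a_star, m_s))
  mc_cde <- (w(a, m_star) - w(a_star, m_star)) / p0
  mc_intref <- (mean(w(a, m_s)) - p0 - w(a, m_star) + w(a_star, m_star)) / p0
  mc_intmed <- (mean(w(a, m_a)) - mean(w(a_star, m_a)) - mean(w(a, m_s)) + p0) / p0
  mc_pie <- (mean(w(a_star, m_a)) - p0) / p0
  got <- fw$err$components
  expect_equal(unname(got),
               c(mc_cde, mc_intref, mc_intmed, mc_pie), tolerance = 0.02)
})

test_that("proportion mediated handles signs, zeros and percentages", {
  expect_equal(proportion_mediated(0.5, 0)$pm, 0)
  expect_equal(proportion_mediated(0, 0.3)$pm, 1)
  expect_equal(proportion_mediated(0.9, 0.1)$pm, 0.1)
  expect_true(proportion_mediated(-0.2, 0.1)$inconsistent)
  expect_warning(out <- proportion_mediated(0.1, -0.1), "undefined")
  expect_true(out$undefined)
})

test_that("the high-level mediate() wrapper ties the pieces together", {
  sim <- simulate_cohort(single_marker_params(beta_per_hlf = -0.2,
                                              theta2 = 0.3, seed = 5L,
                                              n_source = 30000L,
                                              n_cases_chd = 500L,
                                              n_controls = 900L),
                         compute_truth = FALSE)
  adf <- make_analysis_df(sim, "M1")
  chd <- chd_subset(adf)
  row <- mediate(chd, "M1")
  expect_equal(row$te, row$nde + row$nie, tolerance = 1e-12)
  expect_true(row$p_interaction > 0 && row$p_interaction <= 1)
  expect_true(is.finite(row$pm_se))
  # interaction policy switches are honored
  row_on <- mediate(chd, "M1", interaction = "on")
  expect_true(row_on$interaction_used)
  row_off <- mediate(chd, "M1", interaction = "off")
  expect_false(row_off$interaction_used)

  panel <- mediate_panel(chd, "M1")
  expect_equal(panel$p_nie_fdr, panel$p_nie)
})

test_that("joint PC mediation reduces to its algebraic definition", {
  sim <- simulate_cohort(small_params(seed = 19L), compute_truth = FALSE)
  adf <- make_analysis_df(sim)
  tm <- attr(adf, "transformed_matrix")
  pcs <- top_principal_components(tm, k = 5)
  for (k in 1:5) adf[[paste0("PC", k)]] <- pcs$scores[, k]
  chd <- chd_subset(adf)
  jm <- joint_mediation_via_pcs(chd, paste0("PC", 1:5))
  expect_equal(jm$nie, sum(jm$theta2 * jm$beta1), tolerance = 1e-12)
  expect_equal(jm$te, jm$nde + jm$nie, tolerance = 1e-12)
  expect_equal(jm$pm, jm$nie / jm$te, tolerance = 1e-12)
  expect_true(jm$se[["nie"]] > 0)
})

test_that("dichotomizing the exposure is unbiased only when the mediator path is weak", {
  tab <- dichotomization_bias_experiment(beta1_grid = c(0, 0.8),
                                         n = 800, n_sim = 60, seed = 4)
  expect_equal(nrow(tab), 2)
  # nothing to distort at beta1 = 0
  expect_lt(abs(tab$bias_dichotomized[1]), 3 * tab$mc_se_dichotomized[1] + 1e-3)
  # determinism
  tab2 <- dichotomization_bias_experiment(beta1_grid = c(0, 0.8),
                                          n = 800, n_sim = 60, seed = 4)
  expect_identical(tab, tab2)
})
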