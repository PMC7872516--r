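test_that("simulation is deterministic given the seed", {
  p <- small_params(seed = 101L)
  s1 <- simulate_cohort(p, compute_truth = FALSE)
  s2 <- simulate_cohort(p, compute_truth = FALSE)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$metabolites, s2$metabolites)
  expect_identical(s1$genotypes$dosages, s2$genotypes$dosages)
  expect_identical(s1$selection$ldl_c, s2$selection$ldl_c)
  # a different seed changes the draw
  s3 <- simulate_cohort(small_params(seed = 102L), compute_truth = FALSE)
  expect_false(identical(s1$cohort$age, s3$cohort$age))
})

test_that("source-cohort HLF prevalences hit their targets", {
  p <- small_params(seed = 7L)
  sim <- simulate_cohort(p, compute_truth = FALSE, keep_source = TRUE)
  src <- sim$source
  flags <- c("never_smoking", "moderate_alcohol", "healthy_diet",
             "physically_active", "healthy_adiposity")
  for (i in seq_along(flags)) {
    target <- unname(p$hlf_prevalences[i])
    se <- sqrt(target * (1 - target) / nrow(src))
    expect_lt(abs(mean(src[[flags[i]]]) - target), 3 * se + 1 / nrow(src))
  }
  expect_true(all(src$age >= 30 & src$age <= 79))
  expect_true(all(src$bmi > 0) && all(src$wc > 0) &&
                all(src$activity_met_h >= 0))
})

test_that("case and control counts and eligibility match the requested design", {
  p <- small_params(seed = 21L)
  sim <- simulate_cohort(p, compute_truth = FALSE)
  tab <- table(sim$cohort$status)
  expect_equal(unname(tab["chd_case"]), 180)
  expect_equal(unname(tab["ischemic_stroke_case"]), 200)
  expect_equal(unname(tab["ich_case"]), 200)
  expect_equal(unname(tab["control"]), 320)
  expect_equal(nrow(sim$cohort), 900)
  expect_true(all(sim$cohort$eligible))
  # status levels mutually exclusive by construction
  expect_true(all(sim$cohort$status %in%
                    c("control", "chd_case", "ischemic_stroke_case", "ich_case")))
})

test_that("frequency matching aligns control strata with combined cases", {
  set.seed(44)
  # background population kept out of the case stratum's age bin
  src <- data.frame(
    participant_id = as.character(1:6000),
    age = runif(6000, 45, 74),
    sex = rep(c("male", "female"), 3000),
    area = sample(paste0("A", 1:3), 6000, replace = TRUE),
    status = "none"
  )
  # stratum A: 30 cases + 20 potential controls, all in one unique stratum
  src$age[1:50] <- 42
  src$sex[1:50] <- "male"
  src$area[1:50] <- "A1"
  src$status[1:30] <- "chd_case"
  out <- sample_nested_case_control(src, c(chd_case = 30), n_controls = 10,
                                    seed = 2)
  ctrl <- out[out$status == "control", ]
  expect_equal(nrow(ctrl), 10)
  expect_true(all(ctrl$age == 42 & ctrl$sex == "male" & ctrl$area == "A1"))

  # exhausted stratum fails by name in strict mode
  expect_error(
    sample_nested_case_control(src, c(chd_case = 30), n_controls = 50,
                               seed = 2),
    "exhausted")
  # globally insufficient controls fail even when redistribution is allowed
  expect_error(
    sample_nested_case_control(src, c(chd_case = 30), n_controls = 50,
                               seed = 2, strict = FALSE),
    "eligible controls")

  # two case strata, one nearly exhausted: redistribution fills from the other
  src2 <- src
  src2$age[51:80] <- 52; src2$sex[51:80] <- "female"; src2$area[51:80] <- "A2"
  src2$status[51:60] <- "chd_case"
  # stratum A demand: 40 * 30/40 = 30 > 20 available
  expect_message(
    out2 <- sample_nested_case_control(src2, c(chd_case = 40), n_controls = 40,
                                       seed = 2, strict = FALSE),
    "redistributing")
  expect_equal(sum(out2$status == "control"), 40)

  # unattainable case counts fail naming the shortfall
  expect_error(sample_nested_case_control(src, c(chd_case = 31), 10, seed = 1),
               "shortfall")
})

test_that("matched controls are statistically indistinguishable on matching vars", {
  # chi-square test of stratum x case/control on the sampled output
  pvals <- vapply(1:10, function(s) {
    sim <- simulate_cohort(small_params(seed = 300L + s), compute_truth = FALSE)
    co <- sim$cohort
    co$age_bin <- cut(co$age, seq(30, 80, 10))
    co$is_control <- co$status == "control"
    suppressWarnings(chisq.test(table(co$age_bin, co$is_control))$p.value)
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.8)
})

test_that("genotype simulator honors frequency, HWE block LD, and independence", {
  spec <- data.frame(
    id = paste0("v", 1:4), chrom = "chr1", pos = c(1, 2, 3, 4) * 1000L,
    ref = "A", alt = "G", allele_freq = c(0.5, 0.5, 0.3, 0.3),
    ldl_effect = 0, ld_block_id = c("b1", "b1", "b2", "b3"),
    gene_window = "G1")
  g <- simulate_genotypes(2000, spec, seed = 5, ld_decay = 1)
  expect_true(all(g$dosages %in% 0:2))
  af <- colMeans(g$dosages) / 2
  se <- sqrt(0.5 * 0.5 / (2 * 2000))
  expect_lt(abs(af[1] - 0.5), 3 * se)
  # configured r^2 = 1 within the block
  expect_gt(ld_r2(g$dosages, "v1", "v2"), 0.95)
  # across blocks: independent
  expect_lt(abs(cor(g$dosages[, "v3"], g$dosages[, "v4"])), 3 / sqrt(2000))
  # decay < 1 weakens within-block correlation
  g2 <- simulate_genotypes(2000, spec, seed = 5, ld_decay = 0.5)
  expect_lt(ld_r2(g2$dosages, "v1", "v2"), 0.95)
  # determinism
  g3 <- simulate_genotypes(2000, spec, seed = 5, ld_decay = 1)
  expect_identical(g$dosages, g3$dosages)
})

test_that("ground truth satisfies the structural identities", {
  # no mediation pathway: all lifestyle effects and metabolite log-ORs zero
  p0 <- single_marker_params(beta_per_hlf = 0, theta2 = 0, seed = 2L,
                             n_source = 30000L, n_cases_chd = 400L,
                             n_controls = 700L)
  t0 <- true_mediation_effects(p0, n_draws = 5e4)
  expect_equal(unname(t0$true_nie_log_or["M1"]), 0)
  expect_equal(unname(t0$true_pm["M1"]), 0)

  # closed form: beta1 = 0.5 per HLF, theta2 = 0.3 -> nie = 0.15 per +1 HLF
  p1 <- single_marker_params(beta_per_hlf = 0.5, theta2 = 0.3, seed = 2L,
                             n_source = 30000L, n_cases_chd = 400L,
                             n_controls = 700L)
  t1 <- true_mediation_effects(p1, n_draws = 5e4)
  expect_equal(unname(t1$true_nie_log_or["M1"]), 0.15, tolerance = 1e-10)
  # TE = NDE + NIE identically, and pm follows
  expect_equal(unname(t1$true_te_log_or["M1"]),
               unname(t1$true_nde_log_or["M1"] + t1$true_nie_log_or["M1"]),
               tolerance = 1e-12)
  expect_equal(unname(t1$true_pm["M1"]),
               0.15 / (-0.18 + 0.15), tolerance = 1e-10)
  # homogeneous per-factor effects: mediator slope equals the shared effect
  expect_equal(unname(t1$mediator_slopes["M1"]), 0.5, tolerance = 1e-10)
  # the full default panel satisfies the identity marker-wise
  pd <- small_params(seed = 5L)
  td <- true_mediation_effects(pd, n_draws = 5e4)
  expect_equal(td$true_te_log_or, td$true_nde_log_or + td$true_nie_log_or,
               tolerance = 1e-12)
  expect_identical(td$causal_variant_ids,
                   pd$variant_spec$id[pd$variant_spec$ldl_effect != 0])
})

test_that("generator parameter validation guards impossible designs", {
  expect_error(generative_params(hlf_prevalences = c(0, .1, .4, .5, .7)),
               "hlf_prevalences")
  expect_error(generative_params(n_source = 5000L), "CHD cases")
  spec <- default_variant_spec()
  spec$allele_freq[1] <- 0.001
  expect_error(generative_params(variant_spec = spec), "allele_freq")
})

test_that("duplicate QC pairs reproduce the configured measurement CV", {
  sim <- simulate_cohort(small_params(seed = 55L), compute_truth = FALSE)
  qc <- duplicate_cv(sim$duplicates)
  expect_lt(abs(qc$median_cv - 0.05), 0.01)
  expect_lt(qc$iqr[1], qc$median_cv)
  expect_gt(qc$iqr[2], qc$median_cv)
})
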