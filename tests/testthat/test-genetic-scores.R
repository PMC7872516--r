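# Shared selection fixture: unlinked blocks, one dominant causal variant.
sel_spec <- function(n_var = 20, causal = 5L, effect = 0.12,
                     blocks = rep(1:4, each = 5)) {
  eff <- numeric(n_var)
  eff[causal] <- effect
  data.frame(id = sprintf("s%02d", 1:n_var), chrom = "chr1",
             pos = 1000L * (1:n_var), ref = "A", alt = "G",
             allele_freq = seq(0.15, 0.45, length.out = n_var),
             ldl_effect = eff, ld_block_id = paste0("b", blocks),
             gene_window = "G1")
}

sim_selection <- function(spec, n = 4000, seed = 1, ld_decay = 0.85) {
  g <- simulate_genotypes(n, spec, seed = seed, ld_decay = ld_decay)
  set.seed(seed + 1)
  covs <- cbind(age = runif(n, 35, 70), sex_male = rbinom(n, 1, 0.5),
                matrix(rnorm(n * 10), n, 10,
                       dimnames = list(NULL, paste0("PC", 1:10))))
  ldlc <- 2.3 + as.numeric(g$dosages %*% spec$ldl_effect) +
    0.002 * covs[, "age"] + rnorm(n, 0, 0.5)
  list(g = g, covs = covs, ldlc = ldlc)
}

test_that("ld_r2 equals a brute-force computation and flags constants", {
  set.seed(2)
  d <- cbind(a = rbinom(500, 2, 0.4), b = rbinom(500, 2, 0.3))
  d <- cbind(d, c = d[, "a"])
  expect_equal(ld_r2(d, "a", "c"), 1)
  brute <- function(x, y) {
    sx <- sum((x - mean(x))^2); sy <- sum((y - mean(y))^2)
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    sxy^2 / (sx * sy)
  }
  expect_equal(ld_r2(d, "a", "b"), brute(d[, "a"], d[, "b"]), tolerance = 1e-12)
  expect_lt(ld_r2(d, "a", "b"), 0.05)
  d2 <- cbind(d, k = rep(1L, 500))
  expect_error(ld_r2(d2, "a", "k"), "constant")
})

test_that("a dominant causal signal is selected and weighted correctly", {
  spec <- sel_spec()
  fx <- sim_selection(spec, n = 4000, seed = 9)
  sd1 <- conditional_select_variants(fx$g$dosages, spec, fx$ldlc, fx$covs)
  expect_true("s05" %in% sd1$selected_variants)
  # all selected pairs respect the LD threshold
  if (length(sd1$selected_variants) > 1L) {
    combs <- combn(sd1$selected_variants, 2)
    r2s <- apply(combs, 2, function(pr) ld_r2(fx$g$dosages, pr[1], pr[2]))
    expect_true(all(r2s <= 0.3))
  }
  # every selected variant conditionally significant in the final model
  expect_true(all(sd1$conditional_p < 0.05))
  # weight close to the generative effect (positive magnitude)
  expect_lt(abs(sd1$weights[["s05"]] - 0.12), 3 * sd1$weight_ses[["s05"]])
  expect_true(all(sd1$weights > 0))
  # causal allele raises LDL-C, so the exposure (lowering) allele is ref
  expect_equal(unname(sd1$exposure_alleles[sd1$selected_variants == "s05"]), "A")
})

test_that("perfectly linked duplicates collapse to a single selection", {
  spec <- sel_spec(n_var = 2, causal = 1L, effect = 0.15, blocks = c(1, 1))
  spec$allele_freq <- c(0.3, 0.3)
  fx <- sim_selection(spec, n = 3000, seed = 3, ld_decay = 1)
  sd1 <- conditional_select_variants(fx$g$dosages, spec, fx$ldlc, fx$covs)
  expect_equal(length(sd1$selected_variants), 1L)
})

test_that("selection is invariant to variant ordering and drops monomorphs", {
  spec <- sel_spec()
  fx <- sim_selection(spec, n = 4000, seed = 12)
  sd1 <- conditional_select_variants(fx$g$dosages, spec, fx$ldlc, fx$covs)
  perm <- sample(nrow(spec))
  sd2 <- conditional_select_variants(fx$g$dosages[, perm], spec[perm, ],
                                     fx$ldlc, fx$covs)
  expect_setequal(sd1$selected_variants, sd2$selected_variants)

  # a monomorphic column is excluded before testing
  g2 <- cbind(fx$g$dosages, mono = 0L)
  spec2 <- rbind(spec, data.frame(id = "mono", chrom = "chr1", pos = 99000L,
                                  ref = "A", alt = "G", allele_freq = 0.2,
                                  ldl_effect = 1, ld_block_id = "b9",
                                  gene_window = "G1"))
  sd3 <- conditional_select_variants(g2, spec2, fx$ldlc, fx$covs)
  expect_false("mono" %in% sd3$selected_variants)
  # empty window warns and returns an empty score
  expect_warning(
    empty <- conditional_select_variants(fx$g$dosages, spec, fx$ldlc, fx$covs,
                                         gene = "NOPE"),
    "no variants")
  expect_length(empty$selected_variants, 0)
})

test_that("score construction is the weighted exposure-allele sum", {
  def <- structure(list(gene = "G1", selected_variants = "v1",
                        exposure_alleles = "G",
                        weights = c(v1 = 0.07),
                        weight_ses = c(v1 = 0.01),
                        conditional_p = c(v1 = 1e-5),
                        flip = c(v1 = FALSE)), class = "genetic_score")
  d <- matrix(c(0L, 1L, 2L, 2L), 4, 1, dimnames = list(NULL, "v1"))
  sc <- build_score(d, def)
  expect_equal(sc$raw, c(0, 0.07, 0.14, 0.14))
  # flipped orientation counts the reference allele
  def$flip <- c(v1 = TRUE)
  expect_equal(build_score(d, def)$raw, c(0.14, 0.07, 0, 0))

  # brute-force per-participant loop on a multi-variant score
  spec <- sel_spec()
  fx <- sim_selection(spec, n = 1200, seed = 21)
  sd1 <- conditional_select_variants(fx$g$dosages, spec, fx$ldlc, fx$covs)
  sc1 <- build_score(fx$g$dosages, sd1)
  brute <- vapply(seq_len(1200), function(i) {
    tot <- 0
    for (v in sd1$selected_variants) {
      dv <- fx$g$dosages[i, v]
      if (sd1$flip[[v]]) dv <- 2 - dv
      tot <- tot + sd1$weights[[v]] * dv
    }
    tot
  }, numeric(1))
  expect_equal(sc1$raw, brute, tolerance = 1e-12)

  # linearity: scaling the weights scales the raw score
  sd2 <- sd1; sd2$weights <- 3 * sd1$weights
  expect_equal(build_score(fx$g$dosages, sd2)$raw, 3 * sc1$raw,
               tolerance = 1e-12)
  # permuting participants permutes scores identically
  idx <- sample(1200)
  expect_equal(build_score(fx$g$dosages[idx, ], sd1)$raw, sc1$raw[idx])
  # a missing variant is a named failure
  expect_error(build_score(fx$g$dosages[, -match(sd1$selected_variants[1],
                                                 colnames(fx$g$dosages))], sd1),
               sd1$selected_variants[1], fixed = TRUE)
})

test_that("external-weights mode reproduces build_score on the same list", {
  spec <- sel_spec()
  fx <- sim_selection(spec, n = 1500, seed = 31)
  sd1 <- conditional_select_variants(fx$g$dosages, spec, fx$ldlc, fx$covs)
  path <- tempfile(fileext = ".json")
  write_score_definition(sd1, path)
  ext <- read_score_definition(path)
  expect_equal(build_score(fx$g$dosages, ext)$raw,
               build_score(fx$g$dosages, sd1)$raw, tolerance = 1e-12)
})

test_that("score associations scale linearly and recover generative effects", {
  sim <- simulate_cohort(small_params(seed = 61L), compute_truth = FALSE)
  sel <- sim$selection
  covs <- cbind(age = sel$age, sex_male = as.numeric(sel$sex == "male"),
                sel$ancestry_pcs)
  sd1 <- conditional_select_variants(sel$dosages, sel$variant_meta,
                                     sel$ldl_c, covs, gene = "HMGCR")
  built <- build_score(sim$genotypes$dosages, sd1)
  adf <- make_analysis_df(sim, c("LDL-C", "S-VLDL-P"))
  a2 <- score_association(adf, "LDL-C", built$standardized,
                          ancestry_pcs = sim$genotypes$ancestry_pcs)
  a1 <- score_association(adf, "LDL-C", built$standardized,
                          ancestry_pcs = sim$genotypes$ancestry_pcs,
                          scale_sd = 1)
  expect_equal(a2$estimate, 2 * a1$estimate, tolerance = 1e-12)
  expect_equal(a2$se, 2 * a1$se, tolerance = 1e-12)
  expect_equal(a2$p, a1$p)
  # higher score = more LDL-lowering alleles = lower LDL-related markers
  expect_lt(a2$estimate, 0)

  # shuffled score is null
  set.seed(8)
  null <- score_association(adf, "LDL-C", sample(built$standardized),
                            ancestry_pcs = sim$genotypes$ancestry_pcs)
  expect_lt(abs(null$estimate), 4 * null$se)
})

test_that("sum scores commute and stratified analysis splits at the median", {
  spec <- sel_spec()
  fx <- sim_selection(spec, n = 1000, seed = 41)
  sd1 <- conditional_select_variants(fx$g$dosages, spec, fx$ldlc, fx$covs)
  s1 <- build_score(fx$g$dosages, sd1)
  sd2 <- sd1; sd2$weights <- sd1$weights / 2
  s2 <- build_score(fx$g$dosages, sd2)
  expect_equal(sum_scores(s1, s2)$raw, sum_scores(s2, s1)$raw)
  expect_equal(sum_scores(s1, s2)$raw, s1$raw + s2$raw)
  expect_error(sum_scores(s1, list(raw = 1:3)), "participant")

  sim <- simulate_cohort(small_params(seed = 71L), compute_truth = FALSE)
  adf <- make_analysis_df(sim, "LDL-C")
  set.seed(1)
  score <- rnorm(nrow(adf))
  out <- stratified_hlf_analysis(adf, "LDL-C", score)
  expect_equal(nrow(out$strata), 2)
  expect_true(out$p_interaction > 0 && out$p_interaction <= 1)
  # median split sizes differ by at most 1
  med <- median(score)
  expect_lte(abs(sum(score < med) - sum(score >= med)), 1)
  # inert stratification: estimates agree within sampling error
  se_pool <- sqrt(sum(out$strata$se^2))
  expect_lt(abs(diff(out$strata$estimate)), 4 * se_pool)
})
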