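# Synthetic nested case-control generator. Emulates the structure the
# analysis assumes: five correlated healthy-lifestyle factors driven by
# age/sex/education through a Gaussian copula, a factor-structured lipidomic
# panel influenced by lifestyle and genotype, LD-structured genotypes with
# LDL-C effects, logistic CHD/stroke outcomes with direct and mediated
# lifestyle effects, and frequency-matched control sampling. Ground-truth
# mediation effects are computed from the generative parameters by numerical
# integration, so every downstream stage is testable without real data.

#' Marker names of the synthetic lipidomic panel
#'
#' Sixty-one lipoprotein/lipid measures in the style of a targeted NMR
#' platform: size-specific VLDL/IDL/LDL/HDL particle concentrations, mean
#' particle diameters, apolipoproteins, and cholesterol/triglyceride
#' content of the subfractions plus serum totals.
#' @return Character vector of length 61.
#' @export
nmr_lipid_markers <- function() {
  vldl <- c("XXL", "XL", "L", "M", "S", "XS")
  ldl <- c("L", "M", "S")
  hdl <- c("XL", "L", "M", "S")
  c(
    paste0(vldl, "-VLDL-P"), "IDL-P", paste0(ldl, "-LDL-P"),
    paste0(hdl, "-HDL-P"),
    "VLDL-D", "LDL-D", "HDL-D",
    "ApoA1", "ApoB", "ApoB/ApoA1",
    paste0(vldl, "-VLDL-C"), "IDL-C", paste0(ldl, "-LDL-C"),
    paste0(hdl, "-HDL-C"), "HDL2-C", "HDL3-C",
    "Total-C", "Remnant-C", "non-HDL-C",
    paste0(vldl, "-VLDL-TG"), "IDL-TG", paste0(ldl, "-LDL-TG"),
    paste0(hdl, "-HDL-TG"), "Total-TG",
    "VLDL-C", "LDL-C", "HDL-C",
    "Esterified-C", "Free-C", "Total-PL", "Sphingomyelins"
  )
}

# Coarse class of each marker, used to assemble default effect patterns.
.marker_class <- function(markers) {
  cls <- rep("other", length(markers))
  cls[grepl("VLDL|Total-TG|Remnant", markers)] <- "vldl"
  cls[grepl("IDL", markers) & !grepl("VLDL", markers)] <- "idl"
  cls[grepl("LDL", markers) & !grepl("VLDL|IDL|HDL", markers)] <- "ldl"
  cls[grepl("HDL", markers) & !grepl("non-HDL", markers)] <- "hdl"
  cls[markers == "non-HDL-C"] <- "ldl"
  cls[markers == "ApoB"] <- "ldl"
  cls[markers == "ApoA1"] <- "hdl"
  cls[markers == "ApoB/ApoA1"] <- "ratio"
  cls
}

# Default per-HLF effect (SD units) of each lifestyle factor on each marker;
# healthy factors lower VLDL/LDL/TG-related measures and raise HDL-related
# ones. Magnitudes are set so the 4-5 vs 0-1 HLF contrast (~3.5 factors)
# spans roughly -0.5 SD for the VLDL axis and +0.35 SD for large HDL, the
# scale of the strongest reported lifestyle-lipidome differences.
.default_lifestyle_effects <- function(markers) {
  cls <- .marker_class(markers)
  tg <- grepl("-TG$", markers)
  e <- numeric(length(markers))
  e[cls == "vldl"] <- -0.15
  e[cls == "idl"] <- -0.06
  e[cls == "ldl"] <- -0.06
  e[cls == "hdl"] <- 0.10
  e[cls == "hdl" & tg] <- -0.08
  e[cls == "ratio"] <- -0.13
  e[cls == "other"] <- -0.06
  # homogeneous across the five factors so the per-count mediator slope is
  # exactly the per-factor effect (keeps ground truth in closed form)
  m <- matrix(rep(e, 5L), ncol = 5L,
              dimnames = list(markers,
                              c("never_smoking", "moderate_alcohol",
                                "healthy_diet", "physically_active",
                                "healthy_adiposity")))
  m
}

# Default factor loadings: three latent axes (VLDL/TG, LDL/ApoB, HDL).
# Loadings are high because NMR lipoprotein measures are near-collinear
# (subfraction totals are sums of each other): a handful of components
# carries ~95%+ of the panel variance, as the joint-PC mediation step
# assumes.
.default_loadings <- function(markers) {
  cls <- .marker_class(markers)
  tg <- grepl("-TG$", markers)
  L <- matrix(0, length(markers), 3L,
              dimnames = list(markers, c("vldl_tg_axis", "ldl_axis", "hdl_axis")))
  L[cls == "vldl", 1L] <- 0.98
  L[cls %in% c("idl", "ldl"), 2L] <- 0.98
  L[cls == "hdl" & !tg, 3L] <- 0.98
  L[cls == "hdl" & tg, 1L] <- 0.78
  L[cls == "hdl" & tg, 3L] <- 0.60
  L[cls == "ratio", 2L] <- 0.76
  L[cls == "ratio", 3L] <- -0.63
  L[cls == "other", 1L] <- 0.70
  L[cls == "other", 2L] <- 0.69
  L
}

#' Default variant specification for two synthetic gene windows
#'
#' Two 500-kb-style gene windows ("HMGCR"-like and "ACLY"-like), each with 25
#' variants in five LD blocks of five; a small number of causal variants per
#' window carry LDL-C effects (mmol/l per alternative allele).
#' @return Data frame: `id`, `chrom`, `pos`, `ref`, `alt`, `allele_freq`,
#'   `ldl_effect`, `ld_block_id`, `gene_window`.
#' @export
default_variant_spec <- function() {
  mk <- function(gene, chrom, base_pos, causal_idx, causal_effects, seed_freq) {
    n <- 25L
    freq <- round(seq(0.10, 0.45, length.out = n)[order(seed_freq)], 3)
    eff <- numeric(n)
    eff[causal_idx] <- causal_effects
    data.frame(
      id = sprintf("%s_v%02d", gene, seq_len(n)),
      chrom = chrom,
      pos = base_pos + seq_len(n) * 4000L,
      ref = "A", alt = "G",
      allele_freq = freq,
      ldl_effect = eff,
      ld_block_id = paste0(gene, "_b", rep(1:5, each = 5L)),
      gene_window = gene
    )
  }
  rbind(
    mk("HMGCR", "chr5", 74600000L, c(3L, 12L), c(0.080, 0.050), seq_len(25L)),
    mk("ACLY", "chr17", 40000000L, c(8L, 22L), c(0.055, 0.040), 25L:1L)
  )
}

#' Default outcome-model parameters
#'
#' Logistic CHD model: a protective direct effect per additional HLF, log-ORs
#' per SD for a sparse set of causal metabolites, and age/sex effects. The
#' intercept is calibrated at simulation time to the target marginal risk.
#' @param markers Marker names (to validate the causal set).
#' @return List with `intercept` (NA = calibrate), `direct_hlf_log_or`,
#'   `metabolite_log_ors` (named), `covariate_log_ors`.
#' @export
default_outcome_model <- function(markers = nmr_lipid_markers()) {
  mets <- c("S-VLDL-P" = 0.22, "ApoB/ApoA1" = 0.24, "L-HDL-P" = -0.15)
  stopifnot(all(names(mets) %in% markers))
  list(
    intercept = NA_real_,
    direct_hlf_log_or = -0.20,
    metabolite_log_ors = mets,
    covariate_log_ors = c(age_z = 0.45, sex_male = 0.50)
  )
}

#' Generative parameters for the synthetic nested case-control study
#'
#' Bundles and validates everything the generator needs. Defaults emulate the
#' study conditions: a source cohort large enough to yield 927 CHD cases,
#' 1114 ischemic-stroke cases, 1127 intracerebral-hemorrhage cases and 1513
#' frequency-matched controls at a ~2% marginal CHD risk, five HLFs with
#' baseline-table-like prevalences (activity is structurally ~50% because the
#' flag is defined against the realized sex-specific median), a 61-marker
#' factor-structured lipidome, and two gene windows of LD-structured variants
#' for a disjoint selection cohort of 13,060.
#'
#' @param n_source Source-cohort size.
#' @param hlf_prevalences Length-5 probabilities (smoking, alcohol, diet,
#'   activity, adiposity).
#' @param hlf_latent_corr Pairwise latent (copula) correlation of the HLFs.
#' @param lifestyle_covariate_effects 3 x 5 matrix: effects of standardized
#'   age, female sex, and standardized education on each HLF's latent
#'   propensity.
#' @param marker_names Metabolite names.
#' @param lifestyle_effect_matrix markers x 5 effects (SD per factor).
#' @param metabolite_loading_matrix markers x factors loadings.
#' @param variant_spec Variant table as in [default_variant_spec()].
#' @param ld_decay Within-block latent haplotype correlation decay per
#'   position step.
#' @param metabolite_genetic_scale SD change in IDL/LDL/ApoB-related markers
#'   per mmol/l of a variant's LDL-C effect.
#' @param outcome_model As in [default_outcome_model()].
#' @param chd_marginal_risk,stroke_marginal_risks Target marginal risks used
#'   to calibrate the outcome intercepts (rare-outcome regime).
#' @param n_cases_chd,n_cases_stroke,n_controls Nested case-control sizes
#'   (`n_cases_stroke` = c(ischemic, intracerebral)).
#' @param n_selection Disjoint genetic-score selection cohort size.
#' @param n_duplicates Participants with blind duplicate NMR measurements.
#' @param duplicate_cv Measurement CV for duplicate pairs (proportion).
#' @param seed Integer seed.
#' @return Object of class `generative_params` (a validated list).
#' @export
generative_params <- function(
    n_source = 60000L,
    hlf_prevalences = c(never_smoking = 0.58, moderate_alcohol = 0.10,
                        healthy_diet = 0.45, physically_active = 0.50,
                        healthy_adiposity = 0.70),
    hlf_latent_corr = 0.15,
    lifestyle_covariate_effects = rbind(
      age_z = c(-0.30, -0.10, 0.10, -0.20, -0.25),
      female = c(1.20, -0.60, 0.20, 0.10, 0.25),
      education_z = c(0.15, 0.10, 0.25, -0.10, 0.05)),
    marker_names = nmr_lipid_markers(),
    lifestyle_effect_matrix = .default_lifestyle_effects(marker_names),
    metabolite_loading_matrix = .default_loadings(marker_names),
    variant_spec = default_variant_spec(),
    ld_decay = 0.85,
    metabolite_genetic_scale = 1.3,
    outcome_model = default_outcome_model(marker_names),
    chd_marginal_risk = 0.02,
    stroke_marginal_risks = c(ischemic = 0.024, ich = 0.024),
    n_cases_chd = 927L,
    n_cases_stroke = c(ischemic = 1114L, ich = 1127L),
    n_controls = 1513L,
    n_selection = 13060L,
    n_duplicates = 137L,
    duplicate_cv = 0.05,
    seed = 20260101L) {
  stopifnot(length(hlf_prevalences) == 5L,
            all(hlf_prevalences > 0 & hlf_prevalences < 1),
            abs(hlf_latent_corr) < 1,
            is.matrix(lifestyle_covariate_effects),
            dim(lifestyle_covariate_effects)[2L] == 5L,
            nrow(lifestyle_effect_matrix) == length(marker_names),
            ncol(lifestyle_effect_matrix) == 5L,
            nrow(metabolite_loading_matrix) == length(marker_names),
            all(variant_spec$allele_freq > 0.01 & variant_spec$allele_freq < 0.99),
            ld_decay >= 0 && ld_decay <= 1,
            chd_marginal_risk > 0 && chd_marginal_risk < 1,
            all(stroke_marginal_risks >= 0 & stroke_marginal_risks < 1),
            n_cases_chd >= 0, n_controls >= 0, n_selection >= 0)
  stopifnot(all(names(outcome_model$metabolite_log_ors) %in% marker_names))
  # feasibility of the requested nested case-control counts, in expectation
  expected_chd <- n_source * chd_marginal_risk * 0.9
  if (n_cases_chd > expected_chd) {
    stop(sprintf(paste0("generative_params: %d CHD cases requested but only ",
                        "~%.0f expected eligible at risk %.3f and n_source %d"),
                 n_cases_chd, expected_chd, chd_marginal_risk, n_source),
         call. = FALSE)
  }
  expected_controls <- n_source *
    (1 - chd_marginal_risk - sum(stroke_marginal_risks)) * 0.9
  if (n_controls > expected_controls) {
    stop("generative_params: more controls requested than expected eligible ",
         "non-cases", call. = FALSE)
  }
  structure(list(
    n_source = as.integer(n_source),
    hlf_prevalences = hlf_prevalences,
    hlf_latent_corr = hlf_latent_corr,
    lifestyle_covariate_effects = lifestyle_covariate_effects,
    marker_names = marker_names,
    lifestyle_effect_matrix = lifestyle_effect_matrix,
    metabolite_loading_matrix = metabolite_loading_matrix,
    variant_spec = variant_spec,
    ld_decay = ld_decay,
    metabolite_genetic_scale = metabolite_genetic_scale,
    outcome_model = outcome_model,
    chd_marginal_risk = chd_marginal_risk,
    stroke_marginal_risks = stroke_marginal_risks,
    n_cases_chd = as.integer(n_cases_chd),
    n_cases_stroke = vapply(n_cases_stroke, as.integer, integer(1)),
    n_controls = as.integer(n_controls),
    n_selection = as.integer(n_selection),
    n_duplicates = as.integer(n_duplicates),
    duplicate_cv = duplicate_cv,
    seed = as.integer(seed)
  ), class = "generative_params")
}

# ---- genotypes --------------------------------------------------------------

#' Simulate LD-structured genotype dosages
#'
#' Latent multivariate-Gaussian haplotype model thresholded to the allele
#' frequency: within an LD block the latent correlation between variants i
#' and j is `ld_decay^|i-j|`; across blocks variants are independent. Two
#' independent haplotypes per participant give Hardy-Weinberg genotype
#' frequencies; dosages are in 0/1/2.
#'
#' @param n Number of participants.
#' @param variant_spec Variant table (id, allele_freq, ld_block_id, ...).
#' @param seed Integer seed.
#' @param ld_decay Within-block correlation decay (1 = perfectly linked).
#' @return List with `dosages` (n x variants integer matrix, columns named by
#'   variant id) and `variant_meta` (the variant table passed in).
#' @export
simulate_genotypes <- function(n, variant_spec, seed, ld_decay = 0.85) {
  stopifnot(nrow(variant_spec) >= 1L, n >= 1L)
  set.seed(as.integer(seed))
  k <- nrow(variant_spec)
  dos <- matrix(0L, n, k, dimnames = list(NULL, variant_spec$id))
  for (blk in unique(variant_spec$ld_block_id)) {
    idx <- which(variant_spec$ld_block_id == blk)
    kb <- length(idx)
    C <- ld_decay^abs(outer(seq_len(kb), seq_len(kb), "-"))
    U <- chol(C + diag(1e-10, kb))
    thr <- stats::qnorm(variant_spec$allele_freq[idx])
    for (h in 1:2) {
      Z <- matrix(stats::rnorm(n * kb), n, kb) %*% U
      dos[, idx] <- dos[, idx] +
        (Z < matrix(thr, n, kb, byrow = TRUE))
    }
  }
  storage.mode(dos) <- "integer"
  list(dosages = dos, variant_meta = variant_spec)
}

# ---- lifestyle raw-field construction ---------------------------------------

# Weighted subsets without replacement via exponential keys; returns an
# n x length(w) logical matrix whose i-th row has s_vec[i] TRUE entries.
.weighted_subset_flags <- function(n, s_vec, w) {
  k <- length(w)
  keys <- matrix(stats::runif(n * k), n, k)^
    (1 / matrix(w, n, k, byrow = TRUE))
  out <- matrix(FALSE, n, k)
  for (iter in seq_len(max(s_vec, 0L))) {
    pick <- max.col(keys)
    rows <- which(s_vec >= iter)
    out[cbind(rows, pick[rows])] <- TRUE
    keys[cbind(seq_len(n), pick)] <- -Inf
  }
  out
}

# Latent HLF propensities: covariate effects + copula noise; flags by sample
# quantile thresholding so marginal prevalences hit their targets.
.hlf_latents <- function(covs, params) {
  n <- nrow(covs)
  rho <- params$hlf_latent_corr
  R <- matrix(rho, 5L, 5L); diag(R) <- 1
  Z <- matrix(stats::rnorm(n * 5L), n, 5L) %*% chol(R)
  X <- cbind(age_z = (covs$age - mean(covs$age)) / stats::sd(covs$age),
             female = as.numeric(covs$sex == "female"),
             education_z = (covs$education_num - mean(covs$education_num)) /
               stats::sd(covs$education_num))
  G <- X %*% params$lifestyle_covariate_effects + Z
  colnames(G) <- names(params$hlf_prevalences)
  G
}

# Construct raw lifestyle fields so that classify_hlf() reproduces the
# intended flags; the generator then derives the final flags by actually
# running classify_hlf (single source of truth).
.raw_lifestyle_fields <- function(covs, G, params) {
  n <- nrow(covs)
  p <- params$hlf_prevalences
  intend <- vapply(1:5, function(f) {
    G[, f] >= stats::quantile(G[, f], 1 - p[f], names = FALSE)
  }, logical(n))

  smoking_status <- ifelse(intend[, 1L], "never",
                           ifelse(stats::runif(n) < 0.8, "current", "former"))

  alcohol_freq <- character(n)
  alcohol_g_day <- numeric(n)
  mod <- intend[, 2L]
  weekly <- mod & stats::runif(n) < 0.7
  alcohol_freq[weekly] <- "weekly"
  alcohol_g_day[weekly] <- stats::runif(sum(weekly), 5, 60)
  daily_mod <- mod & !weekly
  alcohol_freq[daily_mod] <- "daily"
  alcohol_g_day[daily_mod] <- stats::runif(sum(daily_mod), 2, 29.9)
  u_non <- stats::runif(n)
  nonreg <- !mod
  nv <- nonreg & u_non < 0.60
  mo <- nonreg & u_non >= 0.60 & u_non < 0.72
  hv <- nonreg & u_non >= 0.72
  alcohol_freq[nv] <- "never"
  alcohol_freq[mo] <- "monthly"
  alcohol_g_day[mo] <- stats::runif(sum(mo), 5, 80)
  alcohol_freq[hv] <- "daily"
  alcohol_g_day[hv] <- stats::runif(sum(hv), 30, 120)

  diet_score <- integer(n)
  hd <- intend[, 3L]
  diet_score[hd] <- sample(4:6, sum(hd), replace = TRUE,
                           prob = c(0.70, 0.25, 0.05))
  diet_score[!hd] <- sample(0:3, sum(!hd), replace = TRUE,
                            prob = c(0.08, 0.22, 0.35, 0.35))
  comp_pop <- c(veg_daily = 0.92, fruit_daily = 0.12, red_meat_lt7 = 0.70,
                soybean_ge4 = 0.08, fish_ge1 = 0.30, coarse_grain_ge4 = 0.22)
  diet <- .weighted_subset_flags(n, diet_score, comp_pop)
  colnames(diet) <- names(comp_pop)

  # activity: map the latent percentile within sex to MET-hours; the active
  # flag falls out of the realized sex-specific median in classify_hlf
  activity_met_h <- numeric(n)
  for (s in c("male", "female")) {
    idx <- which(covs$sex == s)
    u <- (rank(G[idx, 4L]) - 0.5) / length(idx)
    mlog <- if (s == "male") log(21) else log(17)
    activity_met_h[idx] <- stats::qlnorm(u, meanlog = mlog, sdlog = 0.45)
  }

  bmi <- numeric(n)
  wc <- numeric(n)
  ad <- intend[, 5L]
  n_ad <- sum(ad)
  bmi[ad] <- .rtruncnorm(n_ad, 23.2, 2.2, 18.55, 27.85)
  wc[ad] <- ifelse(covs$sex[ad] == "male",
                   .rtruncnorm(n_ad, 80, 5.5, 62, 89.5),
                   .rtruncnorm(n_ad, 74, 5.5, 58, 84.5))
  n_un <- sum(!ad)
  u_un <- stats::runif(n_un)
  bmi_un <- ifelse(u_un < 0.70, .rtruncnorm(n_un, 30.5, 1.8, 28.0, 45),
                   ifelse(u_un < 0.85, .rtruncnorm(n_un, 17.2, 0.8, 14, 18.45),
                          .rtruncnorm(n_un, 24.5, 2.0, 18.55, 27.85)))
  wc_un <- ifelse(u_un < 0.85,
                  ifelse(covs$sex[!ad] == "male",
                         .rtruncnorm(n_un, 98, 5, 85, 130),
                         .rtruncnorm(n_un, 93, 5, 80, 125)),
                  ifelse(covs$sex[!ad] == "male",
                         .rtruncnorm(n_un, 95, 3, 90.2, 120),
                         .rtruncnorm(n_un, 90, 3, 85.2, 115)))
  bmi[!ad] <- bmi_un
  wc[!ad] <- wc_un

  data.frame(smoking_status = smoking_status, alcohol_freq = alcohol_freq,
             alcohol_g_day = alcohol_g_day, diet,
             activity_met_h = activity_met_h, bmi = bmi, wc = wc)
}

# ---- source cohort ----------------------------------------------------------

.simulate_covariates <- function(n, seed) {
  set.seed(seed)
  data.frame(
    participant_id = sprintf("P%06d", seq_len(n)),
    age = round(.rtruncnorm(n, 50, 10.5, 30, 79), 1),
    sex = ifelse(stats::runif(n) < 0.55, "female", "male"),
    area = paste0("A", sample.int(10L, n, replace = TRUE)),
    education = sample(c("no_formal_or_primary", "middle_or_high",
                         "technical_college_or_higher"), n, replace = TRUE,
                       prob = c(0.45, 0.40, 0.15)),
    married = stats::runif(n) < 0.93,
    fasting_ge_8h = stats::runif(n) < 0.60,
    prevalent_hypertension = stats::runif(n) < 0.30,
    prevalent_diabetes = stats::runif(n) < 0.06,
    prevalent_cvd_or_cancer = stats::runif(n) < 0.05,
    statin_use = stats::runif(n) < 0.02
  )
}

.education_num <- function(education) {
  match(education, c("no_formal_or_primary", "middle_or_high",
                     "technical_college_or_higher"))
}

# Calibrate a logistic intercept to a target marginal risk given the rest of
# the linear predictor.
.calibrate_intercept <- function(lp, target) {
  if (target <= 0) return(-Inf)
  stats::uniroot(function(t0) mean(stats::plogis(t0 + lp)) - target,
                 interval = c(-40, 10), tol = 1e-10)$root
}

#' Simulate the full synthetic study
#'
#' Generates the source cohort (covariates, raw lifestyle fields, HLF flags
#' via [classify_hlf()], lipidomic panel, genotypes, LDL-C, outcomes), draws
#' the nested case-control sample by frequency matching, generates a disjoint
#' genetic-score selection cohort, duplicate QC pairs, and the ground-truth
#' mediation effects. Deterministic given the parameter seed: per-stage
#' substreams are derived from it so stages can be regenerated in isolation.
#'
#' @param params A [generative_params()] object.
#' @param compute_truth Compute [true_mediation_effects()] (set FALSE in
#'   tight simulation loops and compute once per parameter set instead).
#' @param truth_draws Monte-Carlo draws for the ground-truth integration.
#' @param keep_source Also return the full source cohort (for diagnostics).
#' @return List of class `lipidmed_simulation`: `cohort` (nested
#'   case-control table with raw fields, HLF columns and `status`),
#'   `metabolites` (aligned raw concentration-like matrix), `duplicates`
#'   (QC pairs), `genotypes` (dosages, variant_meta, ancestry_pcs for the
#'   analysis sample), `selection` (disjoint cohort for variant selection:
#'   dosages, ancestry_pcs, age, sex, ldl_c), `truth`, and optionally
#'   `source`.
#' @export
simulate_cohort <- function(params, compute_truth = TRUE, truth_draws = 1e6,
                            keep_source = FALSE) {
  stopifnot(inherits(params, "generative_params"))
  n <- params$n_source
  covs <- .simulate_covariates(n, .substream_seed(params$seed, "covariates"))
  covs$education_num <- .education_num(covs$education)

  set.seed(.substream_seed(params$seed, "lifestyle"))
  G <- .hlf_latents(covs, params)
  raw <- .raw_lifestyle_fields(covs, G, params)
  source_tbl <- cbind(covs, raw)
  profile <- classify_hlf(source_tbl)
  flag_cols <- c("never_smoking", "moderate_alcohol", "healthy_diet",
                 "physically_active", "healthy_adiposity")
  source_tbl <- cbind(source_tbl,
                      profile[, c(flag_cols, "diet_score", "alcohol_class",
                                  "hlf_count", "hlf_group", "hlf_group2")])

  # genotypes + ancestry PCs for source and the disjoint selection cohort
  geno <- simulate_genotypes(n + params$n_selection, params$variant_spec,
                             .substream_seed(params$seed, "genotypes"),
                             ld_decay = params$ld_decay)
  set.seed(.substream_seed(params$seed, "ldlc"))
  pcs <- matrix(stats::rnorm((n + params$n_selection) * 10L), ncol = 10L,
                dimnames = list(NULL, paste0("ancestryPC", 1:10)))
  ldl_genetic <- as.numeric(geno$dosages %*% params$variant_spec$ldl_effect)
  age_all <- c(covs$age, round(.rtruncnorm(params$n_selection, 50, 10.5, 30, 79), 1))
  sex_all <- c(covs$sex,
               ifelse(stats::runif(params$n_selection) < 0.55, "female", "male"))
  count_all <- c(source_tbl$hlf_count, stats::rbinom(params$n_selection, 5L, 0.47))
  ldl_c <- pmax(0.3, 2.3 + ldl_genetic - 0.04 * count_all +
                  pcs[, 1:3] %*% c(0.03, -0.02, 0.02) +
                  stats::rnorm(n + params$n_selection, 0, 0.55))
  ldl_c <- as.numeric(ldl_c)

  # lipidomic panel (source only): lifestyle + genetic + latent factors
  set.seed(.substream_seed(params$seed, "metabolites"))
  flags_mat <- as.matrix(source_tbl[, flag_cols]) * 1
  L <- params$metabolite_loading_matrix
  resid_sd <- sqrt(pmax(1 - rowSums(L^2), 0.02))
  genetic_eff <- .metabolite_genetic_effects(params)
  F_scores <- matrix(stats::rnorm(n * ncol(L)), n, ncol(L))
  M <- flags_mat %*% t(params$lifestyle_effect_matrix) +
    F_scores %*% t(L) +
    geno$dosages[seq_len(n), , drop = FALSE] %*% t(genetic_eff) +
    matrix(stats::rnorm(n * nrow(L)), n, nrow(L)) %*% diag(resid_sd)
  colnames(M) <- params$marker_names

  # outcomes: rare logistic CHD with direct + mediated lifestyle effects;
  # strokes carried for design realism but modelled without mediation
  set.seed(.substream_seed(params$seed, "outcome"))
  omod <- params$outcome_model
  theta_m <- stats::setNames(numeric(length(params$marker_names)),
                             params$marker_names)
  theta_m[names(omod$metabolite_log_ors)] <- omod$metabolite_log_ors
  age_z <- (covs$age - 50) / 10.5
  lp_chd <- omod$direct_hlf_log_or * source_tbl$hlf_count +
    as.numeric(M %*% theta_m) +
    omod$covariate_log_ors[["age_z"]] * age_z +
    omod$covariate_log_ors[["sex_male"]] * (covs$sex == "male")
  theta0 <- if (is.na(omod$intercept)) {
    .calibrate_intercept(lp_chd, params$chd_marginal_risk)
  } else omod$intercept
  y_chd <- stats::rbinom(n, 1L, stats::plogis(theta0 + lp_chd))
  lp_str <- 0.5 * age_z + 0.3 * (covs$sex == "male") -
    0.08 * source_tbl$hlf_count
  y_is <- stats::rbinom(n, 1L, stats::plogis(
    .calibrate_intercept(lp_str, params$stroke_marginal_risks[["ischemic"]]) + lp_str))
  y_ich <- stats::rbinom(n, 1L, stats::plogis(
    .calibrate_intercept(lp_str, params$stroke_marginal_risks[["ich"]]) + lp_str))
  status <- rep("none", n)
  pos <- cbind(y_chd, y_is, y_ich) == 1L
  lab <- c("chd_case", "ischemic_stroke_case", "ich_case")
  npos <- rowSums(pos)
  one <- which(npos == 1L)
  status[one] <- lab[max.col(pos[one, , drop = FALSE])]
  multi <- which(npos > 1L)
  for (i in multi) { # first-occurring disease: uniform among the events
    status[i] <- sample(lab[pos[i, ]], 1L)
  }
  source_tbl$status <- status
  source_tbl$eligible <- !source_tbl$prevalent_cvd_or_cancer &
    !source_tbl$statin_use

  # nested case-control sample
  sampled <- sample_nested_case_control(
    source_tbl,
    n_cases_by_type = c(chd_case = params$n_cases_chd,
                        ischemic_stroke_case = params$n_cases_stroke[["ischemic"]],
                        ich_case = params$n_cases_stroke[["ich"]]),
    n_controls = params$n_controls,
    seed = .substream_seed(params$seed, "sampling"),
    strict = FALSE)
  rows <- match(sampled$participant_id, source_tbl$participant_id)
  sampled$status_cc <- ifelse(sampled$status == "control", "control", "case")
  sampled$ldl_c <- ldl_c[rows]

  metabolites <- M[rows, , drop = FALSE]
  rownames(metabolites) <- sampled$participant_id

  # blind duplicate pairs with multiplicative measurement error
  duplicates <- NULL
  if (params$n_duplicates > 0L) {
    set.seed(.substream_seed(params$seed, "duplicates"))
    dup_idx <- sample.int(nrow(metabolites), min(params$n_duplicates,
                                                 nrow(metabolites)))
    base <- abs(metabolites[dup_idx, , drop = FALSE]) + 2
    # two-replicate CVs are half-normal with mean sd*sqrt(2/pi), so the
    # measurement noise is scaled for the summary statistic to land on the
    # configured duplicate_cv; markers differ in precision (lognormal
    # multiplier, median 1), spreading the across-marker IQR as real
    # platforms do
    marker_mult <- exp(stats::rnorm(ncol(base), 0, 0.45))
    noise_sd <- matrix(params$duplicate_cv / sqrt(2 / pi) * marker_mult,
                       nrow(base), ncol(base), byrow = TRUE)
    noise <- function() matrix(stats::rnorm(length(base), 1, noise_sd),
                               nrow(base), ncol(base))
    duplicates <- data.frame(
      marker = rep(colnames(base), each = nrow(base)),
      value1 = as.numeric(base * noise()),
      value2 = as.numeric(base * noise())
    )
  }

  truth <- if (compute_truth) {
    true_mediation_effects(params, n_draws = truth_draws)
  } else NULL

  out <- list(
    cohort = sampled,
    metabolites = metabolites,
    duplicates = duplicates,
    genotypes = list(dosages = geno$dosages[rows, , drop = FALSE],
                     variant_meta = geno$variant_meta,
                     ancestry_pcs = pcs[rows, , drop = FALSE]),
    selection = list(
      dosages = geno$dosages[n + seq_len(params$n_selection), , drop = FALSE],
      variant_meta = geno$variant_meta,
      ancestry_pcs = pcs[n + seq_len(params$n_selection), , drop = FALSE],
      age = age_all[n + seq_len(params$n_selection)],
      sex = sex_all[n + seq_len(params$n_selection)],
      ldl_c = ldl_c[n + seq_len(params$n_selection)]),
    truth = truth,
    params = params
  )
  if (keep_source) out$source <- source_tbl
  class(out) <- "lipidmed_simulation"
  out
}

# Per-allele SD effects of variants on the metabolite panel: causal variants
# shift IDL/LDL/ApoB-related markers in proportion to their LDL-C effect.
.metabolite_genetic_effects <- function(params) {
  cls <- .marker_class(params$marker_names)
  affected <- cls %in% c("idl", "ldl") | params$marker_names %in%
    c("Total-C", "ApoB/ApoA1", "LDL-C", "non-HDL-C")
  eff <- outer(as.numeric(affected) * params$metabolite_genetic_scale,
               params$variant_spec$ldl_effect)
  dimnames(eff) <- list(params$marker_names, params$variant_spec$id)
  eff
}

#' Frequency-matched nested case-control sampling
#'
#' Draws the requested numbers of cases of each type and controls from an
#' eligible source cohort. Controls are sampled without replacement so that
#' their joint distribution over the matching strata (5-year age bin, sex,
#' study area) matches the combined-case distribution in frequency (largest
#' remainder allocation), not by 1:1 pairing. Eligibility (no prevalent
#' CVD/cancer, no statin use) is enforced for cases and controls.
#'
#' @param source Source cohort with `status`, `age`, `sex`, `area`, and an
#'   `eligible` flag (all TRUE if absent).
#' @param n_cases_by_type Named counts, e.g. `c(chd_case = 927, ...)`.
#' @param n_controls Number of common controls.
#' @param matching_vars Stratification columns; `age` is binned internally.
#' @param seed Integer seed.
#' @param strict If TRUE (default), an exhausted control stratum is an error
#'   naming the stratum; if FALSE, the shortfall is redistributed
#'   proportionally across strata with remaining capacity (with a message),
#'   and only a globally insufficient control pool is an error.
#' @return The sampled rows with `status` set to "control" for controls.
#' @export
sample_nested_case_control <- function(source, n_cases_by_type, n_controls,
                                       matching_vars = c("age_bin", "sex", "area"),
                                       seed = 1L, strict = TRUE) {
  .require_columns(source, c("status", "age", "sex", "area"),
                   "sample_nested_case_control")
  if (!"eligible" %in% names(source)) source$eligible <- TRUE
  set.seed(as.integer(seed))
  src <- source
  src$age_bin <- cut(src$age, breaks = seq(30, 80, by = 5),
                     right = FALSE, include.lowest = TRUE)

  case_rows <- integer(0)
  for (tp in names(n_cases_by_type)) {
    avail <- which(src$status == tp & src$eligible)
    need <- n_cases_by_type[[tp]]
    if (length(avail) < need) {
      stop(sprintf(paste0("sample_nested_case_control: %d %s requested but ",
                          "only %d eligible (shortfall %d)"),
                   need, tp, length(avail), need - length(avail)),
           call. = FALSE)
    }
    case_rows <- c(case_rows, sample(avail, need))
  }

  strat <- interaction(src[matching_vars], drop = FALSE, sep = "|")
  case_tab <- table(strat[case_rows])
  case_tab <- case_tab[case_tab > 0L]
  alloc <- n_controls * as.numeric(case_tab) / sum(case_tab)
  n_alloc <- floor(alloc)
  rem <- alloc - n_alloc
  short <- n_controls - sum(n_alloc)
  if (short > 0L) {
    bump <- order(rem, decreasing = TRUE)[seq_len(short)]
    n_alloc[bump] <- n_alloc[bump] + 1L
  }
  names(n_alloc) <- names(case_tab)

  ctrl_pool <- src$status == "none" & src$eligible
  capacity <- vapply(names(n_alloc), function(stn) {
    sum(ctrl_pool & strat == stn)
  }, numeric(1))
  over <- n_alloc > capacity
  if (any(over)) {
    if (strict) {
      stn <- names(n_alloc)[which(over)[1L]]
      stop(sprintf(paste0("sample_nested_case_control: control stratum '%s' ",
                          "exhausted (%d needed, %d available)"),
                   stn, n_alloc[[stn]], capacity[[stn]]), call. = FALSE)
    }
    if (sum(capacity) < n_controls) {
      stop(sprintf(paste0("sample_nested_case_control: only %d eligible ",
                          "controls across the case strata, %d requested"),
                   sum(capacity), n_controls), call. = FALSE)
    }
    message(sprintf(paste0("sample_nested_case_control: %d stratum/strata ",
                           "exhausted; redistributing %d control(s)"),
                    sum(over), sum(pmax(n_alloc - capacity, 0))))
    # cap at capacity, then refill strata with headroom by largest remainder
    n_alloc <- pmin(n_alloc, capacity)
    while (sum(n_alloc) < n_controls) {
      head_room <- capacity - n_alloc
      target <- n_controls - sum(n_alloc)
      w <- as.numeric(case_tab) * (head_room > 0)
      add_idx <- order(w, decreasing = TRUE)[seq_len(min(target, sum(w > 0)))]
      n_alloc[add_idx] <- n_alloc[add_idx] + 1L
      n_alloc <- pmin(n_alloc, capacity)
    }
  }

  control_rows <- integer(0)
  for (stn in names(n_alloc)) {
    if (n_alloc[[stn]] == 0L) next
    avail <- which(ctrl_pool & strat == stn)
    control_rows <- c(control_rows,
                      if (length(avail) == 1L) avail else
                        sample(avail, n_alloc[[stn]]))
  }

  out <- src[c(case_rows, control_rows), , drop = FALSE]
  out$status[out$status == "none"] <- "control"
  rownames(out) <- NULL
  out
}

#' Ground-truth mediation effects of the generative model
#'
#' Computes the true per-metabolite natural indirect, direct and total
#' effects (log-RR scale, rare-outcome regime) implied by the generative
#' parameters, for the contrast of one additional HLF. The HLF-count /
#' flag joint distribution is integrated numerically from a large
#' Monte-Carlo draw of the copula lifestyle layer; the mediator slope per
#' HLF count is the covariate-partialled regression slope of each
#' metabolite's lifestyle signal on the count. Because all metabolites enter
#' the outcome linearly with Gaussian noise whose covariance does not depend
#' on exposure, the per-metabolite NIE is exactly
#' `theta_2j * b_j * (a - a*)` on the log-RR scale and the total effect is
#' `(direct + sum_j theta_2j b_j)(a - a*)`, so `TE = NDE_j + NIE_j` holds by
#' construction for every marker.
#'
#' @param params A [generative_params()] object with a rare outcome
#'   (marginal risk below 5%; warned otherwise since OR and RR then diverge).
#' @param n_draws Monte-Carlo draws for the lifestyle-layer integration.
#' @param contrast Exposure contrast `a - a*` (default 1 HLF).
#' @return List of class `simulation_truth`: `true_nie_log_or`,
#'   `true_nde_log_or`, `true_te_log_or`, `true_pm` (per marker),
#'   `mediator_slopes`, `causal_variant_ids`, `marginal_risk_rare`.
#' @export
true_mediation_effects <- function(params, n_draws = 1e6, contrast = 1) {
  stopifnot(inherits(params, "generative_params"))
  set.seed(.substream_seed(params$seed, "truth"))
  n <- as.integer(n_draws)
  covs <- data.frame(
    age = .rtruncnorm(n, 50, 10.5, 30, 79),
    sex = ifelse(stats::runif(n) < 0.55, "female", "male"),
    education_num = sample(1:3, n, replace = TRUE, prob = c(0.45, 0.40, 0.15))
  )
  G <- .hlf_latents(covs, params)
  flags <- vapply(1:5, function(f) {
    if (f == 4L) {
      # activity: at/above the realized sex-specific median of the latent
      out <- logical(n)
      for (s in c("male", "female")) {
        idx <- covs$sex == s
        out[idx] <- G[idx, f] >= stats::median(G[idx, f])
      }
      out
    } else {
      G[, f] >= stats::quantile(G[, f], 1 - params$hlf_prevalences[f],
                                names = FALSE)
    }
  }, logical(n))
  count <- rowSums(flags)

  # covariate-partialled slope of each flag on the count (exact integration
  # target of the adjusted mediator model)
  X <- cbind(1, (covs$age - mean(covs$age)) / stats::sd(covs$age),
             covs$sex == "female",
             (covs$education_num - mean(covs$education_num)) /
               stats::sd(covs$education_num))
  qx <- qr(X)
  r_count <- qr.resid(qx, count)
  gamma <- vapply(1:5, function(f) {
    r_f <- qr.resid(qx, flags[, f] * 1)
    sum(r_f * r_count) / sum(r_count^2)
  }, numeric(1))
  b <- as.numeric(params$lifestyle_effect_matrix %*% gamma)
  names(b) <- params$marker_names

  omod <- params$outcome_model
  theta_m <- stats::setNames(numeric(length(params$marker_names)),
                             params$marker_names)
  theta_m[names(omod$metabolite_log_ors)] <- omod$metabolite_log_ors
  te <- (omod$direct_hlf_log_or + sum(theta_m * b)) * contrast
  nie <- theta_m * b * contrast
  nde <- te - nie
  pm <- if (te == 0) rep(NA_real_, length(nie)) else nie / te

  risk <- params$chd_marginal_risk
  if (!is.na(omod$intercept)) {
    # closed-form marginal risk under the log-linear approximation:
    # lognormal moment of the Gaussian metabolite layer per draw
    L <- params$metabolite_loading_matrix
    resid_sd <- sqrt(pmax(1 - rowSums(L^2), 0.02))
    var_lp <- sum((as.numeric(theta_m %*% L))^2) + sum((theta_m * resid_sd)^2)
    mu_lp <- omod$intercept + omod$direct_hlf_log_or * count +
      as.numeric(flags %*% t(params$lifestyle_effect_matrix) %*% theta_m)
    risk <- mean(exp(mu_lp + var_lp / 2))
  }
  if (risk >= 0.05) {
    warning("true_mediation_effects: marginal risk >= 5%; the odds ratio no ",
            "longer approximates the risk ratio well")
  }

  structure(list(
    true_nie_log_or = nie,
    true_nde_log_or = nde,
    true_te_log_or = stats::setNames(rep(te, length(nie)), names(nie)),
    true_pm = pm,
    mediator_slopes = b,
    flag_count_slopes = gamma,
    causal_variant_ids =
      params$variant_spec$id[params$variant_spec$ldl_effect != 0],
    marginal_risk = risk
  ), class = "simulation_truth")
}
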