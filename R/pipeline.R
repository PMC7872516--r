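# End-to-end orchestration: simulate (or load) -> lifestyle scoring ->
# metabolite preparation -> association layers -> mediation -> genetic
# scores -> report, with a validated run configuration and a reproducibility
# manifest.

#' Default run configuration
#'
#' All tunable settings of a full analysis run, with their defaults: HLF
#' definition mode, exposure contrast (one additional HLF above the control
#' mean), interaction policy for the mediation layer ("auto" = LRT screen at
#' 0.05), FDR level, genetic-score thresholds (r^2 0.3, conditional p 0.05),
#' number of principal components (5, with a 95% variance floor), and the
#' generator settings (a scale factor applied to the source-cohort size for
#' quick runs).
#'
#' @return Named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    hlf_mode = "standard",            # standard | strict | drop_alcohol
    exposure_contrast = 1,            # a - a*, in HLFs
    interaction_policy = "auto",      # auto | on | off
    fdr_level = 0.05,
    r2_threshold = 0.3,
    p_stop = 0.05,
    n_pcs = 5L,
    pc_variance_floor = 0.95,
    source_scale = 1,                 # scales n_source and n_selection
    compute_truth = FALSE,
    seed = 20260101L
  ), class = "run_config")
}

#' Validate a run configuration
#'
#' Unknown keys are rejected; every threshold must lie in its documented
#' domain.
#'
#' @param config Named list (e.g. edited copy of [default_run_config()]).
#' @return The validated config, invisibly usable downstream.
#' @export
validate_run_config <- function(config) {
  ref <- default_run_config()
  unknown <- setdiff(names(config), names(ref))
  if (length(unknown) > 0L) {
    stop("validate_run_config: unknown key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  merged <- utils::modifyList(unclass(ref), config[!vapply(config, is.null,
                                                           logical(1))])
  with(merged, {
    stopifnot(hlf_mode %in% c("standard", "strict", "drop_alcohol"),
              interaction_policy %in% c("auto", "on", "off"),
              exposure_contrast != 0)
    if (fdr_level <= 0 || fdr_level > 1) {
      stop("validate_run_config: fdr_level must be in (0, 1]", call. = FALSE)
    }
    if (r2_threshold < 0 || r2_threshold > 1) {
      stop("validate_run_config: r2_threshold must be in [0, 1]", call. = FALSE)
    }
    if (p_stop <= 0 || p_stop > 1) {
      stop("validate_run_config: p_stop must be in (0, 1]", call. = FALSE)
    }
    if (n_pcs < 1) stop("validate_run_config: n_pcs must be >= 1", call. = FALSE)
    if (source_scale <= 0) {
      stop("validate_run_config: source_scale must be positive", call. = FALSE)
    }
  })
  class(merged) <- "run_config"
  merged
}

#' Read a run configuration from YAML
#' @param path YAML file with a subset of the [default_run_config()] keys.
#' @return Validated `run_config`.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes every stage in order on a freshly simulated study: lifestyle
#' scoring (per the configured mode), pooled inverse-normal transformation of
#' the metabolite panel, principal components, both association layers with
#' FDR control, per-marker mediation with interaction screening, joint
#' mediation through the top principal components, genetic-score selection on
#' the disjoint selection cohort, score building and 2-SD associations on the
#' analysis cohort, the joint four-group analysis, and the score-stratified
#' HLF analysis. Deterministic for a fixed config and seed.
#'
#' @param config A `run_config` (validated internally).
#' @param params Optional [generative_params()]; defaults are derived from
#'   the config seed and `source_scale`.
#' @param markers Optional subset of markers to carry through the association
#'   and mediation layers (default: the full panel).
#' @return List of class `lipidmed_run`: `simulation`, `profile` (lifestyle),
#'   `hlf_metabolite`, `metabolite_chd`, `mediation`, `joint_pc_mediation`,
#'   `scores` (per gene window: definition, 2-SD association with LDL-C-like
#'   markers), `joint_groups`, `stratified`, `pcs`, `manifest`.
#' @export
run_full_analysis <- function(config = default_run_config(), params = NULL,
                              markers = NULL) {
  config <- validate_run_config(config)
  if (is.null(params)) {
    s <- config$source_scale
    params <- generative_params(
      n_source = as.integer(60000 * s),
      n_selection = as.integer(13060 * s),
      n_cases_chd = as.integer(927 * s),
      n_cases_stroke = c(ischemic = as.integer(1114 * s),
                         ich = as.integer(1127 * s)),
      n_controls = as.integer(1513 * s),
      n_duplicates = as.integer(137 * s),
      seed = config$seed)
  }
  message("[simulate] source cohort n = ", params$n_source)
  sim <- simulate_cohort(params, compute_truth = config$compute_truth)
  cohort <- sim$cohort
  if (is.null(markers)) markers <- colnames(sim$metabolites)

  message("[score-lifestyle] mode = ", config$hlf_mode)
  profile <- switch(config$hlf_mode,
    standard = classify_hlf(cohort),
    strict = hlf_sensitivity_variants(cohort, "strict_adiposity"),
    drop_alcohol = hlf_sensitivity_variants(cohort, "drop_alcohol"))
  for (col in c("hlf_count", "hlf_group", "hlf_group2")) {
    cohort[[col]] <- profile[[col]]
  }

  message("[transform] inverse-normal, ", length(markers), " markers")
  tm <- transform_metabolites(sim$metabolites[, markers, drop = FALSE])
  pcs <- top_principal_components(tm, k = config$n_pcs,
                                  variance_floor = config$pc_variance_floor)
  adf <- cbind(cohort, as.data.frame(tm, optional = TRUE),
               as.data.frame(pcs$scores))
  names(adf)[match(markers, names(adf))] <- markers

  message("[associate] HLF -> metabolites")
  hlf_met <- associate_panel(adf, markers, layer = "hlf-metabolite")
  message("[associate] metabolites -> CHD")
  chd_df <- adf[adf$status %in% c("control", "chd_case"), , drop = FALSE]
  met_chd <- associate_panel(chd_df, markers, layer = "metabolite-chd")

  message("[mediate] per-marker mediation")
  a_star <- mean(adf$hlf_count[adf$status == "control"])
  a <- a_star + config$exposure_contrast
  med <- mediate_panel(chd_df, markers,
                       interaction = config$interaction_policy,
                       a = a, a_star = a_star)
  joint <- joint_mediation_via_pcs(chd_df, colnames(pcs$scores),
                                   a = a, a_star = a_star)

  message("[genetic-score] conditional selection per gene window")
  sel <- sim$selection
  sel_cov <- cbind(age = sel$age, sex_male = as.numeric(sel$sex == "male"),
                   sel$ancestry_pcs)
  genes <- unique(sel$variant_meta$gene_window)
  scores <- lapply(genes, function(g) {
    sd <- conditional_select_variants(sel$dosages, sel$variant_meta,
                                      sel$ldl_c, sel_cov, gene = g,
                                      r2_threshold = config$r2_threshold,
                                      p_stop = config$p_stop)
    built <- if (length(sd$selected_variants) > 0L) {
      build_score(sim$genotypes$dosages, sd)
    } else NULL
    assoc <- if (!is.null(built)) {
      do.call(rbind, lapply(c("LDL-C", "IDL-C", "ApoB"), function(mk) {
        if (!mk %in% markers) return(NULL)
        score_association(adf, mk, built$standardized,
                          ancestry_pcs = sim$genotypes$ancestry_pcs)
      }))
    } else NULL
    list(gene = g, definition = sd, score = built, association = assoc)
  })
  names(scores) <- genes

  joint_groups <- NULL
  stratified <- NULL
  lead <- scores[[1L]]
  if (!is.null(lead$score)) {
    mk <- intersect(c("LDL-C", markers[1L]), markers)[1L]
    joint_groups <- joint_group_analysis(adf, mk, lead$score$standardized)
    stratified <- stratified_hlf_analysis(adf, mk, lead$score$standardized)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("lipidmed")),
    seed = config$seed,
    config = unclass(config),
    n_analysis = nrow(cohort),
    n_controls = sum(cohort$status == "control"),
    n_chd_cases = sum(cohort$status == "chd_case"),
    n_markers = length(markers),
    exposure_contrast = c(a = a, a_star = a_star),
    timestamp_free = TRUE  # manifest content is fully deterministic
  )

  structure(list(
    simulation = sim, profile = profile, hlf_metabolite = hlf_met,
    metabolite_chd = met_chd, mediation = med, joint_pc_mediation = joint,
    scores = scores, joint_groups = joint_groups, stratified = stratified,
    pcs = pcs, manifest = manifest
  ), class = "lipidmed_run")
}

#' Human-readable summary of a pipeline run
#'
#' Counts of FDR-significant markers per layer, the top mediators by
#' proportion mediated (stable, descending), the joint-PC proportion
#' mediated, and the joint-group contrasts.
#'
#' @param run A `lipidmed_run`.
#' @param fdr_level Significance level for the FDR-adjusted p-values.
#' @param top Number of top mediators to list.
#' @return Character vector of report lines (also printed).
#' @export
report_bundle <- function(run, fdr_level = 0.05, top = 10L) {
  stopifnot(inherits(run, "lipidmed_run"))
  need <- c("hlf_metabolite", "metabolite_chd", "mediation")
  for (nm in need) {
    if (is.null(run[[nm]])) {
      stop("report_bundle: missing result table '", nm, "'", call. = FALSE)
    }
  }
  med <- run$mediation
  consistent <- med[!med$pm_inconsistent & is.finite(med$pm), , drop = FALSE]
  ord <- order(consistent$pm, decreasing = TRUE)
  topk <- utils::head(consistent[ord, c("marker", "pm", "p_nie_fdr")], top)
  lines <- c(
    sprintf("participants: %d (%d CHD cases, %d controls)",
            run$manifest$n_analysis, run$manifest$n_chd_cases,
            run$manifest$n_controls),
    sprintf("markers analysed: %d", run$manifest$n_markers),
    sprintf("HLF->metabolite associations FDR<%.2g: %d of %d rows",
            fdr_level, sum(run$hlf_metabolite$p_fdr < fdr_level),
            nrow(run$hlf_metabolite)),
    sprintf("metabolite->CHD associations FDR<%.2g: %d of %d",
            fdr_level, sum(run$metabolite_chd$p_fdr < fdr_level),
            nrow(run$metabolite_chd)),
    sprintf("markers with FDR-significant mediation: %d of %d",
            sum(med$p_nie_fdr < fdr_level), nrow(med)),
    sprintf("joint mediation via top PCs: pm = %.1f%% (p = %.3g)",
            100 * run$joint_pc_mediation$pm, run$joint_pc_mediation$p_nie),
    "top mediators by proportion mediated:",
    sprintf("  %-14s pm = %6.2f%%  (FDR p = %.3g)",
            topk$marker, 100 * topk$pm, topk$p_nie_fdr)
  )
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Write a simulated study to plain-text files
#'
#' Cohort and metabolites as tab-separated files with a one-line header;
#' genotypes as a dosage TSV plus a variant-metadata TSV; ground truth as
#' JSON.
#'
#' @param sim A `lipidmed_simulation`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "lipidmed_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(sim$cohort, "cohort.tsv")
  tsv(data.frame(participant_id = rownames(sim$metabolites),
                 sim$metabolites, check.names = FALSE), "metabolites.tsv")
  tsv(data.frame(participant_id = sim$cohort$participant_id,
                 sim$genotypes$dosages, check.names = FALSE), "dosages.tsv")
  tsv(sim$genotypes$variant_meta, "variants.tsv")
  if (!is.null(sim$truth)) {
    jsonlite::write_json(lapply(unclass(sim$truth), as.list),
                         file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Write the tidy result tables of a run
#'
#' @param run A `lipidmed_run`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_result_bundle <- function(run, dir) {
  stopifnot(inherits(run, "lipidmed_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(run$hlf_metabolite, "hlf_metabolite.tsv")
  tsv(run$metabolite_chd, "metabolite_chd.tsv")
  tsv(run$mediation, "mediation.tsv")
  if (!is.null(run$joint_groups)) tsv(run$joint_groups, "joint_groups.tsv")
  for (g in names(run$scores)) {
    sc <- run$scores[[g]]
    if (length(sc$definition$selected_variants) > 0L) {
      write_score_definition(sc$definition,
                             file.path(dir, paste0("score_", g, ".json")))
    }
    if (!is.null(sc$association)) {
      tsv(sc$association, paste0("score_", g, "_associations.tsv"))
    }
  }
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
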