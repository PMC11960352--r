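# End-to-end orchestration: dataset simulation, the full analysis run and a
# human-readable report. File formats are exactly those the readers in
# core_model consume, so a simulated dataset is loadable without edits.

.log_line <- function(con, ...) {
  msg <- paste0(...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
  invisible(msg)
}

.run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_msg("[stage ", name, "] ", conditionMessage(e))
  })
}

#' Write a complete synthetic dataset
#'
#' Generates a parcellation, cohort, expression matrix and candidate gene
#' list from one [sim_config] and writes them, together with a ground-truth
#' sidecar and the full configuration, in the exact formats the pipeline
#' readers consume. Identical configs produce byte-identical datasets.
#'
#' @param config a [sim_config].
#' @param out_dir output directory (created; must be writable).
#' @return `out_dir`, invisibly.
#' @export
pipeline_simulate <- function(config = sim_config(), out_dir) {
  stopifnot(inherits(config, "sim_config"))
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop_msg("cannot create output directory: ", out_dir)
  parc <- make_parcellation(config$n_left, config$n_right,
                            derive_seed(config$seed, "parcellation"))
  sim <- simulate_cohort(parc, config)
  left_ids <- region_ids(parcellation_subset(parc, "left"))
  target <- stats::setNames(rep(0, length(left_ids)), left_ids)
  on_left <- intersect(sim$ground_truth$effect_regions, left_ids)
  target[on_left] <- sim$ground_truth$effect_size *
    sim$ground_truth$effect_signs[match(on_left,
                                        sim$ground_truth$effect_regions)]
  if (stats::sd(target) == 0) {
    # no effect region fell on the left hemisphere (or delta = 0): signal
    # genes then track a smooth reference map instead of the effect map
    target <- simulate_smooth_map(parc, config$feature_corr_length,
                                  seed = derive_seed(config$seed, "target"),
                                  hemisphere = "left")
  }
  expr <- simulate_expression(parc, config, target)

  # candidate panel: signal genes, background genes, plus symbols absent
  # from the universe so that candidate_overlap is non-trivial
  genes <- colnames(expr$expression)
  cand <- with_seed(derive_seed(config$seed, "candidates"), {
    n_sig <- min(6L, length(expr$ground_truth$signal_genes))
    bg <- setdiff(genes, expr$ground_truth$signal_genes)
    c(sample(expr$ground_truth$signal_genes, n_sig),
      sample(bg, min(6L, length(bg))), sprintf("ABSENT%d", 1:4))
  })

  write_parcellation(parc, file.path(out_dir, "parcellation.tsv"))
  write_cohort(sim$cohort, out_dir)
  write_expression_matrix(expr$expression, file.path(out_dir, "expression.tsv"))
  write_gene_list(cand, file.path(out_dir, "candidates.txt"),
                  header = "synthetic candidate panel")
  gt <- rbind(
    data.frame(kind = "effect_region",
               id = sim$ground_truth$effect_regions,
               value = sim$ground_truth$effect_signs *
                 sim$ground_truth$effect_size, stringsAsFactors = FALSE),
    data.frame(kind = "signal_gene", id = expr$ground_truth$signal_genes,
               value = expr$ground_truth$signal_signs,
               stringsAsFactors = FALSE))
  write_tsv(gt, file.path(out_dir, "ground_truth.tsv"))
  cfg <- config
  cfg$effect_regions <- paste(sim$ground_truth$effect_regions, collapse = ",")
  cfg$effect_signs <- paste(cfg$effect_signs, collapse = ",")
  cfg$covariate_effects <- paste(sprintf("%s=%g", names(cfg$covariate_effects),
                                         cfg$covariate_effects),
                                 collapse = ",")
  write.dcf(as.data.frame(unclass(cfg), stringsAsFactors = FALSE),
            file.path(out_dir, "config.dcf"))
  invisible(out_dir)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: Euler quality-control filter, per-subject MSN
#' construction and regional strengths, the covariate-adjusted case-control
#' GLM t-map with the 1/N significance rule (plus a subgroup contrast when a
#' `subgroup` manifest column is present), disease-course correlations in the
#' significant regions, spin-corrected map-map correlations, PLS1 of the
#' left-hemisphere t-map on gene expression with bootstrap gene Z scores and
#' FDR selection, candidate-gene spatial analysis, and export of the
#' enrichment gene lists. Every intermediate table is written as TSV; a run
#' log records seeds and counts at each stage. All randomness derives from
#' one master seed, so a rerun with the same inputs and seed reproduces every
#' table byte for byte.
#'
#' @param input_dir dataset directory as written by [pipeline_simulate()]
#'   (parcellation.tsv, manifest.tsv, features/, expression.tsv,
#'   candidates.txt).
#' @param out_dir report directory (created).
#' @param n_perm spin permutations, default 1000.
#' @param n_boot bootstrap replicates, default 1000.
#' @param fdr_alpha FDR level for gene selection, default 0.005.
#' @param z_cut hard Z threshold for enrichment lists, default 5.
#' @param alpha_candidates significance level of the candidate analysis.
#' @param covariates manifest columns to adjust for.
#' @param hemisphere scope of expression-linked analyses, default `"left"`.
#' @param euler_threshold QC threshold, default -200.
#' @param seed master seed.
#' @return `out_dir`, invisibly.
#' @export
pipeline_run <- function(input_dir, out_dir, n_perm = 1000, n_boot = 1000,
                         fdr_alpha = 0.005, z_cut = 5,
                         alpha_candidates = 0.05,
                         covariates = c("age", "sex", "etiv"),
                         hemisphere = "left", euler_threshold = -200,
                         seed = 1) {
  for (f in c("parcellation.tsv", "manifest.tsv", "expression.tsv",
              "candidates.txt")) {
    if (!file.exists(file.path(input_dir, f))) {
      stop_msg("[stage load] missing input: ", file.path(input_dir, f))
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(out_dir, "run.log"), "w")
  on.exit(close(log_con))
  .log_line(log_con, "# run started ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  .log_line(log_con, "seed\t", seed)

  parc <- .run_stage("load", read_parcellation(
    file.path(input_dir, "parcellation.tsv")))
  cohort <- .run_stage("load", read_subject_features(
    file.path(input_dir, "manifest.tsv"), file.path(input_dir, "features"),
    parc))
  expr <- .run_stage("load", read_expression_matrix(
    file.path(input_dir, "expression.tsv"), parc, hemisphere = hemisphere))
  cand_panel <- .run_stage("load", read_gene_list(
    file.path(input_dir, "candidates.txt")))
  .log_line(log_con, "regions\t", n_regions(parc))
  .log_line(log_con, "subjects_loaded\t", nrow(cohort$subjects))
  .log_line(log_con, "genes_loaded\t", ncol(expr))

  qc <- .run_stage("qc", qc_filter_euler(cohort, euler_threshold))
  cohort <- qc$cohort
  .log_line(log_con, "subjects_after_qc\t", nrow(cohort$subjects))
  .log_line(log_con, "subjects_excluded\t",
            paste(qc$excluded, collapse = ","))

  st <- .run_stage("msn", cohort_strengths(cohort))
  .run_stage("msn", {
    df <- data.frame(subject_id = rownames(st$strengths), st$strengths,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv(df, file.path(out_dir, "strengths.tsv"))
    gm <- data.frame(group = rownames(st$group_means), st$group_means,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv(gm, file.path(out_dir, "group_means.tsv"))
  })

  n_reg <- n_regions(parc)
  tmap <- .run_stage("glm", threshold_map(
    fit_region_glm(st$strengths, cohort, covariates = covariates), n_reg))
  write_tsv(as.data.frame(tmap), file.path(out_dir, "tmap.tsv"))
  sig <- tmap$region_id[tmap$significant]
  .log_line(log_con, "significant_regions\t", length(sig))

  if ("subgroup" %in% names(cohort$subjects) &&
      any(!is.na(cohort$subjects$subgroup))) {
    man_sub <- cohort$subjects
    man_sub$contrast_group <- ifelse(
      man_sub$group == "control", "control",
      ifelse(!is.na(man_sub$subgroup) & man_sub$subgroup == "yes", "case",
             NA_character_))
    man_sub <- man_sub[!is.na(man_sub$contrast_group), , drop = FALSE]
    tmap_sub <- .run_stage("glm_subgroup", threshold_map(
      fit_region_glm(st$strengths, man_sub, covariates = covariates,
                     group_col = "contrast_group",
                     contrast_label = "case_subgroup - control"), n_reg))
    write_tsv(as.data.frame(tmap_sub), file.path(out_dir, "tmap_subgroup.tsv"))
    .log_line(log_con, "significant_regions_subgroup\t",
              sum(tmap_sub$significant))
  }

  course <- if (length(sig) &&
                sum(cohort$subjects$group == "case" &
                    !is.na(cohort$subjects$disease_course)) >= 3) {
    .run_stage("course", course_correlation(st$strengths, cohort, sig))
  } else {
    data.frame(region_id = character(0), r = numeric(0), p = numeric(0))
  }
  write_tsv(course, file.path(out_dir, "course_correlation.tsv"))

  spins <- .run_stage("spins", generate_spins(
    parc, n_perm = n_perm, seed = derive_seed(seed, "spins"),
    hemisphere = hemisphere))
  .log_line(log_con, "spins\t", n_perm)

  scope_ids <- region_ids(parcellation_subset(parc, hemisphere))
  t_scoped <- stats::setNames(tmap$t[match(scope_ids, tmap$region_id)],
                              scope_ids)
  ctrl_mean <- st$group_means["control", scope_ids]
  mapcor <- .run_stage("map_correlation",
                       spin_pvalue(ctrl_mean, t_scoped, spins))
  write_tsv(data.frame(map_a = "mean_control_strength", map_b = "tmap",
                       r = mapcor$r, p_spin = mapcor$p_spin,
                       n_perm = n_perm),
            file.path(out_dir, "map_correlation.tsv"))

  fit <- .run_stage("pls", pls1_fit(expr, t_scoped))
  write_tsv(data.frame(region_id = scope_ids, pls1_score = fit$scores,
                       stringsAsFactors = FALSE),
            file.path(out_dir, "pls1_scores.tsv"))
  plscor <- .run_stage("pls", spin_pvalue(fit$scores, t_scoped, spins))
  write_tsv(data.frame(map_a = "pls1_score", map_b = "tmap", r = plscor$r,
                       p_spin = plscor$p_spin,
                       variance_explained = fit$variance_explained,
                       n_perm = n_perm),
            file.path(out_dir, "pls1_map_correlation.tsv"))

  gz <- .run_stage("bootstrap", bootstrap_gene_z(
    expr, t_scoped, n_boot = n_boot, seed = derive_seed(seed, "bootstrap")))
  selection <- .run_stage("select", select_genes(gz, fdr_alpha = fdr_alpha,
                                                 z_cut = z_cut))
  write_tsv(selection$table, file.path(out_dir, "gene_z.tsv"))
  .log_line(log_con, "boots\t", n_boot)
  .log_line(log_con, "genes_fdr_selected\t",
            length(selection$pls1_pos) + length(selection$pls1_neg))
  export_enrichment_lists(
    selection[c("pls1_pos", "pls1_neg", "enrichment_pos", "enrichment_neg")],
    file.path(out_dir, "gene_lists"),
    provenance = c(paste0("fdr_alpha: ", fdr_alpha),
                   paste0("z_cut: ", z_cut), paste0("seed: ", seed)))

  overlap <- .run_stage("candidates", candidate_overlap(colnames(expr),
                                                        cand_panel))
  cand_res <- if (length(overlap)) {
    .run_stage("candidates", candidate_analysis(expr, overlap, t_scoped,
                                                spins,
                                                alpha = alpha_candidates))
  } else {
    data.frame(gene = character(0), r = numeric(0), p_spin = numeric(0),
               q = numeric(0), significant_pre_fdr = logical(0),
               significant_post_fdr = logical(0))
  }
  write_tsv(as.data.frame(cand_res), file.path(out_dir, "candidates.tsv"))
  .log_line(log_con, "candidates_overlap\t", length(overlap), "/",
            length(cand_panel))
  .log_line(log_con, "# run finished")
  invisible(out_dir)
}

.read_report_table <- function(run_dir, name) {
  path <- file.path(run_dir, name)
  tryCatch(read_tsv(path),
           error = function(e) stop_msg("cannot read ", path, ": ",
                                        conditionMessage(e)))
}

#' Summarize a completed pipeline run
#'
#' Renders a plain-text summary of the tables a run wrote: significant
#' regions with t and p, the PLS1-map correlation with its spin p, the
#' top-ranked genes, and the candidate-gene table.
#'
#' @param run_dir directory written by [pipeline_run()].
#' @return The summary lines, invisibly; they are also printed.
#' @export
pipeline_report <- function(run_dir) {
  if (!dir.exists(run_dir)) stop_msg("run directory not found: ", run_dir)
  tmap <- .read_report_table(run_dir, "tmap.tsv")
  mapcor <- .read_report_table(run_dir, "map_correlation.tsv")
  plscor <- .read_report_table(run_dir, "pls1_map_correlation.tsv")
  gz <- .read_report_table(run_dir, "gene_z.tsv")
  cand <- .read_report_table(run_dir, "candidates.tsv")
  lines <- c("== pipeline report ==", "")
  sig <- tmap[tmap$significant == "TRUE" | tmap$significant == TRUE, ,
              drop = FALSE]
  n_reg <- nrow(tmap)
  if (nrow(sig)) {
    lines <- c(lines, sprintf("significant regions at P < 1/%d:", n_reg))
    sig <- sig[order(-abs(sig$t)), ]
    lines <- c(lines, sprintf("  %s  t = %.2f  p = %.3g", sig$region_id,
                              sig$t, sig$p))
  } else {
    lines <- c(lines, sprintf("no regions at P < 1/%d", n_reg))
  }
  lines <- c(lines, "",
             sprintf("mean control strength vs t-map: r = %.3f, p_spin = %.4g",
                     mapcor$r[1], mapcor$p_spin[1]),
             sprintf("PLS1 score vs t-map: r = %.3f, p_spin = %.4g (%.1f%% of target variance)",
                     plscor$r[1], plscor$p_spin[1],
                     100 * plscor$variance_explained[1]),
             "", "top genes by |z|:")
  top <- gz[order(-abs(gz$z)), ][seq_len(min(10, nrow(gz))), ]
  lines <- c(lines, sprintf("  %-10s z = %+0.2f  q = %.3g  %s", top$gene,
                            top$z, top$q, top$category))
  lines <- c(lines, "", sprintf("candidate genes (%d):", nrow(cand)))
  if (nrow(cand)) {
    lines <- c(lines,
               sprintf("  %-10s r = %+0.3f  p_spin = %.4g  q = %.4g%s",
                       cand$gene, cand$r, cand$p_spin, cand$q,
                       ifelse(cand$significant_post_fdr %in% c(TRUE, "TRUE"),
                              "  *", "")))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
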