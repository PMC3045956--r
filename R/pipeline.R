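# End-to-end orchestration: load -> first-sample selection -> relative
# quantification -> geNorm + model-based stability (per available grouping)
# -> covariate diagnostics -> structured TSV/JSON report.

report_schema_version <- "1"

#' Run the full reference-gene stability pipeline
#'
#' Composes the package's stages over one dataset and writes a report
#' bundle: geNorm ranking and V-series, model-based stability under the
#' disease grouping and (when leukocyte counts are present) under
#' leukocyte-count quartiles, a per-gene diagnostics table (slope on log
#' leukocyte count, leukocytosis dichotomy with Holm correction,
#' disease-group ANOVA), a Spearman rank correlation between the two
#' stability rankings, and a machine-readable JSON mirror of every number.
#' All outputs are computed before anything is written, so a failing stage
#' leaves no partial bundle behind. Reports are byte-identical across reruns
#' with the same inputs (the run log, which carries timestamps and session
#' info, is written separately).
#'
#' @param dataset a [refstab_dataset()]; alternatively give `cq_path`,
#'   `meta_path`, `eff_path`, `layout` to load from disk.
#' @param cq_path,meta_path,eff_path,layout passed to [load_dataset()] when
#'   `dataset` is `NULL`.
#' @param out_dir output directory for the bundle (created if needed).
#' @param cutoff geNorm V cutoff, default 0.15.
#' @param first_sample_only restrict stability analyses to each dog's first
#'   sample (default `TRUE`, the conventional rule).
#' @param alpha significance level annotated in the diagnostics table.
#' @param slope_method passed to [wbc_slope_lmm()].
#' @return invisibly, the report list (also written as `report.json`).
#' @export
run_pipeline <- function(dataset = NULL, cq_path = NULL, meta_path = NULL,
                         eff_path = NULL, layout = c("wide", "long"),
                         out_dir, cutoff = 0.15, first_sample_only = TRUE,
                         alpha = 0.05,
                         slope_method = c("lmm_all_samples",
                                          "ols_first_sample")) {
  slope_method <- match.arg(slope_method)
  stopifnot(cutoff > 0, alpha > 0, alpha < 1)
  if (is.null(dataset)) {
    layout <- match.arg(layout)
    dataset <- load_dataset(cq_path, meta_path, eff_path, layout)
  }
  stopifnot(inherits(dataset, "refstab_dataset"))
  full_ds <- dataset
  stab_ds <- if (first_sample_only) select_first_samples(dataset) else dataset
  n_dropped <- ncol(full_ds$cq) - ncol(stab_ds$cq)

  q <- relative_quantities(stab_ds$cq, stab_ds$efficiencies)
  gn <- genorm(q, cutoff = cutoff)

  groupings <- list(disease_group = stats::setNames(
    factor(stab_ds$meta$disease_group), stab_ds$meta$sample_id))
  if (!anyNA(stab_ds$meta$wbc_count))
    groupings$wbc_quartile <- wbc_quartile_groups(stab_ds)
  nf_results <- lapply(groupings, function(g) {
    res <- normfinder_stability(q, g)
    pair <- normfinder_best_pair(res)
    list(result = res, pair = pair)
  })

  has_wbc <- !all(is.na(full_ds$meta$wbc_count))
  genes <- rownames(full_ds$cq)
  diagnostics <- NULL
  if (has_wbc) {
    slopes <- lapply(genes, function(g)
      wbc_slope_lmm(full_ds, g, method = slope_method))
    dich <- wbc_panel_compare(stab_ds)
    diagnostics <- data.frame(
      gene = genes,
      slope_per_tenfold = vapply(slopes, `[[`, numeric(1), "beta_per_tenfold"),
      slope_se = vapply(slopes, `[[`, numeric(1), "se_per_tenfold"),
      slope_p = vapply(slopes, `[[`, numeric(1), "p"),
      mean_cq_within = dich$mean_within[match(genes, dich$gene)],
      sd_cq_within = dich$sd_within[match(genes, dich$gene)],
      mean_cq_high = dich$mean_high[match(genes, dich$gene)],
      sd_cq_high = dich$sd_high[match(genes, dich$gene)],
      difference = dich$difference[match(genes, dich$gene)],
      dichotomy_p = dich$p[match(genes, dich$gene)],
      dichotomy_p_holm = dich$p_holm[match(genes, dich$gene)])
  }
  anova_tab <- do.call(rbind, lapply(genes, function(g) {
    a <- suppressWarnings(anova_by_group(stab_ds, g))
    data.frame(gene = g, f = a$f, p = a$p, t(a$group_means))
  }))

  genorm_order <- match(genes, gn$ranking)
  # Spearman rho between the geNorm ranking and each model-based ranking;
  # NA when a stability vector is fully tied (gamma = 0, no intergroup
  # variation detected) and a ranking is therefore undefined.
  rank_cor <- lapply(nf_results, function(r) {
    nf_order <- rank(r$result$stability[genes])
    if (stats::sd(nf_order) == 0) NA_real_
    else stats::cor(genorm_order, nf_order, method = "spearman")
  })

  report <- list(
    schema_version = report_schema_version,
    parameters = list(cutoff = cutoff, alpha = alpha,
                      first_sample_only = first_sample_only,
                      slope_method = slope_method),
    data = list(n_genes = length(genes),
                n_samples_total = ncol(full_ds$cq),
                n_samples_stability = ncol(stab_ds$cq),
                n_repeat_samples_excluded = n_dropped,
                genes = genes),
    genorm = list(m_values = as.list(gn$m_values),
                  ranking = gn$ranking,
                  best_pair = gn$best_pair,
                  exclusion_order = gn$exclusion_order,
                  v_series = gn$v_series,
                  optimal_n = if (gn$optimal_reached) gn$optimal_n
                              else "not reached"),
    normfinder = lapply(nf_results, function(r)
      list(stability = as.list(r$result$stability),
           gamma_hat = r$result$gamma_hat,
           best_gene = r$result$best_gene,
           best_pair = r$pair$best_pair,
           pair_stability = r$pair$pair_stability,
           group_sizes = as.list(r$result$group_sizes))),
    diagnostics = diagnostics,
    anova_disease_group = anova_tab,
    ranking_concordance = list(
      method = "spearman",
      rho = rank_cor))

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  tsv(data.frame(gene = gn$ranking,
                 m_full_set = gn$m_values[gn$ranking],
                 rank = seq_along(gn$ranking)), "genorm.tsv")
  tsv(gn$v_series, "v_series.tsv")
  for (nm in names(nf_results)) {
    r <- nf_results[[nm]]$result
    tsv(data.frame(gene = names(r$stability),
                   stability_value = r$stability,
                   r$d_hat, r$sigma2_hat,
                   check.names = TRUE),
        sprintf("normfinder_%s.tsv", nm))
  }
  if (!is.null(diagnostics)) tsv(diagnostics, "diagnostics.tsv")
  tsv(anova_tab, "anova_disease_group.tsv")
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", na = "null")
  log_lines <- c(
    sprintf("refstab %s | R %s.%s", as.character(utils::packageVersion("refstab")),
            R.version$major, R.version$minor),
    sprintf("run at: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    sprintf("samples: %d total, %d used for stability (%d repeat samples excluded)",
            ncol(full_ds$cq), ncol(stab_ds$cq), n_dropped),
    sprintf("missing Cq cells: %d", sum(is.na(full_ds$cq))),
    sprintf("groupings analysed: %s", paste(names(nf_results), collapse = ", ")))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(report)
}

#' Validate a pipeline report against the shipped schema
#'
#' Checks the report produced by [run_pipeline()] (or read back from
#' `report.json`) against the versioned schema in
#' `inst/schema/report-schema-v1.json`: required top-level sections, their
#' required fields, and basic type expectations.
#'
#' @param report a report list or a path to a `report.json`.
#' @return `TRUE` invisibly; errors describe the first violation found.
#' @export
validate_report <- function(report) {
  if (is.character(report)) report <- jsonlite::read_json(report)
  schema_path <- system.file("schema",
                             sprintf("report-schema-v%s.json",
                                     report_schema_version),
                             package = "refstab")
  schema <- jsonlite::read_json(schema_path)
  for (section in names(schema$required_sections)) {
    if (is.null(report[[section]]))
      stop_refstab("report lacks section '%s'", section, module = "cli_report")
    for (field in unlist(schema$required_sections[[section]]))
      if (is.null(report[[section]][[field]]))
        stop_refstab("report section '%s' lacks field '%s'", section, field,
                     module = "cli_report")
  }
  if (!identical(as.character(report$schema_version),
                 as.character(schema$version)))
    stop_refstab("schema version mismatch: report %s, schema %s",
                 report$schema_version, schema$version, module = "cli_report")
  invisible(TRUE)
}
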