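# Seeded synthetic qPCR cohort generator.
#
# Emulates the structure of a canine whole-blood reference-gene study:
# dogs in four disease groups (healthy controls, post-surgical, internal
# medicine, hematologic disease), group-specific lognormal leukocyte
# counts, per-gene baseline Cq plus a linear response to log10 leukocyte
# count, optional gene-by-group offsets, a per-dog random intercept
# (repeated sampling), a per-sample global shift (template amount), and
# per-gene residual noise. Technical duplicates and missing wells are
# optional. The realized latent effects are exported as ground truth so
# recovery tests can compare estimates against what was injected.

#' Cohort generator configuration
#'
#' Assembles and validates the parameters of the synthetic cohort model.
#' The Cq generated for gene i, dog d (group g), sample s is
#' `baseline_i + d_ig + slope_i * log10(WBC_s / 10) + u_d + c_s + eps`,
#' with `u ~ N(0, dog_intercept_sd^2)`, `c ~ N(0, sample_shift_sd^2)`,
#' `eps ~ N(0, residual_sd_i^2)` and `WBC` drawn lognormally per group.
#' Baselines are referenced at WBC = 10 (x 1e9/l), a typical normal count,
#' so they equal the expected Cq of a normal-count dog.
#'
#' @param gene_params data.frame with columns `gene`, `baseline_cq`,
#'   `residual_sd`, `slope_per_tenfold` (Cq change per tenfold leukocyte
#'   increase).
#' @param group_sizes named integer vector of dogs per disease group
#'   (names from A, B, C, D).
#' @param wbc_meanlog,wbc_sdlog named per-group parameters of the lognormal
#'   leukocyte-count distribution (natural-log scale).
#' @param group_offsets genes x groups matrix of Cq offsets `d_ig`; each
#'   gene's row must sum to zero across groups (offsets are contrasts, the
#'   overall level belongs to the baseline). Default all zero.
#' @param dog_intercept_sd SD of the per-dog random intercept (Cq).
#' @param sample_shift_sd SD of the per-sample global shift shared by all
#'   genes of one sample (Cq).
#' @param repeat_counts named list per group: number of dogs with a 2nd,
#'   3rd, 4th sample, as a non-increasing integer vector (e.g. `c(37, 10,
#'   4)`); dogs at the head of each group get the extra samples.
#' @param duplicate_sd SD of technical duplicate noise (Cq); 0 disables
#'   duplicates.
#' @param missing_rate probability a (gene, sample) well fails.
#' @param seed optional default seed used by [generate_cohort()].
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(gene_params,
                          group_sizes,
                          wbc_meanlog,
                          wbc_sdlog,
                          group_offsets = NULL,
                          dog_intercept_sd = 0.3,
                          sample_shift_sd = 0.1,
                          repeat_counts = NULL,
                          duplicate_sd = 0,
                          missing_rate = 0,
                          seed = NULL) {
  problems <- character(0)
  need_cols <- c("gene", "baseline_cq", "residual_sd", "slope_per_tenfold")
  if (!is.data.frame(gene_params) || !all(need_cols %in% names(gene_params)))
    problems <- c(problems, sprintf("gene_params needs columns %s",
                                    paste(need_cols, collapse = ", ")))
  else {
    if (nrow(gene_params) < 1) problems <- c(problems, "gene list is empty")
    if (anyDuplicated(gene_params$gene))
      problems <- c(problems, "duplicate gene ids in gene_params")
    if (any(gene_params$residual_sd < 0))
      problems <- c(problems, "residual_sd must be >= 0")
  }
  groups <- names(group_sizes)
  if (is.null(groups) || !all(groups %in% DISEASE_GROUPS))
    problems <- c(problems, "group_sizes must be named with groups from A-D")
  if (any(group_sizes < 0)) problems <- c(problems, "group sizes must be >= 0")
  for (nm in c("wbc_meanlog", "wbc_sdlog")) {
    v <- get(nm)
    if (!all(groups %in% names(v)))
      problems <- c(problems, sprintf("%s must cover all groups", nm))
  }
  if (any(wbc_sdlog < 0)) problems <- c(problems, "wbc_sdlog must be >= 0")
  if (is.null(group_offsets)) {
    group_offsets <- matrix(0, nrow(gene_params), length(groups),
                            dimnames = list(gene_params$gene, groups))
  }
  if (!is.matrix(group_offsets) ||
      !identical(rownames(group_offsets), gene_params$gene) ||
      !identical(colnames(group_offsets), groups))
    problems <- c(problems, "group_offsets must be a genes x groups matrix matching gene_params and group_sizes")
  else if (any(abs(rowSums(group_offsets)) > 1e-8))
    problems <- c(problems, "each gene's group offsets must sum to 0")
  for (nm in c("dog_intercept_sd", "sample_shift_sd", "duplicate_sd")) {
    if (get(nm) < 0) problems <- c(problems, sprintf("%s must be >= 0", nm))
  }
  if (missing_rate < 0 || missing_rate >= 1)
    problems <- c(problems, "missing_rate must be in [0, 1)")
  if (is.null(repeat_counts))
    repeat_counts <- stats::setNames(rep(list(integer(0)), length(groups)),
                                     groups)
  for (g in groups) {
    rc <- repeat_counts[[g]] %||% integer(0)
    if (length(rc) && (any(diff(rc) > 0) || rc[1] > group_sizes[[g]] ||
                       any(rc < 0)))
      problems <- c(problems,
                    sprintf("repeat_counts[%s] must be non-increasing and <= group size", g))
    repeat_counts[[g]] <- as.integer(rc)
  }
  if (length(problems))
    stop_refstab("invalid cohort configuration:\n  - %s",
                 paste(problems, collapse = "\n  - "), module = "synthdata")
  structure(list(gene_params = gene_params,
                 group_sizes = as.integer(group_sizes) |>
                   stats::setNames(groups),
                 wbc_meanlog = wbc_meanlog[groups],
                 wbc_sdlog = wbc_sdlog[groups],
                 group_offsets = group_offsets,
                 dog_intercept_sd = dog_intercept_sd,
                 sample_shift_sd = sample_shift_sd,
                 repeat_counts = repeat_counts,
                 duplicate_sd = duplicate_sd,
                 missing_rate = missing_rate,
                 seed = seed),
            class = "cohort_config")
}

#' Default canine whole-blood cohort configuration
#'
#' The 9-gene, 263-dog configuration the package's analyses are calibrated
#' on: disease groups A (healthy, n = 6), B (post-surgical, n = 85),
#' C (internal diseases, n = 107), D (hematologic disease, n = 65);
#' published per-gene normal-count baselines, SDs and Cq-per-tenfold-WBC
#' slopes for RPS19, RPL8, RPS5, GUSB, B2M, HNRNPH, HPRT, GAPDH and SRPR;
#' group-wise lognormal leukocyte counts whose medians match 8.6 / 15.9 /
#' 16.8 / 22.6 (x 1e9/l) and whose spread reproduces the observed group
#' ranges via an order-statistic adjustment (the expected range of n
#' lognormal draws spans about `2 * qnorm((n - 0.375)/(n + 0.25))` SDs on
#' the log scale); and the observed repeated-sampling pattern (e.g. 37
#' group-B dogs with a second sample).
#'
#' @param b2m_group_effect add a disease-group contrast on B2M of 0.51 Cq
#'   between groups B and D (half up, half down; the sign convention is
#'   arbitrary), emulating a group-specific regulation of B2M on top of its
#'   leukocyte-count response.
#' @param dog_intercept_sd,sample_shift_sd,duplicate_sd,missing_rate,seed
#'   overrides passed to [cohort_config()].
#' @return a `cohort_config`.
#' @export
canine_blood_config <- function(b2m_group_effect = FALSE,
                                dog_intercept_sd = 0.3,
                                sample_shift_sd = 0.1,
                                duplicate_sd = 0,
                                missing_rate = 0,
                                seed = NULL) {
  gene_params <- data.frame(
    gene = c("RPS19", "RPL8", "RPS5", "GUSB", "B2M", "HNRNPH", "HPRT",
             "GAPDH", "SRPR"),
    baseline_cq = c(17.35, 19.20, 18.30, 21.09, 15.85, 22.40, 21.14, 14.87,
                    18.30),
    residual_sd = c(0.82, 0.67, 0.86, 0.97, 0.86, 0.86, 0.93, 0.97, 1.09),
    slope_per_tenfold = c(0.92, 0.52, 1.06, -0.07, 1.28, -0.09, -0.87,
                          -0.51, 0.10))
  group_sizes <- c(A = 6L, B = 85L, C = 107L, D = 65L)
  medians <- c(A = 8.6, B = 15.9, C = 16.8, D = 22.6)
  ranges <- list(A = c(6.6, 12.5), B = c(3.8, 107.8), C = c(2.1, 44.6),
                 D = c(4.8, 175.9))
  # expected half-range of n standard-normal draws, Blom approximation
  half_range_z <- stats::qnorm((group_sizes - 0.375) / (group_sizes + 0.25))
  sdlog <- vapply(DISEASE_GROUPS, function(g)
    diff(log(ranges[[g]])) / (2 * half_range_z[[g]]), numeric(1))
  offsets <- NULL
  if (b2m_group_effect) {
    offsets <- matrix(0, nrow(gene_params), 4,
                      dimnames = list(gene_params$gene, names(group_sizes)))
    offsets["B2M", ] <- c(0, 0.255, 0, -0.255)
  }
  cohort_config(gene_params = gene_params,
                group_sizes = group_sizes,
                wbc_meanlog = log(medians),
                wbc_sdlog = sdlog,
                group_offsets = offsets,
                dog_intercept_sd = dog_intercept_sd,
                sample_shift_sd = sample_shift_sd,
                repeat_counts = list(A = integer(0),
                                     B = c(37L, 10L, 4L),
                                     C = c(30L, 6L, 3L),
                                     D = c(32L, 18L, 6L)),
                duplicate_sd = duplicate_sd,
                missing_rate = missing_rate,
                seed = seed)
}

#' Generate a synthetic cohort
#'
#' Draws a full cohort from a [cohort_config()] under a fixed seed:
#' identical (config, seed) pairs give identical output; the caller's RNG
#' stream is left untouched. Returns the analysis-ready dataset (technical
#' duplicates already averaged, as at load time), the per-replicate long
#' table (when duplicates are enabled), and the realized ground truth.
#'
#' @param config a `cohort_config`.
#' @param seed integer seed; defaults to `config$seed`.
#' @return list of class `refstab_cohort`: `dataset` (a
#'   [refstab_dataset()]), `long_cq` (long-format data.frame with replicate
#'   rows, or `NULL` when duplicates are off), `truth` (list: `config`,
#'   `seed`, `dog_effects`, `sample_shifts`, `wbc`, `expected_cq`).
#' @export
generate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(seed))
    stop_refstab("a seed is required for reproducible generation",
                 module = "synthdata")
  with_preserved_seed(seed, {
    groups <- names(config$group_sizes)
    dog_group <- rep(groups, config$group_sizes)
    n_dogs <- length(dog_group)
    dog_id <- sprintf("dog%03d", seq_len(n_dogs))
    # samples per dog from the per-group repeat pattern: the first k dogs of
    # a group carry the extra samples (deterministic given the config)
    n_samples_dog <- rep(1L, n_dogs)
    for (g in groups) {
      in_g <- which(dog_group == g)
      for (extra in config$repeat_counts[[g]])
        if (extra > 0)
          n_samples_dog[in_g[seq_len(extra)]] <-
            n_samples_dog[in_g[seq_len(extra)]] + 1L
    }
    samp_dog <- rep(seq_len(n_dogs), n_samples_dog)
    samp_number <- unlist(lapply(n_samples_dog, seq_len), use.names = FALSE)
    n_samples <- length(samp_dog)
    sample_id <- sprintf("s%04d", seq_len(n_samples))
    g_of_sample <- dog_group[samp_dog]

    u_dog <- stats::rnorm(n_dogs, 0, config$dog_intercept_sd)
    c_sample <- stats::rnorm(n_samples, 0, config$sample_shift_sd)
    wbc <- stats::rlnorm(n_samples,
                         meanlog = config$wbc_meanlog[g_of_sample],
                         sdlog = config$wbc_sdlog[g_of_sample])

    gp <- config$gene_params
    n_genes <- nrow(gp)
    expected <- gp$baseline_cq +
      config$group_offsets[, g_of_sample, drop = FALSE][, seq_len(n_samples)] +
      outer(gp$slope_per_tenfold, log10(wbc / 10)) +
      matrix(u_dog[samp_dog] + c_sample, n_genes, n_samples, byrow = TRUE)
    dimnames(expected) <- list(gp$gene, sample_id)
    eps <- matrix(stats::rnorm(n_genes * n_samples, 0, gp$residual_sd),
                  n_genes, n_samples)
    cq <- expected + eps

    long_cq <- NULL
    if (config$duplicate_sd > 0) {
      rep1 <- cq + matrix(stats::rnorm(length(cq), 0, config$duplicate_sd),
                          n_genes, n_samples)
      rep2 <- cq + matrix(stats::rnorm(length(cq), 0, config$duplicate_sd),
                          n_genes, n_samples)
      cq <- (rep1 + rep2) / 2
      long_cq <- data.frame(
        sample = rep(rep(sample_id, each = n_genes), 2),
        gene = rep(gp$gene, 2 * n_samples),
        cq = c(as.vector(rep1), as.vector(rep2)))
    }
    if (config$missing_rate > 0) {
      mask <- matrix(stats::runif(length(cq)) < config$missing_rate,
                     n_genes, n_samples)
      cq[mask] <- NA_real_
      if (!is.null(long_cq)) {
        miss_key <- paste(rep(gp$gene, n_samples)[mask],
                          rep(sample_id, each = n_genes)[mask])
        long_cq <- long_cq[!paste(long_cq$gene, long_cq$sample) %in% miss_key, ]
      }
    }
    meta <- data.frame(sample_id = sample_id,
                       dog_id = dog_id[samp_dog],
                       sample_number = samp_number,
                       disease_group = g_of_sample,
                       sex = NA_character_, breed = NA_character_,
                       age_years = NA_real_,
                       wbc_count = wbc)
    ds <- refstab_dataset(cq, meta)
    truth <- list(config = config, seed = seed,
                  dog_effects = stats::setNames(u_dog, dog_id),
                  sample_shifts = stats::setNames(c_sample, sample_id),
                  wbc = stats::setNames(wbc, sample_id),
                  expected_cq = expected)
    structure(list(dataset = ds, long_cq = long_cq, truth = truth),
              class = "refstab_cohort")
  })
}

#' Write a synthetic cohort to CSV
#'
#' Emits the same CSV formats [load_dataset()] reads: a long-format Cq table
#' (with technical-replicate rows when duplicates were generated) and the
#' metadata table.
#'
#' @param cohort a `refstab_cohort` from [generate_cohort()].
#' @param dir output directory, created if needed.
#' @return invisibly, a named vector of the paths written (`cq`, `meta`).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "refstab_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cq_path <- file.path(dir, "cq.csv")
  meta_path <- file.path(dir, "meta.csv")
  if (!is.null(cohort$long_cq)) {
    out <- cohort$long_cq
    out$cq <- fmt_full(out$cq)
    utils::write.csv(out, cq_path, row.names = FALSE, quote = FALSE)
  } else {
    write_dataset(cohort$dataset, cq_path, meta_path, layout = "long")
  }
  utils::write.csv(cohort$dataset$meta, meta_path, row.names = FALSE)
  invisible(c(cq = cq_path, meta = meta_path))
}
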