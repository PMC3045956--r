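# Cq ingestion and validation.
#
# A dataset couples a genes x samples Cq matrix with per-sample metadata
# (dog id, sample number, disease group, optional sex/breed/age and leukocyte
# count) and an optional per-gene amplification-efficiency map. Technical
# duplicate reactions ("duplo") are averaged on the Cq scale at load time,
# matching the instrument-software convention.

DISEASE_GROUPS <- c("A", "B", "C", "D")
META_COLUMNS <- c("sample_id", "dog_id", "sample_number", "disease_group",
                  "sex", "breed", "age_years", "wbc_count")

validate_cq_matrix <- function(cq) {
  if (!is.matrix(cq) || !is.numeric(cq))
    stop_refstab("Cq data must be a numeric matrix", module = "cq_io")
  if (is.null(rownames(cq)) || is.null(colnames(cq)))
    stop_refstab("Cq matrix needs gene rownames and sample colnames",
                 module = "cq_io")
  if (anyDuplicated(rownames(cq)))
    stop_refstab("duplicate gene ids: %s",
                 paste(unique(rownames(cq)[duplicated(rownames(cq))]),
                       collapse = ", "), module = "cq_io")
  if (anyDuplicated(colnames(cq)))
    stop_refstab("duplicate sample ids: %s",
                 paste(unique(colnames(cq)[duplicated(colnames(cq))]),
                       collapse = ", "), module = "cq_io")
  present <- cq[!is.na(cq)]
  if (length(present) && (any(present <= 0) || any(present >= 50)))
    stop_refstab("Cq values must lie in (0, 50); offending range [%g, %g]",
                 min(present), max(present), module = "cq_io")
  invisible(cq)
}

validate_meta <- function(meta) {
  if (!is.data.frame(meta))
    stop_refstab("metadata must be a data.frame", module = "cq_io")
  required <- c("sample_id", "dog_id", "sample_number", "disease_group")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols))
    stop_refstab("metadata lacks required columns: %s",
                 paste(missing_cols, collapse = ", "), module = "cq_io")
  for (col in setdiff(META_COLUMNS, names(meta))) meta[[col]] <- NA
  meta <- meta[, META_COLUMNS]
  meta$sample_id <- as.character(meta$sample_id)
  meta$dog_id <- as.character(meta$dog_id)
  meta$sample_number <- as.integer(meta$sample_number)
  meta$disease_group <- as.character(meta$disease_group)
  meta$wbc_count <- as.numeric(meta$wbc_count)
  meta$age_years <- as.numeric(meta$age_years)
  if (anyDuplicated(meta$sample_id))
    stop_refstab("duplicate sample_id in metadata", module = "cq_io")
  if (any(is.na(meta$sample_number)) || any(meta$sample_number < 1))
    stop_refstab("sample_number must be a positive integer", module = "cq_io")
  key <- paste(meta$dog_id, meta$sample_number)
  if (anyDuplicated(key))
    stop_refstab("(dog_id, sample_number) pairs must be unique; duplicated: %s",
                 paste(unique(key[duplicated(key)]), collapse = "; "),
                 module = "cq_io")
  bad_group <- setdiff(unique(meta$disease_group), DISEASE_GROUPS)
  if (length(bad_group))
    stop_refstab("disease_group must be one of %s; found: %s",
                 paste(DISEASE_GROUPS, collapse = "/"),
                 paste(bad_group, collapse = ", "), module = "cq_io")
  wbc <- meta$wbc_count
  if (any(!is.na(wbc) & wbc <= 0))
    stop_refstab("wbc_count must be > 0 when present", module = "cq_io")
  meta
}

#' Construct a Cq dataset
#'
#' Bundles a genes x samples Cq matrix, per-sample metadata and an optional
#' per-gene amplification-efficiency map into a validated `refstab_dataset`.
#' Genes absent from `efficiencies` default to E = 2 (100% efficiency).
#'
#' @param cq numeric matrix of quantification-cycle values with gene rownames
#'   and sample colnames; `NA` marks failed/missing wells.
#' @param meta data.frame with at least `sample_id`, `dog_id`,
#'   `sample_number`, `disease_group`; optional `sex`, `breed`, `age_years`,
#'   `wbc_count` (leukocytes, 1e9/l).
#' @param efficiencies named numeric vector of per-gene amplification
#'   efficiencies E (fold change per cycle), or `NULL` for E = 2 throughout.
#' @return an object of class `refstab_dataset` with elements `cq`, `meta`,
#'   `efficiencies`.
#' @export
refstab_dataset <- function(cq, meta, efficiencies = NULL) {
  validate_cq_matrix(cq)
  meta <- validate_meta(meta)
  missing_meta <- setdiff(colnames(cq), meta$sample_id)
  if (length(missing_meta))
    stop_refstab("no metadata record for sample(s): %s",
                 paste(missing_meta, collapse = ", "), module = "cq_io")
  meta <- meta[match(colnames(cq), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  eff <- rep(2.0, nrow(cq))
  names(eff) <- rownames(cq)
  if (!is.null(efficiencies)) {
    unknown <- setdiff(names(efficiencies), rownames(cq))
    if (length(unknown))
      stop_refstab("efficiency given for unknown gene(s): %s",
                   paste(unknown, collapse = ", "), module = "cq_io")
    eff[names(efficiencies)] <- efficiencies
  }
  validate_efficiencies(eff)
  structure(list(cq = cq, meta = meta, efficiencies = eff),
            class = "refstab_dataset")
}

#' @export
print.refstab_dataset <- function(x, ...) {
  cat(sprintf("refstab_dataset: %d genes x %d samples (%d dogs)\n",
              nrow(x$cq), ncol(x$cq), length(unique(x$meta$dog_id))))
  cat(sprintf("  missing Cq cells: %d\n", sum(is.na(x$cq))))
  grp <- table(x$meta$disease_group)
  cat("  samples per disease group:",
      paste(sprintf("%s=%d", names(grp), grp), collapse = ", "), "\n")
  invisible(x)
}

parse_numeric_cells <- function(chr, what, row_ids, col_ids) {
  chr <- trimws(chr)
  chr[chr == ""] <- NA_character_
  num <- suppressWarnings(as.numeric(chr))
  bad <- !is.na(chr) & is.na(num)
  if (any(bad)) {
    i <- which(bad)[1]
    stop_refstab("unparseable numeric in %s at row '%s', column '%s': '%s'",
                 what, row_ids[i], col_ids[i], chr[i], module = "cq_io")
  }
  num
}

read_cq_wide <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (!ncol(raw) >= 2 || tolower(names(raw)[1]) != "gene")
    stop_refstab("wide Cq CSV must have a leading 'gene' column", module = "cq_io")
  genes <- raw[[1]]
  if (anyDuplicated(genes))
    stop_refstab("duplicate gene row(s) in wide Cq CSV: %s",
                 paste(unique(genes[duplicated(genes)]), collapse = ", "),
                 module = "cq_io")
  samples <- names(raw)[-1]
  cells <- as.matrix(raw[, -1, drop = FALSE])
  num <- parse_numeric_cells(as.vector(cells), "Cq table",
                             rep(genes, times = length(samples)),
                             rep(samples, each = length(genes)))
  cq <- matrix(num, nrow = length(genes), dimnames = list(genes, samples))
  if (anyNA(cq))
    warn_refstab("%d empty Cq cell(s) read as missing", sum(is.na(cq)),
                 module = "cq_io")
  cq
}

read_cq_long <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  need <- c("sample", "gene", "cq")
  if (!all(need %in% tolower(names(raw))))
    stop_refstab("long Cq CSV needs columns sample, gene, cq", module = "cq_io")
  names(raw) <- tolower(names(raw))
  cqv <- parse_numeric_cells(raw$cq, "Cq table", raw$sample, raw$gene)
  if (anyNA(cqv))
    warn_refstab("%d empty Cq cell(s) read as missing", sum(is.na(cqv)),
                 module = "cq_io")
  genes <- unique(raw$gene)
  samples <- unique(raw$sample)
  # replicate rows (same sample, gene) averaged on the Cq scale
  key <- interaction(factor(raw$gene, genes), factor(raw$sample, samples),
                     drop = FALSE)
  means <- tapply(cqv, key, function(v) {
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  })
  cq <- matrix(as.numeric(means), nrow = length(genes),
               dimnames = list(genes, samples))
  cq
}

read_efficiencies <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (!all(c("gene", "efficiency") %in% tolower(names(raw))))
    stop_refstab("efficiency CSV needs columns gene, efficiency", module = "cq_io")
  names(raw) <- tolower(names(raw))
  val <- parse_numeric_cells(raw$efficiency, "efficiency table",
                             raw$gene, rep("efficiency", nrow(raw)))
  if (anyNA(val))
    stop_refstab("missing efficiency value(s)", module = "cq_io")
  # values > 3 are percentages (e.g. 94 for E = 1.94), auto-detected
  pct <- val > 3
  val[pct] <- 1 + val[pct] / 100
  stats::setNames(val, raw$gene)
}

validate_efficiencies <- function(eff) {
  if (any(eff < 1.5 | eff > 2.2))
    stop_refstab("amplification efficiency outside plausible range [1.5, 2.2]: %s",
                 paste(sprintf("%s=%g", names(eff)[eff < 1.5 | eff > 2.2],
                               eff[eff < 1.5 | eff > 2.2]), collapse = ", "),
                 module = "quantify")
  soft <- eff < 1.939 | eff > 2.067
  if (any(soft))
    warn_refstab("efficiency outside the assay-validated band 93.9%%-106.7%%: %s",
                 paste(sprintf("%s=%g", names(eff)[soft], eff[soft]),
                       collapse = ", "), module = "quantify")
  invisible(eff)
}

#' Load a Cq dataset from CSV files
#'
#' Reads a Cq table (wide: genes as rows, samples as columns, first column
#' `gene`; long: columns `sample, gene, cq` with technical-replicate rows
#' allowed), the sample metadata table, and optionally a two-column
#' `gene, efficiency` table. Replicate wells for the same (sample, gene) are
#' averaged by arithmetic mean of Cq; empty cells are kept as missing with a
#' warning. Efficiencies may be fold-change values (e.g. 1.94) or percentages
#' (e.g. 94), auto-detected by magnitude.
#'
#' @param cq_path path to the Cq CSV.
#' @param meta_path path to the metadata CSV.
#' @param eff_path optional path to the efficiency CSV; when absent all genes
#'   get E = 2.
#' @param layout `"wide"` or `"long"`.
#' @return a [refstab_dataset()].
#' @export
load_dataset <- function(cq_path, meta_path, eff_path = NULL,
                         layout = c("wide", "long")) {
  layout <- match.arg(layout)
  for (p in c(cq_path, meta_path, eff_path))
    if (!file.exists(p)) stop_refstab("file not found: %s", p, module = "cq_io")
  cq <- switch(layout, wide = read_cq_wide(cq_path), long = read_cq_long(cq_path))
  meta <- utils::read.csv(meta_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  eff <- if (!is.null(eff_path)) read_efficiencies(eff_path) else NULL
  refstab_dataset(cq, meta, eff)
}

#' Write a Cq dataset to CSV files
#'
#' Inverse of [load_dataset()]; Cq values are written at full precision so a
#' write/load cycle round-trips bit-exactly.
#'
#' @param ds a [refstab_dataset()].
#' @param cq_path,meta_path output paths.
#' @param layout `"wide"` or `"long"`.
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(ds, cq_path, meta_path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  stopifnot(inherits(ds, "refstab_dataset"))
  if (layout == "wide") {
    df <- data.frame(gene = rownames(ds$cq), check.names = FALSE)
    for (s in colnames(ds$cq)) df[[s]] <- fmt_full(ds$cq[, s])
    utils::write.csv(df, cq_path, row.names = FALSE, quote = FALSE)
  } else {
    long <- expand.grid(gene = rownames(ds$cq), sample = colnames(ds$cq),
                        stringsAsFactors = FALSE)
    long$cq <- fmt_full(ds$cq[cbind(long$gene, long$sample)])
    utils::write.csv(long[, c("sample", "gene", "cq")], cq_path,
                     row.names = FALSE, quote = FALSE)
  }
  utils::write.csv(ds$meta, meta_path, row.names = FALSE)
  invisible(c(cq_path, meta_path))
}

#' Keep each dog's first (study-entry) sample
#'
#' Stability calculations use only the sample taken when the dog entered the
#' study, to avoid repeated-measures dependence between samples of one dog.
#' For each dog the sample with minimal `sample_number` is retained.
#'
#' @param ds a [refstab_dataset()].
#' @return a dataset with one sample per dog; idempotent.
#' @export
select_first_samples <- function(ds) {
  stopifnot(inherits(ds, "refstab_dataset"))
  meta <- ds$meta
  keep <- unlist(lapply(split(seq_len(nrow(meta)), meta$dog_id), function(idx) {
    mn <- min(meta$sample_number[idx])
    hit <- idx[meta$sample_number[idx] == mn]
    if (length(hit) > 1)
      stop_refstab("dog '%s' has %d samples sharing minimal sample_number %d",
                   meta$dog_id[hit[1]], length(hit), mn, module = "cq_io")
    hit
  }), use.names = FALSE)
  keep <- sort(keep)
  refstab_dataset(ds$cq[, meta$sample_id[keep], drop = FALSE],
                  meta[keep, , drop = FALSE],
                  ds$efficiencies)
}
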