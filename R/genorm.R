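# geNorm expression-stability analysis.
#
# For every pair of candidate genes (j, k) the log2 expression ratio
# A_jk,s = log2(q_js / q_ks) is computed across samples; its sample standard
# deviation V_jk measures how differently the two genes behave. The gene
# stability M_j is the arithmetic mean of V_jk over all partners k. Stepwise
# exclusion of the highest-M gene yields a ranking whose final two genes are
# reported as a jointly most stable pair (the pairwise measure cannot
# separate them). Normalization factors (geometric means of the top-n genes)
# and the pairwise variation V_{n/n+1} between sequential factors determine
# how many reference genes are sufficient (cutoff 0.15 by convention).

# Complete-case sample filter: samples missing any evaluated gene are dropped.
complete_samples <- function(q, warn = TRUE) {
  ok <- colSums(is.na(q)) == 0
  if (warn && any(!ok))
    warn_refstab("dropping %d sample(s) with missing values among %d evaluated gene(s)",
                 sum(!ok), nrow(q), module = "genorm")
  q[, ok, drop = FALSE]
}

as_quantity_matrix <- function(q) {
  if (inherits(q, "refstab_dataset"))
    stop_refstab("pass a quantity matrix (see relative_quantities()), not a dataset",
                 module = "genorm")
  stopifnot(is.matrix(q), is.numeric(q))
  if (is.null(rownames(q)) || is.null(colnames(q)))
    stop_refstab("quantity matrix needs gene rownames and sample colnames",
                 module = "genorm")
  if (any(q[!is.na(q)] <= 0))
    stop_refstab("relative quantities must be positive", module = "genorm")
  q
}

#' geNorm gene-stability M-values
#'
#' Computes, for each gene, the mean over partner genes of the sample
#' standard deviation of pairwise log2 expression ratios. Lower M means more
#' stable. Samples with a missing value in any evaluated gene are dropped
#' (complete-case) with a warning.
#'
#' @param q relative-quantity matrix (genes x samples), e.g. from
#'   [relative_quantities()].
#' @return named numeric vector of M-values.
#' @export
genorm_m_values <- function(q) {
  q <- as_quantity_matrix(q)
  if (nrow(q) < 3)
    stop_refstab("geNorm needs at least 3 genes (got %d)", nrow(q),
                 module = "genorm")
  q <- complete_samples(q)
  if (ncol(q) < 3)
    stop_refstab("geNorm needs at least 3 complete samples (got %d)", ncol(q),
                 module = "genorm")
  l <- log2(q)
  n_genes <- nrow(l)
  v <- matrix(0, n_genes, n_genes, dimnames = list(rownames(l), rownames(l)))
  for (j in seq_len(n_genes - 1)) {
    for (k in seq.int(j + 1, n_genes)) {
      v[j, k] <- v[k, j] <- stats::sd(l[j, ] - l[k, ])
    }
  }
  rowSums(v) / (n_genes - 1)
}

# Highest-M gene under the deterministic tie rule: among genes sharing the
# maximal M, the lexicographically larger id is removed first.
least_stable_gene <- function(m) {
  cand <- names(m)[m == max(m)]
  sort(cand, method = "radix")[length(cand)]
}

#' geNorm stepwise-exclusion ranking
#'
#' Iteratively removes the gene with the highest M-value and recomputes M on
#' the remaining set until two genes are left; those two form the jointly
#' most stable pair (their relative order is unresolvable by the pairwise
#' measure). Ties on M remove the lexicographically larger gene id.
#'
#' @inheritParams genorm_m_values
#' @return list with `m_values` (full-set M), `exclusion_order` (least to
#'   most stable, as removed), `best_pair` (sorted), `ranking` (most stable
#'   first: best pair then remaining genes by reverse exclusion), and
#'   `m_trace` (named list of M vectors per round).
#' @export
genorm_rank <- function(q) {
  q <- as_quantity_matrix(q)
  m_full <- genorm_m_values(q)
  current <- q
  exclusion <- character(0)
  trace <- list()
  round <- 1
  while (nrow(current) > 2) {
    m <- if (round == 1) m_full else suppressWarnings(genorm_m_values(current))
    trace[[round]] <- m
    worst <- least_stable_gene(m)
    exclusion <- c(exclusion, worst)
    current <- current[setdiff(rownames(current), worst), , drop = FALSE]
    round <- round + 1
  }
  best_pair <- sort(rownames(current), method = "radix")
  list(m_values = m_full,
       exclusion_order = exclusion,
       best_pair = best_pair,
       ranking = c(best_pair, rev(exclusion)),
       m_trace = trace)
}

#' Per-sample normalization factors
#'
#' The normalization factor NF_s is the geometric mean of the relative
#' quantities of the selected reference genes in sample s.
#'
#' @inheritParams genorm_m_values
#' @param genes character vector (length >= 2) of gene ids to combine.
#' @return named numeric vector of normalization factors per sample.
#' @export
normalization_factors <- function(q, genes) {
  q <- as_quantity_matrix(q)
  if (length(genes) < 2)
    stop_refstab("normalization needs at least 2 genes (got %d)",
                 length(genes), module = "genorm")
  missing_genes <- setdiff(genes, rownames(q))
  if (length(missing_genes))
    stop_refstab("unknown gene(s): %s", paste(missing_genes, collapse = ", "),
                 module = "genorm")
  sub <- q[genes, , drop = FALSE]
  if (anyNA(sub))
    stop_refstab("missing quantities for the selected genes; drop incomplete samples first",
                 module = "genorm")
  apply(sub, 2, geomean)
}

#' Pairwise variation between sequential normalization factors
#'
#' For n = 2 .. (genes - 1), V_{n/n+1} is the sample standard deviation over
#' samples of log2(NF_n / NF_{n+1}), where NF_n uses the n top-ranked genes.
#' A small V means the (n+1)-th gene adds little to the normalization factor.
#'
#' @inheritParams genorm_m_values
#' @param ranking character vector covering all genes, most stable first
#'   (e.g. `genorm_rank(q)$ranking`).
#' @return data.frame with columns `n` and `v`; zero rows when fewer than 3
#'   genes are available.
#' @export
pairwise_variation_series <- function(q, ranking) {
  q <- as_quantity_matrix(q)
  if (!setequal(ranking, rownames(q)) || length(ranking) != nrow(q))
    stop_refstab("ranking must be a permutation of the gene ids",
                 module = "genorm")
  q <- complete_samples(q)
  n_genes <- length(ranking)
  if (n_genes < 3)
    return(data.frame(n = integer(0), v = numeric(0)))
  v <- vapply(2:(n_genes - 1), function(n) {
    nf_n <- normalization_factors(q, ranking[1:n])
    nf_n1 <- normalization_factors(q, ranking[1:(n + 1)])
    stats::sd(log2(nf_n / nf_n1))
  }, numeric(1))
  data.frame(n = 2:(n_genes - 1), v = v)
}

#' Optimal number of reference genes
#'
#' Applies the conventional cutoff rule: the optimal count is the smallest n
#' whose pairwise variation V_{n/n+1} falls below the cutoff (default 0.15).
#' When no V is below the cutoff the count is reported as not reached.
#'
#' @param v_series data.frame from [pairwise_variation_series()].
#' @param cutoff positive cutoff on V, default 0.15.
#' @return list with `optimal_n` (integer or `NA`), `reached` (logical) and
#'   the `v_series` examined.
#' @export
optimal_gene_count <- function(v_series, cutoff = 0.15) {
  stopifnot(is.data.frame(v_series), all(c("n", "v") %in% names(v_series)),
            cutoff > 0)
  if (nrow(v_series) == 0)
    stop_refstab("empty V-series", module = "genorm")
  hit <- which(v_series$v < cutoff)
  if (length(hit)) {
    list(optimal_n = as.integer(v_series$n[hit[1]]), reached = TRUE,
         v_series = v_series)
  } else {
    list(optimal_n = NA_integer_, reached = FALSE, v_series = v_series)
  }
}

#' Full geNorm analysis
#'
#' Convenience wrapper running [genorm_m_values()], [genorm_rank()],
#' [pairwise_variation_series()], per-n normalization factors and
#' [optimal_gene_count()] in one call.
#'
#' @inheritParams genorm_m_values
#' @param cutoff V cutoff for the optimal gene count, default 0.15.
#' @return object of class `genorm_result`: `m_values`, `exclusion_order`,
#'   `best_pair`, `ranking`, `m_trace`, `nf_table` (samples x n, columns
#'   `NF2..NFk`), `v_series`, `optimal_n`, `optimal_reached`, `cutoff`,
#'   `n_samples_used`.
#' @export
genorm <- function(q, cutoff = 0.15) {
  q <- as_quantity_matrix(q)
  rk <- genorm_rank(q)
  qc <- suppressWarnings(complete_samples(q))
  n_genes <- nrow(q)
  nf_table <- sapply(2:n_genes, function(n)
    normalization_factors(qc, rk$ranking[1:n]))
  colnames(nf_table) <- paste0("NF", 2:n_genes)
  vs <- suppressWarnings(pairwise_variation_series(q, rk$ranking))
  opt <- optimal_gene_count(vs, cutoff)
  structure(c(rk, list(nf_table = nf_table, v_series = vs,
                       optimal_n = opt$optimal_n,
                       optimal_reached = opt$reached, cutoff = cutoff,
                       n_samples_used = ncol(qc))),
            class = "genorm_result")
}

#' @export
print.genorm_result <- function(x, ...) {
  cat("geNorm stability analysis\n")
  cat(sprintf("  %d genes, %d complete samples\n",
              length(x$m_values), x$n_samples_used))
  ord <- x$ranking
  m <- x$m_values[ord]
  cat("  ranking (most stable first):\n")
  for (i in seq_along(ord))
    cat(sprintf("    %d. %-10s M = %.4f%s\n", i, ord[i], m[i],
                if (ord[i] %in% x$best_pair) "  (best pair)" else ""))
  if (x$optimal_reached) {
    cat(sprintf("  optimal gene count: %d (first V < %.2f)\n",
                x$optimal_n, x$cutoff))
  } else {
    cat(sprintf("  optimal gene count not reached (no V < %.2f)\n", x$cutoff))
  }
  invisible(x)
}
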