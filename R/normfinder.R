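# Model-based (NormFinder-style) stability estimation.
#
# Expression on the log2-quantity scale is modelled additively:
#   x_igj = alpha_i + c_gj + d_ig + eps_igj,   eps ~ N(0, sigma2_ig)
# for gene i, sample group g, sample j: a gene level, a per-sample effect
# (template amount), a gene-by-group interaction d_ig (the systematic
# intergroup deviation a bad reference gene shows) and within-group noise.
# Sample effects are removed exactly by centering each sample over genes;
# the centering induces a covariance between genes that the variance
# estimator corrects for. Intergroup deviations are shrunken toward zero by
# an empirical-Bayes factor using gamma, the variance of true deviations
# across genes and groups. A gene's stability value is the average over
# groups of the shrunken deviation magnitude plus its posterior spread;
# lower is more stable.

#' Model-based stability values
#'
#' Estimates per-gene, per-group intergroup deviations and intragroup
#' variances from log2 relative quantities and combines them into a single
#' stability value per gene (lower = more stable). With a single group the
#' stability value reduces to the intragroup standard deviation.
#'
#' The estimator: with `z` the gene-centered log2 quantities, group means
#' `m_ig` are row-centered into deviations `d_ig`; within-group variances
#' `s2_ig` are bias-corrected to `sigma2_ig = (I/(I-2)) (s2_ig -
#' T_g/(I(I-1)))` with `T_g` the per-group sum of `s2`; the deviation
#' variance `gamma` is a clipped method-of-moments estimate with
#' `(I-1)(G-1)` degrees of freedom; deviations are shrunk by
#' `gamma/(gamma + sigma2_ig/n_g)`.
#'
#' @param q relative-quantity matrix (genes x samples); samples missing any
#'   gene are dropped with a warning.
#' @param groups vector or factor of group labels, either named by sample id
#'   or in column order of `q`.
#' @param var_floor lower bound on variance estimates keeping stability
#'   defined for degenerate (noise-free) inputs.
#' @return object of class `normfinder_result`: `stability` (named, log2
#'   units), `d_hat` (genes x groups), `sigma2_hat`, `gamma_hat`,
#'   `best_gene`, `group_sizes`, `n_samples_used`.
#' @export
normfinder_stability <- function(q, groups, var_floor = 1e-12) {
  q <- as_quantity_matrix(q)
  n_genes <- nrow(q)
  if (n_genes < 3)
    stop_refstab("model-based stability needs at least 3 genes (got %d)",
                 n_genes, module = "normfinder")
  if (!is.null(names(groups))) {
    miss <- setdiff(colnames(q), names(groups))
    if (length(miss))
      stop_refstab("no group label for sample(s): %s",
                   paste(miss, collapse = ", "), module = "normfinder")
    groups <- groups[colnames(q)]
  } else if (length(groups) != ncol(q)) {
    stop_refstab("groups must be named by sample or match the sample count",
                 module = "normfinder")
  }
  ok <- colSums(is.na(q)) == 0
  if (any(!ok)) {
    warn_refstab("dropping %d incomplete sample(s)", sum(!ok),
                 module = "normfinder")
    q <- q[, ok, drop = FALSE]
    groups <- groups[ok]
  }
  groups <- droplevels(factor(groups))
  sizes <- table(groups)
  if (any(sizes < 2))
    stop_refstab("every group needs at least 2 complete samples; too small: %s",
                 paste(names(sizes)[sizes < 2], collapse = ", "),
                 module = "normfinder")
  g_levels <- levels(groups)
  n_groups <- length(g_levels)

  x <- log2(q)
  z <- sweep(x, 2, colMeans(x))               # remove per-sample effects
  m <- sapply(g_levels, function(g) rowMeans(z[, groups == g, drop = FALSE]))
  s2 <- sapply(g_levels, function(g)
    apply(z[, groups == g, drop = FALSE], 1, stats::var))
  m <- matrix(m, n_genes, n_groups, dimnames = list(rownames(q), g_levels))
  s2 <- matrix(s2, n_genes, n_groups, dimnames = list(rownames(q), g_levels))
  n_g <- as.numeric(sizes[g_levels])

  # centering-bias correction: E[s2_ig] = sigma2_ig (1 - 2/I) + S_g / I^2
  t_g <- colSums(s2)
  sigma2 <- (n_genes / (n_genes - 2)) *
    sweep(s2, 2, t_g / (n_genes * (n_genes - 1)))
  sigma2 <- pmax(sigma2, var_floor)

  if (n_groups == 1) {
    rho <- sqrt(sigma2[, 1])
    d_hat <- matrix(0, n_genes, 1, dimnames = dimnames(m))
    gamma_hat <- NA_real_
  } else {
    d_hat <- m - rowMeans(m)                  # double-centered by construction
    noise <- sweep(sigma2, 2, n_g, "/")       # sigma2_ig / n_g
    gamma_hat <- max(0, sum(d_hat^2) / ((n_genes - 1) * (n_groups - 1)) -
                          mean(noise))
    shrink <- gamma_hat / (gamma_hat + noise)
    d_tilde <- d_hat * shrink
    spread <- sqrt(gamma_hat * noise / (gamma_hat + noise))
    rho <- rowMeans(abs(d_tilde) + spread)
  }
  names(rho) <- rownames(q)
  structure(list(stability = rho,
                 d_hat = d_hat,
                 sigma2_hat = sigma2,
                 gamma_hat = gamma_hat,
                 best_gene = names(rho)[which.min(rho)],
                 group_sizes = stats::setNames(n_g, g_levels),
                 n_samples_used = ncol(q)),
            class = "normfinder_result")
}

#' Best pair of reference genes under the model-based criterion
#'
#' Averaging two genes averages their intergroup deviations and quarters the
#' sum of their variances; the pair stability applies the same shrinkage and
#' spread rule to the averaged quantities. Genes whose deviations cancel
#' (opposite signs) make particularly good pairs. Requires at least two
#' sample groups.
#'
#' @param result a `normfinder_result` with two or more groups.
#' @return list with `best_pair` (sorted gene ids), `pair_stability`, and
#'   `pair_table` (all pairs with their stability, ascending).
#' @export
normfinder_best_pair <- function(result) {
  stopifnot(inherits(result, "normfinder_result"))
  if (ncol(result$d_hat) < 2 || is.na(result$gamma_hat))
    stop_refstab("pair stability needs at least 2 groups", module = "normfinder")
  genes <- rownames(result$d_hat)
  n_g <- result$group_sizes
  gamma <- result$gamma_hat
  pairs <- utils::combn(genes, 2)
  rho <- apply(pairs, 2, function(pr) {
    d_pair <- (result$d_hat[pr[1], ] + result$d_hat[pr[2], ]) / 2
    s2_pair <- (result$sigma2_hat[pr[1], ] + result$sigma2_hat[pr[2], ]) / 4
    noise <- s2_pair / n_g
    d_tilde <- d_pair * gamma / (gamma + noise)
    mean(abs(d_tilde) + sqrt(gamma * noise / (gamma + noise)))
  })
  ord <- order(rho, pairs[1, ], pairs[2, ], method = "radix")
  tab <- data.frame(gene1 = pairs[1, ord], gene2 = pairs[2, ord],
                    stability = rho[ord], row.names = NULL)
  list(best_pair = sort(c(tab$gene1[1], tab$gene2[1]), method = "radix"),
       pair_stability = tab$stability[1],
       pair_table = tab)
}

#' @export
print.normfinder_result <- function(x, ...) {
  cat("Model-based stability analysis\n")
  cat(sprintf("  %d genes, %d samples, groups: %s\n",
              length(x$stability), x$n_samples_used,
              paste(sprintf("%s (n=%d)", names(x$group_sizes),
                            x$group_sizes), collapse = ", ")))
  if (!is.na(x$gamma_hat))
    cat(sprintf("  intergroup deviation variance (gamma): %.4g\n", x$gamma_hat))
  ord <- order(x$stability)
  for (i in seq_along(ord))
    cat(sprintf("    %d. %-10s stability = %.4f\n", i,
                names(x$stability)[ord[i]], x$stability[ord[i]]))
  cat(sprintf("  best gene: %s\n", x$best_gene))
  invisible(x)
}

#' Leukocyte-count quartile grouping
#'
#' Builds a four-level grouping of samples by quartiles of the leukocyte
#' count (sample quantiles, type 7), an alternative stratification to the
#' disease groups for the model-based stability analysis.
#'
#' @param ds a [refstab_dataset()] (typically after
#'   [select_first_samples()]); all samples need `wbc_count`.
#' @return factor named by sample id with levels `Q1..Q4`.
#' @export
wbc_quartile_groups <- function(ds) {
  stopifnot(inherits(ds, "refstab_dataset"))
  wbc <- ds$meta$wbc_count
  if (anyNA(wbc))
    stop_refstab("wbc_count missing for %d sample(s)", sum(is.na(wbc)),
                 module = "normfinder")
  br <- stats::quantile(wbc, probs = seq(0, 1, 0.25), type = 7)
  br <- unique(br)
  if (length(br) < 3)
    stop_refstab("leukocyte counts too tied for quartile grouping",
                 module = "normfinder")
  g <- cut(wbc, breaks = br, include.lowest = TRUE,
           labels = paste0("Q", seq_len(length(br) - 1)))
  stats::setNames(g, ds$meta$sample_id)
}
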