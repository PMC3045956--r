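# Covariate diagnostics: does the experimental condition move a candidate
# reference gene's Cq? Disease-group ANOVA, the leukocytosis dichotomy
# (reference-range vs clinically relevant leukocytosis) with Holm-corrected
# Welch t-tests, Cq-versus-log(leukocyte count) slopes with a per-dog random
# intercept, and a likelihood-ratio test for a sampling-occasion effect.

#' Holm step-down multiple-testing adjustment
#'
#' Validated wrapper around the Holm step-down procedure: p-values are
#' sorted ascending, p_(k) is multiplied by (m - k + 1), running maxima
#' enforce monotonicity, results are capped at 1 and returned in input
#' order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))  # 0.03, 0.06, 0.06
#' @export
holm_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop_refstab("p-values must be numbers in [0, 1]", module = "cohort_stats")
  stats::p.adjust(p, method = "holm")
}

gene_cq <- function(ds, gene) {
  stopifnot(inherits(ds, "refstab_dataset"))
  if (!gene %in% rownames(ds$cq))
    stop_refstab("unknown gene '%s'", gene, module = "cohort_stats")
  ds$cq[gene, ]
}

#' One-way ANOVA of Cq across a grouping factor
#'
#' Compares mean Cq across disease groups (or any metadata factor) by
#' fixed-effects one-way ANOVA, optionally followed by all-pairs Welch
#' t-tests with Holm correction. Groups with fewer than 2 observations are
#' dropped with a warning. Analyses of group differences conventionally use
#' each dog's first sample; pass a dataset through [select_first_samples()]
#' for that behaviour.
#'
#' @param ds a [refstab_dataset()].
#' @param gene gene id.
#' @param factor_name metadata column to group by (default `disease_group`).
#' @param pairwise also run all-pairs Welch t-tests with [holm_adjust()].
#' @return list with `f`, `df`, `p`, `group_means`, `group_sd`, `group_n`
#'   and, when requested, `pairwise` (data.frame with raw and Holm p).
#' @export
anova_by_group <- function(ds, gene, factor_name = "disease_group",
                           pairwise = FALSE) {
  cq <- gene_cq(ds, gene)
  if (!factor_name %in% names(ds$meta))
    stop_refstab("no metadata column '%s'", factor_name, module = "cohort_stats")
  grp <- as.character(ds$meta[[factor_name]])
  keep <- !is.na(cq) & !is.na(grp)
  cq <- cq[keep]; grp <- grp[keep]
  sizes <- table(grp)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warn_refstab("dropping group(s) with < 2 samples: %s",
                 paste(small, collapse = ", "), module = "cohort_stats")
    keep <- !grp %in% small
    cq <- cq[keep]; grp <- grp[keep]
  }
  grp <- factor(grp)
  if (nlevels(grp) < 2)
    stop_refstab("need at least 2 usable groups for gene '%s'", gene,
                 module = "cohort_stats")
  fit <- stats::aov(cq ~ grp)
  tab <- summary(fit)[[1]]
  out <- list(gene = gene,
              f = tab[1, "F value"],
              df = c(tab[1, "Df"], tab[2, "Df"]),
              p = tab[1, "Pr(>F)"],
              group_means = c(tapply(cq, grp, mean)),
              group_sd = c(tapply(cq, grp, stats::sd)),
              group_n = as.integer(table(grp)))
  names(out$group_n) <- levels(grp)
  if (pairwise) {
    prs <- utils::combn(levels(grp), 2)
    rows <- apply(prs, 2, function(pr) {
      tt <- stats::t.test(cq[grp == pr[1]], cq[grp == pr[2]])
      data.frame(group1 = pr[1], group2 = pr[2],
                 difference = mean(cq[grp == pr[2]]) - mean(cq[grp == pr[1]]),
                 statistic = unname(tt$statistic), p = tt$p.value)
    })
    pw <- do.call(rbind, rows)
    pw$p_holm <- holm_adjust(pw$p)
    out$pairwise <- pw
  }
  out
}

#' Cq comparison between normal-range and high leukocyte counts
#'
#' Welch two-sample t-test of a gene's Cq between dogs whose leukocyte count
#' lies within the reference range (default 4.5-14.6 x 1e9/l) and dogs above
#' a clinically relevant leukocytosis cutoff (default 30 x 1e9/l). Samples
#' between the two strata are excluded by construction. Holm correction
#' across a gene panel is the caller's job (see [wbc_panel_compare()]).
#'
#' @param ds a [refstab_dataset()] with `wbc_count` present.
#' @param gene gene id.
#' @param ref_range length-2 numeric reference range for the leukocyte count.
#' @param high_cutoff leukocytosis threshold.
#' @return list with per-stratum `n`, `mean`, `sd`, `difference`
#'   (high minus within-range, in Cq), Welch `statistic`, `df` and `p`.
#' @export
wbc_dichotomous_compare <- function(ds, gene, ref_range = c(4.5, 14.6),
                                    high_cutoff = 30) {
  cq <- gene_cq(ds, gene)
  wbc <- ds$meta$wbc_count
  keep <- !is.na(cq) & !is.na(wbc)
  cq <- cq[keep]; wbc <- wbc[keep]
  within <- cq[wbc >= ref_range[1] & wbc <= ref_range[2]]
  high <- cq[wbc > high_cutoff]
  if (length(within) < 2)
    stop_refstab("within-reference-range stratum has %d sample(s) (< 2) for '%s'",
                 length(within), gene, module = "cohort_stats")
  if (length(high) < 2)
    stop_refstab("high-count stratum has %d sample(s) (< 2) for '%s'",
                 length(high), gene, module = "cohort_stats")
  tt <- stats::t.test(high, within)  # Welch
  list(gene = gene,
       n_within = length(within), n_high = length(high),
       mean_within = mean(within), sd_within = stats::sd(within),
       mean_high = mean(high), sd_high = stats::sd(high),
       difference = mean(high) - mean(within),
       statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Leukocyte-count dichotomy across a gene panel
#'
#' Runs [wbc_dichotomous_compare()] for every gene and applies the Holm
#' correction across the panel.
#'
#' @inheritParams wbc_dichotomous_compare
#' @param genes gene ids (default: all genes in the dataset).
#' @return data.frame, one row per gene, with stratum summaries, raw `p` and
#'   `p_holm`.
#' @export
wbc_panel_compare <- function(ds, genes = rownames(ds$cq),
                              ref_range = c(4.5, 14.6), high_cutoff = 30) {
  rows <- lapply(genes, function(g)
    as.data.frame(wbc_dichotomous_compare(ds, g, ref_range, high_cutoff)))
  out <- do.call(rbind, rows)
  out$p_holm <- holm_adjust(out$p)
  out
}

# Profiled-REML random-intercept fit.
#
# Model: y = X beta + u[dog] + eps, u ~ N(0, tau2), eps ~ N(0, sigma2).
# For a candidate ratio lambda = tau2/sigma2 the marginal covariance is
# sigma2 (I + lambda Z Z'); whitening is a per-dog partial centering
# y* = y - theta_d * ybar_d with theta_d = 1 - 1/sqrt(1 + m_d lambda), after
# which GLS reduces to OLS. The REML criterion is profiled over lambda by
# 1-D bounded search on the log scale.
reml_random_intercept <- function(y, x, dog, lambda_bounds = c(1e-8, 1e4)) {
  dog <- factor(dog)
  n <- length(y)
  xmat <- cbind(1, x)
  p <- ncol(xmat)
  m_d <- tabulate(dog)
  dog_i <- as.integer(dog)
  ybar <- (rowsum(y, dog_i) / m_d)[dog_i]
  xbar <- (rowsum(xmat, dog_i) / m_d)[dog_i, , drop = FALSE]

  fit_for <- function(lambda) {
    theta <- (1 - 1 / sqrt(1 + m_d * lambda))[dog_i]
    ystar <- y - theta * ybar
    xstar <- xmat - theta * xbar
    qr_x <- qr(xstar)
    beta <- qr.coef(qr_x, ystar)
    rss <- sum(qr.resid(qr_x, ystar)^2)
    xtx <- crossprod(xstar)
    logdet_v <- sum(log(1 + m_d * lambda))
    logdet_xvx <- determinant(xtx, logarithm = TRUE)$modulus
    crit <- (n - p) * log(rss) + logdet_v + as.numeric(logdet_xvx)
    list(crit = crit, beta = beta, rss = rss, xtx = xtx)
  }

  opt <- stats::optimize(function(ll) fit_for(exp(ll))$crit,
                         interval = log(lambda_bounds), tol = 1e-9)
  lambda <- exp(opt$minimum)
  # snap to the lower boundary when the profile is flat or boundary-optimal
  # (e.g. one observation per dog, where the ratio is unidentified)
  if (fit_for(lambda_bounds[1])$crit <= opt$objective + 1e-6)
    lambda <- lambda_bounds[1]
  final <- fit_for(lambda)
  sigma2 <- final$rss / (n - p)
  tau2 <- lambda * sigma2
  vcov_beta <- sigma2 * solve(final$xtx)
  list(beta = final$beta, se = sqrt(diag(vcov_beta)), sigma2 = sigma2,
       tau2 = tau2, lambda = lambda, n = n, n_dogs = length(m_d), p = p)
}

#' Cq slope on log leukocyte count
#'
#' Estimates how a gene's Cq changes with the leukocyte count, reported both
#' per unit ln(count) and per tenfold increase (the two differ exactly by a
#' factor ln(10)). Two estimators: ordinary least squares on first samples
#' only, or a random-intercept linear mixed model over all samples with the
#' dog as grouping factor, fitted by REML with the variance ratio profiled
#' by one-dimensional bounded search.
#'
#' @param ds a [refstab_dataset()] with `wbc_count`.
#' @param gene gene id.
#' @param method `"lmm_all_samples"` (default) or `"ols_first_sample"`.
#' @return list of class `slope_estimate`: `gene`, `beta_ln`,
#'   `beta_per_tenfold`, `se_ln`, `se_per_tenfold`, `p` (Wald), `tau2` and
#'   `sigma2` (mixed model) or `sigma2` only (OLS), `n`, `method`.
#' @export
wbc_slope_lmm <- function(ds, gene,
                          method = c("lmm_all_samples", "ols_first_sample")) {
  method <- match.arg(method)
  if (method == "ols_first_sample") ds <- select_first_samples(ds)
  cq <- gene_cq(ds, gene)
  wbc <- ds$meta$wbc_count
  keep <- !is.na(cq) & !is.na(wbc)
  y <- cq[keep]
  x <- log(wbc[keep])
  dog <- ds$meta$dog_id[keep]
  if (length(y) < 10)
    stop_refstab("need at least 10 observations with Cq and leukocyte count (got %d)",
                 length(y), module = "cohort_stats")
  if (stats::sd(x) == 0)
    stop_refstab("leukocyte counts are constant; slope not identifiable",
                 module = "cohort_stats")
  if (method == "ols_first_sample") {
    fit <- stats::lm(y ~ x)
    sm <- summary(fit)
    beta_ln <- unname(stats::coef(fit)[2])
    se_ln <- sm$coefficients[2, "Std. Error"]
    pval <- sm$coefficients[2, "Pr(>|t|)"]
    tau2 <- NA_real_
    sigma2 <- sm$sigma^2
  } else {
    fit <- reml_random_intercept(y, x, dog)
    beta_ln <- unname(fit$beta[2])
    se_ln <- unname(fit$se[2])
    pval <- 2 * stats::pnorm(-abs(beta_ln / se_ln))
    tau2 <- fit$tau2
    sigma2 <- fit$sigma2
  }
  structure(list(gene = gene, beta_ln = beta_ln,
                 beta_per_tenfold = beta_ln * log(10),
                 se_ln = se_ln, se_per_tenfold = se_ln * log(10),
                 p = pval, tau2 = tau2, sigma2 = sigma2,
                 n = length(y), method = method),
            class = "slope_estimate")
}

#' Likelihood-ratio test for a sampling-occasion effect
#'
#' Tests whether the sampling occasion ("sample number") explains Cq beyond
#' between-dog differences: fixed-effects least-squares fits of
#' `Cq ~ dog` against `Cq ~ dog + sample_number` (both as factors) compared
#' by the likelihood-ratio statistic `N * ln(RSS0/RSS1)` on a chi-square
#' with (sample-number levels - 1) degrees of freedom.
#'
#' @param ds a [refstab_dataset()] with repeated samples.
#' @param gene gene id.
#' @return list with `statistic`, `df`, `p`, `models` (labels), `n`.
#' @export
sample_number_lrt <- function(ds, gene) {
  cq <- gene_cq(ds, gene)
  keep <- !is.na(cq)
  y <- cq[keep]
  dog <- factor(ds$meta$dog_id[keep])
  occ <- factor(ds$meta$sample_number[keep])
  if (nlevels(occ) < 2)
    stop_refstab("sample_number is constant; nothing to test",
                 module = "cohort_stats")
  n_rep <- sum(table(dog) >= 2)
  if (n_rep < 2)
    stop_refstab("need at least 2 dogs with repeated samples (got %d)", n_rep,
                 module = "cohort_stats")
  x0 <- stats::model.matrix(~dog)
  x1 <- stats::model.matrix(~ dog + occ)
  rss0 <- sum(stats::lm.fit(x0, y)$residuals^2)
  rss1 <- sum(stats::lm.fit(x1, y)$residuals^2)
  n <- length(y)
  tol <- 1e-12 * (sum(y^2) + 1)
  stat <- if (rss0 - rss1 <= tol) 0       # occasion adds nothing (incl. exact fits)
          else if (rss1 <= tol) Inf       # occasion removes all residual error
          else n * log(rss0 / rss1)
  df <- nlevels(occ) - 1L
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE),
       models = c(null = "Cq ~ dog", alt = "Cq ~ dog + sample_number"),
       n = n)
}
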