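test_that("Holm adjustment matches the hand-computed step-down rule", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(c(1, 1)), c(1, 1))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(holm_adjust(c(-0.1)), "\\[0, 1\\]")
})

test_that("Holm adjustment is permutation-equivariant and monotone", {
  set.seed(31)
  for (i in 1:20) {
    p <- runif(7)
    perm <- sample(7)
    expect_equal(holm_adjust(p)[perm], holm_adjust(p[perm]))
    adj <- holm_adjust(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    # raising one raw p never lowers any adjusted p
    p2 <- p
    p2[3] <- min(1, p2[3] + 0.1)
    expect_true(all(holm_adjust(p2) >= adj - 1e-12))
  }
})

test_that("group ANOVA matches textbook hand computation", {
  cq <- matrix(c(1, 2, 3, 1, 2, 3), 1,
               dimnames = list("G1", paste0("S", 1:6)))
  ds <- make_dataset(cq, disease_group = rep(c("A", "B"), each = 3))
  a0 <- anova_by_group(ds, "G1")
  expect_equal(a0$f, 0)
  expect_equal(a0$p, 1)
  cq2 <- matrix(c(1, 2, 3, 4, 5, 6), 1,
                dimnames = list("G1", paste0("S", 1:6)))
  ds2 <- make_dataset(cq2, disease_group = rep(c("A", "B"), each = 3))
  a1 <- anova_by_group(ds2, "G1", pairwise = TRUE)
  expect_equal(a1$f, 13.5, tolerance = 1e-12)  # MSB 13.5 / MSW 1
  expect_equal(unname(a1$group_means), c(2, 5))
  expect_equal(a1$pairwise$difference, 3)
  expect_equal(a1$pairwise$p_holm, a1$pairwise$p)
})

test_that("undersized groups are dropped before the ANOVA", {
  cq <- matrix(c(1, 2, 3, 4, 5, 6, 9), 1,
               dimnames = list("G1", paste0("S", 1:7)))
  ds <- make_dataset(cq, disease_group = c(rep(c("A", "B"), each = 3), "C"))
  expect_warning(a <- anova_by_group(ds, "G1"), "dropping group")
  expect_named(a$group_means, c("A", "B"))
  ds2 <- make_dataset(cq[, 1:4, drop = FALSE],
                      disease_group = c("A", "A", "A", "B"))
  expect_warning(expect_error(anova_by_group(ds2, "G1"), "2 usable groups"))
})

test_that("the leukocytosis dichotomy uses only the two strata", {
  # counts 5-12 within range, 16-29 in the excluded gap, > 30 high
  wbc <- c(5, 8, 10, 12, 16, 20, 29, 31, 45, 60)
  cq <- matrix(c(20.1, 19.9, 20.2, 19.8, 35, 35, 35, 21.1, 20.9, 21.0), 1,
               dimnames = list("G1", sprintf("S%02d", 1:10)))
  ds <- make_dataset(cq, wbc_count = wbc)
  r <- wbc_dichotomous_compare(ds, "G1")
  expect_identical(r$n_within, 4L)
  expect_identical(r$n_high, 3L)
  expect_equal(r$difference, 1)  # gap samples at Cq 35 never contribute
  ds_empty <- make_dataset(cq, wbc_count = rep(8, 10))
  expect_error(wbc_dichotomous_compare(ds_empty, "G1"), "high-count stratum")
})

test_that("Welch test equals the pooled t on balanced equal-variance data", {
  set.seed(32)
  x <- rnorm(30, 20, 1)
  y <- rnorm(30, 20.5, 1)
  welch <- t.test(x, y)
  pooled <- t.test(x, y, var.equal = TRUE)
  expect_equal(unname(welch$statistic), unname(pooled$statistic),
               tolerance = 1e-9)
})

test_that("panel-wide dichotomy applies Holm across genes", {
  set.seed(33)
  cq <- matrix(rnorm(4 * 40, 20, 0.5), 4,
               dimnames = list(paste0("G", 1:4), sprintf("S%02d", 1:40)))
  wbc <- rep(c(8, 40), each = 20)
  cq[1, wbc > 30] <- cq[1, wbc > 30] + 2  # one truly shifted gene
  ds <- make_dataset(cq, wbc_count = wbc)
  tab <- wbc_panel_compare(ds)
  expect_identical(nrow(tab), 4L)
  expect_equal(tab$p_holm, holm_adjust(tab$p))
  expect_lt(tab$p_holm[1], 0.001)
})

test_that("per-tenfold slopes are the ln-scale coefficient times ln(10)", {
  set.seed(34)
  n <- 60
  wbc <- rlnorm(n, log(15), 0.6)
  cq <- matrix(21 + 0.4 * log(wbc) + rnorm(n, 0, 0.3), 1,
               dimnames = list("G1", sprintf("S%02d", seq_len(n))))
  ds <- make_dataset(cq, wbc_count = wbc)
  for (method in c("ols_first_sample", "lmm_all_samples")) {
    s <- wbc_slope_lmm(ds, "G1", method = method)
    expect_equal(s$beta_per_tenfold, s$beta_ln * log(10), tolerance = 1e-12)
    expect_equal(s$beta_ln, 0.4, tolerance = 0.2)
  }
})

test_that("one sample per dog collapses the mixed model onto OLS", {
  set.seed(35)
  n <- 40
  wbc <- rlnorm(n, log(12), 0.5)
  cq <- matrix(18 + 0.9 * log(wbc) + rnorm(n, 0, 0.4), 1,
               dimnames = list("G1", sprintf("S%02d", seq_len(n))))
  ds <- make_dataset(cq, wbc_count = wbc)
  ols <- wbc_slope_lmm(ds, "G1", method = "ols_first_sample")
  lmm <- wbc_slope_lmm(ds, "G1", method = "lmm_all_samples")
  expect_equal(lmm$beta_ln, ols$beta_ln, tolerance = 1e-6)
  expect_lt(lmm$tau2, 1e-6)
})

test_that("the mixed-model fit agrees with an established REML implementation", {
  skip_if_not_installed("lme4")
  set.seed(36)
  n_dogs <- 50
  dogs <- rep(sprintf("d%02d", seq_len(n_dogs)), each = 3)
  u <- rnorm(n_dogs, 0, 0.5)[rep(seq_len(n_dogs), each = 3)]
  wbc <- rlnorm(length(dogs), log(15), 0.6)
  y <- 19 + 0.5 * log(wbc) + u + rnorm(length(dogs), 0, 0.4)
  cq <- matrix(y, 1, dimnames = list("G1", sprintf("S%03d", seq_along(y))))
  ds <- make_dataset(cq, dog_id = dogs,
                     sample_number = rep(1:3, n_dogs),
                     wbc_count = wbc)
  s <- wbc_slope_lmm(ds, "G1", method = "lmm_all_samples")
  fit <- lme4::lmer(y ~ x + (1 | dog),
                    data = data.frame(y = y, x = log(wbc), dog = dogs),
                    REML = TRUE)
  expect_equal(s$beta_ln, unname(lme4::fixef(fit)[2]), tolerance = 1e-5)
  expect_equal(s$tau2, as.numeric(lme4::VarCorr(fit)$dog), tolerance = 1e-4)
  expect_equal(s$sigma2, stats::sigma(fit)^2, tolerance = 1e-5)
  expect_equal(s$se_ln, sqrt(as.matrix(stats::vcov(fit))[2, 2]),
               tolerance = 1e-5)
})

test_that("the REML objective is unimodal over the profiled ratio", {
  # grid scan of an independently coded REML criterion: down, then up
  set.seed(37)
  n_dogs <- 30
  dogs <- factor(rep(seq_len(n_dogs), each = 4))
  u <- rnorm(n_dogs, 0, 0.6)[as.integer(dogs)]
  x <- rnorm(length(dogs))
  y <- 2 + 0.3 * x + u + rnorm(length(dogs), 0, 0.5)
  xmat <- cbind(1, x)
  crit_at <- function(lambda) {
    vinv <- matrix(0, length(y), length(y))
    for (d in levels(dogs)) {
      i <- which(dogs == d)
      m <- length(i)
      vinv[i, i] <- diag(m) - lambda / (1 + m * lambda)
    }
    xvx <- t(xmat) %*% vinv %*% xmat
    beta <- solve(xvx, t(xmat) %*% vinv %*% y)
    r <- y - xmat %*% beta
    rss <- as.numeric(t(r) %*% vinv %*% r)
    logdet_v <- sum(log(1 + lengths(split(y, dogs)) * lambda))
    (length(y) - 2) * log(rss) + logdet_v +
      as.numeric(determinant(xvx, logarithm = TRUE)$modulus)
  }
  grid <- exp(seq(log(1e-6), log(100), length.out = 60))
  obj <- vapply(grid, crit_at, numeric(1))
  slope_sign <- sign(diff(obj))
  changes <- sum(diff(slope_sign[slope_sign != 0]) != 0)
  expect_lte(changes, 1)
  # the package optimum is no worse than the best grid point
  fit <- refstab:::reml_random_intercept(y, x, dogs)
  expect_lte(crit_at(fit$lambda), min(obj) + 1e-6)
})

test_that("degenerate slope inputs are rejected", {
  cq <- matrix(rnorm(12, 20), 1, dimnames = list("G1", sprintf("S%02d", 1:12)))
  ds_const <- make_dataset(cq, wbc_count = rep(10, 12))
  expect_error(wbc_slope_lmm(ds_const, "G1"), "constant")
  ds_few <- make_dataset(cq[, 1:5, drop = FALSE], wbc_count = c(5, 7, 9, 11, 13))
  expect_error(wbc_slope_lmm(ds_few, "G1"), "at least 10")
})

test_that("the sampling-occasion LRT is null at zero and powered at 1 Cq", {
  # occasion deltas +1/-1/+1/-1 across dogs: its coefficient is exactly 0,
  # RSS0 = RSS1 -> statistic 0, p 1
  cq <- matrix(c(20, 21, 23, 22, 24, 25, 27, 26), 1,
               dimnames = list("G1", paste0("S", 1:8)))
  ds <- make_dataset(cq, dog_id = rep(c("w", "x", "y", "z"), each = 2),
                     sample_number = rep(1:2, 4))
  r <- sample_number_lrt(ds, "G1")
  expect_equal(r$statistic, 0, tolerance = 1e-9)
  expect_equal(r$p, 1, tolerance = 1e-9)
  expect_identical(r$df, 1L)

  # power: 20 dogs x 3 occasions, occasion effect 1 Cq, sigma 0.3
  set.seed(38)
  n_dogs <- 20
  reject <- vapply(1:200, function(i) {
    dogs <- rep(sprintf("d%02d", 1:n_dogs), each = 3)
    occ <- rep(1:3, n_dogs)
    y <- rnorm(n_dogs, 20, 1)[rep(1:n_dogs, each = 3)] +
      1 * (occ == 3) + rnorm(length(dogs), 0, 0.3)
    cqm <- matrix(y, 1, dimnames = list("G1", sprintf("S%03d", seq_along(y))))
    dsi <- make_dataset(cqm, dog_id = dogs, sample_number = occ)
    sample_number_lrt(dsi, "G1")$p < 0.05
  }, logical(1))
  expect_gte(mean(reject), 0.95)
})

test_that("constant sampling occasions are rejected", {
  cq <- matrix(rnorm(6, 20), 1, dimnames = list("G1", paste0("S", 1:6)))
  ds <- make_dataset(cq, dog_id = paste0("d", 1:6))
  expect_error(sample_number_lrt(ds, "G1"), "constant")
})
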