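test_that("the default cohort reproduces the study design", {
  coh <- generate_cohort(canine_blood_config(), seed = 101)
  ds <- coh$dataset
  first <- select_first_samples(ds)
  expect_identical(ncol(first$cq), 263L)
  expect_identical(as.vector(table(first$meta$disease_group)[c("A", "B", "C", "D")]),
                   c(6L, 85L, 107L, 65L))
  expect_identical(nrow(ds$cq), 9L)
  # repeated sampling pattern: 99 second, 34 third, 13 fourth samples
  expect_identical(as.vector(table(ds$meta$sample_number)),
                   c(263L, 99L, 34L, 13L))
  expect_true(all(ds$meta$wbc_count > 0))
})

test_that("generation is bit-exact under a fixed seed and seed-sensitive", {
  cfg <- canine_blood_config(duplicate_sd = 0.15, missing_rate = 0.01)
  a <- generate_cohort(cfg, seed = 7)
  b <- generate_cohort(cfg, seed = 7)
  expect_identical(a$dataset$cq, b$dataset$cq)
  expect_identical(a$long_cq, b$long_cq)
  expect_identical(a$truth$dog_effects, b$truth$dog_effects)
  c_ <- generate_cohort(cfg, seed = 8)
  expect_false(identical(a$dataset$cq, c_$dataset$cq))
  # the caller's RNG stream is not disturbed
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(generate_cohort(cfg, seed = 7)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("a noise-free generator returns the gene baselines exactly", {
  cfg <- canine_blood_config(dog_intercept_sd = 0, sample_shift_sd = 0)
  cfg$gene_params$residual_sd[] <- 0
  cfg$gene_params$slope_per_tenfold[] <- 0
  coh <- generate_cohort(cfg, seed = 5)
  expect_equal(unname(coh$dataset$cq[, 1]),
               cfg$gene_params$baseline_cq, tolerance = 1e-12)
  expect_equal(max(abs(coh$dataset$cq - cfg$gene_params$baseline_cq)), 0,
               tolerance = 1e-12)
})

test_that("simulated leukocyte medians match the target group medians", {
  cfg <- canine_blood_config()
  targets <- c(A = 8.6, B = 15.9, C = 16.8, D = 22.6)
  acc <- matrix(0, 500, 4, dimnames = list(NULL, names(targets)))
  for (i in 1:500) {
    coh <- generate_cohort(cfg, seed = 300 + i)
    first <- select_first_samples(coh$dataset)
    acc[i, ] <- tapply(first$meta$wbc_count, first$meta$disease_group, median)
  }
  rel <- apply(acc, 2, median) / targets - 1
  expect_lt(max(abs(rel)), 0.10)
})

test_that("generated within-range dispersion matches the variance budget", {
  # slopes off: total per-gene SD should approach
  # sqrt(residual^2 + dog^2 + shift^2)
  cfg <- canine_blood_config(dog_intercept_sd = 0.3, sample_shift_sd = 0.1)
  cfg$gene_params$slope_per_tenfold[] <- 0
  cfg$group_sizes <- c(A = 6L, B = 2000L, C = 107L, D = 65L)
  cfg$repeat_counts$B <- integer(0)
  coh <- generate_cohort(cfg, seed = 55)
  first <- select_first_samples(coh$dataset)
  b_samples <- first$meta$sample_id[first$meta$disease_group == "B"]
  sds <- apply(first$cq[, b_samples], 1, sd)
  expected <- sqrt(cfg$gene_params$residual_sd^2 + 0.3^2 + 0.1^2)
  expect_equal(unname(sds), expected, tolerance = 0.06)
})

test_that("technical duplicates average to the stored Cq and reload identically", {
  cfg <- canine_blood_config(duplicate_sd = 0.2)
  coh <- generate_cohort(cfg, seed = 12)
  expect_identical(nrow(coh$long_cq), 2L * length(coh$dataset$cq))
  means <- tapply(coh$long_cq$cq,
                  list(coh$long_cq$gene, coh$long_cq$sample), mean)
  expect_equal(unname(means[rownames(coh$dataset$cq),
                            colnames(coh$dataset$cq)]),
               unname(coh$dataset$cq), tolerance = 1e-12)
  dirp <- withr::local_tempdir()
  paths <- write_cohort(coh, dirp)
  back <- load_dataset(paths["cq"], paths["meta"], layout = "long")
  expect_equal(back$cq, coh$dataset$cq, tolerance = 1e-15)
})

test_that("missingness masks cells at the configured rate", {
  cfg <- canine_blood_config(missing_rate = 0.05)
  coh <- generate_cohort(cfg, seed = 13)
  rate <- mean(is.na(coh$dataset$cq))
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("the group-offset option encodes the B-versus-D contrast", {
  cfg <- canine_blood_config(b2m_group_effect = TRUE)
  off <- cfg$group_offsets
  expect_equal(unname(off["B2M", "B"] - off["B2M", "D"]), 0.51)
  expect_equal(unname(rowSums(off)), rep(0, 9))
  expect_true(all(off[rownames(off) != "B2M", ] == 0))
})

test_that("invalid configurations are rejected with a problem list", {
  gp <- data.frame(gene = c("a", "b"), baseline_cq = c(20, 21),
                   residual_sd = c(0.5, -0.1), slope_per_tenfold = 0)
  expect_error(
    cohort_config(gp, c(A = 5L), c(A = log(10)), c(A = -0.5)),
    "residual_sd.*\n.*wbc_sdlog|invalid cohort configuration")
  gp$residual_sd <- c(0.5, 0.5)
  off <- matrix(c(0.2, 0), 2, 1, dimnames = list(c("a", "b"), "A"))
  expect_error(cohort_config(gp, c(A = 5L), c(A = log(10)), c(A = 0.5),
                             group_offsets = off), "sum to 0")
})

test_that("generation requires a seed", {
  expect_error(generate_cohort(canine_blood_config()), "seed")
  cfg <- canine_blood_config(seed = 4)
  expect_identical(generate_cohort(cfg)$truth$seed, 4)
})
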