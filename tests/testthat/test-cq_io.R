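test_that("long-layout technical replicates are averaged on the Cq scale", {
  cq_csv <- withr::local_tempfile(fileext = ".csv")
  meta_csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,gene,cq",
               "S1,G1,20.0", "S1,G1,21.0",
               "S1,G2,25.0",
               "S2,G1,19.0", "S2,G2,24.0"), cq_csv)
  writeLines(c("sample_id,dog_id,sample_number,disease_group",
               "S1,d1,1,A", "S2,d2,1,B"), meta_csv)
  ds <- load_dataset(cq_csv, meta_csv, layout = "long")
  expect_equal(ds$cq["G1", "S1"], 20.5)
  expect_equal(ds$cq["G2", "S1"], 25.0)
  expect_equal(dim(ds$cq), c(2L, 2L))
})

test_that("wide layout loads values verbatim and flags defects", {
  dirp <- withr::local_tempdir()
  cq_csv <- file.path(dirp, "cq.csv")
  meta_csv <- file.path(dirp, "meta.csv")
  writeLines(c("gene,S1,S2", "G1,20.25,21.5", "G2,25,24.125"), cq_csv)
  writeLines(c("sample_id,dog_id,sample_number,disease_group",
               "S1,d1,1,A", "S2,d2,1,B"), meta_csv)
  ds <- load_dataset(cq_csv, meta_csv, layout = "wide")
  expect_identical(unname(ds$cq["G1", ]), c(20.25, 21.5))
  expect_identical(unname(ds$cq["G2", ]), c(25, 24.125))

  # empty cell -> missing entry, loads with a warning
  writeLines(c("gene,S1,S2", "G1,20.25,", "G2,25,24.125"), cq_csv)
  expect_warning(ds2 <- load_dataset(cq_csv, meta_csv, layout = "wide"),
                 "missing")
  expect_true(is.na(ds2$cq["G1", "S2"]))

  # unparseable numeric names the offending cell
  writeLines(c("gene,S1,S2", "G1,20.25,oops", "G2,25,24.125"), cq_csv)
  expect_error(load_dataset(cq_csv, meta_csv, layout = "wide"),
               "G1.*S2|unparseable")

  # duplicate gene row = duplicate (gene, sample) cells in wide layout
  writeLines(c("gene,S1,S2", "G1,20,21", "G1,25,24"), cq_csv)
  expect_error(load_dataset(cq_csv, meta_csv, layout = "wide"), "duplicate")

  # sample without a metadata record
  writeLines(c("gene,S1,S2", "G1,20,21", "G2,25,24"), cq_csv)
  writeLines(c("sample_id,dog_id,sample_number,disease_group", "S1,d1,1,A"),
             meta_csv)
  expect_error(load_dataset(cq_csv, meta_csv, layout = "wide"),
               "no metadata record.*S2")
})

test_that("write/load round-trips Cq bit-exactly in both layouts", {
  set.seed(71)
  cq <- matrix(runif(20, 10, 40), 4,
               dimnames = list(paste0("G", 1:4), paste0("S", 1:5)))
  cq[2, 3] <- NA
  ds <- make_dataset(cq)
  for (layout in c("wide", "long")) {
    dirp <- withr::local_tempdir()
    write_dataset(ds, file.path(dirp, "cq.csv"), file.path(dirp, "meta.csv"),
                  layout = layout)
    back <- suppressWarnings(load_dataset(file.path(dirp, "cq.csv"),
                                          file.path(dirp, "meta.csv"),
                                          layout = layout))
    expect_identical(back$cq, ds$cq, label = layout)
  }
})

test_that("efficiency files support fold-change and percent conventions", {
  dirp <- withr::local_tempdir()
  cq_csv <- file.path(dirp, "cq.csv")
  meta_csv <- file.path(dirp, "meta.csv")
  eff_csv <- file.path(dirp, "eff.csv")
  writeLines(c("gene,S1,S2", "G1,20,21", "G2,25,24"), cq_csv)
  writeLines(c("sample_id,dog_id,sample_number,disease_group",
               "S1,d1,1,A", "S2,d2,1,B"), meta_csv)
  writeLines(c("gene,efficiency", "G1,1.95", "G2,98.2"), eff_csv)
  ds <- load_dataset(cq_csv, meta_csv, eff_csv, layout = "wide")
  expect_equal(unname(ds$efficiencies), c(1.95, 1.982))

  # efficiency for an unknown gene is rejected
  writeLines(c("gene,efficiency", "G9,1.95"), eff_csv)
  expect_error(load_dataset(cq_csv, meta_csv, eff_csv, layout = "wide"),
               "unknown gene")

  # outside the validated band -> warning; absent genes default to 2
  writeLines(c("gene,efficiency", "G1,1.6"), eff_csv)
  expect_warning(ds3 <- load_dataset(cq_csv, meta_csv, eff_csv,
                                     layout = "wide"), "band")
  expect_equal(unname(ds3$efficiencies["G2"]), 2.0)
})

test_that("first-sample selection keeps one entry sample per dog", {
  cq <- matrix(rep(20, 8), 1,
               dimnames = list("G1", paste0("S", 1:8)))
  ds <- make_dataset(cq,
                     dog_id = c("x", "x", "x", "x", "y", "y", "z", "z"),
                     sample_number = c(1L, 2L, 3L, 4L, 2L, 5L, 1L, 2L),
                     disease_group = rep("B", 8))
  first <- select_first_samples(ds)
  expect_identical(first$meta$sample_id, c("S1", "S5", "S7"))
  expect_identical(first$meta$sample_number, c(1L, 2L, 1L))
  # idempotent, sample count equals dog count
  expect_identical(select_first_samples(first), first)
  expect_identical(ncol(first$cq), length(unique(ds$meta$dog_id)))
})

test_that("ambiguous entry samples and invalid metadata are rejected", {
  cq <- matrix(c(20, 21), 1, dimnames = list("G1", c("S1", "S2")))
  meta <- data.frame(sample_id = c("S1", "S2"), dog_id = c("x", "x"),
                     sample_number = c(1L, 1L), disease_group = "A")
  expect_error(refstab_dataset(cq, meta), "unique")
  meta$dog_id <- c("x", "y")
  meta$disease_group <- c("A", "E")
  expect_error(refstab_dataset(cq, meta), "disease_group")
  meta$disease_group <- "A"
  meta$wbc_count <- c(-1, 5)
  expect_error(refstab_dataset(cq, meta), "wbc_count")
})
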