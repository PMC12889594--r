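test_that("matrix round-trips through TSV with exact missingness", {
  set.seed(1)
  v <- matrix(rnorm(12, 20, 2), 3, 4)
  v[2, 3] <- NA
  m <- toy_matrix(v, n_pairs = 2)
  d <- withr::local_tempdir()
  write_intensity_matrix(m, file.path(d, "m.tsv"), file.path(d, "md.tsv"))
  m2 <- read_intensity_matrix(file.path(d, "m.tsv"), file.path(d, "md.tsv"))
  expect_equal(m2$values, m$values, tolerance = 1e-7)
  expect_identical(is.na(m2$values), is.na(m$values))
  # second round trip is byte-identical
  write_intensity_matrix(m2, file.path(d, "m2.tsv"), file.path(d, "md2.tsv"))
  expect_identical(readLines(file.path(d, "m.tsv")),
                   readLines(file.path(d, "m2.tsv")))
})

test_that("empty cells and NA/NaN tokens parse as missing; raw scale is log2-transformed", {
  d <- withr::local_tempdir()
  writeLines(c("protein_id\tpl01\tpl02\tnp01\tnp02",
               "A\t1024\t\tNA\tNaN",
               "B\t2\t4\t8\t16"), file.path(d, "m.tsv"))
  writeLines(c("# scale=raw",
               "sample_id\tmodel\tage_months\tregion\tpair_id\treplicate",
               "pl01\t5xFAD\t3\tplaque\tp1\t1",
               "pl02\t5xFAD\t3\tplaque\tp2\t2",
               "np01\t5xFAD\t3\tnonplaque\tp1\t1",
               "np02\t5xFAD\t3\tnonplaque\tp2\t2"), file.path(d, "md.tsv"))
  m <- read_intensity_matrix(file.path(d, "m.tsv"), file.path(d, "md.tsv"))
  expect_equal(m$values["A", "pl01"], 10.0)
  expect_identical(unname(is.na(m$values["A", ])), c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(unname(m$values["B", ]), c(1, 2, 3, 4))
})

test_that("metadata validation rejects broken pairing and unknown samples", {
  v <- matrix(rnorm(8, 20), 2, 4,
              dimnames = list(c("A", "B"), paste0("s", 1:4)))
  md <- data.frame(sample_id = paste0("s", 1:4), model = "5xFAD",
                   age_months = 3,
                   region = c("plaque", "plaque", "nonplaque", "nonplaque"),
                   pair_id = c("p1", "p2", "p1", "p2"), replicate = 1:4)
  expect_s3_class(IntensityMatrix(v, md), "IntensityMatrix")
  bad <- md; bad$pair_id <- c("p1", "p1", "p1", "p2")
  expect_error(IntensityMatrix(v, bad), "pair ids")
  expect_error(IntensityMatrix(v, md[-1, ]), "metadata")
})

test_that("contaminant filtering is substring-based, case-insensitive, and exact on planted fractions", {
  v <- matrix(rnorm(20, 20), 5, 4,
              dimnames = list(c("KRT10_HUMAN", "TRYP_PIG", "AKRT1",
                                "APOE_MOUSE", "CLUS_MOUSE"), NULL))
  m <- toy_matrix(v, n_pairs = 2)
  f <- filter_contaminants(m, c("KRT", "TRYP"))
  expect_identical(rownames(f$values), c("APOE_MOUSE", "CLUS_MOUSE"))
  expect_identical(attr(f, "n_removed"), 3L)
  # empty overlap leaves the matrix unchanged
  f2 <- filter_contaminants(m, c("ZZZX"))
  expect_identical(f2$values, m$values)
  # planted contaminant fraction removed exactly
  cfg <- cohort_config(n_proteins = 400, n_pairs_per_age = 4,
                       frac_contaminant = 0.05, seed = 6)
  co <- generate_cohort(cfg)
  fc <- filter_contaminants(co$matrix, default_contaminants())
  expect_identical(attr(fc, "n_removed"), length(co$truth$contaminant_ids))
  expect_identical(attr(fc, "n_removed"), as.integer(0.05 * 400))
  # idempotent
  expect_identical(filter_contaminants(fc, default_contaminants())$values,
                   fc$values)
})

test_that("minimum-detection filter keeps the boundary and is idempotent", {
  v <- matrix(rnorm(40, 20), 4, 10)
  v[1, 3:10] <- NA   # 2 detections -> removed at default
  v[2, 4:10] <- NA   # 3 detections -> retained
  m <- toy_matrix(v, n_pairs = 5)
  f <- filter_min_detection(m)
  expect_identical(rownames(f$values), rownames(m$values)[-1])
  expect_identical(filter_min_detection(f)$values, f$values)
  full <- toy_matrix(matrix(rnorm(40, 20), 4, 10), n_pairs = 5)
  expect_identical(filter_min_detection(full)$values, full$values)
})

test_that("median normalization removes per-sample offsets exactly and preserves scale", {
  set.seed(2)
  v <- matrix(rnorm(200, 20, 2), 20, 10)
  m <- toy_matrix(v, n_pairs = 5)
  offs <- c(2, rep(0, 9))
  shifted <- m
  shifted$values <- sweep(m$values, 2, offs, "+")
  n1 <- median_normalize(m)
  n2 <- median_normalize(shifted)
  expect_equal(n1$values, n2$values, tolerance = 1e-12)
  meds <- apply(n1$values, 2, median, na.rm = TRUE)
  expect_lt(max(meds) - min(meds), 1e-9)
  # already-equal medians: unchanged
  expect_equal(median_normalize(n1)$values, n1$values, tolerance = 1e-12)
  # grand-median target keeps the intensity scale
  expect_equal(median(n1$values), median(m$values), tolerance = 0.5)
})

test_that("tracer extraction errors on absent ids", {
  m <- toy_matrix(matrix(rnorm(8, 20), 2, 4), n_pairs = 2)
  expect_error(extract_tracer(m, "NOPE"), "not present")
})
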