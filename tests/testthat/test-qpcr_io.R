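test_that("undetermined, empty, and above-ceiling cells are imputed at the ceiling", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "assay\tP01_pre\tP01_post",
    "cel-miR-39-3p\t20.0\t20.5",
    "hsa-miR-21-5p\t27.31\tUndetermined",
    "hsa-miR-22-3p\t41.2\t",
    "hsa-miR-23a-3p\t40\t39.999"), tf)
  meta <- make_meta(1)
  x <- read_ct_table(tf, "wide", spike_in = "cel-miR-39-3p",
                     sample_meta = meta)
  expect_equal(unname(x$ct["hsa-miR-21-5p", ]), c(27.31, 40))
  expect_equal(unname(x$detected["hsa-miR-21-5p", ]), c(TRUE, FALSE))
  # numeric >= ceiling clamps; empty imputes
  expect_equal(unname(x$ct["hsa-miR-22-3p", ]), c(40, 40))
  expect_false(any(x$detected["hsa-miR-22-3p", ]))
  # exactly at the ceiling is not detected; just below is
  expect_equal(unname(x$detected["hsa-miR-23a-3p", ]), c(FALSE, TRUE))
})

test_that("malformed inputs are fatal with context", {
  meta <- make_meta(1)
  tf <- withr::local_tempfile(fileext = ".tsv")

  writeLines(c("assay\tP01_pre\tP01_post",
               "hsa-miR-21-5p\t25\t26"), tf)
  expect_error(read_ct_table(tf, "wide", spike_in = "cel-miR-39-3p",
                             sample_meta = meta),
               "spike-in assay 'cel-miR-39-3p' not present")

  writeLines(c("assay\tP01_pre\tP01_post",
               "cel-miR-39-3p\t20\t20",
               "hsa-miR-21-5p\tabc\t26"), tf)
  expect_error(read_ct_table(tf, "wide", spike_in = "cel-miR-39-3p",
                             sample_meta = meta),
               "non-numeric CT value 'abc'.*P01_pre")

  # spike-in undetected in one sample makes normalization undefined
  writeLines(c("assay\tP01_pre\tP01_post",
               "cel-miR-39-3p\t20\tundetermined",
               "hsa-miR-21-5p\t25\t26"), tf)
  expect_error(read_ct_table(tf, "wide", spike_in = "cel-miR-39-3p",
                             sample_meta = meta),
               "not detected in sample")

  # duplicate (assay, sample) record in long format
  writeLines(c("assay\tsample\tpatient\ttimepoint\tct",
               "hsa-miR-21-5p\tS1\tP1\tpre\t25",
               "hsa-miR-21-5p\tS1\tP1\tpre\t26"), tf)
  expect_error(read_ct_table(tf, "long", spike_in = "cel-miR-39-3p"),
               "duplicate \\(assay, sample\\)")

  # a patient missing one timepoint breaks the paired design
  writeLines(c("assay\tP1_pre\tP1_post\tP2_pre",
               "cel-miR-39-3p\t20\t20\t20",
               "hsa-miR-21-5p\t25\t26\t27"), tf)
  meta3 <- data.frame(sample_id = c("P1_pre", "P1_post", "P2_pre"),
                      patient_id = c("P1", "P1", "P2"),
                      timepoint = c("pre", "post", "pre"))
  expect_error(read_ct_table(tf, "wide", spike_in = "cel-miR-39-3p",
                             sample_meta = meta3),
               "patient 'P2'")
})

test_that("canonical long format round-trips and imputation is idempotent", {
  sim <- simulate_ct(sim_config(n_patients = 3, n_assays = 40,
                                fraction_near_lod = 0.5), seed = 11)
  x <- sim$ct
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_ct_table(x, tf)
  y <- read_ct_table(tf, "long", spike_in = x$spike_in, ceiling = x$ceiling)
  expect_identical(y$ct, x$ct)
  expect_identical(y$detected, x$detected)
  expect_identical(y$samples, x$samples)

  # re-reading an already-imputed table changes nothing
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  write_ct_table(y, tf2)
  z <- read_ct_table(tf2, "long", spike_in = x$spike_in, ceiling = x$ceiling)
  expect_identical(z$ct, x$ct)

  # the instrument-style export with "undetermined" tokens reads back too
  tf3 <- withr::local_tempfile(fileext = ".tsv")
  write_ct_table(x, tf3, censored_as = "undetermined")
  w <- read_ct_table(tf3, "long", spike_in = x$spike_in, ceiling = x$ceiling)
  expect_identical(w$ct, x$ct)
  expect_identical(w$detected, x$detected)
})

test_that("detection flags and CT values satisfy the ceiling invariant", {
  for (seed in 1:5) {
    sim <- simulate_ct(sim_config(n_patients = 4, n_assays = 60,
                                  fraction_near_lod = 0.6), seed = seed)
    x <- sim$ct
    expect_true(all(x$ct[x$detected] < x$ceiling))
    expect_true(all(x$ct[!x$detected] == x$ceiling))
    expect_identical(dim(x$ct), dim(x$detected))
  }
})
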