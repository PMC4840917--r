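test_that("subject table parses, flags below-detection values and keeps covariates", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("child_id\texperiment_id\tchannel\tpivka2_ugL\tage_y",
               "c1\te1\t1\t1.31\t7.2",
               "c2\te1\t2\t2.5\t7.9",
               "c3\te2\t1\t0.0005\t6.8"), f)
  s <- read_subject_table(f)
  expect_equal(nrow(s), 3)
  expect_equal(s$below_detection, c(FALSE, FALSE, TRUE))
  expect_true("age_y" %in% names(s))
  st <- dichotomize_vk(s)
  expect_equal(sum(st$vk_status == "deficient"), 1)
})

test_that("subject reader reports schema and integrity violations by name", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("child_id\texperiment_id\tchannel", "c1\te1\t1"), f)
  expect_error(read_subject_table(f), "pivka2_ugL")
  writeLines(c("child_id\texperiment_id\tchannel\tpivka2_ugL",
               "c1\texp1\t3\t1.0",
               "c2\texp1\t3\t1.5"), f)
  expect_error(read_subject_table(f), "duplicate \\(experiment, channel\\)")
})

test_that("column mapping reads exports with foreign header names", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SubjectID\tiTRAQ_run\tch\tPIVKA2",
               "c1\te1\t1\t1.31"), f)
  s <- read_subject_table(f, col_map = list(child_id = "SubjectID",
                                            experiment_id = "iTRAQ_run",
                                            channel = "ch",
                                            pivka2_ugL = "PIVKA2"))
  expect_equal(s$pivka2_ugL, 1.31)
  expect_error(read_subject_table(f, col_map = list(child_id = "nope")),
               "nope")
})

test_that("abundance table parses, rejects duplicates and bad numerics", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tgi_accession\tchild_id\texperiment_id\tvalue",
               "F2\t4503635\tc1\te1\t0.5",
               "F2\t4503635\tc2\te1\t-0.25",
               "GSN\t4504165\tc1\te1\t1.0"), f)
  o <- read_abundance_table(f)
  expect_equal(nrow(o), 3)
  expect_equal(length(unique(o$gi_accession)), 2)

  writeLines(c("protein_id\tgi_accession\tchild_id\texperiment_id\tvalue",
               "F2\t4503635\tc7\te1\t0.5",
               "F2\t4503635\tc7\te1\t0.7"), f)
  expect_error(read_abundance_table(f), "duplicate \\(protein, child\\)")

  writeLines(c("protein_id\tgi_accession\tchild_id\texperiment_id\tvalue",
               "F2\t4503635\tc1\te1\tabc"), f)
  expect_error(read_abundance_table(f), "row 1")

  writeLines("protein_id\tgi_accession\tchild_id\texperiment_id\tvalue", f)
  expect_warning(o <- read_abundance_table(f), "header only")
  expect_equal(nrow(o), 0)
})

test_that("cohort validation enforces slot uniqueness and referential integrity", {
  s <- data.frame(child_id = c("c1", "c2"), experiment_id = "exp1",
                  channel = c(3L, 3L), pivka2_ugL = 1)
  o <- data.frame(gene_symbol = "F2", gi_accession = "1", child_id = "c1",
                  experiment_id = "exp1", value = 1)
  expect_error(cohort_dataset(s, o), "duplicate \\(experiment, channel\\)")
  s$channel <- c(3L, 4L)
  o$child_id <- "ghost"
  expect_error(cohort_dataset(s, o), "unknown child_id")
  o$child_id <- "c1"; o$experiment_id <- "exp9"
  expect_error(cohort_dataset(s, o), "does not match")
})

test_that("write-then-read round trip reproduces the cohort to 1e-9", {
  sim <- generate_cohort(sim_config(n_proteins_total = 40, n_children = 48,
                                    n_experiments = 8, block_size = 3,
                                    mean_proteins_per_experiment = 20,
                                    coverage_target = 11,
                                    min_children_covered = 40), seed = 5)
  ds <- sim$dataset
  fs <- withr::local_tempfile(fileext = ".tsv")
  fa <- withr::local_tempfile(fileext = ".tsv")
  write_subject_table(ds$subjects, fs)
  write_abundance_table(ds$observations, fa)
  s2 <- read_subject_table(fs)
  o2 <- read_abundance_table(fa)
  expect_equal(s2$pivka2_ugL, ds$subjects$pivka2_ugL, tolerance = 1e-9)
  key <- function(d) order(d$gi_accession, d$child_id)
  expect_equal(o2$value[key(o2)], ds$observations$value[key(ds$observations)],
               tolerance = 1e-9)
  ds2 <- cohort_dataset(s2, data.frame(gene_symbol = o2$gene_symbol,
                                       o2[-1]), normalized = FALSE)
  expect_s3_class(ds2, "cohort_dataset")
})

test_that("results tables render percent (CI) formatting and sort by p", {
  res <- data.frame(
    gene_symbol = c("GSN", "F2"), gi_accession = c("4504165", "4503635"),
    n_obs = c(467L, 474L), beta = c(-0.703, 1.2479), se_beta = c(0.2, 0.24),
    percent_change = c(-38.6, 137.5), ci_lo = c(-53.8, 50.1),
    ci_hi = c(-18.6, 275.8), p_value = c(0.0007, 0.0002),
    q_value = c(0.0895, 0.0556), r2 = c(0.30, 0.29))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_results_table(res, f, "association")
  out <- read.delim(f, check.names = FALSE)
  expect_equal(out$gene_symbol, c("F2", "GSN"))  # ascending p
  expect_equal(out$percent_change[1], "137.5 (50.1, 275.8)")
  write_results_table(res[0, ], f, "association")
  out <- read.delim(f)
  expect_equal(nrow(out), 0)
  expect_true("percent_change" %in% names(out))
})
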