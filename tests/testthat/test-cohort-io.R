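test_that("a cohort CSV round-trips field-by-field", {
  cohort <- exclusion_fixture()
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  expect_equal(nrow(back), nrow(cohort))
  for (col in names(cohort)) {
    expect_equal(back[[col]], cohort[[col]], ignore_attr = TRUE,
                 info = paste("column", col))
  }
})

test_that("categorical values are matched case-insensitively, others reported", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("family_id,member_index,zygosity,sex",
               "f1,1,mz,m", "f1,2,MZ,M",
               "f2,1,dz,F", "f2,2,XX,F"), path)
  cohort <- read_cohort(path)
  expect_equal(cohort$zygosity[1:3], c("MZ", "MZ", "DZ"))
  expect_equal(cohort$sex, c("M", "M", "F", "F"))
  rep <- attr(cohort, "validation_report")
  expect_equal(nrow(rep), 1)
  expect_equal(rep$row, 4)
  expect_equal(rep$value, "XX")
  expect_true(is.na(cohort$zygosity[4]))
})

test_that("schema_config maps foreign headers; missing required columns error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("fam,member,zyg,gender",
               "f1,1,MZ,M", "f1,2,MZ,M"), path)
  cohort <- read_cohort(path, schema_config = c(
    family_id = "fam", member_index = "member", zygosity = "zyg", sex = "gender"))
  expect_equal(cohort$family_id, c("f1", "f1"))
  expect_error(read_cohort(path), "required columns missing")
  expect_error(read_cohort(path, schema_config = c(family_id = "nope")),
               "absent from file header")
})

test_that("exclusion rules fire in order and partition the entry count", {
  rec <- rbind(
    make_records("f1", 1:2, c("MZ", "MZ")),          # clean
    make_records("f2", 1:2, c(NA, "DZ")),            # missing
    make_records("f3", 1:2, c(NA, NA)),              # missing
    make_records("f4", 1:2, c("MZ", "DZ")),          # inconsistent
    make_records("f5", 1, "DZ"),                     # singleton
    make_records("f6", 1:3, c("MZ", "MZ", "MZ")),    # triplet
    make_records("f7", 1:2, c(NA, NA))[1, ]          # singleton AND missing
  )
  res <- apply_exclusions(rec)
  r <- res$report
  expect_equal(r$entry_pairs, 7)
  expect_equal(r$missing_zygosity_pairs, 3)  # f2, f3, and f7 (missing first)
  expect_equal(r$inconsistent_zygosity_pairs, 1)
  expect_equal(r$wrong_size_families, 2)     # f5 singleton, f6 triplet
  expect_equal(r$retained_pairs, 1)
  expect_equal(r$entry_pairs,
               r$retained_pairs + r$missing_zygosity_pairs +
                 r$inconsistent_zygosity_pairs + r$wrong_size_families)
  expect_equal(sort(unique(res$cohort$family_id)), "f1")
})

test_that("apply_exclusions with clean input retains everything", {
  cfg <- twin_sim_config(n_pairs = 50, seed = 3)
  cohort <- simulate_cohort(cfg)
  res <- apply_exclusions(cohort)
  expect_equal(res$report$retained_pairs, 50)
  expect_equal(res$report$missing_zygosity_pairs, 0)
  expect_equal(res$report$inconsistent_zygosity_pairs, 0)
  expect_equal(res$report$wrong_size_families, 0)
})

test_that("apply_exclusions is idempotent and conserves counts under random defects", {
  for (seed in 1:5) {
    set.seed(seed)
    dr <- c(missing_zygosity = runif(1, 0, 0.2),
            inconsistent_zygosity = runif(1, 0, 0.2),
            singleton = runif(1, 0, 0.2))
    cohort <- simulate_cohort(twin_sim_config(n_pairs = 400,
                                              defect_rates = dr,
                                              seed = seed))
    res <- apply_exclusions(cohort)
    r <- res$report
    expect_equal(r$entry_pairs,
                 r$retained_pairs + r$missing_zygosity_pairs +
                   r$inconsistent_zygosity_pairs + r$wrong_size_families)
    expect_equal(r$missing_zygosity_individuals, 2 * r$missing_zygosity_pairs)
    expect_equal(r$retained_individuals, 2 * r$retained_pairs)
    again <- apply_exclusions(res$cohort)
    expect_equal(again$report$retained_pairs, r$retained_pairs)
    expect_equal(again$report$missing_zygosity_pairs, 0)
    expect_equal(again$report$inconsistent_zygosity_pairs, 0)
    expect_equal(again$report$wrong_size_families, 0)
    expect_equal(again$cohort, res$cohort)
  }
})

test_that("pair_twins orders members by index and enforces the same-sex design", {
  rec <- make_records("f1", c(2, 1), c("MZ", "MZ"))
  rec$score <- c(20, 10)
  pairs <- pair_twins(rec, traits = "score")
  expect_equal(pairs$score_1, 10)
  expect_equal(pairs$score_2, 20)

  expect_equal(nrow(pair_twins(rec[0, ])), 0)

  bad <- make_records("f9", 1:2, c("DZ", "DZ"), sex = c("M", "F"))
  expect_error(pair_twins(bad), "sex-discordant.*f9")
  expect_error(pair_twins(make_records("f1", 1, "MZ")), "exactly two members")
})
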