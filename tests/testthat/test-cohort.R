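test_that("largest-remainder apportionment reproduces the validation stage mix", {
  expect_equal(largest_remainder(207, c(0.309, 0.391, 0.300)), c(64L, 81L, 62L))
  expect_equal(sum(largest_remainder(100, c(1, 1, 1) / 3)), 100L)
  # always sums to n over fuzzed proportions
  set.seed(61)
  for (i in 1:50) {
    p <- runif(3); p <- p / sum(p)
    n <- sample(0:400, 1)
    q <- largest_remainder(n, p)
    expect_equal(sum(q), n)
    expect_true(all(q >= floor(n * p)))
  }
})

test_that("default specs encode the two study populations", {
  tr <- default_training_spec()
  expect_equal(tr$n, 327L)
  expect_equal(tr$gfr_shift, 1)
  va <- default_validation_spec()
  expect_equal(va$n, 207L)
  expect_equal(va$stage_proportions, c(0.309, 0.391, 0.300))
  expect_lt(va$gfr_shift, 1)
  expect_equal(va$gfr_shift, 0.85)
})

test_that("generate_cohort is deterministic, leaves the caller RNG alone, and stages are consistent", {
  spec <- default_training_spec(seed = 9)
  c1 <- generate_cohort(spec)
  set.seed(999)
  before <- runif(1)
  set.seed(999)
  c2 <- generate_cohort(spec)
  expect_identical(cohort_records(c1), cohort_records(c2))
  expect_equal(runif(1), before)  # caller stream undisturbed

  r <- cohort_records(c1)
  expect_equal(nrow(r), 327)
  expect_false(anyDuplicated(r$id) > 0)
  expect_identical(r$stage_group, stage_group(r$sgfr))
  expect_true(all(r$scr > 0 & r$sgfr > 0 & r$bun > 0 & r$alb > 0 & r$age >= 18))
  expect_true(all(!r$black))
})

test_that("degenerate and noise-free specs behave as stated", {
  expect_equal(nrow(cohort_records(generate_cohort(cohort_spec(n = 0)))), 0)

  spec <- cohort_spec(n = 40, noise_sd_log = 0, gfr_shift = 1,
                      gfr_curve = list(a = 80, b = 1), seed = 3)
  r <- cohort_records(generate_cohort(spec))
  expect_equal(r$sgfr, 80 * r$scr^-1, tolerance = 1e-12)

  # noise-free with a shift: backbone exact, shift applied multiplicatively
  spec2 <- cohort_spec(n = 25, noise_sd_log = 0, gfr_shift = 0.85, seed = 3)
  r2 <- cohort_records(generate_cohort(spec2))
  expect_equal(r2$sgfr, 0.85 * 80 * r2$scr^-1, tolerance = 1e-12)
})

test_that("infeasible specs fail loudly at the retry cap", {
  # noise so large relative to the bounded stage III band that almost nothing
  # lands in it
  spec <- cohort_spec(n = 5, stage_proportions = c(0, 1, 0), noise_sd_log = 8,
                      retry_cap = 3, seed = 1)
  expect_error(generate_cohort(spec), "retry_cap")
  # a creatinine range that cannot reach stage IV/V at all
  spec2 <- cohort_spec(n = 5, stage_proportions = c(0, 0, 1),
                       scr_range = c(0.3, 1.0), seed = 1)
  expect_error(generate_cohort(spec2), "empty creatinine band")
})

test_that("validation cohorts stay inside the per-stage calibration bands", {
  # per-stage medians of SCr and sGFR across 20 seeds, each within the
  # published IQR band of the population being emulated
  scr_bands <- list(I_II = c(0.57, 1.09), III = c(1.09, 2.39), IV_V = c(2.99, 7.01))
  gfr_bands <- list(I_II = c(66.86, 87.89), III = c(35.81, 54.82), IV_V = c(14.58, 23.19))
  for (s in 1:20) {
    r <- cohort_records(generate_cohort(default_validation_spec(seed = s)))
    expect_equal(unname(table(r$stage_group)), c(64L, 81L, 62L), ignore_attr = TRUE)
    for (g in stage_levels()) {
      sub <- r[r$stage_group == g, ]
      ms <- median(sub$scr); mg <- median(sub$sgfr)
      expect_true(ms >= scr_bands[[g]][1] && ms <= scr_bands[[g]][2],
                  label = sprintf("seed %d %s scr median %.3f in band", s, g, ms))
      expect_true(mg >= gfr_bands[[g]][1] && mg <= gfr_bands[[g]][2],
                  label = sprintf("seed %d %s sgfr median %.2f in band", s, g, mg))
    }
    expect_true(median(r[r$stage_group == "I_II", "sgfr"]) >= 60)
  }
})

test_that("cohort CSV round trip is exact and validation is row-numbered", {
  coh <- generate_cohort(default_validation_spec(seed = 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  r0 <- cohort_records(coh); r1 <- cohort_records(back)
  for (f in c("scr", "age", "bun", "alb", "sgfr")) {
    expect_identical(r1[[f]], r0[[f]])
  }
  expect_identical(r1$id, r0$id)
  expect_identical(r1$female, r0$female)
  expect_identical(r1$stage_group, r0$stage_group)

  lines <- readLines(path)
  # negative creatinine: error names row and column
  bad <- withr::local_tempfile(fileext = ".csv")
  broken <- lines
  broken[3] <- sub("^([^,]*),[^,]*", "\\1,-1", broken[3])
  writeLines(broken, bad)
  expect_error(read_cohort(bad), "row 2, column 'scr_mg_dl'")
  # non-numeric cell
  broken2 <- lines
  broken2[4] <- sub("^([^,]*),[^,]*", "\\1,abc", broken2[4])
  writeLines(broken2, bad)
  expect_error(read_cohort(bad), "row 3, column 'scr_mg_dl'")
  # missing column
  writeLines(gsub("sgfr_ml_min_173m2", "gfr", lines), bad)
  expect_error(read_cohort(bad), "missing columns")
})

test_that("stage group is recomputed from sGFR on read; 60.0 is stage I/II", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,scr_mg_dl,age_years,female,black,bun_mg_dl,alb_g_dl,sgfr_ml_min_173m2",
               "A,1.1,60,0,0,20,4,60.0",
               "B,2.0,60,1,0,30,3.8,59.999",
               "C,6.0,70,0,0,55,3.2,29.0"), path)
  r <- cohort_records(read_cohort(path))
  expect_equal(as.character(r$stage_group), c("I_II", "III", "IV_V"))
})

test_that("cohort specs serialize to JSON and back", {
  spec <- default_validation_spec(seed = 17)
  path <- withr::local_tempfile(fileext = ".json")
  write_cohort_spec(spec, path)
  spec2 <- read_cohort_spec(path)
  expect_equal(spec2, spec)
  expect_identical(cohort_records(generate_cohort(spec2)),
                   cohort_records(generate_cohort(spec)))
})
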