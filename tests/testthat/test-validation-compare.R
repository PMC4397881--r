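angles_ <- function(fl, ab, ir0, ir30, ir60, ir90) {
  c(max_flexion = fl, max_abduction = ab, max_ir_0 = ir0,
    max_ir_30 = ir30, max_ir_60 = ir60, max_ir_90 = ir90)
}

# hip joint 5 of the validation experiment: simulation and tracking-system
# endpoint angles, native and with the artificial cam
hip5_sim_native <- function()
  rom_record("hip5", "simulation", "native", angles_(105, 29, 60, 34, 27, 20))
hip5_sim_cam <- function()
  rom_record("hip5", "simulation", "cam", angles_(93, 26, 60, 31, 26, 1))
hip5_ref_native <- function()
  rom_record("hip5", "reference", "native", angles_(110, 35, 38, 32, 37, 32))
hip5_ref_cam <- function()
  rom_record("hip5", "reference", "cam", angles_(94, 34, 37, 34, 31, 18))

test_that("condition comparison computes strict-threshold limitation flags", {
  cmp <- compare_conditions(hip5_sim_native(), hip5_sim_cam(), threshold = 5)
  expect_equal(cmp$difference[cmp$motion == "max_ir_0"], 0)
  expect_false(cmp$limited[cmp$motion == "max_ir_0"])
  expect_equal(cmp$difference[cmp$motion == "max_ir_90"], 19)
  expect_true(cmp$limited[cmp$motion == "max_ir_90"])
  expect_equal(cmp$difference[cmp$motion == "max_flexion"], 12)

  # identical records: no differences, no flags
  same <- compare_conditions(
    hip5_sim_native(),
    dplyr::mutate(hip5_sim_native(), condition = "cam"))
  expect_true(all(same$difference == 0))
  expect_false(any(same$limited))

  # a difference exactly at the threshold is NOT a limitation (strictly more)
  at_thr <- compare_conditions(
    rom_record("s", "simulation", "native", angles_(105, 30, 60, 34, 27, 20)),
    rom_record("s", "simulation", "cam", angles_(100, 30, 60, 34, 27, 20)),
    threshold = 5)
  expect_false(any(at_thr$limited))

  bad <- dplyr::mutate(hip5_sim_cam(), subject = "other")
  expect_error(compare_conditions(hip5_sim_native(), bad), "subject")
  p <- autoplot(cmp)
  expect_s3_class(p, "ggplot")
})

test_that("errors against the reference reproduce worked rows", {
  sim <- compare_conditions(hip5_sim_native(), hip5_sim_cam())
  ref <- compare_conditions(hip5_ref_native(), hip5_ref_cam())
  err <- error_vs_reference(sim, ref)
  e <- stats::setNames(err$error, err$motion)
  expect_equal(e[["max_ir_90"]], 5)     # simulated 19 vs reference 14
  expect_equal(e[["max_ir_0"]], -1)     # simulated 0 vs reference 1
  expect_true(all(error_vs_reference(sim, sim)$error == 0))
})

test_that("error statistics match hand-computed order statistics", {
  s0 <- error_stats(0)
  expect_equal(s0$median, 0)
  expect_equal(c(s0$q25, s0$q75), c(0, 0))
  expect_equal(s0$max_abs, 0)

  s <- error_stats(c(1, -2, 3, -4, 5))
  expect_equal(s$median, 1)
  expect_equal(s$max_abs, 5)
  expect_equal(c(s$q25, s$q75), c(-2, 3))   # type-7 on sorted -4 -2 1 3 5

  expect_error(error_stats(numeric()), "empty")
  g <- glance(s)
  expect_equal(g$n, 5)
})

test_that("error statistics agree with an independent percentile oracle", {
  # hand-rolled type-7 percentile: linear interpolation of order statistics
  pctl <- function(x, p) {
    x <- sort(x); n <- length(x)
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }
  set.seed(33)
  for (i in 1:200) {
    x <- stats::rnorm(sample(1:40, 1), sd = 5)
    s <- error_stats(x)
    expect_equal(s$q25, pctl(x, 0.25), tolerance = 1e-12)
    expect_equal(s$q75, pctl(x, 0.75), tolerance = 1e-12)
    med <- if (length(x) %% 2) sort(x)[(length(x) + 1) / 2] else
      mean(sort(x)[length(x) / 2 + 0:1])
    expect_equal(s$median, med, tolerance = 1e-12)
    expect_equal(s$max_abs, max(abs(x)))
  }
})

test_that("detection confusion counts partition subjects x motions", {
  sim <- compare_conditions(hip5_sim_native(), hip5_sim_cam())
  ref <- compare_conditions(hip5_ref_native(), hip5_ref_cam())
  cc <- detection_confusion(list(sim), list(ref), threshold = 5)
  expect_equal(cc$n, 6)
  expect_equal(cc$tp + cc$fp + cc$fn + cc$tn, cc$n)

  cc_same <- detection_confusion(list(sim), list(sim), threshold = 5)
  expect_equal(cc_same$fp, 0)
  expect_equal(cc_same$fn, 0)
  expect_equal(cc_same$tp, sum(sim$difference > 5))

  all_flag <- dplyr::mutate(sim, difference = 10)
  no_flag <- dplyr::mutate(sim, difference = 0)
  cc2 <- detection_confusion(list(all_flag), list(no_flag), threshold = 5)
  expect_equal(cc2$fp, 6)
  expect_equal(cc2$tp, 0)
})

test_that("ROM CSV round-trips and rejects malformed rows with line numbers", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  recs <- dplyr::bind_rows(hip5_sim_native(), hip5_sim_cam())
  write_rom_csv(recs, tmp)
  back <- read_rom_csv(tmp)
  expect_equal(as.data.frame(back), as.data.frame(recs))

  lines <- readLines(tmp)
  lines[3] <- "hip5,simulation,native,max_ir_0,not_a_number"
  writeLines(lines, tmp)
  expect_error(read_rom_csv(tmp), "line 3")
  lines[3] <- "hip5,simulation,native"
  writeLines(lines, tmp)
  expect_error(read_rom_csv(tmp), "line 3")
})

test_that("reports carry the per-motion table and summary statistics", {
  sim <- compare_conditions(hip5_sim_native(), hip5_sim_cam())
  ref <- compare_conditions(hip5_ref_native(), hip5_ref_cam())
  st <- error_stats(error_vs_reference(sim, ref)$error)
  cc <- detection_confusion(list(sim), list(ref), 5)
  tmp <- withr::local_tempdir()
  prefix <- file.path(tmp, "report")
  write_report(list(sim), stats = st, confusion = cc, prefix = prefix)
  tab <- utils::read.csv(paste0(prefix, ".csv"))
  expect_equal(nrow(tab), 6)
  expect_true(all(c("subject", "motion", "native", "cam", "difference",
                    "limited") %in% names(tab)))
  js <- jsonlite::read_json(paste0(prefix, ".json"))
  expect_equal(js$error_stats$n, 6)
  expect_equal(js$detection$fp, cc$fp)
})
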