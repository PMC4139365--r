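test_that("read_beats parses CSV and flags bad input", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("time_s,label", path)
  expect_equal(n_beats(read_beats(path)), 0)

  writeLines(c("time_s,label", "0.800,N", "1.600,N", "2.400,V", "3.200,N"),
             path)
  bs <- read_beats(path)
  expect_equal(n_beats(bs), 4)
  expect_equal(sum(bs$beats$label == "V"), 1)

  writeLines(c("time_s,label", "0.800,N", "1.600,Q", "2.400,N"), path)
  expect_warning(bs2 <- read_beats(path), "mapped to X")
  expect_equal(bs2$beats$label[2], "X")

  writeLines(c("time_s,label", "0.800,N", "0.800,N", "1.600,N"), path)
  expect_error(read_beats(path), "row 2")
})

test_that("read_beats handles WFDB-style annotation dumps", {
  path <- withr::local_tempfile(fileext = ".ann")
  # clock-time, elapsed seconds, mnemonic
  writeLines(c("0:00:00.800    0.800 N",
               "0:00:01.600    1.600 N",
               "0:00:02.400    2.400 V"), path)
  bs <- read_beats(path, dialect = "wfdb-ann")
  expect_equal(bs$beats$time_s, c(0.8, 1.6, 2.4))
  expect_equal(bs$beats$label, c("N", "N", "V"))
  # sample-index form
  writeLines(c("100 N", "200 N", "300 A"), path)
  bs2 <- read_beats(path, dialect = "wfdb-ann", fs = 125)
  expect_equal(bs2$beats$time_s, c(0.8, 1.6, 2.4))
})

test_that("build_nn keeps only in-bound intervals flanked by N beats", {
  bs <- beat_stream(0:3, rep("N", 4))
  nn <- build_nn(bs)
  expect_equal(nn$intervals$nn_ms, rep(1000, 3))
  expect_equal(unname(nn$exclusions[c("retained", "total")]), c(3L, 3L))

  bs2 <- beat_stream(0:4, c("N", "N", "V", "N", "N"))
  nn2 <- build_nn(bs2)
  expect_equal(nrow(nn2$intervals), 2)
  expect_equal(unname(nn2$exclusions[["ectopic_adjacent"]]), 2L)
  expect_equal(nn2$intervals$onset_time_s, c(0, 3))

  # bounds: a 4-second interval is excluded as out-of-physiological-range
  bs3 <- beat_stream(c(0, 1, 2, 6, 7, 8), rep("N", 6))
  nn3 <- build_nn(bs3)
  expect_equal(unname(nn3$exclusions[["out_of_bounds"]]), 1L)
  expect_equal(nrow(nn3$intervals), 4)
  # wider bounds retain it
  nn3b <- build_nn(bs3, bounds_ms = c(200, 5000))
  expect_equal(nrow(nn3b$intervals), 5)
})

test_that("exclusion accounting is conserved on fuzzed streams", {
  for (seed in 1:10) {
    st <- random_stream(300, seed)
    nn <- tryCatch(build_nn(st), error = function(e) NULL)
    if (is.null(nn)) next
    e <- nn$exclusions
    expect_identical(e[["total"]], n_beats(st) - 1L)
    expect_identical(e[["retained"]] + e[["ectopic_adjacent"]] +
                       e[["out_of_bounds"]], e[["total"]])
    expect_true(all(nn$intervals$nn_ms >= 200 & nn$intervals$nn_ms <= 3000))
    expect_true(all(diff(nn$intervals$onset_time_s) > 0))
  }
})

test_that("an all-N in-bounds stream loses no intervals", {
  st <- constant_stream(0.5, bpm = 75)
  e <- build_nn(st)$exclusions
  expect_equal(unname(e[["retained"]]), unname(e[["total"]]))
})

test_that("windows tile the day and use the half-open convention", {
  st <- constant_stream(24, bpm = 80)
  nn <- build_nn(st)
  expect_length(segment_windows(st, nn, bin_h = 3), 8)
  q <- segment_windows(st, nn, bin_h = 6)
  expect_length(q, 4)
  expect_equal(vapply(q, `[[`, 0.0, "start_clock_h"), c(0, 6, 12, 18))
  expect_error(segment_windows(st, nn, bin_h = 5), "divide")

  # per-window NN counts sum to the total
  expect_equal(sum(vapply(q, function(w) nrow(w$nn), 0L)),
               nrow(nn$intervals))

  # an interval with onset exactly on a boundary joins the later window
  bs <- beat_stream(c(6 * 3600 - 1, 6 * 3600, 6 * 3600 + 1),
                    rep("N", 3), duration_s = 24 * 3600)
  wq <- segment_windows(bs, build_nn(bs), bin_h = 6)
  expect_equal(wq[[1]]$nn$onset_time_s, 6 * 3600 - 1)  # onset 05:59:59
  expect_equal(wq[[2]]$nn$onset_time_s, 6 * 3600)      # onset 06:00:00
})

test_that("recordings not starting at midnight are windowed by wall clock", {
  st <- constant_stream(2, bpm = 60, start_clock_h = 23)
  nn <- build_nn(st)
  w <- segment_windows(st, nn, bin_h = 6)
  # one hour before midnight lands in [18,24), one hour after in [0,6)
  expect_gt(nrow(w[[4]]$nn), 0)
  expect_gt(nrow(w[[1]]$nn), 0)
  expect_equal(nrow(w[[2]]$nn) + nrow(w[[3]]$nn), 0)
})

test_that("exclusion log sidecar is written", {
  st <- beat_stream(0:4, c("N", "N", "V", "N", "N"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_exclusion_log(build_nn(st), path)
  log <- utils::read.csv(path)
  expect_setequal(log$reason,
                  c("retained", "ectopic_adjacent", "out_of_bounds", "total"))
  expect_equal(log$count[log$reason == "retained"], 2)
})
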