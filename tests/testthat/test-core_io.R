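test_that("rr_only files reconstruct beat times by cumulative sum", {
  p <- withr::local_tempfile(lines = c("# comment", "800", "820", "790"))
  s <- read_rr_file(p, "rr_only")
  expect_equal(s$beat_times_s, c(0.8, 1.62, 2.41))
  expect_equal(s$rr_ms, c(800, 820, 790))
  expect_true(all(s$valid))
})

test_that("time_rr files round-trip the same series", {
  p <- withr::local_tempfile(lines = c("0.8,800", "1.62,820"))
  s <- read_rr_file(p, "time_rr")
  expect_equal(s$beat_times_s, c(0.8, 1.62))
  expect_equal(s$rr_ms, c(800, 820))
})

test_that("malformed RR files raise informative errors", {
  p <- withr::local_tempfile(lines = c("0.8,800", "0.7,820"))
  expect_error(read_rr_file(p, "time_rr"), "ascending")
  p2 <- withr::local_tempfile(lines = c("800", "abc"))
  expect_error(read_rr_file(p2, "rr_only"), "line 2")
  p3 <- withr::local_tempfile(lines = c("800", "-100"))
  expect_error(read_rr_file(p3, "rr_only"), "positive")
})

test_that("ibi_series enforces its invariants", {
  expect_error(ibi_series(c(1, 1), c(1000, 1000)), "increasing")
  expect_error(ibi_series(c(1, 2), c(1000, -5)), "positive")
  expect_error(ibi_series(c(1, 2), c(1000, 900)), "inconsistent")
  s <- ibi_series(c(1, 2), c(1000, 1000), duration_s = 10)
  expect_equal(s$duration_s, 10)
})

test_that("clean_ibi flags absolute and relative outliers, keeps values", {
  mk <- function(rr) {
    t <- cumsum(rr) / 1000
    structure(list(beat_times_s = t, rr_ms = rr,
                   valid = rep(TRUE, length(rr)), recording_id = "x",
                   duration_s = max(t)), class = "ibi_series")
  }
  s <- clean_ibi(mk(c(1000, 1000, 250, 1000)))
  expect_equal(s$valid, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(s$rr_ms[3], 250)   # value retained, only the mask changes

  s2 <- clean_ibi(mk(rep(1000, 10)))
  expect_true(all(s2$valid))

  s3 <- clean_ibi(mk(c(1000, 1000, 1400, 1000, 1000)))
  expect_equal(which(!s3$valid), 3L)  # 40% above the local median

  expect_equal(attr(s3, "valid_fraction"), 4 / 5)
})

test_that("epoch grid uses floor and half-open 30-s intervals", {
  mk <- function(dur) ibi_series(seq(1, dur, by = 1), rep(1000, dur),
                                 duration_s = dur)
  expect_equal(build_epoch_grid(mk(120))$n_epochs, 4)
  expect_equal(build_epoch_grid(mk(125))$n_epochs, 4)
  expect_error(build_epoch_grid(mk(25)), "30")
  s <- mk(120)
  g <- build_epoch_grid(s)
  e <- beat_epochs(s, g)
  expect_equal(e[s$beat_times_s == 60], 2L)  # boundary beat: epoch 2, 0-based
  # partition: every in-range beat has exactly one epoch, counts add up
  expect_false(anyNA(e[s$beat_times_s < 30 * g$n_epochs]))
  expect_equal(sum(table(e)), sum(s$beat_times_s < 30 * g$n_epochs))
})

test_that("hypnograms produce annotator fractions and tie-ordered consensus", {
  p <- withr::local_tempfile(lines = c("epoch,stage", "0,W", "1,R"))
  h <- read_hypnogram(p)
  expect_equal(unname(h$fractions),
               matrix(c(1, 0, 0, 0, 0, 1, 0, 0), 2, 4, byrow = TRUE))
  expect_equal(h$stages, c("W", "R"))

  p2 <- withr::local_tempfile(lines = c("epoch,annotator_1,annotator_2",
                                        "0,W,R"))
  h2 <- read_hypnogram(p2)
  expect_equal(unname(h2$fractions[1, ]), c(0.5, 0.5, 0, 0))
  expect_equal(h2$stages, "W")  # tie broken by fixed column order

  p3 <- withr::local_tempfile(
    lines = c("epoch,annotator_1,annotator_2,annotator_3", "0,N1N2,N1N2,N3"))
  h3 <- read_hypnogram(p3)
  expect_equal(unname(h3$fractions[1, ]), c(0, 0, 2 / 3, 1 / 3))
  expect_equal(h3$stages, "N1N2")
  expect_equal(unname(rowSums(h3$fractions)), 1, tolerance = 1e-9)

  p4 <- withr::local_tempfile(lines = c("epoch,stage", "0,W", "1,REM"))
  expect_error(read_hypnogram(p4), "REM")
  p5 <- withr::local_tempfile(lines = c("epoch,stage", "0,W", "2,R"))
  expect_error(read_hypnogram(p5), "contiguous")
})

test_that("feature tables round-trip losslessly with missing cells", {
  reg <- feature_registry()
  tab <- matrix(rnorm(3 * 132) * 1000, 3, 132,
                dimnames = list(NULL, reg$name))
  tab[2, 5] <- NA
  p <- withr::local_tempfile()
  write_feature_table(tab, p)
  hdr <- strsplit(readLines(p, n = 1), ",")[[1]]
  expect_length(hdr, 1 + 132)
  back <- read_feature_table(p)
  expect_equal(back, tab, tolerance = 1e-9)
  expect_true(is.na(back[2, 5]))
})

test_that("the feature registry is fixed at 132 with the printed family counts", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 132)
  counts <- feature_family_counts()
  expect_equal(sum(counts), 132)
  expect_equal(unname(counts),
               c(4L, 12L, 28L, 6L, 4L, 4L, 4L, 20L, 1L, 2L, 7L, 1L, 21L,
                 5L, 13L))
})
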