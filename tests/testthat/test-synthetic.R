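test_that("hypnogram simulation is seeded, bout-structured and 4-class", {
  cfg <- sim_config(tib_hours = 8)
  h1 <- simulate_hypnogram(cfg, seed = 5)
  h2 <- simulate_hypnogram(cfg, seed = 5)
  expect_identical(h1, h2)
  expect_length(h1, 960)
  expect_true(all(h1 %in% STAGES))
  expect_equal(h1[1], "W")
  r <- rle(h1)
  expect_true(all(r$lengths >= 1))
})

test_that("realized stage mix sits near the configured targets", {
  cfg <- sim_config(tib_hours = 8)
  fr <- vapply(1:40, function(i) {
    h <- simulate_hypnogram(cfg, seed = 100 + i)
    sleep <- h[h != "W"]
    c(rem = mean(sleep == "R"), n3 = mean(sleep == "N3"),
      se = mean(h != "W"))
  }, numeric(3))
  expect_lt(abs(mean(fr["rem", ]) - 0.182), 0.06)
  expect_lt(abs(mean(fr["n3", ]) - 0.138), 0.06)
  expect_lt(abs(mean(fr["se", ]) - 0.81), 0.08)
})

test_that("IPFM beat generation is consistent and stage-faithful", {
  h <- rep("N3", 40)  # 20 minutes of N3
  s <- simulate_ibi(h, seed = 6)
  prof <- stage_profiles()
  expect_equal(mean(s$rr_ms[-1]), prof$mean_rr_ms[prof$stage == "N3"],
               tolerance = 0.02 * 1080)
  # beat count ~ integral of instantaneous rate
  expect_equal(length(s$rr_ms), 40 * 30 * 1000 / 1080, tolerance = 0.03)
  s2 <- simulate_ibi(h, seed = 6)
  expect_identical(s$beat_times_s, s2$beat_times_s)
  # series passes its own type validation (time/interval consistency)
  expect_s3_class(ibi_series(s$beat_times_s, s$rr_ms,
                             duration_s = s$duration_s), "ibi_series")
})

test_that("deep sleep nights carry more respiratory HRV power than wake", {
  hf_power <- function(stage, seed) {
    s <- simulate_ibi(rep(stage, 20), seed = seed)
    g <- build_epoch_grid(s)
    seg <- window_slice(s, g, 10, 270)
    spectral_features(seg)["ln_hf"]
  }
  expect_gt(hf_power("N3", 7), hf_power("W", 7))
})

test_that("annotator simulation produces k-fraction soft labels at the rate", {
  h <- simulate_hypnogram(sim_config(tib_hours = 8), seed = 8)
  f0 <- simulate_annotators(h, 2, error_rate = 0, seed = 9)
  expect_equal(soft_to_stages(f0), h)
  expect_true(all(f0 %in% c(0, 1)))
  f2 <- simulate_annotators(h, 2, error_rate = 0.15, seed = 9)
  expect_true(all(f2 %in% c(0, 0.5, 1)))
  expect_equal(rowSums(f2), rep(1, length(h)), tolerance = 1e-9)
  # law of large numbers on the true-stage fraction
  hs <- do.call(c, lapply(1:11, function(i)
    simulate_hypnogram(sim_config(tib_hours = 8), seed = i)))
  fr <- simulate_annotators(hs, 3, error_rate = 0.15, seed = 10)
  true_frac <- fr[cbind(seq_along(hs), match(hs, STAGES))]
  expect_equal(mean(true_frac), 0.85, tolerance = 0.02)
})

test_that("make_cohort writes a reproducible, loadable cohort", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- sim_config(n_participants = 2, nights_per_participant = 2,
                    tib_hours = 1, seed = 11)
  man <- cmd_simulate(d1, participants = 2, nights = 2, tib_hours = 1,
                      seed = 11)
  expect_equal(nrow(man), 4)
  expect_length(list.files(d1, pattern = "_rr\\.csv$"), 4)
  expect_length(list.files(d1, pattern = "_hypnogram\\.csv$"), 4)
  expect_true(file.exists(file.path(d1, "metadata.csv")))
  make_cohort(cfg, d2)
  for (f in list.files(d1, pattern = "\\.csv$")) {
    if (f == "manifest.csv") next
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # generated nights pass io validation and extraction end to end
  rrf <- list.files(d1, pattern = "_rr\\.csv$", full.names = TRUE)[1]
  s <- clean_ibi(read_rr_file(rrf, "time_rr"))
  tab <- extract_all(s, build_epoch_grid(s))
  expect_equal(ncol(tab), 132)
  meta <- read_metadata(file.path(d1, "metadata.csv"))
  expect_equal(nrow(meta), 4)
})

test_that("stage-conditional features separate wake from deep sleep", {
  # distinguishability that makes the downstream recovery task well-posed
  mu <- function(stage, seed) {
    s <- simulate_ibi(rep(stage, 10), seed = seed)
    mean(s$rr_ms[-1])
  }
  w <- vapply(1:8, function(i) mu("W", i), numeric(1))
  n3 <- vapply(1:8, function(i) mu("N3", 100 + i), numeric(1))
  pooled <- sqrt((var(w) + var(n3)) / 2)
  expect_gt(abs(mean(n3) - mean(w)) / pooled, 3)
})
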