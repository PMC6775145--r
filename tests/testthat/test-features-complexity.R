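test_that("sample entropy equals the brute-force template counter", {
  set.seed(21)
  for (i in 1:15) {
    x <- rnorm(sample(40:200, 1))
    r <- 0.2 * sd(x)
    for (m in 1:2) {
      expect_identical(hrvstager:::sampen_counts_cpp(x, m, r),
                       sampen_counts_oracle(x, m, r))
    }
    # the joint diagonal-sweep kernel agrees with the generic one
    expect_identical(hrvstager:::sampen12_counts_cpp(x, r),
                     c(sampen_counts_oracle(x, 1, r),
                       sampen_counts_oracle(x, 2, r)))
  }
})

test_that("sample entropy limits: periodic zero, shuffled above sorted", {
  per <- rep(c(1, 2), 150)
  expect_equal(sample_entropy(per, 1, 0.2 * sd(per)), 0)
  expect_equal(sample_entropy(per, 2, 0.2 * sd(per)), 0)
  set.seed(22)
  vals <- rnorm(120)
  r <- 0.2 * sd(vals)
  expect_gte(sample_entropy(sample(vals), 1, r),
             sample_entropy(sort(vals), 1, r))
})

test_that("multiscale entropy family obeys its missing rules", {
  expect_true(all(is.na(mse_features(rep(1000, 300)))))   # r = 0
  expect_true(all(is.na(mse_features(rnorm(150, 1000, 30)))))  # < 200 beats
  set.seed(23)
  f <- mse_features(rnorm(520, 1000, 30))
  expect_length(f, 20)
  expect_true(all(f[!is.na(f)] >= 0))
  # scale-10 coarse series has 52 points (>= 30), so it must be present
  expect_false(is.na(f["mse_m1_s10"]))
  # reversal invariance: with a length divisible by every scale the
  # coarse-grained series mirror exactly; only the template-edge convention
  # can differ, by a vanishing amount
  x <- rnorm(2520, 1000, 30)
  expect_equal(mse_features(x), mse_features(rev(x)), tolerance = 0.02)
})

test_that("symbolic entropy: degenerate, alternating, and fair-coin limits", {
  expect_true(is.na(symbolic_entropy(seq(1000, 1100, length.out = 60))))
  expect_equal(symbolic_entropy(rep(c(800, 900), 40)), 0)
  set.seed(24)
  # RR whose difference signs are fair coin flips
  rr <- 1000 + cumsum(sample(c(-20, 20), 501, replace = TRUE))
  expect_equal(symbolic_entropy(rr), log(2), tolerance = 0.1)
})

test_that("DFA recovers white and pink scaling exponents", {
  set.seed(25)
  aw <- mean(replicate(5, dfa(rnorm(10000))$alpha))
  expect_lt(abs(aw - 0.5), 0.05)
  ap <- mean(replicate(5, dfa(pink_noise(10000))$alpha))
  expect_lt(abs(ap - 1.0), 0.1)
  expect_true(is.na(dfa(rep(1, 500))$alpha))  # constant -> no fluctuation
})

test_that("the DFA feature family emits its six members and is reversal-safe", {
  set.seed(26)
  rr <- rnorm(350, 1000, 40)
  t <- cumsum(rr) / 1000
  seg <- list(t = t, rr = rr[t >= 30 & t < 300],
              n_total = sum(t >= 30 & t < 300))
  seg$t <- t[t >= 30 & t < 300]
  seg330 <- list(t = t[t >= 15 & t < 345], rr = rr[t >= 15 & t < 345])
  f <- dfa_features(seg, seg330)
  expect_length(f, 6)
  expect_false(anyNA(f))
  # alpha on the same segment is reversal invariant
  a1 <- dfa(seg$rr)$alpha
  a2 <- dfa(rev(seg$rr))$alpha
  expect_equal(a1, a2, tolerance = 1e-6)
})

test_that("Higuchi fractal dimension hits the analytic anchors", {
  expect_equal(higuchi_fd(seq_len(1000) * 0.5), 1.0, tolerance = 0.05)
  set.seed(27)
  fd <- mean(replicate(5, higuchi_fd(rnorm(1000))))
  expect_equal(fd, 2.0, tolerance = 0.1)
  expect_true(is.na(higuchi_fd(rep(3, 500))))
  x <- rnorm(400)
  expect_equal(higuchi_fd(x), higuchi_fd(rev(x)))
})

test_that("Teager energy operator matches its closed form", {
  expect_equal(teager_energy(rep(5, 100)), rep(0, 98))
  A <- 2; omega <- 0.3
  x <- A * sin(omega * seq_len(200))
  psi <- teager_energy(x)
  expect_equal(psi, rep(A^2 * sin(omega)^2, 198), tolerance = 1e-9)
})

test_that("Teager family emits 21 values and EMD extracts the fast mode", {
  set.seed(28)
  rr <- 1000 + 30 * sin(2 * pi * seq_len(300) / 4) +
    200 * sin(2 * pi * seq_len(300) / 100)
  f <- teager_features(rr)
  expect_length(f, 21)
  expect_false(is.na(f["teager_energy_mean"]))
  # first IMF should capture the fast oscillation, not the slow one
  z <- (rr - mean(rr)) / sd(rr)
  imf <- emd_first_imf(z)
  fast <- sin(2 * pi * seq_len(300) / 4)
  expect_gt(abs(cor(imf, fast)), 0.8)
  expect_true(all(is.na(teager_features(rep(1000, 200)))))
})

test_that("phase coordination flags constructed runs, stays low on noise", {
  # (+,+,-,-) repeated: one long coordinated run
  base <- rep(c(10, 10, -10, -10), 10)
  rr <- 1000 + cumsum(c(rep(base, 2)))
  f <- phase_coordination_features(rr)
  expect_gt(f["phase_coord_long"], 0.9)
  expect_lt(f["phase_coord_short"], 0.1)
  set.seed(29)
  fr <- colMeans(t(replicate(10, {
    rr <- 1000 + cumsum(sample(c(-15, 15), 500, replace = TRUE))
    phase_coordination_features(rr)
  })))
  expect_lt(fr["phase_coord_long"], 0.4)
})

test_that("phase synchronization detects locked rhythms, not random signs", {
  sgn <- rep(c(8, 8, 8, -8, -8, -8), 45)
  rr <- 1000 + cumsum(sgn)
  seg <- list(t = cumsum(rr) / 1000, rr = rr)
  f <- phase_sync_features(seg)
  expect_length(f, 7)
  expect_gt(f["sync_rate_6"], 0.95)
  expect_equal(unname(f["sync_dominant_ratio"]), 6)
  expect_gt(f["sync_long_fraction"], 0.9)
  # dominant ratio is the argmax of the four rates by definition
  expect_equal(unname(f["sync_dominant_ratio"]),
               c(6, 7, 8, 9)[which.max(f[1:4])])
  set.seed(30)
  for (i in 1:5) {
    rr <- 1000 + cumsum(sample(c(-10, 10), 300, replace = TRUE))
    f <- phase_sync_features(list(t = cumsum(rr) / 1000, rr = rr))
    expect_true(all(f[1:4] <= 0.3))
  }
})

test_that("visibility graphs equal the cubic-time oracle and the examples", {
  e1 <- hrvstager:::nvg_edges_cpp(1:3, c(1, 2, 3))
  expect_equal(unname(e1[order(e1[, 1]), , drop = FALSE]),
               matrix(c(1, 2, 2, 3), 2, 2, byrow = TRUE))
  e2 <- hrvstager:::nvg_edges_cpp(1:3, c(3, 1, 2))
  expect_equal(nrow(e2), 3)  # all pairs mutually visible
  set.seed(31)
  for (i in 1:8) {
    n <- sample(20:120, 1)
    y <- rnorm(n); t <- sort(runif(n, 0, 100))
    got <- hrvstager:::nvg_edges_cpp(t, y)
    want <- nvg_edges_oracle(t, y)
    o <- order(got[, 1], got[, 2])
    expect_equal(unname(got[o, , drop = FALSE]), unname(want))
  }
})

test_that("visibility features: adjacency floor and 13-value family", {
  set.seed(32)
  rr <- rnorm(100, 1000, 30)
  seg <- list(t = cumsum(rr) / 1000, rr = rr)
  f <- visibility_features(seg)
  expect_length(f, 13)
  st <- hrvstager:::nvg_stats_cpp(seg$t, seg$rr)
  expect_true(all(st$degree >= 1))  # adjacent beats are always visible
  expect_true(all(is.na(visibility_features(list(t = 1:10, rr = rnorm(10))))))
})

test_that("arousal surrogate is quiet at rest and fires on an HR surge", {
  rr_fun_steady <- function(t) 1000
  b <- synthetic_beats(600, rr_fun_steady)
  # add tiny jitter so the baseline SD is nonzero
  set.seed(33)
  rr <- b$rr + rnorm(length(b$rr), 0, 5)
  t <- cumsum(rr) / 1000
  s <- ibi_series(t, rr)
  g <- build_epoch_grid(s)
  f <- arousal_features(s, g, 10)
  expect_length(f, 5)
  expect_lt(f["arousal_p_max"], 0.2)
  expect_lt(f["arousal_p_sd"], 0.2)
  # 20-bpm surge for 10 s inside the window of epoch 10 (300-330 s)
  surge <- function(t) if (t >= 310 && t < 320) 750 else 1000
  b2 <- synthetic_beats(600, surge)
  rr2 <- b2$rr + rnorm(length(b2$rr), 0, 5)
  s2 <- ibi_series(cumsum(rr2) / 1000, rr2)
  f2 <- arousal_features(s2, build_epoch_grid(s2), 10)
  expect_gt(f2["arousal_p_max"], 0.9)
  expect_true(all(f2[1:4] >= 0 & f2[1:4] <= 1))
})
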