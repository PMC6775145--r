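#' Teager energy operator
#'
#' \eqn{\psi(x_i) = x_i^2 - x_{i-1} x_{i+1}}, defined for interior samples.
#'
#' @param x Numeric series (>= 3 points).
#' @return Vector of length \code{length(x) - 2}.
#' @export
teager_energy <- function(x) {
  n <- length(x)
  if (n < 3) return(numeric(0))
  x[2:(n - 1)]^2 - x[1:(n - 2)] * x[3:n]
}

#' First intrinsic mode function by empirical mode decomposition
#'
#' Standard sifting with natural-cubic-spline envelopes through local
#' extrema (series endpoints included in both envelopes), stopped by the
#' Cauchy criterion \eqn{\sum m^2 / \sum h^2 < sd\_tol} or after
#' \code{max_sift} iterations.
#'
#' @param x Numeric series.
#' @param sd_tol Cauchy stopping tolerance.
#' @param max_sift Maximum sifting iterations.
#' @return The first IMF, or NULL when the series has too few extrema.
#' @export
emd_first_imf <- function(x, sd_tol = 0.3, max_sift = 100L) {
  n <- length(x)
  if (n < 10) return(NULL)
  h <- x
  for (iter in seq_len(max_sift)) {
    d <- diff(h)
    sgn <- ifelse(d > 0, 1L, -1L)
    turn <- diff(sgn)
    imax <- which(turn < 0) + 1L
    imin <- which(turn > 0) + 1L
    if (length(imax) < 2 || length(imin) < 2) {
      return(if (iter == 1L) NULL else h)
    }
    up_i <- unique(c(1L, imax, n))
    lo_i <- unique(c(1L, imin, n))
    upper <- stats::spline(up_i, h[up_i], xout = seq_len(n),
                           method = "natural")$y
    lower <- stats::spline(lo_i, h[lo_i], xout = seq_len(n),
                           method = "natural")$y
    m <- (upper + lower) / 2
    denom <- sum(h^2)
    if (denom == 0) return(h)
    crit <- sum(m^2) / denom
    h <- h - m
    if (crit < sd_tol) break
  }
  h
}

# transition points: indices where the sign of the first difference of the
# 3-point moving average changes (zero differences count as falling)
transition_points <- function(x) {
  n <- length(x)
  if (n < 4) return(integer(0))
  ma <- (x[1:(n - 2)] + x[2:(n - 1)] + x[3:n]) / 3
  s <- ifelse(diff(ma) > 0, 1L, -1L)
  which(diff(s) != 0L) + 2L    # index into x at the centre of the turn
}

# strict local maxima
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
}

# 10 summary stats of transitions/maxima for one signal representation
rep_stats <- function(x) {
  n <- length(x)
  tr <- transition_points(x)
  mx <- local_maxima(x)
  iv_stats <- function(idx) {
    if (length(idx) < 2) c(NA_real_, NA_real_)
    else c(mean(diff(idx)), stats::sd(diff(idx)))
  }
  amp_stats <- function(idx) {
    if (!length(idx)) c(NA_real_, NA_real_)
    else c(mean(x[idx]), if (length(idx) > 1) stats::sd(x[idx]) else NA_real_)
  }
  c(trans_pct = 100 * length(tr) / n, max_pct = 100 * length(mx) / n,
    trans_iv = iv_stats(tr), max_iv = iv_stats(mx),
    trans_amp = amp_stats(tr), max_amp = amp_stats(mx))
}

#' Teager / transition-point feature family (21 values)
#'
#' The mean Teager energy of the z-scored RR segment, plus 10 summary
#' statistics (percentages of transition points and local maxima, mean/SD of
#' the intervals between them in beats, mean/SD of the signal amplitude at
#' them) for each of two representations: the z-scored RR series and its
#' first intrinsic mode function after empirical mode decomposition.
#'
#' @param rr RR segment; needs >= 100 beats with positive SD.
#' @return Named numeric vector of 21 values in registry order.
#' @export
teager_features <- function(rr) {
  stat_names <- c("trans_pct", "max_pct", "trans_iv_mean", "trans_iv_sd",
                  "max_iv_mean", "max_iv_sd", "trans_amp_mean", "trans_amp_sd",
                  "max_amp_mean", "max_amp_sd")
  nm <- c("teager_energy_mean", paste0("teager_ibi_", stat_names),
          paste0("teager_imf1_", stat_names))
  out <- stats::setNames(rep(NA_real_, 21), nm)
  n <- length(rr)
  if (n < 100 || stats::sd(rr) == 0) return(out)
  z <- (rr - mean(rr)) / stats::sd(rr)
  out["teager_energy_mean"] <- mean(teager_energy(z))
  out[2:11] <- rep_stats(z)
  imf <- emd_first_imf(z)
  if (!is.null(imf)) out[12:21] <- rep_stats(imf)
  out
}

#' Surrogate arousal-probability features (5 values)
#'
#' A stand-in arousal-probability signal built from heart-rate surges: per
#' 10-s step inside the window, the step's mean HR is z-scored against the
#' trailing 120 s of the recording and pushed through a logistic
#' \eqn{p = 1 / (1 + e^{-(z - 2)/0.5})}. Emitted: max, mean, median, min and
#' SD of p over the window's steps. This is a synthetic surrogate of an
#' external arousal model, not a validated arousal detector.
#'
#' @param series Full [ibi_series()] (the trailing baseline may reach before
#'   the window).
#' @param grid Epoch grid.
#' @param epoch 0-based epoch index.
#' @param window_len_s Window length.
#' @return Named numeric vector of 5 values.
#' @export
arousal_features <- function(series, grid, epoch, window_len_s = WIN_DEFAULT) {
  nm <- paste0("arousal_p_", c("max", "mean", "median", "min", "sd"))
  out <- stats::setNames(rep(NA_real_, 5), nm)
  center <- 30 * epoch + 15
  lo <- max(center - window_len_s / 2, 0)
  hi <- min(center + window_len_s / 2, series$duration_s)
  t <- series$beat_times_s[series$valid]
  hr <- 60000 / series$rr_ms[series$valid]
  if (!length(t)) return(out)
  # cumulative sums give O(1) step / trailing-baseline means and SDs
  cs <- c(0, cumsum(hr)); cs2 <- c(0, cumsum(hr^2))
  rng_stats <- function(a, b) {   # beats with a <= t < b
    i <- findInterval(a, t, left.open = TRUE) + 1L
    j <- findInterval(b, t, left.open = TRUE)
    n <- j - i + 1L
    if (n < 1) return(c(0, NA, NA))
    s1 <- cs[j + 1L] - cs[i]; s2 <- cs2[j + 1L] - cs2[i]
    mu <- s1 / n
    va <- if (n > 1) max(0, (s2 - n * mu^2) / (n - 1)) else NA_real_
    c(n, mu, sqrt(va))
  }
  if (rng_stats(lo, hi)[1] < 60) return(out)
  starts <- seq(lo, hi - 10, by = 10)
  p <- vapply(starts, function(s0) {
    step <- rng_stats(s0, s0 + 10)
    base <- rng_stats(s0 - 120, s0)
    if (step[1] < 3 || base[1] < 30) return(NA_real_)
    if (!is.finite(base[3]) || base[3] == 0) return(NA_real_)
    z <- (step[2] - base[2]) / base[3]
    stats::plogis((z - 2) / 0.5)
  }, numeric(1))
  p <- p[!is.na(p)]
  if (length(p) < 5) return(out)
  out[] <- c(max(p), mean(p), stats::median(p), min(p), stats::sd(p))
  out
}

#' Visibility-graph feature family (13 values)
#'
#' A natural visibility graph (NVG) is built on the RR values at their beat
#' times (strict visibility) and a difference visibility graph (DVG) on the
#' first-difference series. From the NVG: degree assortativity, mean and SD
#' of local clustering coefficients, mean and SD of degrees, the
#' least-squares slope of log frequency versus log degree, and the
#' percentage of nodes with degree <= 3 and >= 10. From the DVG: mean/SD
#' degree, power-law slope and the two degree percentages.
#'
#' @param seg List with \code{t}, \code{rr} of >= 50 valid beats.
#' @return Named numeric vector of 13 values.
#' @export
visibility_features <- function(seg) {
  nm <- c("nvg_assortativity", "nvg_clust_mean", "nvg_clust_sd",
          "nvg_degree_mean", "nvg_degree_sd", "nvg_powerlaw_slope",
          "nvg_low_degree_pct", "nvg_high_degree_pct",
          "dvg_degree_mean", "dvg_degree_sd", "dvg_powerlaw_slope",
          "dvg_low_degree_pct", "dvg_high_degree_pct")
  out <- stats::setNames(rep(NA_real_, 13), nm)
  if (length(seg$rr) < 50) return(out)
  nvg <- nvg_stats_cpp(seg$t, seg$rr)
  deg <- nvg$degree
  out["nvg_assortativity"] <- nvg$assortativity
  out["nvg_clust_mean"] <- mean(nvg$clustering)
  out["nvg_clust_sd"] <- stats::sd(nvg$clustering)
  out["nvg_degree_mean"] <- mean(deg)
  out["nvg_degree_sd"] <- stats::sd(deg)
  out["nvg_powerlaw_slope"] <- powerlaw_slope(deg)
  out["nvg_low_degree_pct"] <- 100 * mean(deg <= 3)
  out["nvg_high_degree_pct"] <- 100 * mean(deg >= 10)
  d <- diff(seg$rr)
  dvg <- nvg_stats_cpp(seq_along(d), d)
  out["dvg_degree_mean"] <- mean(dvg$degree)
  out["dvg_degree_sd"] <- stats::sd(dvg$degree)
  out["dvg_powerlaw_slope"] <- powerlaw_slope(dvg$degree)
  out["dvg_low_degree_pct"] <- 100 * mean(dvg$degree <= 3)
  out["dvg_high_degree_pct"] <- 100 * mean(dvg$degree >= 10)
  out
}

# least-squares slope of log frequency vs log degree
powerlaw_slope <- function(deg) {
  tab <- table(deg[deg > 0])
  k <- as.numeric(names(tab))
  if (length(k) < 2) return(NA_real_)
  unname(stats::coef(stats::lm.fit(cbind(1, log(k)), log(as.numeric(tab))))[2])
}
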