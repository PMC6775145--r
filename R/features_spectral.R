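# Canonical HRV band edges (Hz)
BAND_VLF <- c(0.003, 0.04)
BAND_LF <- c(0.04, 0.15)
BAND_HF <- c(0.15, 0.40)
LN_POWER_FLOOR <- 1e-10  # added inside ln() so empty bands stay finite

#' Welch power spectral density
#'
#' Hann-tapered segments with 50% overlap, one-sided density normalized so
#' that summing \code{psd * df} over all frequencies recovers the signal
#' variance (Parseval).
#'
#' @param x Evenly sampled, mean-removed signal.
#' @param fs Sampling rate (Hz).
#' @param seg_len Segment length in samples (truncated to \code{length(x)}).
#' @return List with \code{freq} and \code{psd}.
#' @export
welch_psd <- function(x, fs, seg_len = 480L) {
  n <- length(x)
  seg_len <- min(seg_len, n)
  step <- max(1L, seg_len %/% 2L)
  starts <- seq(1L, n - seg_len + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))  # Hann
  U <- sum(w^2)
  nf <- seg_len %/% 2L
  acc <- numeric(nf + 1L)
  for (s0 in starts) {
    seg <- x[s0:(s0 + seg_len - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg)[1:(nf + 1L)])^2
    acc <- acc + sp
  }
  psd <- acc / (length(starts) * fs * U)
  psd[2:(nf + 1L)] <- 2 * psd[2:(nf + 1L)]  # one-sided (fold negative freqs)
  if (seg_len %% 2L == 0L) psd[nf + 1L] <- psd[nf + 1L] / 2
  list(freq = (0:nf) * fs / seg_len, psd = psd)
}

band_power <- function(spec, band) {
  df <- spec$freq[2] - spec$freq[1]
  sel <- spec$freq >= band[1] & spec$freq < band[2]
  sum(spec$psd[sel]) * df
}

# Resample valid (t, rr) beats onto a uniform 4 Hz tachogram by cubic spline;
# gaps left by invalid beats are bridged by the spline.
resample_tachogram <- function(t, rr, fs = 4) {
  grid <- seq(min(t), max(t), by = 1 / fs)
  stats::spline(t, rr, xout = grid, method = "fmm")$y
}

#' Spectral feature family (12 values)
#'
#' From a 4 Hz cubic-spline tachogram of the window: Welch PSD (120-s
#' segments, 50% overlap, Hann) gives ln band powers in the canonical VLF
#' (0.003-0.04), LF (0.04-0.15) and HF (0.15-0.4 Hz) bands plus the LF/HF
#' ratio; boundary-adapted variants re-centre the HF band on the detected
#' respiratory peak (+/- 0.1 Hz, clipped to [0.1, 0.5] Hz) with the LF upper
#' edge moved to the adapted band's lower edge; the respiratory frequency is
#' the largest HF-band spectral peak with ln power in +/- 0.015 Hz around it;
#' and an order-9 Burg autoregressive fit contributes the phase and modulus
#' of the largest-modulus pole whose angle falls in the HF band.
#'
#' @param seg List with valid-beat \code{t} (s) and \code{rr} (ms); needs
#'   >= 60 beats.
#' @return Named numeric vector of 12 values.
#' @export
spectral_features <- function(seg) {
  nm <- c("ln_vlf", "ln_lf", "ln_hf", "lf_hf_ratio",
          "adapt_ln_vlf", "adapt_ln_lf", "adapt_ln_hf", "adapt_lf_hf_ratio",
          "resp_freq", "resp_power", "hf_pole_phase", "hf_pole_modulus")
  out <- stats::setNames(rep(NA_real_, 12), nm)
  if (length(seg$rr) < 60) return(out)
  fs <- 4
  x <- resample_tachogram(seg$t, seg$rr, fs)
  x <- x - mean(x)
  spec <- welch_psd(x, fs, seg_len = 120L * fs)
  vlf <- band_power(spec, BAND_VLF)
  lf <- band_power(spec, BAND_LF)
  hf <- band_power(spec, BAND_HF)
  out["ln_vlf"] <- log(vlf + LN_POWER_FLOOR)
  out["ln_lf"] <- log(lf + LN_POWER_FLOOR)
  out["ln_hf"] <- log(hf + LN_POWER_FLOOR)
  if (hf > 1e-9) out["lf_hf_ratio"] <- lf / hf

  hf_sel <- which(spec$freq >= BAND_HF[1] & spec$freq < BAND_HF[2])
  if (length(hf_sel) && any(spec$psd[hf_sel] > 0)) {
    fr <- spec$freq[hf_sel[which.max(spec$psd[hf_sel])]]
    out["resp_freq"] <- fr
    out["resp_power"] <- log(band_power(spec, c(fr - 0.015, fr + 0.015)) +
                               LN_POWER_FLOOR)
    hf_band <- pmin(pmax(c(fr - 0.1, fr + 0.1), 0.1), 0.5)
    lf_band <- c(BAND_LF[1], hf_band[1])
    a_vlf <- band_power(spec, BAND_VLF)
    a_lf <- band_power(spec, lf_band)
    a_hf <- band_power(spec, hf_band)
    out["adapt_ln_vlf"] <- log(a_vlf + LN_POWER_FLOOR)
    out["adapt_ln_lf"] <- log(a_lf + LN_POWER_FLOOR)
    out["adapt_ln_hf"] <- log(a_hf + LN_POWER_FLOOR)
    if (a_hf > 1e-9) out["adapt_lf_hf_ratio"] <- a_lf / a_hf
  }

  pole <- tryCatch(hf_pole(x, fs), error = function(e) NULL)
  if (!is.null(pole)) {
    out["hf_pole_phase"] <- pole[1]
    out["hf_pole_modulus"] <- pole[2]
  }
  out
}

# Largest-modulus pole of an order-9 Burg AR fit whose angle lies in the HF
# band; returns c(phase, modulus) or NULL.
hf_pole <- function(x, fs, order = 9L) {
  if (stats::sd(x) == 0) return(NULL)
  fit <- stats::ar.burg(x, aic = FALSE, order.max = order, demean = TRUE)
  a <- fit$ar
  if (!length(a)) return(NULL)
  roots <- polyroot(c(1, -a))       # roots of 1 - a1 z - ... (z = 1/pole)
  poles <- 1 / roots
  theta <- Arg(poles)
  freq <- theta * fs / (2 * pi)
  sel <- which(freq >= BAND_HF[1] & freq < BAND_HF[2])
  if (!length(sel)) return(NULL)
  best <- sel[which.max(Mod(poles)[sel])]
  c(theta[best], Mod(poles)[best])
}
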