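#' Slice the valid beats of a centred epoch window
#'
#' The window for epoch \code{e} covers \code{[c - L/2, c + L/2)} with
#' \code{c = 30 e + 15}; at recording edges it is truncated, never padded.
#'
#' @param series An [ibi_series()].
#' @param grid Epoch grid of the recording.
#' @param epoch 0-based epoch index.
#' @param window_len_s Window length in seconds.
#' @return List with \code{t} (beat times, s), \code{rr} (RR, ms) of the valid
#'   beats, \code{n_total} (all beats in window), \code{valid_fraction}, and
#'   \code{span_fraction} (available window span / nominal).
#' @export
window_slice <- function(series, grid, epoch, window_len_s = WIN_DEFAULT) {
  stopifnot(epoch >= 0, epoch < grid$n_epochs)
  center <- 30 * epoch + 15
  lo <- center - window_len_s / 2
  hi <- center + window_len_s / 2
  lo_eff <- max(lo, 0)
  hi_eff <- min(hi, series$duration_s)
  t <- series$beat_times_s
  i1 <- findInterval(lo_eff, t, left.open = TRUE) + 1L
  i2 <- findInterval(hi_eff, t, left.open = TRUE)  # t < hi (half-open)
  if (i2 >= i1) {
    idx <- i1:i2
    ok <- series$valid[idx]
    list(t = t[idx][ok], rr = series$rr_ms[idx][ok],
         n_total = length(idx), valid_fraction = mean(ok),
         span_fraction = (hi_eff - lo_eff) / window_len_s)
  } else {
    list(t = numeric(0), rr = numeric(0), n_total = 0L,
         valid_fraction = NA_real_,
         span_fraction = (hi_eff - lo_eff) / window_len_s)
  }
}

#' Remove the linear trend of an RR segment
#'
#' Subtracts the ordinary-least-squares line of RR versus beat index.
#'
#' @param rr Numeric RR segment (>= 3 beats, else \code{NULL}).
#' @return Detrended segment with zero mean and zero linear trend.
#' @export
detrend_rr <- function(rr) {
  n <- length(rr)
  if (n < 3) return(NULL)
  x <- seq_len(n) - (n + 1) / 2          # centred index
  beta <- sum(x * rr) / sum(x * x)
  rr - mean(rr) - beta * x
}

# Mean absolute deviation from the mean (the time-domain "MAD" of HRV work,
# not the median absolute deviation).
mad_mean <- function(x) mean(abs(x - mean(x)))

#' Basic and variability time-domain features
#'
#' Emits the 4 basic features (mean/median RR and HR on the absolute signal;
#' HR per beat is 60000/RR) and 12 variability features (SDNN, range, pNN50,
#' RMSSD, SDSD, mean absolute deviation; each on the absolute and the
#' linearly detrended RR).
#'
#' @param rr RR segment (ms) of valid beats.
#' @return Named numeric vector of 16 values (NA where undefined).
#' @export
basic_variability_features <- function(rr) {
  reg_names <- c("rr_mean", "rr_median", "hr_mean", "hr_median",
                 paste0(c("sdnn", "rr_range", "pnn50", "rmssd", "sdsd", "mad"),
                        "_abs"),
                 paste0(c("sdnn", "rr_range", "pnn50", "rmssd", "sdsd", "mad"),
                        "_det"))
  out <- stats::setNames(rep(NA_real_, 16L), reg_names)
  n <- length(rr)
  if (n >= 1) {
    hr <- 60000 / rr
    out["rr_mean"] <- mean(rr); out["rr_median"] <- stats::median(rr)
    out["hr_mean"] <- mean(hr); out["hr_median"] <- stats::median(hr)
  }
  variability <- function(x) {
    d <- diff(x)
    c(sdnn = stats::sd(x), rr_range = max(x) - min(x),
      pnn50 = 100 * mean(abs(d) > 50), rmssd = sqrt(mean(d^2)),
      sdsd = stats::sd(d), mad = mad_mean(x))
  }
  if (n >= 2) out[5:10] <- variability(rr)
  det <- detrend_rr(rr)
  if (!is.null(det)) out[11:16] <- variability(det)
  out
}

#' Percentile features of RR and HR
#'
#' 7 percentiles (5, 10, 25, 50, 75, 90, 95) of RR and HR, each on the
#' absolute and detrended signal (detrending applied to RR and to HR
#' separately); linear-interpolation percentile definition.
#'
#' @param rr RR segment (ms) of valid beats; needs >= 20 beats.
#' @return Named numeric vector of 28 values.
#' @export
percentile_features <- function(rr) {
  pcts <- c(5, 10, 25, 50, 75, 90, 95)
  nm <- c(paste0("rr_abs_p", pcts), paste0("rr_det_p", pcts),
          paste0("hr_abs_p", pcts), paste0("hr_det_p", pcts))
  out <- stats::setNames(rep(NA_real_, 28L), nm)
  if (length(rr) < 20) return(out)
  q <- function(x) stats::quantile(x, pcts / 100, names = FALSE, type = 7)
  hr <- 60000 / rr
  out[1:7] <- q(rr)
  out[8:14] <- q(detrend_rr(rr))
  out[15:21] <- q(hr)
  out[22:28] <- q(detrend_rr(hr))
  out
}
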