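#' Detrended fluctuation analysis scaling exponent
#'
#' First-order DFA: integrate the mean-centred series, split into
#' non-overlapping boxes of each size, remove a least-squares line per box,
#' and regress the log RMS residual on log box size.
#'
#' @param x Numeric series.
#' @param scales Integer box sizes.
#' @return List with \code{alpha} and the fluctuation function \code{f}
#'   (named by scale); \code{alpha} is NA when fewer than 2 usable scales or
#'   the series is (near) constant.
#' @export
dfa <- function(x, scales = dfa_scales()) {
  f <- dfa_profile(x, scales)
  list(alpha = dfa_fit(f), f = f)
}

# fluctuation function F(n) over the usable scales
dfa_profile <- function(x, scales) {
  scales <- scales[scales >= 4 & scales <= length(x) %/% 2]
  if (length(scales) < 2) return(stats::setNames(numeric(0), integer(0)))
  stats::setNames(dfa_profile_cpp(as.numeric(x), as.integer(scales)), scales)
}

# scaling exponent from a (sub-range of a) fluctuation profile: closed-form
# least-squares slope of log F vs log scale
dfa_fit <- function(f, lo = -Inf, hi = Inf) {
  s <- as.numeric(names(f))
  keep <- s >= lo & s <= hi & f > 0
  if (sum(keep) < 2) return(NA_real_)
  lx <- log(s[keep]); ly <- log(f[keep])
  sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
}

# box-size ladder covering 4..64, denser at the short end
DFA_SCALE_LADDER <- local({
  s <- unique(round(exp(seq(log(4), log(64), length.out = 16))))
  sort(unique(c(s, 16)))
})

dfa_scales <- function(lo = 4, hi = 64) {
  DFA_SCALE_LADDER[DFA_SCALE_LADDER >= lo & DFA_SCALE_LADDER <= hi]
}

#' DFA feature family (6 values)
#'
#' \code{dfa_alpha_all} (scales 4-64), \code{dfa_alpha_short} (4-16),
#' \code{dfa_alpha_long} (16-64) and \code{dfa_f16} (RMS fluctuation at box
#' size 16) are computed on the 270-s window. \code{wdfa} is the mean
#' all-scale exponent over 150-s sub-windows stepped by 30 s across the 330-s
#' window; \code{pdfa} is the mean exponent (scales 4-16) over consecutive
#' non-overlapping 64-beat segments.
#'
#' @param seg270 List with \code{t}, \code{rr} for the 270-s window.
#' @param seg330 Same for the 330-s window.
#' @return Named numeric vector of 6 values.
#' @export
dfa_features <- function(seg270, seg330) {
  out <- stats::setNames(rep(NA_real_, 6),
                         c("dfa_alpha_all", "dfa_alpha_short",
                           "dfa_alpha_long", "dfa_f16", "wdfa", "pdfa"))
  rr <- seg270$rr
  if (length(rr) >= 100) {
    # one fluctuation profile serves the three exponent ranges and F(16)
    f <- dfa_profile(rr, dfa_scales())
    out["dfa_alpha_all"] <- dfa_fit(f)
    out["dfa_alpha_short"] <- dfa_fit(f, 4, 16)
    out["dfa_alpha_long"] <- dfa_fit(f, 16, 64)
    if ("16" %in% names(f) && f[["16"]] > 0) out["dfa_f16"] <- f[["16"]]
    # PDFA: consecutive non-overlapping 64-beat segments
    nseg <- length(rr) %/% 64
    if (nseg >= 1) {
      a <- vapply(seq_len(nseg), function(k) {
        dfa_fit(dfa_profile(rr[((k - 1) * 64 + 1):(k * 64)],
                            dfa_scales(4, 16)))
      }, numeric(1))
      if (any(!is.na(a))) out["pdfa"] <- mean(a, na.rm = TRUE)
    }
  }
  # WDFA: 150-s sub-windows, 30-s step, over the 330-s window
  t <- seg330$t; rr3 <- seg330$rr
  if (length(rr3) >= 100) {
    lo <- min(t)
    starts <- seq(lo, lo + 330 - 150, by = 30)
    a <- vapply(starts, function(s0) {
      i1 <- findInterval(s0, t, left.open = TRUE) + 1L
      i2 <- findInterval(s0 + 150, t, left.open = TRUE)
      if (i2 - i1 + 1 < 64) return(NA_real_)
      dfa_fit(dfa_profile(rr3[i1:i2], dfa_scales(4, 32)))
    }, numeric(1))
    if (any(!is.na(a))) out["wdfa"] <- mean(a, na.rm = TRUE)
  }
  out
}

#' Higuchi fractal dimension
#'
#' Curve-length method on the z-scored series with \code{k_max = 10}; the
#' dimension is minus the slope of log mean curve length versus log k.
#'
#' @param x Numeric series (>= 100 points; SD must be positive).
#' @param k_max Maximum delay.
#' @return Fractal dimension (1 for a smooth line, 2 for white noise), or NA.
#' @export
higuchi_fd <- function(x, k_max = 10L) {
  n <- length(x)
  if (n < 100 || stats::sd(x) == 0) return(NA_real_)
  z <- (x - mean(x)) / stats::sd(x)
  lk <- vapply(seq_len(k_max), function(k) {
    lm_ <- vapply(seq_len(k), function(m) {
      idx <- seq(m, n, by = k)
      if (length(idx) < 2) return(NA_real_)
      norm <- (n - 1) / (k * (length(idx) - 1))
      sum(abs(diff(z[idx]))) * norm / k
    }, numeric(1))
    mean(lm_, na.rm = TRUE)
  }, numeric(1))
  fit <- stats::coef(stats::lm.fit(cbind(1, log(seq_len(k_max))), log(lk)))
  -unname(fit[2])
}
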