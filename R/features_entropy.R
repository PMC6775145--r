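#' Sample entropy
#'
#' \eqn{SampEn(m, r) = -\ln(A/B)} where B and A count template pairs matching
#' within Chebyshev tolerance r at lengths m and m+1 (self-matches excluded,
#' both counted over the N - m template positions).
#'
#' @param x Numeric series.
#' @param m Template length.
#' @param r Tolerance (absolute units of x).
#' @return Entropy in nats; NA when A or B is zero or the series is too
#'   short.
#' @export
sample_entropy <- function(x, m = 2L, r = 0.2 * stats::sd(x)) {
  if (length(x) < m + 2 || !is.finite(r) || r <= 0) return(NA_real_)
  ab <- sampen_counts_cpp(as.numeric(x), as.integer(m), r)
  if (ab[1] == 0 || ab[2] == 0) return(NA_real_)
  -log(ab[1] / ab[2])
}

#' Multiscale sample entropy family (20 values)
#'
#' For scale tau in 1..10 the series is coarse-grained by non-overlapping
#' means of tau beats and SampEn(m, r) computed for m in {1, 2} with r frozen
#' at 0.2 x SD of the original (scale-1) segment. Scales whose coarse-grained
#' series is shorter than 30 points are missing.
#'
#' @param rr RR segment from the 510-s window; needs >= 200 beats.
#' @return Named numeric vector of 20 values (\code{mse_m1_s1..10},
#'   \code{mse_m2_s1..10}).
#' @export
mse_features <- function(rr) {
  nm <- c(paste0("mse_m1_s", 1:10), paste0("mse_m2_s", 1:10))
  out <- stats::setNames(rep(NA_real_, 20), nm)
  n <- length(rr)
  if (n < 200) return(out)
  r <- 0.2 * stats::sd(rr)
  if (!is.finite(r) || r <= 0) return(out)  # constant series
  for (tau in 1:10) {
    ncg <- n %/% tau
    if (ncg < 30) next
    cg <- if (tau == 1) rr else
      colMeans(matrix(rr[seq_len(ncg * tau)], nrow = tau))
    # single diagonal sweep yields the m = 1 and m = 2 counts together
    ab <- sampen12_counts_cpp(as.numeric(cg), r)
    out[paste0("mse_m1_s", tau)] <-
      if (ab[1] > 0 && ab[2] > 0) -log(ab[1] / ab[2]) else NA_real_
    out[paste0("mse_m2_s", tau)] <-
      if (ab[3] > 0 && ab[4] > 0) -log(ab[3] / ab[4]) else NA_real_
  }
  out
}

#' Sample entropy of symbolic RR changes (1 value)
#'
#' Successive RR differences are mapped to binary symbols (1 if the next RR
#' is larger, else 0; zero differences count as 0) and SampEn(m = 2) with
#' exact matching is computed on the symbol string.
#'
#' @param rr RR segment; needs >= 50 beats.
#' @return Entropy in nats; NA for degenerate (all-identical) symbol strings.
#' @export
symbolic_entropy <- function(rr) {
  if (length(rr) < 50) return(NA_real_)
  b <- as.numeric(diff(rr) > 0)
  if (length(unique(b)) < 2) return(NA_real_)
  sample_entropy(b, 2L, 0.5)  # r < 1 on a 0/1 string = exact matching
}
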