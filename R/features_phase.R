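# Sign sequence of RR differences; zero differences map to '-' (-1) by
# convention so the alphabet is always binary.
rr_signs <- function(rr) ifelse(diff(rr) > 0, 1L, -1L)

#' Phase coordination of RR sign patterns (2 values)
#'
#' The sign sequence of RR differences is scanned for stretches where a fixed
#' pattern of length p (3..8) repeats back-to-back. A beat is coordinated
#' when it lies inside a run of >= 2 repetitions; short-range coordination is
#' the fraction of beats inside runs of exactly 2 repetitions, long-range the
#' fraction inside runs of >= 3 repetitions.
#'
#' @param rr RR segment; needs >= 50 beats.
#' @return Named vector \code{phase_coord_short}, \code{phase_coord_long}.
#' @export
phase_coordination_features <- function(rr) {
  out <- c(phase_coord_short = NA_real_, phase_coord_long = NA_real_)
  if (length(rr) < 50) return(out)
  s <- rr_signs(rr)
  n <- length(s)
  short_mask <- logical(n)
  long_mask <- logical(n)
  for (p in 3:8) {
    if (n < 2 * p) next
    # blockmatch[i]: s[i..i+p-1] equals s[i+p..i+2p-1]
    eq <- s[seq_len(n - p)] == s[(p + 1):n]
    nb <- n - 2 * p + 1
    run <- cumsum(eq)
    bm <- (run[p:(nb + p - 1)] - c(0, run[seq_len(nb - 1)])) == p
    # chains along stride p: a run of (k-1) consecutive blockmatches starting
    # at i means k back-to-back repetitions covering beats i .. i + k*p - 1
    for (off in seq_len(min(p, nb))) {
      chain <- seq(off, nb, by = p)
      r <- rle(bm[chain])
      pos <- cumsum(c(0, r$lengths[-length(r$lengths)]))
      for (j in seq_along(r$lengths)) {
        if (!r$values[j]) next
        i0 <- chain[pos[j] + 1]
        k <- r$lengths[j] + 1          # repetitions
        beats <- i0:min(n, i0 + k * p - 1)
        if (k == 2) short_mask[beats] <- TRUE else long_mask[beats] <- TRUE
      }
    }
  }
  # a beat in any >= 3 run is long-range; short-range only if never in one
  short_mask <- short_mask & !long_mask
  c(phase_coord_short = mean(short_mask), phase_coord_long = mean(long_mask))
}

#' Cardiorespiratory phase synchronization features (7 values)
#'
#' Windows of n consecutive difference signs (n in 6..9) matching the
#' two-cycle template (ceil(n/2) rises then floor(n/2) falls, one sign
#' alternation per respiratory half-cycle) mark those beats as n:2
#' synchronized; phase offsets of a locked rhythm are still caught because a
#' shifted periodic pattern contains the canonical window once per period.
#' Emitted: the four synchronized-beat fractions, the dominant
#' ratio (the n with the largest rate, ties to the smaller n), the mean
#' duration (s) of synchronized episodes across the union mask, and the
#' fraction of window time inside episodes lasting >= 30 s.
#'
#' @param seg List with \code{t}, \code{rr} of >= 60 valid beats.
#' @return Named numeric vector of 7 values.
#' @export
phase_sync_features <- function(seg) {
  nm <- c("sync_rate_6", "sync_rate_7", "sync_rate_8", "sync_rate_9",
          "sync_dominant_ratio", "sync_episode_mean_s", "sync_long_fraction")
  out <- stats::setNames(rep(NA_real_, 7), nm)
  rr <- seg$rr
  if (length(rr) < 60) return(out)
  s <- rr_signs(rr)
  ns <- length(s)
  union_mask <- logical(ns)
  rates <- numeric(4)
  for (k in seq_along(6:9)) {
    p <- (6:9)[k]
    template <- c(rep(1L, ceiling(p / 2)), rep(-1L, floor(p / 2)))
    mask <- logical(ns)
    if (ns >= p) {
      E <- stats::embed(s, p)[, p:1, drop = FALSE]  # rows = windows in order
      hit <- rowSums(E == matrix(template, nrow(E), p, byrow = TRUE)) == p
      for (i in which(hit)) mask[i:(i + p - 1)] <- TRUE
    }
    rates[k] <- mean(mask)
    union_mask <- union_mask | mask
  }
  out[1:4] <- rates
  out["sync_dominant_ratio"] <- (6:9)[which.max(rates)]
  r <- rle(union_mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ep <- which(r$values)
  if (length(ep)) {
    # episode duration: sum of the RR spanned by the synchronized signs
    durs <- vapply(ep, function(j) {
      sum(rr[(starts[j] + 1):(ends[j] + 1)]) / 1000
    }, numeric(1))
    out["sync_episode_mean_s"] <- mean(durs)
    total <- (max(seg$t) - min(seg$t))
    out["sync_long_fraction"] <-
      if (total > 0) min(1, sum(durs[durs >= 30]) / total) else 0
  } else {
    out["sync_episode_mean_s"] <- 0
    out["sync_long_fraction"] <- 0
  }
  out
}
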