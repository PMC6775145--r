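#' Extract the full 132-feature table of a recording
#'
#' Runs every feature family for every 30-s epoch using the family-specific
#' centred windows (270 s for most families, 330 s for windowed DFA, 510 s
#' for multiscale entropy). A family's features are missing for an epoch when
#' its window retains less than half of its nominal span at the recording
#' edge, when the window's valid-beat fraction falls below
#' \code{spec$min_valid_fraction}, or when the family's own minimum beat
#' count is not met. Missing values are left as NA (imputation is the model
#' module's job).
#'
#' @param series A cleaned [ibi_series()].
#' @param grid Epoch grid from [build_epoch_grid()].
#' @param spec A [window_spec()].
#' @return n_epochs x 132 numeric matrix, columns in registry order; the
#'   attribute \code{valid_fraction} carries the per-epoch default-window
#'   valid-beat fraction.
#' @export
extract_all <- function(series, grid, spec = window_spec()) {
  ctx <- make_slice_ctx(series, grid)
  extract_all_impl(series, grid, spec, ctx)
}

# Precomputed beat-index boundaries at the 30-s and 10-s grids. Every window
# edge used by extract_all is a multiple of 30 s (epoch centres are 30e + 15
# and all window half-lengths are odd multiples of 15), and arousal steps lie
# on the 10-s grid, so slicing becomes a table lookup instead of a
# findInterval scan over the whole night.
make_slice_ctx <- function(series, grid) {
  t_all <- series$beat_times_s
  valid <- series$valid
  tv <- t_all[valid]
  hr <- 60000 / series$rr_ms[valid]
  k30 <- 0:(grid$n_epochs + 9L)
  k10 <- 0:((grid$n_epochs * 30L + 300L) %/% 10L)
  list(tv = tv, rrv = series$rr_ms[valid],
       b30_all = findInterval(k30 * 30, t_all, left.open = TRUE),
       b30_val = findInterval(k30 * 30, tv, left.open = TRUE),
       b10_val = findInterval(k10 * 10, tv, left.open = TRUE),
       cs_hr = c(0, cumsum(hr)), cs_hr2 = c(0, cumsum(hr^2)))
}

# fast equivalent of window_slice for edges on the 30-s grid
slice_fast <- function(ctx, series, grid, epoch, window_len_s) {
  center <- 30 * epoch + 15
  lo <- max(center - window_len_s / 2, 0)
  hi <- min(center + window_len_s / 2, series$duration_s)
  if (lo %% 30 != 0 || hi %% 30 != 0 ||
      hi / 30 + 1 > length(ctx$b30_all))
    return(window_slice(series, grid, epoch, window_len_s))
  p1 <- lo / 30 + 1L; p2 <- hi / 30 + 1L
  i1a <- ctx$b30_all[p1] + 1L; i2a <- ctx$b30_all[p2]
  i1v <- ctx$b30_val[p1] + 1L; i2v <- ctx$b30_val[p2]
  n_total <- max(0L, i2a - i1a + 1L)
  if (i2v >= i1v) {
    idx <- i1v:i2v
    list(t = ctx$tv[idx], rr = ctx$rrv[idx], n_total = n_total,
         valid_fraction = if (n_total) (i2v - i1v + 1L) / n_total else NA_real_,
         span_fraction = (hi - lo) / window_len_s)
  } else {
    list(t = numeric(0), rr = numeric(0), n_total = n_total,
         valid_fraction = if (n_total) 0 else NA_real_,
         span_fraction = (hi - lo) / window_len_s)
  }
}

# fast arousal features using the precomputed 10-s boundaries and HR cumsums
arousal_fast <- function(ctx, series, grid, epoch, window_len_s) {
  nm <- paste0("arousal_p_", c("max", "mean", "median", "min", "sd"))
  out <- stats::setNames(rep(NA_real_, 5), nm)
  center <- 30 * epoch + 15
  lo <- max(center - window_len_s / 2, 0)
  hi <- min(center + window_len_s / 2, series$duration_s)
  nb <- length(ctx$tv)
  rng <- function(a, b) {  # beats with a <= t < b; a, b on the 10-s grid
    i <- if (a <= 0) 1L else ctx$b10_val[a / 10 + 1L] + 1L
    j <- ctx$b10_val[min(b / 10 + 1L, length(ctx$b10_val))]
    n <- j - i + 1L
    if (n < 1L) return(c(0, NA, NA))
    s1 <- ctx$cs_hr[j + 1L] - ctx$cs_hr[i]
    s2 <- ctx$cs_hr2[j + 1L] - ctx$cs_hr2[i]
    mu <- s1 / n
    va <- if (n > 1) max(0, (s2 - n * mu^2) / (n - 1)) else NA_real_
    c(n, mu, sqrt(va))
  }
  if (lo %% 10 != 0) return(arousal_features(series, grid, epoch, window_len_s))
  starts <- seq(lo, hi - 10, by = 10)
  if (any(starts %% 10 != 0)) return(arousal_features(series, grid, epoch,
                                                      window_len_s))
  p <- vapply(starts, function(s0) {
    step <- rng(s0, s0 + 10)
    base <- rng(s0 - 120, s0)
    if (step[1] < 3 || base[1] < 30) return(NA_real_)
    if (!is.finite(base[3]) || base[3] == 0) return(NA_real_)
    stats::plogis(((step[2] - base[2]) / base[3] - 2) / 0.5)
  }, numeric(1))
  p <- p[!is.na(p)]
  if (length(p) < 5) return(out)
  out[] <- c(max(p), mean(p), stats::median(p), min(p), stats::sd(p))
  out
}

extract_all_impl <- function(series, grid, spec, ctx) {
  reg <- feature_registry()
  n_epochs <- grid$n_epochs
  out <- matrix(NA_real_, n_epochs, nrow(reg),
                dimnames = list(NULL, reg$name))
  vf <- rep(NA_real_, n_epochs)
  fam_cols <- split(seq_len(nrow(reg)),
                    factor(reg$family, levels = unique(reg$family)))
  usable <- function(seg) {
    seg$n_total > 0 && seg$span_fraction >= 0.5 &&
      !is.na(seg$valid_fraction) &&
      seg$valid_fraction >= spec$min_valid_fraction
  }
  for (e in seq_len(n_epochs) - 1L) {
    seg <- slice_fast(ctx, series, grid, e, spec$default_len_s)
    vf[e + 1L] <- seg$valid_fraction
    row <- e + 1L
    if (usable(seg)) {
      nb <- length(seg$rr)
      bv <- basic_variability_features(seg$rr)
      out[row, fam_cols$basic] <- bv[1:4]
      out[row, fam_cols$variability] <- bv[5:16]
      out[row, fam_cols$percentiles] <- percentile_features(seg$rr)
      if (nb >= 100) {
        seg330 <- slice_fast(ctx, series, grid, e, spec$wdfa_len_s)
        out[row, fam_cols$dfa] <- dfa_features(seg270 = seg, seg330 = seg330)
        out[row, fam_cols$higuchi] <- higuchi_fd(seg$rr)
        out[row, fam_cols$teager] <- teager_features(seg$rr)
      }
      if (nb >= 60) {
        sp <- spectral_features(seg)
        out[row, fam_cols$spectral] <- sp[1:4]
        out[row, fam_cols$spectral_adapted] <- sp[5:8]
        out[row, fam_cols$hf_pole] <- sp[9:12]
        out[row, fam_cols$phase_sync] <- phase_sync_features(seg)
        out[row, fam_cols$arousal] <-
          arousal_fast(ctx, series, grid, e, spec$default_len_s)
      }
      if (nb >= 50) {
        out[row, fam_cols$symbolic] <- symbolic_entropy(seg$rr)
        out[row, fam_cols$phase_coord] <- phase_coordination_features(seg$rr)
        out[row, fam_cols$visibility] <- visibility_features(seg)
      }
    }
    seg510 <- slice_fast(ctx, series, grid, e, spec$mse_len_s)
    if (usable(seg510) && length(seg510$rr) >= 200)
      out[row, fam_cols$mse] <- mse_features(seg510$rr)
  }
  attr(out, "valid_fraction") <- vf
  attr(out, "recording_id") <- series$recording_id
  out
}

#' Extract features for a set of RR files
#'
#' @param rr_paths Character vector of RR file paths.
#' @param dialect RR file dialect, see [read_rr_file()].
#' @param spec A [window_spec()].
#' @param clean Apply [clean_ibi()] before extraction.
#' @return Named list of feature matrices.
#' @export
extract_files <- function(rr_paths, dialect = "time_rr", spec = window_spec(),
                          clean = TRUE) {
  out <- lapply(rr_paths, function(p) {
    s <- read_rr_file(p, dialect)
    if (clean) s <- clean_ibi(s)
    extract_all(s, build_epoch_grid(s), spec)
  })
  names(out) <- vapply(rr_paths, function(p) sub("\\.[^.]*$", "", basename(p)),
                       character(1))
  out
}
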