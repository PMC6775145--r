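#' Sleep stage alphabet
#'
#' The fixed four-class stage alphabet and its column order, used everywhere a
#' stage axis appears (soft-label matrices, posteriors, confusion matrices).
#' Rechtschaffen & Kales stages S1/S2 map to \code{N1N2} and S3/S4 to
#' \code{N3}.
#'
#' @format Character vector \code{c("W", "R", "N1N2", "N3")}.
#' @export
STAGES <- c("W", "R", "N1N2", "N3")

# Window lengths (seconds) per feature family; odd multiples of 30 s so each
# window centres exactly on an epoch.
WIN_DEFAULT <- 270
WIN_WDFA <- 330
WIN_MSE <- 510

#' Window configuration for feature extraction
#'
#' @param default_len_s Window length (s) used by most families; centred on
#'   the epoch.
#' @param mse_len_s Window length (s) for multiscale sample entropy.
#' @param wdfa_len_s Window length (s) for windowed DFA.
#' @param min_valid_fraction Minimum fraction of valid beats a window must
#'   contain for its family's features to be computed.
#' @return A \code{window_spec} list.
#' @export
window_spec <- function(default_len_s = WIN_DEFAULT, mse_len_s = WIN_MSE,
                        wdfa_len_s = WIN_WDFA, min_valid_fraction = 0.8) {
  stopifnot(default_len_s > 0, mse_len_s > 0, wdfa_len_s > 0,
            min_valid_fraction >= 0, min_valid_fraction <= 1)
  if (any(c(default_len_s, mse_len_s, wdfa_len_s) %% 30 != 0) ||
      any((c(default_len_s, mse_len_s, wdfa_len_s) / 30) %% 2 != 1)) {
    stop("window lengths must be odd multiples of 30 s so they centre on an epoch")
  }
  structure(list(default_len_s = default_len_s, mse_len_s = mse_len_s,
                 wdfa_len_s = wdfa_len_s,
                 min_valid_fraction = min_valid_fraction),
            class = "window_spec")
}

#' Feature registry
#'
#' The fixed, ordered catalogue of the 132 per-epoch HRV features. Column
#' order of every feature table follows this registry; family counts are
#' (basic 4, variability 12, percentiles 28, dfa 6, spectral 4,
#' spectral_adapted 4, hf_pole 4, mse 20, symbolic 1, phase_coord 2,
#' phase_sync 7, higuchi 1, teager 21, arousal 5, visibility 13).
#'
#' @return A data.frame with columns \code{name}, \code{family},
#'   \code{window_s} (seconds of IBI data the feature looks at) and
#'   \code{units}.
#' @export
feature_registry <- function() {
  reg <- local({
    pcts <- c(5, 10, 25, 50, 75, 90, 95)
    rows <- list()
    add <- function(names, family, window_s, units) {
      rows[[length(rows) + 1L]] <<- data.frame(
        name = names, family = family, window_s = window_s, units = units,
        stringsAsFactors = FALSE)
    }
    add(c("rr_mean", "rr_median", "hr_mean", "hr_median"),
        "basic", WIN_DEFAULT, c("ms", "ms", "bpm", "bpm"))
    v <- c("sdnn", "rr_range", "pnn50", "rmssd", "sdsd", "mad")
    add(c(paste0(v, "_abs"), paste0(v, "_det")), "variability", WIN_DEFAULT,
        rep(c("ms", "ms", "pct", "ms", "ms", "ms"), 2))
    add(c(paste0("rr_abs_p", pcts), paste0("rr_det_p", pcts),
          paste0("hr_abs_p", pcts), paste0("hr_det_p", pcts)),
        "percentiles", WIN_DEFAULT,
        rep(c("ms", "bpm"), each = 14))
    add(c("dfa_alpha_all", "dfa_alpha_short", "dfa_alpha_long", "dfa_f16",
          "wdfa", "pdfa"),
        "dfa", c(rep(WIN_DEFAULT, 4), WIN_WDFA, WIN_DEFAULT),
        c("", "", "", "ms", "", ""))
    add(c("ln_vlf", "ln_lf", "ln_hf", "lf_hf_ratio"),
        "spectral", WIN_DEFAULT, c("ln_ms2", "ln_ms2", "ln_ms2", ""))
    add(c("adapt_ln_vlf", "adapt_ln_lf", "adapt_ln_hf", "adapt_lf_hf_ratio"),
        "spectral_adapted", WIN_DEFAULT, c("ln_ms2", "ln_ms2", "ln_ms2", ""))
    add(c("resp_freq", "resp_power", "hf_pole_phase", "hf_pole_modulus"),
        "hf_pole", WIN_DEFAULT, c("Hz", "ln_ms2", "rad", ""))
    add(c(paste0("mse_m1_s", 1:10), paste0("mse_m2_s", 1:10)),
        "mse", WIN_MSE, "nats")
    add("symbolic_sampen", "symbolic", WIN_DEFAULT, "nats")
    add(c("phase_coord_short", "phase_coord_long"),
        "phase_coord", WIN_DEFAULT, "fraction")
    add(c("sync_rate_6", "sync_rate_7", "sync_rate_8", "sync_rate_9",
          "sync_dominant_ratio", "sync_episode_mean_s", "sync_long_fraction"),
        "phase_sync", WIN_DEFAULT,
        c(rep("fraction", 4), "", "s", "fraction"))
    add("higuchi_fd", "higuchi", WIN_DEFAULT, "")
    tg <- function(rep_) paste0("teager_", rep_, "_",
      c("trans_pct", "max_pct", "trans_iv_mean", "trans_iv_sd",
        "max_iv_mean", "max_iv_sd", "trans_amp_mean", "trans_amp_sd",
        "max_amp_mean", "max_amp_sd"))
    add(c("teager_energy_mean", tg("ibi"), tg("imf1")),
        "teager", WIN_DEFAULT,
        c("", rep(c("pct", "pct", "beats", "beats", "beats", "beats",
                    "", "", "", ""), 2)))
    add(paste0("arousal_p_", c("max", "mean", "median", "min", "sd")),
        "arousal", WIN_DEFAULT, "probability")
    add(c("nvg_assortativity", "nvg_clust_mean", "nvg_clust_sd",
          "nvg_degree_mean", "nvg_degree_sd", "nvg_powerlaw_slope",
          "nvg_low_degree_pct", "nvg_high_degree_pct",
          "dvg_degree_mean", "dvg_degree_sd", "dvg_powerlaw_slope",
          "dvg_low_degree_pct", "dvg_high_degree_pct"),
        "visibility", WIN_DEFAULT,
        c("", "", "", "", "", "", "pct", "pct", "", "", "", "pct", "pct"))
    do.call(rbind, rows)
  })
  stopifnot(nrow(reg) == 132L, !anyDuplicated(reg$name))
  reg
}

#' Per-family feature counts
#'
#' @return Named integer vector of registry column counts by family.
#' @export
feature_family_counts <- function() {
  reg <- feature_registry()
  tab <- table(factor(reg$family, levels = unique(reg$family)))
  stats::setNames(as.integer(tab), names(tab))
}
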