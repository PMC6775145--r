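#' Stage-conditional cardiac dynamics profiles
#'
#' Default per-stage parameters of the night simulator. Mean RR lengthens
#' with sleep depth (heart rate W > R > N1N2 > N3) and respiratory sinus
#' arrhythmia amplitude (HF) is largest in N3, reflecting growing
#' parasympathetic dominance with depth; Mayer-band (LF, ~0.1 Hz) amplitude
#' moves the opposite way.
#'
#' @return data.frame with one row per stage (W, R, N1N2, N3): mean_rr_ms,
#'   rr_sd_ms (white component), lf_amp_ms, lf_freq_hz, hf_amp_ms,
#'   resp_freq_hz, mean_bout_min, bout_shape.
#' @export
stage_profiles <- function() {
  data.frame(
    stage = STAGES,
    mean_rr_ms = c(850, 900, 1000, 1080),
    rr_sd_ms = c(30, 25, 20, 15),
    lf_amp_ms = c(40, 35, 25, 15),
    lf_freq_hz = 0.1,
    hf_amp_ms = c(10, 15, 30, 45),
    resp_freq_hz = 0.25,
    mean_bout_min = c(10, 11.5, 13, 6),
    bout_shape = 2,
    stringsAsFactors = FALSE)
}

# stage-to-stage transition matrix of the embedded chain (rows sum to 1);
# favours the W -> N1N2 -> N3 -> N1N2 -> R cycle with sparse awakenings
stage_transitions <- function() {
  m <- matrix(0, 4, 4, dimnames = list(STAGES, STAGES))
  m["W", "N1N2"] <- 1
  m["N1N2", c("W", "R", "N3")] <- c(0.25, 0.30, 0.45)
  m["N3", c("W", "N1N2")] <- c(0.15, 0.85)
  m["R", c("W", "N1N2")] <- c(0.30, 0.70)
  m
}

#' Simulation configuration
#'
#' Defaults are tuned so realized stage proportions land near a typical
#' middle-aged polysomnography cohort: about 67% N1/N2, 14% N3 and 18% REM
#' of total sleep time, with sleep efficiency around 81%.
#'
#' @param n_participants Number of simulated participants.
#' @param nights_per_participant Recordings per participant.
#' @param tib_hours Time in bed per night (hours).
#' @param n_annotators Simulated scorers per night.
#' @param annotator_error_rate Per-epoch relabeling probability per scorer.
#' @param seed Master seed; the whole cohort is a pure function of it.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(n_participants = 25L, nights_per_participant = 2L,
                       tib_hours = 8.0, n_annotators = 2L,
                       annotator_error_rate = 0.15, seed = 1L) {
  stopifnot(n_participants >= 1, nights_per_participant >= 1, tib_hours >= 1,
            n_annotators >= 1, annotator_error_rate >= 0,
            annotator_error_rate < 1)
  structure(list(n_participants = as.integer(n_participants),
                 nights_per_participant = as.integer(nights_per_participant),
                 tib_hours = tib_hours, n_annotators = as.integer(n_annotators),
                 annotator_error_rate = annotator_error_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a whole-night hypnogram
#'
#' Semi-Markov chain over (W, R, N1N2, N3): gamma-distributed bout durations
#' per stage (shape/mean from [stage_profiles()]) and the embedded
#' transition matrix of \code{stage_transitions()}; the night starts in W.
#'
#' @param config A [sim_config()].
#' @param seed Night-level seed.
#' @return Character stage vector of length \code{tib_hours * 120}.
#' @export
simulate_hypnogram <- function(config = sim_config(), seed = config$seed) {
  prof <- stage_profiles()
  trans <- stage_transitions()
  n_epochs <- round(config$tib_hours * 120)
  withr_seed(seed, {
    stages <- character(0)
    cur <- "W"
    while (length(stages) < n_epochs) {
      i <- match(cur, STAGES)
      dur_min <- stats::rgamma(1, shape = prof$bout_shape[i],
                               scale = prof$mean_bout_min[i] /
                                 prof$bout_shape[i])
      n_ep <- max(1L, round(dur_min * 2))
      stages <- c(stages, rep(cur, n_ep))
      cur <- sample(STAGES, 1, prob = trans[cur, ])
    }
    stages[seq_len(n_epochs)]
  })
}

#' Simulate an IBI series conditioned on a hypnogram
#'
#' An instantaneous RR signal is built on a 0.25-s grid as the stage's mean
#' RR plus Mayer-band and respiratory sinusoids plus white noise, with
#' stage-parameter steps smoothed over 15 s. Beat times are generated by
#' integral pulse frequency modulation: a beat fires whenever the integral
#' of the instantaneous rate crosses the next integer.
#'
#' @param stages Character stage vector (one per 30-s epoch).
#' @param profiles [stage_profiles()]-shaped data.frame.
#' @param seed RNG seed.
#' @param recording_id Identifier for the returned series.
#' @return An [ibi_series()].
#' @export
simulate_ibi <- function(stages, profiles = stage_profiles(),
                         seed = 1L, recording_id = "sim") {
  dt <- 0.25
  duration <- length(stages) * 30
  tgrid <- seq(0, duration - dt, by = dt)
  si <- match(stages, profiles$stage)
  gi <- si[pmin(length(stages), floor(tgrid / 30) + 1L)]
  smooth15 <- function(x) {
    k <- round(15 / dt)
    stats::filter(x, rep(1 / k, k), sides = 2) |>
      (\(f) ifelse(is.na(f), x, f))()
  }
  mean_rr <- smooth15(profiles$mean_rr_ms[gi])
  lf_amp <- smooth15(profiles$lf_amp_ms[gi])
  hf_amp <- smooth15(profiles$hf_amp_ms[gi])
  sd_rr <- smooth15(profiles$rr_sd_ms[gi])
  withr_seed(seed, {
    phi1 <- stats::runif(1, 0, 2 * pi)
    phi2 <- stats::runif(1, 0, 2 * pi)
    noise <- stats::rnorm(length(tgrid))
    rr_ms <- mean_rr +
      lf_amp * sin(2 * pi * profiles$lf_freq_hz[1] * tgrid + phi1) +
      hf_amp * sin(2 * pi * profiles$resp_freq_hz[1] * tgrid + phi2) +
      sd_rr * noise
    rr_ms <- pmax(rr_ms, 300)
    # IPFM: beat when the integrated instantaneous rate crosses an integer
    phase <- cumsum(dt / (rr_ms / 1000))
    nbeats <- floor(phase[length(phase)])
    k <- seq_len(nbeats)
    idx <- findInterval(k, phase)  # phase[idx] < k <= phase[idx+1]
    frac <- (k - phase[idx]) / (phase[pmin(idx + 1L, length(phase))] - phase[idx])
    beat_t <- tgrid[idx] + dt * (1 + pmin(pmax(frac, 0), 1))
    beat_t <- beat_t[beat_t <= duration]
    rr_out <- c(beat_t[1] * 1000, diff(beat_t) * 1000)
    ibi_series(beat_t, rr_out, recording_id = recording_id,
               duration_s = duration)
  })
}

#' Simulate multiple annotators over a hypnogram
#'
#' Each annotator independently keeps the true stage with probability
#' \code{1 - error_rate} and otherwise draws from an adjacent-stage confusion
#' kernel (W is confused mostly with N1N2; N1N2 with W, N3 and R; N3 and R
#' mostly with N1N2).
#'
#' @param stages True hypnogram.
#' @param n_annotators Number of scorers.
#' @param error_rate Per-epoch relabeling probability.
#' @param seed RNG seed.
#' @return n_epochs x 4 soft-label matrix (annotator fractions, columns
#'   [STAGES]).
#' @export
simulate_annotators <- function(stages, n_annotators = 2L, error_rate = 0.15,
                                seed = 1L) {
  conf <- matrix(c(0, 0.10, 0.80, 0.10,
                   0.10, 0, 0.80, 0.10,
                   1 / 3, 1 / 3, 0, 1 / 3,
                   0.10, 0.10, 0.80, 0),
                 4, 4, byrow = TRUE, dimnames = list(STAGES, STAGES))
  n <- length(stages)
  withr_seed(seed, {
    labels <- matrix(rep(stages, n_annotators), n, n_annotators)
    for (a in seq_len(n_annotators)) {
      err <- stats::runif(n) < error_rate
      for (i in which(err))
        labels[i, a] <- sample(STAGES, 1, prob = conf[stages[i], ])
    }
    frac <- t(apply(labels, 1, function(r)
      tabulate(match(r, STAGES), nbins = 4L) / n_annotators))
    colnames(frac) <- STAGES
    attr(frac, "annotator_labels") <- labels
    frac
  })
}

#' Generate a full synthetic cohort on disk
#'
#' Writes per-night RR files (\code{time_rr} dialect), hypnogram CSVs with
#' one column per simulated annotator, a metadata CSV (randomized age, sex,
#' BMI and clinical-group labels) and a manifest. Byte-identical given the
#' same configuration and seed.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created).
#' @return The manifest data.frame, invisibly written to
#'   \code{manifest.csv}.
#' @export
make_cohort <- function(config = sim_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prof <- stage_profiles()
  groups <- c("healthy", "apnea", "insomnia", "parkinson", "plmd")
  gprob <- c(0.66, 0.17, 0.09, 0.05, 0.03)
  meta <- withr_seed(config$seed, {
    data.frame(
      participant_id = sprintf("P%03d", seq_len(config$n_participants)),
      age = round(pmin(pmax(stats::rnorm(config$n_participants, 51.5, 17.3),
                            20), 95), 1),
      sex = sample(c("M", "F"), config$n_participants, replace = TRUE),
      bmi = round(pmin(pmax(stats::rnorm(config$n_participants, 25.6, 4.5),
                            16.5), 43.3), 1),
      group = sample(groups, config$n_participants, replace = TRUE,
                     prob = gprob),
      stringsAsFactors = FALSE)
  })
  rows <- list()
  for (p in seq_len(config$n_participants)) {
    for (nn in seq_len(config$nights_per_participant)) {
      rid <- sprintf("%s_n%d", meta$participant_id[p], nn)
      night_seed <- (config$seed * 10007L + p * 131L + nn) %% .Machine$integer.max
      stages <- simulate_hypnogram(config, seed = night_seed)
      series <- simulate_ibi(stages, prof, seed = night_seed + 1L,
                             recording_id = rid)
      frac <- simulate_annotators(stages, config$n_annotators,
                                  config$annotator_error_rate,
                                  seed = night_seed + 2L)
      rr_path <- file.path(out_dir, paste0(rid, "_rr.csv"))
      writeLines(c("# beat_time_s,rr_ms",
                   sprintf("%.6f,%.6f", series$beat_times_s, series$rr_ms)),
                 rr_path)
      hyp_path <- file.path(out_dir, paste0(rid, "_hypnogram.csv"))
      labs <- attr(frac, "annotator_labels")
      colnames(labs) <- paste0("annotator_", seq_len(ncol(labs)))
      utils::write.csv(cbind(data.frame(epoch = seq_along(stages) - 1L),
                             as.data.frame(labs)),
                       hyp_path, row.names = FALSE, quote = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        recording_id = rid, participant_id = meta$participant_id[p],
        rr_file = basename(rr_path), hypnogram_file = basename(hyp_path),
        night_seed = night_seed, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  meta_out <- merge(manifest[c("recording_id", "participant_id")], meta,
                    by = "participant_id")
  meta_out <- meta_out[order(meta_out$recording_id),
                       c("recording_id", "participant_id", "age", "sex",
                         "bmi", "group")]
  utils::write.csv(meta_out, file.path(out_dir, "metadata.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest$seed <- config$seed
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
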