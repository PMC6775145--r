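#' Desk-scale held-out staging benchmark
#'
#' Runs the full pipeline at a size suited to a single CPU: simulate a
#' default synthetic cohort, extract the 132-feature table for every night,
#' train a reduced sequence model (1 bidirectional LSTM layer, 16 units per
#' direction by default) on the training participants' nights with
#' soft-label supervision, and score the held-out participants' nights
#' against their true hypnograms.
#'
#' @param n_participants Cohort size (2 nights each).
#' @param train_participants Number of participants whose nights form the
#'   training set; the rest are held out.
#' @param units,layers Reduced model size.
#' @param tib_hours Night length (hours).
#' @param max_passes,patience Training schedule.
#' @param seed Master seed for simulation, initialization and training.
#' @param verbose Print progress.
#' @return List with \code{mean_kappa}, \code{mean_accuracy_pct},
#'   \code{per_night} (data.frame of held-out night metrics), and the
#'   trained \code{model}.
#' @export
holdout_benchmark <- function(n_participants = 25L, train_participants = 20L,
                              units = 16L, layers = 1L, tib_hours = 8,
                              max_passes = 120L, patience = 20L, seed = 1L,
                              verbose = FALSE) {
  stopifnot(train_participants < n_participants)
  cfg <- sim_config(n_participants = n_participants, tib_hours = tib_hours,
                    seed = seed)
  prof <- stage_profiles()
  tables <- list(); labels <- list(); refs <- list(); pid <- character(0)
  for (p in seq_len(n_participants)) {
    for (nn in 1:2) {
      ns <- (seed * 10007L + p * 131L + nn) %% .Machine$integer.max
      stages <- simulate_hypnogram(cfg, seed = ns)
      series <- clean_ibi(simulate_ibi(stages, prof, seed = ns + 1L))
      i <- length(tables) + 1L
      tables[[i]] <- extract_all(series, build_epoch_grid(series))
      labels[[i]] <- simulate_annotators(stages, cfg$n_annotators,
                                         cfg$annotator_error_rate,
                                         seed = ns + 2L)
      attr(labels[[i]], "annotator_labels") <- NULL
      refs[[i]] <- stages
      pid <- c(pid, sprintf("P%03d", p))
      if (verbose) message("night ", i, " extracted")
    }
  }
  train_idx <- which(pid %in% sprintf("P%03d", seq_len(train_participants)))
  test_idx <- setdiff(seq_along(tables), train_idx)
  mcfg <- model_config(n_lstm_layers = layers,
                       lstm_units_per_direction = units, seed = seed)
  tcfg <- train_config(patience = patience, max_passes = max_passes,
                       seed = seed)
  model <- train_stager(build_model(mcfg), tables[train_idx],
                        labels[train_idx], pid[train_idx], tcfg,
                        verbose = verbose)
  per_night <- do.call(rbind, lapply(test_idx, function(i) {
    pr <- predict(model, tables[[i]])
    cbind(data.frame(night = i, participant_id = pid[i]),
          night_metrics(refs[[i]], pr$stages))
  }))
  list(mean_kappa = mean(per_night$kappa),
       mean_accuracy_pct = mean(per_night$accuracy_pct),
       per_night = per_night, model = model)
}
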