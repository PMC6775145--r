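#' Model architecture configuration
#'
#' The default architecture is a 5-layer network: a 32-unit sigmoid
#' perceptron layer, three bidirectional LSTM layers (64 cells per direction,
#' forward and backward outputs concatenated between layers), a 32-unit
#' sigmoid perceptron layer and a 4-class softmax output. Dropout is applied
#' during training only: 20% on the input features, 50% on LSTM outputs and
#' 50% on the recurrent connections.
#'
#' @param input_dim Number of input features per epoch.
#' @param pre_dense_units,post_dense_units Sizes of the sigmoid perceptron
#'   layers before and after the LSTM stack.
#' @param n_lstm_layers Number of bidirectional LSTM layers (1..6).
#' @param lstm_units_per_direction LSTM cells per direction (16, 32, 64, 128).
#' @param n_classes Output classes.
#' @param dropout_input,dropout_output,dropout_recurrent Dropout rates.
#' @param learning_rate RMSprop learning rate.
#' @param seed Seed for weight initialization.
#' @return A \code{model_config} list.
#' @export
model_config <- function(input_dim = 132L, pre_dense_units = 32L,
                         n_lstm_layers = 3L, lstm_units_per_direction = 64L,
                         post_dense_units = 32L, n_classes = 4L,
                         dropout_input = 0.2, dropout_output = 0.5,
                         dropout_recurrent = 0.5, learning_rate = 1e-3,
                         seed = 1L) {
  stopifnot(n_lstm_layers %in% 1:6,
            lstm_units_per_direction %in% c(16L, 32L, 64L, 128L),
            dropout_input >= 0, dropout_input < 1,
            dropout_output >= 0, dropout_output < 1,
            dropout_recurrent >= 0, dropout_recurrent < 1,
            input_dim > 0, n_classes > 1)
  structure(list(input_dim = as.integer(input_dim),
                 pre_dense_units = as.integer(pre_dense_units),
                 n_lstm_layers = as.integer(n_lstm_layers),
                 lstm_units_per_direction = as.integer(lstm_units_per_direction),
                 post_dense_units = as.integer(post_dense_units),
                 n_classes = as.integer(n_classes),
                 dropout_input = dropout_input,
                 dropout_output = dropout_output,
                 dropout_recurrent = dropout_recurrent,
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "model_config")
}

#' Training protocol configuration
#'
#' @param k_folds Cross-validation folds; folds partition participants, never
#'   recordings.
#' @param patience Early-stopping patience in passes over the training data.
#' @param max_passes Hard cap on training passes.
#' @param batch_nights Nights per gradient update.
#' @param inner_val_fraction Fraction of training participants held out to
#'   monitor early stopping (see [train_stager()] for the paper_faithful
#'   alternative).
#' @param paper_faithful If TRUE, early stopping is monitored on the test
#'   fold itself (the protocol the source method describes, which leaks test
#'   information); default FALSE uses the inner validation split.
#' @param seed RNG seed for shuffling and dropout.
#' @return A \code{train_config} list.
#' @export
train_config <- function(k_folds = 4L, patience = 100L, max_passes = 500L,
                         batch_nights = 8L, inner_val_fraction = 0.1,
                         paper_faithful = FALSE, seed = 1L) {
  stopifnot(k_folds >= 2, patience >= 1, max_passes >= 1, batch_nights >= 1,
            inner_val_fraction > 0, inner_val_fraction < 1)
  structure(list(k_folds = as.integer(k_folds), patience = as.integer(patience),
                 max_passes = as.integer(max_passes),
                 batch_nights = as.integer(batch_nights),
                 inner_val_fraction = inner_val_fraction,
                 paper_faithful = isTRUE(paper_faithful),
                 seed = as.integer(seed)),
            class = "train_config")
}

# Weight shapes in storage order; gate columns within 4H are (i, f, g, o).
weight_shapes <- function(config) {
  D <- config$input_dim; P <- config$pre_dense_units
  H <- config$lstm_units_per_direction; L <- config$n_lstm_layers
  Pd <- config$post_dense_units; K <- config$n_classes
  sh <- list(W0 = c(D, P), b0 = c(1, P))
  input <- P
  for (l in seq_len(L)) {
    sh[[paste0("Wf", l)]] <- c(input, 4 * H)
    sh[[paste0("Uf", l)]] <- c(H, 4 * H)
    sh[[paste0("bf", l)]] <- c(1, 4 * H)
    sh[[paste0("Wb", l)]] <- c(input, 4 * H)
    sh[[paste0("Ub", l)]] <- c(H, 4 * H)
    sh[[paste0("bb", l)]] <- c(1, 4 * H)
    input <- 2 * H
  }
  sh$Wd <- c(input, Pd); sh$bd <- c(1, Pd)
  sh$Wo <- c(Pd, K); sh$bo <- c(1, K)
  sh
}

#' Count trainable parameters
#'
#' Exact closed-form count of all weights and biases of the architecture
#' described by a [model_config()]. For the default configuration this is
#' 255,812, i.e. 2.6e5 at two significant figures.
#'
#' @param config A [model_config()].
#' @return Integer parameter count.
#' @export
count_parameters <- function(config) {
  sum(vapply(weight_shapes(config), prod, numeric(1)))
}

#' Build (initialize) the sequence classifier
#'
#' Glorot-uniform weight initialization from the seeded generator; LSTM
#' forget-gate biases start at 1, all other biases at 0.
#'
#' @param config A [model_config()].
#' @return An \code{hrv_stager} model handle holding weights and config.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  H <- config$lstm_units_per_direction
  shapes <- weight_shapes(config)
  weights <- withr_seed(config$seed, {
    lapply(names(shapes), function(nm) {
      d <- shapes[[nm]]
      if (startsWith(nm, "b")) {
        m <- matrix(0, d[1], d[2])
        if (grepl("^b[fb]\\d+$", nm)) m[1, (H + 1):(2 * H)] <- 1
        m
      } else {
        lim <- sqrt(6 / (d[1] + d[2]))
        matrix(stats::runif(prod(d), -lim, lim), d[1], d[2])
      }
    })
  })
  names(weights) <- names(shapes)
  structure(list(weights = weights, config = config,
                 feature_names = NULL, impute_medians = NULL,
                 scale_mean = NULL, scale_sd = NULL, history = NULL),
            class = "hrv_stager")
}

# evaluate expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' @export
print.hrv_stager <- function(x, ...) {
  cat(sprintf(
    "<hrv_stager: %d BiLSTM layer(s) x %d units/direction, %s parameters%s>\n",
    x$config$n_lstm_layers, x$config$lstm_units_per_direction,
    format(count_parameters(x$config), big.mark = ","),
    if (is.null(x$impute_medians)) ", untrained" else ", trained"))
  invisible(x)
}

#' Soft-label categorical cross-entropy
#'
#' \eqn{H = -(1/N) \sum_i \sum_c P(Y_i = C_c) \log \hat P(Y_i = C_c)}
#' with natural logarithm; rows of \code{labels} are annotator fractions and
#' rows of \code{preds} softmax posteriors.
#'
#' @param labels n x 4 soft-label matrix.
#' @param preds n x 4 posterior matrix; must be strictly positive wherever
#'   the label fraction is nonzero (terms with zero label contribute zero).
#' @return Scalar loss (nats).
#' @export
soft_cross_entropy <- function(labels, preds) {
  stopifnot(identical(dim(labels), dim(preds)))
  if (any(preds < 0) || any(preds[labels > 0] <= 0))
    stop("predicted probabilities must be strictly positive")
  terms <- labels * ifelse(labels > 0, log(pmax(preds, .Machine$double.xmin)),
                           0)
  -sum(terms) / nrow(labels)
}

#' Assign participants to cross-validation folds
#'
#' Participants are shuffled with the seed and dealt round-robin to k folds,
#' so all recordings of a participant share a fold.
#'
#' @param meta data.frame with \code{recording_id} and \code{participant_id}.
#' @param k Number of folds.
#' @param seed Shuffle seed.
#' @return Integer fold (1..k) per row of \code{meta}.
#' @export
assign_folds <- function(meta, k = 4L, seed = 1L) {
  stopifnot(k >= 2)
  participants <- unique(meta$participant_id)
  if (length(participants) < k) stop("fewer participants than folds")
  shuffled <- withr_seed(seed, sample(participants))
  pf <- stats::setNames(rep(seq_len(k), length.out = length(shuffled)),
                        shuffled)
  unname(pf[as.character(meta$participant_id)])
}

# Fit imputation medians and z-scoring statistics on a list of feature
# matrices (training portion only).
fit_standardizer <- function(tables) {
  all <- do.call(rbind, tables)
  med <- apply(all, 2, stats::median, na.rm = TRUE)
  med[is.na(med)] <- 0
  imputed <- all
  for (j in seq_len(ncol(all))) imputed[is.na(all[, j]), j] <- med[j]
  mu <- colMeans(imputed)
  sd <- apply(imputed, 2, stats::sd)
  sd[!is.finite(sd) | sd < 1e-12] <- 1
  list(impute_medians = med, scale_mean = mu, scale_sd = sd)
}

apply_standardizer <- function(table, std) {
  for (j in seq_len(ncol(table)))
    table[is.na(table[, j]), j] <- std$impute_medians[j]
  sweep(sweep(table, 2, std$scale_mean), 2, std$scale_sd, "/")
}

#' Train the sequence classifier
#'
#' Minimizes the soft-label cross-entropy with RMSprop over whole-night
#' sequences (gradient accumulation over \code{batch_nights} nights per
#' update), with early stopping on a validation set. Features are imputed
#' with per-feature training-set medians and z-scored with training-set
#' statistics before training; the fitted statistics are stored on the model
#' and re-applied at prediction time.
#'
#' @param model An [build_model()] handle.
#' @param tables List of per-night feature matrices (n_epochs x 132).
#' @param soft_labels List of per-night soft-label matrices (n_epochs x 4).
#' @param participant_id Participant per night; used to split off the inner
#'   validation participants.
#' @param tconfig A [train_config()].
#' @param val_nights Optional explicit validation night indices (used by
#'   \code{paper_faithful} cross-validation); overrides the inner split.
#' @param verbose Print progress.
#' @return The trained model with \code{history} (data.frame pass,
#'   train_loss, val_loss).
#' @export
train_stager <- function(model, tables, soft_labels, participant_id,
                         tconfig = train_config(), val_nights = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(model, "hrv_stager"), length(tables) == length(soft_labels),
            length(tables) == length(participant_id))
  if (!length(tables)) stop("empty training set")
  cfg <- model$config
  for (tb in tables)
    if (ncol(tb) != cfg$input_dim) stop("feature column count mismatch")
  for (sl in soft_labels) check_soft_labels(sl)

  if (is.null(val_nights)) {
    parts <- unique(participant_id)
    n_val <- max(1L, round(tconfig$inner_val_fraction * length(parts)))
    if (n_val >= length(parts)) stop("too few participants for an inner split")
    val_parts <- withr_seed(tconfig$seed, sample(parts, n_val))
    val_nights <- which(participant_id %in% val_parts)
    train_nights <- setdiff(seq_along(tables), val_nights)
  } else {
    train_nights <- setdiff(seq_along(tables), val_nights)
  }
  std <- fit_standardizer(tables[train_nights])
  Xs <- lapply(tables, apply_standardizer, std = std)
  fit <- lstm_train_cpp(model$weights, Xs, soft_labels,
                        train_idx = as.integer(train_nights - 1L),
                        val_idx = as.integer(val_nights - 1L),
                        n_layers = cfg$n_lstm_layers,
                        units = cfg$lstm_units_per_direction,
                        lr = cfg$learning_rate, rho = 0.9, eps = 1e-7,
                        max_passes = tconfig$max_passes,
                        patience = tconfig$patience,
                        batch_size = tconfig$batch_nights,
                        p_in = cfg$dropout_input, p_out = cfg$dropout_output,
                        p_rec = cfg$dropout_recurrent, clipnorm = 5,
                        seed = tconfig$seed, verbose = verbose)
  model$weights <- fit$weights
  model$impute_medians <- std$impute_medians
  model$scale_mean <- std$scale_mean
  model$scale_sd <- std$scale_sd
  model$history <- data.frame(pass = seq_along(fit$train_loss),
                              train_loss = fit$train_loss,
                              val_loss = fit$val_loss)
  attr(model$history, "best_pass") <- fit$best_pass
  model
}

#' Predict sleep stages for one night
#'
#' @param object Trained \code{hrv_stager}.
#' @param table Feature matrix (n_epochs x 132) with registry column names.
#' @param ... Unused.
#' @return List with \code{posteriors} (n_epochs x 4, columns [STAGES]) and
#'   \code{stages} (argmax hypnogram, ties to the earlier fixed column).
#' @export
predict.hrv_stager <- function(object, table, ...) {
  cfg <- object$config
  if (ncol(table) != cfg$input_dim) stop("feature column count mismatch")
  if (!is.null(object$feature_names) && !is.null(colnames(table)) &&
      !identical(colnames(table), object$feature_names))
    stop("feature columns do not match the registry order the model was trained on")
  if (is.null(object$impute_medians)) stop("model has not been trained")
  X <- apply_standardizer(table,
                          list(impute_medians = object$impute_medians,
                               scale_mean = object$scale_mean,
                               scale_sd = object$scale_sd))
  P <- lstm_forward_cpp(object$weights, X, cfg$n_lstm_layers,
                        cfg$lstm_units_per_direction)
  colnames(P) <- STAGES
  list(posteriors = P, stages = soft_to_stages(P))
}

#' Participant-level k-fold cross-validation
#'
#' Every night is predicted exactly once, by the model whose training folds
#' never contained that night's participant. Standardization statistics are
#' fitted per fold on the training portion only.
#'
#' @param tables,soft_labels Per-night feature matrices and soft labels.
#' @param meta data.frame with one row per night (\code{recording_id},
#'   \code{participant_id}).
#' @param mconfig A [model_config()].
#' @param tconfig A [train_config()].
#' @param verbose Print fold progress.
#' @return List with \code{predictions} (per night: posteriors + stages),
#'   \code{fold} assignment, and \code{models} (one per fold).
#' @export
cross_validate <- function(tables, soft_labels, meta, mconfig = model_config(),
                           tconfig = train_config(), verbose = FALSE) {
  stopifnot(nrow(meta) == length(tables))
  fold <- assign_folds(meta, tconfig$k_folds, tconfig$seed)
  predictions <- vector("list", length(tables))
  models <- vector("list", tconfig$k_folds)
  for (f in seq_len(tconfig$k_folds)) {
    test_nights <- which(fold == f)
    train_nights <- which(fold != f)
    if (verbose) message("fold ", f, ": ", length(train_nights), " train / ",
                         length(test_nights), " test nights")
    model <- build_model(mconfig)
    model$feature_names <- colnames(tables[[1]])
    if (tconfig$paper_faithful) {
      # the source protocol: early stopping monitored on the test fold
      model <- train_stager(model, tables, soft_labels, meta$participant_id,
                            tconfig, val_nights = test_nights,
                            verbose = verbose)
    } else {
      model <- train_stager(model, tables[train_nights],
                            soft_labels[train_nights],
                            meta$participant_id[train_nights], tconfig,
                            verbose = verbose)
    }
    for (i in test_nights) predictions[[i]] <- predict(model, tables[[i]])
    models[[f]] <- model
  }
  list(predictions = predictions, fold = fold, models = models)
}

#' Save a trained model checkpoint
#'
#' Single-file archive holding the weights, architecture configuration,
#' imputation medians and scaling statistics, a hash of the feature registry
#' the model was trained against, and a format version.
#'
#' @param model A trained \code{hrv_stager}.
#' @param path Destination file.
#' @export
save_stager <- function(model, path) {
  stopifnot(inherits(model, "hrv_stager"))
  reg <- feature_registry()
  chk <- list(format_version = 1L,
              registry_hash = sum(utf8ToInt(paste(reg$name, collapse = ","))),
              weights = model$weights, config = model$config,
              feature_names = model$feature_names,
              impute_medians = model$impute_medians,
              scale_mean = model$scale_mean, scale_sd = model$scale_sd,
              history = model$history)
  saveRDS(chk, path)
  invisible(path)
}

#' Load a model checkpoint written by [save_stager()]
#'
#' @param path Checkpoint file.
#' @return An \code{hrv_stager} model.
#' @export
load_stager <- function(path) {
  chk <- readRDS(path)
  if (!identical(chk$format_version, 1L))
    stop("unsupported checkpoint format version")
  reg <- feature_registry()
  if (!identical(chk$registry_hash,
                 sum(utf8ToInt(paste(reg$name, collapse = ",")))))
    stop("checkpoint was written against a different feature registry")
  structure(list(weights = chk$weights, config = chk$config,
                 feature_names = chk$feature_names,
                 impute_medians = chk$impute_medians,
                 scale_mean = chk$scale_mean, scale_sd = chk$scale_sd,
                 history = chk$history),
            class = "hrv_stager")
}
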