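#' Construct an inter-beat-interval series
#'
#' @param beat_times_s Numeric vector of beat times in seconds from recording
#'   start, strictly increasing.
#' @param rr_ms RR interval (ms) ending at the corresponding beat; all > 0.
#' @param valid Logical per beat; \code{FALSE} marks artifact/ectopic beats.
#' @param recording_id Opaque identifier.
#' @param duration_s Total recording span; defaults to the last beat time.
#' @return An \code{ibi_series} object.
#' @export
ibi_series <- function(beat_times_s, rr_ms, valid = rep(TRUE, length(rr_ms)),
                       recording_id = "recording", duration_s = NULL) {
  beat_times_s <- as.numeric(beat_times_s)
  rr_ms <- as.numeric(rr_ms)
  n <- length(beat_times_s)
  if (length(rr_ms) != n || length(valid) != n)
    stop("beat_times_s, rr_ms and valid must have equal length")
  if (n > 1 && any(diff(beat_times_s) <= 0))
    stop("beat_times_s must be strictly increasing")
  if (any(rr_ms <= 0)) stop("all rr_ms must be positive")
  if (is.null(duration_s)) duration_s <- if (n) beat_times_s[n] else 0
  if (n && duration_s < beat_times_s[n])
    stop("duration_s must cover the last beat")
  # interval/beat-time consistency for runs of consecutive valid beats
  if (n > 1) {
    ok_pair <- valid[-1] & valid[-n]
    dev <- abs(rr_ms[-1] / 1000 - diff(beat_times_s))
    if (any(ok_pair & dev > 1e-3 + 1e-9))
      stop("rr_ms inconsistent with beat time differences (> 1 ms)")
  }
  structure(list(beat_times_s = beat_times_s, rr_ms = rr_ms,
                 valid = as.logical(valid), recording_id = recording_id,
                 duration_s = as.numeric(duration_s)),
            class = "ibi_series")
}

#' @export
print.ibi_series <- function(x, ...) {
  cat(sprintf("<ibi_series '%s': %d beats, %.1f s, %.1f%% valid>\n",
              x$recording_id, length(x$rr_ms), x$duration_s,
              100 * mean(x$valid)))
  invisible(x)
}

#' Read an RR-interval file
#'
#' Two plain-text dialects are supported. \code{rr_only}: one RR value (ms)
#' per line; beat times are reconstructed by cumulative sum with the first
#' beat anchored at \code{rr_ms[1] / 1000} seconds. \code{time_rr}: two
#' comma-separated columns, beat time (s) and RR (ms). Lines starting with
#' \code{#} are skipped.
#'
#' @param path File path.
#' @param dialect \code{"rr_only"} or \code{"time_rr"}.
#' @param recording_id Identifier stored on the series; defaults to the file
#'   base name.
#' @return An [ibi_series()] with all beats marked valid.
#' @export
read_rr_file <- function(path, dialect = c("time_rr", "rr_only"),
                         recording_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(recording_id))
    recording_id <- sub("\\.[^.]*$", "", basename(path))
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- raw[keep]
  lineno <- which(keep)
  if (!length(lines)) stop("no data lines in ", path)
  parts <- strsplit(lines, ",", fixed = TRUE)
  ncol_exp <- if (dialect == "rr_only") 1L else 2L
  vals <- matrix(NA_real_, length(lines), ncol_exp)
  for (i in seq_along(parts)) {
    p <- trimws(parts[[i]])
    if (length(p) != ncol_exp)
      stop(sprintf("line %d: expected %d column(s), got %d",
                   lineno[i], ncol_exp, length(p)))
    v <- suppressWarnings(as.numeric(p))
    if (anyNA(v))
      stop(sprintf("line %d: non-numeric token '%s'", lineno[i],
                   p[which(is.na(v))[1]]))
    vals[i, ] <- v
  }
  if (dialect == "rr_only") {
    rr <- vals[, 1]
    if (any(rr <= 0)) stop("rr_ms must be positive")
    t <- cumsum(rr) / 1000
  } else {
    t <- vals[, 1]
    rr <- vals[, 2]
    if (any(diff(t) <= 0)) stop("beat times must be strictly ascending")
    if (any(rr <= 0)) stop("rr_ms must be positive")
  }
  ibi_series(t, rr, recording_id = recording_id)
}

#' Mark artifactual beats in an IBI series
#'
#' A beat is marked invalid when its RR lies outside
#' \code{[rr_min_ms, rr_max_ms]} or deviates from the median of its 5 nearest
#' valid neighbours (by beat index, the beat itself excluded) by more than
#' \code{rel_jump} relative. Values are retained; only the validity mask
#' changes.
#'
#' @param series An [ibi_series()].
#' @param rr_min_ms,rr_max_ms Physiologic absolute bounds (ms).
#' @param rel_jump Maximum tolerated relative deviation from the local median.
#' @return The series with an updated \code{valid} mask; the attribute
#'   \code{valid_fraction} reports the surviving fraction.
#' @export
clean_ibi <- function(series, rr_min_ms = 300, rr_max_ms = 2000,
                      rel_jump = 0.3) {
  stopifnot(inherits(series, "ibi_series"))
  rr <- series$rr_ms
  n <- length(rr)
  if (!n) return(series)
  valid <- series$valid & rr >= rr_min_ms & rr <= rr_max_ms
  # relative-jump pass against the median of the 5 nearest valid beats
  # (nearest by beat index, the beat itself excluded)
  idx_valid <- which(valid)
  nv <- length(idx_valid)
  for (j in seq_len(nv)) {
    i <- idx_valid[j]
    lo <- max(1L, j - 5L); hi <- min(nv, j + 5L)
    others <- idx_valid[lo:hi]
    others <- others[others != i]
    if (length(others) < 2) next
    nb <- others[order(abs(others - i))][seq_len(min(5L, length(others)))]
    med <- stats::median(rr[nb])
    if (abs(rr[i] - med) > rel_jump * med) valid[i] <- FALSE
  }
  series$valid <- valid
  attr(series, "valid_fraction") <- mean(valid)
  series
}

#' Build the 30-second epoch grid of a recording
#'
#' Epochs are 0-indexed and half-open: epoch \code{e} covers
#' \code{[30e, 30e + 30)} seconds from recording start; a trailing partial
#' epoch is dropped.
#'
#' @param series An [ibi_series()] with \code{duration_s >= 30}.
#' @return An \code{epoch_grid} list with \code{epoch_len_s = 30} and
#'   \code{n_epochs}.
#' @export
build_epoch_grid <- function(series) {
  stopifnot(inherits(series, "ibi_series"))
  if (series$duration_s < 30) stop("recording shorter than one 30-s epoch")
  structure(list(epoch_len_s = 30, n_epochs = floor(series$duration_s / 30)),
            class = "epoch_grid")
}

#' Epoch index of each beat
#'
#' @param series An [ibi_series()].
#' @param grid An [build_epoch_grid()] grid.
#' @return 0-based epoch index per beat; \code{NA} for beats past the grid.
#' @export
beat_epochs <- function(series, grid) {
  e <- floor(series$beat_times_s / grid$epoch_len_s)
  e[e >= grid$n_epochs] <- NA_integer_
  as.integer(e)
}

#' Read a hypnogram file
#'
#' CSV with a column \code{epoch} (0-based, contiguous) and either one
#' \code{stage} column or columns \code{annotator_1 .. annotator_k}, values in
#' \code{W, R, N1N2, N3}. Returns both the per-epoch annotator-fraction
#' matrix (soft labels) and the consensus hypnogram: the per-row argmax with
#' ties broken by the fixed column order (W, R, N1N2, N3).
#'
#' @param path File path.
#' @return List with \code{stages} (character vector) and \code{fractions}
#'   (n_epochs x 4 matrix, columns [STAGES]).
#' @export
read_hypnogram <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!"epoch" %in% names(df)) stop("hypnogram needs an 'epoch' column")
  ann_cols <- if ("stage" %in% names(df)) "stage" else
    grep("^annotator_\\d+$", names(df), value = TRUE)
  if (!length(ann_cols)) stop("hypnogram needs 'stage' or annotator_* columns")
  df <- df[order(df$epoch), , drop = FALSE]
  if (!identical(as.integer(df$epoch), seq_len(nrow(df)) - 1L))
    stop("epoch column must be contiguous 0..n-1 with no gaps")
  labs <- as.matrix(df[, ann_cols, drop = FALSE])
  bad <- setdiff(unique(as.vector(labs)), STAGES)
  if (length(bad))
    stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  frac <- t(apply(labs, 1, function(r) {
    tabulate(match(r, STAGES), nbins = 4L) / length(r)
  }))
  colnames(frac) <- STAGES
  stages <- soft_to_stages(frac)
  list(stages = stages, fractions = frac)
}

#' Consensus stages from a soft-label matrix
#'
#' Per-row argmax; ties resolved in favour of the earlier column in the fixed
#' (W, R, N1N2, N3) order.
#'
#' @param fractions n x 4 matrix with rows summing to 1.
#' @return Character vector of stage labels.
#' @export
soft_to_stages <- function(fractions) {
  stopifnot(ncol(fractions) == 4)
  STAGES[apply(fractions, 1, which.max)]
}

#' Validate a soft-label matrix
#' @param fractions n x 4 numeric matrix.
#' @return Invisibly \code{TRUE}; errors when rows fail to sum to 1.
#' @export
check_soft_labels <- function(fractions) {
  stopifnot(is.matrix(fractions), ncol(fractions) == 4)
  if (any(fractions < -1e-12 | fractions > 1 + 1e-12))
    stop("soft label entries must lie in [0, 1]")
  if (any(abs(rowSums(fractions) - 1) > 1e-9))
    stop("soft label rows must sum to 1 within 1e-9")
  invisible(TRUE)
}

#' Write a per-epoch feature table to CSV
#'
#' Header is \code{epoch} followed by the 132 registry names in registry
#' order; missing values are written as empty cells. Values survive a write /
#' read round trip to within 1e-9.
#'
#' @param table Numeric matrix (n_epochs x 132) with registry column names.
#' @param path Output path.
#' @export
write_feature_table <- function(table, path) {
  reg <- feature_registry()
  stopifnot(is.matrix(table), identical(colnames(table), reg$name))
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.15g", x))
  lines <- c(paste(c("epoch", reg$name), collapse = ","),
             vapply(seq_len(nrow(table)), function(i) {
               paste(c(as.character(i - 1L), fmt(table[i, ])), collapse = ",")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path CSV path.
#' @return Numeric matrix with registry column names; empty cells become NA.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  reg <- feature_registry()
  if (!identical(names(df), c("epoch", reg$name)))
    stop("feature table header does not match the registry")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- NULL
  m
}

#' Read a recording metadata table
#'
#' CSV with columns recording_id, participant_id, age, sex, bmi, group.
#' @param path CSV path.
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("recording_id", "participant_id", "age", "sex", "bmi", "group")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  ok_age <- is.na(df$age) | df$age > 0
  ok_bmi <- is.na(df$bmi) | df$bmi > 0
  if (!all(ok_age) || !all(ok_bmi)) stop("age and bmi must be positive")
  df
}
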