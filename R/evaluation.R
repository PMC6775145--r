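#' Confusion matrix of two hypnograms
#'
#' Rows are the reference stage, columns the predicted stage, both in the
#' fixed (W, R, N1N2, N3) order.
#'
#' @param reference,predicted Character stage vectors of equal length.
#' @return 4 x 4 integer matrix.
#' @export
confusion <- function(reference, predicted) {
  if (length(reference) != length(predicted))
    stop("hypnogram lengths differ")
  table(factor(reference, levels = STAGES),
        factor(predicted, levels = STAGES))
}

#' Cohen's kappa of a confusion matrix
#'
#' \eqn{\kappa = (p_o - p_e) / (1 - p_e)} with observed agreement
#' \eqn{p_o = trace/total} and chance agreement
#' \eqn{p_e = \sum_c row_c col_c / total^2}. When \eqn{p_e = 1} the value is
#' 1 for perfect agreement and 0 otherwise (degenerate-marginal rule).
#'
#' @param cm Square count matrix.
#' @return Kappa in [-1, 1].
#' @export
cohen_kappa <- function(cm) {
  cm <- as.matrix(cm)
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  po <- sum(diag(cm)) / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (abs(1 - pe) < 1e-12) return(if (abs(po - 1) < 1e-12) 1 else 0)
  (po - pe) / (1 - pe)
}

# collapse a 4x4 matrix to stage-vs-rest 2x2
collapse_stage <- function(cm, stage) {
  i <- match(stage, STAGES)
  tp <- cm[i, i]
  fn <- sum(cm[i, -i])
  fp <- sum(cm[-i, i])
  tn <- sum(cm[-i, -i])
  matrix(c(tp, fn, fp, tn), 2, 2,
         dimnames = list(c("stage", "rest"), c("stage", "rest")))
}

#' Per-night agreement metrics
#'
#' Overall Cohen's kappa and accuracy (percent) on an epoch-per-epoch basis,
#' plus per-stage precision, recall, accuracy and kappa from the
#' stage-vs-rest 2x2 collapse. A stage absent from both reference and
#' prediction yields missing per-stage values.
#'
#' @param reference,predicted Character stage vectors of equal length.
#' @return A one-row data.frame (kappa, accuracy_pct, then
#'   \code{<stage>_{precision,recall,accuracy,kappa}} for the 4 stages).
#' @export
night_metrics <- function(reference, predicted) {
  cm <- confusion(reference, predicted)
  total <- sum(cm)
  out <- data.frame(kappa = cohen_kappa(cm),
                    accuracy_pct = 100 * sum(diag(cm)) / total)
  for (s in STAGES) {
    c2 <- collapse_stage(cm, s)
    tp <- c2[1, 1]; fn <- c2[1, 2]; fp <- c2[2, 1]
    absent <- (tp + fn) == 0 && (tp + fp) == 0
    out[[paste0(s, "_precision")]] <-
      if (absent || (tp + fp) == 0) NA_real_ else tp / (tp + fp)
    out[[paste0(s, "_recall")]] <-
      if (absent || (tp + fn) == 0) NA_real_ else tp / (tp + fn)
    out[[paste0(s, "_accuracy")]] <-
      if (absent) NA_real_ else sum(diag(c2)) / total
    out[[paste0(s, "_kappa")]] <-
      if (absent) NA_real_ else cohen_kappa(c2)
  }
  out
}

#' Cohort-level summary and subgroup statistics
#'
#' Mean and SD of every metric over nights; Pearson correlation (with
#' two-sided t-test p) of kappa and accuracy against age and BMI; two-sided
#' Mann-Whitney U tests between the sexes and between each clinical group
#' and the healthy group. Group and sex comparisons are performed on
#' participant-level averages of the per-night metrics.
#'
#' @param metrics data.frame of per-night metrics (one row per night, as
#'   returned by [night_metrics()], row-bound).
#' @param meta data.frame aligned with \code{metrics} (recording_id,
#'   participant_id, age, sex, bmi, group).
#' @param age_split Optional age threshold (years) adding a per-stage
#'   young-vs-old Mann-Whitney comparison; NULL disables it.
#' @return List with \code{summary} (metric, mean, sd, n),
#'   \code{correlations}, \code{group_tests} and optionally
#'   \code{age_split_tests} data.frames.
#' @export
cohort_summary <- function(metrics, meta, age_split = NULL) {
  stopifnot(nrow(metrics) == nrow(meta))
  num_cols <- names(metrics)[vapply(metrics, is.numeric, logical(1))]
  summ <- data.frame(
    metric = num_cols,
    mean = vapply(num_cols, function(c) mean(metrics[[c]], na.rm = TRUE),
                  numeric(1)),
    sd = vapply(num_cols, function(c) stats::sd(metrics[[c]], na.rm = TRUE),
                numeric(1)),
    n = vapply(num_cols, function(c) sum(!is.na(metrics[[c]])), integer(1)),
    row.names = NULL)

  cor_rows <- list()
  for (metric in c("kappa", "accuracy_pct")) {
    for (covar in c("age", "bmi")) {
      ok <- !is.na(metrics[[metric]]) & !is.na(meta[[covar]])
      n <- sum(ok)
      if (n >= 3 && stats::sd(meta[[covar]][ok]) > 0 &&
          stats::sd(metrics[[metric]][ok]) > 0) {
        ct <- stats::cor.test(metrics[[metric]][ok], meta[[covar]][ok])
        cor_rows[[length(cor_rows) + 1]] <- data.frame(
          metric = metric, covariate = covar, r = unname(ct$estimate),
          p = ct$p.value, n = n)
      } else {
        cor_rows[[length(cor_rows) + 1]] <- data.frame(
          metric = metric, covariate = covar, r = NA_real_, p = NA_real_,
          n = n)
      }
    }
  }

  # participant-level averages for the rank tests
  pk <- stats::aggregate(cbind(kappa, accuracy_pct) ~ participant_id,
                         data = cbind(metrics[c("kappa", "accuracy_pct")],
                                      participant_id = meta$participant_id),
                         FUN = mean, na.action = stats::na.omit)
  pmeta <- meta[!duplicated(meta$participant_id),
                c("participant_id", "age", "sex", "group")]
  pk <- merge(pk, pmeta, by = "participant_id")

  utest <- function(x, y) {
    if (length(x) < 1 || length(y) < 1)
      return(c(U = NA_real_, p = NA_real_))
    wt <- stats::wilcox.test(x, y, exact = NULL)
    c(U = unname(wt$statistic), p = wt$p.value)
  }
  gt <- list()
  for (metric in c("kappa", "accuracy_pct")) {
    a <- pk[[metric]][pk$sex == "M"]; b <- pk[[metric]][pk$sex == "F"]
    u <- suppressWarnings(utest(a, b))
    gt[[length(gt) + 1]] <- data.frame(
      metric = metric, comparison = "M vs F", U = u["U"], p = u["p"],
      n1 = length(a), n2 = length(b), row.names = NULL)
    healthy <- pk[[metric]][pk$group == "healthy"]
    for (g in setdiff(unique(pk$group), "healthy")) {
      u <- suppressWarnings(utest(pk[[metric]][pk$group == g], healthy))
      gt[[length(gt) + 1]] <- data.frame(
        metric = metric, comparison = paste(g, "vs healthy"),
        U = u["U"], p = u["p"], n1 = sum(pk$group == g),
        n2 = length(healthy), row.names = NULL)
    }
  }

  out <- list(summary = summ, correlations = do.call(rbind, cor_rows),
              group_tests = do.call(rbind, gt))
  if (!is.null(age_split)) {
    at <- list()
    young <- meta$age <= age_split
    for (col in num_cols) {
      a <- metrics[[col]][young & !is.na(metrics[[col]])]
      b <- metrics[[col]][!young & !is.na(metrics[[col]])]
      u <- suppressWarnings(utest(a, b))
      at[[length(at) + 1]] <- data.frame(
        metric = col,
        comparison = sprintf("age<=%g vs >%g", age_split, age_split),
        U = u["U"], p = u["p"], n1 = length(a), n2 = length(b),
        row.names = NULL)
    }
    out$age_split_tests <- do.call(rbind, at)
  }
  class(out) <- "cohort_report"
  out
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Cohort report (", x$summary$n[1], " nights)\n", sep = "")
  top <- x$summary[x$summary$metric %in% c("kappa", "accuracy_pct"), ]
  for (i in seq_len(nrow(top)))
    cat(sprintf("  %-14s %6.3f +/- %.3f\n", top$metric[i], top$mean[i],
                top$sd[i]))
  cat("  (", nrow(x$summary) - nrow(top), " per-stage metrics, ",
      nrow(x$group_tests), " group tests)\n", sep = "")
  invisible(x)
}

#' Write a cohort report to files
#'
#' @param report A [cohort_summary()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(report$correlations, file.path(dir, "correlations.csv"),
                   row.names = FALSE)
  utils::write.csv(report$group_tests, file.path(dir, "group_tests.csv"),
                   row.names = FALSE)
  if (!is.null(report$age_split_tests))
    utils::write.csv(report$age_split_tests,
                     file.path(dir, "age_split_tests.csv"), row.names = FALSE)
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}
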