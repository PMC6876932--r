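#' Confusion counts
#'
#' @param tp,tn,fp,fn Non-negative integer counts (PD is the positive
#'   class throughout the package).
#' @return Object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  structure(as.list(counts), class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Exact confusion-matrix arithmetic: accuracy `(TP+TN)/(TP+TN+FP+FN)`,
#' sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, and the Matthews
#' correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. MCC lies in
#' `[-1, 1]` whenever defined; it is flagged undefined (value `NA`)
#' when any factor of the denominator is zero, as are sensitivity and
#' specificity when their denominators vanish (e.g. a test cohort
#' containing a single class).
#'
#' @param counts A [confusion_counts()] object, or `tp` when the four
#'   counts are given separately.
#' @param tn,fp,fn Counts when not using a `confusion_counts` object.
#' @return List of class `classification_metrics`: `accuracy`,
#'   `sensitivity`, `specificity`, `mcc`, plus logical
#'   `mcc_defined`, `sensitivity_defined`, `specificity_defined`.
#' @examples
#' metrics_from_counts(confusion_counts(10, 10, 0, 0))
#' @export
metrics_from_counts <- function(counts, tn = NULL, fp = NULL, fn = NULL) {
  if (!inherits(counts, "confusion_counts")) {
    counts <- confusion_counts(counts, tn, fp, fn)
  }
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  total <- tp + tn + fp + fn
  if (total < 1L) stop("at least one evaluated unit required")
  sens_def <- (tp + fn) > 0
  spec_def <- (tn + fp) > 0
  marg <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  mcc_def <- all(marg > 0)
  structure(list(
    accuracy = (tp + tn) / total,
    sensitivity = if (sens_def) tp / (tp + fn) else NA_real_,
    specificity = if (spec_def) tn / (tn + fp) else NA_real_,
    mcc = if (mcc_def) (tp * tn - fp * fn) / sqrt(prod(marg)) else NA_real_,
    sensitivity_defined = sens_def,
    specificity_defined = spec_def,
    mcc_defined = mcc_def,
    counts = counts
  ), class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  fmt <- function(v, def) if (def) sprintf("%.4f", v) else "undefined"
  cat(sprintf("accuracy %.4f | sensitivity %s | specificity %s | MCC %s\n",
              x$accuracy, fmt(x$sensitivity, x$sensitivity_defined),
              fmt(x$specificity, x$specificity_defined),
              fmt(x$mcc, x$mcc_defined)))
  invisible(x)
}

#' Leave-one-subject-out folds
#'
#' One fold per subject: all of that subject's recordings form the test
#' set and every other subject's recordings the training set, so no
#' subject ever appears on both sides of a split (the leakage that
#' row-wise k-fold splitting would introduce with several recordings
#' per subject).
#'
#' @param db A `phonation_db` with at least two subjects.
#' @return List of folds, each `list(subject_id, train_idx, test_idx)`
#'   (row indices into `db`), in subject order of first appearance.
#' @export
loso_folds <- function(db) {
  subjects <- db_subjects(db)
  if (length(subjects) < 2L) stop("at least two subjects required")
  lapply(subjects, function(s) {
    test <- which(db$subject_id == s)
    list(subject_id = s, train_idx = setdiff(seq_len(nrow(db)), test),
         test_idx = test)
  })
}

#' Row-wise k-fold splitter (comparison utility)
#'
#' Plain row-level k-fold splitting, provided only as a labelled
#' comparison baseline: with several recordings per subject it places
#' the same subject in training and test partitions (subject overlap)
#' and therefore overstates performance. Use [loso_folds()] for honest
#' validation.
#'
#' @param db A `phonation_db`.
#' @param k Number of folds.
#' @param seed Seed for the row shuffle.
#' @return List of folds `list(train_idx, test_idx)`.
#' @export
rowwise_kfold_folds <- function(db, k = 10L, seed = 1L) {
  n <- nrow(db)
  if (k < 2L || k > n) stop("k must lie in 2..nrow(db)")
  assign_fold <- withr::with_seed(seed, sample(rep(seq_len(k),
                                                   length.out = n)))
  lapply(seq_len(k), function(i) {
    list(train_idx = which(assign_fold != i),
         test_idx = which(assign_fold == i))
  })
}

# deterministic per-fold seed from the held-out subject's id, so fold
# models are independent of row and subject ordering
.fold_seed <- function(seed, subject_id) {
  h <- 0
  for (b in utf8ToInt(subject_id)) h <- (h * 31 + b) %% 1000003
  (seed + h) %% .Machine$integer.max
}

# majority vote over a subject's row labels; even splits go to PD
# (sensitivity-favoring tie-break)
.aggregate_subject <- function(row_labels) {
  n_pd <- sum(row_labels == "PD")
  if (n_pd * 2L >= length(row_labels)) "PD" else "healthy"
}

.counts_from_pairs <- function(truth, pred) {
  confusion_counts(
    tp = sum(truth == "PD" & pred == "PD"),
    tn = sum(truth == "healthy" & pred == "healthy"),
    fp = sum(truth == "healthy" & pred == "PD"),
    fn = sum(truth == "PD" & pred == "healthy"))
}

.make_report <- function(per_fold) {
  counts <- .counts_from_pairs(per_fold$truth, per_fold$predicted)
  structure(list(
    per_fold = per_fold,
    counts = counts,
    metrics = metrics_from_counts(counts)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation over %d subject(s)\n", nrow(x$per_fold)))
  print(x$metrics)
  invisible(x)
}

#' Leave-one-subject-out evaluation
#'
#' For each fold, `model_factory` is called to fit a fresh model on the
#' training rows only — every preprocessing step (feature scaling,
#' discriminant reduction) must happen inside the factory so no
#' statistic of the held-out subject leaks into training. The held-out
#' subject's rows are then classified and aggregated to one
#' subject-level prediction by majority vote (ties classified PD).
#' Metrics are reported at subject granularity.
#'
#' @param db A `phonation_db`, at least two subjects, both classes
#'   present overall.
#' @param model_factory Function `(X_train, y_train, seed)` returning a
#'   prediction function `(X_new) -> PD probabilities`.
#' @param seed Base seed; each fold receives a deterministic seed
#'   derived from the held-out subject's id, so a fold's model depends
#'   only on its training rows and the evaluation is invariant to row
#'   order.
#' @param on_degenerate What to do when a training fold contains a
#'   single class: `"error"` (default; cannot occur in balanced
#'   designs) or `"misclassify"` (score the fold as wrong).
#' @param granularity `"subject"` (default) or `"row"` for
#'   recording-level metrics.
#' @return An `evaluation_report`: `per_fold` data frame
#'   (`subject_id`, `truth`, `predicted`), `counts`, `metrics`.
#' @export
evaluate_loso <- function(db, model_factory, seed = 1L,
                          on_degenerate = c("error", "misclassify"),
                          granularity = c("subject", "row")) {
  on_degenerate <- match.arg(on_degenerate)
  granularity <- match.arg(granularity)
  if (length(unique(db_labels(db))) < 2L) {
    stop("both classes must be present in the database")
  }
  folds <- loso_folds(db)
  X <- feature_matrix(db)
  y <- db_labels(db)
  rows <- list()
  for (i in seq_along(folds)) {
    f <- folds[[i]]
    ytr <- y[f$train_idx]
    truth_rows <- y[f$test_idx]
    if (length(unique(ytr)) < 2L) {
      if (on_degenerate == "error") {
        stop("training fold for subject '", f$subject_id,
             "' contains a single class")
      }
      pred_rows <- ifelse(truth_rows == "PD", "healthy", "PD")
    } else {
      predict_fn <- model_factory(X[f$train_idx, , drop = FALSE], ytr,
                                  seed = .fold_seed(seed, f$subject_id))
      probs <- predict_fn(X[f$test_idx, , drop = FALSE])
      pred_rows <- ifelse(probs >= 0.5, "PD", "healthy")
    }
    if (granularity == "subject") {
      rows[[i]] <- data.frame(
        subject_id = f$subject_id,
        truth = truth_rows[1L],
        predicted = .aggregate_subject(pred_rows),
        stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- data.frame(
        subject_id = f$subject_id,
        truth = truth_rows,
        predicted = pred_rows,
        stringsAsFactors = FALSE)
    }
  }
  .make_report(do.call(rbind, rows))
}

#' Train on one database, evaluate per subject of another
#'
#' The cross-database protocol: a single model is fitted on the full
#' training database and each testing-database subject is classified by
#' aggregating its row predictions (majority vote, ties PD). When the
#' testing cohort contains a single class — as in an all-patient
#' validation cohort — specificity and MCC are flagged undefined in the
#' report; accuracy and sensitivity remain available.
#'
#' @param train_db,test_db `phonation_db` objects with identical
#'   feature schemas.
#' @param model_factory As in [evaluate_loso()].
#' @param seed Seed passed to the factory.
#' @return An `evaluation_report` with one evaluated unit per testing
#'   subject.
#' @export
evaluate_cross_database <- function(train_db, test_db, model_factory,
                                    seed = 1L) {
  if (!identical(db_schema(train_db)$name, db_schema(test_db)$name)) {
    stop("training and testing schemas differ")
  }
  if (length(unique(db_labels(train_db))) < 2L) {
    stop("training database must contain both classes")
  }
  predict_fn <- model_factory(feature_matrix(train_db),
                              db_labels(train_db), seed = seed)
  Xte <- feature_matrix(test_db)
  rows <- lapply(db_subjects(test_db), function(s) {
    idx <- which(test_db$subject_id == s)
    probs <- predict_fn(Xte[idx, , drop = FALSE])
    data.frame(
      subject_id = s,
      truth = db_labels(test_db)[idx[1L]],
      predicted = .aggregate_subject(ifelse(probs >= 0.5, "PD", "healthy")),
      stringsAsFactors = FALSE)
  })
  .make_report(do.call(rbind, rows))
}

#' Write an evaluation report as JSON or TSV
#'
#' The TSV layout mirrors the result tables of architecture-search
#' experiments: columns `L`, `H1`, `H2`, then `ACC`, `Sen.`, `Spec.`
#' and `MCC` with percentages rounded to two decimals (`NA` for
#' undefined metrics).
#'
#' @param report An `evaluation_report`.
#' @param path Output path.
#' @param genome Optional [architecture_genome()] for the architecture
#'   columns of the TSV.
#' @return `path`, invisibly.
#' @export
report_to_json <- function(report, path) {
  m <- report$metrics
  jsonlite::write_json(list(
    per_fold = report$per_fold,
    counts = unclass(report$counts),
    accuracy = m$accuracy,
    sensitivity = if (m$sensitivity_defined) m$sensitivity else NULL,
    specificity = if (m$specificity_defined) m$specificity else NULL,
    mcc = if (m$mcc_defined) m$mcc else NULL,
    specificity_defined = m$specificity_defined,
    mcc_defined = m$mcc_defined
  ), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname report_to_json
#' @export
report_to_tsv <- function(report, path, genome = NULL) {
  m <- report$metrics
  pct <- function(v, def) if (def) sprintf("%.2f", 100 * v) else "NA"
  row <- data.frame(
    L = if (is.null(genome)) NA_integer_ else genome$n_hidden_layers,
    H1 = if (is.null(genome)) NA_integer_ else genome$neurons_per_layer[1L],
    H2 = if (is.null(genome) || genome$n_hidden_layers < 2L) NA_integer_
         else genome$neurons_per_layer[2L],
    `ACC(%)` = pct(m$accuracy, TRUE),
    `Sen.(%)` = pct(m$sensitivity, m$sensitivity_defined),
    `Spec.(%)` = pct(m$specificity, m$specificity_defined),
    MCC = if (m$mcc_defined) sprintf("%.4f", m$mcc) else "NA",
    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(row, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
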