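#' Classification metrics from confusion counts
#'
#' Accuracy, precision, recall and F1 (the harmonic mean of precision and
#' recall). A ratio with a zero denominator is reported as 0 and flagged in
#' the `undefined` attribute rather than propagating NaN.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts; their total must be
#'   positive.
#' @return Named list: `accuracy`, `precision`, `recall`, `f1`, and
#'   `undefined` (character vector naming any zero-denominator metrics).
#' @examples
#' compute_metrics(tp = 3, fp = 1, tn = 4, fn = 2)
#' @export
compute_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  total <- sum(counts)
  if (total == 0) stop("confusion counts are all zero")
  undefined <- character()
  ratio <- function(num, den, name) {
    if (den == 0) {
      undefined <<- c(undefined, name)
      0
    } else num / den
  }
  precision <- ratio(tp, tp + fp, "precision")
  recall <- ratio(tp, tp + fn, "recall")
  f1 <- ratio(2 * precision * recall, precision + recall, "f1")
  list(accuracy = (tp + tn) / total, precision = precision,
       recall = recall, f1 = f1, undefined = undefined)
}

confusion_counts <- function(calls, truth) {
  calls <- as.logical(calls)
  truth <- as_binary_labels(truth) == 1L
  list(tp = sum(calls & truth), fp = sum(calls & !truth),
       tn = sum(!calls & !truth), fn = sum(!calls & truth))
}

#' Stratified k-fold cross-validation of a motif classifier
#'
#' `trainer(x_train, y_train)` must return a prediction function
#' `function(x_test) -> logical calls`; anything fold-specific (cutoff
#' calibration, grid search) must happen inside the trainer so no test-fold
#' information leaks. `x` may be a feature matrix (rows subset) or a motif
#' character vector (elements subset), so score-based models and
#' feature-based classifiers share one harness.
#'
#' @param trainer Model-fitting function as described above.
#' @param x Features: matrix/data.frame or character vector of motifs.
#' @param labels Binary labels.
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the stratified fold assignment.
#' @return List of class `cv_report`: `per_fold` (data.frame of metrics),
#'   `mean`, `sd` (named numeric), `k`, `seed`.
#' @export
cross_validate <- function(trainer, x, labels, k = 10L, seed = 1L) {
  y <- as_binary_labels(labels)
  n <- if (is.null(dim(x))) length(x) else nrow(x)
  if (n != length(y)) stop("x and labels disagree in length")
  if (k > n) stop("more folds than observations")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  take <- function(obj, idx) {
    if (is.null(dim(obj))) obj[idx] else obj[idx, , drop = FALSE]
  }
  fold <- stratified_folds(y, k, seed)
  per_fold <- lapply(seq_len(k), function(f) {
    tr <- fold != f
    predict_fn <- trainer(take(x, which(tr)), y[tr])
    calls <- predict_fn(take(x, which(!tr)))
    cc <- confusion_counts(calls, y[!tr])
    m <- compute_metrics(cc$tp, cc$fp, cc$tn, cc$fn)
    data.frame(fold = f, accuracy = m$accuracy, precision = m$precision,
               recall = m$recall, f1 = m$f1)
  })
  per_fold <- do.call(rbind, per_fold)
  metric_cols <- c("accuracy", "precision", "recall", "f1")
  structure(
    list(per_fold = per_fold,
         mean = vapply(per_fold[metric_cols], mean, numeric(1)),
         sd = vapply(per_fold[metric_cols], stats::sd, numeric(1)),
         k = as.integer(k), seed = as.integer(seed)),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold, seed %d\n", x$k, x$seed))
  for (m in names(x$mean)) {
    cat(sprintf("  %-9s %.1f%% +/- %.1f\n", m, 100 * x$mean[[m]],
                100 * x$sd[[m]]))
  }
  invisible(x)
}

#' Trainer factories for the score-based models
#'
#' Adapters that let [cross_validate()] drive the PSSM and Freq models from
#' motif vectors: each fold refits the model (and, for the PSSM, recalibrates
#' the cutoff) on the training motifs only.
#'
#' @param background,pseudocount Passed to the underlying fit.
#' @param task,threshold Passed to [fit_freq()].
#' @return A trainer function for [cross_validate()].
#' @export
pssm_trainer <- function(background = background_from_blosum62(),
                         pseudocount = 0.05) {
  function(motifs, labels) {
    y <- as_binary_labels(labels)
    model <- fit_pssm(motifs[y == 1L], background, pseudocount)
    model$cutoff <- calibrate_cutoff(score_pssm(model, motifs[y == 1L]),
                                     score_pssm(model, motifs[y == 0L]))
    function(new_motifs) call_pssm(model, new_motifs)
  }
}

#' @rdname pssm_trainer
#' @export
freq_trainer <- function(pseudocount = 0.05,
                         task = c("prenylation", "cleavage"),
                         threshold = NULL) {
  task <- match.arg(task)
  function(motifs, labels) {
    y <- as_binary_labels(labels)
    model <- fit_freq(motifs[y == 1L], motifs[y == 0L],
                      pseudocount = pseudocount, task = task,
                      threshold = threshold)
    function(new_motifs) call_freq(model, new_motifs)
  }
}

#' Trainer factory for grid-searched classifiers
#'
#' @param spec A [classifier_spec()].
#' @param calibrate Platt-calibrate inside each fold (default FALSE for
#'   speed; calls then use the decision sign).
#' @return A trainer function for [cross_validate()]; expects feature-matrix
#'   input.
#' @export
classifier_trainer <- function(spec, calibrate = FALSE) {
  function(x, labels) {
    fitted <- grid_search_fit(spec, x, labels, calibrate = calibrate)
    function(x_new) as.logical(stats::predict(fitted, x_new, type = "call"))
  }
}

validation_methods <- list(
  prenylation = c(svm = "svm", preps = "preps", freq = "freq", fpb = "fpb"),
  cleavage = c(svm = "svm_cleave", freq = "freq_cleave")
)

check_validation_table <- function(table) {
  need <- c("motif", "observed_prenylation")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("validation table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (!nrow(table)) stop("validation table is empty")
  # cleavage can only be observed on prenylated motifs
  if ("observed_cleavage" %in% names(table)) {
    bad <- !is.na(table$observed_cleavage) & table$observed_prenylation != "+"
    if (any(bad)) {
      stop("cleavage observation on non-prenylated motif(s): ",
           paste(table$motif[bad], collapse = ", "))
    }
  }
  table
}

#' Read a validation table of per-method calls and observed outcomes
#'
#' CSV with columns `motif`, per-method prenylation call columns (`svm`,
#' `preps`, `freq`, `fpb`), `observed_prenylation`, per-method cleavage call
#' columns (`svm_cleave`, `freq_cleave`) and `observed_cleavage`; calls are
#' `+`, `-`, or `NA`. Cleavage entries are NA for motifs not observed
#' prenylated (cleavage is prenyl-dependent).
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_validation_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  check_validation_table(df)
}

#' Tally validation-table agreement for one method
#'
#' For prenylation every motif in the table is eligible and a match means
#' the method's call equals the observed prenylation status. For cleavage
#' only motifs observed prenylated are eligible (cleavage is
#' prenyl-dependent) and a match means the method's cleavage call equals the
#' observed cleavage status.
#'
#' @param table Validation table (see [read_validation_table()]).
#' @param method One of `"svm"`, `"preps"`, `"freq"`, `"fpb"`.
#' @param task `"prenylation"` or `"cleavage"`.
#' @return List: `matches`, `eligible`, `percent`.
#' @export
tally_validation <- function(table, method,
                             task = c("prenylation", "cleavage")) {
  task <- match.arg(task)
  table <- check_validation_table(table)
  cols <- validation_methods[[task]]
  if (!method %in% names(cols)) {
    stop("no ", task, " calls for method '", method, "'")
  }
  col <- cols[[method]]
  if (!col %in% names(table)) {
    stop("validation table lacks column '", col, "'")
  }
  if (task == "prenylation") {
    eligible <- rep(TRUE, nrow(table))
    observed <- table$observed_prenylation
  } else {
    eligible <- table$observed_prenylation == "+"
    observed <- table$observed_cleavage
  }
  pred <- table[[col]][eligible]
  obs <- observed[eligible]
  if (anyNA(pred) || anyNA(obs)) {
    stop("missing calls among eligible rows for method '", method, "'")
  }
  matches <- sum(pred == obs)
  list(matches = matches, eligible = sum(eligible),
       percent = 100 * matches / sum(eligible))
}

#' False-call rates for one method on a validation table
#'
#' Denominators are the method's own calls, not the ground-truth counts:
#' the false positive rate is wrong positive calls over all positive calls,
#' and the false negative rate is wrong negative calls over all negative
#' calls. A class with zero calls yields an NA rate flagged in `undefined`.
#'
#' @inheritParams tally_validation
#' @return List: `false_positive` (wrong/total positive calls),
#'   `false_negative`, the four underlying counts, and `undefined`.
#' @export
false_rate_summary <- function(table, method,
                               task = c("prenylation", "cleavage")) {
  task <- match.arg(task)
  table <- check_validation_table(table)
  col <- validation_methods[[task]][[method]]
  if (is.null(col) || !col %in% names(table)) {
    stop("no ", task, " calls for method '", method, "'")
  }
  if (task == "prenylation") {
    keep <- rep(TRUE, nrow(table))
    observed <- table$observed_prenylation
  } else {
    keep <- table$observed_prenylation == "+"
    observed <- table$observed_cleavage
  }
  pred <- table[[col]][keep]
  obs <- observed[keep]
  pos_calls <- sum(pred == "+")
  neg_calls <- sum(pred == "-")
  wrong_pos <- sum(pred == "+" & obs == "-")
  wrong_neg <- sum(pred == "-" & obs == "+")
  undefined <- character()
  fp <- if (pos_calls == 0) {
    undefined <- c(undefined, "false_positive"); NA_real_
  } else wrong_pos / pos_calls
  fn <- if (neg_calls == 0) {
    undefined <- c(undefined, "false_negative"); NA_real_
  } else wrong_neg / neg_calls
  list(false_positive = fp, false_negative = fn,
       wrong_positive = wrong_pos, positive_calls = pos_calls,
       wrong_negative = wrong_neg, negative_calls = neg_calls,
       undefined = undefined)
}
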