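# BLOSUM62 joint target frequencies (matblas blosum62.qij, lower triangle,
# residue order as published). The marginal of this table is the standard
# BLOSUM62 background distribution; the log-odds form distributed with
# alignment packages cannot recover these frequencies, so the published
# joint table is embedded as data.
blosum62_qij_order <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                        "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

blosum62_qij_lower <- c(
  0.0215,
  0.0023, 0.0178,
  0.0019, 0.0020, 0.0141,
  0.0022, 0.0016, 0.0037, 0.0213,
  0.0016, 0.0004, 0.0004, 0.0004, 0.0119,
  0.0019, 0.0025, 0.0015, 0.0016, 0.0003, 0.0073,
  0.0030, 0.0027, 0.0022, 0.0049, 0.0004, 0.0035, 0.0161,
  0.0058, 0.0017, 0.0029, 0.0025, 0.0008, 0.0014, 0.0019, 0.0378,
  0.0011, 0.0012, 0.0014, 0.0010, 0.0002, 0.0010, 0.0014, 0.0010, 0.0093,
  0.0032, 0.0012, 0.0010, 0.0012, 0.0011, 0.0009, 0.0012, 0.0014, 0.0006,
  0.0184,
  0.0044, 0.0024, 0.0014, 0.0015, 0.0016, 0.0016, 0.0020, 0.0021, 0.0010,
  0.0114, 0.0371,
  0.0033, 0.0062, 0.0024, 0.0024, 0.0005, 0.0031, 0.0041, 0.0025, 0.0012,
  0.0016, 0.0025, 0.0161,
  0.0013, 0.0008, 0.0005, 0.0005, 0.0004, 0.0007, 0.0007, 0.0007, 0.0004,
  0.0025, 0.0049, 0.0009, 0.0040,
  0.0016, 0.0009, 0.0008, 0.0008, 0.0005, 0.0005, 0.0009, 0.0012, 0.0008,
  0.0030, 0.0054, 0.0009, 0.0012, 0.0183,
  0.0022, 0.0010, 0.0009, 0.0012, 0.0004, 0.0008, 0.0014, 0.0014, 0.0005,
  0.0010, 0.0014, 0.0016, 0.0004, 0.0005, 0.0191,
  0.0063, 0.0023, 0.0031, 0.0028, 0.0010, 0.0019, 0.0030, 0.0038, 0.0011,
  0.0017, 0.0024, 0.0031, 0.0009, 0.0012, 0.0017, 0.0126,
  0.0037, 0.0018, 0.0022, 0.0019, 0.0009, 0.0014, 0.0020, 0.0022, 0.0007,
  0.0027, 0.0033, 0.0023, 0.0010, 0.0012, 0.0014, 0.0047, 0.0125,
  0.0004, 0.0003, 0.0002, 0.0002, 0.0001, 0.0002, 0.0003, 0.0004, 0.0002,
  0.0004, 0.0007, 0.0003, 0.0002, 0.0008, 0.0001, 0.0003, 0.0003, 0.0065,
  0.0013, 0.0009, 0.0007, 0.0006, 0.0003, 0.0007, 0.0009, 0.0008, 0.0015,
  0.0014, 0.0022, 0.0010, 0.0006, 0.0042, 0.0005, 0.0010, 0.0009, 0.0009,
  0.0102,
  0.0051, 0.0016, 0.0012, 0.0013, 0.0014, 0.0012, 0.0017, 0.0018, 0.0006,
  0.0120, 0.0095, 0.0019, 0.0023, 0.0026, 0.0012, 0.0024, 0.0036, 0.0004,
  0.0015, 0.0196
)

#' BLOSUM62 joint target-frequency matrix
#'
#' The symmetric 20 x 20 pair-frequency table underlying the BLOSUM62
#' substitution matrix, in [AA_ALPHABET] order.
#'
#' @return Numeric 20 x 20 matrix; entries sum to 1 (off-diagonals counted
#'   once on each side).
#' @export
blosum62_frequencies <- function() {
  q <- matrix(0, 20L, 20L,
              dimnames = list(blosum62_qij_order, blosum62_qij_order))
  idx <- 1L
  for (i in seq_len(20L)) {
    for (j in seq_len(i)) {
      # each published lower-triangle entry is the per-direction ordered-pair
      # probability, so the symmetric matrix carries it in both cells and
      # row sums give the standard marginals (A 0.074, R 0.052, ...)
      q[i, j] <- blosum62_qij_lower[idx]
      q[j, i] <- q[i, j]
      idx <- idx + 1L
    }
  }
  q[AA_ALPHABET, AA_ALPHABET]
}

#' Background residue distribution derived from BLOSUM62
#'
#' The marginal residue probabilities of the published BLOSUM62 joint
#' target-frequency table (row sums of the symmetric pair-frequency matrix),
#' normalized to sum to one.
#'
#' @return Named numeric vector of 20 probabilities in [AA_ALPHABET] order.
#' @export
background_from_blosum62 <- function() {
  q <- blosum62_frequencies()
  p <- rowSums(q)
  p / sum(p)
}

position_counts <- function(motifs) {
  pos <- motif_positions(motifs)
  counts <- matrix(0L, nrow = 3L, ncol = 20L,
                   dimnames = list(c("x1", "x2", "x3"), AA_ALPHABET))
  for (p in 1:3) {
    tab <- table(factor(pos[, p], levels = AA_ALPHABET))
    counts[p, ] <- as.integer(tab)
  }
  counts
}

#' Fit a position-specific scoring matrix from positive motifs
#'
#' For variable position p and residue a, the log-odds entry is
#' `ln(((count + pseudocount) / (n + 20 * pseudocount)) / background[a])`:
#' pseudocounted positional frequencies of the positive set against a fixed
#' background. The pseudocount (default 0.05) is an additive count per
#' (position, residue) cell. The invariant cysteine carries no information
#' and is excluded. The decision cutoff is left unset; see
#' [calibrate_cutoff()].
#'
#' @param positives Character vector of positive motifs (non-empty).
#' @param background Named residue probability vector, by default
#'   [background_from_blosum62()].
#' @param pseudocount Additive count per cell (default 0.05).
#' @param task Label carried on the model (e.g. "prenylation").
#' @return List of class `pssm_model` with `log_odds` (3 x 20),
#'   `background`, `pseudocount`, `n_train`, `cutoff` (NA until calibrated)
#'   and `task`.
#' @export
fit_pssm <- function(positives, background = background_from_blosum62(),
                     pseudocount = 0.05, task = "prenylation") {
  if (length(positives) == 0) stop("positive set is empty")
  stopifnot(pseudocount >= 0, all(AA_ALPHABET %in% names(background)))
  background <- background[AA_ALPHABET]
  positives <- unique(toupper(positives))
  n <- length(positives)
  counts <- position_counts(positives)
  fg <- (counts + pseudocount) / (n + 20 * pseudocount)
  log_odds <- log(sweep(fg, 2L, background, "/"))
  structure(
    list(log_odds = log_odds, background = background,
         pseudocount = pseudocount, n_train = n, cutoff = NA_real_,
         task = task),
    class = "pssm_model"
  )
}

#' @export
print.pssm_model <- function(x, ...) {
  cat(sprintf("<pssm_model: %s>  n = %d, pseudocount = %g, cutoff = %s\n",
              x$task, x$n_train, x$pseudocount,
              if (is.na(x$cutoff)) "unset" else format(x$cutoff)))
  invisible(x)
}

#' Score motifs with a PSSM
#'
#' The score is the sum over the three variable positions of the log-odds
#' entries for the motif's residues; the invariant cysteine contributes
#' nothing. Scores are additive: substituting one position changes the score
#' by exactly the difference of the two log-odds entries.
#'
#' @param model A `pssm_model`.
#' @param motifs Character vector of motifs.
#' @return Named numeric vector of log-odds scores.
#' @export
score_pssm <- function(model, motifs) {
  stopifnot(inherits(model, "pssm_model"))
  pos <- motif_positions(motifs)
  s <- numeric(nrow(pos))
  for (p in 1:3) {
    s <- s + model$log_odds[p, match(pos[, p], AA_ALPHABET)]
  }
  names(s) <- rownames(pos)
  s
}

#' Calibrate the decision cutoff that best separates two score sets
#'
#' Exhaustively evaluates the rule `score > t => positive` over candidate
#' thresholds: midpoints of adjacent sorted unique scores plus sentinels
#' below and above all scores. Returns the threshold maximizing training
#' accuracy; ties break toward the smallest threshold.
#'
#' @param scores_pos,scores_neg Numeric score vectors (both non-empty).
#' @return The calibrated threshold (numeric scalar).
#' @export
calibrate_cutoff <- function(scores_pos, scores_neg) {
  if (!length(scores_pos) || !length(scores_neg)) {
    stop("both score sets must be non-empty")
  }
  all_scores <- sort(unique(c(scores_pos, scores_neg)))
  cands <- c(all_scores[1] - 1,
             if (length(all_scores) > 1)
               (all_scores[-1] + all_scores[-length(all_scores)]) / 2,
             all_scores[length(all_scores)] + 1)
  n <- length(scores_pos) + length(scores_neg)
  acc <- vapply(cands, function(t) {
    (sum(scores_pos > t) + sum(scores_neg <= t)) / n
  }, numeric(1))
  cands[which.max(acc)]  # which.max takes the first (smallest) on ties
}

#' Fit PSSM and calibrate its cutoff on a training set
#'
#' Convenience wrapper: fits the PSSM on the positives and sets the cutoff
#' that best separates positive from negative training scores.
#'
#' @param ts A `training_set`.
#' @inheritParams fit_pssm
#' @return A calibrated `pssm_model`.
#' @export
train_pssm <- function(ts, background = background_from_blosum62(),
                       pseudocount = 0.05) {
  stopifnot(inherits(ts, "training_set"))
  model <- fit_pssm(ts$positives, background, pseudocount, task = ts$task)
  model$cutoff <- calibrate_cutoff(score_pssm(model, ts$positives),
                                   score_pssm(model, ts$negatives))
  model
}

#' Binary PSSM calls (score strictly above the calibrated cutoff)
#' @param model A calibrated `pssm_model`.
#' @param motifs Character vector of motifs.
#' @return Logical vector.
#' @export
call_pssm <- function(model, motifs) {
  if (is.na(model$cutoff)) stop("PSSM cutoff has not been calibrated")
  score_pssm(model, motifs) > model$cutoff
}

#' Fit a positional frequency-ratio ("Freq") scorer
#'
#' Scores motifs by the positional frequency of their residues in the
#' positive versus the negative training set: per variable position the
#' pseudocounted class frequencies are formed as in [fit_pssm()], and the
#' motif score is the sum over positions of `log2(pos_freq / neg_freq)`.
#' Decision cutoffs are fixed anchors on this scale: scores strictly above
#' -1 call prenylation positive, strictly above 0 call cleavage positive.
#'
#' @param positives,negatives Character vectors of motifs (non-empty).
#' @param pseudocount Additive count per cell (default 0.05).
#' @param task `"prenylation"` or `"cleavage"`; sets the default threshold
#'   (-1 and 0 respectively).
#' @param threshold Override the decision threshold.
#' @return List of class `freq_model` with `pos_freq`, `neg_freq` (3 x 20
#'   row-stochastic tables), `pseudocount`, `threshold`, `task`.
#' @export
fit_freq <- function(positives, negatives, pseudocount = 0.05,
                     task = c("prenylation", "cleavage"),
                     threshold = NULL) {
  task <- match.arg(task)
  if (!length(positives) || !length(negatives)) {
    stop("both motif sets must be non-empty")
  }
  if (is.null(threshold)) threshold <- if (task == "prenylation") -1 else 0
  freq_of <- function(motifs) {
    motifs <- unique(toupper(motifs))
    counts <- position_counts(motifs)
    (counts + pseudocount) / (length(motifs) + 20 * pseudocount)
  }
  structure(
    list(pos_freq = freq_of(positives), neg_freq = freq_of(negatives),
         pseudocount = pseudocount, threshold = threshold, task = task),
    class = "freq_model"
  )
}

#' @export
print.freq_model <- function(x, ...) {
  cat(sprintf("<freq_model: %s>  pseudocount = %g, threshold = %g\n",
              x$task, x$pseudocount, x$threshold))
  invisible(x)
}

#' Score motifs with a Freq model
#' @param model A `freq_model`.
#' @param motifs Character vector of motifs.
#' @return Named numeric vector of log2 frequency-ratio scores.
#' @export
score_freq <- function(model, motifs) {
  stopifnot(inherits(model, "freq_model"))
  pos <- motif_positions(motifs)
  s <- numeric(nrow(pos))
  for (p in 1:3) {
    idx <- match(pos[, p], AA_ALPHABET)
    s <- s + log2(model$pos_freq[p, idx] / model$neg_freq[p, idx])
  }
  names(s) <- rownames(pos)
  s
}

#' Binary Freq calls (score strictly above the task threshold)
#' @param model A `freq_model`.
#' @param motifs Character vector of motifs.
#' @return Logical vector.
#' @export
call_freq <- function(model, motifs) {
  score_freq(model, motifs) > model$threshold
}

#' Fit a Freq model from a training set
#' @param ts A `training_set`.
#' @inheritParams fit_freq
#' @return A `freq_model`.
#' @export
train_freq <- function(ts, pseudocount = 0.05, threshold = NULL) {
  stopifnot(inherits(ts, "training_set"))
  fit_freq(ts$positives, ts$negatives, pseudocount = pseudocount,
           task = ts$task, threshold = threshold)
}

#' Printed decision cutoffs for external prenylation predictors
#'
#' Scores strictly greater than the cutoff are positive calls: -2 for
#' PrePS, -1.1 for FlexPepBind, -1 for Freq prenylation and 0 for Freq
#' cleavage.
#'
#' @return Named list of cutoffs.
#' @export
method_thresholds <- function() {
  list(preps_cutoff = -2, fpb_cutoff = -1.1,
       freq_prenylation_cutoff = -1, freq_cleavage_cutoff = 0)
}

#' Apply an external predictor's decision cutoff to a score table
#'
#' For pre-computed score columns from external methods (PrePS,
#' FlexPepBind): calls are positive iff the score is strictly greater than
#' the cutoff.
#'
#' @param scores Named numeric vector (names are motifs) or numeric vector.
#' @param cutoff Decision cutoff.
#' @return Logical vector of calls, names preserved.
#' @export
apply_external_threshold <- function(scores, cutoff) {
  stopifnot(is.numeric(scores), is.numeric(cutoff), length(cutoff) == 1L)
  scores > cutoff
}

#' Read a two-column (motif, score) table of external predictor scores
#' @param path CSV/TSV path; separator inferred from the extension.
#' @return Named numeric vector of scores.
#' @export
read_external_scores <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected columns: motif, score")
  stats::setNames(as.numeric(df[[2]]), as.character(parse_motif(df[[1]])))
}

#' Serialize a PSSM or Freq model to JSON
#' @param model A `pssm_model` or `freq_model`.
#' @param path Output path.
#' @export
write_model_json <- function(model, path) {
  kind <- class(model)[1]
  payload <- c(list(kind = kind, alphabet = AA_ALPHABET), unclass(model))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", na = "null")
  invisible(path)
}

#' Read a PSSM or Freq model serialized by [write_model_json()]
#' @param path JSON path.
#' @return The deserialized model.
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(unname(unlist(x$alphabet)), AA_ALPHABET)) {
    stop("serialized model uses a different alphabet order")
  }
  kind <- x$kind
  x$kind <- NULL
  x$alphabet <- NULL
  fix_tab <- function(m) {
    # jsonlite restores the row-major nested arrays as a 3 x 20 matrix
    m <- if (is.matrix(m)) m else matrix(unlist(m), nrow = 3L, byrow = TRUE)
    dimnames(m) <- list(c("x1", "x2", "x3"), AA_ALPHABET)
    m
  }
  if (kind == "pssm_model") {
    x$log_odds <- fix_tab(x$log_odds)
    x$background <- stats::setNames(as.numeric(x$background), AA_ALPHABET)
    if (is.null(x$cutoff)) x$cutoff <- NA_real_
  } else if (kind == "freq_model") {
    x$pos_freq <- fix_tab(x$pos_freq)
    x$neg_freq <- fix_tab(x$neg_freq)
  } else {
    stop("unknown serialized model kind: ", kind)
  }
  structure(x, class = kind)
}
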