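#' Uniform per-motif prediction interface
#'
#' Dispatches over the model kinds in this package and returns one row per
#' motif with the model's score, its binary call, and a calibrated
#' probability where the model provides one (NA otherwise; PSSM and Freq
#' emit scores, not probabilities).
#'
#' @param object A `pssm_model`, `freq_model`, or `motif_predictor` (see
#'   [classifier_predictor()]).
#' @param motifs Character vector of motifs.
#' @return data.frame with columns `motif`, `score`, `probability`, `call`.
#' @export
predict_motifs <- function(object, motifs) UseMethod("predict_motifs")

#' @export
predict_motifs.pssm_model <- function(object, motifs) {
  data.frame(motif = as.character(parse_motif(motifs)),
             score = unname(score_pssm(object, motifs)),
             probability = NA_real_,
             call = unname(call_pssm(object, motifs)),
             stringsAsFactors = FALSE)
}

#' @export
predict_motifs.freq_model <- function(object, motifs) {
  data.frame(motif = as.character(parse_motif(motifs)),
             score = unname(score_freq(object, motifs)),
             probability = NA_real_,
             call = unname(call_freq(object, motifs)),
             stringsAsFactors = FALSE)
}

#' Bind a fitted classifier to its feature encoder
#'
#' A `caax_classifier` consumes feature matrices, not motifs; this wrapper
#' pairs it with the encoder that produced its training features (e.g.
#' one-hot + a PCA reducer fitted on the training set) so it can be used
#' wherever a motif-level model is expected. `use_probability` selects
#' whether calls come from the Platt probability (> 0.5) or the raw
#' decision sign.
#'
#' @param fitted A `caax_classifier`.
#' @param encoder Function motifs -> feature matrix.
#' @param model_id Identifier recorded in outputs.
#' @param use_probability Call via calibrated probability when available
#'   (default TRUE when the model is calibrated).
#' @return List of class `motif_predictor`.
#' @export
classifier_predictor <- function(fitted, encoder,
                                 model_id = fitted$spec$algorithm,
                                 use_probability = !is.null(fitted$calibration)) {
  stopifnot(inherits(fitted, "caax_classifier"), is.function(encoder))
  structure(list(fitted = fitted, encoder = encoder, model_id = model_id,
                 use_probability = use_probability),
            class = "motif_predictor")
}

#' @export
predict_motifs.motif_predictor <- function(object, motifs) {
  X <- object$encoder(as.character(parse_motif(motifs)))
  dv <- stats::predict(object$fitted, X, type = "decision")
  prob <- if (!is.null(object$fitted$calibration)) {
    stats::predict(object$fitted, X, type = "probability")
  } else {
    rep(NA_real_, length(dv))
  }
  call <- if (object$use_probability && !anyNA(prob)) prob > 0.5 else dv > 0
  data.frame(motif = as.character(parse_motif(motifs)),
             score = dv, probability = prob, call = call,
             stringsAsFactors = FALSE)
}

model_id_of <- function(object) {
  if (inherits(object, "motif_predictor")) return(object$model_id)
  if (inherits(object, "pssm_model")) return(paste0("pssm_", object$task))
  if (inherits(object, "freq_model")) return(paste0("freq_", object$task))
  class(object)[1]
}

#' Two-stage prediction over a motif set and three-way partition
#'
#' Prenylation is evaluated for every motif; cleavage is evaluated only for
#' prenylation-positive motifs, because CaaX cleavage is prenyl-dependent.
#' The three-way class is derived, never predicted directly: `unmodified`
#' (not prenylated; cleavage not applicable), `shunted` (prenylated,
#' cleavage-negative), `cleaved` (prenylated, cleavage-positive).
#'
#' @param prenylation_model,cleavage_model Motif-level models accepted by
#'   [predict_motifs()].
#' @param motifs Motifs to score (default the full 8000-motif space).
#' @return List of class `space_prediction`: `records` (data.frame with
#'   per-motif scores, calls and `klass`) and `partition` (counts and
#'   fractions per class).
#' @export
predict_space <- function(prenylation_model, cleavage_model,
                          motifs = enumerate_cxxx_space()) {
  motifs <- as.character(parse_motif(motifs))
  pren <- predict_motifs(prenylation_model, motifs)
  records <- data.frame(
    motif = pren$motif,
    prenylation_score = pren$score,
    prenylation_probability = pren$probability,
    prenylation_call = pren$call,
    cleavage_score = NA_real_,
    cleavage_probability = NA_real_,
    cleavage_call = NA,
    stringsAsFactors = FALSE
  )
  if (any(pren$call)) {
    clv <- predict_motifs(cleavage_model, motifs[pren$call])
    records$cleavage_score[pren$call] <- clv$score
    records$cleavage_probability[pren$call] <- clv$probability
    records$cleavage_call[pren$call] <- clv$call
  }
  records$klass <- ifelse(!records$prenylation_call, "unmodified",
                          ifelse(records$cleavage_call, "cleaved", "shunted"))
  records$prenylation_model <- model_id_of(prenylation_model)
  records$cleavage_model <- model_id_of(cleavage_model)
  stopifnot(!any(records$klass %in% c("shunted", "cleaved") &
                   !records$prenylation_call))
  counts <- vapply(c("unmodified", "shunted", "cleaved"),
                   function(k) sum(records$klass == k), numeric(1))
  structure(
    list(records = records,
         partition = list(counts = counts,
                          fractions = counts / sum(counts))),
    class = "space_prediction"
  )
}

#' @export
print.space_prediction <- function(x, ...) {
  n <- sum(x$partition$counts)
  cat(sprintf("<space_prediction> %d motifs [%s + %s]\n", n,
              x$records$prenylation_model[1], x$records$cleavage_model[1]))
  for (k in names(x$partition$counts)) {
    cat(sprintf("  %-10s %5d  (%.1f%%)\n", k, x$partition$counts[[k]],
                100 * x$partition$fractions[[k]]))
  }
  invisible(x)
}

#' Scan a proteome for C-terminal Cxxx motifs and predict their fate
#'
#' Proteins whose C-terminus is not a Cxxx motif are reported as ineligible
#' with NA predictions; eligible proteins carry the motif-level prediction
#' of [predict_space()].
#'
#' @param fasta FASTA path or [Biostrings::AAStringSet].
#' @inheritParams predict_space
#' @return data.frame: one row per protein, with `id`, `motif`, `eligible`
#'   and the per-motif prediction columns.
#' @export
scan_proteome <- function(fasta, prenylation_model, cleavage_model) {
  prot <- read_proteome_motifs(fasta)
  pred_cols <- c("prenylation_score", "prenylation_probability",
                 "prenylation_call", "cleavage_score",
                 "cleavage_probability", "cleavage_call", "klass",
                 "prenylation_model", "cleavage_model")
  for (col in pred_cols) prot[[col]] <- NA
  prot$klass <- NA_character_
  if (any(prot$eligible)) {
    sp <- predict_space(prenylation_model, cleavage_model,
                        unique(prot$motif[prot$eligible]))
    hit <- match(prot$motif, sp$records$motif)
    for (col in pred_cols) {
      prot[[col]][!is.na(hit)] <- sp$records[[col]][hit[!is.na(hit)]]
    }
  }
  prot
}

#' Histogram of calibrated probabilities per modification class
#'
#' Bins the per-motif probabilities of a [predict_space()] result for
#' stacked-histogram plotting: equal-width bins on the unit interval, one
#' count vector per class label.
#'
#' @param records data.frame from a `space_prediction`.
#' @param which `"prenylation"` or `"cleavage"` probability column.
#' @param bins Number of equal-width bins over the unit interval
#'   (default 20).
#' @param class_column Column to stratify counts by (default `klass`; for
#'   training sets, pass a label column).
#' @return List: `breaks`, `mids` and `counts` (class x bin matrix whose
#'   total equals the number of records with a probability).
#' @export
probability_histogram <- function(records,
                                  which = c("prenylation", "cleavage"),
                                  bins = 20L, class_column = "klass") {
  which <- match.arg(which)
  col <- paste0(which, "_probability")
  if (!col %in% names(records)) stop("no column '", col, "' in records")
  p <- records[[col]]
  if (all(is.na(p))) {
    stop("no calibrated probabilities present in '", col, "'")
  }
  keep <- !is.na(p)
  p <- p[keep]
  stopifnot(all(p >= 0 & p <= 1))
  breaks <- seq(0, 1, length.out = bins + 1L)
  bin <- pmin(findInterval(p, breaks, rightmost.closed = TRUE), bins)
  cls <- as.character(records[[class_column]])[keep]
  classes <- sort(unique(cls))
  counts <- t(vapply(classes, function(k) {
    tabulate(bin[cls == k], nbins = bins)
  }, numeric(bins)))
  rownames(counts) <- classes
  list(breaks = breaks, mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
       counts = counts)
}

#' Write per-motif predictions as TSV
#' @param x A `space_prediction` or its `records`.
#' @param path Output TSV path.
#' @export
write_prediction_tsv <- function(x, path) {
  records <- if (inherits(x, "space_prediction")) x$records else x
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
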