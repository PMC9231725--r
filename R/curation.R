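#' Curation thresholds and exclusion lists
#'
#' Defaults follow the screen analysis this package models: prenylation
#' positives require an enrichment score strictly greater than 3 at 37C and
#' at least 5 occurrences; negatives require enrichment at most 0.036 at 37C
#' and at least 5 occurrences at 25C. Exclusion lists (motifs native to the
#' host proteome, motifs previously built into reporters, motifs genetically
#' confirmed as cleaved) are explicit inputs so users can substitute their
#' own proteome.
#'
#' @param pos_enrichment_min Exclusive lower bound on 37C enrichment for
#'   positives (default 3).
#' @param pos_occurrence_min Inclusive minimum 37C occurrence count
#'   (default 5).
#' @param neg_enrichment_max Inclusive upper bound on 37C enrichment for
#'   negatives (default 0.036).
#' @param neg_occurrence_min_25C Inclusive minimum 25C occurrence count for
#'   negatives (default 5).
#' @param proteome_exclusions,reporter_exclusions,confirmed_cleaved_exclusions
#'   Character vectors of motifs to remove during curation.
#' @return List of class `curation_config`.
#' @export
curation_config <- function(pos_enrichment_min = 3,
                            pos_occurrence_min = 5L,
                            neg_enrichment_max = 0.036,
                            neg_occurrence_min_25C = 5L,
                            proteome_exclusions = character(),
                            reporter_exclusions = character(),
                            confirmed_cleaved_exclusions = character()) {
  stopifnot(pos_enrichment_min >= 0, pos_occurrence_min >= 0,
            neg_enrichment_max >= 0, neg_occurrence_min_25C >= 0)
  structure(
    list(
      pos_enrichment_min = pos_enrichment_min,
      pos_occurrence_min = as.integer(pos_occurrence_min),
      neg_enrichment_max = neg_enrichment_max,
      neg_occurrence_min_25C = as.integer(neg_occurrence_min_25C),
      proteome_exclusions = toupper(proteome_exclusions),
      reporter_exclusions = toupper(reporter_exclusions),
      confirmed_cleaved_exclusions = toupper(confirmed_cleaved_exclusions)
    ),
    class = "curation_config"
  )
}

check_screen_records <- function(records) {
  need <- c("motif", "enrichment_37C", "occurrences_37C", "occurrences_25C")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("screen table lacks column(s): ", paste(miss, collapse = ", "))
  }
  records$motif <- as.character(parse_motif(records$motif))
  if (any(records$enrichment_37C < 0, na.rm = TRUE) ||
      any(records$occurrences_37C < 0, na.rm = TRUE) ||
      any(records$occurrences_25C < 0, na.rm = TRUE)) {
    stop("screen counts and enrichment scores must be non-negative")
  }
  records
}

#' Select prenylation-positive hits from a Ras61 screen table
#'
#' Motifs with `enrichment_37C` strictly greater than the positive threshold
#' and `occurrences_37C` at or above the occurrence minimum; deduplicated.
#'
#' @param records data.frame with columns `motif`, `enrichment_37C`,
#'   `occurrences_37C`, `occurrences_25C`.
#' @param cfg A [curation_config()].
#' @return Character vector of unique motifs.
#' @export
select_ras61_positives <- function(records, cfg = curation_config()) {
  records <- check_screen_records(records)
  keep <- records$enrichment_37C > cfg$pos_enrichment_min &
    records$occurrences_37C >= cfg$pos_occurrence_min
  unique(records$motif[keep])
}

#' Select prenylation-negative hits from a Ras61 screen table
#'
#' Motifs with `enrichment_37C` at or below the negative threshold
#' (inclusive) and `occurrences_25C` at or above the 25C occurrence minimum.
#'
#' @inheritParams select_ras61_positives
#' @return Character vector of unique motifs.
#' @export
select_ras61_negatives <- function(records, cfg = curation_config()) {
  records <- check_screen_records(records)
  keep <- records$enrichment_37C <= cfg$neg_enrichment_max &
    records$occurrences_25C >= cfg$neg_occurrence_min_25C
  unique(records$motif[keep])
}

drop_motifs <- function(set, exclusions, what) {
  absent <- setdiff(exclusions, set)
  if (length(absent)) {
    warning("exclusion motif(s) not present in ", what, ": ",
            paste(absent, collapse = ", "))
  }
  setdiff(set, exclusions)
}

new_training_set <- function(task, positives, negatives) {
  positives <- unique(toupper(positives))
  negatives <- unique(toupper(negatives))
  overlap <- intersect(positives, negatives)
  if (length(overlap)) {
    stop("curated positives and negatives overlap for task '", task, "': ",
         paste(overlap, collapse = ", "))
  }
  structure(
    list(task = task, positives = positives, negatives = negatives),
    class = "training_set"
  )
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("<training_set: %s>  %d positives, %d negatives\n",
              x$task, length(x$positives), length(x$negatives)))
  invisible(x)
}

#' Curate the prenylation training set
#'
#' Positives are the union of Ras61 and Ydj1 screen hits (duplicates between
#' the screens collapse in the union) minus proteome-native and
#' reporter-incorporated motifs; negatives are the low-scoring Ras61 motifs
#' minus proteome-native motifs. Final positives and negatives must be
#' disjoint.
#'
#' @param ras61_pos,ydj1_pos,ras61_neg Character vectors of motifs.
#' @param cfg A [curation_config()] carrying the exclusion lists.
#' @return A `training_set` with `task = "prenylation"`.
#' @export
curate_prenylation_sets <- function(ras61_pos, ydj1_pos, ras61_neg,
                                    cfg = curation_config()) {
  pos <- union(unique(toupper(ras61_pos)), unique(toupper(ydj1_pos)))
  pos <- drop_motifs(pos, intersect(cfg$proteome_exclusions, pos),
                     "prenylation positives")
  pos <- drop_motifs(pos, intersect(cfg$reporter_exclusions, pos),
                     "prenylation positives")
  neg <- unique(toupper(ras61_neg))
  neg <- setdiff(neg, cfg$proteome_exclusions)
  new_training_set("prenylation", pos, neg)
}

#' Curate the cleavage training set
#'
#' Positives (cleaved) are the top-scoring Ras61 motifs minus any that
#' overlap the Ydj1 screen, are proteome-native, or were previously
#' incorporated into reporters. Negatives (shunted) are the Ydj1 screen hits
#' minus motifs genetically confirmed to be canonically modified,
#' proteome-native motifs, and reporter-incorporated motifs.
#'
#' @param ras61_top Character vector: top-scoring Ras61 screen motifs.
#' @param ydj1_hits Character vector: Ydj1 screen motifs.
#' @param cfg A [curation_config()] carrying the exclusion lists.
#' @return A `training_set` with `task = "cleavage"`.
#' @export
curate_cleavage_sets <- function(ras61_top, ydj1_hits,
                                 cfg = curation_config()) {
  ras61_top <- unique(toupper(ras61_top))
  ydj1_hits <- unique(toupper(ydj1_hits))
  pos <- setdiff(ras61_top, ydj1_hits)
  pos <- setdiff(pos, cfg$proteome_exclusions)
  pos <- setdiff(pos, cfg$reporter_exclusions)
  neg <- drop_motifs(ydj1_hits, cfg$confirmed_cleaved_exclusions,
                     "cleavage negatives")
  neg <- setdiff(neg, cfg$proteome_exclusions)
  neg <- setdiff(neg, cfg$reporter_exclusions)
  new_training_set("cleavage", pos, neg)
}

#' Load an already-curated training set from a CSV file
#'
#' For the path where only the final curated lists are available (no raw
#' screen tables): a two-column CSV with `motif` and `label`
#' (positive/negative, or 1/0) is ingested directly.
#'
#' @param path CSV file path.
#' @param task `"prenylation"` or `"cleavage"`.
#' @return A `training_set`.
#' @export
read_training_set <- function(path, task = c("prenylation", "cleavage")) {
  task <- match.arg(task)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("motif", "label") %in% names(df))) {
    stop("training-set file needs columns 'motif' and 'label'")
  }
  lab <- tolower(as.character(df$label))
  is_pos <- lab %in% c("positive", "pos", "1", "true", "cleaved")
  is_neg <- lab %in% c("negative", "neg", "0", "false", "shunted")
  if (!all(is_pos | is_neg)) {
    stop("unrecognized label(s): ",
         paste(unique(df$label[!(is_pos | is_neg)]), collapse = ", "))
  }
  new_training_set(task,
                   as.character(parse_motif(df$motif[is_pos])),
                   as.character(parse_motif(df$motif[is_neg])))
}

#' Write a training set to CSV
#' @param ts A `training_set`.
#' @param path Output CSV path.
#' @export
write_training_set <- function(ts, path) {
  stopifnot(inherits(ts, "training_set"))
  df <- data.frame(
    motif = c(ts$positives, ts$negatives),
    label = rep(c("positive", "negative"),
                c(length(ts$positives), length(ts$negatives))),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Labels and motifs of a training set in modelling order
#' @param ts A `training_set`.
#' @return List with `motifs` (character) and `labels` (integer 0/1).
#' @export
training_matrix <- function(ts) {
  stopifnot(inherits(ts, "training_set"))
  list(
    motifs = c(ts$positives, ts$negatives),
    labels = rep(c(1L, 0L), c(length(ts$positives), length(ts$negatives)))
  )
}

#' Read a plain-text exclusion list (one motif per line)
#' @param path File path; lines starting with `#` are skipped.
#' @return Character vector of motifs.
#' @export
read_motif_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  as.character(parse_motif(lines))
}
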