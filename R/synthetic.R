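# Residue pools for the synthetic sequence models. Canonical CaaX-like
# positives are aliphatic at the a-positions; non-canonical (Ydj1-like)
# positives are polar-uncharged; negatives carry charged residues.
POLAR_UNCHARGED <- c("S", "T", "N", "Q", "A", "G", "H")
NEG_CHARGED <- c("D", "E", "K", "R")
NON_CHARGED <- setdiff(AA_ALPHABET, CHARGED)

sample_canonical <- function(n, aliphatic_enrichment) {
  x1 <- ifelse(stats::runif(n) < 0.5, sample(ALIPHATIC, n, replace = TRUE),
               sample(NON_CHARGED, n, replace = TRUE))
  x2 <- ifelse(stats::runif(n) < aliphatic_enrichment,
               sample(ALIPHATIC, n, replace = TRUE),
               sample(AA_ALPHABET, n, replace = TRUE))
  x3 <- sample(AA_ALPHABET, n, replace = TRUE)
  paste0("C", x1, x2, x3)
}

sample_noncanonical <- function(n) {
  draw <- function() {
    ifelse(stats::runif(n) < 0.8,
           sample(POLAR_UNCHARGED, n, replace = TRUE),
           sample(AA_ALPHABET, n, replace = TRUE))
  }
  paste0("C", draw(), draw(), draw())
}

sample_negative <- function(n, charge_bias) {
  x <- matrix(sample(AA_ALPHABET, 3L * n, replace = TRUE), ncol = 3L)
  charged <- stats::runif(n) < charge_bias
  pos <- sample(1:2, n, replace = TRUE)
  x[cbind(which(charged), pos[charged])] <-
    sample(NEG_CHARGED, sum(charged), replace = TRUE)
  paste0("C", x[, 1], x[, 2], x[, 3])
}

# Draw until `n` unique motifs not in `avoid` are collected.
sample_unique <- function(n, sampler, avoid = character()) {
  out <- character()
  tries <- 0L
  while (length(out) < n) {
    cand <- setdiff(unique(sampler(2L * n)), c(avoid, out))
    out <- c(out, cand)[seq_len(min(n, length(out) + length(cand)))]
    tries <- tries + 1L
    if (tries > 100L) stop("motif space exhausted while sampling")
  }
  out
}

#' Configuration of a synthetic prenylation screen
#'
#' Describes the sequence and score model of a simulated reporter screen:
#' positives mix a canonical CaaX component (aliphatic a-positions, with
#' `aliphatic_enrichment` the probability that x2 is drawn from L/I/V) with
#' a non-canonical polar component at `1 - canonical_fraction`; negatives
#' carry a charged residue at x1 or x2 with probability
#' `negative_charge_bias`. Enrichment scores are drawn log-normally around
#' the class means and clamped to the eligible side of the default curation
#' thresholds; occurrence counts are uniform over `occurrence_range`.
#'
#' @param n_positive,n_negative Class sizes.
#' @param aliphatic_enrichment Probability a canonical positive draws x2
#'   from L/I/V (default 0.9).
#' @param negative_charge_bias Probability a negative carries a charged
#'   residue at x1 or x2 (default 0.7).
#' @param canonical_fraction Fraction of positives from the canonical
#'   component (default 1: a strongly separated screen).
#' @param enrichment_score_means Named class means of the 37C enrichment
#'   score.
#' @param occurrence_range Inclusive range for occurrence counts.
#' @param seed Integer seed.
#' @return List of class `synthetic_screen_config`.
#' @export
synthetic_screen_config <- function(n_positive = 500L, n_negative = 500L,
                                    aliphatic_enrichment = 0.9,
                                    negative_charge_bias = 0.7,
                                    canonical_fraction = 1,
                                    enrichment_score_means = c(positive = 8,
                                                               negative = 0.01),
                                    occurrence_range = c(5L, 50L),
                                    seed = 1L) {
  stopifnot(n_positive > 0, n_negative > 0,
            aliphatic_enrichment >= 0, aliphatic_enrichment <= 1,
            negative_charge_bias >= 0, negative_charge_bias <= 1,
            canonical_fraction >= 0, canonical_fraction <= 1)
  structure(list(n_positive = as.integer(n_positive),
                 n_negative = as.integer(n_negative),
                 aliphatic_enrichment = aliphatic_enrichment,
                 negative_charge_bias = negative_charge_bias,
                 canonical_fraction = canonical_fraction,
                 enrichment_score_means = enrichment_score_means,
                 occurrence_range = as.integer(occurrence_range),
                 seed = as.integer(seed)),
            class = "synthetic_screen_config")
}

# enrichment scores strictly above `at_least`, log-normal-shaped
enrich_above <- function(n, at_least, meanlog_shift = 0.4) {
  at_least * exp(abs(stats::rnorm(n, meanlog_shift, 0.5))) + 1e-6
}

# enrichment scores at or below `at_most`
enrich_below <- function(n, at_most) {
  at_most * exp(-abs(stats::rnorm(n, 0.8, 0.6)))
}

#' Generate a synthetic screen hit table with known ground truth
#'
#' Deterministic under `cfg$seed`. Positive rows pass the default positive
#' curation filter (enrichment > 3 at 37C, >= 5 occurrences) and negative
#' rows pass the negative filter (enrichment <= 0.036, >= 5 occurrences at
#' 25C).
#'
#' @param cfg A [synthetic_screen_config()].
#' @return data.frame with columns `motif`, `enrichment_37C`,
#'   `occurrences_37C`, `occurrences_25C`, `source`, `truth` (1 positive /
#'   0 negative).
#' @export
generate_screen <- function(cfg = synthetic_screen_config()) {
  stopifnot(inherits(cfg, "synthetic_screen_config"))
  dcfg <- curation_config()
  with_local_seed(cfg$seed, {
    n_canon <- round(cfg$canonical_fraction * cfg$n_positive)
    pos <- sample_unique(n_canon, function(n) {
      sample_canonical(n, cfg$aliphatic_enrichment)
    })
    if (n_canon < cfg$n_positive) {
      pos <- c(pos, sample_unique(cfg$n_positive - n_canon,
                                  sample_noncanonical, avoid = pos))
    }
    neg <- sample_unique(cfg$n_negative, function(n) {
      sample_negative(n, cfg$negative_charge_bias)
    }, avoid = pos)
    occ <- function(n) {
      sample(seq(cfg$occurrence_range[1], cfg$occurrence_range[2]), n,
             replace = TRUE)
    }
    data.frame(
      motif = c(pos, neg),
      enrichment_37C = c(enrich_above(length(pos), dcfg$pos_enrichment_min),
                         enrich_below(length(neg), dcfg$neg_enrichment_max)),
      occurrences_37C = occ(length(pos) + length(neg)),
      occurrences_25C = occ(length(pos) + length(neg)),
      source = "Ras61",
      truth = rep(c(1L, 0L), c(length(pos), length(neg))),
      stringsAsFactors = FALSE
    )
  })
}

#' Synthetic stand-in for the deposited screen training-set archive
#'
#' Builds Ras61 and Ydj1 screen tables plus exclusion lists whose
#' cardinalities and overlap structure reproduce the published curation
#' arithmetic: 369 Ras61 prenylation positives and 153 Ydj1 hits sharing 8
#' motifs, 21 proteome-native and 4 reporter-incorporated motifs among the
#' positives (union 514 -> 489), 514 negatives with 6 proteome-native
#' motifs (-> 508); the 153 top-scoring Ras61 motifs overlap Ydj1 by 2 and
#' contain 8 proteome-native and 3 reporter motifs (-> 140 cleaved), and
#' the Ydj1 set carries 15 confirmed-cleaved, 1 proteome-native and 1
#' reporter motif (-> 136 shunted). Motif identities are synthetic draws
#' from the screen sequence models; only the structure is fixed.
#'
#' @param seed Integer seed.
#' @param aliphatic_enrichment,negative_charge_bias Sequence-model
#'   parameters shared with [generate_screen()].
#' @return List: `ras61_screen` (hit table including sub-threshold filler
#'   rows), `ras61_top` (the 153 top-scoring positive motifs), `ydj1_hits`,
#'   `config` (a [curation_config()] carrying the exclusion lists).
#' @export
synthetic_screen_archive <- function(seed = 1L,
                                     aliphatic_enrichment = 0.9,
                                     negative_charge_bias = 0.7) {
  dcfg <- curation_config()
  with_local_seed(seed, {
    ras61_pos <- sample_unique(369L, function(n) {
      sample_canonical(n, aliphatic_enrichment)
    })
    ydj1_only <- sample_unique(145L, sample_noncanonical, avoid = ras61_pos)
    negatives <- sample_unique(514L, function(n) {
      sample_negative(n, negative_charge_bias)
    }, avoid = c(ras61_pos, ydj1_only))
    filler <- sample_unique(40L, function(n) {
      paste0("C", sample(AA_ALPHABET, n, TRUE), sample(AA_ALPHABET, n, TRUE),
             sample(AA_ALPHABET, n, TRUE))
    }, avoid = c(ras61_pos, ydj1_only, negatives))

    # enrichment: the first 153 positives are the top scorers; the rest sit
    # strictly between the positive threshold and the top block
    enr_pos <- c(enrich_above(153L, 8), stats::runif(216L, 3.001, 7.9))
    top153 <- ras61_pos[1:153]
    # Ydj1 overlaps Ras61 by 8 motifs: 2 inside the top 153, 6 outside
    overlap <- c(top153[1:2], ras61_pos[154:159])
    ydj1_hits <- c(ydj1_only, overlap)

    # slots for exclusion lists, all pairwise disjoint within each pool;
    # top153[1:2] are the Ydj1 overlap, so proteome/reporter slots start at 3
    proteome <- c(top153[3:10],          # 8 proteome-native among top Ras61
                  ras61_pos[160:171],    # 12 among the remaining positives
                  ydj1_only[1],          # 1 among Ydj1-only hits
                  negatives[1:6])        # 6 among the negatives
    reporter <- c(top153[11:13], ydj1_only[2])
    confirmed_cleaved <- ydj1_only[3:17]

    occ <- function(n) sample(5:60, n, replace = TRUE)
    ras61_screen <- data.frame(
      motif = c(ras61_pos, negatives, filler),
      enrichment_37C = c(enr_pos,
                         enrich_below(514L, dcfg$neg_enrichment_max),
                         stats::runif(40L, 0.05, 2.9)),
      occurrences_37C = occ(369L + 514L + 40L),
      occurrences_25C = occ(369L + 514L + 40L),
      source = "Ras61",
      stringsAsFactors = FALSE
    )
    list(
      ras61_screen = ras61_screen,
      ras61_top = top153,
      ydj1_hits = ydj1_hits,
      config = curation_config(
        proteome_exclusions = proteome,
        reporter_exclusions = reporter,
        confirmed_cleaved_exclusions = confirmed_cleaved
      )
    )
  })
}

#' Curate both training sets from a synthetic screen archive
#'
#' Runs the full curation path (threshold selection on the Ras61 table,
#' union with Ydj1 hits, exclusion-list removal) on a
#' [synthetic_screen_archive()].
#'
#' @param archive A [synthetic_screen_archive()].
#' @return List with `prenylation` and `cleavage` `training_set`s.
#' @export
curate_archive <- function(archive) {
  ras61_pos <- select_ras61_positives(archive$ras61_screen, archive$config)
  ras61_neg <- select_ras61_negatives(archive$ras61_screen, archive$config)
  list(
    prenylation = curate_prenylation_sets(ras61_pos, archive$ydj1_hits,
                                          ras61_neg, archive$config),
    cleavage = curate_cleavage_sets(archive$ras61_top, archive$ydj1_hits,
                                    archive$config)
  )
}

#' Generate a synthetic validation table with configurable agreement
#'
#' Observed prenylation calls are fair coin flips; observed cleavage is
#' flipped only for prenylated motifs (cleavage is prenyl-dependent,
#' non-prenylated rows carry NA). Each method's calls agree with the
#' observation independently with the configured probability.
#'
#' @param methods Method names; prenylation columns are created for each,
#'   and cleavage columns (`<m>_cleave`) for methods in `cleavage_methods`.
#' @param n Number of motifs.
#' @param agreement Scalar or per-method named vector of agreement
#'   probabilities in `[0, 1]`.
#' @param seed Integer seed.
#' @param cleavage_methods Methods that also call cleavage (default svm and
#'   freq).
#' @return Validation-table data.frame.
#' @export
generate_validation_table <- function(methods = c("svm", "preps", "freq",
                                                  "fpb"),
                                      n = 50L, agreement = 0.8, seed = 1L,
                                      cleavage_methods =
                                        intersect(methods, c("svm", "freq"))) {
  if (is.null(names(agreement))) {
    agreement <- stats::setNames(rep_len(agreement, length(methods)), methods)
  }
  stopifnot(all(agreement >= 0 & agreement <= 1))
  with_local_seed(seed, {
    motifs <- sample_unique(n, function(m) {
      paste0("C", sample(AA_ALPHABET, m, TRUE), sample(AA_ALPHABET, m, TRUE),
             sample(AA_ALPHABET, m, TRUE))
    })
    obs_pren <- ifelse(stats::runif(n) < 0.5, "+", "-")
    obs_cleave <- ifelse(obs_pren == "+",
                         ifelse(stats::runif(n) < 0.5, "+", "-"),
                         NA_character_)
    flip <- function(x) ifelse(x == "+", "-", "+")
    df <- data.frame(motif = motifs, stringsAsFactors = FALSE)
    for (m in methods) {
      agree <- stats::runif(n) < agreement[[m]]
      df[[m]] <- ifelse(agree, obs_pren, flip(obs_pren))
    }
    df$observed_prenylation <- obs_pren
    for (m in cleavage_methods) {
      agree <- stats::runif(n) < agreement[[m]]
      df[[paste0(m, "_cleave")]] <- ifelse(is.na(obs_cleave), NA_character_,
                                           ifelse(agree, obs_cleave,
                                                  flip(obs_cleave)))
    }
    df$observed_cleavage <- obs_cleave
    df
  })
}

#' Generate a syntactically valid AAindex1 fixture
#'
#' Emits `k` synthetic property records in the AAindex1 flat-file layout
#' (H/D/I lines, two rows of ten values, `//` terminators). Values are
#' rounded to three decimals and attached as the `values` attribute (k x 20
#' matrix in [AA_ALPHABET] order) so round-trips through [parse_aaindex()]
#' can be checked exactly. The first `n_missing` records carry an NA token.
#'
#' @param k Number of records (>= 1).
#' @param seed Integer seed.
#' @param n_missing Number of records given a missing value (default 0).
#' @return Character vector of file lines with attributes `values` and
#'   `accession`.
#' @export
generate_aaindex_fixture <- function(k, seed = 1L, n_missing = 0L) {
  stopifnot(k >= 1, n_missing <= k)
  i_order <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  with_local_seed(seed, {
    vals <- matrix(round(stats::runif(20L * k, -2, 5), 3), nrow = k)
    colnames(vals) <- i_order
    acc <- sprintf("SYNTH%03d", seq_len(k))
    lines <- character()
    for (i in seq_len(k)) {
      v <- vals[i, ]
      tok <- sprintf("%8.3f", v)
      if (n_missing >= i) {
        miss_at <- sample(20L, 1L)
        vals[i, miss_at] <- NA_real_
        tok[miss_at] <- sprintf("%8s", "NA")
      }
      lines <- c(
        lines,
        paste0("H ", acc[i]),
        paste0("D Synthetic amino acid property ", i,
               " (randomly generated fixture)"),
        "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
        paste0(" ", paste(tok[1:10], collapse = "")),
        paste0(" ", paste(tok[11:20], collapse = "")),
        "//"
      )
    }
    out <- lines
    attr(out, "values") <- vals[, AA_ALPHABET, drop = FALSE]
    attr(out, "accession") <- acc
    out
  })
}
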