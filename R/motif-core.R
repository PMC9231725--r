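#' The 20-letter amino acid alphabet
#'
#' Canonical one-letter codes in fixed alphabetical order. All encodings and
#' scoring tables in this package index residues in this order, so the order
#' is part of every serialized model.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

#' Aliphatic (branched-chain) residues used throughout the CaaX literature
#' @keywords internal
ALIPHATIC <- c("L", "I", "V")

#' Charged residues
#' @keywords internal
CHARGED <- c("D", "E", "K", "R", "H")

#' Parse and validate a Cxxx motif
#'
#' A Cxxx motif is a four-residue C-terminal sequence whose first residue is
#' the invariant cysteine; the three variable positions (x1, x2, x3) may be
#' any of the 20 canonical residues. Input is upper-cased before validation.
#' Ambiguity codes (B, J, O, U, X, Z) and non-residue characters are
#' rejected rather than imputed.
#'
#' @param text Character vector of candidate motifs.
#' @return Character vector of validated upper-case motifs (class
#'   `cxxx_motif`).
#' @examples
#' parse_motif("CVIA")
#' parse_motif(c("cvia", "CASQ"))
#' @export
parse_motif <- function(text) {
  if (!is.character(text) || length(text) == 0) {
    stop("motifs must be a non-empty character vector")
  }
  up <- toupper(text)
  bad_len <- nchar(up) != 4L
  if (any(bad_len)) {
    stop("motif(s) not of length 4: ", paste(text[bad_len], collapse = ", "))
  }
  no_cys <- substr(up, 1L, 1L) != "C"
  if (any(no_cys)) {
    stop("motif(s) lacking the invariant leading Cys: ",
         paste(text[no_cys], collapse = ", "))
  }
  tail3 <- strsplit(substr(up, 2L, 4L), "", fixed = TRUE)
  bad_aa <- vapply(tail3, function(ch) !all(ch %in% AA_ALPHABET), logical(1))
  if (any(bad_aa)) {
    stop("motif(s) containing non-canonical residues: ",
         paste(text[bad_aa], collapse = ", "))
  }
  structure(up, class = "cxxx_motif")
}

#' Residues at the three variable motif positions
#'
#' @param motifs Validated motifs (or strings coercible through
#'   [parse_motif()]).
#' @return n x 3 character matrix with columns x1, x2, x3.
#' @export
motif_positions <- function(motifs) {
  motifs <- as.character(parse_motif(as.character(motifs)))
  m <- matrix("", nrow = length(motifs), ncol = 3L,
              dimnames = list(motifs, c("x1", "x2", "x3")))
  for (p in 1:3) m[, p] <- substr(motifs, p + 1L, p + 1L)
  m
}

#' Enumerate the full Cxxx sequence space
#'
#' All 20^3 = 8000 motifs C-x1-x2-x3, in lexicographic order of the variable
#' positions under the alphabetical residue order. Deterministic across runs.
#'
#' @return Character vector of 8000 motifs.
#' @examples
#' space <- enumerate_cxxx_space()
#' length(space)   # 8000
#' space[1]        # "CAAA"
#' @export
enumerate_cxxx_space <- function() {
  g <- expand.grid(x3 = AA_ALPHABET, x2 = AA_ALPHABET, x1 = AA_ALPHABET,
                   stringsAsFactors = FALSE)
  paste0("C", g$x1, g$x2, g$x3)
}

#' Extract the C-terminal Cxxx motif of a protein sequence
#'
#' Returns the last four residues as a motif when the fourth-from-last
#' residue is cysteine, otherwise `NA`. A single trailing stop symbol `*`
#' (common FASTA dialect) is stripped first; sequences shorter than four
#' residues yield `NA`. Non-residue characters within the last four
#' positions are an error.
#'
#' @param sequences Character vector of protein sequences.
#' @return Character vector: the motif, or `NA` where the terminus is not
#'   Cxxx or the sequence is too short.
#' @examples
#' extract_cterminal_motif("MKLSDQCVIA")   # "CVIA"
#' extract_cterminal_motif("MKLSDQAVIA")   # NA
#' @export
extract_cterminal_motif <- function(sequences) {
  sequences <- toupper(as.character(sequences))
  sequences <- sub("\\*$", "", sequences)
  if (any(grepl("*", sequences, fixed = TRUE))) {
    stop("internal stop symbol '*' in protein sequence")
  }
  out <- rep(NA_character_, length(sequences))
  long_enough <- nchar(sequences) >= 4L
  tail4 <- substr(sequences[long_enough],
                  nchar(sequences[long_enough]) - 3L,
                  nchar(sequences[long_enough]))
  bad <- vapply(strsplit(tail4, "", fixed = TRUE),
                function(ch) !all(ch %in% AA_ALPHABET), logical(1))
  if (any(bad)) {
    stop("non-canonical residues in the C-terminal four positions: ",
         paste(tail4[bad], collapse = ", "))
  }
  has_cys <- substr(tail4, 1L, 1L) == "C"
  motif <- rep(NA_character_, length(tail4))
  if (any(has_cys)) {
    motif[has_cys] <- as.character(parse_motif(tail4[has_cys]))
  }
  out[long_enough] <- motif
  out
}

#' Scan a protein FASTA file for C-terminal Cxxx motifs
#'
#' @param fasta Path to a protein FASTA file, or a
#'   [Biostrings::AAStringSet].
#' @return data.frame with columns `id`, `sequence_length`, `motif` (NA for
#'   proteins not ending in Cxxx) and `eligible`.
#' @export
read_proteome_motifs <- function(fasta) {
  if (is.character(fasta)) {
    aa <- Biostrings::readAAStringSet(fasta)
  } else {
    aa <- fasta
  }
  seqs <- as.character(aa)
  ids <- names(aa)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  motif <- extract_cterminal_motif(seqs)
  data.frame(
    id = ids,
    sequence_length = nchar(sub("\\*$", "", seqs)),
    motif = motif,
    eligible = !is.na(motif),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
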