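# Shared fixtures built in code at test time.

toy_pssm_sets <- function() {
  list(positives = c("CVIA", "CVIS"),
       negatives = c("CDDD", "CEEE"))
}

uniform_background <- function() {
  stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
}

validation_fixture <- function() {
  read_validation_table(
    system.file("extdata", "validation_calls.csv", package = "caaxpred")
  )
}

# Small archive-independent training set with clean class structure.
separable_screen <- function(n = 200L, seed = 7L) {
  generate_screen(synthetic_screen_config(
    n_positive = n, n_negative = n,
    aliphatic_enrichment = 1, negative_charge_bias = 1, seed = seed
  ))
}

write_temp_fasta <- function(records) {
  path <- tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(names(records), function(id) {
    c(paste0(">", id), records[[id]])
  })), path)
  path
}

# memoised synthetic archive + curated sets shared across test files
archive_cache <- new.env(parent = emptyenv())
cached_archive <- function(seed = 1L) {
  key <- paste0("a", seed)
  if (is.null(archive_cache[[key]])) {
    archive_cache[[key]] <- synthetic_screen_archive(seed = seed)
  }
  archive_cache[[key]]
}
cached_sets <- function(seed = 1L) {
  key <- paste0("s", seed)
  if (is.null(archive_cache[[key]])) {
    archive_cache[[key]] <- curate_archive(cached_archive(seed))
  }
  archive_cache[[key]]
}
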