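#' One-hot encoding of Cxxx motifs
#'
#' Each of the three variable positions contributes a 20-column block in the
#' alphabetical residue order of [AA_ALPHABET], giving a 60-column matrix.
#' Column `20*(p-1)+a` is 1 iff the motif carries alphabet residue `a` at
#' variable position `p`; every row sums to 3. The invariant cysteine is not
#' encoded.
#'
#' @param motifs Character vector of motifs.
#' @return Numeric n x 60 matrix with class attribute `feature_matrix` and
#'   attribute `scheme = "sequence"`; rownames are the motifs.
#' @export
encode_onehot <- function(motifs) {
  pos <- motif_positions(motifs)
  n <- nrow(pos)
  cols <- as.vector(outer(AA_ALPHABET, paste0("x", 1:3),
                          function(a, p) paste0(p, ".", a)))
  m <- matrix(0, nrow = n, ncol = 60L, dimnames = list(rownames(pos), cols))
  for (p in 1:3) {
    idx <- match(pos[, p], AA_ALPHABET)
    m[cbind(seq_len(n), 20L * (p - 1L) + idx)] <- 1
  }
  feature_matrix(m, scheme = "sequence")
}

#' Decode one-hot rows back to motifs
#' @param m Matrix produced by [encode_onehot()].
#' @return Character vector of motifs.
#' @export
decode_onehot <- function(m) {
  stopifnot(ncol(m) == 60L)
  res <- vapply(seq_len(nrow(m)), function(i) {
    paste0("C", paste(vapply(1:3, function(p) {
      block <- m[i, (20L * (p - 1L) + 1L):(20L * p)]
      AA_ALPHABET[which.max(block)]
    }, character(1)), collapse = ""))
  }, character(1))
  res
}

feature_matrix <- function(m, scheme) {
  stopifnot(is.matrix(m), !anyNA(m))
  attr(m, "scheme") <- scheme
  class(m) <- c("feature_matrix", class(m))
  m
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix: %s>  %d motifs x %d features\n",
              attr(x, "scheme"), nrow(x), ncol(x)))
  invisible(x)
}

feature_scheme <- function(m) attr(m, "scheme")

#' Parse an AAindex1 flat file
#'
#' The AAindex1 format stores one amino acid property per record: an `H`
#' accession line, `D` description, an `I` line naming the residue order
#' (A/L R/K N/M D/F C/P Q/S E/T G/W H/Y I/V) followed by two data lines of
#' ten values each, and a `//` terminator. `NA` tokens mark missing values.
#'
#' @param path Path to an AAindex1-format file (or a character vector of its
#'   lines).
#' @return data.frame with one row per record: `accession`, `description`,
#'   `has_missing`, and 20 residue columns in [AA_ALPHABET] order.
#' @export
parse_aaindex <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) {
    readLines(path, warn = FALSE)
  } else {
    as.character(path)
  }
  # residue order on the standard I line, top row then bottom row
  i_order <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  recs <- list()
  i <- 1L
  acc <- NULL; desc <- ""; vals <- NULL
  flush <- function() {
    if (is.null(acc)) return(invisible())
    stop("AAindex record ended without value block: ", acc)
  }
  while (i <= length(lines)) {
    line <- lines[i]
    tag <- substr(line, 1L, 1L)
    if (tag == "H") {
      acc <- trimws(substr(line, 2L, nchar(line)))
      desc <- ""
      vals <- NULL
    } else if (tag == "D") {
      desc <- trimws(substr(line, 2L, nchar(line)))
      # description may continue on indented lines
      while (i + 1L <= length(lines) && grepl("^\\s", lines[i + 1L])) {
        i <- i + 1L
        desc <- paste(desc, trimws(lines[i]))
      }
    } else if (tag == "I") {
      if (i + 2L > length(lines)) {
        stop("truncated value block in AAindex record ",
             if (is.null(acc)) "<unknown>" else acc)
      }
      toks <- unlist(strsplit(trimws(paste(lines[i + 1L], lines[i + 2L])),
                              "\\s+"))
      if (length(toks) != 20L) {
        stop("AAindex record ", if (is.null(acc)) "<unknown>" else acc,
             " has ", length(toks), " values, expected 20")
      }
      vals <- suppressWarnings(as.numeric(toks))
      vals[toupper(toks) == "NA"] <- NA_real_
      bad <- is.na(vals) & toupper(toks) != "NA"
      if (any(bad)) {
        stop("unparseable value(s) in AAindex record ", acc, ": ",
             paste(toks[bad], collapse = ", "))
      }
      i <- i + 2L
    } else if (startsWith(line, "//")) {
      if (is.null(acc) || is.null(vals)) {
        stop("malformed AAindex record terminator at line ", i)
      }
      names(vals) <- i_order
      recs[[length(recs) + 1L]] <- c(
        list(accession = acc, description = desc,
             has_missing = anyNA(vals)),
        as.list(vals[AA_ALPHABET])
      )
      acc <- NULL; vals <- NULL
    }
    i <- i + 1L
  }
  if (!is.null(acc)) flush()
  if (!length(recs)) stop("no AAindex records found")
  out <- do.call(rbind, lapply(recs, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Encode motifs with AAindex physico-biochemical properties
#'
#' Each usable AAindex entry contributes one column per variable position
#' (d = 3K for K entries). Before lookup, each index's 20 residue values are
#' min-max rescaled to the unit interval, so the encoding is a fixed
#' property of the index set and independent of any training sample. An
#' index that is constant across residues rescales to all zeros. Entries
#' with missing values are dropped by default.
#'
#' @param motifs Character vector of motifs.
#' @param entries data.frame from [parse_aaindex()].
#' @param drop_missing Drop entries flagged `has_missing` (default TRUE).
#' @return Numeric n x 3K `feature_matrix` with `scheme = "aaindex"`.
#' @export
encode_aaindex <- function(motifs, entries, drop_missing = TRUE) {
  if (drop_missing) entries <- entries[!entries$has_missing, , drop = FALSE]
  if (!nrow(entries)) stop("no usable AAindex entries")
  vals <- as.matrix(entries[, AA_ALPHABET, drop = FALSE])  # K x 20
  rng <- apply(vals, 1L, function(v) diff(range(v)))
  lo <- apply(vals, 1L, min)
  scaled <- (vals - lo) / ifelse(rng == 0, 1, rng)
  scaled[rng == 0, ] <- 0
  pos <- motif_positions(motifs)
  K <- nrow(entries)
  out <- matrix(0, nrow = nrow(pos), ncol = 3L * K)
  colnames(out) <- as.vector(outer(entries$accession, paste0("x", 1:3),
                                   function(a, p) paste0(p, ".", a)))
  for (p in 1:3) {
    idx <- match(pos[, p], AA_ALPHABET)
    out[, (K * (p - 1L) + 1L):(K * p)] <- t(scaled[, idx, drop = FALSE])
  }
  rownames(out) <- rownames(pos)
  feature_matrix(out, scheme = "aaindex")
}

#' Configuration for language-model embedding extraction
#'
#' A motif is presented to the embedding model as `pad_length` unspecified
#' residues followed by the four motif residues; the adapter itself adds
#' begin- and end-of-sequence tokens. From the resulting per-token matrix
#' the four motif-residue vectors plus the end-of-sequence vector are
#' retained (5 positions) and flattened position-major.
#'
#' @param pad_length Number of leading unspecified residues (default 100).
#' @param pad_symbol Padding residue symbol (default "X", the unknown
#'   residue).
#' @param per_token_dim Embedding dimension E per token (default 1280).
#' @return List of class `embedding_config`.
#' @export
embedding_config <- function(pad_length = 100L, pad_symbol = "X",
                             per_token_dim = 1280L) {
  stopifnot(pad_length >= 0, per_token_dim > 0, nchar(pad_symbol) == 1L)
  structure(list(pad_length = as.integer(pad_length),
                 pad_symbol = pad_symbol,
                 per_token_dim = as.integer(per_token_dim)),
            class = "embedding_config")
}

#' Encode motifs with per-token embeddings from a frozen language model
#'
#' The adapter contract: `adapter(sequence)` receives the plain padded
#' residue string (`pad_length` pad symbols + 4 motif residues) and returns
#' a numeric matrix of shape `(per_token_dim, pad_length + 4 + 2)` whose
#' columns are token vectors in sequence order, including the begin- and
#' end-of-sequence special tokens that the model prepends/appends. The four
#' motif-residue token vectors (the invariant cysteine is kept because the
#' model encodes context) and the end-of-sequence vector are retained and
#' flattened position-major; with E = 1280 the row length is 6400.
#'
#' @param motifs Character vector of motifs.
#' @param adapter Function implementing the adapter contract.
#' @param cfg An [embedding_config()].
#' @return Numeric n x 5E `feature_matrix` with `scheme = "embedding"`.
#' @export
encode_embedding <- function(motifs, adapter, cfg = embedding_config()) {
  motifs <- as.character(parse_motif(motifs))
  if (!is.function(adapter)) stop("adapter must be a function")
  E <- cfg$per_token_dim
  n_tok <- cfg$pad_length + 4L + 2L
  pad <- strrep(cfg$pad_symbol, cfg$pad_length)
  rows <- lapply(motifs, function(m) {
    emb <- adapter(paste0(pad, m))
    if (!is.matrix(emb) || nrow(emb) != E || ncol(emb) != n_tok) {
      stop(sprintf(
        "adapter output must be a %d x %d matrix (per_token_dim x tokens), got %s",
        E, n_tok,
        if (is.matrix(emb)) paste(dim(emb), collapse = " x ") else class(emb)[1]
      ))
    }
    # tokens: [BOS, pad..., motif x4, EOS]; keep motif tokens and EOS
    keep <- c(cfg$pad_length + 2L:5L, n_tok)
    as.vector(emb[, keep])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- motifs
  colnames(out) <- as.vector(outer(seq_len(E),
                                   c("tokC", "tokX1", "tokX2", "tokX3", "tokEOS"),
                                   function(e, t) paste0(t, ".", e)))
  feature_matrix(out, scheme = "embedding")
}

#' Deterministic mock embedding adapter
#'
#' Stands in for a pretrained protein language model in tests and offline
#' runs: it is synthetic and carries no learned information. Each token
#' vector is a deterministic function of the token symbol and its position,
#' so identical sequences always embed identically.
#'
#' @param per_token_dim Embedding dimension (default 1280).
#' @param mode `"hash"` for pseudo-random but reproducible values;
#'   `"index"` for token-index-valued constant vectors (every component of
#'   token t equals t), convenient for layout tests.
#' @return An adapter function.
#' @export
mock_embedding_adapter <- function(per_token_dim = 1280L,
                                   mode = c("hash", "index")) {
  mode <- match.arg(mode)
  E <- as.integer(per_token_dim)
  function(sequence) {
    chars <- c("<", strsplit(sequence, "", fixed = TRUE)[[1]], ">")
    n_tok <- length(chars)
    if (mode == "index") {
      return(matrix(rep(seq_len(n_tok), each = E), nrow = E))
    }
    out <- matrix(0, nrow = E, ncol = n_tok)
    for (j in seq_len(n_tok)) {
      code <- utf8ToInt(chars[j])
      k <- seq_len(E)
      out[, j] <- sin(code * 0.7 + k * 0.13 + (j %% 7L) * 1.9)
    }
    out
  }
}

#' Fit a principal-component reducer retaining a target variance fraction
#'
#' Exact (full) PCA via singular value decomposition; the number of retained
#' components k is the smallest count whose cumulative explained variance
#' reaches `variance_target`. Component signs follow a deterministic
#' convention (the largest-magnitude loading of each component is positive)
#' so serialized reducers reproduce across platforms. Fit the reducer on
#' training features only and project everything else with it.
#'
#' @param m A `feature_matrix` (n >= 2 rows).
#' @param variance_target Fraction of total variance to retain, in (0, 1]
#'   (default 0.99).
#' @return List of class `pca_reducer`: `scheme`, `mean_vector`,
#'   `components` (k x d), `explained_fraction`, `k`, `variance_target`.
#' @export
fit_pca <- function(m, variance_target = 0.99) {
  if (!(variance_target > 0 && variance_target <= 1)) {
    stop("variance_target must be in (0, 1]")
  }
  if (nrow(m) < 2L) stop("PCA needs at least 2 rows")
  pr <- stats::prcomp(unclass(m), center = TRUE, scale. = FALSE)
  var_frac <- pr$sdev^2 / sum(pr$sdev^2)
  # drop numerically null components, then take the smallest k reaching the
  # target (cumulative sums are capped so 1.0 targets survive rounding)
  cum <- pmin(cumsum(var_frac), 1)
  k <- which(cum >= variance_target - 1e-12)[1]
  rot <- t(pr$rotation[, seq_len(k), drop = FALSE])  # k x d
  for (i in seq_len(k)) {
    j <- which.max(abs(rot[i, ]))
    if (rot[i, j] < 0) rot[i, ] <- -rot[i, ]
  }
  structure(
    list(scheme = feature_scheme(m),
         mean_vector = pr$center,
         components = rot,
         explained_fraction = var_frac[seq_len(k)],
         k = k,
         variance_target = variance_target),
    class = "pca_reducer"
  )
}

#' @export
print.pca_reducer <- function(x, ...) {
  cat(sprintf(
    "<pca_reducer: %s>  %d -> %d dims (%.4f of variance, target %.2f)\n",
    x$scheme, ncol(x$components), x$k, sum(x$explained_fraction),
    x$variance_target))
  invisible(x)
}

#' Project features onto a fitted PCA reducer
#' @param reducer A [fit_pca()] result.
#' @param m A `feature_matrix` with the same scheme and width.
#' @return n x k `feature_matrix` (scheme preserved).
#' @export
pca_transform <- function(reducer, m) {
  stopifnot(inherits(reducer, "pca_reducer"))
  if (!is.null(feature_scheme(m)) && !is.null(reducer$scheme) &&
      feature_scheme(m) != reducer$scheme) {
    stop("feature scheme mismatch: reducer is '", reducer$scheme,
         "', matrix is '", feature_scheme(m), "'")
  }
  if (ncol(m) != ncol(reducer$components)) {
    stop("feature width mismatch: reducer expects ",
         ncol(reducer$components), " columns")
  }
  centred <- sweep(unclass(m), 2L, reducer$mean_vector)
  out <- centred %*% t(reducer$components)
  colnames(out) <- paste0("PC", seq_len(reducer$k))
  rownames(out) <- rownames(m)
  feature_matrix(out, scheme = reducer$scheme)
}
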