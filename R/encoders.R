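# Feature encodings: position one-hot binary, AAindex physicochemical,
# composition of k-spaced amino-acid pairs (CKSAAP), and k-mer composition.
# Each scheme has a fixed, documented feature-name order (positions ascending,
# alphabet alphabetical, k/K ascending) so selected-subset files are portable
# across runs.

#' Describe an encoding
#'
#' @param scheme One of `"binary"`, `"aaindex"`, `"cksaap"`, `"kmer"`.
#' @param w Half-window size; windows have length `2w + 1` (default 20,
#'   window length 41).
#' @param k_values CKSAAP gap lengths; the default `0:4` yields
#'   5 x 400 = 2000 features.
#' @param K_values k-mer word lengths; the default `1:3` yields
#'   20 + 400 + 8000 = 8420 features (use `c(1, 3)` for an 8020-feature
#'   variant).
#' @param properties Property tibble for the aaindex scheme; default the
#'   bundled 15-property set ([default_properties()]), giving 41 x 15 = 615
#'   features.
#' @param normalize For cksaap/kmer, divide counts by the number of valid
#'   slots (composition); `FALSE` keeps raw counts.
#' @return An `nts_encoding_spec` object.
#' @export
encoding_spec <- function(scheme = c("binary", "aaindex", "cksaap", "kmer"),
                          w = 20, k_values = 0:4, K_values = 1:3,
                          properties = NULL, normalize = TRUE) {
  scheme <- match.arg(scheme)
  stopifnot(w >= 1, all(k_values >= 0), all(K_values >= 1))
  if (scheme == "aaindex" && is.null(properties)) {
    properties <- default_properties()
  }
  structure(list(scheme = scheme, w = as.integer(w),
                 k_values = as.integer(sort(k_values)),
                 K_values = as.integer(sort(K_values)),
                 properties = properties, normalize = normalize),
            class = "nts_encoding_spec")
}

#' @export
print.nts_encoding_spec <- function(x, ...) {
  cat(sprintf("<nts_encoding_spec> %s, w = %d (%d features)\n",
              x$scheme, x$w, length(feature_names(x))))
  invisible(x)
}

#' Canonical feature names of an encoding
#'
#' @param spec An `nts_encoding_spec`.
#' @return Character vector of feature names in canonical order.
#' @export
feature_names <- function(spec) {
  L <- 2L * spec$w + 1L
  switch(spec$scheme,
    binary = as.vector(t(outer(seq_len(L), AA21,
                               function(p, a) paste0("bin_p", p, "_", a)))),
    aaindex = as.vector(t(outer(seq_len(L), spec$properties$property_id,
                                function(p, id) paste0("aai_p", p, "_", id)))),
    cksaap = unlist(lapply(spec$k_values, function(k) {
      paste0("cks_k", k, "_", as.vector(t(outer(AA20, AA20, paste0))))
    })),
    kmer = unlist(lapply(spec$K_values, function(K) {
      # first letter varies slowest: lexicographic order, matching the
      # base-20 word index used by the encoder
      words <- do.call(paste0,
                       rev(expand.grid(replicate(K, AA20, simplify = FALSE),
                                       stringsAsFactors = FALSE)))
      paste0("kmer_K", K, "_", words)
    }))
  )
}

# Integer codes 1..20 for standard letters, 21 for gap, NA for 'X'/other.
codes_matrix <- function(strings) {
  M <- window_char_matrix(strings)
  C <- match(M, AA21)
  C[M == "X"] <- NA_integer_
  matrix(C, nrow = nrow(M))
}

encode_binary_matrix <- function(strings, spec) {
  L <- 2L * spec$w + 1L
  n <- length(strings)
  X <- matrix(0, n, L * 21L)
  if (n > 0) {
    C <- codes_matrix(strings)
    if (ncol(C) != L) abort_fmt("windows must have length %d for w = %d",
                                L, spec$w)
    if (anyNA(C)) warning("unencodable residues ('X') give zero blocks",
                          call. = FALSE)
    for (p in seq_len(L)) {
      ok <- which(!is.na(C[, p]))
      X[cbind(ok, (p - 1L) * 21L + C[ok, p])] <- 1
    }
  }
  X
}

encode_aaindex_matrix <- function(strings, spec) {
  lk <- property_lookup(spec$properties)
  np <- ncol(lk)
  L <- 2L * spec$w + 1L
  n <- length(strings)
  X <- matrix(0, n, L * np)
  if (n > 0) {
    C <- codes_matrix(strings)
    if (ncol(C) != L) abort_fmt("windows must have length %d for w = %d",
                                L, spec$w)
    for (p in seq_len(L)) {
      ok <- which(!is.na(C[, p]))
      X[ok, (p - 1L) * np + seq_len(np)] <- lk[C[ok, p], , drop = FALSE]
    }
  }
  X
}

encode_cksaap_matrix <- function(strings, spec) {
  n <- length(strings)
  X <- matrix(0, n, 400L * length(spec$k_values))
  if (n == 0) return(X)
  C <- codes_matrix(strings)
  L <- ncol(C)
  if (L <= max(spec$k_values) + 1L) {
    abort_fmt("window length %d too short for k = %d", L, max(spec$k_values))
  }
  C[C == 21L] <- NA_integer_  # pairs involving the gap are skipped
  for (bi in seq_along(spec$k_values)) {
    k <- spec$k_values[bi]
    counts <- matrix(0, n, 400L)
    for (i in seq_len(L - k - 1L)) {
      a <- C[, i]
      b <- C[, i + k + 1L]
      ok <- which(!is.na(a) & !is.na(b))
      if (length(ok) > 0) {
        idx <- cbind(ok, (a[ok] - 1L) * 20L + b[ok])
        counts[idx] <- counts[idx] + 1
      }
    }
    # denominator = number of pair slots in the window, gaps included, so
    # heavily padded windows yield smaller block sums (terminal proximity)
    if (spec$normalize) counts <- counts / (L - k - 1L)
    X[, (bi - 1L) * 400L + seq_len(400L)] <- counts
  }
  X
}

encode_kmer_matrix <- function(strings, spec) {
  n <- length(strings)
  dims <- 20L^spec$K_values
  X <- matrix(0, n, sum(dims))
  if (n == 0) return(X)
  C <- codes_matrix(strings)
  L <- ncol(C)
  if (L < max(spec$K_values)) {
    abort_fmt("window length %d too short for K = %d", L, max(spec$K_values))
  }
  C[C == 21L] <- NA_integer_  # words containing the gap are skipped
  offset <- 0L
  for (bi in seq_along(spec$K_values)) {
    K <- spec$K_values[bi]
    counts <- matrix(0, n, dims[bi])
    for (i in seq_len(L - K + 1L)) {
      word <- rep(0, n)
      ok <- rep(TRUE, n)
      for (j in seq_len(K)) {
        cj <- C[, i + j - 1L]
        ok <- ok & !is.na(cj)
        word <- word * 20 + (ifelse(is.na(cj), 1L, cj) - 1L)
      }
      okw <- which(ok)
      if (length(okw) > 0) {
        idx <- cbind(okw, word[okw] + 1)
        counts[idx] <- counts[idx] + 1
      }
    }
    if (spec$normalize) counts <- counts / (L - K + 1L)
    X[, offset + seq_len(dims[bi])] <- counts
    offset <- offset + dims[bi]
  }
  X
}

#' Encode windows into a named feature matrix
#'
#' Rows follow input order; columns follow the scheme's canonical name
#' order. The returned matrix carries a `row_ids` attribute (tibble of
#' `protein_id`, `position`).
#'
#' @param windows A window table (from [extract_windows()]) or a character
#'   vector of window strings.
#' @param spec An `nts_encoding_spec`.
#' @return A numeric matrix, `n x d`, with feature names as column names.
#' @examples
#' sp <- encoding_spec("cksaap", w = 2)
#' encode_dataset("AYAYA", sp)[, c("cks_k1_AA", "cks_k1_YY")]
#' @export
encode_dataset <- function(windows, spec) {
  win <- as_window_strings(windows)
  X <- switch(spec$scheme,
              binary = encode_binary_matrix(win$strings, spec),
              aaindex = encode_aaindex_matrix(win$strings, spec),
              cksaap = encode_cksaap_matrix(win$strings, spec),
              kmer = encode_kmer_matrix(win$strings, spec))
  colnames(X) <- feature_names(spec)
  attr(X, "row_ids") <- win$row_ids
  attr(X, "scheme") <- spec$scheme
  X
}

encode_one <- function(window, spec) {
  if (is_windows_tbl(window)) window <- window$window
  stopifnot(is.character(window), length(window) == 1)
  drop(encode_dataset(window, spec)[1, ])
}

#' Encode a single window under one scheme
#'
#' Convenience wrappers around [encode_dataset()] returning one named
#' numeric vector.
#'
#' @param window A single window string (or one-row window table).
#' @param spec An `nts_encoding_spec` of the matching scheme.
#' @return Named numeric feature vector.
#' @export
encode_binary <- function(window, spec = encoding_spec("binary")) {
  stopifnot(spec$scheme == "binary"); encode_one(window, spec)
}

#' @rdname encode_binary
#' @export
encode_aaindex <- function(window, spec = encoding_spec("aaindex")) {
  stopifnot(spec$scheme == "aaindex"); encode_one(window, spec)
}

#' @rdname encode_binary
#' @export
encode_cksaap <- function(window, spec = encoding_spec("cksaap")) {
  stopifnot(spec$scheme == "cksaap"); encode_one(window, spec)
}

#' @rdname encode_binary
#' @export
encode_kmer <- function(window, spec = encoding_spec("kmer")) {
  stopifnot(spec$scheme == "kmer"); encode_one(window, spec)
}

#' Write a feature matrix to TSV
#'
#' @param X Feature matrix from [encode_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(X, path) {
  ids <- attr(X, "row_ids")
  tbl <- dplyr::bind_cols(ids, tibble::as_tibble(unclass(X)[, , drop = FALSE]))
  readr::write_tsv(tbl, path)
  invisible(path)
}
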