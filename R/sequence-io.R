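# Sequence and site-label I/O: FASTA reading/writing, tyrosine-centred window
# extraction with terminal padding, label attachment, redundancy reduction and
# train/independent splitting.

#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased and non-standard residue letters (B, J, O, U, Z)
#' are collapsed to `X` with a warning; `X` later encodes as an all-zero block
#' in every feature scheme.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (first whitespace-delimited header
#'   token), `sequence`, and `n_nonstandard` (count of residues that were not
#'   one of the 20 standard letters).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "MKYR"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort_fmt("FASTA file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) {
    return(tibble::tibble(id = character(0), sequence = character(0),
                          n_nonstandard = integer(0)))
  }
  headers <- startsWith(trimws(lines), ">")
  if (!headers[nonblank[1]]) {
    abort_fmt("malformed FASTA: line %d does not start a record ('>')",
              nonblank[1])
  }
  hdr_idx <- which(headers)
  for (i in hdr_idx) {
    tok <- sub("^>", "", trimws(lines[i]))
    if (!nzchar(strsplit(tok, "\\s+")[[1]][1] %||% "")) {
      abort_fmt("malformed FASTA: empty header at line %d", i)
    }
    nxt <- nonblank[nonblank > i]
    if (length(nxt) == 0 || headers[nxt[1]]) {
      abort_fmt("malformed FASTA: record at line %d has no sequence", i)
    }
  }
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  seqs <- unname(toupper(as.character(set)))
  n_nonstd <- vapply(seqs, function(s) {
    sum(!strsplit(s, "")[[1]] %in% AA20)
  }, integer(1), USE.NAMES = FALSE)
  if (any(n_nonstd > 0)) {
    warning(sprintf("%d sequence(s) contain non-standard residues; mapped to 'X'",
                    sum(n_nonstd > 0)), call. = FALSE)
    seqs <- vapply(seqs, function(s) {
      ch <- strsplit(s, "")[[1]]
      ch[!ch %in% AA20] <- "X"
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  tibble::tibble(id = ids, sequence = seqs, n_nonstandard = n_nonstd)
}

#' Write protein sequences to a FASTA file
#'
#' @param proteins A data frame with columns `id` and `sequence`.
#' @param path Output path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60) {
  set <- Biostrings::BStringSet(proteins$sequence)
  names(set) <- proteins$id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Extract tyrosine-centred sequence windows
#'
#' One window of length `2w + 1` is produced per tyrosine (Y) in each
#' sequence, with the Y at the centre; positions falling outside the protein
#' are padded with `-`.
#'
#' @param proteins A data frame with columns `id` and `sequence` (as from
#'   [read_fasta()]), or a single sequence string.
#' @param w Half-window size; the default 20 gives the standard window
#'   length of 41.
#' @return A tibble with columns `protein_id`, `position` (1-based index of
#'   the central Y), `window`, `label` (`"unknown"`).
#' @examples
#' extract_windows(tibble::tibble(id = "p", sequence = "AYAYA"), w = 2)
#' @export
extract_windows <- function(proteins, w = 20) {
  stopifnot(w >= 1)
  if (is.character(proteins)) {
    proteins <- tibble::tibble(id = paste0("seq", seq_along(proteins)),
                               sequence = proteins)
  }
  pad <- strrep(GAP, w)
  out <- purrr::map2(proteins$id, proteins$sequence, function(id, s) {
    pos <- stringr::str_locate_all(s, stringr::fixed("Y"))[[1]][, 1]
    if (length(pos) == 0) return(NULL)
    padded <- paste0(pad, s, pad)
    tibble::tibble(protein_id = id,
                   position = as.integer(pos),
                   window = substr(rep(padded, length(pos)),
                                   pos, pos + 2 * w))
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    out <- tibble::tibble(protein_id = character(0), position = integer(0),
                          window = character(0))
  }
  out$label <- rep("unknown", nrow(out))
  out
}

#' Read a site-label table
#'
#' @param path TSV with columns `protein_id`, `position` (1-based), `label`
#'   (1 = nitrated, 0 = not).
#' @return A tibble with those columns.
#' @export
read_site_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    protein_id = readr::col_character(),
    position = readr::col_integer(),
    label = readr::col_integer()
  ))
  if (!all(c("protein_id", "position", "label") %in% names(tbl))) {
    abort_fmt("site table must have columns protein_id, position, label")
  }
  tbl
}

#' Attach experimental labels to extracted windows
#'
#' Windows whose centre appears in `sites` with label 1 become `positive`;
#' every other window of a protein that appears in `sites` becomes
#' `negative` (the remaining tyrosines of a characterised protein are taken
#' as non-nitrated); windows of proteins absent from `sites` stay `unknown`.
#'
#' @param windows A window table from [extract_windows()].
#' @param sites A site table (`protein_id`, `position`, `label`).
#' @return The window table with `label` filled in.
#' @export
attach_labels <- function(windows, sites) {
  key <- function(id, pos) paste(id, pos, sep = "\r")
  wkey <- key(windows$protein_id, windows$position)
  skey <- key(sites$protein_id, sites$position)
  bad <- !(skey %in% wkey)
  if (any(bad)) {
    offenders <- paste(sites$protein_id[bad], sites$position[bad],
                       sep = ":", collapse = ", ")
    abort_fmt("site positions do not point at a tyrosine: %s", offenders)
  }
  pos_key <- skey[as_label01(sites$label) == 1L]
  in_table <- windows$protein_id %in% unique(sites$protein_id)
  windows$label <- dplyr::case_when(
    wkey %in% pos_key ~ "positive",
    in_table ~ "negative",
    .default = "unknown"
  )
  windows
}

#' Remove redundant windows by greedy identity clustering
#'
#' Greedy longest-first clustering on window strings: windows are visited in
#' decreasing length order (ties keep input order) and a window joins the
#' first retained representative with which its position-wise identity
#' (matching characters / window length; two aligned gaps count as a match)
#' reaches `identity_threshold`; otherwise it is retained as a new
#' representative. This mirrors the 40 % redundancy threshold conventionally
#' applied with CD-HIT; an externally produced CD-HIT `.clstr` file can be
#' supplied instead via `clstr`.
#'
#' @param windows A window table.
#' @param identity_threshold Fraction in (0, 1]; default 0.4.
#' @param clstr Optional path to a CD-HIT `.clstr` file; if given, the
#'   clustering is taken from the file (representatives kept, by window
#'   index) and `identity_threshold` is ignored.
#' @return The table restricted to cluster representatives, input order.
#' @export
reduce_redundancy <- function(windows, identity_threshold = 0.4, clstr = NULL) {
  if (!is.null(clstr)) {
    keep <- read_cdhit_representatives(clstr, nrow(windows))
    return(windows[sort(keep), , drop = FALSE])
  }
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  n <- nrow(windows)
  if (n <= 1) return(windows)
  ord <- order(-nchar(windows$window), seq_len(n))
  M <- window_char_matrix(windows$window)
  L <- ncol(M)
  reps <- integer(0)
  rep_mat <- NULL
  for (i in ord) {
    if (length(reps) > 0) {
      ident <- rowMeans(rep_mat == matrix(M[i, ], nrow = length(reps),
                                          ncol = L, byrow = TRUE))
      if (any(ident >= identity_threshold)) next
    }
    reps <- c(reps, i)
    rep_mat <- M[reps, , drop = FALSE]
  }
  windows[sort(reps), , drop = FALSE]
}

# Parse a CD-HIT .clstr file and return the (1-based) indices of cluster
# representatives, assuming sequences were exported in window-table order and
# named by index (">1", ">2", ...) or "<anything>_<index>".
read_cdhit_representatives <- function(path, n) {
  lines <- readLines(path, warn = FALSE)
  rep_lines <- grep("\\*\\s*$", lines, value = TRUE)
  idx <- suppressWarnings(as.integer(
    sub(".*?(\\d+)[^0-9]*$", "\\1",
        sub("\\.\\.\\..*$", "", sub("^[^>]*>", "", rep_lines)))
  ))
  if (anyNA(idx) || any(idx < 1) || any(idx > n)) {
    abort_fmt("could not parse representative indices from %s", path)
  }
  idx
}

#' Split labelled windows into balanced training and independent sets
#'
#' A stratified `independent_fraction` of each class is held out as the
#' independent set (left unbalanced); the remaining windows form the training
#' set, balanced 1:1 by uniform random down-sampling of the majority class.
#'
#' @param windows A labelled window table (labels `positive`/`negative`).
#' @param independent_fraction Fraction of each class held out; default 0.2.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return An object of class `nts_split`: a list with tibbles `training`
#'   and `independent` and the `split_seed`.
#' @export
make_split <- function(windows, independent_fraction = 0.2, seed = 1) {
  stopifnot(independent_fraction >= 0, independent_fraction < 1)
  y <- as_label01(windows$label)
  if (anyNA(y)) abort_fmt("make_split() needs fully labelled windows")
  pos <- which(y == 1L)
  neg <- which(y == 0L)
  if (length(pos) < 2 || length(neg) < 2) {
    abort_fmt("need at least 2 windows of each class (have %d pos, %d neg)",
              length(pos), length(neg))
  }
  withr::with_seed(seed, {
    ind_pos <- sort(sample(pos, round(length(pos) * independent_fraction)))
    ind_neg <- sort(sample(neg, round(length(neg) * independent_fraction)))
    tr_pos <- setdiff(pos, ind_pos)
    tr_neg <- setdiff(neg, ind_neg)
    n_bal <- min(length(tr_pos), length(tr_neg))
    if (n_bal < 1) abort_fmt("too few samples left to form a training set")
    tr_pos <- sort(sample(tr_pos, n_bal))
    tr_neg <- sort(sample(tr_neg, n_bal))
  })
  structure(list(training = windows[sort(c(tr_pos, tr_neg)), , drop = FALSE],
                 independent = windows[c(ind_pos, ind_neg), , drop = FALSE],
                 split_seed = seed),
            class = "nts_split")
}

#' @export
print.nts_split <- function(x, ...) {
  cat(sprintf("<nts_split> training: %d (balanced), independent: %d, seed %d\n",
              nrow(x$training), nrow(x$independent), x$split_seed))
  invisible(x)
}

#' Write a window table to TSV
#'
#' Columns: `protein_id`, `position` (1-based), `window`, `label`.
#' @param windows A window table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_windows <- function(windows, path) {
  readr::write_tsv(windows[, c("protein_id", "position", "window", "label")],
                   path)
  invisible(path)
}
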