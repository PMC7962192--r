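# Shared constants and small helpers.

# The 20 standard amino acids in the canonical (alphabetical) order used for
# every feature-name layout in the package. The terminal-padding gap character
# '-' is appended as a 21st letter where an encoding admits it.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
GAP <- "-"
AA21 <- c(AA20, GAP)

# Ambiguity / non-standard letters collapsed to 'X' on input; 'X' encodes as
# an all-zero block in every scheme.
NONSTANDARD <- c("B", "J", "O", "U", "Z")

#' @importFrom rlang %||% .data
#' @importFrom stats predict
NULL

abort_fmt <- function(...) stop(sprintf(...), call. = FALSE)

# Deterministic per-stage seed derived from one top-level seed; stays well
# inside 32-bit integer range for seeds up to ~2e6.
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 11L, split = 23L, rank = 37L, grid = 53L,
               train = 71L, fuse = 89L, cv = 101L, fold = 131L)
  off <- offsets[[stage]] %||% 151L
  as.integer((as.numeric(seed) * 1009 + off) %% 2147483587)
}

# Split window strings into an n x L character matrix.
window_char_matrix <- function(windows) {
  L <- unique(nchar(windows))
  if (length(L) > 1) {
    abort_fmt("all windows must share one length; saw lengths {%s}",
              paste(sort(L), collapse = ", "))
  }
  if (length(windows) == 0) {
    return(matrix(character(0), nrow = 0, ncol = 0))
  }
  matrix(unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
         nrow = length(windows), byrow = TRUE)
}

is_windows_tbl <- function(x) {
  is.data.frame(x) && all(c("protein_id", "position", "window") %in% names(x))
}

# Accept either a window table or a bare character vector of windows and
# return list(strings, row_ids).
as_window_strings <- function(windows) {
  if (is_windows_tbl(windows)) {
    list(strings = windows$window,
         row_ids = tibble::tibble(protein_id = windows$protein_id,
                                  position = windows$position))
  } else if (is.character(windows)) {
    list(strings = windows,
         row_ids = tibble::tibble(protein_id = NA_character_,
                                  position = seq_along(windows)))
  } else {
    abort_fmt("`windows` must be a window table or a character vector")
  }
}

as_label01 <- function(label) {
  if (is.factor(label)) label <- as.character(label)
  if (is.character(label)) {
    out <- dplyr::case_match(label,
                             c("positive", "1") ~ 1L,
                             c("negative", "0") ~ 0L,
                             .default = NA_integer_)
  } else {
    out <- as.integer(label)
    out[!out %in% c(0L, 1L)] <- NA_integer_
  }
  out
}

# Binary labels as a factor with levels 0/1 (positive = "1") for classifiers.
label_factor <- function(y) {
  y01 <- as_label01(y)
  if (anyNA(y01)) abort_fmt("labels must be 0/1 or negative/positive")
  factor(y01, levels = c(0L, 1L))
}
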