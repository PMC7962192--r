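# Synthetic planted-motif data: proteins drawn from a background amino-acid
# distribution, with the flanks of designated positive tyrosines re-drawn
# from a motif-boosted distribution (charged residues K/R/E enriched,
# Y/S/F/L depleted near the centre), so the full pipeline can be trained and
# benchmarked without any external dataset.

default_motif_boost <- function() {
  b <- stats::setNames(rep(1, 20), AA20)
  b[c("K", "R", "E")] <- 2
  b[c("Y", "S", "F", "L")] <- 0.5
  b
}

#' Configuration for the synthetic generator
#'
#' @param n_proteins Number of proteins, default 150.
#' @param length_range Protein length range (uniform), default 80--300.
#' @param background Named letter probabilities (default uniform over the
#'   20 standard amino acids).
#' @param motif_boost Named multiplicative boosts applied to the background
#'   at motif offsets for positive sites; default K/R/E x2, Y/S/F/L x0.5.
#' @param motif_offsets Window offsets (relative to the central Y) where the
#'   boost applies; default -5..+5 excluding 0.
#' @param positive_fraction Probability a tyrosine is designated positive,
#'   default 0.25.
#' @param effect_size Exponent scaling the boost (`boost^effect_size`);
#'   0 makes positives and negatives identically distributed. Default 1.5.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A `SyntheticConfig`-style list.
#' @export
synthetic_config <- function(n_proteins = 150, length_range = c(80, 300),
                             background = NULL, motif_boost = NULL,
                             motif_offsets = setdiff(-5:5, 0),
                             positive_fraction = 0.25, effect_size = 1.5,
                             seed = 1) {
  background <- background %||% stats::setNames(rep(1 / 20, 20), AA20)
  stopifnot(abs(sum(background) - 1) < 1e-9,
            positive_fraction > 0, positive_fraction < 1,
            effect_size >= 0, length_range[1] >= 1)
  list(n_proteins = n_proteins, length_range = length_range,
       background = background[AA20],
       motif_boost = (motif_boost %||% default_motif_boost())[AA20],
       motif_offsets = motif_offsets,
       positive_fraction = positive_fraction,
       effect_size = effect_size, seed = seed)
}

#' Generate synthetic proteins with planted nitration sites
#'
#' Residues are drawn i.i.d. from the background distribution; each
#' tyrosine is designated positive with probability `positive_fraction`,
#' and the residues at the motif offsets around a positive tyrosine are
#' re-drawn from the boosted distribution
#' `p(a) proportional to background(a) * boost(a)^effect_size`
#' (skipping positions that are themselves designated positive centres).
#' The site table lists every tyrosine of the final sequences with label 1
#' (designated positive, still tyrosine) or 0.
#'
#' @param config A list from [synthetic_config()].
#' @return A list with `proteins` (tibble `id`, `sequence`) and `sites`
#'   (tibble `protein_id`, `position`, `label`).
#' @export
generate_synthetic <- function(config) {
  if (config$length_range[2] < 1) abort_fmt("infeasible protein length range")
  boosted <- config$background * config$motif_boost^config$effect_size
  boosted <- boosted / sum(boosted)
  withr::with_seed(config$seed, {
    proteins <- purrr::map(seq_len(config$n_proteins), function(i) {
      len <- sample(seq(config$length_range[1], config$length_range[2]), 1)
      ch <- sample(AA20, len, replace = TRUE, prob = config$background)
      ypos <- which(ch == "Y")
      pos_sites <- ypos[stats::runif(length(ypos)) < config$positive_fraction]
      for (p in pos_sites) {
        at <- p + config$motif_offsets
        at <- at[at >= 1 & at <= len & !(at %in% pos_sites)]
        if (length(at) > 0) {
          ch[at] <- sample(AA20, length(at), replace = TRUE, prob = boosted)
        }
      }
      ypos_final <- which(ch == "Y")
      list(id = sprintf("synth%04d", i),
           sequence = paste(ch, collapse = ""),
           sites = tibble::tibble(
             protein_id = sprintf("synth%04d", i),
             position = as.integer(ypos_final),
             label = as.integer(ypos_final %in% pos_sites)))
    })
  })
  sites <- dplyr::bind_rows(purrr::map(proteins, "sites"))
  list(proteins = tibble::tibble(
         id = purrr::map_chr(proteins, "id"),
         sequence = purrr::map_chr(proteins, "sequence")),
       sites = sites)
}

#' Labelled synthetic windows in one call
#'
#' Convenience wrapper: generate, extract windows at half-window `w`, attach
#' labels.
#'
#' @param config A [synthetic_config()].
#' @param w Half-window size, default 20.
#' @param n_windows Optional cap: keep the first `n_windows` windows
#'   (balanced per class when possible).
#' @return A labelled window table.
#' @export
synthetic_windows <- function(config, w = 20, n_windows = NULL) {
  dat <- generate_synthetic(config)
  win <- attach_labels(extract_windows(dat$proteins, w = w), dat$sites)
  if (!is.null(n_windows) && nrow(win) > n_windows) {
    # subsample uniformly at random within each class (a positional cut
    # would confound protein identity with the label)
    pos <- which(win$label == "positive")
    neg <- which(win$label == "negative")
    half <- min(n_windows %/% 2, length(pos))
    withr::with_seed(config$seed + 1L, {
      keep <- c(sample(pos, half),
                sample(neg, min(n_windows - half, length(neg))))
    })
    win <- win[sort(keep), , drop = FALSE]
  }
  win
}

#' Small deterministic bundled fixture
#'
#' A 24-protein synthetic dataset regenerated deterministically in code;
#' copies of the same FASTA/site-table/manifest ship under
#' `inst/extdata/fixture/` for command-line examples. All data are
#' synthetic.
#'
#' @return A list with `proteins`, `sites`, and a `manifest` of counts.
#' @export
fixture_small <- function() {
  cfg <- synthetic_config(n_proteins = 24, length_range = c(60, 140),
                          effect_size = 1.5, positive_fraction = 0.3,
                          seed = 420)
  dat <- generate_synthetic(cfg)
  dat$manifest <- list(n_proteins = nrow(dat$proteins),
                       n_sites = nrow(dat$sites),
                       n_positive = sum(dat$sites$label == 1L),
                       n_negative = sum(dat$sites$label == 0L))
  dat
}
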