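# Feature selection: random-forest recursive feature elimination (RFE) and
# top-N grid selection by cross-validated AUC.

fit_forest <- function(X, y, n_trees, seed, importance = "impurity",
                       mtry = NULL) {
  ranger::ranger(x = X, y = label_factor(y), num.trees = n_trees,
                 probability = TRUE, importance = importance,
                 mtry = mtry %||% floor(sqrt(ncol(X))),
                 seed = seed, num.threads = 1)
}

forest_prob <- function(fit, X) {
  stats::predict(fit, data = X, num.threads = 1)$predictions[, "1"]
}

#' Rank features by recursive feature elimination
#'
#' Classic RFE with a random-forest ranker: fit a probability forest,
#' drop the `step` features with the smallest impurity importance (ties
#' broken by canonical feature order), and repeat on the survivors until
#' `step` or fewer remain. The final ranking is the reverse elimination
#' order. The reported `score` is an RFE elimination score — the number of
#' rounds a feature survived plus its within-round normalised importance in
#' [0, 1) — which is non-increasing along the ranking by construction.
#'
#' @param X Feature matrix (named columns).
#' @param y Binary labels, both classes present.
#' @param step Features dropped per round (default 50, the grid
#'   granularity).
#' @param n_trees Trees per forest fit (default 500).
#' @param seed Integer seed; the ranking is deterministic given the seed.
#' @param rerank If `FALSE`, rank once by a single forest's importance
#'   instead of re-fitting every round.
#' @param importance `"impurity"` (default) or `"permutation"`.
#' @return An `nts_ranking`: tibble `rank`, `feature`, `score` with
#'   attribute `ranking_seed`.
#' @export
rfe_rank <- function(X, y, step = 50, n_trees = 500, seed = 1,
                     rerank = TRUE, importance = "impurity") {
  if (ncol(X) < 2) abort_fmt("RFE needs at least 2 features")
  y01 <- as_label01(y)
  if (length(unique(y01)) < 2) abort_fmt("both classes must be present in y")
  p <- ncol(X)
  canon <- colnames(X)

  round_importance <- function(cols, round_seed) {
    fit <- fit_forest(X[, cols, drop = FALSE], y01, n_trees, round_seed,
                      importance = importance)
    imp <- fit$variable.importance[cols]
    # ties broken by canonical order: later canonical position loses
    ord <- order(imp, -match(cols, canon), decreasing = TRUE)
    list(cols = cols[ord], imp = imp[ord])
  }

  within_score <- function(imp) {
    rng <- diff(range(imp))
    if (rng > 0) (imp - min(imp)) / rng * 0.999 else
      seq(0.999, 0, length.out = length(imp))
  }

  if (!rerank) {
    # single-shot ranking: one fit, score = raw importance
    ri <- round_importance(canon, seed + 1L)
    out <- tibble::tibble(rank = seq_len(p), feature = ri$cols,
                          score = unname(ri$imp))
  } else {
    ranked <- character(0)   # assembled back to front (least important first)
    scores <- numeric(0)
    dropped_round <- integer(0)
    remaining <- canon
    round_i <- 0L
    repeat {
      round_i <- round_i + 1L
      ri <- round_importance(remaining, seed + round_i)
      within <- within_score(ri$imp)
      if (length(remaining) <= step) {
        ranked <- c(ri$cols, ranked)
        scores <- c(within, scores)
        dropped_round <- c(rep(round_i, length(ri$cols)), dropped_round)
        break
      }
      keep_n <- length(ri$cols) - step
      ranked <- c(utils::tail(ri$cols, step), ranked)
      scores <- c(utils::tail(within, step), scores)
      dropped_round <- c(rep(round_i, step), dropped_round)
      remaining <- ri$cols[seq_len(keep_n)]
    }
    # rounds outlived: a feature eliminated in round r scores r - 1 plus its
    # within-round term in [0, 0.999]; the retained block sits on top. The
    # full score is therefore non-increasing along the ranking.
    offset <- dropped_round - 1L
    out <- tibble::tibble(rank = seq_along(ranked), feature = ranked,
                          score = scores + offset)
  }
  attr(out, "ranking_seed") <- seed
  class(out) <- c("nts_ranking", class(tibble::tibble()))
  out
}

#' Choose the best top-N feature subset on a size grid
#'
#' Evaluates top-`grid_step`, top-`2*grid_step`, ..., all features by
#' stratified cross-validated AUC (a fresh forest per size and fold) and
#' keeps the smallest size achieving the maximum.
#'
#' @param ranking An `nts_ranking` from [rfe_rank()].
#' @param X,y Feature matrix and labels (same rows as used for ranking, or
#'   an inner training fold).
#' @param grid_step Grid interval, default 50.
#' @param cv_folds Folds for the per-size evaluation, default 5.
#' @param n_trees Trees per evaluation forest (default 500).
#' @param seed Integer seed.
#' @param sizes Optional explicit vector of subset sizes, overriding the
#'   grid (the full-feature point is always appended).
#' @param max_size Optional cap on the largest evaluated size.
#' @return An `nts_subset`: list with `scheme`, `features` (a prefix of the
#'   ranking), `chosen_size`, and `grid_scores` (tibble `size`, `mean_auc`,
#'   `se_auc`).
#' @export
grid_select <- function(ranking, X, y, grid_step = 50, cv_folds = 5,
                        n_trees = 500, seed = 1, sizes = NULL,
                        max_size = NULL) {
  stopifnot(grid_step >= 1, cv_folds >= 2)
  p <- nrow(ranking)
  if (is.null(sizes)) {
    sizes <- seq(grid_step, p, by = grid_step)
    if (!is.null(max_size)) sizes <- sizes[sizes <= max_size]
    if (length(sizes) == 0 || max(sizes) < min(p, max_size %||% p)) {
      sizes <- c(sizes, min(p, max_size %||% p))
    }
  } else {
    sizes <- sort(unique(pmin(sizes, p)))
  }
  y01 <- as_label01(y)
  fold <- make_folds(y01, cv_folds, stage_seed(seed, "grid"))
  grid <- purrr::map_dfr(sizes, function(sz) {
    feats <- ranking$feature[seq_len(sz)]
    aucs <- vapply(seq_len(cv_folds), function(f) {
      tr <- fold != f
      fit <- fit_forest(X[tr, feats, drop = FALSE], y01[tr], n_trees,
                        seed + f, importance = "none")
      roc_auc(forest_prob(fit, X[!tr, feats, drop = FALSE]), y01[!tr])$auc
    }, numeric(1))
    tibble::tibble(size = sz, mean_auc = mean(aucs),
                   se_auc = stats::sd(aucs) / sqrt(cv_folds))
  })
  # ties broken toward the smaller subset
  best <- min(grid$size[grid$mean_auc >= max(grid$mean_auc) - 1e-12])
  prefix <- sub("_.*$", "", ranking$feature[1])
  scheme <- c(bin = "binary", aai = "aaindex", cks = "cksaap",
              kmer = "kmer")[prefix]
  if (is.na(scheme)) scheme <- prefix
  structure(list(scheme = unname(scheme),
                 features = ranking$feature[seq_len(best)],
                 chosen_size = best, grid_scores = grid,
                 selection_seed = seed),
            class = "nts_subset")
}

#' @export
print.nts_subset <- function(x, ...) {
  cat(sprintf("<nts_subset> %s: %d features kept (grid of %d sizes, best AUC %.3f)\n",
              x$scheme, x$chosen_size, nrow(x$grid_scores),
              max(x$grid_scores$mean_auc)))
  invisible(x)
}

#' Write a ranking or subset report to TSV
#'
#' @param x An `nts_ranking` or `nts_subset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection <- function(x, path) {
  if (inherits(x, "nts_ranking")) {
    readr::write_tsv(x, path)
  } else if (inherits(x, "nts_subset")) {
    readr::write_tsv(x$grid_scores, path)
  } else {
    abort_fmt("write_selection() expects an nts_ranking or nts_subset")
  }
  invisible(path)
}
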