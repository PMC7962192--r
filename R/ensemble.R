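# Ensemble model: one probability classifier per encoding scheme, convex
# linear fusion of the four probability scores, weight optimization on
# out-of-fold predictions, and (de)serialization.

SCHEMES <- c("binary", "aaindex", "cksaap", "kmer")

# Fusion weights in scheme order binary/aaindex/cksaap/kmer. The reference
# operating point for the fused predictor.
DEFAULT_FUSION_WEIGHTS <- c(binary = 0.01, aaindex = 0.01,
                            cksaap = 0.30, kmer = 0.68)

BUNDLE_VERSION <- "nitrosite-ensemble-1"

#' Train a single-encoding classifier
#'
#' Fits a probability model on (a selected subset of) one encoding's feature
#' matrix. The default classifier is a random forest (500 trees, sqrt(p)
#' candidate features per split); naive Bayes and k-nearest-neighbour
#' comparators sit behind the same interface.
#'
#' @param X Feature matrix (named columns).
#' @param y Binary labels.
#' @param subset Optional `nts_subset` (or character vector of feature
#'   names); training is restricted to those columns.
#' @param n_trees Number of trees for the forest, default 500.
#' @param seed Integer seed; training is deterministic given the seed.
#' @param method `"rf"` (default), `"nb"`, or `"knn"` (k chosen by
#'   cross-validated AUC from 3, 5, 7, 9).
#' @return An `nts_model`.
#' @export
train_single <- function(X, y, subset = NULL, n_trees = 500, seed = 1,
                         method = c("rf", "nb", "knn")) {
  method <- match.arg(method)
  feats <- if (is.null(subset)) colnames(X)
           else if (inherits(subset, "nts_subset")) subset$features
           else as.character(subset)
  missing <- setdiff(feats, colnames(X))
  if (length(missing) > 0) {
    abort_fmt("subset feature(s) absent from X: %s",
              paste(utils::head(missing, 5), collapse = ", "))
  }
  Xs <- X[, feats, drop = FALSE]
  y01 <- as_label01(y)
  fitted <- switch(method,
    rf = fit_forest(Xs, y01, n_trees, seed),
    nb = e1071::naiveBayes(x = as.data.frame(Xs), y = label_factor(y01)),
    knn = {
      k <- choose_knn_k(Xs, y01, seed)
      list(train = Xs, y = label_factor(y01), k = k)
    })
  structure(list(scheme = attr(X, "scheme") %||% "unknown",
                 method = method, features = feats, fit = fitted,
                 n_trees = if (method == "rf") n_trees else NA_integer_,
                 train_seed = seed),
            class = "nts_model")
}

choose_knn_k <- function(X, y01, seed, candidates = c(3, 5, 7, 9)) {
  fold <- make_folds(y01, 5, stage_seed(seed, "fold"))
  aucs <- vapply(candidates, function(k) {
    mean(vapply(1:5, function(f) {
      tr <- fold != f
      pr <- knn_prob(X[tr, , drop = FALSE], y01[tr],
                     X[!tr, , drop = FALSE], k, seed)
      roc_auc(pr, y01[!tr])$auc
    }, numeric(1)))
  }, numeric(1))
  candidates[which.max(aucs)]
}

knn_prob <- function(train, y01, test, k, seed) {
  withr::with_seed(seed, {
    pred <- class::knn(train, test, cl = factor(y01, levels = c(0L, 1L)),
                       k = k, prob = TRUE, use.all = TRUE)
  })
  p <- attr(pred, "prob")
  ifelse(pred == "1", p, 1 - p)
}

#' Predict positive-class probabilities from a single-encoding model
#'
#' @param model An `nts_model`.
#' @param X Feature matrix containing the model's feature columns.
#' @return Numeric vector of probabilities in \[0, 1\], one per row.
#' @export
predict_single <- function(model, X) {
  missing <- setdiff(model$features, colnames(X))
  if (length(missing) > 0) {
    abort_fmt("model feature(s) absent from X: %s",
              paste(utils::head(missing, 5), collapse = ", "))
  }
  Xs <- X[, model$features, drop = FALSE]
  switch(model$method,
    rf = forest_prob(model$fit, Xs),
    nb = stats::predict(model$fit, as.data.frame(Xs), type = "raw",
                        threshold = 0.001)[, "1"],
    knn = knn_prob(model$fit$train, as_label01(as.character(model$fit$y)),
                   Xs, model$fit$k, model$train_seed))
}

#' @export
print.nts_model <- function(x, ...) {
  cat(sprintf("<nts_model> %s (%s), %d features\n",
              x$scheme, x$method, length(x$features)))
  invisible(x)
}

validate_weights <- function(weights) {
  if (is.null(names(weights))) names(weights) <- SCHEMES
  weights <- weights[SCHEMES]
  if (anyNA(weights) || any(weights < 0)) {
    abort_fmt("fusion weights must be non-negative and cover all schemes")
  }
  if (abs(sum(weights) - 1) > 1e-9) {
    abort_fmt("fusion weights must sum to 1 (got %.12f)", sum(weights))
  }
  weights
}

#' Fuse per-encoding probability scores linearly
#'
#' `fused_i = sum_s weight_s * prob_{s,i}`: a convex combination, so the
#' fused score stays within the range of the per-scheme scores.
#'
#' @param probs A data frame or matrix with one column per scheme
#'   (`binary`, `aaindex`, `cksaap`, `kmer`).
#' @param weights Named non-negative weights summing to 1; default the
#'   reference weights 0.01/0.01/0.30/0.68.
#' @return Numeric vector of fused scores.
#' @export
fuse_scores <- function(probs, weights = DEFAULT_FUSION_WEIGHTS) {
  weights <- validate_weights(weights)
  probs <- as.data.frame(probs)
  if (!all(SCHEMES %in% names(probs))) {
    abort_fmt("probs must have columns %s", paste(SCHEMES, collapse = ", "))
  }
  lens <- lengths(probs[SCHEMES])
  if (length(unique(lens)) != 1) abort_fmt("per-scheme score lengths differ")
  as.vector(as.matrix(probs[SCHEMES]) %*% weights)
}

# Lattice of non-negative integer 4-compositions of `total`.
simplex_lattice <- function(total) {
  g <- expand.grid(i = 0:total, j = 0:total, k = 0:total)
  g <- g[g$i + g$j + g$k <= total, ]
  cbind(g$i, g$j, g$k, total - g$i - g$j - g$k)
}

#' Optimize fusion weights on out-of-fold probabilities
#'
#' Exhaustive search over the weight simplex: a coarse lattice pass (step
#' `coarse_step`) followed by a fine pass (step `grid_step`) restricted to a
#' box around the coarse optimum, maximizing the AUC of the fused score.
#' Ties prefer the weight vector with the largest single-scheme mass
#' (sparser fusion). Feed this out-of-fold probabilities, never
#' training-fold ones, or the weights will be optimistically biased.
#'
#' @param probs Data frame of out-of-fold per-scheme probabilities.
#' @param y Binary labels.
#' @param grid_step Fine lattice step, default 0.01.
#' @param coarse_step Coarse lattice step, default 0.05.
#' @return An `nts_weights` named vector (attributes: achieved `auc`).
#' @export
optimize_weights <- function(probs, y, grid_step = 0.01, coarse_step = 0.05) {
  y01 <- as_label01(y)
  if (length(unique(y01)) < 2) abort_fmt("both classes must be present in y")
  probs <- as.data.frame(probs)[SCHEMES]
  P <- as.matrix(probs)
  npos <- sum(y01 == 1L); nneg <- sum(y01 == 0L)
  auc_of <- function(s) {
    r <- rank(s, ties.method = "average")
    (sum(r[y01 == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
  }
  eval_lattice <- function(W) {  # W: m x 4 integer lattice, scaled later
    scores <- P %*% t(W)
    apply(scores, 2, auc_of)
  }
  pick_best <- function(W, aucs) {
    best <- max(aucs)
    cand <- which(aucs >= best - 1e-12)
    # sparser fusion: largest single-scheme mass wins; then lattice order
    cand[which.max(apply(W[cand, , drop = FALSE], 1, max))]
  }
  n_coarse <- round(1 / coarse_step)
  Wc <- simplex_lattice(n_coarse) * coarse_step
  ac <- eval_lattice(Wc)
  w0 <- Wc[pick_best(Wc, ac), ]
  n_fine <- round(1 / grid_step)
  ratio <- round(coarse_step / grid_step)
  ctr <- round(w0 * n_fine)
  rng <- lapply(1:3, function(i) {
    seq(max(0, ctr[i] - ratio), min(n_fine, ctr[i] + ratio))
  })
  g <- expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]])
  l <- n_fine - g$i - g$j - g$k
  ok <- l >= max(0, ctr[4] - ratio) & l <= min(n_fine, ctr[4] + ratio)
  Wf <- cbind(g$i, g$j, g$k, l)[ok, , drop = FALSE] * grid_step
  Wf <- rbind(matrix(w0, 1), Wf)
  af <- eval_lattice(Wf)
  w <- Wf[pick_best(Wf, af), ]
  w <- stats::setNames(as.numeric(w), SCHEMES)
  structure(w / sum(w), class = "nts_weights", auc = max(af))
}

#' Train the four-encoding fused ensemble
#'
#' Encodes the training windows under all four schemes, optionally selects
#' features per encoding (RFE ranking + top-N grid), trains one forest per
#' encoding, and sets the fusion weights — either fixed or optimized on
#' out-of-fold probabilities from an internal cross-validation.
#'
#' @param windows Labelled window table (training split).
#' @param w Half-window size, default 20.
#' @param select `"rfe"` (rank + grid per encoding), or `"none"` (all
#'   features).
#' @param weights `"fixed"` (use `fixed_weights`) or `"optimize"`.
#' @param fixed_weights Weights used when `weights = "fixed"`; default
#'   0.01/0.01/0.30/0.68.
#' @param n_trees Trees per forest, default 500.
#' @param cv_folds Folds for grid selection and weight optimization.
#' @param rfe_step Features eliminated per RFE round (default 50); may be a
#'   named per-scheme vector.
#' @param grid_max_size Optional cap on grid subset sizes (may be named per
#'   scheme).
#' @param properties Property tibble for the aaindex encoder.
#' @param K_values k-mer word lengths, default `1:3`.
#' @param seed Integer seed governing every random stage.
#' @return An `nts_ensemble`.
#' @export
train_ensemble <- function(windows, w = 20,
                           select = c("rfe", "none"),
                           weights = c("fixed", "optimize"),
                           fixed_weights = DEFAULT_FUSION_WEIGHTS,
                           n_trees = 500, cv_folds = 5, rfe_step = 50,
                           grid_max_size = NULL, properties = NULL,
                           K_values = 1:3, seed = 1) {
  select <- match.arg(select)
  weights <- match.arg(weights)
  y <- as_label01(windows$label)
  if (anyNA(y)) abort_fmt("train_ensemble() needs fully labelled windows")
  specs <- make_specs(w, properties, K_values)
  per_scheme <- function(x, s, default) {
    if (is.null(x)) default
    else if (!is.null(names(x))) {
      if (s %in% names(x)) unname(x[[s]]) else default
    } else x
  }
  models <- list()
  subsets <- list()
  Xs <- list()
  for (s in SCHEMES) {
    X <- encode_dataset(windows, specs[[s]])
    Xs[[s]] <- X
    subset <- NULL
    if (select == "rfe") {
      rk <- rfe_rank(X, y, step = per_scheme(rfe_step, s, 50),
                     n_trees = n_trees, seed = stage_seed(seed, "rank"))
      subset <- grid_select(rk, X, y, cv_folds = cv_folds, n_trees = n_trees,
                            seed = stage_seed(seed, "grid"),
                            max_size = per_scheme(grid_max_size, s, NULL))
    }
    subsets[[s]] <- subset
    models[[s]] <- train_single(X, y, subset = subset, n_trees = n_trees,
                                seed = stage_seed(seed, "train"))
    models[[s]]$scheme <- s
  }
  if (weights == "optimize") {
    oof <- oof_probs(Xs, y, models, n_trees, cv_folds, seed)
    fusion <- optimize_weights(oof, y)
  } else {
    fusion <- structure(validate_weights(fixed_weights), class = "nts_weights")
  }
  structure(list(models = models, fusion = fusion, specs = specs,
                 subsets = subsets, w = w, seed = seed,
                 version = BUNDLE_VERSION),
            class = "nts_ensemble")
}

make_specs <- function(w, properties = NULL, K_values = 1:3) {
  list(binary = encoding_spec("binary", w = w),
       aaindex = encoding_spec("aaindex", w = w, properties = properties),
       cksaap = encoding_spec("cksaap", w = w),
       kmer = encoding_spec("kmer", w = w, K_values = K_values))
}

# Out-of-fold per-scheme probabilities for weight optimization: refit each
# scheme's model (same subset) inside each training fold.
oof_probs <- function(Xs, y, models, n_trees, cv_folds, seed) {
  fold <- make_folds(y, cv_folds, stage_seed(seed, "fuse"))
  out <- matrix(NA_real_, length(y), length(SCHEMES),
                dimnames = list(NULL, SCHEMES))
  for (s in SCHEMES) {
    feats <- models[[s]]$features
    for (f in seq_len(cv_folds)) {
      tr <- fold != f
      fit <- fit_forest(Xs[[s]][tr, feats, drop = FALSE], y[tr], n_trees,
                        stage_seed(seed, "train") + f, importance = "none")
      out[!tr, s] <- forest_prob(fit, Xs[[s]][!tr, feats, drop = FALSE])
    }
  }
  as.data.frame(out)
}

#' @export
print.nts_ensemble <- function(x, ...) {
  cat("<nts_ensemble>\n")
  for (s in SCHEMES) {
    cat(sprintf("  %-8s %4d features, weight %.2f\n", s,
                length(x$models[[s]]$features), x$fusion[[s]]))
  }
  invisible(x)
}

#' Score tyrosine windows with a trained ensemble
#'
#' @param object An `nts_ensemble`.
#' @param windows A window table (or a protein tibble from [read_fasta()],
#'   in which case windows are extracted first).
#' @param threshold Decision threshold for the `call` column, default 0.5.
#' @param ... Unused.
#' @return The window table with per-scheme probabilities, the fused
#'   `score`, and `call` (1 if `score >= threshold`).
#' @export
predict.nts_ensemble <- function(object, windows, threshold = 0.5, ...) {
  if (is.data.frame(windows) && "sequence" %in% names(windows) &&
      !"window" %in% names(windows)) {
    windows <- extract_windows(windows, w = object$w)
  }
  out <- tibble::as_tibble(windows)
  if (nrow(out) == 0) {
    warning("no tyrosine windows to score", call. = FALSE)
    probs <- matrix(numeric(0), 0, 4, dimnames = list(NULL, SCHEMES))
  } else {
    probs <- vapply(SCHEMES, function(s) {
      predict_single(object$models[[s]],
                     encode_dataset(out, object$specs[[s]]))
    }, numeric(nrow(out)))
    if (nrow(out) == 1) probs <- matrix(probs, 1, dimnames = list(NULL, SCHEMES))
  }
  out[paste0("prob_", SCHEMES)] <- as.data.frame(probs)
  out$score <- if (nrow(out) == 0) numeric(0) else
    fuse_scores(stats::setNames(as.data.frame(probs), SCHEMES), object$fusion)
  out$call <- as.integer(out$score >= threshold)
  out
}

#' Save / load a trained ensemble
#'
#' The bundle is an RDS archive holding the four fitted forests, their
#' selected subsets, encoding specs and fusion weights, tagged with a format
#' version; loading verifies the version and that all four schemes are
#' present, and a reloaded ensemble reproduces predictions bit-identically.
#'
#' @param ensemble An `nts_ensemble`.
#' @param path File path for the bundle.
#' @return `save_ensemble()`: `path`, invisibly. `load_ensemble()`: the
#'   restored `nts_ensemble`.
#' @export
save_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "nts_ensemble"))
  saveRDS(ensemble, path)
  invisible(path)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) abort_fmt(
                    "cannot read model bundle %s: %s", path, conditionMessage(e)))
  if (!inherits(obj, "nts_ensemble")) {
    abort_fmt("file %s is not an ensemble bundle", path)
  }
  if (!identical(obj$version, BUNDLE_VERSION)) {
    abort_fmt("bundle version '%s' does not match supported '%s'",
              obj$version %||% "<none>", BUNDLE_VERSION)
  }
  if (!all(SCHEMES %in% names(obj$models))) {
    abort_fmt("bundle is missing scheme(s): %s",
              paste(setdiff(SCHEMES, names(obj$models)), collapse = ", "))
  }
  obj
}
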