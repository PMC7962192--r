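# Stratified k-fold cross-validation of the full pipeline.

#' Cross-validate the fused predictor
#'
#' Stratified k-fold cross-validation over labelled windows. Encoding is
#' computed once; feature selection (when requested) and model training
#' happen inside each training fold only, so test folds stay untouched.
#' Per-fold Sn/Sp/Acc/MCC/AUC are reported with their mean and standard
#' error across folds, together with pooled out-of-fold AUCs per scheme and
#' for the fused score.
#'
#' @param windows Labelled window table.
#' @param folds Number of folds, default 5.
#' @param seed Integer seed (fold assignment, selection, training).
#' @param w Half-window size, default 20.
#' @param select `"none"` (default: all features), `"rfe"` (selection
#'   nested inside each training fold), or `"once"` (selection performed
#'   once on the full data before cross-validation; faster and mirrors
#'   reporting per subset size, but optimistically biased).
#' @param weights `"fixed"` or `"optimize"` (simplex search on the pooled
#'   out-of-fold probabilities).
#' @param fixed_weights Fusion weights when `weights = "fixed"`.
#' @param threshold `"0.5"` (plain cut) or `"specificity"` (per-fold
#'   threshold calibrated on the training fold to `target_sp`).
#' @param target_sp Target specificity for `threshold = "specificity"`.
#' @param n_trees,rfe_step,grid_max_size,K_values,properties Passed through
#'   to the per-encoding stages (see [train_ensemble()]).
#' @return An `nts_cv` object: list with `per_fold`, `summary`, `oof`
#'   (out-of-fold scores), `auc` (per-scheme + fused pooled OOF AUC),
#'   `fusion` weights used and `fold` assignment.
#' @export
cross_validate <- function(windows, folds = 5, seed = 1, w = 20,
                           select = c("none", "rfe", "once"),
                           weights = c("fixed", "optimize"),
                           fixed_weights = DEFAULT_FUSION_WEIGHTS,
                           threshold = c("0.5", "specificity"),
                           target_sp = 0.8, n_trees = 500, rfe_step = 50,
                           grid_max_size = NULL, K_values = 1:3,
                           properties = NULL) {
  select <- match.arg(select)
  weights <- match.arg(weights)
  threshold <- match.arg(threshold)
  stopifnot(folds >= 2)
  y <- as_label01(windows$label)
  if (anyNA(y)) abort_fmt("cross_validate() needs fully labelled windows")
  specs <- make_specs(w, properties, K_values)
  Xs <- lapply(specs, function(sp) encode_dataset(windows, sp))
  fold <- make_folds(y, folds, stage_seed(seed, "cv"))

  feats_full <- lapply(SCHEMES, function(s) colnames(Xs[[s]]))
  names(feats_full) <- SCHEMES
  if (select == "once") {
    for (s in SCHEMES) {
      rk <- rfe_rank(Xs[[s]], y, step = rfe_step, n_trees = n_trees,
                     seed = stage_seed(seed, "rank"))
      sub <- grid_select(rk, Xs[[s]], y, cv_folds = folds, n_trees = n_trees,
                         seed = stage_seed(seed, "grid"),
                         max_size = grid_max_size)
      feats_full[[s]] <- sub$features
    }
  }

  oof <- matrix(NA_real_, length(y), 4, dimnames = list(NULL, SCHEMES))
  thr_fold <- rep(0.5, folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    tr_probs <- NULL
    for (s in SCHEMES) {
      feats <- feats_full[[s]]
      if (select == "rfe") {
        rk <- rfe_rank(Xs[[s]][tr, , drop = FALSE], y[tr], step = rfe_step,
                       n_trees = n_trees, seed = stage_seed(seed, "rank") + f)
        sub <- grid_select(rk, Xs[[s]][tr, , drop = FALSE], y[tr],
                           cv_folds = min(folds, 5), n_trees = n_trees,
                           seed = stage_seed(seed, "grid") + f,
                           max_size = grid_max_size)
        feats <- sub$features
      }
      fit <- fit_forest(Xs[[s]][tr, feats, drop = FALSE], y[tr], n_trees,
                        stage_seed(seed, "train") + f, importance = "none")
      oof[!tr, s] <- forest_prob(fit, Xs[[s]][!tr, feats, drop = FALSE])
      if (threshold == "specificity") {
        tr_probs <- cbind(tr_probs,
                          forest_prob(fit, Xs[[s]][tr, feats, drop = FALSE]))
      }
    }
    if (threshold == "specificity") {
      colnames(tr_probs) <- SCHEMES
      fw <- validate_weights(if (weights == "fixed") fixed_weights
                             else DEFAULT_FUSION_WEIGHTS)
      thr_fold[f] <- threshold_for_specificity(
        fuse_scores(as.data.frame(tr_probs), fw), y[tr], target_sp)
    }
  }

  fusion <- if (weights == "optimize") {
    optimize_weights(as.data.frame(oof), y)
  } else {
    structure(validate_weights(fixed_weights), class = "nts_weights")
  }
  fused <- fuse_scores(as.data.frame(oof), fusion)

  per_fold <- purrr::map_dfr(seq_len(folds), function(f) {
    te <- fold == f
    m <- evaluate_scores(fused[te], y[te], threshold = thr_fold[f])
    dplyr::bind_cols(tibble::tibble(fold = f), m)
  })
  mets <- c("Sn", "Sp", "Acc", "MCC", "AUC")
  summary <- tibble::tibble(
    metric = mets,
    mean = vapply(mets, function(m) mean(per_fold[[m]]), numeric(1)),
    se = vapply(mets, function(m) stats::sd(per_fold[[m]]) / sqrt(folds),
                numeric(1))
  )
  auc <- c(vapply(SCHEMES, function(s) roc_auc(oof[, s], y)$auc, numeric(1)),
           fused = roc_auc(fused, y)$auc)
  structure(list(per_fold = per_fold, summary = summary,
                 oof = dplyr::bind_cols(
                   tibble::as_tibble(oof),
                   tibble::tibble(fused = fused, label = y, fold = fold)),
                 auc = auc, fusion = fusion, fold = fold,
                 n = length(y), folds = folds, seed = seed),
            class = "nts_cv")
}

#' @export
print.nts_cv <- function(x, ...) {
  cat(sprintf("<nts_cv> %d-fold on %d windows; fused OOF AUC = %.3f\n",
              x$folds, x$n, x$auc[["fused"]]))
  s <- x$summary
  cat(paste(sprintf("  %s = %.3f (%.3f)", s$metric, s$mean, s$se),
            collapse = "\n"), "\n")
  invisible(x)
}
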