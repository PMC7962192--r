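# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cross-validation result
#'
#' @param x An `nts_cv`.
#' @param ... Unused.
#' @return Per-fold metrics, one row per fold.
#' @method tidy nts_cv
#' @export
tidy.nts_cv <- function(x, ...) x$per_fold

#' @rdname tidy.nts_cv
#' @return `glance()`: one row with mean metrics (SE in `*_se` columns),
#'   pooled out-of-fold AUCs per scheme, n and folds.
#' @method glance nts_cv
#' @export
glance.nts_cv <- function(x, ...) {
  s <- x$summary
  wide <- stats::setNames(as.list(s$mean), s$metric)
  wide_se <- stats::setNames(as.list(s$se), paste0(s$metric, "_se"))
  dplyr::bind_cols(tibble::as_tibble(wide), tibble::as_tibble(wide_se),
                   tibble::as_tibble(as.list(x$auc[SCHEMES])),
                   tibble::tibble(auc_fused = x$auc[["fused"]],
                                  n = x$n, folds = x$folds))
}

#' Tidy a trained ensemble
#'
#' @param x An `nts_ensemble`.
#' @param ... Unused.
#' @return One row per scheme: fusion weight, number of features, trees.
#' @method tidy nts_ensemble
#' @export
tidy.nts_ensemble <- function(x, ...) {
  tibble::tibble(
    scheme = SCHEMES,
    weight = as.numeric(x$fusion[SCHEMES]),
    n_features = vapply(SCHEMES, function(s)
      length(x$models[[s]]$features), integer(1)),
    n_trees = vapply(SCHEMES, function(s)
      as.integer(x$models[[s]]$n_trees), integer(1))
  )
}

#' @rdname tidy.nts_ensemble
#' @method glance nts_ensemble
#' @export
glance.nts_ensemble <- function(x, ...) {
  tibble::tibble(w = x$w, window_length = 2L * x$w + 1L,
                 n_schemes = length(x$models), seed = x$seed,
                 version = x$version)
}

#' Tidy a feature ranking or selected subset
#'
#' @param x An `nts_ranking` or `nts_subset`.
#' @param ... Unused.
#' @return For a ranking: `rank`, `feature`, `score`. For a subset: the
#'   grid of evaluated sizes with mean/SE AUC.
#' @method tidy nts_subset
#' @export
tidy.nts_subset <- function(x, ...) x$grid_scores

#' Plot an ROC curve
#'
#' @param object An `nts_roc`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot nts_roc
#' @export
autoplot.nts_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate (1 - Sp)",
                  y = "True positive rate (Sn)",
                  title = sprintf("ROC curve (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot the subset-size selection grid
#'
#' @param object An `nts_subset`.
#' @param ... Unused.
#' @return A ggplot of cross-validated AUC against subset size, with the
#'   chosen size marked.
#' @method autoplot nts_subset
#' @export
autoplot.nts_subset <- function(object, ...) {
  g <- object$grid_scores
  ggplot2::ggplot(g, ggplot2::aes(x = .data$size, y = .data$mean_auc)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_auc - .data$se_auc,
                                      ymax = .data$mean_auc + .data$se_auc),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$chosen_size,
                        linetype = "dashed") +
    ggplot2::labs(x = "Top-N features", y = "CV AUC",
                  title = sprintf("%s: chosen size %d", object$scheme,
                                  object$chosen_size)) +
    ggplot2::theme_minimal()
}
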