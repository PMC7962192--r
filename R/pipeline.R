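# High-level workflow entry points backing the command-line interface:
# simulate / encode / select / train / predict / evaluate. Each writes its
# outputs (TSV reports, model bundle, plain-text log) under an output
# directory and is reproducible from the logged config and seed.

default_run_config <- function() {
  list(w = 20, folds = 5, grid_step = 50, rfe_step = 50, n_trees = 500,
       select = "rfe", weights = "fixed",
       fixed_weights = as.list(DEFAULT_FUSION_WEIGHTS),
       threshold = 0.5, independent_fraction = 0.2, seed = 1,
       K_values = c(1, 2, 3))
}

#' Read a run configuration
#'
#' YAML key/value file merged over the documented defaults (`w = 20`,
#' `folds = 5`, RFE/grid step 50, 500 trees, fixed fusion weights
#' 0.01/0.01/0.30/0.68, threshold 0.5, independent fraction 0.2).
#'
#' @param path Optional YAML file; `NULL` returns the defaults.
#' @return A named list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg[names(user)] <- user
  }
  cfg
}

write_log <- function(out_dir, lines) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(c(sprintf("nitrosite %s | R %s | ranger %s",
                       as.character(utils::packageVersion("nitrosite")),
                       paste(R.version$major, R.version$minor, sep = "."),
                       as.character(utils::packageVersion("ranger"))),
               lines),
             file.path(out_dir, "run.log"))
}

#' Generate a synthetic dataset from the command line
#'
#' @param out_dir Output directory; writes `proteins.fasta`, `sites.tsv`
#'   and a log.
#' @param n_proteins,effect_size,positive_fraction,seed Generator settings
#'   (see [synthetic_config()]).
#' @return Paths of the written files, invisibly.
#' @export
run_simulate <- function(out_dir, n_proteins = 150, effect_size = 1.5,
                         positive_fraction = 0.25, seed = 1) {
  cfg <- synthetic_config(n_proteins = n_proteins, effect_size = effect_size,
                          positive_fraction = positive_fraction, seed = seed)
  dat <- generate_synthetic(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(out_dir, "proteins.fasta")
  st <- file.path(out_dir, "sites.tsv")
  write_fasta(dat$proteins, fa)
  readr::write_tsv(dat$sites, st)
  write_log(out_dir, sprintf(
    "simulate: n_proteins=%d effect_size=%g positive_fraction=%g seed=%d",
    n_proteins, effect_size, positive_fraction, seed))
  invisible(c(fasta = fa, sites = st))
}

load_labelled_windows <- function(fasta, sites, w) {
  proteins <- read_fasta(fasta)
  win <- extract_windows(proteins, w = w)
  if (!is.null(sites)) {
    win <- attach_labels(win, read_site_table(sites))
  }
  win
}

#' Encode windows from the command line
#'
#' @param fasta Input FASTA.
#' @param scheme Encoding scheme.
#' @param out Output TSV of the feature matrix.
#' @param w Half-window size.
#' @return `out`, invisibly.
#' @export
run_encode <- function(fasta, scheme, out, w = 20) {
  win <- load_labelled_windows(fasta, NULL, w)
  spec <- make_specs(w)[[match.arg(scheme, SCHEMES)]]
  write_features(encode_dataset(win, spec), out)
  invisible(out)
}

#' Rank and select features from the command line
#'
#' Writes `<scheme>_ranking.tsv` (rank, feature, score) and
#' `<scheme>_grid.tsv` (size, mean/SE AUC) under `out_dir`.
#'
#' @param fasta,sites Labelled input.
#' @param scheme Encoding scheme.
#' @param out_dir Output directory.
#' @param config Optional YAML config path.
#' @return The selected subset, invisibly.
#' @export
run_select <- function(fasta, sites, scheme, out_dir, config = NULL) {
  cfg <- read_run_config(config)
  scheme <- match.arg(scheme, SCHEMES)
  win <- load_labelled_windows(fasta, sites, cfg$w)
  win <- win[win$label != "unknown", , drop = FALSE]
  X <- encode_dataset(win, make_specs(cfg$w, K_values = cfg$K_values)[[scheme]])
  rk <- rfe_rank(X, win$label, step = cfg$rfe_step, n_trees = cfg$n_trees,
                 seed = stage_seed(cfg$seed, "rank"))
  sub <- grid_select(rk, X, win$label, grid_step = cfg$grid_step,
                     cv_folds = cfg$folds, n_trees = cfg$n_trees,
                     seed = stage_seed(cfg$seed, "grid"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_selection(rk, file.path(out_dir, paste0(scheme, "_ranking.tsv")))
  write_selection(sub, file.path(out_dir, paste0(scheme, "_grid.tsv")))
  write_log(out_dir, sprintf("select: scheme=%s chosen_size=%d seed=%d",
                             scheme, sub$chosen_size, cfg$seed))
  invisible(sub)
}

#' Train the fused predictor from the command line
#'
#' Splits the labelled windows into a balanced training set and an
#' unbalanced independent set, cross-validates on the training set, trains
#' the final ensemble on all training windows, and writes the model bundle
#' (`ensemble.rds`), the CV report (`cv_metrics.tsv`), per-encoding grid
#' reports, the held-out windows (`independent.tsv`) and a log with all
#' seeds.
#'
#' @param fasta,sites Labelled input.
#' @param out_dir Output directory.
#' @param config Optional YAML config path (see [read_run_config()]).
#' @return The trained `nts_ensemble`, invisibly.
#' @export
run_train <- function(fasta, sites, out_dir, config = NULL) {
  cfg <- read_run_config(config)
  win <- load_labelled_windows(fasta, sites, cfg$w)
  win <- win[win$label != "unknown", , drop = FALSE]
  split <- make_split(win, cfg$independent_fraction,
                      seed = stage_seed(cfg$seed, "split"))
  cv <- cross_validate(split$training, folds = cfg$folds, seed = cfg$seed,
                       w = cfg$w, select = "none", weights = cfg$weights,
                       fixed_weights = unlist(cfg$fixed_weights),
                       n_trees = cfg$n_trees, K_values = cfg$K_values)
  ens <- train_ensemble(split$training, w = cfg$w, select = cfg$select,
                        weights = cfg$weights,
                        fixed_weights = unlist(cfg$fixed_weights),
                        n_trees = cfg$n_trees, cv_folds = cfg$folds,
                        rfe_step = cfg$rfe_step, K_values = cfg$K_values,
                        seed = cfg$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  save_ensemble(ens, file.path(out_dir, "ensemble.rds"))
  readr::write_tsv(cv$summary, file.path(out_dir, "cv_metrics.tsv"))
  readr::write_tsv(tidy(cv), file.path(out_dir, "cv_folds.tsv"))
  for (s in SCHEMES) {
    if (!is.null(ens$subsets[[s]])) {
      write_selection(ens$subsets[[s]],
                      file.path(out_dir, paste0(s, "_grid.tsv")))
    }
  }
  write_windows(split$independent, file.path(out_dir, "independent.tsv"))
  write_log(out_dir, c(
    sprintf("train: seed=%d split_seed=%d w=%d folds=%d n_trees=%d select=%s",
            cfg$seed, split$split_seed, cfg$w, cfg$folds, cfg$n_trees,
            cfg$select),
    sprintf("fusion: %s",
            paste(sprintf("%s=%.2f", SCHEMES, ens$fusion[SCHEMES]),
                  collapse = " "))))
  invisible(ens)
}

#' Score a FASTA file with a trained model bundle
#'
#' One output row per tyrosine: 1-based position, window, per-scheme
#' probabilities, fused score and the call at the threshold.
#'
#' @param bundle Path to an `ensemble.rds` bundle.
#' @param fasta Input FASTA.
#' @param out Output TSV.
#' @param threshold Decision threshold, default 0.5.
#' @return The prediction tibble, invisibly.
#' @export
run_predict <- function(bundle, fasta, out, threshold = 0.5) {
  ens <- load_ensemble(bundle)
  preds <- predict(ens, read_fasta(fasta), threshold = threshold)
  readr::write_tsv(preds, out)
  invisible(preds)
}

#' Evaluate a trained bundle on labelled data
#'
#' Writes a metrics report (Sn, Sp, Acc, MCC, AUC and confusion counts) at
#' both operating points: the plain 0.5 threshold and a fixed-specificity
#' threshold calibrated on the evaluated scores.
#'
#' @param bundle Path to an `ensemble.rds` bundle.
#' @param fasta,sites Labelled input.
#' @param out Output TSV.
#' @param target_sp Specificity for the calibrated operating point.
#' @return The metrics tibble, invisibly.
#' @export
run_evaluate <- function(bundle, fasta, sites, out, target_sp = 0.8) {
  ens <- load_ensemble(bundle)
  win <- load_labelled_windows(fasta, sites, ens$w)
  win <- win[win$label != "unknown", , drop = FALSE]
  y <- as_label01(win$label)
  if (length(unique(y)) < 2) {
    abort_fmt("evaluation needs both classes present (AUC undefined)")
  }
  preds <- predict(ens, win)
  m1 <- evaluate_scores(preds$score, y, threshold = 0.5)
  thr <- threshold_for_specificity(preds$score, y, target_sp)
  m2 <- evaluate_scores(preds$score, y, threshold = thr)
  rep <- dplyr::bind_cols(
    tibble::tibble(operating_point = c("threshold_0.5", "fixed_specificity")),
    dplyr::bind_rows(m1, m2))
  readr::write_tsv(rep, out)
  invisible(rep)
}
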