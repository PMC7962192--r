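# Single-encoding models, score fusion, weight optimization, serialization.

make_training <- function(n = 140, w = 5, seed = 17) {
  win <- toy_windows(n = n, w = w, seed = seed)
  X <- encode_dataset(win, encoding_spec("binary", w = w))
  list(win = win, X = X, y = as.integer(win$label == "positive"))
}

test_that("train_single/predict_single honour contracts for all methods", {
  d <- make_training()
  for (method in c("rf", "nb", "knn")) {
    m <- train_single(d$X, d$y, n_trees = 120, seed = 5, method = method)
    p <- predict_single(m, d$X)
    expect_length(p, nrow(d$X))
    expect_true(all(p >= 0 & p <= 1))
    # determinism
    m2 <- train_single(d$X, d$y, n_trees = 120, seed = 5, method = method)
    expect_identical(p, predict_single(m2, d$X))
    # duplicated rows score identically
    Xdup <- d$X[c(1, 1), , drop = FALSE]
    pd <- predict_single(m, Xdup)
    expect_equal(pd[1], pd[2])
  }
})

test_that("a forest overfits separable training data (sanity) and nulls to chance", {
  d <- make_training(n = 160)
  m <- train_single(d$X, d$y, n_trees = 300, seed = 1)
  expect_equal(roc_auc(predict_single(m, d$X), d$y)$auc, 1, tolerance = 0.01)
  expect_true(all(predict_single(m, d$X)[d$y == 1] > 0.5))

  # label permutation: CV AUC near 0.5 on average
  aucs <- vapply(1:10, function(s) {
    yperm <- withr::with_seed(s, sample(d$y))
    fold <- nitrosite:::make_folds(yperm, 5, s)
    mean(vapply(1:5, function(f) {
      tr <- fold != f
      fit <- train_single(d$X[tr, ], yperm[tr], n_trees = 60, seed = s)
      roc_auc(predict_single(fit, d$X[!tr, ]), yperm[!tr])$auc
    }, numeric(1)))
  }, numeric(1))
  expect_gte(mean(aucs), 0.4)
  expect_lte(mean(aucs), 0.6)
})

test_that("train_single validates subset features against the matrix", {
  d <- make_training(n = 60)
  expect_error(train_single(d$X, d$y, subset = c("bin_p1_A", "nope"), seed = 1),
               "nope")
  m <- train_single(d$X, d$y, subset = colnames(d$X)[1:30], seed = 1)
  expect_error(predict_single(m, d$X[, 31:60]), "absent")
})

test_that("fuse_scores is the stated convex combination", {
  probs <- tibble::tibble(binary = 1, aaindex = 1, cksaap = 1, kmer = 1)
  expect_equal(fuse_scores(probs), 1)

  w_kmer <- c(binary = 0, aaindex = 0, cksaap = 0, kmer = 1)
  p2 <- tibble::tibble(binary = 0.2, aaindex = 0.9, cksaap = 0.4,
                       kmer = c(0.123, 0.9))
  expect_equal(fuse_scores(p2, w_kmer), p2$kmer)

  p3 <- tibble::tibble(binary = 0, aaindex = 1, cksaap = 0.5, kmer = 0.5)
  expect_equal(fuse_scores(p3, rep(0.25, 4)), 0.5)

  # convexity bounds on random inputs
  withr::with_seed(2, {
    P <- tibble::tibble(binary = runif(50), aaindex = runif(50),
                        cksaap = runif(50), kmer = runif(50))
  })
  f <- fuse_scores(P)
  expect_true(all(f >= do.call(pmin, P) - 1e-12))
  expect_true(all(f <= do.call(pmax, P) + 1e-12))

  expect_error(fuse_scores(p3, c(0.5, 0.5, 0.5, 0.5)), "sum to 1")
  expect_error(fuse_scores(p3, c(-0.5, 0.5, 0.5, 0.5)), "non-negative")
})

test_that("optimize_weights recovers a planted optimum and satisfies contracts", {
  withr::with_seed(8, {
    y <- rbinom(240, 1, 0.5)
    probs <- tibble::tibble(
      binary = runif(240), aaindex = runif(240), cksaap = runif(240),
      kmer = 0.9 * y + 0.1 * runif(240))  # kmer nearly equals the labels
  })
  w <- optimize_weights(probs, y)
  expect_gte(w[["kmer"]], 0.9)
  expect_equal(sum(w), 1, tolerance = 1e-9)
  expect_true(all(w >= 0))

  # all schemes identical: AUC constant, tie-break returns a vertex
  same <- tibble::tibble(binary = probs$kmer, aaindex = probs$kmer,
                         cksaap = probs$kmer, kmer = probs$kmer)
  wv <- optimize_weights(same, y)
  expect_equal(max(wv), 1)
})

test_that("train_ensemble + predict produce fused scores; save/load round-trips", {
  win <- toy_windows(n = 120, w = 4, seed = 33)
  ens <- train_ensemble(win, w = 4, select = "none", weights = "fixed",
                        n_trees = 80, seed = 9)
  expect_s3_class(ens, "nts_ensemble")
  expect_setequal(names(ens$models), c("binary", "aaindex", "cksaap", "kmer"))

  preds <- predict(ens, win)
  expect_true(all(preds$score >= 0 & preds$score <= 1))
  expect_true(all(c("prob_binary", "prob_kmer", "score", "call") %in%
                    names(preds)))
  # fused score within per-scheme bounds (convexity)
  pm <- as.matrix(preds[paste0("prob_", c("binary", "aaindex", "cksaap",
                                          "kmer"))])
  expect_true(all(preds$score >= apply(pm, 1, min) - 1e-12))
  expect_true(all(preds$score <= apply(pm, 1, max) + 1e-12))

  f <- tempfile(fileext = ".rds")
  save_ensemble(ens, f)
  back <- load_ensemble(f)
  expect_identical(predict(back, win)$score, preds$score)

  # corrupted file and wrong object are load errors
  bad <- tempfile(fileext = ".rds")
  writeLines("not an rds", bad)
  expect_error(load_ensemble(bad), "cannot read")
  notens <- tempfile(fileext = ".rds")
  saveRDS(list(a = 1), notens)
  expect_error(load_ensemble(notens), "not an ensemble")
  # missing scheme is an integrity error
  crippled <- ens
  crippled$models$kmer <- NULL
  cf <- tempfile(fileext = ".rds")
  saveRDS(crippled, cf)
  expect_error(load_ensemble(cf), "kmer")

  # tidiers
  td <- tidy(ens)
  expect_equal(nrow(td), 4)
  expect_equal(sum(td$weight), 1)
  expect_equal(glance(ens)$window_length, 9)
})

test_that("optimized fusion is at least as good as the best single scheme", {
  win <- toy_windows(n = 150, w = 5, seed = 51)
  cv <- cross_validate(win, folds = 5, seed = 2, w = 5, select = "none",
                       weights = "optimize", n_trees = 80)
  expect_gte(cv$auc[["fused"]] + 1e-9,
             max(cv$auc[c("binary", "aaindex", "cksaap", "kmer")]))
})
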