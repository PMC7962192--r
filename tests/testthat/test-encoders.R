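# Feature encodings: dimensions, hand-enumerated values, block-sum
# invariants, oracle equivalence on short windows, AAindex handling.

test_that("binary encoding is one-hot per position with gap as 21st letter", {
  sp <- encoding_spec("binary", w = 20)
  v <- encode_binary(paste0(strrep("-", 20), "Y", strrep("-", 20)), sp)
  expect_length(v, 861)
  expect_equal(sum(v), 41)  # exactly one 1 per position
  expect_equal(unname(v["bin_p21_Y"]), 1)
  expect_equal(sum(v[grepl("_-$", names(v))]), 40)

  sp2 <- encoding_spec("binary", w = 2)
  v2 <- encode_binary("A-Y-A", sp2)
  on <- names(v2)[v2 == 1]
  expect_equal(on, c("bin_p1_A", "bin_p2_-", "bin_p3_Y", "bin_p4_-",
                     "bin_p5_A"))
  expect_equal(sum(v2), 5)

  # every 21-block sums to 1 for gap/standard-only windows
  win <- toy_windows(n = 25, w = 4)
  X <- encode_dataset(win, encoding_spec("binary", w = 4))
  expect_true(all(rowSums(X) == 9))
  blocks <- matrix(colSums(X), nrow = 21)
  expect_equal(colSums(matrix(t(X[1, ]), nrow = 21)), rep(1, 9),
               ignore_attr = TRUE)
})

test_that("unencodable X residues give an all-zero block with a warning", {
  sp <- encoding_spec("binary", w = 1)
  expect_warning(v <- encode_binary("XYX", sp), "zero block")
  expect_equal(sum(v), 1)
})

test_that("aaindex encoding concatenates standardized per-position properties", {
  sp <- encoding_spec("aaindex", w = 20)
  v <- encode_aaindex(paste0(strrep("-", 20), "Y", strrep("-", 20)), sp)
  expect_length(v, 615)
  # all-gap window except the centre: only the 15 central entries nonzero
  expect_true(all(v[-(300 + 1:15)] == 0))
  expect_true(any(v[300 + 1:15] != 0))

  # constructed single-property table: value(A) = 1, others arbitrary
  props <- tibble::tibble(property_id = "CONST", description = "test")
  vals <- stats::setNames(as.list(rep(0, 20)), AA20_T)
  vals$A <- 1
  props <- dplyr::bind_cols(props, tibble::as_tibble(vals))
  sp1 <- encoding_spec("aaindex", w = 2, properties = props)
  v1 <- encode_aaindex("AAYAA", sp1)
  # after z-standardization across letters the A/Y pattern is preserved:
  # four equal A values and a different central Y value
  expect_length(v1, 5)
  expect_equal(v1[1], v1[2], ignore_attr = TRUE)
  expect_equal(v1[4], v1[5], ignore_attr = TRUE)
  expect_false(v1[3] == v1[1])
})

test_that("aaindex standardization gives mean 0 / sd 1 across letters and 0 for gaps", {
  lk <- nitrosite:::property_lookup(default_properties())
  expect_equal(dim(lk), c(21, 15), ignore_attr = TRUE)
  expect_equal(colMeans(lk[1:20, ]), rep(0, 15), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(apply(lk[1:20, ], 2, sd), rep(1, 15), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(lk[21, ] == 0))
})

test_that("read_aaindex parses the AAindex1 flat format", {
  path <- system.file("extdata", "aaindex_example_synthetic.txt",
                      package = "nitrosite")
  tbl <- read_aaindex(path)
  expect_equal(tbl$property_id, c("SYNT000101", "SYNT000201"))
  expect_equal(tbl$A, c(0.1, -1.0))
  expect_equal(tbl$V, c(0.85, 1.25))
  expect_equal(tbl$Y, c(0.5, -0.75))

  bad <- tempfile()
  writeLines(c("H BADREC0101", "D incomplete",
               "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
               "  0.1 0.2 0.3"), bad)
  expect_error(read_aaindex(bad), "value block|missing a letter")
})

test_that("cksaap counts k-spaced pairs, skipping gaps, slot denominator", {
  sp0 <- encoding_spec("cksaap", w = 2, k_values = 0)
  v0 <- encode_cksaap("AAAAA", sp0)
  expect_equal(unname(v0["cks_k0_AA"]), 1)
  expect_equal(sum(v0), 1)

  sp1 <- encoding_spec("cksaap", w = 2, k_values = 1)
  v1 <- encode_cksaap("AYAYA", sp1)
  expect_equal(unname(v1["cks_k1_AA"]), 2 / 3)
  expect_equal(unname(v1["cks_k1_YY"]), 1 / 3)
  expect_equal(sum(v1 > 0), 2)

  # gap-containing pairs reduce the numerator only
  vg <- encode_cksaap("-AYAY", sp1)
  expect_equal(sum(vg), 2 / 3)  # slots (1,3) lost to the gap

  # per-k block sums: 1 for gap-free windows, in [0, 1] with gaps
  win <- toy_windows(n = 30, w = 6)
  X <- encode_dataset(win, encoding_spec("cksaap", w = 6, k_values = 0:4))
  for (bi in 0:4) {
    bs <- rowSums(X[, bi * 400 + 1:400])
    gapfree <- !grepl("-", win$window, fixed = TRUE)
    expect_equal(bs[gapfree], rep(1, sum(gapfree)), ignore_attr = TRUE)
    expect_true(all(bs >= 0 & bs <= 1 + 1e-12))
  }
})

test_that("kmer counts contiguous words, blocks concatenated in ascending K", {
  spk <- encoding_spec("kmer", w = 2, K_values = 2)
  vk <- encode_kmer("AAAAA", spk)
  expect_equal(unname(vk["kmer_K2_AA"]), 1)
  expect_equal(sum(vk), 1)

  sp13 <- encoding_spec("kmer", w = 2, K_values = c(1, 3))
  expect_length(feature_names(sp13), 8020)
  v13 <- encode_kmer("AYAYA", sp13)
  expect_equal(unname(v13["kmer_K1_A"]), 3 / 5)
  expect_equal(unname(v13["kmer_K1_Y"]), 2 / 5)
  expect_equal(unname(v13["kmer_K3_AYA"]), 2 / 3)
  expect_equal(unname(v13["kmer_K3_YAY"]), 1 / 3)

  # gap-free K-blocks sum to 1
  win <- toy_windows(n = 20, w = 5)
  X <- encode_dataset(win, encoding_spec("kmer", w = 5, K_values = 1:2))
  gapfree <- !grepl("-", win$window, fixed = TRUE)
  expect_equal(rowSums(X[gapfree, 1:20]), rep(1, sum(gapfree)),
               ignore_attr = TRUE)
  expect_equal(rowSums(X[gapfree, 20 + 1:400]), rep(1, sum(gapfree)),
               ignore_attr = TRUE)
})

test_that("cksaap and kmer match the naive double-loop oracles", {
  withr::with_seed(31, {
    wins <- c(
      replicate(40, paste(sample(c(AA20_T[1:5], "-"), 7, TRUE), collapse = "")),
      replicate(40, paste(sample(AA20_T, 9, TRUE), collapse = "")))
  })
  for (win in wins) {
    L <- nchar(win)
    for (k in 0:2) {
      got <- encode_cksaap(win, encoding_spec("cksaap", w = (L - 1) / 2,
                                              k_values = k))
      expect_equal(got, naive_cksaap(win, k))
    }
    for (K in 1:2) {
      got <- encode_kmer(win, encoding_spec("kmer", w = (L - 1) / 2,
                                            K_values = K))
      expect_equal(got, naive_kmer(win, K))
    }
  }
})

test_that("encode_dataset keeps row order, handles 0 rows, is deterministic", {
  win <- toy_windows(n = 3, w = 20)
  sp <- encoding_spec("binary", w = 20)
  X <- encode_dataset(win, sp)
  expect_equal(dim(X), c(3, 861))
  expect_equal(attr(X, "row_ids")$position, win$position)

  X0 <- encode_dataset(character(0), sp)
  expect_equal(dim(X0), c(0, 861))
  expect_equal(colnames(X0), feature_names(sp))

  expect_identical(unclass(X), unclass(encode_dataset(win, sp)))

  expect_error(encode_dataset(c("AYA", "AYAYA"), encoding_spec("binary", w = 1)),
               "length")
})
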