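# FASTA / site-table I/O, window extraction, redundancy reduction, splitting.

test_that("read_fasta parses records in order and round-trips with write_fasta", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">p1 some description", "MKY", ">p2", "ayya", "KK"), fa)
  tbl <- read_fasta(fa)
  expect_equal(tbl$id, c("p1", "p2"))
  expect_equal(tbl$sequence, c("MKY", "AYYAKK"))

  out <- tempfile(fileext = ".fasta")
  write_fasta(tbl, out)
  expect_equal(read_fasta(out)$sequence, tbl$sequence)

  empty <- tempfile(fileext = ".fasta")
  file.create(empty)
  expect_equal(nrow(read_fasta(empty)), 0)
})

test_that("read_fasta rejects malformed input, naming the line", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c("MKY", ">p1", "MKY"), fa)
  expect_error(read_fasta(fa), "line 1")

  fa2 <- tempfile(fileext = ".fasta")
  writeLines(c(">p1", "MKY", ">p2"), fa2)
  expect_error(read_fasta(fa2), "no sequence")
})

test_that("non-standard residues are collapsed to X with a warning", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">p1", "MKBYU"), fa)
  expect_warning(tbl <- read_fasta(fa), "non-standard")
  expect_equal(tbl$sequence, "MKXYX")
  expect_equal(tbl$n_nonstandard, 2L)
})

test_that("extract_windows yields one centred, padded window per tyrosine", {
  w1 <- extract_windows(tibble::tibble(id = "p", sequence = "Y"), w = 20)
  expect_equal(nrow(w1), 1)
  expect_equal(w1$window, paste0(strrep("-", 20), "Y", strrep("-", 20)))
  expect_equal(nchar(w1$window), 41)

  # hand enumeration: Y at 2 spans 0..4, Y at 4 spans 2..6 (one pad each)
  w2 <- extract_windows(tibble::tibble(id = "p", sequence = "AYAYA"), w = 2)
  expect_equal(w2$position, c(2L, 4L))
  expect_equal(w2$window, c("-AYAY", "YAYA-"))
  expect_true(all(substr(w2$window, 3, 3) == "Y"))

  expect_equal(nrow(extract_windows(tibble::tibble(id = "p", sequence = "AKA"),
                                    w = 2)), 0)
})

test_that("window count equals Y count and the centre is always Y", {
  withr::with_seed(7, {
    for (i in 1:20) {
      s <- paste(sample(AA20_T, sample(5:120, 1), replace = TRUE),
                 collapse = "")
      win <- extract_windows(tibble::tibble(id = "r", sequence = s), w = 20)
      expect_equal(nrow(win), stringr::str_count(s, "Y"))
      if (nrow(win) > 0) {
        expect_true(all(substr(win$window, 21, 21) == "Y"))
        expect_true(all(nchar(win$window) == 41))
        # padding only in maximal terminal runs
        core <- gsub("^-+|-+$", "", win$window)
        expect_false(any(grepl("-", core, fixed = TRUE)))
      }
    }
  })
})

test_that("attach_labels marks listed sites positive, the rest negative", {
  p <- tibble::tibble(id = "p", sequence = "YAYAY")
  win <- extract_windows(p, w = 2)
  sites <- tibble::tibble(protein_id = "p", position = 3L, label = 1L)
  lab <- attach_labels(win, sites)
  expect_equal(lab$label, c("negative", "positive", "negative"))

  # protein listed with zero positive sites -> all its windows negative
  sites0 <- tibble::tibble(protein_id = "p", position = c(1L, 5L),
                           label = c(0L, 0L))
  expect_equal(attach_labels(win, sites0)$label, rep("negative", 3))

  # protein absent from the table keeps unknown
  win2 <- dplyr::bind_rows(win, extract_windows(
    tibble::tibble(id = "q", sequence = "AYA"), w = 2))
  lab2 <- attach_labels(win2, sites)
  expect_equal(lab2$label[lab2$protein_id == "q"], "unknown")

  # a position that is not a tyrosine is a validation error naming it
  bad <- tibble::tibble(protein_id = "p", position = 2L, label = 1L)
  expect_error(attach_labels(win, bad), "p:2")
})

test_that("reduce_redundancy keeps one representative per identity cluster", {
  mk <- function(...) tibble::tibble(protein_id = "p",
                                     position = seq_along(c(...)),
                                     window = c(...), label = "unknown")
  two_same <- mk("AYAAA", "AYAAA")
  expect_equal(nrow(reduce_redundancy(two_same, 0.4)), 1)

  all_diff <- mk("AYAAA", "CWCCC")
  expect_equal(nrow(reduce_redundancy(all_diff, 0.4)), 2)

  # hand-computed identities on constructed strings
  five <- mk("AYAAA",  # representative
             "AYACC",  # identity 3/5 = 0.6 with w1 -> dropped
             "CYACC",  # identity 2/5 = 0.4 with w1 -> dropped (ties drop)
             "CWCCC",  # 0/5 with w1 -> kept
             "DWDDD")  # 0/5 with w1, 1/5 with w4 -> kept
  out <- reduce_redundancy(five, 0.4)
  expect_equal(out$window, c("AYAAA", "CWCCC", "DWDDD"))
})

test_that("no retained pair reaches the identity threshold (brute force)", {
  win <- toy_windows(n = 150, w = 5, seed = 9)
  out <- reduce_redundancy(win, 0.4)
  M <- do.call(rbind, strsplit(out$window, ""))
  n <- nrow(M)
  for (i in seq_len(n - 1)) {
    ident <- rowMeans(M[(i + 1):n, , drop = FALSE] ==
                        matrix(M[i, ], n - i, ncol(M), byrow = TRUE))
    expect_true(all(ident < 0.4))
  }
})

test_that("make_split balances training and holds out the stated fraction", {
  win <- tibble::tibble(
    protein_id = "p", position = 1:50,
    window = replicate(50, paste(sample(AA20_T, 5, TRUE), collapse = "")),
    label = rep(c("positive", "negative"), c(10, 40)))
  sp <- make_split(win, independent_fraction = 0.2, seed = 3)
  expect_equal(sum(sp$independent$label == "positive"), 2)
  expect_equal(sum(sp$independent$label == "negative"), 8)
  expect_equal(sum(sp$training$label == "positive"), 8)
  expect_equal(sum(sp$training$label == "negative"), 8)

  # partitions disjoint, union within input
  key <- function(d) paste(d$protein_id, d$position)
  expect_length(intersect(key(sp$training), key(sp$independent)), 0)
  expect_true(all(c(key(sp$training), key(sp$independent)) %in% key(win)))

  # determinism
  sp2 <- make_split(win, independent_fraction = 0.2, seed = 3)
  expect_identical(sp, sp2)

  # fraction 0: empty independent set, training balanced from all
  sp0 <- make_split(win, independent_fraction = 0, seed = 3)
  expect_equal(nrow(sp0$independent), 0)
  expect_equal(sum(sp0$training$label == "positive"),
               sum(sp0$training$label == "negative"))

  expect_error(make_split(win[1:3, ], 0.2, 1), "at least 2")
})

test_that("site tables and window tables round-trip through TSV", {
  win <- toy_windows(n = 30, w = 5)
  f <- tempfile(fileext = ".tsv")
  write_windows(win, f)
  back <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(back$window, win$window)
  expect_equal(back$position, win$position)

  sites <- tibble::tibble(protein_id = "p", position = c(2L, 9L),
                          label = c(1L, 0L))
  sf <- tempfile(fileext = ".tsv")
  readr::write_tsv(sites, sf)
  expect_equal(read_site_table(sf), sites)
})
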