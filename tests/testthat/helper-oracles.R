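# Independent brute-force oracles and small data builders used across tests.

AA20_T <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Naive CKSAAP: explicit double loop over pair slots; pairs touching a
# non-standard character are skipped, denominator is the slot count.
naive_cksaap <- function(window, k, normalize = TRUE) {
  ch <- strsplit(window, "")[[1]]
  L <- length(ch)
  counts <- matrix(0, 20, 20, dimnames = list(AA20_T, AA20_T))
  for (i in seq_len(L - k - 1)) {
    a <- ch[i]
    b <- ch[i + k + 1]
    if (a %in% AA20_T && b %in% AA20_T) counts[a, b] <- counts[a, b] + 1
  }
  v <- as.vector(t(counts))
  names(v) <- paste0("cks_k", k, "_",
                     as.vector(t(outer(AA20_T, AA20_T, paste0))))
  if (normalize) v / (L - k - 1) else v
}

# Naive k-mer composition: loop over word starts.
naive_kmer <- function(window, K, normalize = TRUE) {
  ch <- strsplit(window, "")[[1]]
  L <- length(ch)
  words <- do.call(paste0,
                   rev(expand.grid(replicate(K, AA20_T, simplify = FALSE),
                                   stringsAsFactors = FALSE)))
  counts <- stats::setNames(rep(0, 20^K), words)
  for (i in seq_len(L - K + 1)) {
    wd <- paste(ch[i:(i + K - 1)], collapse = "")
    if (wd %in% words) counts[wd] <- counts[wd] + 1
  }
  names(counts) <- paste0("kmer_K", K, "_", words)
  if (normalize) counts / (L - K + 1) else counts
}

# Brute-force AUC over all positive/negative pairs (ties count 1/2).
pairwise_auc <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  g <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(g)
}

# A feature matrix with known informative columns: class-shifted Gaussians.
planted_matrix <- function(n = 400, p_inf = 10, p_noise = 40, shift = 0.8,
                           seed = 1) {
  withr::with_seed(seed, {
    y <- rep(0:1, each = n / 2)
    X <- matrix(rnorm(n * (p_inf + p_noise)), n)
    X[, seq_len(p_inf)] <- X[, seq_len(p_inf)] + outer(y, rep(shift, p_inf))
  })
  colnames(X) <- c(sprintf("inf%03d", seq_len(p_inf)),
                   sprintf("noise%03d", seq_len(p_noise)))
  list(X = X, y = y, informative = sprintf("inf%03d", seq_len(p_inf)))
}

# Tiny deterministic labelled window set for classifier contract tests.
toy_windows <- function(n = 120, w = 5, seed = 42) {
  synthetic_windows(
    synthetic_config(n_proteins = 30, length_range = c(40, 80),
                     effect_size = 3, seed = seed),
    w = w, n_windows = n)
}

write_temp_fasta <- function(proteins) {
  fa <- tempfile(fileext = ".fasta")
  write_fasta(proteins, fa)
  fa
}

# Drop names/attributes so encoded matrices compare on values alone.
strip_attrs <- function(X) matrix(as.numeric(X), nrow(X))
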