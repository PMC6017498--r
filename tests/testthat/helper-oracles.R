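# Independent brute-force oracles, deliberately naive implementations
# kept separate from the code paths they check.

# Window-count oracle for the neural response: explicit loop, no table().
oracle_response <- function(seq, size) {
  n <- nchar(seq)
  wins <- vapply(seq_len(n - size + 1L),
                 function(i) substr(seq, i, i + size - 1L), character(1L))
  out <- numeric(0L)
  for (w in wins) out[w] <- (if (is.na(out[w])) 0 else out[w]) + 1
  out / length(wins)
}

# All strings of a given length over an alphabet.
all_strings <- function(alphabet, len) {
  grid <- do.call(expand.grid, rep(list(alphabet), len))
  apply(grid, 1L, paste, collapse = "")
}

# Dense feature vector of a sequence over the full template set A^size.
dense_response <- function(seq, size, alphabet) {
  templates <- all_strings(alphabet, size)
  f <- oracle_response(seq, size)
  out <- stats::setNames(numeric(length(templates)), templates)
  out[names(f)] <- f
  out
}

# Cosine similarity of dense k-mer feature vectors.
oracle_cosine <- function(s1, s2, size, alphabet) {
  v1 <- dense_response(s1, size, alphabet)
  v2 <- dense_response(s2, size, alphabet)
  sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
}

# Explicit leave-one-out retraining for ridge on a Gram matrix, at a
# fixed effective ridge value.
oracle_loo <- function(K, y, ridge) {
  m <- nrow(K)
  vapply(seq_len(m), function(i) {
    co <- solve(K[-i, -i] + diag(ridge, m - 1L), y[-i])
    drop(K[i, -i] %*% co)
  }, numeric(1L))
}

# Pairwise-comparison AUC with half-counted ties.
oracle_auc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == -1]
  total <- 0
  for (a in sp) for (b in sn)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(sp) * length(sn))
}

# Random PSD Gram matrix (not necessarily unit-diagonal).
random_psd <- function(m) {
  X <- matrix(stats::rnorm(m * m), m)
  crossprod(X) / m
}

random_string <- function(alphabet, len) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

pair_key <- function(pairs) paste(pairs$protein_id, pairs$rna_id)

# Small FASTA writer used to build fixtures the reader is tested against
# (independent of the package's own write_fasta).
write_fasta_lines <- function(records, path, wrap = NULL) {
  lines <- unlist(lapply(names(records), function(id) {
    s <- records[[id]]
    body <- if (is.null(wrap)) s
    else substring(s, seq(1L, nchar(s), wrap),
                   pmin(seq(1L, nchar(s), wrap) + wrap - 1L, nchar(s)))
    c(paste0(">", id), body)
  }))
  writeLines(lines, path)
  path
}
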