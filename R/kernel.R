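#' Second-layer neural response of a sequence
#'
#' The neural response at template size \eqn{k} maps each \eqn{k}-mer
#' \eqn{t} to the fraction of the sequence's \eqn{n - k + 1} contiguous
#' windows equal to \eqn{t}: averaging the exact-match first-layer kernel
#' over all window translations. Only observed templates are stored (the
#' response is zero off its support), so the full template set \eqn{A^k}
#' is never materialized.
#'
#' @param seq a single sequence string (already canonicalized/reduced).
#' @param size template size \eqn{k \ge 1}.
#' @return An object of class \code{"neural_response"}: a list with
#'   \code{entries} (named numeric vector of template frequencies, summing
#'   to 1), \code{size}, and \code{n_windows}.
#' @examples
#' neural_response("ACAC", 2)  # AC: 2/3, CA: 1/3
#' @export
neural_response <- function(seq, size) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  size <- as.integer(size)
  if (size < 1L) stopf("template size must be >= 1")
  n <- nchar(seq)
  if (n < size)
    stopf("sequence of length %d is shorter than template size %d", n, size)
  entries <- kmer_frequencies(seq, size)
  structure(
    list(entries = entries, size = size, n_windows = n - size + 1L),
    class = "neural_response"
  )
}

# Named frequency vector of contiguous k-mers (the response's entries).
kmer_frequencies <- function(seq, size) {
  n <- nchar(seq)
  windows <- substring(seq, 1:(n - size + 1L), size:n)
  tab <- table(windows)
  f <- as.numeric(tab) / (n - size + 1L)
  names(f) <- names(tab)
  f
}

#' @export
print.neural_response <- function(x, ...) {
  cat("Neural response (template size ", x$size, ", ",
      length(x$entries), " of ", x$n_windows, " windows distinct)\n",
      sep = "")
  print(utils::head(sort(x$entries, decreasing = TRUE), 10L))
  invisible(x)
}

#' Raw and normalized second-layer kernels
#'
#' \code{k2_raw} is the \eqn{L^2} inner product of two neural responses
#' under the uniform measure on the template set \eqn{A^k}: the dot
#' product of the two frequency vectors divided by \eqn{|A|^k}.
#' \code{k2_normalized} applies correlation normalization,
#' \eqn{\hat K_2(f,g) = K_2(f,g) / \sqrt{K_2(f,f) K_2(g,g)}}, under which
#' the uniform-measure factor cancels and the value equals the cosine
#' similarity of the k-mer frequency vectors; every self-similarity is 1.
#'
#' @param f,g \code{\link{neural_response}} objects at the same template
#'   size.
#' @param alphabet_size size of the alphabet \eqn{|A|} the sequences are
#'   drawn from (20, 7 or 4).
#' @return A single numeric kernel value; \code{k2_normalized} lies in
#'   \eqn{[0, 1]}.
#' @examples
#' f <- neural_response("ACAC", 2)
#' g <- neural_response("CACA", 2)
#' k2_normalized(f, g, 4)  # 0.8
#' @export
k2_raw <- function(f, g, alphabet_size) {
  stopifnot(inherits(f, "neural_response"), inherits(g, "neural_response"))
  if (f$size != g$size)
    stopf("template sizes differ (%d vs %d)", f$size, g$size)
  alphabet_size <- as.numeric(alphabet_size)
  stopifnot(length(alphabet_size) == 1L, alphabet_size >= 1)
  shared <- intersect(names(f$entries), names(g$entries))
  dot <- if (length(shared)) sum(f$entries[shared] * g$entries[shared]) else 0
  dot / alphabet_size^f$size
}

#' @rdname k2_raw
#' @export
k2_normalized <- function(f, g, alphabet_size) {
  num <- k2_raw(f, g, alphabet_size)
  ff <- k2_raw(f, f, alphabet_size)
  gg <- k2_raw(g, g, alphabet_size)
  stopifnot(ff > 0, gg > 0) # guaranteed for any response with >= 1 window
  num / sqrt(ff * gg)
}

#' Tensor-product kernel between two RNA-protein pairs
#'
#' The similarity of pairs \eqn{(r, p)} and \eqn{(r', p')} is the product
#' of the normalized RNA-RNA kernel at template size \code{l} and the
#' normalized protein-protein kernel at template size \code{k}. Under the
#' reduced alphabet the proteins are mapped to their 7-group encoding
#' before k-mer extraction.
#'
#' @param r1,p1,r2,p2 raw RNA and protein sequence strings.
#' @param k protein template size.
#' @param l RNA template size.
#' @param alphabet protein representation: \code{"full20"} or
#'   \code{"reduced7g"}.
#' @return Kernel value in \eqn{[0, 1]}; 1 iff both factors are 1.
#' @export
pair_kernel <- function(r1, p1, r2, p2, k = 2L, l = 5L,
                        alphabet = c("full20", "reduced7g")) {
  alphabet <- match.arg(alphabet)
  r1 <- canonicalize_rna(r1); r2 <- canonicalize_rna(r2)
  p1 <- canonicalize_protein(p1); p2 <- canonicalize_protein(p2)
  if (alphabet == "reduced7g") {
    p1 <- reduce_protein(p1); p2 <- reduce_protein(p2)
  }
  asize <- if (alphabet == "reduced7g") 7 else 20
  kr <- k2_normalized(neural_response(r1, l), neural_response(r2, l), 4)
  kp <- k2_normalized(neural_response(p1, k), neural_response(p2, k), asize)
  kr * kp
}

# ---- matrix machinery -----------------------------------------------------

# Sparse k-mer frequency matrix (templates x sequences) with unit-L2
# columns. `resps` is a named list of frequency vectors.
response_matrix <- function(resps) {
  keys <- unique(unlist(lapply(resps, names), use.names = FALSE))
  i <- unlist(lapply(resps, function(r) match(names(r), keys)),
              use.names = FALSE)
  j <- rep.int(seq_along(resps), vapply(resps, length, integer(1L)))
  M <- Matrix::sparseMatrix(i = i, j = j, x = unlist(resps, use.names = FALSE),
                            dims = c(length(keys), length(resps)))
  nrm <- sqrt(Matrix::colSums(M^2))
  M %*% Matrix::Diagonal(x = 1 / nrm)
}

# Normalized kernel matrix among `resps` (and optionally against a second
# response set): cosine of frequency vectors, diagonal clamped to exactly 1
# after asserting it is 1 within 1e-12.
response_kernel_matrix <- function(resps, resps2 = NULL) {
  if (is.null(resps2)) {
    M <- response_matrix(resps)
    K <- as.matrix(Matrix::crossprod(M))
    stopifnot(max(abs(diag(K) - 1)) < 1e-12)
    diag(K) <- 1
    K[K < 0] <- 0
    K[K > 1] <- 1
    dimnames(K) <- list(names(resps), names(resps))
  } else {
    all <- response_matrix(c(resps, resps2))
    i1 <- seq_along(resps)
    K <- as.matrix(Matrix::crossprod(all[, i1, drop = FALSE],
                                     all[, -i1, drop = FALSE]))
    K[K < 0] <- 0
    K[K > 1] <- 1
    dimnames(K) <- list(names(resps), names(resps2))
  }
  K
}

# Frequency profiles for a named vector of canonical sequences, with an
# error listing every sequence shorter than the template size.
sequence_responses <- function(seqs, size, what) {
  short <- names(seqs)[nchar(seqs) < size]
  if (length(short))
    stopf("%s sequence(s) shorter than template size %d: %s",
          what, size, abbrev(short))
  lapply(seqs, kmer_frequencies, size = size)
}

# Prepare (canonicalize, optionally reduce) the sequences a pair table
# touches and compute the per-sequence k-mer profiles once.
prepare_responses <- function(pairs, proteins, rnas, k, l, alphabet) {
  proteins <- canonicalize_protein(proteins)
  rnas <- canonicalize_rna(rnas)
  validate_pairs(pairs, proteins, rnas)
  if (alphabet == "reduced7g") proteins <- reduce_protein(proteins)
  pids <- unique(pairs$protein_id)
  rids <- unique(pairs$rna_id)
  list(
    protein = sequence_responses(proteins[pids], k, "protein"),
    rna = sequence_responses(rnas[rids], l, "RNA")
  )
}

#' Gram matrix of the tensor-product pair kernel
#'
#' Assembles the full kernel matrix for a set of RNA-protein pairs. Each
#' distinct sequence's k-mer profile is computed once and reused across
#' all pairs touching it, so the cost is driven by the number of distinct
#' proteins and RNAs rather than the number of pairs.
#'
#' @param pairs data.frame with columns \code{protein_id}, \code{rna_id}.
#' @param proteins,rnas named character vectors of sequences covering all
#'   ids in \code{pairs}.
#' @inheritParams pair_kernel
#' @return A symmetric matrix with unit diagonal and entries in
#'   \eqn{[0,1]}, positive semidefinite up to numerical tolerance;
#'   dimnames are \code{"protein_id|rna_id"} pair identifiers. Write it
#'   with \code{write.table} for external inspection.
#' @export
rpi_gram <- function(pairs, proteins, rnas, k = 2L, l = 5L,
                     alphabet = c("full20", "reduced7g")) {
  alphabet <- match.arg(alphabet)
  resp <- prepare_responses(pairs, proteins, rnas, k, l, alphabet)
  KP <- response_kernel_matrix(resp$protein)
  KR <- response_kernel_matrix(resp$rna)
  G <- KR[pairs$rna_id, pairs$rna_id, drop = FALSE] *
    KP[pairs$protein_id, pairs$protein_id, drop = FALSE]
  ids <- pair_ids(pairs)
  dimnames(G) <- list(ids, ids)
  G
}

pair_ids <- function(pairs) paste(pairs$protein_id, pairs$rna_id, sep = "|")
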