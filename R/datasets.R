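#' Remove redundant RNA-protein pairs
#'
#' Collapses pairs in which the same protein chain interacts with the
#' same RNA chain. By default identity is judged on the residue strings
#' (PDB-derived chains often share a sequence under different ids), with
#' \code{by = "ids"} available for purely id-based tables. The first
#' occurrence of each distinct pair is kept; the operation is
#' idempotent.
#'
#' @param pairs pair table (\code{protein_id}, \code{rna_id}, optional
#'   \code{label}).
#' @param proteins,rnas named sequence vectors; required for
#'   \code{by = "residues"}.
#' @param by judge pair identity on \code{"residues"} (default) or
#'   \code{"ids"}.
#' @return The deduplicated pair table.
#' @export
dedupe_pairs <- function(pairs, proteins = NULL, rnas = NULL,
                         by = c("residues", "ids")) {
  by <- match.arg(by)
  validate_pairs(pairs, proteins, rnas)
  if (nrow(pairs) == 0L) return(pairs)
  if (by == "residues") {
    if (is.null(proteins) || is.null(rnas))
      stopf("residue-based deduplication needs `proteins` and `rnas`")
    key <- paste(proteins[pairs$protein_id], rnas[pairs$rna_id], sep = "\r")
  } else {
    key <- paste(pairs$protein_id, pairs$rna_id, sep = "\r")
  }
  out <- pairs[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter pairs by minimum sequence length
#'
#' Drops every pair whose protein is shorter than
#' \code{min_protein_len} residues or whose RNA is shorter than
#' \code{min_rna_len} nucleotides (strict inequality: a protein of
#' exactly \code{min_protein_len} residues is kept). The dropped rows
#' and their reasons are attached as the \code{"drop_log"} attribute of
#' the result.
#'
#' @inheritParams dedupe_pairs
#' @param min_protein_len minimum amino-acid length (default 25).
#' @param min_rna_len minimum nucleotide length (default 15).
#' @return The filtered pair table with attribute \code{"drop_log"}, a
#'   data.frame of dropped rows with a \code{reason} column.
#' @export
apply_length_filter <- function(pairs, proteins, rnas,
                                min_protein_len = 25L, min_rna_len = 15L) {
  validate_pairs(pairs, proteins, rnas)
  plen <- nchar(proteins[pairs$protein_id])
  rlen <- nchar(rnas[pairs$rna_id])
  short_p <- plen < min_protein_len
  short_r <- rlen < min_rna_len
  drop <- short_p | short_r
  reason <- character(sum(drop))
  reason[short_p[drop] & short_r[drop]] <- "protein and RNA too short"
  reason[short_p[drop] & !short_r[drop]] <-
    sprintf("protein length < %d", min_protein_len)
  reason[!short_p[drop] & short_r[drop]] <-
    sprintf("RNA length < %d", min_rna_len)
  log <- cbind(pairs[drop, , drop = FALSE], reason = reason)
  out <- pairs[!drop, , drop = FALSE]
  rownames(out) <- rownames(log) <- NULL
  attr(out, "drop_log") <- log
  out
}

#' Sample non-interacting pairs by protein permutation
#'
#' Constructs a balanced negative set from a positive pair table by
#' randomly permuting the protein column while keeping the RNA column
#' fixed, repeating the permutation until no generated pair occurs in
#' the positive set (and no pair is duplicated). The protein and RNA
#' multisets of the result therefore equal those of the positives. Pure
#' rejection sampling can stall on hub-heavy tables, so after
#' \code{max_restarts / 2} failed draws a local repair pass swaps
#' conflicting entries pairwise; if no valid assignment is found within
#' \code{max_restarts} attempts the function fails with a diagnosis.
#'
#' @param positives pair table of interacting pairs.
#' @param seed integer seed; the result is deterministic given
#'   \code{(positives, seed)}.
#' @param max_restarts attempts before giving up.
#' @return A pair table of the same size with \code{label = -1},
#'   disjoint from \code{positives}.
#' @export
sample_negatives <- function(positives, seed, max_restarts = 100L) {
  validate_pairs(positives)
  n <- nrow(positives)
  if (n == 0L) stopf("positive pair table is empty")
  pos_key <- paste(positives$protein_id, positives$rna_id, sep = "\r")
  prot <- positives$protein_id
  rna <- positives$rna_id

  conflicts <- function(perm) {
    key <- paste(perm, rna, sep = "\r")
    which(key %in% pos_key | duplicated(key) | duplicated(key, fromLast = TRUE))
  }
  repair <- function(perm) {
    for (iter in seq_len(20L * n)) {
      bad <- conflicts(perm)
      if (!length(bad)) return(perm)
      i <- bad[[1L]]
      j <- sample.int(n, 1L)
      if (j == i) next
      cand <- perm
      cand[c(i, j)] <- perm[c(j, i)]
      if (length(conflicts(cand)) < length(bad)) perm <- cand
    }
    perm
  }

  perm <- with_seed(seed, {
    found <- NULL
    for (attempt in seq_len(max_restarts)) {
      p <- sample(prot)
      if (attempt > max_restarts / 2) p <- repair(p)
      if (!length(conflicts(p))) { found <- p; break }
    }
    found
  })
  if (is.null(perm)) {
    n_rna <- length(unique(rna))
    partners <- tapply(rna, prot, function(x) length(unique(x)))
    hubs <- names(partners)[partners == n_rna]
    hint <- if (length(hubs))
      sprintf(" (protein(s) %s partner every RNA, so no conflict-free permutation exists)",
              abbrev(hubs))
    else " (interaction table may be too dense for a conflict-free permutation)"
    stopf("could not sample a negative set disjoint from the positives within %d restarts%s",
          max_restarts, hint)
  }
  out <- data.frame(protein_id = perm, rna_id = rna, label = -1L,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
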