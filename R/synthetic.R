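#' Simulate RNA-protein pairs with plantable interaction motifs
#'
#' Generates a balanced, labeled set of synthetic RNA-protein pairs for
#' testing and benchmarking the classifier without any external data.
#' Every pair gets its own background protein and RNA sequence drawn
#' i.i.d. from the alphabet (uniformly, or from an optional composition
#' table to emulate organism-specific skew). In interacting pairs, a
#' short protein motif and a short RNA motif are planted at random
#' positions (each positive pair carries both motifs with probability
#' \code{signal_rate}); planting replaces residues, so lengths are
#' unchanged. Non-interacting pairs are pure background. Labels can
#' optionally be flipped with probability \code{label_noise}.
#'
#' @param n_pairs total number of pairs (even; half interacting, half
#'   not).
#' @param protein_len_range,rna_len_range inclusive length ranges the
#'   background sequences are drawn from.
#' @param protein_motif,rna_motif motif strings over the protein /
#'   RNA alphabet.
#' @param signal_rate fraction of positive pairs carrying both motifs.
#' @param label_noise probability of flipping each label.
#' @param seed integer seed; output is fully reproducible.
#' @param protein_composition,rna_composition optional named weight
#'   vectors over the alphabet for background residue sampling.
#' @return A list with \code{proteins} and \code{rnas} (named character
#'   vectors, ids \code{P0001...}/\code{R0001...}) and \code{pairs} (a
#'   labeled pair table).
#' @examples
#' sim <- simulate_rpi_data(n_pairs = 20, seed = 42)
#' table(sim$pairs$label)
#' @export
simulate_rpi_data <- function(n_pairs = 200L,
                              protein_len_range = c(50L, 200L),
                              rna_len_range = c(30L, 120L),
                              protein_motif = "KWR",
                              rna_motif = "UGCA",
                              signal_rate = 1,
                              label_noise = 0,
                              seed = 1L,
                              protein_composition = NULL,
                              rna_composition = NULL) {
  n_pairs <- as.integer(n_pairs)
  if (n_pairs < 2L || n_pairs %% 2L != 0L)
    stopf("n_pairs must be an even number >= 2 (balanced classes)")
  protein_motif <- canonicalize_protein(protein_motif)
  rna_motif <- canonicalize_rna(rna_motif)
  if (nchar(protein_motif) > protein_len_range[1L])
    stopf("protein motif longer than the minimum protein length")
  if (nchar(rna_motif) > rna_len_range[1L])
    stopf("RNA motif longer than the minimum RNA length")
  if (signal_rate < 0 || signal_rate > 1 || label_noise < 0 || label_noise > 1)
    stopf("signal_rate and label_noise must lie in [0, 1]")

  prot_weights <- composition_weights(protein_composition, .alphabets$protein20)
  rna_weights <- composition_weights(rna_composition, .alphabets$rna4)

  with_seed(seed, {
    npos <- n_pairs %/% 2L
    labels <- rep(c(1L, -1L), c(npos, n_pairs - npos))
    proteins <- character(n_pairs)
    rnas <- character(n_pairs)
    for (i in seq_len(n_pairs)) {
      p <- random_seq(.alphabets$protein20, protein_len_range, prot_weights)
      r <- random_seq(.alphabets$rna4, rna_len_range, rna_weights)
      if (labels[i] == 1L && stats::runif(1L) <= signal_rate) {
        p <- plant_motif(p, protein_motif)
        r <- plant_motif(r, rna_motif)
      }
      proteins[i] <- p
      rnas[i] <- r
    }
    if (label_noise > 0) {
      flip <- stats::runif(n_pairs) < label_noise
      labels[flip] <- -labels[flip]
    }
    names(proteins) <- sprintf("P%04d", seq_len(n_pairs))
    names(rnas) <- sprintf("R%04d", seq_len(n_pairs))
    pairs <- data.frame(protein_id = names(proteins),
                        rna_id = names(rnas),
                        label = labels, stringsAsFactors = FALSE)
    list(proteins = proteins, rnas = rnas, pairs = pairs)
  })
}

composition_weights <- function(composition, alphabet) {
  if (is.null(composition)) return(rep(1, length(alphabet)))
  if (is.null(names(composition)) ||
      !all(names(composition) %in% alphabet) ||
      any(composition < 0) || sum(composition) <= 0)
    stopf("composition must be a non-negative named vector over the alphabet")
  w <- stats::setNames(rep(0, length(alphabet)), alphabet)
  w[names(composition)] <- composition
  unname(w)
}

random_seq <- function(alphabet, len_range, weights) {
  len <- if (len_range[1L] == len_range[2L]) len_range[1L]
  else sample(len_range[1L]:len_range[2L], 1L)
  paste(sample(alphabet, len, replace = TRUE, prob = weights), collapse = "")
}

# Replace len(motif) residues at a random position; length preserved.
plant_motif <- function(seq, motif) {
  n <- nchar(seq)
  w <- nchar(motif)
  start <- sample.int(n - w + 1L, 1L)
  paste0(substr(seq, 1L, start - 1L), motif, substr(seq, start + w, n))
}

#' Write a simulated data set to FASTA and TSV files
#'
#' Emits the simulated sequences and pair table in exactly the formats
#' real inputs use, so downstream commands cannot tell the difference.
#'
#' @param sim result of \code{\link{simulate_rpi_data}}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Named character vector of the three written paths,
#'   invisibly.
#' @export
write_rpi_data <- function(sim, dir, prefix = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    proteins = file.path(dir, paste0(prefix, "_proteins.fasta")),
    rnas = file.path(dir, paste0(prefix, "_rnas.fasta")),
    pairs = file.path(dir, paste0(prefix, "_pairs.tsv"))
  )
  write_fasta(sim$proteins, paths[["proteins"]])
  write_fasta(sim$rnas, paths[["rnas"]])
  write_pairs(sim$pairs, paths[["pairs"]])
  invisible(paths)
}
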