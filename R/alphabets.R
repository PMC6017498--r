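#' Sequence alphabets
#'
#' The three alphabets used throughout the package: the 20 standard amino
#' acids (\code{"protein20"}), the 7-group reduced amino-acid alphabet
#' (\code{"protein7g"}, groups encoded as the digits \code{1}--\code{7}),
#' and the 4 ribonucleotides (\code{"rna4"}).
#'
#' The reduced alphabet partitions the amino acids by dipole moment and
#' side-chain volume into seven physicochemical groups:
#' \{A,G,V\}, \{I,L,F,P\}, \{Y,M,T,S\}, \{H,N,Q,W\}, \{R,K\}, \{D,E\},
#' \{C\}, encoded in that order as \code{"1"} ... \code{"7"}.
#'
#' @param name one of \code{"protein20"}, \code{"protein7g"}, \code{"rna4"}.
#' @return Character vector of single-character symbols, in canonical order.
#' @examples
#' rpi_alphabet("rna4")
#' length(rpi_alphabet("protein7g"))
#' @export
rpi_alphabet <- function(name = c("protein20", "protein7g", "rna4")) {
  name <- match.arg(name)
  .alphabets[[name]]
}

.alphabets <- list(
  protein20 = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]],
  protein7g = as.character(1:7),
  rna4      = c("A", "C", "G", "U")
)

# Amino acid -> 7-group digit, groups listed in canonical order.
.group7 <- c(
  A = "1", G = "1", V = "1",
  I = "2", L = "2", F = "2", P = "2",
  Y = "3", M = "3", T = "3", S = "3",
  H = "4", N = "4", Q = "4", W = "4",
  R = "5", K = "5",
  D = "6", E = "6",
  C = "7"
)

# Shared validator: uppercase `x`, check every character against `alphabet`.
# ambiguous = "error": reject, naming element and first bad position;
# ambiguous = "drop":  remove offending elements (names preserved).
.canonicalize <- function(x, alphabet, what, ambiguous = c("error", "drop")) {
  ambiguous <- match.arg(ambiguous)
  if (length(x) == 0L) return(character(0L))
  if (!is.character(x)) stopf("%s sequences must be character strings", what)
  if (any(is.na(x)) || any(!nzchar(x)))
    stopf("%s sequences must be non-empty and non-missing", what)
  x2 <- toupper(x)
  if (what == "RNA") x2 <- chartr("T", "U", x2)
  chars <- strsplit(x2, "", fixed = TRUE)
  bad <- vapply(chars, function(ch) {
    w <- which(!ch %in% alphabet)
    if (length(w)) w[1L] else 0L
  }, integer(1L))
  if (any(bad > 0L)) {
    if (ambiguous == "drop") {
      x2 <- x2[bad == 0L]
    } else {
      i <- which(bad > 0L)[1L]
      id <- if (!is.null(names(x))) names(x)[i] else paste0("#", i)
      stopf(
        "invalid %s residue '%s' at position %d of sequence %s",
        what, chars[[i]][bad[i]], bad[i], id
      )
    }
  }
  x2
}

#' Canonicalize RNA sequences
#'
#' Uppercases, maps DNA-style \code{T} to \code{U}, and validates every
#' residue against the 4-letter RNA alphabet. Applying the function twice
#' gives the same result as applying it once.
#'
#' @param x character vector of raw sequences (optionally named by id).
#' @param ambiguous policy for residues outside \code{A,C,G,U,T}:
#'   \code{"error"} (default) rejects with the offending position;
#'   \code{"drop"} silently removes the whole offending sequence. Silent
#'   single-residue substitution is deliberately not offered, because it
#'   would perturb k-mer profiles invisibly.
#' @return Character vector of validated RNA sequences over \code{A,C,G,U}.
#' @examples
#' canonicalize_rna("acgt")
#' @export
canonicalize_rna <- function(x, ambiguous = c("error", "drop")) {
  .canonicalize(x, .alphabets$rna4, "RNA", ambiguous)
}

#' Canonicalize protein sequences
#'
#' Uppercases and validates against the 20 standard amino acids. Ambiguity
#' codes (X, B, Z, J, O, U, ...) follow the same policy as
#' \code{\link{canonicalize_rna}}.
#'
#' @inheritParams canonicalize_rna
#' @return Character vector of validated protein sequences.
#' @export
canonicalize_protein <- function(x, ambiguous = c("error", "drop")) {
  .canonicalize(x, .alphabets$protein20, "protein", ambiguous)
}

#' Reduce protein sequences to the 7-group alphabet
#'
#' Replaces every amino acid by the digit of its physicochemical group
#' (see \code{\link{rpi_alphabet}}); the result has the same length and
#' names as the input. The mapping is a total function on the 20 amino
#' acids: every residue belongs to exactly one group.
#'
#' @param x character vector of protein sequences over the 20-letter
#'   alphabet (validated first).
#' @return Character vector over the digits \code{1}--\code{7}.
#' @examples
#' reduce_protein("ARNDC")  # "15467"
#' @export
reduce_protein <- function(x) {
  x <- canonicalize_protein(x)
  chartr(paste(names(.group7), collapse = ""),
         paste(unname(.group7), collapse = ""), x)
}
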