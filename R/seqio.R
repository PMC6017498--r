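#' Read sequences from a FASTA file
#'
#' Reads a (possibly line-wrapped) multi-record FASTA file and returns a
#' named character vector of canonicalized sequences. The id of each
#' record is the first whitespace-delimited token of its header line.
#'
#' @param path path to a FASTA file.
#' @param type \code{"protein"} or \code{"rna"}; controls which alphabet
#'   the sequences are validated against (RNA additionally maps T to U).
#' @param ambiguous policy for residues outside the alphabet; see
#'   \code{\link{canonicalize_rna}}. With \code{"drop"} the offending
#'   records are removed and a message names them.
#' @return Named character vector of sequences.
#' @seealso \code{\link{write_fasta}}, \code{\link{read_pairs}}
#' @export
read_fasta <- function(path, type = c("protein", "rna"),
                       ambiguous = c("error", "drop")) {
  type <- match.arg(type)
  ambiguous <- match.arg(ambiguous)
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stopf("malformed FASTA '%s': %s",
                                            path, conditionMessage(e)))
  if (length(set) == 0L) stopf("FASTA file '%s' contains no records", path)
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[`, character(1L), 1L)
  if (anyDuplicated(ids))
    stopf("duplicate FASTA ids in '%s': %s", path,
          abbrev(unique(ids[duplicated(ids)])))
  seqs <- as.character(set)
  if (any(!nzchar(seqs)))
    stopf("empty sequence for record(s): %s in '%s'",
          abbrev(ids[!nzchar(seqs)]), path)
  names(seqs) <- ids
  canon <- if (type == "rna") canonicalize_rna else canonicalize_protein
  out <- canon(seqs, ambiguous = ambiguous)
  if (ambiguous == "drop" && length(out) < length(seqs))
    message("dropped ", length(seqs) - length(out),
            " record(s) with ambiguous residues: ",
            abbrev(setdiff(ids, names(out))))
  out
}

#' Write sequences to a FASTA file
#'
#' @param x named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width for residues.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stopf("sequences must be named by id to write FASTA")
  set <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Read a labeled pair table
#'
#' Reads a tab-separated table of RNA-protein pairs with columns
#' \code{protein_id}, \code{rna_id} and (optionally) \code{label}. A
#' header row is detected automatically. Labels are parsed to the
#' canonical \eqn{\{-1, +1\}} coding; the \code{0/1} dialect (0 =
#' non-interacting) is accepted via \code{labels = "01"}. Tables without
#' a label column are allowed only for prediction and yield \code{NA}
#' labels.
#'
#' @param path path to a TSV file with 2 or 3 columns.
#' @param proteins,rnas optional named sequence vectors; when supplied,
#'   every id in the table must resolve against them.
#' @param labels label dialect: \code{"auto"} (default) infers
#'   \code{"pm1"} (\eqn{-1/+1}) unless the values are all in \{0, 1\}
#'   and a 0 is present, \code{"pm1"}, or \code{"01"}.
#' @return A \code{data.frame} with columns \code{protein_id},
#'   \code{rna_id}, \code{label} (integer \eqn{-1/+1}, or \code{NA} if
#'   unlabeled).
#' @export
read_pairs <- function(path, proteins = NULL, rnas = NULL,
                       labels = c("auto", "pm1", "01")) {
  labels <- match.arg(labels)
  if (!file.exists(path)) stopf("pair table not found: %s", path)
  raw <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           blank.lines.skip = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L || ncol(raw) > 3L)
    stopf("pair table '%s' must have 2 or 3 tab-separated columns, found %d",
          path, ncol(raw))
  # header detection: the first row is a header when its fields name the
  # columns rather than containing data
  looks_header <- any(grepl("^(protein|rna|label)", unlist(raw[1L, ]),
                            ignore.case = TRUE))
  if (looks_header) raw <- raw[-1L, , drop = FALSE]
  if (nrow(raw) == 0L) stopf("pair table '%s' has no data rows", path)
  out <- data.frame(protein_id = raw[[1L]], rna_id = raw[[2L]],
                    stringsAsFactors = FALSE)
  if (ncol(raw) == 3L) {
    out$label <- parse_labels(raw[[3L]], labels)
  } else {
    out$label <- NA_integer_
  }
  validate_pairs(out, proteins, rnas)
  rownames(out) <- NULL
  out
}

parse_labels <- function(x, dialect) {
  x <- trimws(x)
  bad <- setdiff(unique(x), c("-1", "1", "+1", "0"))
  if (length(bad)) stopf("unparseable pair label(s): %s", abbrev(bad))
  if (dialect == "auto")
    dialect <- if (any(x == "0") && !any(x %in% c("-1", "+1"))) "01" else "pm1"
  if (dialect == "pm1") {
    if (any(x == "0")) stopf("label '0' not valid under the -1/+1 dialect")
    ifelse(x %in% c("1", "+1"), 1L, -1L)
  } else {
    if (any(x %in% c("-1", "+1"))) stopf("label outside {0,1} under the 0/1 dialect")
    ifelse(x == "1", 1L, -1L)
  }
}

# Invariants every pair table must satisfy; ids checked when sequences given.
validate_pairs <- function(pairs, proteins = NULL, rnas = NULL,
                           need_labels = FALSE) {
  stopifnot(is.data.frame(pairs))
  if (!all(c("protein_id", "rna_id") %in% names(pairs)))
    stopf("pair table needs columns protein_id and rna_id")
  key <- paste(pairs$protein_id, pairs$rna_id, sep = "\r")
  if (anyDuplicated(key))
    stopf("duplicate (protein_id, rna_id) pair(s): %s",
          abbrev(sub("\r", " / ", unique(key[duplicated(key)]))))
  if (!is.null(proteins)) {
    miss <- setdiff(pairs$protein_id, names(proteins))
    if (length(miss)) stopf("unknown protein id(s) in pair table: %s", abbrev(miss))
  }
  if (!is.null(rnas)) {
    miss <- setdiff(pairs$rna_id, names(rnas))
    if (length(miss)) stopf("unknown RNA id(s) in pair table: %s", abbrev(miss))
  }
  if (need_labels) {
    lab <- pairs$label
    if (is.null(lab) || any(is.na(lab)) || !all(lab %in% c(-1L, 1L)))
      stopf("pair table must carry labels in {-1, +1} for this operation")
  }
  invisible(pairs)
}

#' Write a pair table as TSV
#'
#' @param pairs data.frame with columns \code{protein_id}, \code{rna_id}
#'   and optionally \code{label} (and any extra columns, e.g. scores).
#' @param path output path.
#' @param header write a header row?
#' @return \code{path}, invisibly.
#' @export
write_pairs <- function(pairs, path, header = TRUE) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = header)
  invisible(path)
}
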