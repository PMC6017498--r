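#' Build a predicted interaction network from scored pairs
#'
#' Thresholds prediction scores into an undirected bipartite edge list
#' (an edge for every pair scored above \code{threshold}) and tabulates
#' node degrees, which makes hub proteins and hub RNAs easy to spot.
#'
#' @param scores data.frame with columns \code{protein_id},
#'   \code{rna_id}, \code{score} (e.g. from
#'   \code{\link{predict.rpirls}}).
#' @param threshold scores strictly above this value become edges
#'   (default 0, matching the classifier's decision rule).
#' @return An object of class \code{"rpi_network"}: \code{edges}
#'   (protein_id, rna_id, score) and \code{degrees} (node, type,
#'   degree, sorted by degree).
#' @export
interaction_network <- function(scores, threshold = 0) {
  stopifnot(is.data.frame(scores),
            all(c("protein_id", "rna_id", "score") %in% names(scores)))
  keep <- !is.na(scores$score) & scores$score > threshold
  edges <- scores[keep, c("protein_id", "rna_id", "score"), drop = FALSE]
  rownames(edges) <- NULL
  deg <- data.frame(
    node = c(edges$protein_id, edges$rna_id),
    type = rep(c("protein", "rna"), each = nrow(edges)),
    stringsAsFactors = FALSE
  )
  degrees <- if (nrow(deg)) {
    agg <- stats::aggregate(list(degree = rep(1L, nrow(deg))),
                            by = deg[c("node", "type")], FUN = sum)
    agg[order(-agg$degree, agg$node), , drop = FALSE]
  } else {
    data.frame(node = character(0L), type = character(0L),
               degree = integer(0L), stringsAsFactors = FALSE)
  }
  rownames(degrees) <- NULL
  structure(list(edges = edges, degrees = degrees, threshold = threshold),
            class = "rpi_network")
}

#' @export
print.rpi_network <- function(x, ...) {
  cat(sprintf("Predicted interaction network: %d edge(s) above threshold %g\n",
              nrow(x$edges), x$threshold))
  cat(sprintf("  %d protein node(s), %d RNA node(s)\n",
              sum(x$degrees$type == "protein"), sum(x$degrees$type == "rna")))
  hubs <- utils::head(x$degrees, 5L)
  if (nrow(hubs)) {
    cat("  highest-degree nodes:\n")
    for (i in seq_len(nrow(hubs)))
      cat(sprintf("    %s (%s): %d\n", hubs$node[i], hubs$type[i],
                  hubs$degree[i]))
  }
  invisible(x)
}

#' Write a network as a SIF file
#'
#' One line per edge in Cytoscape's simple interaction format:
#' \code{protein interacts rna}. An empty network yields a valid empty
#' file.
#'
#' @param network an \code{\link{interaction_network}} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_sif <- function(network, path) {
  stopifnot(inherits(network, "rpi_network"))
  lines <- if (nrow(network$edges))
    paste(network$edges$protein_id, "interacts", network$edges$rna_id)
  else character(0L)
  writeLines(lines, path)
  invisible(path)
}
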