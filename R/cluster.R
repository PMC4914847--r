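#' All-vs-all local alignment scores
#'
#' Symmetric matrix of Smith-Waterman local-alignment scores under BLOSUM62
#' with affine gaps (open 11, extend 1); the diagonal holds self-scores. The
#' matrix carries the sequence lengths as an attribute for later
#' normalization.
#'
#' @param records an \code{AAStringSet} of at least two sequences.
#' @param gapOpening,gapExtension affine gap costs.
#' @param substitutionMatrix name of the substitution matrix (default
#'   \code{"BLOSUM62"}).
#' @return numeric matrix with dimnames = record ids and attribute
#'   \code{"lengths"}.
#' @export
pairwiseScores <- function(records, gapOpening = 11, gapExtension = 1,
                           substitutionMatrix = "BLOSUM62") {
  n <- length(records)
  if (n < 2L) stop("need at least two records")
  if (is.null(names(records))) names(records) <- paste0("record", seq_len(n))
  mcols(records) <- NULL
  m <- matrix(0, n, n, dimnames = list(names(records), names(records)))
  for (i in seq_len(n)) {
    sc <- Biostrings::pairwiseAlignment(
      pattern = records[i:n], subject = records[[i]], type = "local",
      substitutionMatrix = substitutionMatrix,
      gapOpening = gapOpening, gapExtension = gapExtension, scoreOnly = TRUE)
    m[i, i:n] <- sc
    m[i:n, i] <- sc
  }
  attr(m, "lengths") <- stats::setNames(Biostrings::width(records),
                                        names(records))
  m
}

#' Build a threshold similarity graph
#'
#' Keeps edges whose (normalized) score reaches the threshold and computes the
#' connected components deterministically (components numbered by their
#' lexicographically smallest member). Under \code{BITS_PER_SHORTER} the raw
#' score is halved (BLOSUM62 is in half-bits) and divided by the length of the
#' shorter sequence, so the threshold is in bits per residue.
#'
#' @param scores matrix from \code{\link{pairwiseScores}}.
#' @param threshold numeric cutoff; must be >= 0 under
#'   \code{BITS_PER_SHORTER}.
#' @param normalization \code{"BITS_PER_SHORTER"} (default) or \code{"RAW"}.
#' @return a \linkS4class{SimilarityGraph}.
#' @export
buildSimilarityGraph <- function(scores, threshold = 0.5,
                                 normalization = c("BITS_PER_SHORTER", "RAW")) {
  normalization <- match.arg(normalization)
  if (normalization == "BITS_PER_SHORTER" && threshold < 0)
    stop("threshold must be >= 0 under BITS_PER_SHORTER")
  if (!isTRUE(all.equal(scores, t(scores), check.attributes = FALSE)))
    stop("score matrix must be symmetric")
  lens <- attr(scores, "lengths")
  ids <- sort(rownames(scores))
  scores <- scores[ids, ids]
  norm <- scores
  if (normalization == "BITS_PER_SHORTER") {
    if (is.null(lens)) stop("scores lack the 'lengths' attribute")
    lens <- lens[ids]
    shorter <- outer(lens, lens, pmin)
    norm <- (scores / 2) / shorter
    selfBits <- diag(scores) / 2
  }
  n <- length(ids)
  keep <- which(upper.tri(norm) & norm >= threshold, arr.ind = TRUE)
  edges <- data.frame(from = ids[keep[, 1]], to = ids[keep[, 2]],
                      score = scores[keep],
                      normalized = norm[keep],
                      stringsAsFactors = FALSE)
  if (normalization == "BITS_PER_SHORTER" && nrow(edges)) {
    denom <- pmin(selfBits[keep[, 1]], selfBits[keep[, 2]]) /
      pmin(lens[keep[, 1]], lens[keep[, 2]])
    edges$attraction <- pmin(1, pmax(0, edges$normalized / denom))
  } else {
    edges$attraction <- if (nrow(edges))
      pmin(1, edges$normalized / max(edges$normalized)) else numeric(0)
  }
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = FALSE, vertices = ids)
  memb <- igraph::components(g)$membership[ids]
  first <- vapply(split(names(memb), memb), min, character(1))
  relabel <- stats::setNames(rank(first, ties.method = "first"), names(first))
  memb <- as.integer(relabel[as.character(memb)])
  names(memb) <- ids
  new("SimilarityGraph", nodes = ids, edges = edges, threshold = threshold,
      normalization = normalization, membership = memb)
}

#' Cluster ligand records by sequence similarity
#'
#' Convenience wrapper: all-vs-all Smith-Waterman scores, threshold graph at
#' the default stringency (0.5 bits per residue of the shorter sequence),
#' connected components. Used to contrast the coherent NRG-type cluster with
#' the dispersed EGF-type ligands.
#'
#' @param records an \code{AAStringSet} of ligand sequences.
#' @param threshold bits-per-residue cutoff.
#' @return a \linkS4class{SimilarityGraph}.
#' @export
clusterLigands <- function(records, threshold = 0.5) {
  buildSimilarityGraph(pairwiseScores(records), threshold = threshold,
                       normalization = "BITS_PER_SHORTER")
}

#' Force-directed 2D layout of a similarity graph
#'
#' Optional visualization helper (fixed seed, Fruchterman-Reingold, 500
#' iterations); never used in any assertion.
#'
#' @param graph a \linkS4class{SimilarityGraph}.
#' @param seed integer seed.
#' @param iterations layout iterations.
#' @return data.frame with columns \code{node}, \code{x}, \code{y}.
#' @export
layoutSimilarityGraph <- function(graph, seed = 1, iterations = 500) {
  g <- igraph::graph_from_data_frame(graph@edges[, c("from", "to")],
                                     directed = FALSE, vertices = graph@nodes)
  xy <- .withSeed(seed,
                  igraph::layout_with_fr(g, niter = iterations))
  data.frame(node = graph@nodes, x = xy[, 1], y = xy[, 2],
             stringsAsFactors = FALSE)
}
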