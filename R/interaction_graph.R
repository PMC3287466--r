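#' Build the residue interaction graph
#'
#' Two residues are joined by an edge when the distance between any pair of
#' their CA, CB and carbonyl-O atoms is strictly less than the contact
#' threshold (10 Angstroms by default, the ROSETTA value). Glycine, having
#' no CB, contributes only its CA and O. Candidate rotamer lists are
#' attached per vertex from the backbone-dependent library.
#'
#' @param bb a `backbone` object with dihedrals annotated
#' @param lib a `rotamer_library`
#' @param threshold contact threshold in Angstroms (strict `<`)
#' @param max_candidates optional cap on rotamers per residue (default:
#'   keep all, as the method prescribes)
#' @return object of class `interaction_graph`: list with `n`, `edges`
#'   (2-column matrix of 1-based vertex pairs, i < j, lexicographic order),
#'   `candidates` (list of rotamer data.frames per vertex) and `threshold`
#' @export
build_graph <- function(bb, lib, threshold = 10.0, max_candidates = Inf) {
  res <- bb$residues
  n <- length(res)
  coords <- lapply(res, function(r) {
    nm <- intersect(c("CA", "CB", "O"), names(r$atoms))
    do.call(rbind, r$atoms[nm])
  })
  edges <- matrix(integer(0), ncol = 2)
  if (n >= 2) {
    # contact if the closest relevant atom pair is under the threshold
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    hit <- vapply(seq_len(nrow(pairs)), function(k) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      min(cross_dist(coords[[i]], coords[[j]])) < threshold
    }, logical(1))
    edges <- pairs[hit, , drop = FALSE]
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  candidates <- lapply(res, function(r) {
    cand <- lookup(lib, r$aa, r$phi, r$psi)
    if (nrow(cand) > max_candidates) cand <- cand[seq_len(max_candidates), ]
    cand$prob <- cand$prob / sum(cand$prob)
    cand
  })
  structure(list(n = n, edges = edges, candidates = candidates,
                 threshold = threshold),
            class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat("interaction_graph:", x$n, "vertices,", nrow(x$edges), "edges",
      sprintf("(threshold %.1f A)\n", x$threshold))
  invisible(x)
}

#' Neighbor lists of an interaction graph
#' @param graph an `interaction_graph` (or any list with `n` and `edges`)
#' @return list of integer neighbor vectors per vertex
#' @keywords internal
neighbor_list <- function(graph) {
  nb <- vector("list", graph$n)
  for (k in seq_len(nrow(graph$edges))) {
    i <- graph$edges[k, 1]; j <- graph$edges[k, 2]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  nb
}

#' Dump a graph as edge-list text (debugging aid)
#' @param graph an `interaction_graph`
#' @return character vector, one `i j` pair per line (1-based)
#' @export
graph_edge_list <- function(graph) {
  apply(graph$edges, 1, paste, collapse = " ")
}
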