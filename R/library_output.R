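#' Re-rank rotamer candidates by their marginal probabilities
#'
#' Produces the protein-dependent rotamer library: per residue, the
#' candidate records of the input library ordered by descending updated
#' (marginal) probability, ties broken by the input prior order (stable
#' sort), with the updated probability attached.
#'
#' @param marginals a `marginal_set`
#' @param graph the `interaction_graph` whose candidate lists the
#'   marginals were computed over
#' @return object of class `protein_library`: list with `residues` (list
#'   of data.frames, each the candidate table plus a `prob_updated`
#'   column, re-sorted) and `provenance`
#' @export
rerank <- function(marginals, graph) {
  if (length(marginals$beliefs) != length(graph$candidates)) {
    stop("marginal set and candidate lists have different lengths")
  }
  residues <- lapply(seq_along(graph$candidates), function(i) {
    cand <- graph$candidates[[i]]
    p <- marginals$beliefs[[i]]
    if (length(p) != nrow(cand)) {
      stop("marginal length mismatch at residue ", i, ": ",
           length(p), " vs ", nrow(cand))
    }
    cand$prob_updated <- p / sum(p)
    cand[order(-cand$prob_updated), , drop = FALSE]  # stable: prior order on ties
  })
  structure(list(residues = residues,
                 provenance = list(algorithm = marginals$algorithm,
                                   converged = marginals$converged,
                                   iterations = marginals$iterations)),
            class = "protein_library")
}

#' @export
print.protein_library <- function(x, ...) {
  cat("protein_library:", length(x$residues), "residues, algorithm",
      x$provenance$algorithm, "\n")
  invisible(x)
}

#' Top-1 side-chain prediction from a protein-dependent library
#'
#' Thresholds each residue's marginal distribution to its most probable
#' rotamer. No clash resolution is attempted: the per-residue argmax need
#' not be a jointly valid packing.
#'
#' @param lib a `protein_library` from [rerank()]
#' @return list of single-row data.frames, one top rotamer per residue
#' @export
predict_top1 <- function(lib) {
  if (length(lib$residues) == 0) stop("empty protein library")
  lapply(lib$residues, function(df) df[1, , drop = FALSE])
}
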