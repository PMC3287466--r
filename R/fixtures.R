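# Deterministic synthetic fixtures: backbones, rotamer libraries, toy MRFs
# and ground-truth bundles. Fixtures target correctness of every pipeline
# stage, not statistical realism of the PDB.

AA1 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")

expand_sequence <- function(sequence) {
  if (length(sequence) == 1 && !sequence %in% AA3 && nchar(sequence) > 1) {
    out <- AA1[strsplit(toupper(sequence), "")[[1]]]
    if (any(is.na(out))) stop("unknown one-letter code in sequence")
    return(unname(out))
  }
  out <- toupper(sequence)
  if (!all(out %in% AA3)) stop("unknown residue code in sequence")
  out
}

#' Generate a synthetic protein backbone
#'
#' Builds a geometrically valid single-chain backbone (N, CA, C, O, CB)
#' by internal-coordinate construction with standard bond lengths and
#' angles. Helix mode uses phi = -57, psi = -47; extended mode phi = -139,
#' psi = 135; perturbed mode adds seeded Gaussian coordinate noise (sigma
#' in Angstroms) to the helix.
#'
#' @param n_residues chain length (>= 1)
#' @param sequence three-letter vector, one-letter string, or `NULL` to
#'   sample uniformly from the 18 chi-bearing residue types
#' @param mode `"helix"`, `"extended"` or `"perturbed"`
#' @param noise coordinate noise sigma, Angstroms (perturbed mode)
#' @param seed integer; same spec + seed gives byte-identical output
#' @return list with `pdb` (character lines) and `backbone` (parsed,
#'   dihedral-annotated `backbone` object)
#' @export
make_backbone <- function(n_residues, sequence = NULL,
                          mode = c("helix", "extended", "perturbed"),
                          noise = 0.1, seed = 1L) {
  stopifnot(n_residues >= 1)
  mode <- match.arg(mode)
  set.seed(seed)
  if (is.null(sequence)) {
    pool <- setdiff(AA3, c("ALA", "GLY"))
    sequence <- sample(pool, n_residues, replace = TRUE)
  } else {
    sequence <- expand_sequence(sequence)
    if (length(sequence) == 1) sequence <- rep(sequence, n_residues)
    stopifnot(length(sequence) == n_residues)
  }
  ang <- switch(mode,
                helix = c(phi = -57, psi = -47),
                extended = c(phi = -139, psi = 135),
                perturbed = c(phi = -57, psi = -47))
  # standard backbone internal coordinates
  b_NCA <- 1.458; b_CAC <- 1.525; b_CN <- 1.329; b_CO <- 1.231
  a_NCAC <- 111.2; a_CACN <- 116.2; a_CNCA <- 121.7; a_CACO <- 120.8
  residues <- vector("list", n_residues)
  N <- c(0, 0, 0)
  CA <- c(b_NCA, 0, 0)
  C <- place_atom(c(0, 1, 0), N, CA, b_CAC, a_NCAC, 0)
  for (i in seq_len(n_residues)) {
    O <- place_atom(N, CA, C, b_CO, a_CACO, wrap_angle(ang["psi"] + 180))
    atoms <- list(N = N, CA = CA, C = C, O = O)
    if (sequence[i] != "GLY") {
      atoms$CB <- place_atom(C, N, CA, 1.530, 110.5, 123.0)
    }
    residues[[i]] <- list(index = i - 1L, aa = sequence[i], chain = "A",
                          resno = i, insert = "", atoms = atoms,
                          phi = NA_real_, psi = NA_real_, omega = NA_real_)
    if (i < n_residues) {
      N2 <- place_atom(N, CA, C, b_CN, a_CACN, ang["psi"])
      CA2 <- place_atom(CA, C, N2, b_NCA, a_CNCA, 180)       # omega trans
      C2 <- place_atom(C, N2, CA2, b_CAC, a_NCAC, ang["phi"])
      N <- N2; CA <- CA2; C <- C2
    }
  }
  if (mode == "perturbed") {
    for (i in seq_along(residues)) {
      residues[[i]]$atoms <- lapply(residues[[i]]$atoms, function(p) {
        p + stats::rnorm(3, 0, noise)
      })
    }
  }
  bb <- structure(list(residues = residues, chain_break_dist = 4.5),
                  class = "backbone")
  bb <- annotate_backbone_dihedrals(bb)
  list(pdb = write_structure(bb), backbone = bb)
}

#' Generate a synthetic Dunbrack-style rotamer library
#'
#' Per (aa, phi, psi) bin, `rotamers_per_bin` records with probabilities
#' drawn from a symmetric Dirichlet (sorted descending) and chi means near
#' the canonical gauche-/gauche+/trans wells with Gaussian jitter.
#'
#' @param aas amino acids to cover (three-letter codes)
#' @param centers data.frame of bin centers with columns `phi`, `psi`
#'   (default: a 60-degree grid over the full torus)
#' @param rotamers_per_bin records per bin (>= 1)
#' @param concentration Dirichlet concentration (large = near-uniform)
#' @param chi_jitter sd of the chi-mean jitter, degrees
#' @param seed integer seed
#' @return character vector: library text in the count-column dialect
#' @export
make_library <- function(aas, centers = NULL, rotamers_per_bin = 3,
                         concentration = 1, chi_jitter = 8, seed = 1L) {
  stopifnot(rotamers_per_bin >= 1)
  aas <- unique(toupper(aas))
  aas <- aas[n_chi(aas) > 0]
  if (length(aas) == 0) stop("no chi-bearing amino acids requested")
  if (is.null(centers)) {
    centers <- expand.grid(phi = seq(-180, 120, by = 60),
                           psi = seq(-180, 120, by = 60))
  }
  set.seed(seed)
  canonical <- c(-60, 60, 180)
  lines <- c("# synthetic backbone-dependent rotamer library",
             "# aa phi psi count r1 r2 r3 r4 prob chi1 chi2 chi3 chi4 sig1 sig2 sig3 sig4")
  for (aa in aas) {
    nc <- n_chi(aa)
    for (b in seq_len(nrow(centers))) {
      g <- stats::rgamma(rotamers_per_bin, shape = concentration)
      p <- sort(g / sum(g), decreasing = TRUE)
      # chi-class assignment: distinct chi1 wells for the first three
      for (r in seq_len(rotamers_per_bin)) {
        cls <- rep(0L, 4)
        chi <- rep(NA_real_, 4)
        for (k in seq_len(nc)) {
          cls[k] <- if (k == 1) ((r - 1) %% 3) + 1 else sample.int(3, 1)
          chi[k] <- wrap_angle(canonical[cls[k]] +
                                 stats::rnorm(1, 0, chi_jitter))
        }
        lines <- c(lines, paste(
          aa, centers$phi[b], centers$psi[b], 100,
          cls[1], cls[2], cls[3], cls[4],
          formatC(p[r], format = "f", digits = 6),
          fmt_num(chi[1]), fmt_num(chi[2]), fmt_num(chi[3]), fmt_num(chi[4]),
          "8.0 8.0 8.0 8.0"))
      }
    }
  }
  lines
}

#' Generate a toy Markov random field
#'
#' Log-potentials are i.i.d. standard normal (exponentiated), on a chain,
#' random tree, cycle or complete topology; the substrate for testing the
#' inference algorithms against exact enumeration.
#'
#' @param n_vertices number of vertices
#' @param topology `"chain"`, `"tree"`, `"cycle"` or `"complete"`
#' @param states states per vertex (scalar or vector)
#' @param seed integer seed
#' @return an object of class `mrf`
#' @export
make_toy_mrf <- function(n_vertices,
                         topology = c("chain", "tree", "cycle", "complete"),
                         states = 2, seed = 1L) {
  topology <- match.arg(topology)
  set.seed(seed)
  ns <- rep(states, length.out = n_vertices)
  edges <- switch(topology,
    chain = if (n_vertices > 1) cbind(1:(n_vertices - 1), 2:n_vertices),
    tree = if (n_vertices > 1) {
      par <- vapply(2:n_vertices, function(v) sample.int(v - 1, 1), integer(1))
      cbind(par, 2:n_vertices)
    },
    cycle = {
      stopifnot(n_vertices >= 3)
      rbind(cbind(1:(n_vertices - 1), 2:n_vertices), c(1, n_vertices))
    },
    complete = t(utils::combn(n_vertices, 2)))
  if (is.null(edges)) edges <- matrix(integer(0), ncol = 2)
  edges <- matrix(as.integer(edges), ncol = 2)
  edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  node_pot <- lapply(ns, function(k) exp(stats::rnorm(k)))
  edge_pot <- lapply(seq_len(nrow(edges)), function(e) {
    matrix(exp(stats::rnorm(ns[edges[e, 1]] * ns[edges[e, 2]])),
           ns[edges[e, 1]], ns[edges[e, 2]])
  })
  structure(list(n = n_vertices, edges = edges, n_states = as.integer(ns),
                 node_pot = node_pot, edge_pot = edge_pot,
                 node_energy = NULL, edge_energy = NULL, candidates = NULL),
            class = "mrf")
}

# Reorder each used bin's prior probabilities so the least backbone-
# clashing rotamer carries the largest prior (see make_bundle docs).
clash_order_priors <- function(lib, bb, params = energy_params()) {
  graph <- build_graph(bb, lib)
  nb <- neighbor_list(graph)
  acc <- list()  # bin key -> matrix rows = records, cols = residues
  for (i in seq_len(graph$n)) {
    r <- bb$residues[[i]]
    if (n_chi(r$aa) == 0 || is.na(r$phi) || is.na(r$psi)) next
    ctr <- lib$centers[[r$aa]]
    d <- angular_distance(ctr$phi, r$phi)^2 + angular_distance(ctr$psi, r$psi)^2
    best <- which.min(d)
    key <- paste(r$aa, ctr$phi[best], ctr$psi[best], sep = "|")
    recs <- lib$bins[[key]]
    en <- vapply(seq_len(nrow(recs)), function(k) {
      sc <- candidate_side_chain(r, recs, k)
      scm <- sc_matrix(sc, params)
      e <- 0
      for (j in nb[[i]]) {
        bbm <- backbone_matrix(bb$residues[[j]], params)
        e <- e + clash_sum(scm$xyz, scm$r, bbm$xyz, bbm$r, params)
      }
      e
    }, numeric(1))
    acc[[key]] <- cbind(acc[[key]], en)
  }
  for (key in names(acc)) {
    recs <- lib$bins[[key]]
    idx <- order(rowMeans(acc[[key]]))
    recs$prob[idx] <- sort(recs$prob, decreasing = TRUE)
    lib$bins[[key]] <- recs[order(-recs$prob), , drop = FALSE]
  }
  lib
}

#' Generate a ground-truth fixture bundle
#'
#' Builds a backbone, a synthetic rotamer library, and a full-atom "truth"
#' structure whose side chains sit exactly at one library rotamer per
#' residue - either each residue's most probable rotamer (`"top"`) or a
#' draw from its prior (`"sample"`). Evaluation metrics then have known
#' optima: the placed rotamer is always in the candidate list.
#'
#' Real backbone-dependent libraries assign low prior probability to
#' rotamers that are sterically strained against the local backbone; raw
#' Dirichlet draws do not. To preserve that property - without which a
#' placed "truth" rotamer can be one the energy model rightly rejects -
#' the bundle reorders each bin's probabilities so that the least-clashing
#' candidate (mean repulsive energy against neighboring backbones on this
#' fixture's backbone) carries the largest prior.
#'
#' @param n_residues chain length
#' @param mode which library rotamer the truth uses per residue
#' @param backbone_mode passed to [make_backbone()]
#' @param rotamers_per_bin library size per bin
#' @param seed integer seed controlling every random draw
#' @return list: `backbone_pdb`, `truth_pdb` (character lines),
#'   `library_text`, `bb`, `lib`, `graph`, `true_index` (candidate-row of
#'   the placed rotamer per residue), `true_chi` (list of chi vectors)
#' @export
make_bundle <- function(n_residues = 20, mode = c("top", "sample"),
                        backbone_mode = "extended", rotamers_per_bin = 3,
                        seed = 1L) {
  mode <- match.arg(mode)
  bbfix <- make_backbone(n_residues, mode = backbone_mode, seed = seed)
  bb <- bbfix$backbone
  aas <- vapply(bb$residues, `[[`, "", "aa")
  lib_text <- make_library(unique(aas), rotamers_per_bin = rotamers_per_bin,
                           seed = seed + 1000L)
  lib <- parse_library(lib_text)
  lib <- clash_order_priors(lib, bb)
  lib_text <- format_library(lib)
  graph <- build_graph(bb, lib)
  set.seed(seed + 2000L)
  true_index <- integer(n_residues)
  true_chi <- vector("list", n_residues)
  assignments <- vector("list", n_residues)
  for (i in seq_len(n_residues)) {
    cand <- graph$candidates[[i]]
    k <- if (mode == "top") 1L else sample.int(nrow(cand), 1,
                                               prob = cand$prob)
    true_index[i] <- k
    nc <- n_chi(aas[i])
    chi <- if (nc > 0) as.numeric(cand[k, paste0("chi", seq_len(nc))]) else numeric(0)
    true_chi[[i]] <- chi
    assignments[[i]] <- build_side_chain(bb$residues[[i]], chi)
  }
  list(backbone_pdb = bbfix$pdb,
       truth_pdb = write_structure(bb, assignments),
       library_text = lib_text,
       bb = bb, lib = lib, graph = graph,
       true_index = true_index, true_chi = true_chi)
}
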