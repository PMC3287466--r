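#' Energy-model parameters
#'
#' Defaults follow the method's published constants: `kBT` = 0.6 kcal/mol,
#' prior-term scale `k_d` = 3.0, repulsive plateau `E_max` = 10 with ramp
#' start `k_sc` = 0.8254, and a 10 Angstrom contact threshold. Interaction
#' radii are element-class defaults (SCWRL3-style; configurable).
#'
#' @param kBT Boltzmann factor temperature, kcal/mol
#' @param k_d scale of the rotamer log-prior energy term (dimensionless)
#' @param E_max plateau of the piecewise repulsive energy
#' @param k_sc fractional distance (of `r_ab`) where the plateau ends
#' @param radius_table named numeric vector of interaction radii per
#'   element (Angstroms)
#' @param prob_floor floor applied to rotamer prior probabilities before
#'   the log term (guards against zero-probability rotamers)
#' @param clash when `FALSE`, all repulsive clash terms are zeroed (the
#'   energy reduces to the prior term alone)
#' @param hbond an [hbond_params()] list
#' @return list of class `energy_params`
#' @export
energy_params <- function(kBT = 0.6, k_d = 3.0, E_max = 10, k_sc = 0.8254,
                          radius_table = c(C = 1.6, N = 1.3, O = 1.3,
                                           S = 1.7),
                          prob_floor = 1e-6, clash = TRUE,
                          hbond = hbond_params()) {
  stopifnot(kBT > 0, E_max > 0, k_sc > 0, k_sc < 1, all(radius_table > 0))
  structure(list(kBT = kBT, k_d = k_d, E_max = E_max, k_sc = k_sc,
                 radius_table = radius_table, prob_floor = prob_floor,
                 clash = isTRUE(clash), hbond = hbond),
            class = "energy_params")
}

#' Hydrogen-bond surrogate parameters
#'
#' A side-chain-mediated hydrogen bond between a donor and an acceptor
#' heavy atom is scored as `weight * exp(-(d - distance_opt)^2 /
#' (2 distance_width^2))`, gated by the donor-antecedent angle
#' (antecedent-donor-acceptor >= `angle_min`). Favorable energies are
#' negative, so `weight` <= 0.
#'
#' @param enabled toggle the term
#' @param weight energy at the distance optimum, kcal/mol (<= 0)
#' @param distance_opt optimal donor-acceptor distance, Angstroms
#' @param distance_width Gaussian width, Angstroms
#' @param angle_min minimum antecedent-donor-acceptor angle, degrees
#' @return list of class `hbond_params`
#' @export
hbond_params <- function(enabled = TRUE, weight = -2.0, distance_opt = 2.8,
                         distance_width = 0.3, angle_min = 90) {
  stopifnot(weight <= 0, distance_opt > 0, distance_width > 0)
  structure(list(enabled = isTRUE(enabled), weight = weight,
                 distance_opt = distance_opt,
                 distance_width = distance_width, angle_min = angle_min),
            class = "hbond_params")
}

#' Piecewise repulsive atom-pair energy (SCWRL3 form)
#'
#' Approximates the repulsive branch of a Lennard-Jones 12-6 potential:
#' zero beyond the contact radius sum `r_ab = r_a + r_b`, the plateau
#' `E_max` inside `k_sc * r_ab`, and a linear ramp between the two
#' breakpoints. Continuous and non-increasing in `d`.
#'
#' @param d distance(s), Angstroms (vectorized)
#' @param r_a,r_b interaction radii of the two atoms, Angstroms
#' @param params an [energy_params()] list
#' @return energy value(s) in `[0, E_max]`
#' @export
atom_pair_energy <- function(d, r_a, r_b, params = energy_params()) {
  r_ab <- r_a + r_b
  ramp <- params$E_max * (r_ab - d) / ((1 - params$k_sc) * r_ab)
  pmin(pmax(ramp, 0), params$E_max)
}

# sum of pairwise repulsive energies between two atom sets
# a, b: 3-col coordinate matrices; ra, rb: radii vectors
clash_sum <- function(a, ra, b, rb, params) {
  if (is.null(a) || is.null(b) || nrow(a) == 0 || nrow(b) == 0) return(0)
  d <- cross_dist(a, b)
  rab <- outer(ra, rb, "+")
  ramp <- params$E_max * (rab - d) / ((1 - params$k_sc) * rab)
  sum(pmin(pmax(ramp, 0), params$E_max))
}

#' Side-chain hydrogen-bond energy between a donor and an acceptor residue
#'
#' Evaluates the surrogate well for every side-chain donor atom of the
#' donor residue against every side-chain acceptor atom of the acceptor
#' residue and returns the single most favorable (lowest) value; 0 when the
#' term is disabled or no donor/acceptor pair is in range.
#'
#' @param donor_res,acceptor_res residue records (backbone atoms)
#' @param donor_sc,acceptor_sc `side_chain` objects for the two rotamers
#' @param params an [energy_params()] list (uses its `hbond` component)
#' @return energy <= 0
#' @export
hbond_energy <- function(donor_res, acceptor_res, donor_sc, acceptor_sc,
                         params = energy_params()) {
  hb <- params$hbond
  if (!hb$enabled) return(0)
  dons <- hbond_donors[[toupper(donor_res$aa)]]
  accs <- hbond_acceptors[[toupper(acceptor_res$aa)]]
  if (is.null(dons) || is.null(accs)) return(0)
  dpos <- c(donor_res$atoms, donor_sc$atoms)
  apos <- c(acceptor_res$atoms, acceptor_sc$atoms)
  best <- 0
  for (dn in dons) {
    if (!all(dn %in% names(dpos))) next
    don <- dpos[[dn[1]]]
    ante <- dpos[[dn[2]]]
    for (an in accs) {
      if (!an %in% names(apos)) next
      acc <- apos[[an]]
      d <- sqrt(sum((don - acc)^2))
      if (abs(d - hb$distance_opt) > 5 * hb$distance_width) next
      u <- ante - don
      v <- acc - don
      ang <- acos(pmin(pmax(sum(u * v) /
                              sqrt(sum(u^2) * sum(v^2)), -1), 1)) * 180 / pi
      if (ang < hb$angle_min) next
      e <- hb$weight *
        exp(-(d - hb$distance_opt)^2 / (2 * hb$distance_width^2))
      if (e < best) best <- e
    }
  }
  best
}

#' Vertex energy of one rotamer candidate
#'
#' The sum of (a) the prior term `k_d * ln(p(r_imax) / p(r_ij))` - zero for
#' the most probable rotamer of the residue's bin and increasing as the
#' prior decreases - and (b) the repulsive interactions between the
#' rotamer's side-chain atoms and the backbone atoms (N, CA, C, O, CB) of
#' every residue adjacent in the interaction graph.
#'
#' @param i vertex index (1-based position in the backbone)
#' @param k candidate index into `graph$candidates[[i]]`
#' @param bb `backbone` object
#' @param graph `interaction_graph`
#' @param params [energy_params()]
#' @param sc optional prebuilt `side_chain` for the candidate
#' @return energy (kcal/mol-compatible units)
#' @export
vertex_energy <- function(i, k, bb, graph, params = energy_params(),
                          sc = NULL) {
  cand <- graph$candidates[[i]]
  p <- pmax(cand$prob, params$prob_floor)
  prior <- params$k_d * log(max(p) / p[k])
  if (!params$clash) return(prior)
  if (is.null(sc)) sc <- candidate_side_chain(bb$residues[[i]], cand, k)
  scm <- sc_matrix(sc, params)
  e <- prior
  nb <- neighbor_list(graph)[[i]]
  for (j in nb) {
    bbm <- backbone_matrix(bb$residues[[j]], params)
    e <- e + clash_sum(scm$xyz, scm$r, bbm$xyz, bbm$r, params)
  }
  e
}

#' Edge energy of a rotamer pair
#'
#' Sum of repulsive energies over all side-chain-atom pairs of the two
#' rotamers, plus the most favorable hydrogen bond between them (in either
#' donor/acceptor direction).
#'
#' @param i,j vertex indices of an edge
#' @param ki,kj candidate indices at the two vertices
#' @param bb `backbone` object
#' @param graph `interaction_graph`
#' @param params [energy_params()]
#' @param sc_i,sc_j optional prebuilt `side_chain`s
#' @return energy
#' @export
edge_energy <- function(i, j, ki, kj, bb, graph, params = energy_params(),
                        sc_i = NULL, sc_j = NULL) {
  if (is.null(sc_i)) {
    sc_i <- candidate_side_chain(bb$residues[[i]], graph$candidates[[i]], ki)
  }
  if (is.null(sc_j)) {
    sc_j <- candidate_side_chain(bb$residues[[j]], graph$candidates[[j]], kj)
  }
  e <- 0
  if (params$clash) {
    mi <- sc_matrix(sc_i, params)
    mj <- sc_matrix(sc_j, params)
    e <- clash_sum(mi$xyz, mi$r, mj$xyz, mj$r, params)
  }
  if (params$hbond$enabled) {
    ri <- bb$residues[[i]]; rj <- bb$residues[[j]]
    e <- e + min(hbond_energy(ri, rj, sc_i, sc_j, params),
                 hbond_energy(rj, ri, sc_j, sc_i, params))
  }
  e
}

# build the side chain for candidate row k of a residue's candidate table
candidate_side_chain <- function(residue, cand, k) {
  nc <- n_chi(residue$aa)
  chi <- numeric(0)
  if (nc > 0) {
    chi <- as.numeric(cand[k, paste0("chi", seq_len(nc))])
  }
  build_side_chain(residue, chi)
}

sc_matrix <- function(sc, params) {
  if (length(sc$atoms) == 0) return(list(xyz = NULL, r = numeric(0)))
  xyz <- do.call(rbind, sc$atoms)
  list(xyz = xyz, r = unname(params$radius_table[atom_element(names(sc$atoms))]))
}

backbone_matrix <- function(residue, params) {
  nm <- intersect(c("N", "CA", "C", "O", "CB"), names(residue$atoms))
  xyz <- do.call(rbind, residue$atoms[nm])
  list(xyz = xyz, r = unname(params$radius_table[atom_element(nm)]))
}

#' Boltzmann potential of an energy
#'
#' @param E energy (vectorized)
#' @param kBT temperature factor, kcal/mol
#' @return `exp(-E / kBT)`
#' @export
boltzmann_potential <- function(E, kBT = 0.6) {
  exp(-E / kBT)
}

#' Assemble the Markov random field for a protein
#'
#' Converts vertex/edge energies to Boltzmann potentials. Energies are
#' shifted by their per-vertex (per-edge) minimum before exponentiation -
#' a pure rescaling that leaves all marginals invariant while preventing
#' underflow at large clash energies.
#'
#' @param bb `backbone` object
#' @param graph `interaction_graph` with candidate lists
#' @param params [energy_params()]
#' @return object of class `mrf`: list with `n`, `edges`, `n_states`,
#'   `node_pot` (list of positive vectors), `edge_pot` (list of positive
#'   matrices, rows = first endpoint), `candidates`
#' @export
assemble_mrf <- function(bb, graph, params = energy_params()) {
  n <- graph$n
  nb <- neighbor_list(graph)
  # cache built side chains and atom matrices per candidate
  scs <- vector("list", n)
  mats <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- graph$candidates[[i]]
    scs[[i]] <- lapply(seq_len(nrow(cand)), function(k) {
      candidate_side_chain(bb$residues[[i]], cand, k)
    })
    mats[[i]] <- lapply(scs[[i]], sc_matrix, params = params)
  }
  bbm <- lapply(bb$residues, backbone_matrix, params = params)

  node_en <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- graph$candidates[[i]]
    p <- pmax(cand$prob, params$prob_floor)
    prior <- params$k_d * log(max(p) / p)
    en <- prior
    if (params$clash) {
      for (k in seq_along(en)) {
        for (j in nb[[i]]) {
          en[k] <- en[k] + clash_sum(mats[[i]][[k]]$xyz, mats[[i]][[k]]$r,
                                     bbm[[j]]$xyz, bbm[[j]]$r, params)
        }
      }
    }
    node_en[[i]] <- en
  }

  edge_en <- vector("list", nrow(graph$edges))
  for (e in seq_len(nrow(graph$edges))) {
    i <- graph$edges[e, 1]; j <- graph$edges[e, 2]
    ni <- length(node_en[[i]]); nj <- length(node_en[[j]])
    m <- matrix(0, ni, nj)
    for (ki in seq_len(ni)) {
      for (kj in seq_len(nj)) {
        m[ki, kj] <- edge_energy(i, j, ki, kj, bb, graph, params,
                                 sc_i = scs[[i]][[ki]],
                                 sc_j = scs[[j]][[kj]])
      }
    }
    edge_en[[e]] <- m
  }

  node_pot <- lapply(node_en, function(en) boltzmann_potential(en - min(en),
                                                               params$kBT))
  edge_pot <- lapply(edge_en, function(m) boltzmann_potential(m - min(m),
                                                              params$kBT))
  structure(list(n = n, edges = graph$edges,
                 n_states = vapply(node_pot, length, integer(1)),
                 node_pot = node_pot, edge_pot = edge_pot,
                 node_energy = node_en, edge_energy = edge_en,
                 candidates = graph$candidates),
            class = "mrf")
}

#' @export
print.mrf <- function(x, ...) {
  cat("mrf:", x$n, "vertices,", nrow(x$edges), "edges, states:",
      paste(range(x$n_states), collapse = "-"), "\n")
  invisible(x)
}
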