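# Shared test helpers: hand-built residues/backbones and brute-force
# oracles kept independent of the implementation paths they check.

# a residue record with all contact-relevant atoms at one point (lets tests
# control inter-residue distances exactly)
point_residue <- function(i, xyz, aa = "ALA", chain = "A") {
  list(index = i - 1L, aa = aa, chain = chain, resno = i, insert = "",
       atoms = list(N = xyz, CA = xyz, C = xyz, O = xyz),
       phi = NA_real_, psi = NA_real_, omega = NA_real_)
}

fake_backbone <- function(residues) {
  structure(list(residues = residues, chain_break_dist = 4.5),
            class = "backbone")
}

# library whose every aa bin is a single uniform record set (for graph tests)
tiny_library <- function(aas = "SER") {
  parse_library(make_library(aas, centers = data.frame(phi = -60, psi = -60),
                             rotamers_per_bin = 2, seed = 1))
}

# independent dihedral oracle: bio3d's torsion routine
bio3d_dihedral <- function(p1, p2, p3, p4) {
  bio3d::torsion.xyz(c(p1, p2, p3, p4), atm.inc = 4)[1]
}

# brute-force edge appearance: enumerate all (n-1)-edge subsets, count
# spanning trees containing each edge
brute_edge_appearance <- function(n, edges) {
  m <- nrow(edges)
  if (n == 1 || m < n - 1) return(rep(NA_real_, m))
  connected <- function(sub) {
    seen <- rep(FALSE, n)
    seen[1] <- TRUE
    repeat {
      grew <- FALSE
      for (k in seq_len(nrow(sub))) {
        a <- sub[k, 1]; b <- sub[k, 2]
        if (seen[a] != seen[b]) {
          seen[a] <- seen[b] <- TRUE
          grew <- TRUE
        }
      }
      if (!grew) break
    }
    all(seen)
  }
  combos <- utils::combn(m, n - 1)
  total <- 0
  contain <- rep(0, m)
  for (c_idx in seq_len(ncol(combos))) {
    sel <- combos[, c_idx]
    if (connected(edges[sel, , drop = FALSE])) {
      total <- total + 1
      contain[sel] <- contain[sel] + 1
    }
  }
  contain / total
}

# all labeled connected graphs on n vertices (edge matrices)
all_connected_graphs <- function(n) {
  pairs <- t(utils::combn(n, 2))
  m <- nrow(pairs)
  out <- list()
  for (mask in seq_len(2^m) - 1L) {
    sel <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    if (length(sel) < n - 1) next
    edges <- pairs[sel, , drop = FALSE]
    seen <- rep(FALSE, n); seen[1] <- TRUE
    repeat {
      grew <- FALSE
      for (k in seq_len(nrow(edges))) {
        if (seen[edges[k, 1]] != seen[edges[k, 2]]) {
          seen[edges[k, ]] <- TRUE; grew <- TRUE
        }
      }
      if (!grew) break
    }
    if (all(seen)) out[[length(out) + 1]] <- edges
  }
  out
}

max_belief_diff <- function(a, b) {
  max(mapply(function(x, y) max(abs(x - y)), a$beliefs, b$beliefs))
}
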