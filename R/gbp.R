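# Generalized belief propagation on a region graph.
#
# Outer regions are all triangles of the interaction graph plus every edge
# not covered by a triangle (plus isolated vertices); inner regions are the
# closure under intersection. Counting numbers follow the cluster variation
# rule c_R = 1 - sum of c_A over strict ancestors, which counts every vertex
# and edge factor exactly once. Messages run parent -> child along the Hasse
# diagram; on a triangle-free graph the construction degenerates to the
# Bethe region graph and the updates coincide with loopy BP.

region_key <- function(v) paste(sort(v), collapse = ",")

find_triangles <- function(n, edges) {
  if (nrow(edges) == 0) return(list())
  adj <- matrix(FALSE, n, n)
  adj[edges] <- TRUE
  adj[edges[, c(2, 1), drop = FALSE]] <- TRUE
  tri <- list()
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1]; j <- edges[e, 2]
    ks <- which(adj[i, ] & adj[j, ])
    for (k in ks[ks > j]) tri[[length(tri) + 1]] <- c(i, j, k)
  }
  tri
}

# region graph: regions (vertex sets), Hasse parent->child edges,
# counting numbers
build_region_graph <- function(n, edges) {
  tri <- find_triangles(n, edges)
  covered <- rep(FALSE, nrow(edges))
  if (length(tri) > 0) {
    ekey <- paste(edges[, 1], edges[, 2])
    for (t in tri) {
      for (pr in list(t[1:2], t[c(1, 3)], t[2:3])) {
        covered[match(paste(pr[1], pr[2]), ekey)] <- TRUE
      }
    }
  }
  outer <- c(tri, lapply(which(!covered), function(e) edges[e, ]))
  in_edge <- unique(as.integer(edges))
  for (v in setdiff(seq_len(n), in_edge)) outer[[length(outer) + 1]] <- v

  regions <- lapply(outer, sort)
  keys <- vapply(regions, region_key, "")
  keep <- !duplicated(keys)
  regions <- regions[keep]
  keys <- keys[keep]
  # close under pairwise intersection
  repeat {
    added <- FALSE
    nr <- length(regions)
    for (a in seq_len(nr - 1)) {
      for (b in seq((a + 1), nr)) {
        z <- intersect(regions[[a]], regions[[b]])
        if (length(z) > 0 && !(region_key(z) %in% keys)) {
          regions[[length(regions) + 1]] <- sort(z)
          keys <- c(keys, region_key(z))
          added <- TRUE
        }
      }
    }
    if (!added) break
  }

  nr <- length(regions)
  subset_of <- matrix(FALSE, nr, nr)  # [a, b] = region a strict subset of b
  for (a in seq_len(nr)) {
    for (b in seq_len(nr)) {
      if (a != b && length(regions[[a]]) < length(regions[[b]]) &&
          all(regions[[a]] %in% regions[[b]])) {
        subset_of[a, b] <- TRUE
      }
    }
  }
  # Hasse: parent P -> child C with no intermediate region between them
  hasse <- NULL
  for (cc in seq_len(nr)) {
    for (p in which(subset_of[cc, ])) {
      inter <- any(subset_of[cc, ] & subset_of[, p])
      if (!inter) hasse <- rbind(hasse, c(p, cc))
    }
  }
  # counting numbers by descending region size
  cnt <- rep(NA_real_, nr)
  for (a in order(-lengths(regions))) {
    anc <- which(subset_of[a, ])
    cnt[a] <- 1 - sum(cnt[anc])
  }
  list(regions = regions, hasse = hasse, counting = cnt,
       subset_of = subset_of)
}

# configuration index arithmetic for a region: vertices sorted ascending,
# first vertex fastest (expand.grid convention)
region_cfg <- function(verts, n_states) {
  as.matrix(expand.grid(lapply(n_states[verts], seq_len),
                        KEEP.OUT.ATTRS = FALSE))
}

# for each config of region A, the config index of sub-region C
sub_index <- function(cfgA, vertsA, vertsC, n_states) {
  stride <- cumprod(c(1, n_states[vertsC]))[seq_along(vertsC)]
  idx <- rep(1L, nrow(cfgA))
  for (k in seq_along(vertsC)) {
    col <- match(vertsC[k], vertsA)
    idx <- idx + (cfgA[, col] - 1L) * stride[k]
  }
  idx
}

#' Generalized belief propagation (parent-to-child region graph)
#'
#' Runs sum-product GBP on a region graph whose outer regions are the
#' triangles of the graph plus uncovered edges; inner regions are the
#' intersection closure and counting numbers follow the cluster variation
#' rule. Triangle-free graphs reduce to the Bethe construction (loopy BP);
#' a graph that is a single triangle is covered by one outer region, making
#' the result exact.
#'
#' @inheritParams lbp
#' @return a `marginal_set`
#' @export
gbp <- function(mrf, config = inference_config()) {
  n <- mrf$n
  ns <- mrf$n_states
  rg <- build_region_graph(n, mrf$edges)
  regions <- rg$regions
  nr <- length(regions)
  cfgs <- lapply(regions, region_cfg, n_states = ns)

  # factor products per region: all vertex and edge factors inside it
  ekey <- paste(mrf$edges[, 1], mrf$edges[, 2])
  F_of <- vector("list", nr)
  for (a in seq_len(nr)) {
    vs <- regions[[a]]
    cfg <- cfgs[[a]]
    w <- rep(1, nrow(cfg))
    for (k in seq_along(vs)) w <- w * mrf$node_pot[[vs[k]]][cfg[, k]]
    if (length(vs) >= 2 && nrow(mrf$edges) > 0) {
      prs <- utils::combn(seq_along(vs), 2)
      for (q in seq_len(ncol(prs))) {
        i <- vs[prs[1, q]]; j <- vs[prs[2, q]]
        e <- match(paste(i, j), ekey)
        if (!is.na(e)) {
          w <- w * mrf$edge_pot[[e]][cbind(cfg[, prs[1, q]],
                                           cfg[, prs[2, q]])]
        }
      }
    }
    F_of[[a]] <- w
  }

  hasse <- rg$hasse
  if (is.null(hasse)) {
    # no messages at all: beliefs are normalized region factors
    beliefs <- vertex_beliefs_gbp(mrf, regions, cfgs, F_of, NULL, NULL, NULL)
    return(marginal_set(beliefs, TRUE, 1L, 0, "gbp"))
  }

  desc <- lapply(seq_len(nr), function(a) which(rg$subset_of[, a]))
  family <- lapply(seq_len(nr), function(a) c(a, desc[[a]]))
  nh <- nrow(hasse)
  # M(R): hasse-edge ids whose child is in family(R) and parent outside it
  M_of <- lapply(seq_len(nr), function(a) {
    which(hasse[, 2] %in% family[[a]] & !(hasse[, 1] %in% family[[a]]))
  })
  N_of <- vector("list", nh)  # numerator messages, broadcast maps onto P
  D_of <- vector("list", nh)  # denominator messages, maps onto R
  GG <- vector("list", nh)    # factors in P not contained in R
  mapPR <- vector("list", nh)
  for (h in seq_len(nh)) {
    p <- hasse[h, 1]; r <- hasse[h, 2]
    N_of[[h]] <- setdiff(M_of[[p]], M_of[[r]])
    D_of[[h]] <- setdiff(setdiff(M_of[[r]], M_of[[p]]), h)
    # G = F_P / (F_R broadcast to P)
    mapPR[[h]] <- sub_index(cfgs[[p]], regions[[p]], regions[[r]], ns)
    GG[[h]] <- F_of[[p]] / F_of[[r]][mapPR[[h]]]
  }
  bmap <- function(a, cc) sub_index(cfgs[[a]], regions[[a]], regions[[cc]], ns)

  msg <- lapply(seq_len(nh), function(h) {
    k <- nrow(cfgs[[hasse[h, 2]]])
    rep(1 / k, k)
  })
  # vertex belief regions: smallest region containing each vertex
  vb_region <- vapply(seq_len(n), function(v) {
    hit <- which(vapply(regions, function(z) v %in% z, logical(1)))
    hit[which.min(lengths(regions)[hit])]
  }, integer(1))

  vertex_beliefs <- function() {
    lapply(seq_len(n), function(v) {
      a <- vb_region[v]
      w <- F_of[[a]]
      for (h in M_of[[a]]) w <- w * msg[[h]][bmap(a, hasse[h, 2])]
      col <- match(v, regions[[a]])
      b <- as.numeric(rowsum(w, cfgs[[a]][, col]))
      if (!all(is.finite(b)) || sum(b) <= 0) b <- rep(1, ns[v])
      b / sum(b)
    })
  }

  # update larger parents first within a sweep
  h_order <- order(-lengths(regions)[hasse[, 1]])
  beliefs <- vertex_beliefs()
  converged <- FALSE
  resid <- Inf
  iter <- 0L
  while (iter < config$max_iterations) {
    iter <- iter + 1L
    for (h in h_order) {
      p <- hasse[h, 1]; r <- hasse[h, 2]
      w <- GG[[h]]
      for (h2 in N_of[[h]]) w <- w * msg[[h2]][bmap(p, hasse[h2, 2])]
      num <- as.numeric(rowsum(w, mapPR[[h]]))
      den <- rep(1, nrow(cfgs[[r]]))
      for (h2 in D_of[[h]]) den <- den * msg[[h2]][bmap(r, hasse[h2, 2])]
      m_new <- num / pmax(den, 1e-300)
      # a degenerate update (under/overflow on a diverging run) keeps the
      # old message; divergence is reported via the converged flag
      if (!all(is.finite(m_new)) || sum(m_new) <= 0) next
      m_new <- m_new / sum(m_new)
      if (config$damping > 0) {
        m_new <- (1 - config$damping) * m_new + config$damping * msg[[h]]
        m_new <- m_new / sum(m_new)
      }
      msg[[h]] <- m_new
    }
    nb <- vertex_beliefs()
    resid <- belief_delta(nb, beliefs)
    beliefs <- nb
    if (resid < config$tolerance) {
      converged <- TRUE
      break
    }
  }
  marginal_set(beliefs, converged, iter, resid, "gbp")
}

# belief readout when the region graph carries no messages
vertex_beliefs_gbp <- function(mrf, regions, cfgs, F_of, ...) {
  lapply(seq_len(mrf$n), function(v) {
    hit <- which(vapply(regions, function(z) v %in% z, logical(1)))
    a <- hit[which.min(lengths(regions)[hit])]
    col <- match(v, regions[[a]])
    b <- as.numeric(rowsum(F_of[[a]], cfgs[[a]][, col]))
    b / sum(b)
  })
}
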