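#' Inference configuration
#'
#' @param max_iterations sweep cap (the method's default is 100)
#' @param tolerance convergence threshold on the L-infinity change of all
#'   beliefs between successive sweeps
#' @param damping message damping in `[0, 1)`; 0 (off) by default
#' @param schedule `"fixed"` (input vertex order) or `"random"` (seeded
#'   permutation per sweep)
#' @param init `"uniform"` messages/beliefs, or `"random"` (seeded)
#' @param seed integer seed used by random schedule/initialization
#' @return list of class `inference_config`
#' @export
inference_config <- function(max_iterations = 100, tolerance = 1e-6,
                             damping = 0, schedule = c("fixed", "random"),
                             init = c("uniform", "random"), seed = 1L) {
  stopifnot(max_iterations >= 1, tolerance > 0, damping >= 0, damping < 1)
  structure(list(max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, damping = damping,
                 schedule = match.arg(schedule), init = match.arg(init),
                 seed = as.integer(seed)),
            class = "inference_config")
}

marginal_set <- function(beliefs, converged, iterations, max_residual,
                         algorithm) {
  beliefs <- lapply(beliefs, function(b) b / sum(b))
  structure(list(beliefs = beliefs, converged = converged,
                 iterations = iterations, max_residual = max_residual,
                 algorithm = algorithm),
            class = "marginal_set")
}

#' @export
print.marginal_set <- function(x, ...) {
  cat("marginal_set (", x$algorithm, "): ", length(x$beliefs),
      " vertices, converged = ", x$converged, " after ", x$iterations,
      " sweeps (residual ", formatC(x$max_residual, format = "e", digits = 2),
      ")\n", sep = "")
  invisible(x)
}

belief_delta <- function(a, b) {
  d <- max(vapply(seq_along(a), function(i) max(abs(a[[i]] - b[[i]])),
                  numeric(1)))
  if (is.na(d)) Inf else d
}

init_messages <- function(mrf, config) {
  n_dir <- 2L * nrow(mrf$edges)
  msg <- vector("list", n_dir)
  if (config$init == "random") set.seed(config$seed)
  for (e in seq_len(nrow(mrf$edges))) {
    i <- mrf$edges[e, 1]; j <- mrf$edges[e, 2]
    for (dir in 1:2) {
      to <- if (dir == 1) j else i
      m <- if (config$init == "random") {
        stats::runif(mrf$n_states[to], 0.5, 1.5)
      } else rep(1, mrf$n_states[to])
      msg[[2L * (e - 1L) + dir]] <- m / sum(m)
    }
  }
  msg
}

# directed-message index: dir 1 = i->j (edge order), dir 2 = j->i
msg_index <- function(e, dir) 2L * (e - 1L) + dir

# per-vertex incident edge table: rows (edge_id, dir_out, dir_in, neighbor)
incident_table <- function(mrf) {
  inc <- vector("list", mrf$n)
  for (e in seq_len(nrow(mrf$edges))) {
    i <- mrf$edges[e, 1]; j <- mrf$edges[e, 2]
    inc[[i]] <- rbind(inc[[i]], c(e, 1L, 2L, j))
    inc[[j]] <- rbind(inc[[j]], c(e, 2L, 1L, i))
  }
  inc
}

#' Exact marginals by full enumeration
#'
#' Computes the normalized joint of the pairwise model by enumerating every
#' configuration; the reference oracle for the approximate algorithms.
#'
#' @param mrf an `mrf`
#' @param max_states refusal cap on the configuration-space size
#' @return a `marginal_set` (attribute `Z` carries the partition function
#'   of the potentials as given)
#' @export
exact_marginals <- function(mrf, max_states = 1e6) {
  total <- prod(mrf$n_states)
  if (total > max_states) {
    stop("state space too large for exact enumeration: ", total,
         " configurations (cap ", max_states, ")")
  }
  cfg <- as.matrix(expand.grid(lapply(mrf$n_states, seq_len),
                               KEEP.OUT.ATTRS = FALSE))
  w <- rep(1, nrow(cfg))
  for (i in seq_len(mrf$n)) w <- w * mrf$node_pot[[i]][cfg[, i]]
  for (e in seq_len(nrow(mrf$edges))) {
    i <- mrf$edges[e, 1]; j <- mrf$edges[e, 2]
    w <- w * mrf$edge_pot[[e]][cbind(cfg[, i], cfg[, j])]
  }
  Z <- sum(w)
  beliefs <- lapply(seq_len(mrf$n), function(i) {
    as.numeric(rowsum(w, cfg[, i])) / Z
  })
  out <- marginal_set(beliefs, converged = TRUE, iterations = 1L,
                      max_residual = 0, algorithm = "exact")
  attr(out, "Z") <- Z
  out
}

#' Loopy belief propagation (sum-product)
#'
#' Asynchronous message passing: the belief of a vertex is its potential
#' times all incoming messages (normalized); the message from `i` to `j`
#' sums the product of `i`'s potential, the edge potential and messages
#' into `i` from all neighbors except `j` over `i`'s states. Exact on
#' acyclic graphs. Non-convergence within the sweep cap is a reported
#' state, not an error.
#'
#' @param mrf an `mrf`
#' @param config an [inference_config()]
#' @return a `marginal_set`
#' @export
lbp <- function(mrf, config = inference_config()) {
  if (nrow(mrf$edges) == 0) {
    return(marginal_set(mrf$node_pot, TRUE, 1L, 0, "lbp"))
  }
  inc <- incident_table(mrf)
  msg <- init_messages(mrf, config)
  beliefs <- compute_beliefs(mrf, inc, msg)
  if (config$schedule == "random") set.seed(config$seed)
  converged <- FALSE
  resid <- Inf
  iter <- 0L
  while (iter < config$max_iterations) {
    iter <- iter + 1L
    order_v <- if (config$schedule == "random") {
      sample.int(mrf$n)
    } else seq_len(mrf$n)
    for (i in order_v) {
      ti <- inc[[i]]
      if (is.null(ti)) next
      for (r in seq_len(nrow(ti))) {
        e <- ti[r, 1]; dir_out <- ti[r, 2]
        pre <- mrf$node_pot[[i]]
        for (r2 in seq_len(nrow(ti))) {
          if (r2 == r) next
          pre <- pre * msg[[msg_index(ti[r2, 1], ti[r2, 3])]]
        }
        pot <- mrf$edge_pot[[e]]
        m_new <- if (dir_out == 1) {
          as.numeric(crossprod(pot, pre))    # sum over i states (rows)
        } else {
          as.numeric(pot %*% pre)            # i is the column endpoint
        }
        m_new <- m_new / sum(m_new)
        if (config$damping > 0) {
          m_old <- msg[[msg_index(e, dir_out)]]
          m_new <- (1 - config$damping) * m_new + config$damping * m_old
          m_new <- m_new / sum(m_new)
        }
        msg[[msg_index(e, dir_out)]] <- m_new
      }
    }
    new_beliefs <- compute_beliefs(mrf, inc, msg)
    resid <- belief_delta(new_beliefs, beliefs)
    beliefs <- new_beliefs
    if (resid < config$tolerance) {
      converged <- TRUE
      break
    }
  }
  marginal_set(beliefs, converged, iter, resid, "lbp")
}

compute_beliefs <- function(mrf, inc, msg, rho = NULL) {
  lapply(seq_len(mrf$n), function(i) {
    b <- mrf$node_pot[[i]]
    ti <- inc[[i]]
    if (!is.null(ti)) {
      for (r in seq_len(nrow(ti))) {
        m <- msg[[msg_index(ti[r, 1], ti[r, 3])]]
        b <- if (is.null(rho)) b * m else b * m^rho[ti[r, 1]]
      }
    }
    b / sum(b)
  })
}

#' Mean-field approximation
#'
#' Approximates the joint by a product of independent per-vertex
#' distributions; coordinate-ascent updates
#' `b_i propto phi_i * exp(sum_j sum_{x_j} b_j(x_j) log psi_ij(x_i, x_j))`
#' are swept asynchronously until the belief change falls below tolerance.
#'
#' @inheritParams lbp
#' @return a `marginal_set`
#' @export
mean_field <- function(mrf, config = inference_config()) {
  inc <- incident_table(mrf)
  if (config$init == "random") set.seed(config$seed)
  beliefs <- lapply(mrf$n_states, function(ns) {
    b <- if (config$init == "random") stats::runif(ns, 0.5, 1.5) else rep(1, ns)
    b / sum(b)
  })
  log_edge <- lapply(mrf$edge_pot, log)
  if (config$schedule == "random") set.seed(config$seed)
  converged <- FALSE
  resid <- Inf
  iter <- 0L
  while (iter < config$max_iterations) {
    iter <- iter + 1L
    old <- beliefs
    order_v <- if (config$schedule == "random") {
      sample.int(mrf$n)
    } else seq_len(mrf$n)
    for (i in order_v) {
      lg <- log(mrf$node_pot[[i]])
      ti <- inc[[i]]
      if (!is.null(ti)) {
        for (r in seq_len(nrow(ti))) {
          e <- ti[r, 1]; j <- ti[r, 4]
          lg <- lg + if (ti[r, 2] == 1) {
            as.numeric(log_edge[[e]] %*% beliefs[[j]])
          } else {
            as.numeric(crossprod(log_edge[[e]], beliefs[[j]]))
          }
        }
      }
      b <- exp(lg - max(lg))
      beliefs[[i]] <- b / sum(b)
    }
    resid <- belief_delta(beliefs, old)
    if (resid < config$tolerance) {
      converged <- TRUE
      break
    }
  }
  marginal_set(beliefs, converged, iter, resid, "mf")
}

#' Edge appearance probabilities (matrix-tree theorem)
#'
#' For each edge, the fraction of spanning trees of its connected component
#' that contain the edge, computed exactly as
#' `t(G / e) / t(G)` (contraction over deletion) with spanning-tree counts
#' from determinants of reduced Laplacians. Bridges and tree edges get 1.
#'
#' @param graph an `interaction_graph` or `mrf` (uses `n` and `edges`)
#' @return numeric vector of `rho` in `(0, 1]`, one per edge row
#' @export
compute_edge_appearance <- function(graph) {
  n <- graph$n
  edges <- graph$edges
  if (nrow(edges) == 0) return(numeric(0))
  comp <- graph_components(n, edges)
  rho <- numeric(nrow(edges))
  for (cid in unique(comp)) {
    verts <- which(comp == cid)
    eidx <- which(comp[edges[, 1]] == cid)
    if (length(eidx) == 0) next
    sub <- matrix(match(edges[eidx, ], verts), ncol = 2)
    t_all <- spanning_tree_count(length(verts), sub)
    for (k in seq_along(eidx)) {
      rho[eidx[k]] <- spanning_tree_count_contracted(length(verts), sub, k) /
        t_all
    }
  }
  pmin(rho, 1)
}

graph_components <- function(n, edges) {
  nb <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in nb[[v]]) {
        if (is.na(comp[w])) {
          comp[w] <- cid
          queue <- c(queue, w)
        }
      }
    }
  }
  comp
}

# spanning trees of a (multi)graph given as an edge matrix on 1..n
spanning_tree_count <- function(n, edges) {
  if (n == 1) return(1)
  A <- matrix(0, n, n)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    if (i == j) next
    A[i, j] <- A[i, j] + 1
    A[j, i] <- A[j, i] + 1
  }
  L <- diag(rowSums(A)) - A
  det(L[-1, -1, drop = FALSE])
}

# spanning trees containing edge k = spanning trees of G with edge k contracted
spanning_tree_count_contracted <- function(n, edges, k) {
  i <- edges[k, 1]; j <- edges[k, 2]
  e2 <- edges[-k, , drop = FALSE]
  # merge vertex j into i, drop resulting self-loops
  e2[e2 == j] <- i
  e2[e2 > j] <- e2[e2 > j] - 1L
  e2 <- e2[e2[, 1] != e2[, 2], , drop = FALSE]
  spanning_tree_count(n - 1L, e2)
}

#' Tree-reweighted belief propagation (sum-product)
#'
#' Messages are weighted by edge appearance probabilities `rho`: beliefs
#' raise incoming messages to `rho_ki`; the message from `i` to `j` uses
#' the edge potential to the power `1/rho_ij`, the `rho`-weighted product
#' of the other incoming messages, and divides by the reverse message to
#' the power `1 - rho_ij`. With all `rho = 1` the updates reduce exactly
#' to loopy belief propagation.
#'
#' @inheritParams lbp
#' @param rho numeric vector of edge appearance probabilities per edge row
#'   (see [compute_edge_appearance()])
#' @return a `marginal_set`
#' @export
trbp <- function(mrf, rho = compute_edge_appearance(mrf),
                 config = inference_config()) {
  if (nrow(mrf$edges) == 0) {
    return(marginal_set(mrf$node_pot, TRUE, 1L, 0, "trbp"))
  }
  stopifnot(length(rho) == nrow(mrf$edges), all(rho > 0), all(rho <= 1))
  inc <- incident_table(mrf)
  msg <- init_messages(mrf, config)
  pot_pow <- lapply(seq_len(nrow(mrf$edges)), function(e) {
    mrf$edge_pot[[e]]^(1 / rho[e])
  })
  beliefs <- compute_beliefs(mrf, inc, msg, rho = rho)
  if (config$schedule == "random") set.seed(config$seed)
  converged <- FALSE
  resid <- Inf
  iter <- 0L
  while (iter < config$max_iterations) {
    iter <- iter + 1L
    order_v <- if (config$schedule == "random") {
      sample.int(mrf$n)
    } else seq_len(mrf$n)
    for (i in order_v) {
      ti <- inc[[i]]
      if (is.null(ti)) next
      for (r in seq_len(nrow(ti))) {
        e <- ti[r, 1]; dir_out <- ti[r, 2]
        pre <- mrf$node_pot[[i]]
        for (r2 in seq_len(nrow(ti))) {
          if (r2 == r) next
          pre <- pre * msg[[msg_index(ti[r2, 1], ti[r2, 3])]]^rho[ti[r2, 1]]
        }
        pre <- pre / msg[[msg_index(e, ti[r, 3])]]^(1 - rho[e])
        pot <- pot_pow[[e]]
        m_new <- if (dir_out == 1) {
          as.numeric(crossprod(pot, pre))
        } else {
          as.numeric(pot %*% pre)
        }
        m_new <- m_new / sum(m_new)
        if (config$damping > 0) {
          m_old <- msg[[msg_index(e, dir_out)]]
          m_new <- (1 - config$damping) * m_new + config$damping * m_old
          m_new <- m_new / sum(m_new)
        }
        msg[[msg_index(e, dir_out)]] <- m_new
      }
    }
    new_beliefs <- compute_beliefs(mrf, inc, msg, rho = rho)
    resid <- belief_delta(new_beliefs, beliefs)
    beliefs <- new_beliefs
    if (resid < config$tolerance) {
      converged <- TRUE
      break
    }
  }
  marginal_set(beliefs, converged, iter, resid, "trbp")
}
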