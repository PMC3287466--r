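test_that("enumeration oracle handles the analytic corner cases", {
  # flat joint: uniform marginals
  m <- make_toy_mrf(4, "cycle", states = 3, seed = 1)
  m$node_pot <- lapply(m$node_pot, function(v) rep(1, length(v)))
  m$edge_pot <- lapply(m$edge_pot, function(x) x * 0 + 1)
  ex <- exact_marginals(m)
  for (b in ex$beliefs) expect_equal(b, rep(1 / 3, 3))

  # symmetric 2x2 coupling keeps (0.5, 0.5)
  m2 <- list(n = 2, edges = rbind(c(1L, 2L)), n_states = c(2L, 2L),
             node_pot = list(c(1, 1), c(1, 1)),
             edge_pot = list(matrix(c(2, 1, 1, 2), 2, 2)))
  class(m2) <- "mrf"
  ex2 <- exact_marginals(m2)
  expect_equal(ex2$beliefs[[1]], c(0.5, 0.5))
  expect_equal(ex2$beliefs[[2]], c(0.5, 0.5))
  expect_equal(attr(ex2, "Z"), 6)  # 2+1+1+2

  # single vertex: normalized potential
  m3 <- list(n = 1, edges = matrix(integer(0), ncol = 2), n_states = 3L,
             node_pot = list(c(2, 1, 1)), edge_pot = list())
  class(m3) <- "mrf"
  expect_equal(exact_marginals(m3)$beliefs[[1]], c(0.5, 0.25, 0.25))

  # refusal above the state-space cap
  m4 <- make_toy_mrf(8, "chain", states = 4, seed = 2)
  expect_error(exact_marginals(m4, max_states = 100), "too large")
})

test_that("single-vertex models are solved in one sweep by all algorithms", {
  m <- list(n = 1, edges = matrix(integer(0), ncol = 2), n_states = 4L,
            node_pot = list(c(4, 2, 1, 1)), edge_pot = list())
  class(m) <- "mrf"
  want <- c(0.5, 0.25, 0.125, 0.125)
  for (f in list(lbp, mean_field, gbp)) {
    out <- f(m)
    expect_equal(out$beliefs[[1]], want)
    expect_true(out$converged)
  }
  out <- trbp(m, numeric(0))
  expect_equal(out$beliefs[[1]], want)
})

test_that("belief propagation is exact on random trees and chains", {
  cfg <- inference_config(tolerance = 1e-12)
  for (seed in 1:30) {
    n <- 3 + (seed %% 5)
    topo <- if (seed %% 2 == 0) "chain" else "tree"
    m <- make_toy_mrf(n, topo, states = 2 + (seed %% 3), seed = seed)
    ex <- exact_marginals(m)
    expect_lt(max_belief_diff(lbp(m, cfg), ex), 1e-8)
  }
})

test_that("near-flat cycles are approximated closely by loopy BP", {
  set.seed(5)
  m <- make_toy_mrf(4, "cycle", states = 2, seed = 5)
  # weak couplings: potentials close to 1
  m$edge_pot <- lapply(m$edge_pot, function(x) 1 + 0.05 * (x - mean(x)))
  ex <- exact_marginals(m)
  expect_lt(max_belief_diff(lbp(m), ex), 1e-3)
})

test_that("mean field is exact without couplings and reaches a fixed point", {
  m <- make_toy_mrf(5, "chain", states = 3, seed = 3)
  m0 <- m
  m0$edges <- matrix(integer(0), ncol = 2)
  m0$edge_pot <- list()
  ex <- exact_marginals(m0)
  expect_lt(max_belief_diff(mean_field(m0), ex), 1e-10)

  out <- mean_field(m, inference_config(tolerance = 1e-10))
  expect_true(out$converged)
  # one more sweep changes nothing beyond tolerance
  again <- mean_field(m, inference_config(tolerance = 1e-10,
                                          max_iterations = 200))
  expect_lt(max_belief_diff(out, again), 1e-8)
})

test_that("edge appearance probabilities match analytic values", {
  tri <- list(n = 3, edges = rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L)))
  expect_equal(compute_edge_appearance(tri), rep(2 / 3, 3))
  cyc <- list(n = 4, edges = rbind(c(1L, 2L), c(1L, 4L), c(2L, 3L),
                                   c(3L, 4L)))
  expect_equal(compute_edge_appearance(cyc), rep(3 / 4, 4))
  m <- make_toy_mrf(6, "tree", states = 2, seed = 4)
  expect_equal(compute_edge_appearance(m), rep(1, 5))
})

test_that("matrix-tree rho equals brute-force spanning-tree enumeration", {
  for (g in all_connected_graphs(4)) {
    gg <- list(n = 4, edges = g)
    expect_equal(compute_edge_appearance(gg), brute_edge_appearance(4, g),
                 tolerance = 1e-12)
  }
  set.seed(9)
  for (rep in 1:10) {
    n <- sample(5:6, 1)
    pairs <- t(utils::combn(n, 2))
    repeat {
      sel <- which(runif(nrow(pairs)) < 0.5)
      if (length(sel) >= n - 1 &&
          length(unique(c(pairs[sel, ]))) == n) {
        g <- pairs[sel, , drop = FALSE]
        if (!any(is.na(brute_edge_appearance(n, g)))) break
      }
    }
    expect_equal(compute_edge_appearance(list(n = n, edges = g)),
                 brute_edge_appearance(n, g), tolerance = 1e-10)
  }
})

test_that("TRBP with unit edge appearance reproduces loopy BP exactly", {
  for (seed in 1:8) {
    topo <- c("chain", "tree", "cycle", "complete")[1 + seed %% 4]
    m <- make_toy_mrf(4 + seed %% 3, topo, states = 2 + seed %% 2,
                      seed = seed)
    l <- lbp(m)
    t1 <- trbp(m, rep(1, nrow(m$edges)))
    expect_lt(max_belief_diff(t1, l), 1e-10)
  }
})

test_that("TRBP with exact rho is exact on trees", {
  cfg <- inference_config(tolerance = 1e-12)
  for (seed in 1:10) {
    m <- make_toy_mrf(3 + seed %% 4, "tree", states = 2 + seed %% 3,
                      seed = 100 + seed)
    expect_lt(max_belief_diff(trbp(m, config = cfg), exact_marginals(m)),
              1e-8)
  }
})

test_that("GBP matches loopy BP on triangle-free graphs and is exact on a triangle", {
  cfg <- inference_config(tolerance = 1e-12, max_iterations = 300)
  # triangle-free loopy graph: Bethe equivalence
  m <- make_toy_mrf(6, "cycle", states = 3, seed = 17)
  expect_lt(max_belief_diff(gbp(m, cfg), lbp(m, cfg)), 1e-8)
  # one triangle: single outer region, exact
  m2 <- make_toy_mrf(3, "cycle", states = 4, seed = 18)
  expect_lt(max_belief_diff(gbp(m2, cfg), exact_marginals(m2)), 1e-12)
  # two triangles sharing an edge form a junction tree: exact
  m3 <- make_toy_mrf(4, "complete", states = 2, seed = 19)
  drop <- which(m3$edges[, 1] == 1 & m3$edges[, 2] == 4)
  m3$edges <- m3$edges[-drop, , drop = FALSE]
  m3$edge_pot <- m3$edge_pot[-drop]
  expect_lt(max_belief_diff(gbp(m3, cfg), exact_marginals(m3)), 1e-8)
})

test_that("all algorithms return normalized beliefs and honor rescaling", {
  m <- make_toy_mrf(5, "cycle", states = 3, seed = 23)
  scaled <- m
  scaled$node_pot[[2]] <- scaled$node_pot[[2]] * 7.3
  scaled$edge_pot[[1]] <- scaled$edge_pot[[1]] * 0.01
  for (f in list(lbp, mean_field, gbp,
                 function(x, ...) trbp(x, config = inference_config()))) {
    out <- f(m)
    expect_true(all(abs(vapply(out$beliefs, sum, 0) - 1) < 1e-9))
    expect_lt(max_belief_diff(f(scaled), out), 1e-9)
  }
})

test_that("vertex relabeling permutes the marginals and nothing else", {
  m <- make_toy_mrf(5, "tree", states = 3, seed = 31)
  perm <- c(3L, 5L, 1L, 2L, 4L)   # new label of old vertex i
  pm <- m
  pm$node_pot[perm] <- m$node_pot
  pm$n_states[perm] <- m$n_states
  e2 <- cbind(perm[m$edges[, 1]], perm[m$edges[, 2]])
  flip <- e2[, 1] > e2[, 2]
  pot2 <- lapply(seq_len(nrow(e2)), function(k) {
    if (flip[k]) t(m$edge_pot[[k]]) else m$edge_pot[[k]]
  })
  e2 <- cbind(pmin(e2[, 1], e2[, 2]), pmax(e2[, 1], e2[, 2]))
  ord <- order(e2[, 1], e2[, 2])
  pm$edges <- e2[ord, , drop = FALSE]
  pm$edge_pot <- pot2[ord]
  out <- lbp(m, inference_config(tolerance = 1e-12))
  pout <- lbp(pm, inference_config(tolerance = 1e-12))
  for (i in seq_len(5)) {
    expect_equal(pout$beliefs[[perm[i]]], out$beliefs[[i]],
                 tolerance = 1e-9)
  }
})

test_that("non-convergence is reported, not raised", {
  m <- make_toy_mrf(5, "complete", states = 3, seed = 7)
  # strong frustrated couplings in one sweep only
  out <- lbp(m, inference_config(max_iterations = 1, tolerance = 1e-14))
  expect_false(out$converged)
  expect_equal(out$iterations, 1L)
  expect_true(is.finite(out$max_residual))
})

test_that("random initialization and schedule are reproducible by seed", {
  m <- make_toy_mrf(6, "cycle", states = 3, seed = 40)
  cfg <- inference_config(init = "random", schedule = "random", seed = 77)
  a <- lbp(m, cfg)
  b <- lbp(m, cfg)
  expect_identical(a$beliefs, b$beliefs)
})
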