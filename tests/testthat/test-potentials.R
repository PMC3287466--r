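test_that("repulsive energy matches its breakpoints and ramp", {
  p <- energy_params()
  r_ab <- 3.2
  expect_equal(atom_pair_energy(4.0, 1.6, 1.6, p), 0)
  expect_equal(atom_pair_energy(1.0, 1.6, 1.6, p), 10)
  expect_equal(atom_pair_energy(p$k_sc * r_ab, 1.6, 1.6, p), 10)
  expect_equal(atom_pair_energy(r_ab, 1.6, 1.6, p), 0)
  mid <- (p$k_sc * r_ab + r_ab) / 2
  expect_equal(atom_pair_energy(mid, 1.6, 1.6, p), 5)
})

test_that("repulsive energy is continuous, monotone and bounded", {
  p <- energy_params()
  d <- seq(0, 5, length.out = 10000)
  e <- atom_pair_energy(d, 1.6, 1.3, p)
  expect_true(all(diff(e) <= 1e-12))
  expect_true(all(e >= 0 & e <= p$E_max))
  r_ab <- 2.9
  for (bp in c(p$k_sc * r_ab, r_ab)) {
    lo <- atom_pair_energy(bp - 1e-12, 1.6, 1.3, p)
    hi <- atom_pair_energy(bp + 1e-12, 1.6, 1.3, p)
    expect_lt(abs(hi - lo), 1e-9)
  }
})

test_that("hydrogen-bond term obeys its gates and its optimum", {
  off <- energy_params(hbond = hbond_params(enabled = FALSE))
  fx <- make_backbone(2, sequence = c("SER", "ASP"), mode = "extended",
                      seed = 1)
  r1 <- fx$backbone$residues[[1]]
  r2 <- fx$backbone$residues[[2]]
  sc1 <- build_side_chain(r1, -60)
  sc2 <- build_side_chain(r2, c(-60, 0))
  expect_equal(hbond_energy(r1, r2, sc1, sc2, off), 0)

  # no donor/acceptor side-chain pair at all
  fv <- make_backbone(2, sequence = c("VAL", "LEU"), seed = 1)
  v1 <- fv$backbone$residues[[1]]; v2 <- fv$backbone$residues[[2]]
  expect_equal(hbond_energy(v1, v2, build_side_chain(v1, 180),
                            build_side_chain(v2, c(-60, 180)),
                            energy_params()), 0)

  # geometry placed exactly at the optimum: energy equals the weight
  p <- energy_params()
  don <- r1
  don$atoms <- list(N = c(0, 5, 0), CA = c(1, 5, 0), C = c(2, 5, 0),
                    O = c(3, 5, 0))
  dsc <- structure(list(residue_index = 0L, aa = "SER", chi = -60,
                        atoms = list(CB = c(0, 0, 1), OG = c(0, 0, 0))),
                   class = "side_chain")
  acc <- r2
  acc$atoms <- list(N = c(0, -5, 0), CA = c(1, -5, 0), C = c(2, -5, 0),
                    O = c(3, -5, 0))
  asc <- structure(list(residue_index = 1L, aa = "ASP", chi = c(0, 0),
                        atoms = list(CB = c(25, 0, 0), CG = c(24, 0, 0),
                                     OD1 = c(p$hbond$distance_opt, 0, 0),
                                     OD2 = c(20, 0, 0))),
                   class = "side_chain")
  expect_equal(hbond_energy(don, acc, dsc, asc, p), p$hbond$weight)
  # below the angle gate: no contribution
  dsc$atoms$CB <- c(-1, 0, 0)  # antecedent behind the acceptor: angle 180 ok
  expect_equal(hbond_energy(don, acc, dsc, asc, p), p$hbond$weight)
  dsc$atoms$CB <- c(1, 0, 0)   # angle 0, gated out
  expect_equal(hbond_energy(don, acc, dsc, asc, p), 0)
})

test_that("the prior term is zero at the mode and k_d at p_max/e", {
  txt <- c(paste("SER -60 -40 100 1 0 0 0", 0.5, "-60 0 0 0"),
           paste("SER -60 -40 100 2 0 0 0", 0.5 * exp(-1), "60 0 0 0"),
           paste("SER -60 -40 100 3 0 0 0", 0.5 - 0.5 * exp(-1),
                 "180 0 0 0"))
  lib <- parse_library(txt)
  res <- list(point_residue(1, c(0, 0, 0), aa = "SER"))
  res[[1]]$phi <- -60; res[[1]]$psi <- -40
  bb <- fake_backbone(res)
  g <- build_graph(bb, lib)          # isolated vertex: no clash terms
  expect_equal(vertex_energy(1, 1, bb, g), 0)
  k_e <- which(g$candidates[[1]]$chi1 == 60)  # the p_max/e rotamer
  expect_equal(vertex_energy(1, k_e, bb, g), 3.0, tolerance = 1e-12)
  # monotone non-increasing in the prior
  ord <- order(g$candidates[[1]]$prob, decreasing = TRUE)
  en <- vapply(seq_len(3), function(k) vertex_energy(1, k, bb, g), 0)
  expect_true(all(diff(en[ord]) >= 0))
})

test_that("edge energies are symmetric and vanish for distant or GLY pairs", {
  b <- make_bundle(8, seed = 5)
  p <- energy_params(hbond = hbond_params(enabled = FALSE))
  e <- b$graph$edges[1, ]
  for (ki in 1:2) {
    for (kj in 1:2) {
      expect_equal(edge_energy(e[1], e[2], ki, kj, b$bb, b$graph, p),
                   edge_energy(e[2], e[1], kj, ki, b$bb, b$graph, p))
    }
  }
  # distant side chains: zero
  fx <- make_backbone(2, sequence = "LYS", seed = 1)
  res <- fx$backbone$residues
  res[[2]]$atoms <- lapply(res[[2]]$atoms, function(a) a + c(30, 0, 0))
  bb2 <- fake_backbone(res)
  lib <- parse_library(make_library("LYS", rotamers_per_bin = 2, seed = 1))
  g2 <- build_graph(bb2, lib, threshold = 100)
  expect_equal(edge_energy(1, 2, 1, 1, bb2, g2, p), 0)
})

test_that("Boltzmann conversion is exact and potentials are positive", {
  expect_equal(boltzmann_potential(0), 1)
  expect_equal(boltzmann_potential(0.6, 0.6), exp(-1))
  b <- make_bundle(6, seed = 9)
  mrf <- assemble_mrf(b$bb, b$graph)
  expect_true(all(unlist(mrf$node_pot) > 0))
  expect_true(all(is.finite(unlist(mrf$node_pot))))
  for (m in mrf$edge_pot) expect_true(all(m > 0 & is.finite(m)))
})

test_that("the enumerated joint distribution is normalized", {
  b <- make_bundle(3, seed = 14)
  mrf <- assemble_mrf(b$bb, b$graph)
  ex <- exact_marginals(mrf)
  expect_true(all(abs(vapply(ex$beliefs, sum, 0) - 1) < 1e-9))
  expect_gt(attr(ex, "Z"), 0)
})

test_that("shifting all vertex energies of a residue leaves marginals alone", {
  b <- make_bundle(7, seed = 4)
  mrf <- assemble_mrf(b$bb, b$graph)
  for (alg in list(lbp, mean_field, gbp)) {
    base <- alg(mrf)
    shifted <- mrf
    shifted$node_pot[[3]] <- shifted$node_pot[[3]] *
      boltzmann_potential(2.5)    # constant energy offset on residue 3
    moved <- alg(shifted)
    expect_lt(max_belief_diff(base, moved), 1e-9)
  }
})

test_that("parameter validation rejects unphysical settings", {
  expect_error(energy_params(kBT = -1))
  expect_error(energy_params(k_sc = 1.2))
  expect_error(hbond_params(weight = 1))
})
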