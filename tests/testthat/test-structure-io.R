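pdb_line <- function(serial, name, resn, resno, x, y, z, occ = 1.00,
                     alt = " ", chain = "A") {
  sprintf("ATOM  %5d  %-3s%s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, name, alt, resn, chain, resno, x, y, z, occ, 0)
}

three_residue_pdb <- function() {
  fx <- make_backbone(3, sequence = c("SER", "GLY", "VAL"), mode = "helix",
                      seed = 2)
  fx$pdb
}

test_that("parsing a small synthetic structure yields ordered residues", {
  bb <- parse_backbone(three_residue_pdb())
  expect_length(bb$residues, 3)
  expect_equal(vapply(bb$residues, `[[`, "", "aa"), c("SER", "GLY", "VAL"))
  expect_equal(vapply(bb$residues, `[[`, 0L, "resno"), 1:3)
  for (r in bb$residues) {
    expect_true(all(c("N", "CA", "C", "O") %in% names(r$atoms)))
  }
})

test_that("glycine records carry no CB atom", {
  bb <- parse_backbone(three_residue_pdb())
  expect_false("CB" %in% names(bb$residues[[2]]$atoms))
  expect_true("CB" %in% names(bb$residues[[1]]$atoms))
})

test_that("a duplicate backbone atom is rejected with the residue named", {
  lines <- c(pdb_line(1, "N", "ALA", 5, 0, 0, 0),
             pdb_line(2, "CA", "ALA", 5, 1.4, 0, 0),
             pdb_line(3, "CA", "ALA", 5, 1.5, 0, 0),
             pdb_line(4, "C", "ALA", 5, 2.0, 1.0, 0),
             pdb_line(5, "O", "ALA", 5, 2.0, 2.0, 0))
  expect_error(parse_backbone(paste(lines, collapse = "\n")), "A:5")
})

test_that("missing mandatory backbone atoms are rejected", {
  lines <- c(pdb_line(1, "N", "ALA", 1, 0, 0, 0),
             pdb_line(2, "CA", "ALA", 1, 1.4, 0, 0),
             pdb_line(3, "C", "ALA", 1, 2.0, 1.0, 0))
  expect_error(parse_backbone(paste(lines, collapse = "\n")), "missing")
})

test_that("alternate locations resolve to the highest occupancy", {
  lines <- c(pdb_line(1, "N", "ALA", 1, 0, 0, 0),
             pdb_line(2, "CA", "ALA", 1, 1.400, 0, 0, occ = 0.4, alt = "A"),
             pdb_line(3, "CA", "ALA", 1, 1.500, 0, 0, occ = 0.6, alt = "B"),
             pdb_line(4, "C", "ALA", 1, 2.0, 1.0, 0),
             pdb_line(5, "O", "ALA", 1, 2.0, 2.2, 0))
  bb <- parse_backbone(paste(lines, collapse = "\n"))
  expect_equal(bb$residues[[1]]$atoms$CA[1], 1.5)
})

test_that("termini leave dihedrals undefined; ideal helix is recovered", {
  fx <- make_backbone(1, sequence = "SER", seed = 1)
  r <- fx$backbone$residues[[1]]
  expect_true(is.na(r$phi) && is.na(r$psi))

  fx <- make_backbone(10, sequence = "LEU", mode = "helix", seed = 1)
  mids <- fx$backbone$residues[2:9]
  expect_true(all(abs(vapply(mids, `[[`, 0, "phi") + 57) < 1e-3))
  expect_true(all(abs(vapply(mids, `[[`, 0, "psi")[1:7] + 47) < 1e-3))
  expect_true(all(angular_distance(
    vapply(fx$backbone$residues[1:9], `[[`, 0, "omega"), 180) < 1e-3))
})

test_that("alanine side-chain construction places exactly the CB atom", {
  fx <- make_backbone(3, sequence = "ALA", seed = 1)
  sc <- build_side_chain(fx$backbone$residues[[2]], numeric(0))
  expect_equal(names(sc$atoms), "CB")
})

test_that("chi angles round-trip through construction for every residue type", {
  fx <- make_backbone(3, sequence = "SER", mode = "extended", seed = 1)
  r <- fx$backbone$residues[[2]]
  set.seed(123)
  for (aa in setdiff(rotamrf:::AA3, c("ALA", "GLY"))) {
    r$aa <- aa
    for (rep in 1:3) {
      chi <- runif(n_chi(aa), -180, 180)
      sc <- build_side_chain(r, chi)
      back <- measure_chi(r, sc$atoms)
      expect_lt(max(angular_distance(back, chi)), 1e-4)
    }
  }
})

test_that("chi count is enforced and unknown residues are rejected", {
  fx <- make_backbone(2, sequence = "VAL", seed = 1)
  expect_error(build_side_chain(fx$backbone$residues[[1]], c(60, 60)),
               "chi angle")
  bad <- fx$backbone$residues[[1]]
  bad$aa <- "XXX"
  expect_error(build_side_chain(bad, numeric(0)), "unknown amino acid")
})

test_that("CB position does not depend on chi1", {
  fx <- make_backbone(2, sequence = "VAL", seed = 1)
  r <- fx$backbone$residues[[1]]
  a <- build_side_chain(r, -60)
  b <- build_side_chain(r, 60)
  expect_identical(a$atoms$CB, b$atoms$CB)
})

test_that("write/parse round trip preserves backbone exactly as formatted", {
  fx <- make_backbone(5, sequence = c("SER", "GLY", "VAL", "LEU", "THR"),
                      seed = 6)
  bb <- parse_backbone(fx$pdb)
  txt <- write_structure(bb)
  bb2 <- parse_backbone(txt)
  expect_length(bb2$residues, length(bb$residues))
  for (i in seq_along(bb$residues)) {
    for (nm in names(bb$residues[[i]]$atoms)) {
      expect_identical(bb2$residues[[i]]$atoms[[nm]],
                       bb$residues[[i]]$atoms[[nm]])
    }
  }
})

test_that("writing with no assignments emits the backbone unchanged", {
  fx <- make_backbone(4, sequence = "GLY", seed = 3)
  bb <- parse_backbone(fx$pdb)
  out <- write_structure(bb, list())
  atoms_in <- sum(grepl("^ATOM", fx$pdb))
  atoms_out <- sum(grepl("^ATOM", out))
  expect_equal(atoms_out, atoms_in)
})

test_that("predicted side chains appear in the written structure", {
  fx <- make_backbone(2, sequence = "SER", seed = 3)
  bb <- parse_backbone(fx$pdb)
  asn <- lapply(bb$residues, build_side_chain, chi = -60)
  out <- write_structure(bb, asn)
  expect_equal(sum(grepl(" OG ", out)), 2)
  chis <- parse_chi_angles(out)
  expect_lt(max(angular_distance(unlist(chis), -60)), 0.05)
})
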