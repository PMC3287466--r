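#' Parse a protein backbone from PDB-format text
#'
#' Reads ATOM records (model 1, standard residues) and returns one backbone
#' record per residue. Alternate locations are resolved to the highest
#' occupancy (first on tie); residues are ordered by chain, residue number
#' and insertion code. Mirrors a strict input policy: a residue carrying a
#' duplicate backbone atom, or missing any of N/CA/C/O, is a hard error.
#'
#' @param pdb_text character scalar (or vector of lines) of PDB content,
#'   or a path to a PDB file.
#' @param chain_break_dist CA-CA distance (Angstroms) above which
#'   consecutive residues are treated as separated by a chain break.
#' @return An object of class `backbone`: a list with `residues` (a list of
#'   per-residue records: `index`, `aa`, `chain`, `resno`, `insert`,
#'   `atoms` named list of 3-vectors incl. CB when present, and
#'   `phi`/`psi`/`omega` once annotated) and `chain_break_dist`.
#' @export
parse_backbone <- function(pdb_text, chain_break_dist = 4.5) {
  path <- pdb_text
  if (length(pdb_text) > 1 || grepl("\n", pdb_text[1], fixed = TRUE) ||
      grepl("^ATOM", pdb_text[1])) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(paste(pdb_text, collapse = "\n"), path)
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & toupper(at$resid) %in% AA3, , drop = FALSE]
  if (nrow(at) == 0) stop("no standard-residue ATOM records found")
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1

  bb_names <- c("N", "CA", "C", "O", "CB")
  at <- at[at$elety %in% bb_names, , drop = FALSE]
  key <- paste(at$chain, at$resno, at$insert, sep = "|")

  # duplicate backbone atoms at the same altloc are a rejection
  dup <- duplicated(paste(key, at$elety, at$alt))
  if (any(dup)) {
    bad <- unique(paste0(at$chain[dup], ":", at$resno[dup], at$insert[dup]))
    stop("duplicate backbone atom(s) for residue(s): ",
         paste(bad, collapse = ", "))
  }
  # altloc resolution: highest occupancy, first record on ties
  ord <- order(key, at$elety, -at$o)
  at <- at[ord, , drop = FALSE]
  key <- key[ord]
  keep <- !duplicated(paste(key, at$elety))
  at <- at[keep, , drop = FALSE]
  key <- key[keep]

  # residue ordering: chain, then resno, then insertion code
  ukey <- unique(key[order(at$chain, at$resno, at$insert)])
  residues <- vector("list", length(ukey))
  for (i in seq_along(ukey)) {
    rows <- at[key == ukey[i], , drop = FALSE]
    aa <- toupper(rows$resid[1])
    atoms <- list()
    for (k in seq_len(nrow(rows))) {
      atoms[[rows$elety[k]]] <- c(rows$x[k], rows$y[k], rows$z[k])
    }
    missing <- setdiff(c("N", "CA", "C", "O"), names(atoms))
    if (length(missing) > 0) {
      stop("residue ", rows$chain[1], ":", rows$resno[1], rows$insert[1],
           " is missing backbone atom(s): ", paste(missing, collapse = ", "))
    }
    if (aa == "GLY") atoms$CB <- NULL
    residues[[i]] <- list(index = i - 1L, aa = aa, chain = rows$chain[1],
                          resno = rows$resno[1], insert = rows$insert[1],
                          atoms = atoms,
                          phi = NA_real_, psi = NA_real_, omega = NA_real_)
  }
  bb <- structure(list(residues = residues,
                       chain_break_dist = chain_break_dist),
                  class = "backbone")
  annotate_backbone_dihedrals(bb)
}

#' @export
print.backbone <- function(x, ...) {
  cat("backbone:", length(x$residues), "residues,",
      length(unique(vapply(x$residues, `[[`, "", "chain"))), "chain(s)\n")
  invisible(x)
}

#' Annotate phi/psi/omega dihedrals on a parsed backbone
#'
#' phi_i = C(i-1)-N(i)-CA(i)-C(i); psi_i = N(i)-CA(i)-C(i)-N(i+1);
#' omega_i = CA(i)-C(i)-N(i+1)-CA(i+1). Angles spanning a chain change or a
#' chain break (CA-CA distance above the sanity bound) are left `NA`.
#'
#' @param bb a `backbone` object
#' @return the same object with `phi`, `psi`, `omega` filled in degrees
#' @export
annotate_backbone_dihedrals <- function(bb) {
  res <- bb$residues
  n <- length(res)
  linked <- function(i) {
    # TRUE when residues i and i+1 are consecutive in the same chain
    if (i < 1 || i >= n) return(FALSE)
    a <- res[[i]]; b <- res[[i + 1]]
    if (!identical(a$chain, b$chain)) return(FALSE)
    d <- sqrt(sum((a$atoms$CA - b$atoms$CA)^2))
    if (d > bb$chain_break_dist) {
      warning("chain break between residues ", a$chain, ":", a$resno,
              " and ", b$chain, ":", b$resno,
              sprintf(" (CA-CA %.2f A)", d))
      return(FALSE)
    }
    TRUE
  }
  link <- vapply(seq_len(max(n - 1, 0)), linked, logical(1))
  for (i in seq_len(n)) {
    r <- res[[i]]
    if (i > 1 && link[i - 1]) {
      r$phi <- compute_dihedral(res[[i - 1]]$atoms$C, r$atoms$N,
                                r$atoms$CA, r$atoms$C)
    } else r$phi <- NA_real_
    if (i < n && link[i]) {
      r$psi <- compute_dihedral(r$atoms$N, r$atoms$CA, r$atoms$C,
                                res[[i + 1]]$atoms$N)
      r$omega <- compute_dihedral(r$atoms$CA, r$atoms$C,
                                  res[[i + 1]]$atoms$N, res[[i + 1]]$atoms$CA)
    } else {
      r$psi <- NA_real_
      r$omega <- NA_real_
    }
    res[[i]] <- r
  }
  bb$residues <- res
  bb
}

#' Build side-chain heavy atoms from chi angles
#'
#' Sequential internal-coordinate (NeRF) construction from the shipped
#' idealized-geometry table. The chi round trip is exact: recomputing the
#' defining dihedrals from the produced coordinates returns the input chi
#' to well below 1e-4 degrees.
#'
#' @param residue one residue record from a `backbone` object
#' @param chi numeric vector of chi angles in degrees; its length must equal
#'   `n_chi(residue$aa)`
#' @return list of class `side_chain`: `residue_index`, `aa`, `chi`, and
#'   `atoms` (named list of 3-vectors, CB first; empty for GLY)
#' @export
build_side_chain <- function(residue, chi = numeric(0)) {
  aa <- toupper(residue$aa)
  nc <- n_chi(aa)
  if (length(chi) != nc) {
    stop(aa, " requires ", nc, " chi angle(s), got ", length(chi))
  }
  pos <- residue$atoms
  out <- list()
  rows <- sidechain_rows(aa)
  if (!is.null(rows)) {
    for (k in seq_len(nrow(rows))) {
      row <- rows[k, ]
      tor <- if (row$chi > 0) wrap_angle(chi[row$chi] + row$offset) else row$offset
      p <- place_atom(pos[[row$p1]], pos[[row$p2]], pos[[row$p3]],
                      row$length, row$angle, tor)
      pos[[row$atom]] <- p
      out[[row$atom]] <- p
    }
  }
  structure(list(residue_index = residue$index, aa = aa,
                 chi = as.numeric(chi), atoms = out),
            class = "side_chain")
}

#' Measure the chi angles of a built or experimental side chain
#'
#' @param residue residue record supplying backbone atoms
#' @param sc_atoms named list of side-chain atom positions (including CB)
#' @return numeric vector of chi angles in degrees (length `n_chi(aa)`),
#'   `NA` where defining atoms are absent
#' @export
measure_chi <- function(residue, sc_atoms) {
  aa <- toupper(residue$aa)
  nc <- n_chi(aa)
  if (nc == 0) return(numeric(0))
  # side-chain positions take precedence over backbone duplicates (CB)
  pos <- c(sc_atoms, residue$atoms)
  defs <- chi_atoms[[aa]]
  vapply(seq_len(nc), function(k) {
    q <- defs[[k]]
    if (!all(q %in% names(pos))) return(NA_real_)
    compute_dihedral(pos[[q[1]]], pos[[q[2]]], pos[[q[3]]], pos[[q[4]]])
  }, numeric(1))
}

#' Extract true chi angles from a full-atom PDB
#'
#' Reads side-chain heavy atoms of model 1 and measures the canonical chi
#' dihedrals per residue (the role the Dangle program plays for
#' experimental structures).
#'
#' @inheritParams parse_backbone
#' @return list parallel to `parse_backbone(pdb_text)$residues`, each
#'   element a numeric chi vector (possibly with NAs for missing atoms)
#' @export
parse_chi_angles <- function(pdb_text) {
  path <- pdb_text
  if (length(pdb_text) > 1 || grepl("\n", pdb_text[1], fixed = TRUE) ||
      grepl("^ATOM", pdb_text[1])) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(paste(pdb_text, collapse = "\n"), path)
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & toupper(at$resid) %in% AA3, , drop = FALSE]
  at$insert[is.na(at$insert)] <- ""
  key <- paste(at$chain, at$resno, at$insert, sep = "|")
  bb <- parse_backbone(pdb_text)
  lapply(bb$residues, function(r) {
    rows <- at[key == paste(r$chain, r$resno, r$insert, sep = "|"), ,
               drop = FALSE]
    sc <- list()
    for (k in seq_len(nrow(rows))) {
      if (!rows$elety[k] %in% names(sc)) {
        sc[[rows$elety[k]]] <- c(rows$x[k], rows$y[k], rows$z[k])
      }
    }
    measure_chi(r, sc)
  })
}

#' Write a predicted full-atom structure as PDB text
#'
#' Backbone coordinates are copied unchanged from the input; side-chain
#' atoms come from the supplied conformations. Residues without an
#' assignment are written backbone-only.
#'
#' @param bb a `backbone` object
#' @param assignments list mapping residue list-position (1-based) to a
#'   `side_chain` object, or `NULL` entries for backbone-only output
#' @param path optional file path; when given, text is also written there
#' @return character vector of PDB lines, invisibly when `path` is given
#' @export
write_structure <- function(bb, assignments = list(), path = NULL) {
  res <- bb$residues
  xyz <- c(); eleno <- c(); elety <- c(); resid <- c(); chain <- c()
  resno <- c(); insert <- c()
  serial <- 0L
  for (i in seq_along(res)) {
    r <- res[[i]]
    atoms <- r$atoms
    asn <- if (i <= length(assignments)) assignments[[i]] else NULL
    if (!is.null(asn)) for (nm in names(asn$atoms)) atoms[[nm]] <- asn$atoms[[nm]]
    order_names <- c("N", "CA", "C", "O",
                     setdiff(names(atoms), c("N", "CA", "C", "O")))
    for (nm in order_names) {
      serial <- serial + 1L
      xyz <- c(xyz, atoms[[nm]])
      eleno <- c(eleno, serial)
      elety <- c(elety, nm)
      resid <- c(resid, r$aa)
      chain <- c(chain, r$chain)
      resno <- c(resno, r$resno)
      insert <- c(insert, r$insert)
    }
  }
  out <- if (is.null(path)) tempfile(fileext = ".pdb") else path
  insert[insert == ""] <- NA
  suppressWarnings(bio3d::write.pdb(
    file = out, xyz = xyz, eleno = eleno, elety = elety, resid = resid,
    chain = chain, resno = resno, insert = insert
  ))
  lines <- readLines(out)
  if (is.null(path)) {
    unlink(out)
    lines
  } else invisible(lines)
}
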