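#' Parse a Dunbrack-style backbone-dependent rotamer library
#'
#' Accepts whitespace-delimited text in either the classic 2002 dialect
#' (`aa phi psi count r1 r2 r3 r4 prob chi1..chi4 [sig1..sig4]`) or the
#' compact dialect without the count column
#' (`aa phi psi r1 r2 r3 r4 prob chi1..chi4 [sig1..sig4]`); the layout is
#' auto-sniffed from the column count. 2010-style files carry the same
#' leading columns and any continuous-density extras are ignored. Comment
#' lines start with `#`. Per (aa, phi, psi) bin, records are sorted by
#' descending probability and probabilities are renormalized to sum to 1
#' (with a warning when the raw sum deviates by more than 1e-3).
#'
#' @param text library content as a single string, a vector of lines, or a
#'   file path
#' @return object of class `rotamer_library`: list with `bins` (named list
#'   keyed `AA|phi|psi` of data.frames with columns `aa, phi, psi, r1..r4,
#'   prob, chi1..chi4, sig1..sig4`), `bin_width`, and per-aa bin centers
#' @export
parse_library <- function(text) {
  if (length(text) == 1 && !grepl("\n", text, fixed = TRUE) &&
      file.exists(text)) {
    lines <- readLines(text)
  } else {
    lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  }
  lines <- trimws(lines)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0) stop("rotamer library contains no data rows")

  toks <- strsplit(lines, "[[:space:]]+")
  ncols <- vapply(toks, length, integer(1))
  # dialect sniff: 12/16 columns = no count column; 13/17+ = count column
  base <- min(ncols)
  has_count <- base >= 13
  need <- if (has_count) 13 else 12
  rows <- vector("list", length(toks))
  for (k in seq_along(toks)) {
    tk <- toks[[k]]
    if (length(tk) < need) {
      stop("malformed rotamer library row at line ", lineno[k],
           ": expected at least ", need, " fields, got ", length(tk))
    }
    aa <- toupper(tk[1])
    if (!aa %in% AA3) {
      stop("unknown amino acid '", tk[1], "' at line ", lineno[k])
    }
    num <- suppressWarnings(as.numeric(tk[-1]))
    if (any(is.na(num[seq_len(need - 1)]))) {
      stop("malformed numeric field at line ", lineno[k])
    }
    off <- if (has_count) 3 else 2  # numeric index of r1 minus 1
    sig <- rep(0, 4)
    if (length(num) >= need + 3) sig <- num[(need + 0):(need + 3)]
    rows[[k]] <- data.frame(
      aa = aa, phi = num[1], psi = num[2],
      r1 = num[off + 1], r2 = num[off + 2], r3 = num[off + 3],
      r4 = num[off + 4],
      prob = num[off + 5],
      chi1 = num[off + 6], chi2 = num[off + 7], chi3 = num[off + 8],
      chi4 = num[off + 9],
      sig1 = sig[1], sig2 = sig[2], sig3 = sig[3], sig4 = sig[4],
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  if (any(df$prob < 0)) stop("negative rotamer probability in library")

  key <- paste(df$aa, df$phi, df$psi, sep = "|")
  bins <- split(df, key)
  warned <- FALSE
  bins <- lapply(bins, function(b) {
    s <- sum(b$prob)
    if (s <= 0) stop("bin with zero total probability: ", b$aa[1])
    if (abs(s - 1) > 1e-3 && !warned) {
      warning("rotamer bin probabilities do not sum to 1 (e.g. ",
              b$aa[1], " ", b$phi[1], "/", b$psi[1], ", sum ",
              signif(s, 6), "); renormalizing")
      warned <<- TRUE
    }
    b$prob <- b$prob / s
    b[order(-b$prob), , drop = FALSE]
  })

  centers <- lapply(split(df[c("phi", "psi")], df$aa), unique)
  structure(list(bins = bins,
                 bin_width = guess_bin_width(centers),
                 centers = centers),
            class = "rotamer_library")
}

# bin width from the spacing of distinct phi centers (10 for Dunbrack files)
guess_bin_width <- function(centers) {
  phis <- sort(unique(unlist(lapply(centers, function(z) z$phi))))
  if (length(phis) < 2) return(10)
  min(diff(phis))
}

#' @export
print.rotamer_library <- function(x, ...) {
  cat("rotamer_library:", length(x$bins), "bins,",
      length(x$centers), "amino acid(s), bin width", x$bin_width, "deg\n")
  invisible(x)
}

# trivial single record for chi-less residues (ALA/GLY)
trivial_record <- function(aa) {
  data.frame(aa = aa, phi = NA_real_, psi = NA_real_,
             r1 = 0, r2 = 0, r3 = 0, r4 = 0, prob = 1,
             chi1 = NA_real_, chi2 = NA_real_, chi3 = NA_real_,
             chi4 = NA_real_, sig1 = 0, sig2 = 0, sig3 = 0, sig4 = 0,
             stringsAsFactors = FALSE)
}

#' Look up the rotamer candidates for a residue
#'
#' Returns the record list of the nearest (phi, psi) bin, with angular
#' wrap-around, sorted by descending prior probability. Residues with no
#' chi angles (ALA/GLY) get a single trivial record. When phi or psi is
#' undefined (chain termini), the backbone-independent marginal over all
#' bins of that amino acid is returned and flagged via the
#' `backbone_independent` attribute.
#'
#' @param lib a `rotamer_library`
#' @param aa three-letter amino-acid code
#' @param phi,psi backbone dihedrals in degrees (may be `NA`)
#' @return data.frame of rotamer records sorted by descending `prob`
#' @export
lookup <- function(lib, aa, phi, psi) {
  aa <- toupper(aa)
  if (n_chi(aa) == 0) return(trivial_record(aa))
  ctr <- lib$centers[[aa]]
  if (is.null(ctr) || nrow(ctr) == 0) {
    stop("rotamer library has no bins for amino acid ", aa)
  }
  if (is.na(phi) || is.na(psi)) {
    # backbone-independent fallback: average the bins
    keys <- paste(aa, ctr$phi, ctr$psi, sep = "|")
    all <- do.call(rbind, lib$bins[keys])
    id <- paste(all$r1, all$r2, all$r3, all$r4)
    agg <- lapply(split(all, id), function(b) {
      out <- b[1, , drop = FALSE]
      out$prob <- mean(b$prob)
      out$chi1 <- mean(b$chi1); out$chi2 <- mean(b$chi2)
      out$chi3 <- mean(b$chi3); out$chi4 <- mean(b$chi4)
      out
    })
    rec <- do.call(rbind, agg)
    rec$prob <- rec$prob / sum(rec$prob)
    rec <- rec[order(-rec$prob), , drop = FALSE]
    rownames(rec) <- NULL
    attr(rec, "backbone_independent") <- TRUE
    return(rec)
  }
  d <- angular_distance(ctr$phi, phi)^2 + angular_distance(ctr$psi, psi)^2
  best <- which.min(d)
  rec <- lib$bins[[paste(aa, ctr$phi[best], ctr$psi[best], sep = "|")]]
  rownames(rec) <- NULL
  attr(rec, "backbone_independent") <- FALSE
  rec
}

#' Write a protein-dependent rotamer library
#'
#' Emits the input library's column layout (`aa phi psi r1..r4 prob
#' chi1..chi4 sig1..sig4`) with a leading residue-index column; per
#' residue, records are sorted by descending updated probability (stable in
#' the input prior order on ties). A header comment records the inference
#' algorithm, convergence status and parameters.
#'
#' @param marginals a `marginal_set` from an inference algorithm
#' @param graph the `interaction_graph` carrying per-residue candidates
#' @param bb the `backbone` object (for author residue numbering)
#' @param path optional output file path
#' @return character vector of output lines (invisibly when `path` given)
#' @export
write_protein_library <- function(marginals, graph, bb, path = NULL) {
  lines <- c(
    "# protein-dependent rotamer library",
    paste0("# algorithm: ", marginals$algorithm,
           "; converged: ", marginals$converged,
           "; iterations: ", marginals$iterations,
           "; max_residual: ", formatC(marginals$max_residual, format = "e",
                                       digits = 3)),
    "# columns: resi aa phi psi r1 r2 r3 r4 prob chi1 chi2 chi3 chi4 sig1 sig2 sig3 sig4")
  for (i in seq_along(graph$candidates)) {
    cand <- graph$candidates[[i]]
    p <- marginals$beliefs[[i]]
    if (length(p) != nrow(cand)) {
      stop("marginal length (", length(p), ") does not match candidate ",
           "list (", nrow(cand), ") for residue ", i)
    }
    p <- p / sum(p)
    ord <- order(-p)  # radix sort in R is stable: prior order kept on ties
    r <- bb$residues[[i]]
    for (k in ord) {
      lines <- c(lines, paste(
        r$resno, cand$aa[k],
        fmt_num(cand$phi[k]), fmt_num(cand$psi[k]),
        cand$r1[k], cand$r2[k], cand$r3[k], cand$r4[k],
        formatC(p[k], format = "f", digits = 8),
        fmt_num(cand$chi1[k]), fmt_num(cand$chi2[k]),
        fmt_num(cand$chi3[k]), fmt_num(cand$chi4[k]),
        fmt_num(cand$sig1[k]), fmt_num(cand$sig2[k]),
        fmt_num(cand$sig3[k]), fmt_num(cand$sig4[k])))
    }
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

fmt_num <- function(x) {
  ifelse(is.na(x), "0.0", formatC(x, format = "f", digits = 1))
}

#' Serialize a rotamer library back to Dunbrack-style text
#'
#' Emits the count-column dialect accepted by [parse_library()].
#'
#' @param lib a `rotamer_library`
#' @return character vector of lines
#' @export
format_library <- function(lib) {
  lines <- c("# backbone-dependent rotamer library",
             "# aa phi psi count r1 r2 r3 r4 prob chi1 chi2 chi3 chi4 sig1 sig2 sig3 sig4")
  for (key in sort(names(lib$bins))) {
    b <- lib$bins[[key]]
    for (r in seq_len(nrow(b))) {
      lines <- c(lines, paste(
        b$aa[r], b$phi[r], b$psi[r], 100,
        b$r1[r], b$r2[r], b$r3[r], b$r4[r],
        formatC(b$prob[r], format = "f", digits = 6),
        fmt_num(b$chi1[r]), fmt_num(b$chi2[r]), fmt_num(b$chi3[r]),
        fmt_num(b$chi4[r]),
        fmt_num(b$sig1[r]), fmt_num(b$sig2[r]), fmt_num(b$sig3[r]),
        fmt_num(b$sig4[r])))
    }
  }
  lines
}

#' Parse a protein-dependent rotamer library written by this package
#'
#' @param text output of [write_protein_library()] (string, lines, or path)
#' @return list with `residue_index` vector and `records` (list of
#'   data.frames per residue, in file order)
#' @export
parse_protein_library <- function(text) {
  if (length(text) == 1 && !grepl("\n", text, fixed = TRUE) &&
      file.exists(text)) {
    lines <- readLines(text)
  } else {
    lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  }
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("protein library contains no data rows")
  toks <- strsplit(lines, "[[:space:]]+")
  df <- do.call(rbind, lapply(toks, function(tk) {
    data.frame(resi = as.integer(tk[1]), aa = tk[2],
               phi = as.numeric(tk[3]), psi = as.numeric(tk[4]),
               r1 = as.numeric(tk[5]), r2 = as.numeric(tk[6]),
               r3 = as.numeric(tk[7]), r4 = as.numeric(tk[8]),
               prob = as.numeric(tk[9]),
               chi1 = as.numeric(tk[10]), chi2 = as.numeric(tk[11]),
               chi3 = as.numeric(tk[12]), chi4 = as.numeric(tk[13]),
               sig1 = as.numeric(tk[14]), sig2 = as.numeric(tk[15]),
               sig3 = as.numeric(tk[16]), sig4 = as.numeric(tk[17]),
               stringsAsFactors = FALSE)
  }))
  groups <- split(df, factor(df$resi, levels = unique(df$resi)))
  list(residue_index = as.integer(names(groups)),
       records = unname(groups))
}
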