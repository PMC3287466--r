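#' Is a predicted chi angle correct under the 40-degree criterion?
#'
#' A rotamer's chi mean is correct when its wrap-around angular distance to
#' the actual dihedral is strictly less than the cutoff (40 degrees by
#' convention). Symmetric in its two angle arguments.
#'
#' @param pred,true angles in degrees (vectorized)
#' @param cutoff degrees
#' @return logical vector
#' @export
chi_correct <- function(pred, true, cutoff = 40) {
  angular_distance(pred, true) < cutoff
}

# cumulative per-level correctness for one residue; NA above its chi count
chi_levels <- function(pred_chi, true_chi, aa, cutoff = 40,
                       fold_symmetric = FALSE) {
  nc <- n_chi(aa)
  out <- rep(NA, 4)
  if (nc == 0) return(out)
  ok_all <- TRUE
  for (k in seq_len(nc)) {
    p <- pred_chi[k]; t <- true_chi[k]
    if (is.na(p) || is.na(t)) {
      ok <- NA
    } else {
      ok <- chi_correct(p, t, cutoff)
      if (fold_symmetric && !ok && is_symmetric_chi(aa, k)) {
        ok <- chi_correct(wrap_angle(p + 180), t, cutoff)
      }
    }
    ok_all <- ok_all && ok
    out[k] <- ok_all
    if (is.na(ok_all)) {
      out[k:nc] <- NA
      break
    }
    if (!ok_all) {
      if (k < nc) out[(k + 1):nc] <- FALSE
      break
    }
  }
  out
}

# terminal chi angles with 180-degree chemical symmetry
is_symmetric_chi <- function(aa, k) {
  sym <- list(ASP = 2, GLU = 3, PHE = 2, TYR = 2)
  !is.null(sym[[toupper(aa)]]) && k == sym[[toupper(aa)]]
}

#' Per-amino-acid and overall chi accuracy table
#'
#' Cumulative correctness: chi_{1+2} requires both chi1 and chi2 correct,
#' and so on. ALA and GLY are excluded. Overall rows are residue-weighted
#' means.
#'
#' @param predictions list (per residue) of predicted chi vectors, degrees
#' @param truths list (per residue) of actual chi vectors, degrees
#' @param aas character vector of three-letter codes, one per residue
#' @param cutoff correctness cutoff, degrees
#' @param fold_symmetric also accept the 180-degree-flipped value for
#'   terminal symmetric chis (PHE/TYR chi2, ASP chi2, GLU chi3); off by
#'   default and reported in the result when on
#' @return data.frame with columns `aa`, `n`, `chi1`, `chi12`, `chi123`,
#'   `chi1234` (percentages; NA where no residue has that level), final
#'   row `Overall`
#' @export
accuracy_table <- function(predictions, truths, aas, cutoff = 40,
                           fold_symmetric = FALSE) {
  if (length(predictions) == 0) stop("empty prediction set")
  stopifnot(length(predictions) == length(truths),
            length(predictions) == length(aas))
  keep <- n_chi(aas) > 0
  if (!any(keep)) stop("no residues with chi angles to evaluate")
  lv <- t(vapply(which(keep), function(i) {
    chi_levels(predictions[[i]], truths[[i]], aas[i], cutoff,
               fold_symmetric)
  }, numeric(4)))
  aa_sub <- toupper(aas[keep])
  pct <- function(x) if (all(is.na(x))) NA_real_ else 100 * mean(x, na.rm = TRUE)
  per_aa <- do.call(rbind, lapply(sort(unique(aa_sub)), function(a) {
    rows <- lv[aa_sub == a, , drop = FALSE]
    data.frame(aa = a, n = nrow(rows),
               chi1 = pct(rows[, 1]), chi12 = pct(rows[, 2]),
               chi123 = pct(rows[, 3]), chi1234 = pct(rows[, 4]),
               stringsAsFactors = FALSE)
  }))
  overall <- data.frame(aa = "Overall", n = nrow(lv),
                        chi1 = pct(lv[, 1]), chi12 = pct(lv[, 2]),
                        chi123 = pct(lv[, 3]), chi1234 = pct(lv[, 4]),
                        stringsAsFactors = FALSE)
  out <- rbind(per_aa, overall)
  attr(out, "fold_symmetric") <- fold_symmetric
  out
}

# 1-based rank of the first record whose chi means are correct up to level,
# NA when none is
first_correct_rank <- function(records, true_chi, aa, level, cutoff = 40,
                               prob_col = "prob") {
  nc <- n_chi(aa)
  if (nc < level) return(NA_integer_)
  for (r in seq_len(nrow(records))) {
    ok <- TRUE
    for (k in seq_len(level)) {
      p <- records[[paste0("chi", k)]][r]
      if (is.na(p) || is.na(true_chi[k]) ||
          !chi_correct(p, true_chi[k], cutoff)) {
        ok <- FALSE
        break
      }
    }
    if (ok) return(r)
  }
  NA_integer_
}

#' Average rank of the first correct rotamer
#'
#' Mean over residues of the 1-based rank of the first list entry whose chi
#' means pass the cutoff at the requested cumulative level. Residues whose
#' list contains no correct rotamer (or that lack the level) are excluded
#' and counted separately. 1.0 is the ideal value.
#'
#' @param lib a `protein_library` (uses the re-ranked order) or a list of
#'   per-residue record data.frames sorted by the ranking to evaluate
#' @param truths list of actual chi vectors per residue
#' @param aas amino-acid codes per residue
#' @param level cumulative chi level (1 = chi1, 2 = chi1+2, ...)
#' @param cutoff degrees
#' @return list with `mean_rank`, `n_scored`, `n_excluded`
#' @export
average_first_correct_rank <- function(lib, truths, aas, level = 1,
                                       cutoff = 40) {
  records <- if (inherits(lib, "protein_library")) lib$residues else lib
  ranks <- vapply(seq_along(records), function(i) {
    first_correct_rank(records[[i]], truths[[i]], aas[i], level, cutoff)
  }, integer(1))
  eligible <- n_chi(aas) >= level
  scored <- eligible & !is.na(ranks)
  list(mean_rank = mean(ranks[scored]),
       n_scored = sum(scored),
       n_excluded = sum(eligible & is.na(ranks)))
}

#' Average probability mass on correct rotamers among the top k
#'
#' Per residue, sums the library probabilities of the correct rotamers
#' among the first `k` entries, then averages over residues (residues with
#' no correct rotamer in the whole list contribute 0). Non-decreasing in
#' `k`.
#'
#' @inheritParams average_first_correct_rank
#' @param k number of top entries considered
#' @param prob_col which probability column to use (`"prob_updated"` for a
#'   re-ranked library, `"prob"` for a prior library view)
#' @return list with `mean_probability` and `n_scored`
#' @export
topk_correct_probability <- function(lib, truths, aas, k = 1, level = 1,
                                     cutoff = 40,
                                     prob_col = c("prob_updated", "prob")) {
  records <- if (inherits(lib, "protein_library")) lib$residues else lib
  prob_col <- match.arg(prob_col)
  eligible <- which(n_chi(aas) >= level)
  vals <- vapply(eligible, function(i) {
    df <- records[[i]]
    pc <- if (prob_col %in% names(df)) prob_col else "prob"
    top <- df[seq_len(min(k, nrow(df))), , drop = FALSE]
    s <- 0
    for (r in seq_len(nrow(top))) {
      ok <- TRUE
      for (kk in seq_len(level)) {
        p <- top[[paste0("chi", kk)]][r]
        if (is.na(p) || is.na(truths[[i]][kk]) ||
            !chi_correct(p, truths[[i]][kk], cutoff)) {
          ok <- FALSE
          break
        }
      }
      if (ok) s <- s + top[[pc]][r]
    }
    s
  }, numeric(1))
  list(mean_probability = mean(vals), n_scored = length(eligible))
}
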