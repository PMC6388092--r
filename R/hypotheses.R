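# Ranking competing structural interpretations of a bound ligand
# (conformers, tautomers, heteroatom placements, stereoisomers, protonation
# states, presence/absence of cofactor) from their bound-state and, where
# available, free-state energies. Only energy differences matter: inputs
# may be absolute energies or gaps relative to any zero.

#' Construct a hypothesis set
#'
#' A set of competing structural hypotheses for one ligand, each with a
#' bound-state energy and optionally a free-state energy (some comparisons
#' are bound-state only).
#'
#' @param ligand_id Ligand label.
#' @param hypothesis Character vector of hypothesis labels (unique).
#' @param bound_energy Bound-state (complex) energies, kcal/mol.
#' @param free_energy Free-ligand energies, kcal/mol; `NA` where not
#'   computed.
#' @return An object of class `hypothesis_set`.
#' @examples
#' hypothesisSet("compound-1", c("chair", "boat"), c(0, 10), c(0, 9))
#' @export
hypothesisSet <- function(ligand_id, hypothesis, bound_energy,
                          free_energy = rep(NA_real_, length(hypothesis))) {
  hypothesis <- as.character(hypothesis)
  if (length(hypothesis) < 2L) {
    stopSchema("a hypothesis set needs at least 2 entries, got ",
               length(hypothesis))
  }
  if (anyDuplicated(hypothesis)) {
    stopSchema("duplicate hypothesis label(s): ",
               paste(unique(hypothesis[duplicated(hypothesis)]), collapse = ", "))
  }
  if (length(bound_energy) != length(hypothesis) ||
      length(free_energy) != length(hypothesis)) {
    stopSchema("hypothesis, bound_energy and free_energy lengths differ")
  }
  checkFinite(bound_energy, "bound_energy")
  if (any(!is.na(free_energy) & !is.finite(free_energy))) {
    stopSchema("free_energy values must be finite or NA")
  }
  out <- list(ligand_id = as.character(ligand_id)[1L],
              entries = data.frame(hypothesis = hypothesis,
                                   bound_energy = as.numeric(bound_energy),
                                   free_energy = as.numeric(free_energy),
                                   stringsAsFactors = FALSE))
  class(out) <- "hypothesis_set"
  out
}

#' Read hypothesis sets from CSV
#'
#' Reads a long-format CSV with header
#' `ligand_id,hypothesis,state,energy,unit` (`state` is `bound` or `free`;
#' `unit` optional, default kcal/mol) and builds one [hypothesisSet()] per
#' ligand. Every hypothesis must have a bound-state energy.
#'
#' @param path CSV file path.
#' @return A named list of `hypothesis_set` objects.
#' @export
readHypothesisTable <- function(path) {
  if (!file.exists(path)) stopIo("hypothesis table not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  required <- c("ligand_id", "hypothesis", "state", "energy")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stopSchema("hypothesis table ", path, " is missing column(s): ",
               paste(missing_cols, collapse = ", "))
  }
  if (!"unit" %in% names(df)) df$unit <- "kcal_per_mol"
  if (nrow(df) == 0L) stopSchema("no records in hypothesis table ", path)
  bad_state <- setdiff(unique(df$state), c("bound", "free"))
  if (length(bad_state) > 0L) {
    stopSchema("unknown state value(s) in hypothesis table: ",
               paste(bad_state, collapse = ", "), " (expected bound/free)")
  }
  df$energy <- vapply(seq_len(nrow(df)),
                      function(i) convertEnergy(as.numeric(df$energy[i]), df$unit[i]),
                      numeric(1))
  sets <- lapply(split(df, df$ligand_id), function(g) {
    hyps <- unique(g$hypothesis)
    bound <- vapply(hyps, function(h) {
      rows <- g[g$hypothesis == h & g$state == "bound", , drop = FALSE]
      if (nrow(rows) == 0L) {
        stopSchema("hypothesis '", h, "' of ligand '", g$ligand_id[1L],
                   "' has no bound-state energy")
      }
      if (nrow(rows) > 1L) {
        stopSchema("hypothesis '", h, "' of ligand '", g$ligand_id[1L],
                   "' has multiple bound-state rows")
      }
      rows$energy
    }, numeric(1))
    free <- vapply(hyps, function(h) {
      rows <- g[g$hypothesis == h & g$state == "free", , drop = FALSE]
      if (nrow(rows) > 1L) {
        stopSchema("hypothesis '", h, "' of ligand '", g$ligand_id[1L],
                   "' has multiple free-state rows")
      }
      if (nrow(rows) == 0L) NA_real_ else rows$energy
    }, numeric(1))
    hypothesisSet(g$ligand_id[1L], hyps, bound, free)
  })
  sets
}

#' Rank competing structural hypotheses
#'
#' The preferred hypothesis is the one with the lowest bound-state energy
#' (ties broken lexicographically by label). The bound-state margin is the
#' runner-up energy minus the best; the free-state margin is the analogous
#' gap among free-state energies (absent unless at least two hypotheses
#' have them). A bound margin below `threshold` yields the verdict
#' `indistinguishable`: the energies cannot discriminate the
#' interpretations.
#'
#' @param hset A [hypothesisSet()].
#' @param threshold Decisiveness threshold in kcal/mol (default 1.0, which
#'   separates sub-kcal gaps that do not discriminate from the multi-kcal
#'   gaps that do).
#' @return An object of class `preference_report`: `ligand_id`,
#'   `preferred`, `bound_margin`, `free_margin` (`NA` when absent),
#'   `verdict` (`"decisive"` or `"indistinguishable"`), `threshold`, and a
#'   per-pair margin table `pairs`.
#' @examples
#' h <- hypothesisSet("compound-1", c("chair", "boat"), c(0, 10), c(0, 9))
#' rankHypotheses(h)
#' @export
rankHypotheses <- function(hset, threshold = 1.0) {
  if (!inherits(hset, "hypothesis_set")) {
    stopSchema("hset must be created with hypothesisSet()")
  }
  checkScalar(threshold, "threshold")
  if (threshold < 0) stopSchema("threshold must be >= 0, got ", threshold)
  e <- hset$entries
  ord <- order(e$bound_energy, e$hypothesis)
  e <- e[ord, , drop = FALSE]
  bound_margin <- e$bound_energy[2L] - e$bound_energy[1L]
  free <- e$free_energy[!is.na(e$free_energy)]
  free_margin <- if (length(free) >= 2L) {
    sf <- sort(free)
    sf[2L] - sf[1L]
  } else {
    NA_real_
  }
  pairs <- do.call(rbind, lapply(seq_len(nrow(e) - 1L), function(i) {
    do.call(rbind, lapply(seq(i + 1L, nrow(e)), function(j) {
      data.frame(hypothesis_a = e$hypothesis[i], hypothesis_b = e$hypothesis[j],
                 bound_diff = e$bound_energy[j] - e$bound_energy[i],
                 free_diff = e$free_energy[j] - e$free_energy[i],
                 stringsAsFactors = FALSE)
    }))
  }))
  out <- list(
    ligand_id = hset$ligand_id,
    preferred = e$hypothesis[1L],
    bound_margin = bound_margin,
    free_margin = free_margin,
    verdict = if (bound_margin < threshold) "indistinguishable" else "decisive",
    threshold = threshold,
    pairs = pairs,
    entries = e
  )
  class(out) <- "preference_report"
  out
}

#' @export
print.preference_report <- function(x, ...) {
  cat(sprintf("Hypothesis ranking for %s (threshold %.2f kcal/mol)\n",
              x$ligand_id, x$threshold))
  cat(sprintf("  preferred: %s [%s]\n", x$preferred, x$verdict))
  cat(sprintf("  bound-state margin: %.2f kcal/mol\n", x$bound_margin))
  if (!is.na(x$free_margin)) {
    cat(sprintf("  free-state margin:  %.2f kcal/mol\n", x$free_margin))
  }
  print(x$entries, row.names = FALSE)
  invisible(x)
}

#' Conformer-focusing penalty
#'
#' The free-state energy the ligand must pay to adopt its bound (bioactive)
#' form: the free-state energy of the bound-preferred hypothesis minus the
#' lowest free-state energy in the set. Zero when the bioactive form is
#' also the free-state minimum; always non-negative.
#'
#' @param hset A [hypothesisSet()]; the bound-preferred hypothesis must
#'   have a free-state energy and at least two hypotheses must have one.
#' @return Penalty in kcal/mol.
#' @examples
#' h <- hypothesisSet("compound-3", c("axial", "equatorial"), c(0, 4), c(0.6, 0))
#' conformerFocusing(h) # 0.6
#' @export
conformerFocusing <- function(hset) {
  if (!inherits(hset, "hypothesis_set")) {
    stopSchema("hset must be created with hypothesisSet()")
  }
  e <- hset$entries
  if (sum(!is.na(e$free_energy)) < 2L) {
    stopSchema("conformer focusing needs free-state energies for at least ",
               "2 hypotheses of ligand '", hset$ligand_id, "'")
  }
  ord <- order(e$bound_energy, e$hypothesis)
  preferred <- e[ord[1L], , drop = FALSE]
  if (is.na(preferred$free_energy)) {
    stopSchema("bound-preferred hypothesis '", preferred$hypothesis,
               "' of ligand '", hset$ligand_id, "' has no free-state energy")
  }
  preferred$free_energy - min(e$free_energy, na.rm = TRUE)
}
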