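# Harvest final SCF electronic energies from plain-text quantum-chemistry
# output. The recognised dialect is a line containing "SCF Done:" followed
# by "=" and a real number (in Hartree); the last such line in a file wins,
# matching the convention that the final SCF of an optimisation is the
# energy of the converged geometry.

#' Harvest final SCF energies from text output files
#'
#' Scans each file for lines matching `SCF Done: ... = <number>`, takes the
#' last match per file as the final electronic energy (Hartree), and
#' converts it to kcal/mol. Files without any match are reported together in
#' one error naming each offending file.
#'
#' @param paths Character vector of file paths.
#' @return A data frame with columns `file`, `energy_hartree`,
#'   `energy_kcal`.
#' @export
harvestScfEnergies <- function(paths) {
  if (length(paths) == 0L) stopIo("no files to harvest")
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    stopIo("file(s) not found: ", paste(missing, collapse = ", "))
  }
  pattern <- "SCF Done:.*=\\s*(-?[0-9]+\\.?[0-9]*([eEdD][+-]?[0-9]+)?)"
  one <- function(path) {
    lines <- readLines(path, warn = FALSE)
    hits <- regmatches(lines, regexec(pattern, lines))
    vals <- vapply(hits, function(m) if (length(m) >= 2L) m[2L] else NA_character_,
                   character(1))
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0L) return(NA_real_)
    # Fortran-style exponents (1.0D-02) occur in some outputs
    as.numeric(gsub("[dD]", "e", vals[length(vals)]))
  }
  hartree <- vapply(paths, one, numeric(1))
  failed <- paths[is.na(hartree)]
  if (length(failed) > 0L) {
    stopSchema("no 'SCF Done:' energy found in: ", paste(failed, collapse = ", "))
  }
  data.frame(
    file = unname(paths),
    energy_hartree = unname(hartree),
    energy_kcal = unname(convertEnergy(hartree, "hartree")),
    stringsAsFactors = FALSE
  )
}
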