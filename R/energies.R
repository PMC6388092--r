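# Complexation energies: unit conversion, the Delta-E difference, and
# aggregation of conformer ensembles (lowest-energy or Boltzmann).

# Gas constant in kcal/(mol K); CODATA-consistent.
GAS_CONSTANT_KCAL <- 1.98720425864083e-3

# 1 Hartree in kcal/mol, 7 significant figures.
HARTREE_TO_KCAL <- 627.5095

#' Energy units
#'
#' Supported energy units and their conversion factors to kcal/mol. All
#' energies inside the package are kcal/mol; conversion happens once at
#' ingestion.
#'
#' @param name Unit name: `"kcal_per_mol"` (alias `"kcal/mol"`) or
#'   `"hartree"`.
#' @return A list with elements `name` and `to_kcal_factor`.
#' @examples
#' energyUnit("hartree")$to_kcal_factor # 627.5095
#' @export
energyUnit <- function(name) {
  key <- switch(tolower(as.character(name)[1L]),
    "kcal_per_mol" = ,
    "kcal/mol" = ,
    "kcal" = "kcal_per_mol",
    "hartree" = ,
    "au" = "hartree",
    stopSchema("unknown energy unit: '", name, "' (expected kcal_per_mol or hartree)")
  )
  factor <- c(kcal_per_mol = 1.0, hartree = HARTREE_TO_KCAL)[[key]]
  list(name = key, to_kcal_factor = factor)
}

#' Convert an energy to kcal/mol
#'
#' @param value Numeric energy value(s); must be finite.
#' @param from_unit Unit name or the result of [energyUnit()].
#' @return The value(s) in kcal/mol.
#' @examples
#' convertEnergy(1.0, "hartree") # 627.5095
#' @export
convertEnergy <- function(value, from_unit) {
  checkFinite(value, "energy value")
  unit <- if (is.list(from_unit)) from_unit else energyUnit(from_unit)
  value * unit$to_kcal_factor
}

#' Complexation energy
#'
#' The gas-phase electronic complexation energy
#' \eqn{\Delta E = E_{complex} - E_{ligand} - E_{receptor}}, in kcal/mol.
#' Negative values mean binding is electronically favourable. The receptor
#' energy zero is arbitrary (it is shared by all ligands of a system) but it
#' shifts the calibrated \eqn{\alpha} and \eqn{\gamma}, so one receptor
#' energy must be used consistently within a calibration set.
#'
#' @param e_complex,e_ligand,e_receptor Electronic energies in kcal/mol.
#' @return \eqn{\Delta E} in kcal/mol. Vectorised over the first two
#'   arguments.
#' @examples
#' deltaEnergy(-120.3, -60.0, -42.6) # -17.7
#' @export
deltaEnergy <- function(e_complex, e_ligand, e_receptor) {
  for (nm in c("e_complex", "e_ligand", "e_receptor")) {
    v <- get(nm)
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v))) {
      stopSchema("non-finite ", nm, " in complexation energy")
    }
  }
  e_complex - e_ligand - e_receptor
}

#' Boltzmann ensemble energy of a conformer set
#'
#' Combines conformer electronic energies into the ensemble free energy
#' \eqn{-RT \ln \sum_i e^{-E_i/RT}} with
#' \eqn{R = 1.98720425864083 \times 10^{-3}} kcal/(mol K). The sum is
#' computed after shifting by \eqn{\min E_i}, so arbitrarily large energy
#' spreads cannot overflow. The result never exceeds the lowest conformer
#' energy; it reduces to it for a single conformer and in the
#' large-gap or \eqn{T \to 0} limits.
#'
#' @param energies Numeric vector of conformer energies, kcal/mol.
#' @param temperature Absolute temperature in K, default 298.15.
#' @return Ensemble energy in kcal/mol.
#' @examples
#' boltzmannEnergy(c(0, 0))  # -RT log 2, about -0.4106
#' boltzmannEnergy(-17.7)    # single conformer: -17.7
#' @export
boltzmannEnergy <- function(energies, temperature = 298.15) {
  if (length(energies) == 0L) stopSchema("empty conformer energy list")
  checkFinite(energies, "conformer energies")
  checkScalar(temperature, "temperature")
  if (temperature <= 0) stopSchema("temperature must be > 0 K, got ", temperature)
  rt <- GAS_CONSTANT_KCAL * temperature
  e_min <- min(energies)
  e_min - rt * log(sum(exp(-(energies - e_min) / rt)))
}

#' Read an energy table
#'
#' Reads a CSV of electronic energies with required header
#' `species_id,state,hypothesis,conformer_id,energy,unit` (`unit` may be
#' omitted, defaulting to kcal/mol). Energies are converted to kcal/mol at
#' ingestion. `state` must be one of `complex`, `free_ligand`, `receptor`.
#' Unknown columns are ignored with a warning; duplicate
#' (species, state, hypothesis, conformer) keys are rejected.
#'
#' @param path Path to the CSV file.
#' @return A data frame of energy records (energies in kcal/mol) with a
#'   `source` column recording file and row provenance.
#' @export
readEnergyTable <- function(path) {
  if (!file.exists(path)) stopIo("energy table not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  required <- c("species_id", "state", "hypothesis", "conformer_id", "energy")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stopSchema("energy table ", path, " is missing column(s): ",
               paste(missing_cols, collapse = ", "))
  }
  if (!"unit" %in% names(df)) df$unit <- "kcal_per_mol"
  extra <- setdiff(names(df), c(required, "unit"))
  if (length(extra) > 0L) {
    warning("ignoring unknown energy-table column(s): ", paste(extra, collapse = ", "))
  }
  if (nrow(df) == 0L) stopSchema("energy table ", path, " has no records")
  bad_state <- setdiff(unique(df$state), c("complex", "free_ligand", "receptor"))
  if (length(bad_state) > 0L) {
    stopSchema("unknown state value(s): ", paste(bad_state, collapse = ", "))
  }
  energy <- suppressWarnings(as.numeric(df$energy))
  if (anyNA(energy) || any(!is.finite(energy))) {
    bad <- which(is.na(energy) | !is.finite(energy))
    stopSchema("non-finite energy in row(s): ", paste(bad, collapse = ", "))
  }
  out <- data.frame(
    species_id = as.character(df$species_id),
    state = as.character(df$state),
    hypothesis = as.character(df$hypothesis),
    conformer_id = as.character(df$conformer_id),
    energy = vapply(seq_len(nrow(df)),
                    function(i) convertEnergy(energy[i], df$unit[i]),
                    numeric(1)),
    source = sprintf("%s:%d", basename(path), seq_len(nrow(df))),
    stringsAsFactors = FALSE
  )
  key <- with(out, paste(species_id, state, hypothesis, conformer_id, sep = "\r"))
  if (anyDuplicated(key)) {
    dup <- out[duplicated(key), , drop = FALSE]
    stopSchema("duplicate energy record key(s): ",
               paste(sprintf("(%s, %s, %s, %s)", dup$species_id, dup$state,
                             dup$hypothesis, dup$conformer_id), collapse = "; "))
  }
  out
}

#' Assemble a complexation energy from conformer-level records
#'
#' Aggregates the conformer energies of the bound complex and the free
#' ligand for one species (lowest energy by default, Boltzmann ensemble
#' energy on request), then forms
#' \eqn{\Delta E = E_{complex} - E_{ligand} - E_{receptor}}. The receptor
#' energy is a dataset-level constant: exactly one `receptor` record must be
#' present in `records`. Aggregation never mixes hypothesis labels
#' (conformers of different tautomers/placements are distinct species
#' interpretations); when a species carries several hypotheses, name the one
#' to assemble.
#'
#' @param records Energy-record data frame as returned by
#'   [readEnergyTable()] (columns `species_id`, `state`, `hypothesis`,
#'   `conformer_id`, `energy` in kcal/mol).
#' @param species_id Species to assemble.
#' @param temperature Temperature in K for Boltzmann aggregation.
#' @param aggregate `"minimum"` (default) or `"boltzmann"`.
#' @param hypothesis Optional hypothesis label; required when the species
#'   has more than one.
#' @return \eqn{\Delta E} in kcal/mol.
#' @export
assembleDeltaE <- function(records, species_id, temperature = 298.15,
                           aggregate = c("minimum", "boltzmann"),
                           hypothesis = NULL) {
  aggregate <- match.arg(aggregate)
  needed <- c("species_id", "state", "hypothesis", "energy")
  if (!is.data.frame(records) || !all(needed %in% names(records))) {
    stopSchema("records must be a data frame with columns: ",
               paste(needed, collapse = ", "))
  }
  receptor <- records[records$state == "receptor", , drop = FALSE]
  if (nrow(receptor) == 0L) {
    stopSchema("missing receptor energy record (state = receptor)")
  }
  if (nrow(receptor) > 1L) {
    stopSchema("ambiguous receptor energy: ", nrow(receptor),
               " receptor records present, expected exactly one")
  }
  sp <- records[records$species_id == species_id & records$state != "receptor", ,
                drop = FALSE]
  if (!is.null(hypothesis)) sp <- sp[sp$hypothesis == hypothesis, , drop = FALSE]
  aggState <- function(state) {
    rows <- sp[sp$state == state, , drop = FALSE]
    if (nrow(rows) == 0L) {
      stopSchema("species '", species_id, "' has no ", state, " energy record",
                 if (!is.null(hypothesis)) paste0(" for hypothesis '", hypothesis, "'"))
    }
    hyps <- unique(rows$hypothesis)
    if (length(hyps) > 1L) {
      stopSchema("species '", species_id, "' has multiple hypotheses for state ",
                 state, " (", paste(hyps, collapse = ", "),
                 "); pass `hypothesis` to select one")
    }
    switch(aggregate,
      minimum = min(rows$energy),
      boltzmann = boltzmannEnergy(rows$energy, temperature)
    )
  }
  deltaEnergy(aggState("complex"), aggState("free_ligand"), receptor$energy)
}
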