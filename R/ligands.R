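# Ligand calibration tables: one row per affinity measurement, with the
# ligand's complexation energy and calculated log P repeated per row.

LIGAND_COLUMNS <- c("ligand_id", "delta_e", "log_p", "kind", "p_value",
                    "censored", "assay")

# Validate the in-memory ligand-table contract shared by the fitting code.
validateLigandTable <- function(records) {
  if (!is.data.frame(records)) stopSchema("ligand records must be a data frame")
  missing_cols <- setdiff(LIGAND_COLUMNS, names(records))
  if (length(missing_cols) > 0L) {
    stopSchema("ligand table is missing column(s): ",
               paste(missing_cols, collapse = ", "))
  }
  if (nrow(records) == 0L) stopSchema("no records in ligand table")
  checkFinite(records$delta_e, "delta_e")
  checkFinite(records$log_p, "log_p")
  checkFinite(records$p_value, "p_value")
  # delta_e / log_p are per-ligand properties: conflicting duplicates are
  # rejected rather than averaged, forcing explicit upstream resolution.
  by_lig <- split(records, records$ligand_id)
  for (lig in names(by_lig)) {
    g <- by_lig[[lig]]
    if (length(unique(g$delta_e)) > 1L || length(unique(g$log_p)) > 1L) {
      stopSchema("ligand '", lig, "' has conflicting delta_e or log_p values ",
                 "across rows; resolve duplicates upstream")
    }
    key <- paste(g$kind, g$p_value, g$censored, g$assay, sep = "\r")
    if (anyDuplicated(key)) {
      stopSchema("ligand '", lig, "' has duplicate measurement rows")
    }
  }
  invisible(records)
}

#' Read a ligand calibration table
#'
#' Reads a CSV with header
#' `ligand_id,delta_e,log_p,affinity_value,affinity_unit,affinity_kind,censored,assay`.
#' Repeated rows per ligand carry multiple measurements. `affinity_unit` is
#' a concentration unit (`M`, `mM`, `uM`, `nM`), in which case the value is
#' transformed to the p-scale at ingestion, or `p` when the value is already
#' a p-affinity. A leading `<` on `affinity_value` (e.g. `"<3.3"` on the p
#' scale) marks the measurement as an upper bound on potency, as does a
#' truthy `censored` column. Unknown columns are ignored with a warning.
#'
#' @param path CSV file path.
#' @return A ligand-table data frame with columns `ligand_id`, `delta_e`,
#'   `log_p`, `kind`, `p_value`, `censored`, `assay`.
#' @export
readLigandTable <- function(path) {
  if (!file.exists(path)) stopIo("ligand table not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE,
                 colClasses = "character")
  required <- c("ligand_id", "delta_e", "log_p", "affinity_value",
                "affinity_unit", "affinity_kind")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stopSchema("ligand table ", path, " is missing column(s): ",
               paste(missing_cols, collapse = ", "))
  }
  optional <- c("censored", "assay")
  extra <- setdiff(names(df), c(required, optional))
  if (length(extra) > 0L) {
    warning("ignoring unknown ligand-table column(s): ", paste(extra, collapse = ", "))
  }
  if (nrow(df) == 0L) stopSchema("no records in ligand table ", path)
  if (!"censored" %in% names(df)) df$censored <- "FALSE"
  if (!"assay" %in% names(df)) df$assay <- NA_character_

  raw_value <- trimws(df$affinity_value)
  lt <- startsWith(raw_value, "<")
  raw_value[lt] <- sub("^<\\s*", "", raw_value[lt])
  value <- suppressWarnings(as.numeric(raw_value))
  if (anyNA(value)) {
    stopSchema("non-numeric affinity_value in row(s): ",
               paste(which(is.na(value)), collapse = ", "))
  }
  censored <- lt | tolower(trimws(df$censored)) %in%
    c("true", "t", "1", "yes", "upper_bound")

  rows <- lapply(seq_len(nrow(df)), function(i) {
    unit <- trimws(df$affinity_unit[i])
    if (identical(tolower(unit), "p")) {
      kind <- df$affinity_kind[i]
      if (!kind %in% AFFINITY_KINDS) {
        stopSchema("unknown affinity_kind '", kind, "' in row ", i)
      }
      m <- data.frame(kind = kind, p_value = value[i], censored = censored[i],
                      assay = df$assay[i], stringsAsFactors = FALSE)
    } else {
      m <- toPAffinity(value[i], unit, df$affinity_kind[i],
                       censored = censored[i], assay = df$assay[i])
    }
    cbind(
      data.frame(ligand_id = df$ligand_id[i],
                 delta_e = as.numeric(df$delta_e[i]),
                 log_p = as.numeric(df$log_p[i]),
                 stringsAsFactors = FALSE),
      m
    )
  })
  out <- do.call(rbind, rows)
  validateLigandTable(out)
  out
}

#' Write a ligand table in the calibration CSV schema
#'
#' Writes measurements on the p-scale (`affinity_unit = "p"`) with full
#' numeric precision, so a table round-trips losslessly through
#' [readLigandTable()].
#'
#' @param records Ligand-table data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeLigandTable <- function(records, path) {
  validateLigandTable(records)
  fmt <- function(x) sprintf("%.17g", x)
  out <- data.frame(
    ligand_id = records$ligand_id,
    delta_e = fmt(records$delta_e),
    log_p = fmt(records$log_p),
    affinity_value = fmt(records$p_value),
    affinity_unit = "p",
    affinity_kind = records$kind,
    censored = ifelse(records$censored, "upper_bound", "none"),
    assay = ifelse(is.na(records$assay), "", records$assay),
    stringsAsFactors = FALSE
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The packaged LDHA calibration dataset
#'
#' Eleven inhibitors of human lactate dehydrogenase A with enzymatic pIC50,
#' SPR and NMR pKd where measured, ChemAxon-calculated log P, and
#' theoceptor complexation energies (kcal/mol). Censored pIC50 entries
#' (`"<3.3"`, `"<2.7"`) are carried as upper bounds. The packaged file
#' `extdata/ldha_table2.csv` transcribes the published measurements
#' verbatim.
#'
#' @return A ligand-table data frame (one row per measurement).
#' @examples
#' fit <- fitTheoceptor(ldhaLigands(), ldhaPolicy())
#' @export
ldhaLigands <- function() {
  path <- system.file("extdata", "ldha_table2.csv", package = "theoceptor",
                      mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE,
                 colClasses = "character")
  rows <- list()
  for (i in seq_len(nrow(df))) {
    id <- df$compound[i]
    base <- data.frame(ligand_id = id, delta_e = as.numeric(df$delta_e[i]),
                       log_p = as.numeric(df$clogp[i]), stringsAsFactors = FALSE)
    addMeasurement <- function(raw, kind, assay) {
      raw <- trimws(raw)
      if (!nzchar(raw) || raw == "NC") return(NULL)
      lt <- startsWith(raw, "<")
      if (lt) raw <- sub("^<", "", raw)
      cbind(base, data.frame(kind = kind, p_value = as.numeric(raw),
                             censored = lt, assay = assay,
                             stringsAsFactors = FALSE))
    }
    rows <- c(rows, list(
      addMeasurement(df$pic50[i], "IC50", "enzymatic"),
      addMeasurement(df$pkd_spr[i], "Kd", "SPR"),
      addMeasurement(df$pkd_nmr[i], "Kd", "NMR")
    ))
  }
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  rownames(out) <- NULL
  validateLigandTable(out)
  out
}
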