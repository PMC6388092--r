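# Affinity measurements on the p-scale, and policies for choosing one
# measurement per ligand when assays disagree or are censored.

AFFINITY_KINDS <- c("IC50", "Ki", "Kd")

# Concentration units in molar
CONC_UNITS <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9)

#' Transform a measured affinity to the p-scale
#'
#' Converts an IC50/Ki/Kd concentration to pIC50/pKi/pKd, i.e.
#' \eqn{-\log_{10}} of the molar value, so that improved affinity
#' corresponds to larger values and the quantity is linear in binding free
#' energy.
#'
#' @param value Positive concentration(s).
#' @param unit Concentration unit: `"M"`, `"mM"`, `"uM"`, or `"nM"`.
#' @param kind Measurement kind: `"IC50"`, `"Ki"`, or `"Kd"`.
#' @param censored `TRUE` when the measurement is an upper bound on potency
#'   (a "less-than" affinity such as IC50 > some concentration reported as
#'   p-value "<3.3"); the true p-value is then at most the recorded one.
#' @param assay Optional assay label (e.g. `"SPR"`, `"NMR"`, `"enzymatic"`).
#' @return A one-row data frame with columns `kind`, `p_value`, `censored`,
#'   `assay`.
#' @examples
#' toPAffinity(1.0, "uM", "IC50")$p_value # 6
#' @export
toPAffinity <- function(value, unit, kind, censored = FALSE, assay = NA_character_) {
  checkScalar(value, "affinity value")
  if (value <= 0) stopSchema("affinity value must be > 0 (got ", value, ")")
  if (!unit %in% names(CONC_UNITS)) {
    stopSchema("unknown concentration unit: '", unit, "' (expected ",
               paste(names(CONC_UNITS), collapse = ", "), ")")
  }
  kind <- match.arg(kind, AFFINITY_KINDS)
  data.frame(
    kind = kind,
    p_value = -log10(value * CONC_UNITS[[unit]]),
    censored = isTRUE(censored),
    assay = as.character(assay),
    stringsAsFactors = FALSE
  )
}

#' Affinity selection policy
#'
#' An ordered preference list of (kind, assay) pairs used to pick one
#' p-affinity per ligand. `assay = NA` matches any assay.
#'
#' @param kind Character vector of measurement kinds, in preference order.
#' @param assay Character vector of assay labels (recycled); `NA` matches
#'   any assay.
#' @return A data frame of class `affinity_policy`.
#' @examples
#' affinityPolicy(c("IC50", "Kd"), c(NA, "SPR"))
#' @export
affinityPolicy <- function(kind, assay = NA_character_) {
  if (length(kind) == 0L) stopSchema("empty affinity policy")
  bad <- setdiff(kind, AFFINITY_KINDS)
  if (length(bad) > 0L) {
    stopSchema("unknown affinity kind(s) in policy: ", paste(bad, collapse = ", "))
  }
  pol <- data.frame(kind = kind, assay = rep_len(as.character(assay), length(kind)),
                    stringsAsFactors = FALSE)
  class(pol) <- c("affinity_policy", "data.frame")
  pol
}

#' Policy used for the packaged LDHA calibration set
#'
#' Enzymatic pIC50 first; where only censored pIC50 values exist (the weak
#' malonate-derived binders), fall back to the SPR pKd.
#'
#' @return An [affinityPolicy()].
#' @export
ldhaPolicy <- function() affinityPolicy(c("IC50", "Kd"), c(NA, "SPR"))

# Parse "IC50;Kd/SPR" style policy strings (CLI surface).
parsePolicyString <- function(spec) {
  parts <- trimws(strsplit(spec, "[;,]")[[1L]])
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0L) stopSchema("empty policy specification: '", spec, "'")
  kind <- character(0)
  assay <- character(0)
  for (p in parts) {
    bits <- strsplit(p, "/", fixed = TRUE)[[1L]]
    kind <- c(kind, bits[1L])
    assay <- c(assay, if (length(bits) > 1L) bits[2L] else NA_character_)
  }
  affinityPolicy(kind, assay)
}

#' Select one p-affinity per ligand under a policy
#'
#' Walks the policy in order and returns the first *uncensored* measurement
#' whose kind (and assay, when the policy names one) matches. When only
#' censored measurements match, the ligand is excluded (`NA`) by default;
#' with `censored_as_value = TRUE` the censoring bound itself is used and
#' flagged.
#'
#' @param measurements Data frame of measurements for one ligand, with
#'   columns `kind`, `p_value`, `censored`, `assay`.
#' @param policy An [affinityPolicy()].
#' @param censored_as_value Use the bound of a censored measurement when no
#'   uncensored one matches.
#' @return A one-row data frame `p_affinity`, `kind`, `assay`,
#'   `censored_used`; `p_affinity` is `NA` when the ligand is excluded.
#' @examples
#' m <- data.frame(kind = c("IC50", "Kd"), p_value = c(3.3, 3.67),
#'                 censored = c(TRUE, FALSE), assay = c(NA, "SPR"))
#' selectAffinity(m, ldhaPolicy())$p_affinity # 3.67
#' @export
selectAffinity <- function(measurements, policy, censored_as_value = FALSE) {
  if (!inherits(policy, "affinity_policy")) {
    stopSchema("policy must be created with affinityPolicy()")
  }
  if (nrow(measurements) == 0L) stopSchema("ligand has no affinity measurements")
  none <- data.frame(p_affinity = NA_real_, kind = NA_character_,
                     assay = NA_character_, censored_used = FALSE,
                     stringsAsFactors = FALSE)
  pick <- function(censored_ok) {
    for (i in seq_len(nrow(policy))) {
      hit <- measurements$kind == policy$kind[i]
      if (!is.na(policy$assay[i])) {
        hit <- hit & !is.na(measurements$assay) & measurements$assay == policy$assay[i]
      }
      hit <- hit & (measurements$censored == censored_ok)
      if (any(hit)) {
        row <- measurements[which(hit)[1L], , drop = FALSE]
        return(data.frame(p_affinity = row$p_value, kind = row$kind,
                          assay = row$assay, censored_used = censored_ok,
                          stringsAsFactors = FALSE))
      }
    }
    NULL
  }
  pick(FALSE) %||% (if (censored_as_value) pick(TRUE) else NULL) %||% none
}
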