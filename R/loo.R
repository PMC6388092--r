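# Leave-one-out stability of the calibrated coefficients.

#' Leave-one-out coefficient stability
#'
#' Refits the affinity relation n times, omitting each ligand in turn, and
#' summarises each coefficient by its mean and population standard
#' deviation across the refits. The SD measures how much a single ligand
#' can move a coefficient: zero when the data lie exactly on a plane,
#' shrinking as the calibration set grows.
#'
#' At least 5 usable ligands are required so every refit keeps at least 4
#' points for a stable 3-coefficient fit.
#'
#' @inheritParams fitTheoceptor
#' @return An object of class `theoceptor_loo`: list with `coef_mean`,
#'   `coef_sd` (named alpha/beta/gamma), `n_refits`, and the per-refit
#'   coefficient matrix `coefficients` (rows named by the omitted ligand).
#' @examples
#' looAnalysis(ldhaLigands(), ldhaPolicy())
#' @export
looAnalysis <- function(records,
                        policy = affinityPolicy(c("IC50", "Ki", "Kd")),
                        censored_as_value = FALSE) {
  rows <- selectCalibrationRows(records, policy, censored_as_value)
  data <- rows[!is.na(rows$p_affinity), , drop = FALSE]
  n <- nrow(data)
  if (n < 5L) {
    stopStat("leave-one-out needs at least 5 ligands so each refit keeps ",
             ">= 4 points for a 3-coefficient fit; got ", n)
  }
  checkDesign(data, with_log_p = TRUE)
  coefs <- t(vapply(seq_len(n), function(i) {
    sub <- data[-i, , drop = FALSE]
    checkDesign(sub, with_log_p = TRUE)
    m <- lm(p_affinity ~ delta_e + log_p, data = sub)
    c(alpha = unname(coef(m)["delta_e"]),
      beta = unname(coef(m)["log_p"]),
      gamma = unname(coef(m)["(Intercept)"]))
  }, numeric(3)))
  rownames(coefs) <- data$ligand_id
  popSd <- function(x) sqrt(mean((x - mean(x))^2))
  out <- list(
    coef_mean = colMeans(coefs),
    coef_sd = apply(coefs, 2L, popSd),
    n_refits = n,
    coefficients = coefs
  )
  class(out) <- "theoceptor_loo"
  out
}

#' @export
print.theoceptor_loo <- function(x, ...) {
  cat(sprintf("Leave-one-out analysis over %d refits\n", x$n_refits))
  for (nm in c("alpha", "beta", "gamma")) {
    cat(sprintf("  %-5s mean = %8.4f  sd = %.4f\n", nm, x$coef_mean[[nm]],
                x$coef_sd[[nm]]))
  }
  invisible(x)
}
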