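# Calibration of the affinity relation
#   affinity = alpha * deltaE + beta * logP + gamma
# by ordinary least squares, with a deltaE-only reduced model for
# nested-model comparisons.

# Reduce a measurement-level ligand table to one calibration row per ligand
# under a selection policy. Ligands with no usable measurement get NA and
# are dropped by the fitting functions.
selectCalibrationRows <- function(records, policy, censored_as_value = FALSE) {
  validateLigandTable(records)
  ids <- unique(records$ligand_id)
  rows <- lapply(ids, function(id) {
    g <- records[records$ligand_id == id, , drop = FALSE]
    sel <- selectAffinity(g[, c("kind", "p_value", "censored", "assay")],
                          policy, censored_as_value)
    data.frame(ligand_id = id, delta_e = g$delta_e[1L], log_p = g$log_p[1L],
               p_affinity = sel$p_affinity, kind = sel$kind, assay = sel$assay,
               censored_used = sel$censored_used, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

newTheoceptorFit <- function(model, data, policy, terms) {
  y <- data$p_affinity
  res <- setNames(resid(model), data$ligand_id)
  fit <- list(
    alpha = unname(coef(model)["delta_e"]),
    beta = if ("log_p" %in% names(coef(model))) unname(coef(model)["log_p"]) else 0,
    gamma = unname(coef(model)["(Intercept)"]),
    n = nrow(data),
    r_squared = if (sd(fitted(model)) == 0) NA_real_ else cor(fitted(model), y)^2,
    rmse = sqrt(mean(res^2)),
    fitted = setNames(unname(fitted(model)), data$ligand_id),
    residuals = unname(res),
    data = data,
    policy = policy,
    terms = terms
  )
  names(fit$residuals) <- data$ligand_id
  class(fit) <- "theoceptor_fit"
  fit
}

checkDesign <- function(data, with_log_p, min_n = 3L) {
  n <- nrow(data)
  if (n < min_n) {
    stopStat("need at least ", min_n, " ligands with usable affinities to fit ",
             if (with_log_p) "three" else "two", " coefficients; got ", n)
  }
  if (sd(data$delta_e) == 0) {
    stopStat("degenerate design: delta_e is constant across ligands")
  }
  if (with_log_p) {
    if (sd(data$log_p) == 0) {
      stopStat("degenerate design: log_p is constant across ligands")
    }
    if (abs(cor(data$delta_e, data$log_p)) > 1 - 1e-12) {
      stopStat("degenerate design: delta_e and log_p are collinear")
    }
  }
  invisible(data)
}

#' Calibrate the affinity relation
#'
#' Fits \eqn{\mathrm{affinity} = \alpha \Delta E + \beta \log P + \gamma}
#' by ordinary least squares to one selected p-affinity per ligand.
#' \eqn{R^2} is the squared Pearson correlation between fitted and measured
#' values (on OLS training data this equals the coefficient of
#' determination); RMSE is \eqn{\sqrt{\mathrm{mean}(r_i^2)}} with no
#' degrees-of-freedom correction, so an interpolating fit reports exactly 0.
#'
#' @param records Ligand-table data frame (see [readLigandTable()]).
#' @param policy An [affinityPolicy()]; defaults to IC50, then Ki, then Kd,
#'   any assay.
#' @param censored_as_value Use censoring bounds as values instead of
#'   excluding censored-only ligands (flagged in the output).
#' @return An object of class `theoceptor_fit` with elements `alpha`,
#'   `beta`, `gamma`, `n`, `r_squared`, `rmse`, `fitted`, `residuals` (both
#'   named by ligand), `data` (the per-ligand calibration rows used), and
#'   the `policy`.
#' @examples
#' fit <- fitTheoceptor(ldhaLigands(), ldhaPolicy())
#' coef(fit)
#' @export
fitTheoceptor <- function(records,
                          policy = affinityPolicy(c("IC50", "Ki", "Kd")),
                          censored_as_value = FALSE) {
  rows <- selectCalibrationRows(records, policy, censored_as_value)
  data <- rows[!is.na(rows$p_affinity), , drop = FALSE]
  checkDesign(data, with_log_p = TRUE)
  model <- lm(p_affinity ~ delta_e + log_p, data = data)
  newTheoceptorFit(model, data, policy, c("delta_e", "log_p"))
}

#' Reduced model: complexation energy only
#'
#' Same calibration with \eqn{\beta} fixed at zero (the log P column is
#' dropped). Used as the reference in nested-model comparisons: any second
#' covariate, including a random one, can only raise training \eqn{R^2}
#' above this fit's.
#'
#' @inheritParams fitTheoceptor
#' @return A `theoceptor_fit` with `beta = 0`.
#' @export
fitDeltaEOnly <- function(records,
                          policy = affinityPolicy(c("IC50", "Ki", "Kd")),
                          censored_as_value = FALSE) {
  rows <- selectCalibrationRows(records, policy, censored_as_value)
  data <- rows[!is.na(rows$p_affinity), , drop = FALSE]
  checkDesign(data, with_log_p = FALSE)
  model <- lm(p_affinity ~ delta_e, data = data)
  newTheoceptorFit(model, data, policy, "delta_e")
}

#' @export
coef.theoceptor_fit <- function(object, ...) {
  c(alpha = object$alpha, beta = object$beta, gamma = object$gamma)
}

#' Predict p-affinity for new ligands
#'
#' Evaluates \eqn{\alpha \Delta E + \beta \log P + \gamma} at new inputs.
#'
#' @param object A `theoceptor_fit`.
#' @param delta_e Complexation energy (kcal/mol); vectorised.
#' @param log_p Calculated log P; vectorised.
#' @param ... Unused.
#' @return Predicted p-affinity (pIC50/pKi/pKd scale of the training data).
#' @examples
#' fit <- fitTheoceptor(ldhaLigands(), ldhaPolicy())
#' predict(fit, delta_e = -19.5, log_p = 3.84)
#' @export
predict.theoceptor_fit <- function(object, delta_e, log_p, ...) {
  checkFinite(delta_e, "delta_e")
  checkFinite(log_p, "log_p")
  object$alpha * delta_e + object$beta * log_p + object$gamma
}

#' @export
print.theoceptor_fit <- function(x, ...) {
  kind <- if (identical(x$terms, "delta_e")) "deltaE-only" else "deltaE + logP"
  cat(sprintf("Theoceptor affinity fit (%s), n = %d ligands\n", kind, x$n))
  cat(sprintf("  alpha = %8.4f  (per kcal/mol)\n", x$alpha))
  cat(sprintf("  beta  = %8.4f  (per log P unit)\n", x$beta))
  cat(sprintf("  gamma = %8.4f  (intercept)\n", x$gamma))
  cat(sprintf("  R^2 = %.3f   RMSE = %.3f p-affinity units\n", x$r_squared, x$rmse))
  invisible(x)
}

# Serializable report shared by the CLI and the JSON writers.
fitReport <- function(fit) {
  list(
    coefficients = list(alpha = fit$alpha, beta = fit$beta, gamma = fit$gamma),
    n = fit$n,
    r_squared = fit$r_squared,
    rmse = fit$rmse,
    ligands = data.frame(
      ligand_id = fit$data$ligand_id,
      delta_e = fit$data$delta_e,
      log_p = fit$data$log_p,
      measured = fit$data$p_affinity,
      fitted = unname(fit$fitted),
      residual = unname(fit$residuals),
      censored_used = fit$data$censored_used,
      stringsAsFactors = FALSE
    ),
    policy = data.frame(kind = fit$policy$kind, assay = fit$policy$assay,
                        stringsAsFactors = FALSE)
  )
}
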