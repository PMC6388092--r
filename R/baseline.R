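# Random-covariate baseline: does log P beat a random column spanning the
# same range? Because the random-covariate model nests the deltaE-only
# model, every replicate's training R^2 is at least the deltaE-only R^2;
# the question is how often chance matches the real log P term.

#' Random-covariate baseline for the log P term
#'
#' For each replicate, draws one uniform value per ligand on the observed
#' log P range, refits the affinity relation with (deltaE, random,
#' intercept), and records the training \eqn{R^2} and RMSE. Reports the
#' fraction of replicates whose \eqn{R^2} meets or exceeds that of the true
#' log P fit; a small fraction shows the lipophilicity term carries real
#' signal rather than the mechanical gain of any second covariate.
#'
#' @inheritParams fitTheoceptor
#' @param n_reps Number of random replicates (>= 1).
#' @param seed Integer seed; fixed seeds reproduce the replicate lists
#'   exactly.
#' @return An object of class `theoceptor_baseline`: `n_reps`, `seed`,
#'   vectors `r_squared` and `rmse` (one entry per replicate), summary
#'   `quantiles`, `frac_at_least_logp`, and the reference statistics
#'   `r_squared_logp` and `r_squared_delta_e_only`.
#' @examples
#' randomBaseline(ldhaLigands(), ldhaPolicy(), n_reps = 50, seed = 1)
#' @export
randomBaseline <- function(records,
                           policy = affinityPolicy(c("IC50", "Ki", "Kd")),
                           n_reps = 1000L, seed,
                           censored_as_value = FALSE) {
  if (missing(seed)) stopSchema("randomBaseline() requires an explicit seed")
  if (!is.numeric(n_reps) || n_reps < 1L) {
    stopSchema("n_reps must be >= 1, got ", n_reps)
  }
  n_reps <- as.integer(n_reps)
  rows <- selectCalibrationRows(records, policy, censored_as_value)
  data <- rows[!is.na(rows$p_affinity), , drop = FALSE]
  checkDesign(data, with_log_p = TRUE)
  lo <- min(data$log_p)
  hi <- max(data$log_p)
  if (hi == lo) {
    stopStat("degenerate log_p range (max = min = ", lo,
             "): cannot draw a spanning random covariate")
  }
  full <- fitTheoceptor(records, policy, censored_as_value)
  reduced <- fitDeltaEOnly(records, policy, censored_as_value)
  y <- data$p_affinity
  n <- nrow(data)
  stats <- withSeed(seed, {
    vapply(seq_len(n_reps), function(r) {
      rand <- runif(n, lo, hi)
      m <- lm(y ~ data$delta_e + rand)
      res <- resid(m)
      c(r2 = cor(fitted(m), y)^2, rmse = sqrt(mean(res^2)))
    }, numeric(2))
  })
  out <- list(
    n_reps = n_reps,
    seed = as.integer(seed),
    r_squared = unname(stats["r2", ]),
    rmse = unname(stats["rmse", ]),
    quantiles = list(
      r_squared = quantile(stats["r2", ], c(0.05, 0.25, 0.5, 0.75, 0.95)),
      rmse = quantile(stats["rmse", ], c(0.05, 0.25, 0.5, 0.75, 0.95))
    ),
    frac_at_least_logp = mean(stats["r2", ] >= full$r_squared),
    r_squared_logp = full$r_squared,
    r_squared_delta_e_only = reduced$r_squared
  )
  class(out) <- "theoceptor_baseline"
  out
}

#' @export
print.theoceptor_baseline <- function(x, ...) {
  cat(sprintf("Random-covariate baseline: %d replicates (seed %d)\n",
              x$n_reps, x$seed))
  cat(sprintf("  R^2 with true logP:      %.3f\n", x$r_squared_logp))
  cat(sprintf("  R^2 deltaE only:         %.3f\n", x$r_squared_delta_e_only))
  cat(sprintf("  random R^2 median [90%% band]: %.3f [%.3f, %.3f]\n",
              x$quantiles$r_squared[["50%"]], x$quantiles$r_squared[["5%"]],
              x$quantiles$r_squared[["95%"]]))
  cat(sprintf("  fraction of replicates >= logP R^2: %.4f\n",
              x$frac_at_least_logp))
  invisible(x)
}
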