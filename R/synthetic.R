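# Seeded generator of calibration sets with the statistical structure the
# affinity relation assumes: deltaE ~ Normal, logP ~ Uniform, affinity
# linear in both plus Gaussian noise. Defaults mirror the LDHA regime so
# synthetic and packaged-fixture tests exercise the same numeric scales.

#' Configuration for the synthetic calibration-set generator
#'
#' @param alpha,beta,gamma Ground-truth coefficients of the affinity
#'   relation (defaults in the LDHA regime).
#' @param n Number of ligands (>= 3).
#' @param delta_e_mean,delta_e_sd Normal distribution of complexation
#'   energies, kcal/mol (`delta_e_sd > 0`).
#' @param log_p_min,log_p_max Uniform range of calculated log P
#'   (`log_p_max > log_p_min`).
#' @param noise_sd Gaussian noise SD on the p-affinity scale (>= 0).
#' @param seed Integer seed; generation is deterministic given the config.
#' @param censor_below Optional p-affinity cutoff: generated affinities
#'   below it are recorded as upper-bound censored at the cutoff,
#'   emulating assays that only report "weaker than" results.
#' @param kind Measurement kind to emit (default `"IC50"`).
#' @return A validated list of class `synthetic_config`.
#' @examples
#' cfg <- syntheticConfig(n = 20, seed = 1)
#' @export
syntheticConfig <- function(alpha = -0.08, beta = 0.89, gamma = 0.42,
                            n = 50L, delta_e_mean = -15, delta_e_sd = 8,
                            log_p_min = 1.5, log_p_max = 8.1,
                            noise_sd = 0.5, seed = 1L,
                            censor_below = NULL, kind = "IC50") {
  cfg <- list(alpha = alpha, beta = beta, gamma = gamma, n = as.integer(n),
              delta_e_mean = delta_e_mean, delta_e_sd = delta_e_sd,
              log_p_min = log_p_min, log_p_max = log_p_max,
              noise_sd = noise_sd, seed = as.integer(seed),
              censor_below = censor_below, kind = kind)
  problems <- character(0)
  num <- c("alpha", "beta", "gamma", "delta_e_mean", "delta_e_sd",
           "log_p_min", "log_p_max", "noise_sd")
  for (nm in num) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      problems <- c(problems, paste0(nm, " must be a finite number"))
    }
  }
  if (is.na(cfg$n) || cfg$n < 3L) problems <- c(problems, "n must be >= 3")
  if (is.finite(cfg$delta_e_sd) && cfg$delta_e_sd <= 0) {
    problems <- c(problems, "delta_e_sd must be > 0")
  }
  if (is.finite(cfg$log_p_min) && is.finite(cfg$log_p_max) &&
      cfg$log_p_max <= cfg$log_p_min) {
    problems <- c(problems, "log_p_max must exceed log_p_min")
  }
  if (is.finite(cfg$noise_sd) && cfg$noise_sd < 0) {
    problems <- c(problems, "noise_sd must be >= 0")
  }
  if (is.na(cfg$seed)) problems <- c(problems, "seed must be an integer")
  if (!is.null(censor_below) &&
      (!is.numeric(censor_below) || length(censor_below) != 1L ||
       !is.finite(censor_below))) {
    problems <- c(problems, "censor_below must be NULL or a finite number")
  }
  if (!kind %in% AFFINITY_KINDS) {
    problems <- c(problems, paste0("kind must be one of ",
                                   paste(AFFINITY_KINDS, collapse = ", ")))
  }
  if (length(problems) > 0L) {
    stopSchema("invalid synthetic config: ", paste(problems, collapse = "; "))
  }
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a synthetic calibration set
#'
#' Draws `n` ligands with `delta_e ~ Normal(delta_e_mean, delta_e_sd)`,
#' `log_p ~ Uniform(log_p_min, log_p_max)` and
#' `affinity = alpha*delta_e + beta*log_p + gamma + Normal(0, noise_sd)`.
#' Deterministic under the config seed, without disturbing the caller's
#' RNG state. When `censor_below` is set, affinities under the cutoff are
#' replaced by the cutoff and flagged as upper-bound censored.
#'
#' @param config A [syntheticConfig()].
#' @return A ligand-table data frame (see [readLigandTable()]) with one
#'   measurement per ligand; the noiseless linear predictor is kept in
#'   attribute `"truth"`.
#' @examples
#' records <- generateLigands(syntheticConfig(n = 10, noise_sd = 0, seed = 7))
#' fitTheoceptor(records)$r_squared # 1
#' @export
generateLigands <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    config <- do.call(syntheticConfig, as.list(config))
  }
  out <- withSeed(config$seed, {
    delta_e <- rnorm(config$n, config$delta_e_mean, config$delta_e_sd)
    log_p <- runif(config$n, config$log_p_min, config$log_p_max)
    truth <- config$alpha * delta_e + config$beta * log_p + config$gamma
    p_value <- truth + rnorm(config$n, 0, config$noise_sd)
    censored <- rep(FALSE, config$n)
    if (!is.null(config$censor_below)) {
      censored <- p_value < config$censor_below
      p_value[censored] <- config$censor_below
    }
    df <- data.frame(
      ligand_id = sprintf("L%03d", seq_len(config$n)),
      delta_e = delta_e,
      log_p = log_p,
      kind = config$kind,
      p_value = p_value,
      censored = censored,
      assay = "synthetic",
      stringsAsFactors = FALSE
    )
    attr(df, "truth") <- truth
    df
  })
  validateLigandTable(out)
  out
}
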