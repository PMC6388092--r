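# Independent oracles and fixture builders shared across the suite.

# Brute-force normal-equations OLS, independent of the package's lm() path.
olsOracle <- function(X, y) {
  beta <- solve(crossprod(X), crossprod(X, y))
  fitted <- drop(X %*% beta)
  res <- y - fitted
  list(
    coef = drop(beta),
    fitted = fitted,
    residuals = res,
    r_squared = cor(fitted, y)^2,
    rmse = sqrt(mean(res^2))
  )
}

# Ligand table from explicit per-ligand vectors (one uncensored IC50 each).
ligandTable <- function(delta_e, log_p, p_value, censored = FALSE,
                        kind = "IC50", assay = "enzymatic") {
  n <- length(delta_e)
  data.frame(
    ligand_id = sprintf("lig%03d", seq_len(n)),
    delta_e = delta_e, log_p = log_p, kind = kind, p_value = p_value,
    censored = rep_len(censored, n), assay = assay,
    stringsAsFactors = FALSE
  )
}

# Random full-rank calibration instance (noisy plane), fixed by seed.
randomInstance <- function(n, seed, alpha = -0.3, beta = 1.2, gamma = -6.7,
                           noise_sd = 0.4) {
  set.seed(seed)
  delta_e <- rnorm(n, -15, 8)
  log_p <- runif(n, 1.5, 8.1)
  y <- alpha * delta_e + beta * log_p + gamma + rnorm(n, 0, noise_sd)
  ligandTable(delta_e, log_p, y)
}

anyPolicy <- function() affinityPolicy("IC50")
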