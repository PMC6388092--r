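---
title: "Methods: calibrating affinity from complexation energy and log P"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calibrating affinity from complexation energy and log P}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(theoceptor)
```

## The model and its assumptions

A theoceptor is a quantum-cluster model of a binding site: the sidechains
that contact the ligand, anchored in space, treated with electronic
structure methods. It yields a gas-phase electronic complexation energy

$$\Delta E = E_\mathrm{complex} - E_\mathrm{ligand} - E_\mathrm{receptor},$$

in kcal/mol, negative when association is electronically favourable. The
receptor energy is a dataset-level constant; its zero is arbitrary and only
shifts the calibrated $\alpha$ and $\gamma$, which is why
`assembleDeltaE()` insists on exactly one receptor record per dataset.

$\Delta E$ alone omits the vibrational/thermal enthalpy correction, the
entropy of association, and the change in solvation free energy. The
package's central assumption is that, within one congeneric system, those
omitted terms vary with the ligand's hydrophobicity, so the calculated
octanol–water $\log P$ can stand in for them linearly:

$$\mathrm{affinity} = \alpha\,\Delta E + \beta \log P + \gamma,$$

with affinity on the p-scale ($-\log_{10}$ of the molar IC50/Ki/Kd, so
larger is tighter and the quantity is linear in free energy). The three
coefficients are calibrated per system by ordinary least squares; nothing
transfers between systems, so only relative (within-system) affinity is
predicted, and at least three ligands of known affinity are required — the
leave-one-out machinery demands five so each refit keeps four points.
Physically sensible calibrations have $\alpha < 0$ and $\beta > 0$;
$\beta$ grows with the hydrophobicity of the site.

## Tunable parameters

| Parameter | Where | Default | Meaning |
|---|---|---|---|
| `temperature` | `boltzmannEnergy()`, `assembleDeltaE()` | 298.15 K | ensemble temperature for conformer weighting |
| `aggregate` | `assembleDeltaE()` | `"minimum"` | lowest-energy conformer per state; `"boltzmann"` opt-in |
| `policy` | fitting functions | IC50, then Ki, then Kd | ordered (kind, assay) preferences for picking one measurement per ligand |
| `censored_as_value` | fitting functions | `FALSE` | use "<" bounds as values instead of excluding the ligand |
| `threshold` | `rankHypotheses()` | 1.0 kcal/mol | bound-state margin below which hypotheses are indistinguishable |
| `n_reps`, `seed` | `randomBaseline()` | 1000, required | replicates of the random-covariate refit |

Energies are kcal/mol everywhere internally; Hartree inputs are converted
once at ingestion with the factor 627.5095 (CODATA-consistent to 7
significant figures).

## Conformer aggregation

The usual prescription is to take the lowest-energy bound complex and the
lowest-energy free conformer, appropriate when one geometry dominates each
state. When several conformers are thermally accessible we combine them as
an ensemble free energy,

$$E_\mathrm{ens} = -RT \ln \sum_i e^{-E_i/RT},
\qquad R = 1.98720425864083\times10^{-3}\ \mathrm{kcal\,mol^{-1}\,K^{-1}},$$

applied independently to the bound and free ensembles. This is the standard
ensemble result: it reduces to the minimum for a single conformer, in the
large-gap limit, and as $T \to 0$; $m$ degenerate conformers gain
$RT\ln m$ of stabilisation. The sum is evaluated after shifting by
$\min_i E_i$, so arbitrarily large spreads cannot overflow. Aggregation
never mixes hypothesis labels: conformers of different tautomers or
heteroatom placements are competing interpretations to be ranked, not
members of one ensemble. The lowest-energy prescription stays the default;
Boltzmann weighting is opt-in.

## Affinity selection and censoring

Assays disagree, and weak binders are often reported only as bounds
("IC50 weaker than the top concentration", carried here as a censored
p-value such as `<3.3`). A selection policy is an ordered list of
(kind, assay) preferences; the first *uncensored* match wins. Ligands with
only censored matches are excluded by default — using an upper bound as a
value biases the fit — with an explicit opt-in (`censored_as_value`) that
uses and flags the bound.

For the packaged LDHA set the documented policy is enzymatic pIC50 for
compounds 1–7 and SPR pKd for compounds 8–11 (their pIC50 values are
censored). This uses every uncensored published number for those eleven
compounds. The published source did not state its exact rule, nor the
inputs of two further ligands (oxamate and malonate) that entered its
13-point calibration; the packaged refit therefore reproduces the published
coefficients approximately. The intercept $\gamma$ and the error statistics
absorb most of that difference, which is why the package reports, rather
than asserts, agreement with the published values — the acceptance script
recomputes them and the comparison is discussed where it is made.

Duplicate ligand rows with conflicting $\Delta E$ or $\log P$ are rejected
rather than averaged: silent averaging hides upstream bookkeeping errors.

## Fit diagnostics

$R^2$ is the squared Pearson correlation between fitted and measured
values; on OLS training data this equals the coefficient of determination,
so the nested-model property holds exactly — adding any second covariate,
including a random one, cannot lower training $R^2$ below the
$\Delta E$-only fit. That is precisely why the random-covariate baseline
exists: `randomBaseline()` draws, per replicate, one uniform value per
ligand on the observed $\log P$ range and refits, and the question is not
whether the random column helps (it must, mechanically) but how often it
matches the true $\log P$ term. RMSE is $\sqrt{\mathrm{mean}(r_i^2)}$
with no degrees-of-freedom correction, so interpolating fits report exactly
zero. Leave-one-out summaries use the population (divide-by-$n$) standard
deviation across refits.

## Hypothesis ranking

Competing structural interpretations — ring pucker, pseudo-axial versus
pseudo-equatorial substituents, heteroatom placement, tautomers,
protonation states, binding with or without cofactor — are compared through
their bound-state energies; the lowest wins, ties break lexicographically.
Only differences are reported, so inputs may be absolute energies or gaps
relative to any zero (the tests assert shift invariance). The default
decisiveness threshold is 1.0 kcal/mol: sub-kcal gaps are within method
noise and are declared indistinguishable, multi-kcal gaps are decisive;
observed gaps cluster well below (≤0.6) or well above (≥4) this line, so
the split is insensitive to the exact value, and it is configurable. The
conformer-focusing penalty — the free-state cost of adopting the bioactive
form — is the free-state energy of the bound-preferred hypothesis minus the
free-state minimum, non-negative by construction.

## The synthetic generator: what it emulates and what it does not

`generateLigands()` draws $\Delta E \sim N(-15, 8^2)$ kcal/mol and
$\log P \sim U(1.5, 8.1)$ — the ranges of the packaged LDHA set — and adds
Gaussian noise (default SD 0.5 p-units, the scale of assay-to-assay
scatter) to the linear predictor, with defaults
$(\alpha, \beta, \gamma) = (-0.08, 0.89, 0.42)$ mirroring the LDHA regime
so synthetic and fixture tests exercise the same numeric scales. An
optional cutoff censors weak affinities as upper bounds, emulating
top-concentration-limited assays. Generation is deterministic under the
config seed and does not disturb the caller's RNG stream.

The generator emulates only the statistical structure the model assumes:
independent Gaussian noise, exactly linear response, independent
covariates. Real data violate all three — errors correlate within assay
series, the log P surrogate is itself an approximation, and chemists
co-vary potency and lipophilicity by design. Passing recovery tests
therefore validates the estimation machinery, not the physical adequacy of
the model on real systems.

## Numerical choices and degenerate inputs

- OLS is solved by R's QR-based `lm()`; tests cross-check coefficients,
  $R^2$ and RMSE against an independent normal-equations solver at 1e-8.
- Degenerate designs (constant $\Delta E$ or $\log P$, collinear columns,
  fewer than three usable ligands) are rejected with errors naming the
  offending column, as is a zero-width $\log P$ range in the baseline.
- Boltzmann weighting uses the min-shifted log-sum-exp; the $T \to 0$
  limit is exercised at $10^{-6}$ K.
- Energy-unit round trips are exact to 1e-9 relative; CSV writing uses 17
  significant digits so generated tables round-trip losslessly.
- Errors are classed (schema / statistical / I-O) and the CLI maps them to
  exit codes 2 / 3 / 4.

## Problem sizes

The validation suite runs at desk scale: oracle comparisons on 100 random
instances of 4–40 ligands; coefficient recovery over 200 seeded replicates
of 50 ligands at noise SD 0.3; baseline calibration at 1000 replicates of
30 ligands; distributional checks at $n = 10^4$. These sizes give
simulation standard errors comfortably below the tested tolerances.

## Known limitations

- Only relative, within-system affinity: coefficients do not transfer
  between receptors, and the receptor energy zero is folded into
  $\alpha$ and $\gamma$.
- Censored measurements are excluded (or crudely substituted on opt-in);
  no likelihood-based censored regression is attempted.
- No uncertainty propagation from the quantum energies, and no Bayesian
  treatment of the coefficients; leave-one-out SDs are the stability
  measure.
- The quantum-output harvester recognises one plain-text dialect
  (`SCF Done: ... = <number>` in Hartree, last match wins); vendor binary
  formats are out of scope.
- log P is an input. The package neither measures nor predicts it.
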