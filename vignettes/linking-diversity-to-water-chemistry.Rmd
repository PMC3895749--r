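---
title: "Linking benthic diversity indices to water chemistry by symbolic regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking benthic diversity indices to water chemistry by symbolic regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(benthicGP)
```

## The problem and the model

Benthic macroinvertebrate communities summarize river condition, but
biological sampling is expensive and short-lived, while physicochemical
records (temperature T, discharge Q, pH, dissolved oxygen DO, electrical
conductivity EC, BOD₅, TDS) are long and widespread. The package's goal is a
*transfer function*: a closed-form equation estimating a biodiversity index
from chemistry alone.

The procedure is a pipeline of standard steps around one non-standard core:

1. **Indices.** Shannon (−Σ Pᵢ ln Pᵢ), Simpson (1 − Σ Pᵢ²) and Margalef
   ((s − 1)/ln N) per station–month sample. Natural logarithms throughout;
   zero-count taxa contribute nothing (0 · ln 0 := 0). Shannon is stored with
   the conventional negation so that larger always means more diverse.
2. **Screening.** Pearson correlations of indices vs. environment; variables
   in a pair with |r| ≥ 0.95 are pruned by a caller-supplied priority (EC is
   preferred over TDS, which in practice is a fixed multiple of EC).
3. **Seasonal stratification.** 2-means clustering of the min-max-standardized
   samples. Winters sit at the cold/high-DO extreme of the annual cycle and
   form (most of) one cluster; that cluster is excluded, because the
   regression is meant for the growing season, when management decisions
   about flow and quality actually bind.
4. **PCA.** Varimax-rotated principal components of the retained predictors'
   correlation matrix (Kaiser-normalized rotation, the SPSS-style "rotated
   component matrix"), used descriptively to see which variables dominate
   which axes of the chemistry.
5. **Symbolic regression.** Tree-based genetic programming (GP) fit to the
   standardized training split, restarted many times; restarts double as a
   variable-importance probe (the presence tally) and the best restart, by
   training correlation, supplies the final equation.

The assumptions worth stating: samples are exchangeable given their month
(no station effects beyond noise are modelled); Pearson correlation is the
association measure everywhere (monotone nonlinearity is the GP's job, not
the screen's); and the "winter" notion used to label clusters is
meteorological (December–February), configurable via `winter_months`.

## Tunable parameters

| Parameter | Default | Units / scale | Why |
|---|---|---|---|
| `population_size` | 300 | individuals | stated study protocol |
| `generations` | 500 | generations | stated protocol; scaled runs use 100 |
| `mutation_rate` | 0.1 | probability | stated protocol |
| `crossover_rate` | 0.9 | probability | canonical Koza setting; reproduction fills the remainder |
| `tournament_size` | 3 | individuals | scale-invariant selection for an rmse fitness |
| `init_depth` | (2, 6) | tree levels | ramped half-and-half initialization |
| `max_depth` | 12 | tree levels | hard cap, enforced by rejecting oversized offspring in favour of a parent copy |
| `constant_range` | [0, 1] | dimensionless | ephemeral constants on the same scale as standardized predictors |
| `constant_prob` | 0.2 | probability | share of terminals that are constants |
| `elitism` | 1 | individuals | makes the best-fitness trajectory non-increasing |
| `stop_rmse` | 0 (off) | target units | early stop for exactly-solvable targets; affects runtime only |
| `n_runs` | 100 | restarts | stated protocol ("100 runs") |
| `split_fraction` | 0.8 | — | stated 80/20 protocol |
| `collinearity_threshold` | 0.95 | \|r\| | the stated pruning decision names the EC/TDS pair but no cutoff; 0.95 only fires on near-duplicates |
| `n_components` | 4 | components | the leading four components are the ones read |
| `k` | 2 | clusters | the seasonal split observed in this kind of data |

## What the synthetic generator emulates — and what it does not

`generate_dataset()` stands in for an undeposited field dataset: six
stations, twelve monthly samples each. It reproduces the *statistical
structure* the analysis relies on:

- temperature follows an annual sinusoid (mean 19 °C, amplitude 9 °C,
  July peak);
- DO is an affine decreasing function of T plus noise, calibrated so the
  sample T–DO correlation is near −0.8 (strong but not degenerate: with too
  little DO noise, DO becomes a deterministic proxy for T and either variable
  can substitute for the other in evolved equations);
- TDS = 0.64 × EC exactly, so the collinearity-pruning rule always has a
  genuine target;
- discharge has only a weak April-peak seasonal component under dominant
  hydrological noise, mirroring the near-zero discharge correlations typical
  of such tables — Q is the designated *uninformative* predictor for
  recovery tests;
- pH is clamped to [6, 9] and all concentrations to positive ranges;
- the community of each sample is built by *inverting* the Margalef formula:
  a planted target MI\* (by default the closed form
  DO/T + 2·DO/(T + EC + BOD₅), optionally plain DO/T) plus Gaussian noise
  (σ = 0.05) is turned into a richness s = clamp(round(1 + MI\*·ln N), 1,
  pool) with N uniform on [50, 500], and N individuals are allocated over s
  taxa by a Dirichlet(1)-multinomial with at least one individual per chosen
  taxon, so the realized Margalef index is exactly (s − 1)/ln N ≈ MI\*.

What it deliberately does **not** emulate: pollution gradients,
taxon-specific tolerance, between-station habitat structure (stations differ
only by i.i.d. noise), flow-regime dynamics, or realistic evenness profiles
(evenness is irrelevant to Margalef, so the Dirichlet concentration is a
free choice). A green recovery test therefore establishes that *the pipeline
can find a planted chemistry–diversity link of the assumed form under
realistic noise and discretization* — not that any particular river obeys
that link. Note also the discretization: rounding s moves the realized index
by up to 1/ln N (≈ 0.2), which acts as irreducible noise on top of σ and
caps the attainable fit.

## Numerical choices

- **Protected division** returns 1 when |denominator| ≤ 1e−9 (the classical
  convention), making tree evaluation total; evaluation is a compiled
  postfix stack machine, and an independent R interpreter checks it in the
  tests.
- **Zero-variance predictions** get Pearson r = 0 (worst) rather than NA, so
  constant trees never win selection; non-finite predictions get rmse = ∞.
- **Constant columns** standardize to 0 (not 0.5), keeping outputs in [0, 1]
  and making the degeneracy visible; their inverse transform returns the
  stored minimum.
- **Min-max bounds are fitted on the full post-winter-exclusion dataset
  before splitting**, as the protocol standardizes first. The mild
  train→validation leakage this implies is documented rather than silently
  fixed, to stay faithful to the procedure being modelled.
- **K-means** is Lloyd's algorithm from k-means++ starts, best of 10
  restarts; emptied clusters are re-seeded with the point farthest from its
  center; the winning restart's SSE trajectory is kept (and tested to be
  non-increasing). `stats::kmeans` is the cross-check, not the
  implementation, because it exposes neither k-means++ nor the trajectory.
- **PCA** eigendecomposes the correlation matrix; eigenvector signs are
  fixed by making each column's largest-magnitude element positive, so
  loadings are reproducible across platforms. Varimax preserves per-variable
  communalities (tested to 1e−6).
- **Ties** in best-equation selection break by lower training rmse, then
  lower run index — deterministic and permutation-invariant.
- **Serialization** prints constants to 12 significant digits; parsing the
  canonical prefix string back recovers the tree structure exactly and the
  constants to printed precision.
- **Crossover points** are chosen at operator nodes with probability 0.9
  and at leaves otherwise (Koza's convention), so crossover exchanges
  building blocks rather than mostly single terminals.
- **Sample standard deviations** use the n − 1 denominator; estimation
  errors are reported at full precision and rounded only for display.

## Open design decisions

- The within-run objective is training rmse; the *cross-run* selection uses
  the training Pearson r, and the *cross-index* choice uses the mean
  training r over restarts. Validation fitness is recorded for every restart
  but never used for selection, to avoid validation leakage.
- R² is the squared Pearson correlation between observed and calculated
  values (consistent with validation R² occasionally exceeding training R²),
  not 1 − SSres/SStot.
- The reported correlation matrix uses all twelve months by default
  (`correlation_all_months = TRUE`); the post-exclusion variant is a flag,
  since which set a published table used is often ambiguous.
- The closed-form reference equation is read as
  DO/T + 2·DO/(T + EC + BOD₅) — the only dimensionally coherent grouping of
  its fraction structure — and `evaluate_margalef_equation()` applies it to
  whatever scale the caller supplies (raw units or standardized values).
- Presence is *syntactic* occurrence in the raw best tree. No simplification
  is attempted: simplifying would change tallies in unspecifiable ways.
  Consequently tallies saturate as trees bloat; with rmse-only fitness and a
  depth cap (parsimony pressure is out of scope), informative variables can
  only be expected to rank *at or above* uninformative ones, not to reach
  the low absolute percentages a parsimony-pressured tool would print.
- Configuration files are JSON (one nested `gp` block); missing
  environmental values are an error, never imputed.

## Known limitations

- GP is stochastic; per-restart outcomes vary, and only aggregate statements
  (selected index, tally orderings) are stable at the tested scales. All
  randomness is seeded, so every reported number is replayable.
- With ~30 post-exclusion training samples, the validation split holds
  ~7 samples: validation statistics are volatile, and the fit summary should
  be read accordingly.
- The evolved equations are descriptive of the training river-year; nothing
  in the method licenses transfer to other basins without re-fitting.
- Runtime at the full stated protocol (3 indices × 100 restarts × 500
  generations) is substantial in pure R; the compiled evaluator makes the
  scaled configuration (20 × 100) run in minutes, and tests and the
  acceptance script use that scale.
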