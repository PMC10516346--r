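---
title: "Quantifying and modelling competition between ectomycorrhizal fungi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and modelling competition between ectomycorrhizal fungi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Ectomycorrhizal fungi (EMF) compete for territory on the root systems of
their host trees, and the outcomes of that competition shift with the
abiotic environment — in particular with pH, which varies over small spatial
scales in forest soils. Two rival approaches claim to predict which fungus
wins: *phylogenetic distance* (relatedness as a proxy for niche overlap or
shared competitive traits) and *trait distance* (here, the difference in
intrinsic growth rate, the trait most directly tied to substrate
colonisation). This package implements a complete analysis pipeline for
in vitro plate assays that pits the two predictors against each other:

1. estimate each colony's exponential-phase growth rate from area
   trajectories,
2. quantify the effect of interspecific competition relative to an
   intraspecific baseline,
3. fit both distance-based mixed models and compare them,
4. summarise pairwise outcomes as directed competitive networks.

A synthetic-data generator reproduces the experiment end to end with known
parameters, so every stage is validated by parameter recovery rather than by
eyeballing.

## The experimental design being modelled

Five EMF strains (four basidiomycetes — *Amanita muscaria*,
*Hebeloma cylindrosporum*, *Laccaria bicolor*, *Paxillus involutus* — and
the ascomycete *Cenococcum geophilum*) are grown on media at pH 5.6 and
pH 7.0 in three plate layouts:

* **single**: one plug in the centre — the fungus alone;
* **SvS** (self vs. self): two plugs of the same strain — the intraspecific
  baseline;
* **competition**: two plugs of different strains, all 10 unordered pairs.

Each treatment × pH cell has 10 replicates: (5 single + 5 SvS + 10 pairs) ×
2 pH × 10 = 400 plates. Plates showing irregular growth (contamination, a
dislodged plug, dormancy) are flagged and excluded from analysis; in the
study this affected 8% of plates, which is the generator's default attrition
rate.

## Growth rates

Colony area in the exponential phase follows \(A(t) = a_0 e^{rt}\), so the
growth rate \(r\) (day\(^{-1}\)) is the OLS slope of \(\ln A\) on day.
`fit_growth()` restricts the fit to a window — default \([0, 4]\) days,
capturing the "first 3–4 days" of growth before plates saturate — and
requires at least three in-window points. The window is a single shared
configuration knob rather than a per-plate choice; per-plate windows would
let noise pick the window and bias rates upward. Maximum colony area (the
colony-size response used in the alternate analysis) is taken over the full
series, not the window.

Because SvS plates hold two plugs of the same strain, exactly one plug per
plate is kept for analysis, chosen at random (`select_svs_plug()`, seeded
for reproducibility). Using both would pseudo-replicate the baseline.

## The effect of competition (EoC)

For a focal plug on a competition plate,

\[
EoC = \frac{\text{response in competition}}
           {\overline{\text{response on SvS plates}}_{\text{same species, same pH}}}
\]

with response either growth rate or maximum colony size. \(EoC = 1\) means
competition had no effect; values below 1 mean inhibition, above 1
facilitation. The denominator is the **mean** over the pH-matched SvS
baselines: after random plug selection there is no meaningful replicate
pairing between a competition plate and a particular SvS plate, so the mean
is the only well-defined choice. EoC is stored as a raw ratio and
log-transformed at model time, so the ratio view and the log-ratio view are
two reads of one stored value.

## Distances

* **Patristic distance**: the sum of branch lengths on the path between two
  tips of the phylogeny (`patristic_distances()`, via `ape`). Branch lengths
  are used as-is — no ultrametric transformation — and an outgroup in the
  tree never affects ingroup distances. Negative branch lengths are
  rejected; zero-length branches are allowed.
* **Growth-rate distance**: \(|\bar r_i - \bar r_j|\) of mean SvS growth
  rates, computed separately per pH (the trait distance itself responds to
  the environment). The analogous colony-size distance supports the
  alternate response.

## The two mixed models

Both models predict \(\log EoC\) with crossed random intercepts for focal
species and plate (two plugs share a plate, so plate is a genuine grouping
factor, crossed with species):

\[
\log EoC \sim \text{growth-rate distance} + \text{pH} + (1\mid\text{species})
 + (1\mid\text{plate})
\]
\[
\log EoC \sim \text{patristic distance} \times \text{pH} +
 (1\mid\text{species}) + (1\mid\text{plate})
\]

The growth-distance model has no distance × pH interaction because the
growth distance already differs between pH levels; patristic distance is
pH-constant, so its interaction with pH is retained. pH enters as a
two-level factor with 5.6 as the reference level. Random slopes are not
used.

**Estimation.** REML is the default for reported coefficients and
information criteria, with ML available for likelihood comparisons across
different fixed structures; `compare_models()` records which was used.
Singular fits (variance components at zero) are flagged, not errors.

**p-values.** `lme4` does not produce fixed-effect p-values. This package
reports Wald *t* statistics on \(n - p\) residual degrees of freedom (with
~360 usable observations and 3–5 fixed effects the choice of df algorithm
is immaterial: \(t_{355}\) is indistinguishable from normal).
Finer approximations (Satterthwaite, Kenward–Roger) would change p-values
only in the third decimal here; the df convention is stated in the output
contract so results are interpretable.

**Pseudo-R².** Variance-partition coefficients:
\(R^2_m = \sigma^2_f / (\sigma^2_f + \sigma^2_s + \sigma^2_p + \sigma^2_r)\)
and
\(R^2_c = (\sigma^2_f + \sigma^2_s + \sigma^2_p) / (\sigma^2_f + \sigma^2_s
+ \sigma^2_p + \sigma^2_r)\), where \(\sigma^2_f\) is the variance of the
fixed-effect linear predictor and \(\sigma^2_s, \sigma^2_p, \sigma^2_r\) are
the species, plate, and residual components. Always
\(0 \le R^2_m \le R^2_c \le 1\).

**Model comparison.** The two specifications are non-nested, so the report
leads with \(\Delta AIC\). A likelihood-ratio chi-square on the
parameter-count difference is also reported, floored at zero when the
larger model has the *lower* likelihood — the configuration that produces
the degenerate "chi-square = 0, p = 1" outcome, which arises routinely when
the extra interaction term buys no fit. `compare_models()` refuses models
fit to different observation sets.

**Predictor independence.** `distance_correlation_check()` regresses
patristic on growth distance over unordered species pairs with a pH random
intercept. With only two pH levels that intercept is usually estimated at
zero (a boundary fit); the check is reported with its singularity flag
rather than failing.

## Competitive networks

Four directed complete graphs per pH, all sharing the identity *node size =
sum of outgoing edge widths*:

| metric | width of edge i → j |
|---|---|
| single control | mean single-plate rate of i / mean rate of j |
| SvS control | same, with SvS rates |
| EoC wins | % of shared plates where i's EoC beat j's (ties split 50/50) |
| IoA | mean antagonism score of i against j |

"EoC wins" compares the two plugs **within each plate** — each competition
plate is one head-to-head bout — so opposing widths always sum to exactly
100. (Pooling EoC values across plates before comparing would mix plate
effects into the win count.) Control widths are reciprocal:
\(w_{ij} \cdot w_{ji} = 1\).

The index of antagonism (IoA) scores the physical interaction at the
contact zone. The default table — intermingling 2/2, deadlock at a distance
1/1, deadlock with contact 2/2, partial overgrowth 4 vs 1, complete
overgrowth 5 vs 0 — is a Wicklow–Hirschfield-style stand-in: the exact
published point scheme lives in supplementary material not bundled here, so
the table is an explicit, swappable argument (`default_ioa_table()`) rather
than a constant.

## The synthetic world

`simulate_experiment()` generates the full design with known truth. Its
defaults are the stated experimental conditions wherever those exist, and a
single realistic choice elsewhere:

| parameter | default | basis |
|---|---|---|
| design | 5 sp × 2 pH × (single, SvS, 10 pairs) × 10 reps = 400 plates | the study design |
| dropout | 8% of plates | 368/400 plates with regular growth |
| intrinsic rates \(\mu_{ip}\) | 0.12–0.34 day⁻¹, per species × pH | realistic plate-assay rates, mirroring the observed pattern (three species slower at pH 5.6, *H. cylindrosporum* at ~47% of its neutral rate, two species pH-insensitive) |
| log-EoC coefficients | \(\beta_0 = 0.05\), \(\beta_{dist} = -0.05\), \(\beta_{pH} = -0.11\) | signs and magnitudes of the reported phylogenetic-distance model |
| random-effect SDs | \(\sigma_s = 0.1\), \(\sigma_{plate} = 0.05\), \(\sigma_{resid} = 0.1\) | plausible mid-size heterogeneity |
| measurement noise | \(\sigma_{obs} = 0.05\) (lognormal) | ~5% area-tracing error |
| plug area \(a_0\) | 24.6 mm² | a 5.6 mm diameter plug |
| schedule | days 0–10, unit spacing | not published; a daily census |

Competition plugs realise rate \(\mu_{ip} \times EoC\) with
\(\log EoC = \beta_0 + \beta_{dist}\, d(i,j) + \beta_{pH}\, \mathbf{1}[pH
= 7] + u_i + w_{plate} + \varepsilon\). The phylogeny is a seeded Yule tree;
tree and noise use independent seed streams so the topology can be held
fixed across noise replicates. Saturation (a plateau after a configurable
day) is off by default and exists to exercise window selection.

**What the generator does not emulate:** spatially explicit mycelial
interaction, time-varying growth rates within the exponential window,
correlated exclusions (e.g. a contaminated batch), non-lognormal tracing
error, or intraspecific strain variation. A green recovery test therefore
establishes that the estimators are correct *for this generative model*,
not that the model is a complete account of plate biology.

## What the simulation study established

At study scale (200 replicates, ~360 usable observations each):

* \(\beta_{dist}\) and \(\beta_0\) are recovered within ±2 SE in well over
  90% of replicates, and the true-distance model beats an independent
  noise-distance model on AIC in ≥ 95%.
* \(\beta_{pH}\) is recovered **without bias**, but its model SE
  understates the true sampling variability (≈0.016 vs ≈0.024), giving
  ≈82–85% rather than ≈95% coverage for a ±2 SE interval. The cause is
  structural: every EoC in a (species, pH) stratum shares the estimation
  error of that stratum's SvS baseline mean, a disturbance the model's
  species- and plate-level intercepts cannot absorb. This is a property of
  the EoC design itself — invisible on real data, where the truth is
  unknown — and a reason to read pH-contrast p-values from such models with
  some caution. Adding a species × pH random intercept would absorb it at
  the cost of confounding with the pH fixed effect at only two levels.

## Numerical choices and degenerate inputs

* Growth fits require strictly increasing days; duplicated days are data
  errors, rejected rather than averaged.
* Non-positive areas are row-level validation errors on input (reported
  with line numbers), never silently dropped.
* ANOVA with zero residual variance is flagged degenerate instead of
  returning an unstable F.
* The factorial EoC model (`EoC ~ focal × opponent × pH`) is structurally
  rank-deficient (a fungus never meets itself); aliased coefficients are
  reported by name.
* Exact EoC ties in the wins network are split 50/50 — measure-zero on real
  data, required for determinism on synthetic data.
* AIC ordering between the two model specifications is invariant to affine
  rescaling of a distance predictor under ML (log-likelihood and parameter
  count are unchanged); REML criteria do not share this invariance, which
  is why the rescaling property is tested under ML.

## Limitations

The pipeline analyses one strain per species; it cannot separate species
effects from strain effects. The IoA point table is a configurable stand-in
pending the published scheme. The pH-contrast SE undercoverage above
applies to any analysis that normalises by an estimated baseline and then
ignores the sharing of that estimate. Reproducing the original study's
printed coefficients requires its deposited plate measurements, which are
not bundled; all numbers in this package's documentation are computed from
synthetic data by the scripts under `analysis/`.
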