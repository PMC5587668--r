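---
title: "Models and methods behind tilscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tilscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilscreen)
```

tilscreen analyses compound screens for enhancers of T-cell-mediated tumor
killing. This vignette records the models each stage assumes, the tunable
parameters and their defaults, what the synthetic-data generators do and do
not emulate, and the numerical and design choices made where the design was
genuinely open. It states no empirical result that the test suite or the
acceptance script does not itself compute.

## 1. The comboscore screen statistic

A screen plate measures percent cleaved caspase 3 (apoptosis) of tumor
cells under four conditions: vehicle (DMSO), compound alone, vehicle +
TILs, compound + TILs, typically in triplicate wells. Replicates are
aggregated to condition means first; the comboscore of a compound is then

$$\mathrm{comboscore} \;=\;
\frac{\%\mathrm{casp}[\mathrm{compound{+}TILs}] -
      \%\mathrm{casp}[\mathrm{compound}]}
     {\%\mathrm{casp}[\mathrm{TILs}]}.$$

The numerator is the TIL-attributable incremental killing under compound
treatment; the denominator is the killing TILs achieve on untreated
(vehicle) cells. A compound that leaves T-cell killing unchanged scores 1;
values above 1 flag sensitizers ("enhancers"), values below 1 (including
negative values) protection.

Design choices:

* **Unsquared ratio by default.** A squared variant of the statistic is
  sometimes written; squaring would let a strong *protector* (ratio
  < −1) exceed the enhancer threshold, contradicting the interpretation of
  "score > 1 means sensitization". The unsquared ratio is therefore the
  default, with `squared = TRUE` preserving the alternative reading.
* **Denominator = vehicle-treated tumor + TILs.** No background
  subtraction of vehicle-alone apoptosis is applied by default — the plain
  formula has no baseline term. `background_subtract = TRUE` subtracts the
  DMSO-alone mean from all three terms, which is the right choice when
  baseline apoptosis is appreciable (it makes the score equal the
  generative interaction γ below even for nonzero baseline).
* **Condition means, not per-replicate scores**, feed the ratio: the
  formula is defined on condition percentages and plate designs do not
  pair replicates across conditions.
* **Determinism.** Ranks break comboscore ties lexicographically by
  compound id; compounds that cannot be scored (missing condition, TIL
  mean of zero) are kept with a reason code, never silently dropped; a
  tumor line without the vehicle+TILs condition is a hard error since
  nothing on that line is scorable.

Parameters: `enhancer_threshold` (default 1, dimensionless; the call is
strictly greater-than).

## 2. Median-effect model and combination index

Each single agent's dose–response is modelled by the median-effect
equation

$$\frac{f_a}{f_u} = \left(\frac{d}{D_m}\right)^m, \qquad f_u = 1 - f_a,$$

with $D_m$ the dose giving 50% effect (agent units: nM for compounds; the
effector:target ratio is treated as the continuous "dose" of the T-cell
agent) and $m$ the sigmoidicity. On $x = \log_{10} d$, $y = \log_{10}
(f_a/f_u)$ this is a line fitted by unweighted ordinary least squares (the
classical procedure fits the linearized plot directly); the Pearson
correlation $r$ of $(x, y)$ is reported as the linearity diagnostic. A
non-positive slope (response falling with dose) rejects the model with
diagnostics rather than returning an unusable fit. Observations with
$f_a \in \{0, 1\}$ are rejected at ingestion — the transform is undefined
there and silent clamping distorts fits; `clamp_fa()` (to $[\varepsilon,
1-\varepsilon]$, $\varepsilon = 0.005$) exists for users who explicitly
choose to keep saturated points, and is never applied automatically.

For a combination $(d_1, d_2)$ producing effect $f_a$, with
$D_{x,i} = D_{m,i} (f_a/f_u)^{1/m_i}$ the iso-effective single-agent
doses, the combination index is

$$\mathrm{CI} = \frac{d_1}{D_{x,1}} + \frac{d_2}{D_{x,2}}
\quad (\text{mutually exclusive form, default}),$$

optionally plus $(d_1 d_2)/(D_{x,1} D_{x,2})$ (`form = "nonexclusive"`).
The exclusive form is the default because it alone satisfies the Loewe
sham-combination identity exactly (an agent "combined" with itself at any
split gives CI = 1), which anchors the <1 / =1 / >1 reading of the
isobologram. Since strict equality is unusable under noise, classification
uses a configurable additivity band `tol` (default 0.05): CI < 1 − tol
synergy, within the band additivity, above antagonism. Effect levels whose
$D_x$ lies more than two decades outside an agent's fitted dose range are
flagged `extrapolated` but still computed.

Numerical note: the identity
`dose_for_effect(model, effect_at_dose(model, d)) = d` holds to 1e-10
relative only while $f_a$ is representable away from saturation
(about $|\log_{10}(f_a/f_u)| \le 4$). Beyond that, a double carrying
$f_a$ within $10^{-12}$ of 1 has already lost the digits the inversion
needs — a property of the stored value, not of the fit — and at extreme
doses $f_a$ rounds to exactly 1, where the inverse is undefined. The test
suite checks the round trip over the representable window.

## 3. Expression ranking and KS enrichment

Input is an already-normalized log2 expression matrix (probe × sample)
with sample annotations (cell line, treated/control, replicate); array
preprocessing is out of scope. For each cell line the treated replicates'
log2 values are averaged and the control average subtracted per probe; the
probe's score is the mean of these per-line differences across lines, and
probes are ranked by descending score, ties broken lexicographically.
Probes are ranked at probe level by default (no gene collapse); an
optional max-|score| collapse (`collapse_to_genes()`) is provided.
Probes with any missing value are dropped at ingestion and counted.

The enrichment score of a set of $k$ probes in a rank of $N$ is the
classic unweighted Kolmogorov–Smirnov-type statistic: walking the rank
from top to bottom, the running sum gains $1/k$ at each member and loses
$1/(N-k)$ at each non-member; ES is the signed extremum. The weighted
(score-modulated) variant used by the full GSEA tool is deliberately out
of scope. Implementation detail: between members the sum decays linearly,
so its positive extremum occurs at a member and its negative extremum just
before one; ES is computed in $O(k)$ from sorted member positions, and the
exhaustive brute-force walk in the test suite verifies the equivalence on
every possible set for every rank size $N \le 8$. When the positive and
negative extrema tie in magnitude (common in small symmetric
configurations, measure zero in real data) the positive one is returned,
with a $10^{-12}$ rounding guard so closed-form and cumulative-sum
evaluations agree.

Significance uses a **gene-label permutation null** — ES of random
same-size member sets drawn uniformly without replacement — because with
two duplicate arrays per arm a phenotype permutation is degenerate. The
two-sided add-one p-value $(1 + \#\{|ES_{null}| \ge |ES_{obs}|\}) /
(B + 1)$ never returns zero; its floor $1/(B+1)$ is the designed behaviour
for strongly planted sets. The leading edge is the members at or before
the peak (after it, for negative ES). `n_permutations` defaults to 1000
(floor ≈ 0.001) and must be ≥ 100; a seed is required, not optional.

One consequence of the unweighted statistic worth knowing: a *saturated*
set of size $N-1$ has $|ES| = \max(j-1, N-j)/(N-1) \ge 0.5$, where $j$ is
the single non-member's position — large, but never significant, because
every same-size null set has $|ES| \ge 0.5$ too. Magnitude, not
significance, is what degenerates.

## 4. 2^−ΔΔCT quantification

CT replicates are averaged first. Per condition, $\Delta CT =
\overline{CT}_{target} - \overline{CT}_{ref}$ normalizes to a reference
gene (default `GAPDH`); $\Delta\Delta CT = \Delta CT_{sample} -
\Delta CT_{calibrator}$ normalizes to a calibrator sample (default
`DMSO`), and the fold change is $2^{-\Delta\Delta CT}$. Any non-finite CT
is a validation error. The statistic is invariant to a constant CT shift
across all four means, which the suite checks as a property.

## 5. What the simulators state, and what a green test establishes

Each generator is a deterministic function of (config, seed); every
dataset ships with its ground truth.

**Screen** (`simulate_screen`): condition means follow
$b$, $b + c_i$, $b + t$, $b + c_i + \gamma_i t$ for baseline $b$
(default 0), compound effect $c_i \sim U(2, 15)$ percent, TIL-alone
increment $t$ (default 30 percent), and interaction $\gamma_i$ (null 1).
The interaction is *multiplicative on the TIL increment* precisely so that
the comboscore is the exact estimand: noise-free, score $= \gamma_i$ when
$b = 0$ (or with background subtraction). Replicates (default 3, matching
the triplicate design) add Gaussian noise (default sd 1 percentage point,
a realistic flow-cytometry replicate spread) and are clamped to [0, 100]
with the clamp count reported. Noise-free exactness runs in the acceptance
suite use $t = 20$ so that $c_i + \gamma_i t \le 100$ for planted
$\gamma \le 4$ — the zero-clamping regime those checks require and assert.
Not emulated: plate spatial artifacts, edge effects, between-line
heterogeneity of $\gamma$ — so a green recovery test establishes the
estimator is right for the stated generative model, not that real plates
are free of systematic error.

**Dose–response** (`simulate_dose_response`): exact median-effect curve;
noise (default off) is added on the *linearized* scale so the OLS fit is
correctly specified in recovery tests, with a deliberately misspecified
fa-scale option for robustness checks. **Combination**
(`simulate_combination`): dose pairs on the Loewe line scaled by
interaction $\alpha$ — $d_1 = \lambda D_{x,1}/\alpha$, $d_2 =
(1-\lambda) D_{x,2}/\alpha$ — so the true exclusive CI is $1/\alpha$ at
every effect level and split; deterministic by construction.

**Expression** (`simulate_expression`): probe baselines $U(6, 12)$
(typical normalized log2 intensities), 4 lines × 2 duplicates per arm by
default, planted probes shifted by $\delta$ in treated samples, i.i.d.
Gaussian noise (no probe-level covariance or line effects) — the expected
rank score of a planted probe is exactly $\delta$. **qPCR**
(`simulate_ct`): reference gene constant, treated target CT lowered by
$\log_2(\mathrm{fold})$ (one cycle per doubling), triplicates, optional
CT noise.

Generator defaults were chosen once, as stated above, and are not tuned to
test outcomes.

## 6. Pipeline, randomness and determinism

`run_pipeline()` takes one JSON config (JSON rather than YAML so the only
structured-text dependency is jsonlite), validates every referenced input
path before any stage runs, executes stages in dependency order, and
writes a machine-readable manifest last; a failing stage aborts with a
manifest naming it. All randomness flows from one root seed:
`derive_seeds()` expands it into per-stage (and per-set, in
`enrich_collection()`) substreams, so adding a stage does not shift
another's stream, and a rerun under the same config and seed is
byte-identical in every numeric output (the manifest embeds output paths
and is excluded from the byte-identity contract). Simulators save and
restore the caller's RNG state.

## 7. Known limitations

* The screen model treats the TIL:tumor ratio as fixed and implicit; the
  synergy module treats it as a continuous dose when it is titrated.
* Only Loewe-based synergy (CI, isobologram) is implemented — no Bliss,
  HSA, ZIP, response surfaces, or bootstrap confidence bands.
* The enrichment stage is the unweighted KS statistic with a gene-label
  null: no weighted ES, NES, or FDR across collections.
* Differential expression is ranked, not significance-tested, matching
  the screening use case.
* CSV/TSV/GMT/JSON are the only formats; no FCS, array IDAT, or qPCR
  instrument exports.
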