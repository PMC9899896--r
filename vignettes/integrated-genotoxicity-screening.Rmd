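---
title: "Integrated in vitro genotoxicity screening: models, decision rules, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated in vitro genotoxicity screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtxscreen)
```

## The screening problem

Most chemicals in commerce have little or no experimental genotoxicity data.
`gtxscreen` implements an integrated, *in vitro*-only assessment built from
three complementary assay readouts plus quantitative potency modeling:

1. a **transcriptomic DDI classifier** — a biomarker gene panel scored against
   a labeled reference set of chemicals with known DNA-damage-inducing (DDI)
   and non-DDI mechanisms;
2. a **micronucleus (MN) caller** — chromosomal damage from flow-cytometry
   well summaries (MN events per nucleated events);
3. a **mode-of-action (MoA) caller** — multiplexed DNA-damage-response
   biomarkers (γH2AX, nuclear p53, phospho-H3, polyploidy) classified against
   fold-change thresholds (global evaluation factors, GEFs);
4. **benchmark-concentration (BMC) modeling** of every endpoint and a
   **ToxPi-style weighted integration** for potency ranking.

An integrated rule table combines the three hazard calls into one category
(genotoxic with a clastogenic/aneugenic/pan MoA, likely-irrelevant MN
positive, possibly genotoxic with ambiguous MoA, or non-genotoxic).

Every stage is exercised end-to-end on synthetic studies with known ground
truth; nothing in the package requires downloading external data.

## Concentration design

Series are geometric with spacing factor 0.70711 (`build_series()`), i.e.
half-log every two steps: 6 points for the transcriptomic assay, 10 for the
flow assays. Top concentrations come from a viability screen
(`select_top_concentration()`): the highest tested concentration with at
least 40% viability (transcriptomic and MN assays) or 20% viability
(DNA-damage assay), capped at 10 mM. Selection is restricted to tested
concentrations — viability is never interpolated — and concentrations are
carried at full precision internally, rounding only for display.

## The classifier ensemble

Three independent analyses compare each (compound, concentration) profile of
replicate-averaged log2 fold-changes with the reference set; a compound is
DDI if *any* method at *any* concentration says so (a deliberately
conservative disjunction).

**Nearest shrunken centroids.** For gene $j$ and class $k$ the standardized
centroid is
$d_{kj} = (\bar x_{kj} - \bar x_j) / (m_k (s_j + s_0))$ with
$m_k = \sqrt{1/n_k + 1/n}$, pooled within-class SD $s_j$, and fudge constant
$s_0 = \mathrm{median}_j(s_j)$. Soft-thresholding
$d'_{kj} = \mathrm{sign}(d_{kj}) (|d_{kj}| - \Delta)_+$ shrinks centroids
toward the overall mean. A profile $x$ is scored by the discriminant
$\delta_k(x) = \sum_j (x_j - \bar x'_{kj})^2 / (s_j + s_0)^2 - 2 \log \pi_k$,
posteriors $\propto \exp(-\delta_k / 2)$, and assigned only when the winning
posterior exceeds 0.90 (otherwise unclassifiable). Design choices made here:

* $\Delta$ is selected by leave-one-chemical-out cross-validation on the
  reference set, taking the smallest $\Delta$ among those with maximal
  accuracy (ties favor less shrinkage);
* class priors are fixed at 0.5/0.5 — the reference set's composition is a
  design choice, not a prevalence estimate.

**Principal components.** PCs are fitted on the reference chemicals with gene
centering only (no unit-variance scaling by default; a `scale.` flag exists
because the choice is genuinely open). Samples are projected with the
reference centering and loadings. The sign of PC1 is arbitrary in any PCA,
so the axis is oriented to make the mean PC1 of the DDI reference chemicals
negative; a condition is DDI iff its PC1 is strictly negative, and a
condition exactly on the boundary (PC1 = 0) is conservatively non-DDI.

**Joint hierarchical clustering.** Reference chemicals and sample conditions
are clustered together (Euclidean distance, average linkage) and the tree is
cut at its top split. Each of the two main clusters takes the majority label
of its reference chemicals; a sample inherits its cluster's label, and is
unclassifiable if its cluster contains no reference chemicals or the top
split fails to separate the classes by majority.

## Flow-cytometry calling

**Micronucleus.** Per well, %MN = 100 · MN/nucleated; relative survival
RS = 100 · treated density / mean control density; fold-EMA = treated
%apoptotic-necrotic / control mean. The fold-EMA is a ratio and is
implemented without any percent scaling. Wells with RS < 40% or fold-EMA > 4
are gated out (the boundary keeps RS = 40 exactly). Per concentration, MN
counts are compared with plate controls in a Poisson log-linear model with
`log(nucleated)` offset; the treatment indicator is tested by likelihood
ratio ("Poisson regression" does not pin a test statistic, so the choice is
the package's), and the per-concentration p-value family is
Holm–Šidák adjusted ($\tilde p_i = \max_{j \le i} 1 - (1 - p_j)^{m - j + 1}$).
A compound is positive iff some non-gated concentration has replicate-average
fold-%MN ≥ 2.50 *and* adjusted p < 0.05; if every concentration is gated the
result is *undetermined*, deliberately distinct from negative.

**Mode of action.** γH2AX and p53 "shifts" are treated median fluorescence
over control mean; %polyploidy and %p-H3 are event fractions; relative
nuclei count (RNC) defines cytotoxicity = 100 − RNC at 24 h, and
concentrations above 80% cytotoxicity are excluded. The GEF thresholds
(defaults in `default_gef_table()`: 4H γH2AX 1.51, 24H γH2AX 2.11, 4H p53
1.40, 24H p53 1.45, 4H p-H3 1.71, 24H p-H3 1.52, 24H polyploidy 5.86 — with
24H p53 a member of both sets) define biomarker "hits" with *met or
exceeded* semantics (a fold exactly at threshold counts). A set call is
robust when ≥ 2 of its biomarkers hit at the same two consecutive non-gated
concentrations. "Two successive concentrations" admits two readings — the
same biomarkers at both, or any two biomarkers at each; the strict
same-biomarkers reading is the default, the looser one is available via
`strict = FALSE`. Single-concentration evidence (two set biomarkers at one
common concentration) yields a *weak* call. One positive set is
clastogen/aneugen, both is pan-genotoxic, neither is non-genotoxic.

## Benchmark-concentration modeling

**Trend prefilter.** A Williams-type trend statistic compares the isotonic
(pool-adjacent-violators, group-size-weighted) estimate of the highest-dose
mean against the control mean, standardized by pooled within-group variance;
both monotone orientations are evaluated and the larger magnitude kept
(whether the original procedure was one-sided is not documented, so the
orientation-max is used). Significance is by permutation,
$p = (1 + \#\{|t^*| \ge |t|\})/(1 + B)$, which is valid (never anti-
conservative) for any group sizes.

**Model family.** Seven continuous models are fitted by constant-variance
Gaussian maximum likelihood (equivalently least squares): exponential 2–5
($a e^{\pm bx}$, $a e^{\pm (bx)^d}$, $a[c - (c-1)e^{-bx}]$,
$a[c - (c-1)e^{-(bx)^d}]$), linear, quadratic, and restricted power
($a + b x^g$, $g \ge 1$). The quadratic carries the restricted-form
same-sign constraint on its dose coefficients so fits are monotone on the
tested range; an unrestricted quadratic can cross the benchmark band at
implausibly low doses through a local wiggle. Numerically, each model's
linear parameters are profiled out exactly and only the remaining one or two
nonlinear parameters are searched (golden-section or Nelder–Mead from
several starts), which is both faster and more robust than full black-box
optimization; shape parameters respect $d \ge 1$, $g \ge 1$.

The best model minimizes AIC = $2k - 2\ln L$ with $k$ = mean parameters + 1
for the variance. The BMC solves $|f(\mathrm{BMC}) - f(0)| = \mathrm{BMR}
\cdot \hat\sigma$ with BMR = 1 SD by default. $\hat\sigma$ is the
bias-corrected residual SD ($\mathrm{SSE}/(n - p)$): at the small $n$ of a
concentration series the ML variance is noticeably low and would drag every
BMC toward zero. Confidence limits are 2.5/97.5 percentiles of BMCs from a
nonparametric bootstrap resampling replicates within concentration and
refitting the selected model (250 refits by default; refitting only the
selected model rather than the whole family is a deliberate economy).
Fit adequacy is a lack-of-fit F test against the saturated group-means
model. A BMC that only exists beyond the top tested concentration is
retained but flagged; the integration stage substitutes it.

**Gene-set BMC.** Genes pass the prefilter when the Williams permutation
p < 0.05 *and* the maximal linear fold-change ($2^{|\Delta \log_2|}$ vs
control, either direction) is ≥ 1.5. Passing genes are fitted as above and
then removed when fit p < 0.1, BMC/BMCL ≥ 20, BMCU/BMC ≥ 20, or
BMCU/BMCL ≥ 40 (when several rules fire the reported reason follows that
order). The gene-set point estimate is the median surviving BMC; its 95%
interval is the 2.5/97.5 percentile of medians over 2000 bootstrap
resamples of the surviving BMC set.

**Flow endpoints.** Positive flow endpoints are modeled with the canonical
five-parameter exponential $y = a[c - (c-1)\exp(-(x/b)^d)]$ ($a > 0$,
$c \ge 1$, $b > 0$, $d \ge 1$) and a *relative* benchmark response: the BMC
solves $f(\mathrm{BMC})/f(0) - 1 = \mathrm{CES}$ (CES = 1.0 for %MN
induction, 0.5 for the DNA-damage biomarker fold-changes), with the closed
form $\mathrm{BMC} = b \, (-\ln\frac{c - 1 - \mathrm{CES}}{c-1})^{1/d}$
whenever the fitted plateau exceeds the target; otherwise the BMC is
undefined and flagged. The overall DNA-damage-assay BMC is the minimum over
its biomarkers (`lowest_bmc()`), the most conservative choice.

## Potency integration

Each compound-endpoint BMCL/BMCU pair feeds a slice; missing, infinite or
above-top values are substituted with 10,000 µM (the solubility-motivated
cap), and all inputs are capped there. Limits are −log10 transformed *and
then* summed — transform-then-sum versus sum-then-transform is a genuinely
open choice in slice scoring, but −log10 of a sum of concentrations has no
potency interpretation, so transform-then-sum is the default. The
substitution-only baseline (2 × −log10(10⁴) = −8) is shifted to zero so
inactive slices do not protrude, and each slice is divided by its maximum
across compounds, landing in [0, 1]. The overall score is the weighted slice
sum with default weights 1/3 (transcriptomic), 1/3 (MN) and 1/12 for each of
the four DNA-damage endpoints; custom weights are re-normalized. Score
confidence bounds come from deterministic rescoring with all-BMCL and
all-BMCU inputs against the same slice maxima (the bounds are what the data
provide; no resampling procedure is documented for them). Profiles are
clustered on their slice-score vectors (Euclidean, average linkage, k = 2 by
default, matching the two potency groups such screens typically resolve).

Scores are relative to the analyzed compound set: they are invariant to the
concentration unit only jointly with the substitution constant, and scores
from different compound sets are not comparable.

## What the synthetic generator emulates — and what it does not

`simulation_config()` fixes the study shape: a 64-gene panel, a 28-chemical
two-class reference set (14 DDI), 6-point expression series in duplicate
with six solvent controls per plate, 10-point flow series, a
5,000-nucleated-event stop gate, and 0.7% background MN. Responsive genes
split half up-/half down-regulated (exercising centroid sign handling);
DDI test compounds follow a saturating exponential dose-response on the
log2 scale with additive Gaussian replicate noise (SD 0.25 by default —
the distributional form of replicate noise is a modeling choice, not an
observed property); MN counts are Poisson (matching the downstream
regression); fluorescence intensities carry multiplicative log-normal noise
(they are positive by nature); p-H3/polyploidy events are binomial.
Viability decline curves are built in so that gating code paths are
exercised. Seeding is split per compound, so adding compounds to a
configuration never perturbs the ones already there.

Not emulated: raw reads or probe-level sequences, list-mode cytometry
events, plate-position or batch effects, correlated noise across genes, S9
metabolic-activation differences, and real biological heterogeneity of
dose-response shapes. Passing the simulation suite therefore demonstrates
the correctness and calibration of the *statistical machinery* under the
stated noise models, not performance on any real chemical.

## Validation design and numerical choices

The test-suite and acceptance studies use problem sizes chosen to make each
property measurable while keeping a full run inside a normal development
cycle: 100 simulated studies for classifier recovery (effect size six times
the noise SD), 500 simulated inactive compounds for MN null calibration,
50 replicate fits for BMC noise recovery, and 100 studies of 64 genes for
gene-set CI coverage (Williams permutations and per-gene bootstrap sizes
reduced to 40–60 and 20–25 in those loops; the medians they feed are
insensitive to these Monte-Carlo sizes).

Two design points deserve emphasis because they reflect genuine properties
of benchmark-dose methodology rather than implementation details:

* **The benchmark must sit inside the tested range.** When the true
  benchmark falls below the lowest tested concentration, every model
  extrapolates and the estimate inherits model-form bias (we observed
  medians of ~70% of truth in that regime). Recovery and coverage studies
  therefore place the true benchmark mid-series, consistent with standard
  benchmark-dose design guidance.
* **1-SD benchmarks are intrinsically noisy at small n.** The sampling error
  of $\hat\sigma$ alone contributes ~10% relative BMC error for duplicate
  wells; the parameter-recovery study states triplicate wells with six
  controls on the 10-point series, where the median relative error is ~13%.
  Lowest-AIC model selection also mixes in occasional linear fits whose
  benchmark is biased low on convex curves — visible in the gene-set median
  as a few-percent conservative (low) shift. Both effects are reported by
  the validation suite rather than corrected away.

Degenerate inputs are handled explicitly: flat dose-responses yield an
undefined, flagged BMC (never zero); a fully gated compound yields an
*undetermined* MN call; an empty surviving gene set yields an explicitly
empty result; equal NSC posteriors are unclassifiable; PC1 exactly zero is
non-DDI.

## A worked synthetic study

```{r, eval = FALSE}
cfg <- simulation_config(seed = 7)
es <- simulate_expression_study(cfg)
fl <- simulate_flow_study(cfg)

classify_tgxddi(es$training$matrix, es$training$labels, es$biomarker)$overall
mf <- compute_microflow_endpoints(fl$microflow)
call_mn(mf, "cpd_clastogen")
res <- run_study(cfg, tempfile("study"))
res$integrated
```

## Known limitations

* The published biomarker gene panel and reference-set data are not bundled;
  the classifier is generic over any labeled panel in the documented format.
* Confidence limits are bootstrap percentiles, not profile likelihood; with
  very few replicates the bootstrap understates tail uncertainty.
* The MoA caller consumes well-level summaries; no FCS parsing or gating.
* ToxPi scores are relative within an analysis; the package deliberately
  offers no cross-analysis score comparison.
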