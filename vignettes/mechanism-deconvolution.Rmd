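---
title: "Deconvolving dual PI3K / microtubule drug mechanisms from panel pharmacology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolving dual PI3K / microtubule drug mechanisms from panel pharmacology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moadecon)
```

## The problem

Some clinical kinase inhibitors carry a second, unrelated target
activity. The motivating case is a pan-PI3K inhibitor that also binds
the colchicine site of tubulin and destabilizes microtubules. The two
activities produce opposite cellular phenotypes — a cytostatic G1/S
arrest for PI3K inhibition versus a cytotoxic mitotic block for
microtubule destabilization (MDA) — yet both suppress proliferation, so
a plain viability IC50 cannot tell them apart. `moadecon` implements
the quantitative machinery to separate them:

1. variable-slope logistic dose–response fitting with an explicit
   ambiguity rule (`fit_sigmoid()`);
2. IC50-independent mechanism fingerprints across cell-line panels:
   Hill-slope tables, least-square penalty scores, relative-sensitivity
   profiles, pHH3 fold-change summaries (`hill_slope_table()`,
   `penalty_score()`, `sensitivity_profile()`, `phh3_fold_change()`);
3. target-engagement analysis at the growth IC50 and the
   therapeutic-window question (`engagement_at_growth_ic50()`,
   `therapeutic_window()`, `plasma_mean_concentration()`);
4. competitive-binding Kd derivation from TR-FRET tracer displacement
   (`binding_kd()`, `kd_from_ic50()`);
5. microtubule dynamic-instability statistics from kymograph event
   tables and turbidity dose–response (`catastrophe_frequency()`,
   `rescue_frequency()`, `turbidity_analysis()`);
6. per-nucleus high-content summaries: mitotic index, condensed DNA,
   DNA-content cell-cycle gating (`classify_phh3()`,
   `cell_cycle_fractions()`);
7. seeded synthetic-data generators emulating each assay
   (`gen_panel()`, `gen_nuclei()`, `gen_kymo_events()`,
   `gen_binding()`), so the full pipeline is testable without any
   proprietary plate data.

## The dose–response model

All readouts are fitted with the four-parameter logistic on the log10
concentration scale,

$$y(x) = \mathrm{bottom} +
  \frac{\mathrm{top}-\mathrm{bottom}}
       {1 + 10^{(\log_{10}\mathrm{IC}_{50} - \log_{10} x)\,h}},$$

with Hill slope $h < 0$ for readouts that fall with concentration. The
normalized three-parameter variant fixes top = 100 and bottom = 0 and
is used for readouts expressed as percent of vehicle (pPKB in-cell
westerns, tracer displacement, AlphaScreen activity). The full
four-parameter model (used for viability and activation readouts)
enforces top ≥ bottom by parameterizing the span.

**Optimizer.** Steep-slope objectives are multimodal, so the
Levenberg–Marquardt fit is multi-started over Hill magnitudes
{0.5, 1, 2, 4} (signed by the observed response direction; both signs
when the trend is unclear) and log-IC50 values at the quartiles of the
tested range. The lowest residual sum of squares wins; ties go to the
shallower slope, which is the conservative choice for mechanism
classification. Standard errors come from the Gauss–Newton curvature
at the optimum ($\hat\sigma^2 (J^\top J)^{-1}$).

**Ambiguity rule.** Slope-based classification must not use unreliable
slopes. A fit is `ambiguous` when (i) the optimizer fails from every
start, (ii) the relative standard error of the Hill slope exceeds 0.5,
or (iii) the fitted IC50 lies more than one log10 unit outside the
tested concentration range. The 0.5 relative-SE cut is the transparent
criterion we adopt for "high uncertainty of slope steepness"; the
one-decade rule catches curves whose midpoint was never sampled. A
cell line with an ambiguous fit for *any* drug is excluded from the
panel slope table for *all* drugs, so that penalty scores always
compare the same lines.

**Replicates** are fitted jointly as individual points rather than
averaged first; with homoscedastic noise the two give identical point
estimates, but joint fitting propagates the replicate scatter into the
standard errors used by the ambiguity rule.

## Mechanism fingerprints

Cytostatic PI3K inhibition produces viability Hill slopes near −1
(single-site occupancy translated proportionally into growth
inhibition); cytotoxic microtubule disruption produces steep,
switch-like slopes of −2 or beyond. The per-line penalty score for a
drug pair is the squared slope difference $(h_a - h_b)^2$, summed over
the retained panel. For 36 lines with MDA-class slopes
$\mathcal{N}(-3.0, 0.4)$ against PI3K-class slopes
$\mathcal{N}(-1.0, 0.2)$ the expected total is
$36\,(2^2 + 0.4^2 + 0.2^2) = 151.2$, far above the ~100 threshold that
separates unlike from like pairs, while two PI3K-class drugs give
$36 \cdot 2 \cdot 0.2^2 \approx 2.9$. The unnormalized sum is used; a
per-line mean would simply rescale the threshold.

Relative sensitivity profiles divide each line's IC50 by the
*arithmetic* panel mean for that drug, and rows are ordered by the
profile of a chosen reference drug, which makes mechanism-discordant
drugs visible as discordant orderings.

## Target engagement at the growth IC50

For each drug and line the engagement curves (pPKB inhibition for
PI3K; pHH3 induction for MDA, as percent of that drug's own maximal
pHH3 response) are evaluated at the concentration that halves
proliferation. The deconvolution logic rests on an asymmetry: a pure
PI3K inhibitor must engage its target almost completely (≈ 87–95%)
before proliferation halves, whereas a microtubule destabilizer needs
only a small fraction (≈ 13–28%) of its maximal mitotic-arrest
response. The therapeutic window for selective PI3K inhibition is the
interval between the concentration reaching the required PI3K
engagement (default 90%) and the concentration at which the tolerated
MDA effect (default 20%) is exceeded; `window_exists` iff the former
is lower. Mean plasma concentration is the steady-state average
AUC$_{0-24\mathrm{h}}/24$ h — the standard summary when only daily
exposure is published — and the per-line engagement summaries report
both s.d. and s.e.m. because published ± values are often ambiguous
between the two.

The 20 µM cap: when a drug produces no detectable increase in the
mitotic population, its pHH3 EC50 is undefined; by convention it is
set to 20 µM (just above the highest concentrations commonly tested)
so that EC50(pHH3)/IC50(pPKB) ratio tables remain computable and
conservative. In the pipeline a drug is a mitotic non-responder when
its fitted pHH3 induction is below a 1.5-fold rise over baseline or
the fit is ambiguous.

## Competitive binding

TR-FRET displacement plates are reduced to emission ratios
(665 nm / 620 nm after channel-wise background subtraction),
normalized to vehicle, and fitted with the normalized three-parameter
model. The displacement IC50 is converted to a dissociation constant
with the competition (Cheng–Prusoff-type) correction
$K_d = \mathrm{IC}_{50} / (1 + [\mathrm{tracer}]/K_{d,\mathrm{tracer}})$,
the standard correction for tracer-displacement designs. Final tracer
concentrations are the 3× stocks divided by three (equal-volume
three-component mix); tracer constants for the four class-I PI3K
isoforms are bundled in `pi3k_tracer_constants()`. An ATP-competition
term is deliberately omitted: the assay contains no ATP, so the
tracer-only correction is exact for this design. Note that a one-site
competitive displacement curve has unit Hill slope; fitted slopes far
from −1 indicate an assay problem, not cooperative binding.

## Microtubule dynamics

Kymograph event tables (one row per growth or shortening phase) are
filtered before any statistic: growth events shorter than 0.5 µm are
removed — the boundary is inclusive, an exactly-0.5 µm event is kept,
since the rule excludes events *shorter than* the resolution limit —
and so are events without a clearly observed start and end. Growth
rate is length/duration per event, averaged per movie (in vitro) or
per cell (cellular), then summarized across groups.

Two catastrophe estimators are exposed because the conventions are
genuinely different statistics. The in vitro estimator is the inverse
mean growth duration per movie, averaged over movies (per second); the
cellular estimator is the number of growth events divided by total
growth time per cell (per minute). Within a single group the two
coincide: $N/\sum t = 1/\overline{t}$. The per-event variant
mean$(1/t)$ is available (`per_event_inverse = TRUE`) but is *not* the
default: for exponential growth durations its expectation diverges
(it is dominated by the shortest events), so it cannot recover the
switching rate, whereas $1/\overline{t}$ is the maximum-likelihood
rate estimator. Rescue frequency is rescues per total shortening time.
Condition comparisons delegate to the exact two-sided Wilcoxon
rank-sum test on per-movie/per-cell summaries.

## High-content cytometry

pHH3 positivity uses the two-step rule — mean nuclear intensity above
one threshold *and* maximum intensity above a second — with border
nuclei excluded from both numerator and denominator (border exclusion
applies only here, where partial nuclei corrupt intensity features).
Default thresholds are the 99th percentile of vehicle-well
intensities, so vehicle wells score ≈ 1% positive. The condensed-DNA
call is a linear classifier on configurable features; the default pair
(intensity density up-weighted, nuclear area down-weighted) is a
stand-in for a screening platform's trained classifier and should be
re-weighted per campaign.

Cell-cycle gating anchors on the G1 (2N) mode of the integrated
DNA-intensity density and applies fixed gate ratios: sub-G1 < 0.6×,
G1 [0.6, 1.3), S [1.3, 1.7), G2/M [1.7, 2.6]; nuclei above 2.6× are
reported separately as >4N. The G1 mode is the leftmost prominent
density peak with a companion peak at roughly twice its position;
single-peaked distributions fall back to the global mode. This
mode-anchored scheme is scale-invariant (a global gain change cancels)
and assumption-light, at the cost of misassigning nuclei that drift
across a fixed gate; gate ratios are configurable. At least ~100
nuclei are needed for a stable mode estimate.

## What the generators emulate — and what they do not

Every generator is a pure function of (spec, seed); identical inputs
give bitwise-identical tables and the caller's RNG state is restored.

`gen_panel()` draws, per cell line, a shared lognormal sensitivity
factor (default log10 s.d. 0.25) applied to both mechanism arms plus a
small arm-specific jitter (0.05). The shared factor is deliberate:
real panels show correlated sensitivity across drugs — that
correlation is exactly what makes sensitivity profiles informative —
and it keeps a dual drug's two activities in a fixed ratio across
lines, as expected when both potencies are properties of the molecule.
Dual-mechanism viability composes the arms by response independence
(Bliss-type product of surviving fractions); the minimum-survival
alternative can be obtained by fitting the arms separately. The
default scenarios are:

* `pqr309_like` — pure cytostatic PI3K arm, growth EC50 1 µM, Hill −1;
* `mtd147_like` — pure cytotoxic MDA arm, growth EC50 1 µM, Hill −3
  (the center of the steep-slope class);
* `bkm120_like` — both arms, MDA growth arm at 0.9 µM just below the
  PI3K growth arm at 1.4 µM. These anchors mirror the published
  dual-drug observations: the proliferation IC50 (≈ 0.9 µM) is
  microtubule-driven, and near-complete PI3K engagement is reached
  only around 1.4 µM. With equal 1 µM arms the Bliss product fits to a
  composite slope of only ≈ −1.8 (the shallow arm flattens the global
  fit), which contradicts the steep slopes and MDA-dominated phenotype
  the dual drug actually shows; the asymmetric anchor reproduces both
  (composite slope ≈ −2.1, no selective window, window bounds in the
  ratio ≈ 1.4/0.8).

The engagement couplings are chosen so the deconvolution's asymmetry
holds by construction: the pPKB IC50 sits at 1/9 of the PI3K growth
EC50 (90% engagement exactly at the growth EC50 of a pure PI3K
inhibitor) and the pHH3 EC50 at 1.8× the MDA growth EC50 with Hill +2
(≈ 24% of maximal mitotic arrest at the MDA growth EC50, inside the
13–28% band).

`gen_nuclei()` mixes lognormal 2N and 4N DNA peaks (6% log-normal
width), an S-phase band between them, and a broad sub-G1 debris smear
(0.2–0.55× the G1 mode — a smear, not a peak, as apoptotic debris
appears in practice); dose shifts the composition toward G2/M + sub-G1
under an MDA spec and toward G1 under a PI3K spec. pHH3 intensities
are bimodal lognormals. `gen_kymo_events()` draws exponential growth
durations (the dynamic-instability switching model) and shortening
phases whose rescue probability encodes the rescue rate.
`gen_binding()` simulates tracer occupancy under the one-site
competitive model, so the displacement-fit → Cheng–Prusoff route can
be validated against a known ground truth.

What passing tests on these generators show is that the *analysis*
recovers the parameters of the stated statistical model at realistic
sample sizes and noise. They do not show robustness to features real
plates have and the generators lack: edge effects and spatial
gradients, heteroscedastic and non-Gaussian noise, compound
precipitation at high concentrations, segmentation errors upstream of
the nuclei table, pHH3 intensity that is correlated with DNA content,
or drug-death kinetics that violate response independence.

## Numerical choices and problem sizes

* Concentrations are handled internally in molar and on the log10
  scale; percent responses are never clipped before fitting.
* `invert_sigmoid()` refuses ambiguous fits and levels outside
  (bottom, top); engagement levels must lie strictly inside (0, 100).
* Ties in the multi-start are broken toward the shallower slope;
  degenerate flat curves therefore surface as ambiguous rather than as
  spuriously steep fits.
* The test suite sizes its simulations to what the statistics need,
  not more: 200 noiseless random curves for exact recovery, 500 noisy
  replicates for confidence-interval coverage (observed ≈ 93%),
  replicate-averaged event tables of 200–1,000 events for estimator
  consistency (the averaging over ~20–25 tables checks estimator
  *bias* at the stated sizes instead of betting a single draw against
  its own sampling noise), 1,000 replicate panels for the
  penalty-score discrimination, and 4-line panels for the end-to-end
  scenario signatures.

## Known limitations

* No plate-effect or edge-effect correction, and no 5-parameter
  asymmetric logistic; curves with genuinely asymmetric shoulders will
  show slope bias.
* The penalty score compares slopes only; two drugs with identical
  slopes but unrelated IC50 profiles score as "alike".
* The window report compares per-drug mean curves across lines; it
  does not model between-patient pharmacokinetic variability beyond
  the AUC average, nor protein binding.
* Cell-cycle gating assumes a detectable 2N mode; aneuploid lines with
  shifted ploidy need adjusted gate ratios.
* The kymograph interface starts at the event table; tracing (pixels
  to events) is upstream and out of scope.
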