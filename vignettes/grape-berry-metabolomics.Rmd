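---
title: "Rule-based MS2 annotation and profiling of grape berry metabolomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based MS2 annotation and profiling of grape berry metabolomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitimet)
```

## The problem

Untargeted LC-MS/MS profiling of grape berries yields thousands of metabolic
signals, most of them unidentified. Two compound families dominate the
interesting fraction of the berry metabolome and are amenable to rule-based
annotation from their fragmentation chemistry alone:

* **Modified flavonoids.** Flavonoids in planta occur mostly as derivatives:
  glycosylated, acylated, methylated. In positive-mode ESI, the glycosidic
  and ester bonds cleave preferentially, so the MS2 spectrum of, say, a
  flavonol diglycoside shows a *ladder* of fragments, each one sugar (or
  acyl group) lighter than the last, terminating at the protonated aglycone
  (the Y0+ ion). One hexose loss is the familiar [M+H−162]+ step; the
  pattern repeats for every residue.
* **Pentacyclic triterpenoids.** Oleanane-type triterpenoids give a
  characteristic core ion near *m/z* 457.4 ([M+H−glycosyl−H2O]+), a
  carboxyl-loss fragment near *m/z* 393.4, low-mass skeleton ions (203.2,
  189.2) and an isoprene series (119.1, 109.1, 95.1). The *presence* of
  this diagnostic set, not the precursor mass, marks the skeleton.

`vitimet` implements both rule engines over a small mass/registry core,
plus the downstream quantitative pipeline (normalization, differential
accumulation, nested ANOVA, ordination, presence intersections) and a
ground-truthed simulator so that every stage is testable without any
proprietary raw data.

## Mass arithmetic and the registry

All masses are monoisotopic, computed from a fixed internal isotope table;
ions are singly protonated even-electron species [M+H]+ with the proton at
1.007276 Da (the electron mass is accounted for; using the atomic mass of
hydrogen instead would bias every reconstruction by ~1 ppm at *m/z* 500).
Anthocyanidins natively ionize as [M]+ flavylium cations; because the ion
species of anthocyanin signals is ambiguous in practice, a `flavylium`
switch (default off) controls whether anthocyanidin aglycones are matched
at `M − m_e` instead of `M + m_H+`.

The registry ships as two editable CSVs (`inst/extdata/`): aglycones
(quercetin, kaempferol, isorhamnetin, myricetin, catechin, naringenin,
cyanidin, oleanolic acid) and modifications with their net formulas:
hexosyl C6H10O5 (162.0528), deoxyhexosyl C6H10O4 (146.0579), coumaroyl
C9H6O2 (146.0368), malonyl C3H2O3 (86.0004), acetyl C2H2O (42.0106), methyl
CH2 (14.0157), and the small losses H2O, CO, CH3·, OCH3· that occur below
the aglycone ion. Delta masses are *derived* from the formulas at load time,
never stored, so the two can not drift apart.

Coumaroyl and deoxyhexosyl are nominally isobaric (146 Da) but differ by
21 mDa; accurate mass resolves them at any realistic tolerance, and
`match_loss()` flags the result `ambiguous` whenever more than one registry
entry falls inside the window. The registry deliberately contains only the
moieties the annotation rules name. Extending it is supported but has a
real cost the curator must weigh: for example adding caffeoyl (C9H6O3)
creates an *exact* composite isobar (caffeoyl + deoxyhexosyl ≡ coumaroyl +
hexosyl, identical atoms), which no mass accuracy can resolve.

## Ladder decomposition

`decompose()` runs a depth-bounded search downward from the precursor.
Candidate Y0+ peaks are those matching a registry aglycone ion within the
fragment tolerance; if none match, every peak becomes a candidate with
aglycone `"unknown"` (the multiset of losses is still a useful claim).
Parent-to-child *m/z* differences are assigned registry losses; chains that
terminate at a Y0+ candidate become annotation candidates, scored as

> score = (matched ladder steps) − λ · mean |ppm error|,  λ = 0.1 by default

and ranked by confidence tier, then score, with deterministic tie-breaks
(fewer modifications, then lexicographic names), so repeated runs are
bit-identical.

Numerical choices that matter:

* **Error propagation for differences.** A neutral-loss mass inherits error
  from *both* measured ions. At 5 ppm ion accuracy, two ~450 Da ions can
  put ±4 mDa (±25 ppm!) on a 162 Da difference. Windows for loss matching
  are therefore evaluated on the summed ion masses,
  `max(ppm · (m_parent + m_child) · 1e−6, floor)`, and each step's reported
  ppm error uses the same scale. This keeps the per-step error bounded by
  the configured ppm tolerance and keeps the score penalty commensurate
  with one matched step — expressing the same few-mDa error in ppm of a
  small delta (14 Da for methyl) would make the penalty explode for
  perfectly good steps.
* **Tolerances.** Fragment matching defaults to 10 ppm with a 2 mDa floor;
  precursor reconstruction to 5 ppm. These reflect Orbitrap-class accuracy,
  consistent with 4-decimal printed masses.
* **Composite losses.** When an intermediate rung has dropped out of the
  spectrum, a parent-to-child difference spanning two or three losses is
  matched as a composite — but *only* when no peak sits at the intermediate
  position. This bridges broken ladders without double-counting evidence
  whose intermediate is present. A consequence worth knowing: tightening
  the tolerance can occasionally *reveal* an annotation, because a loose
  window may mistake a noise peak for the intermediate and suppress the
  bridge. The per-annotation ladder itself is still monotone: tightening
  never adds steps to a given annotation.
* **Tiers.** `rule_annotated` requires a known aglycone whose reconstructed
  precursor (formula sum + proton) agrees with the observed precursor
  within tolerance; `standard_confirmed` additionally requires a retention
  time match against an authentic standard within ±0.15 min (RTs are
  printed to 3 decimals in practice but no window is ever stated; 0.15 min
  is a typical UHPLC reproducibility bound). Everything else is `partial`.
* **What is claimed.** The primary claim is the aglycone plus the
  modification *multiset*. Attachment positions (3-O vs 7-O) are never
  inferred from the ladder — positional isomers fragment identically — and
  are only implied when a standard upgrades the tier.

## Oleanane classification

`classify_skeleton()` matches each diagnostic ion to the nearest unclaimed
peak (one peak, one rule). A spectrum passes when both required ions (457.367
core, 393.351 carboxyl loss) and at least two optional ions match. The
required-plus-two-optional threshold balances sensitivity against the
false-positive rate on non-triterpenoid spectra (measured ≤ 1% in the seeded
simulations). The core → carboxyl-loss spacing is encoded once as a fixed
64.0163 Da ion-level constant (the 457.3676/393.3513 pair difference); the
rule is stated at the ion level, not mechanistically. The classifier keys on
fragment ions rather than the precursor because for aglycone-only spectra
the glycosyl-loss step is vacuous (the precursor already *is* the core ion).
Matching uses a 20 ppm / 5 mDa window — wider than ladder matching because
rule targets are quoted at millidalton precision, so the window must cover
quoting precision plus instrument error. Ursane, lupane and friedelane rule
sets ship as named empty stubs: the skeleton classes are recognised, but no
diagnostic ions are specified for them, so they are configuration extension
points that never pass.

## The quantitative pipeline

* **Internal standard.** Every feature is divided by its sample's spiked
  lidocaine response (IS row removed afterwards). This removes per-sample
  injection/response factors exactly — by construction in the simulator,
  and to numerical precision in the tests.
* **Z-scoring** is per feature (mean 0, SD 1); constant rows cannot be
  scaled and are set to zero and flagged rather than dropped silently.
* **DAM screening** is a per-feature two-sample Student's *t*-test in its
  classical pooled-variance form (Welch is a switch), called significant at
  raw p < 0.05. No multiple-testing correction is applied by default —
  the screen is deliberately a *screen* — but Benjamini–Hochberg adjusted
  p-values are reported alongside when asked for. Zero-variance features
  get t = 0, p = 1 when means agree (and p = 0 otherwise) instead of an
  error.
* **Nested ANOVA** decomposes each feature as color → variety-within-color
  → residual from the explicit sums-of-squares formulas. The color effect
  is tested against the variety-within-color mean square (varieties are the
  sampled units within a color; testing against the residual would
  pseudo-replicate), which is why this is hand-computed rather than read
  off `aov()` — `aov()`'s sequential sums of squares serve as an
  independent cross-check in the test suite.
* **Presence intersections.** A feature is present in a color if it exceeds
  the presence floor in ≥ 1 sample of that color; exclusive (UpSet-style)
  counts over the 4-set system partition the features present anywhere. The
  floor defaults to the imputation floor (half the feature's minimum
  positive value for missing cells), since no detection threshold is ever
  stated.
* **PCA** is column-centered SVD with samples as observations, run on
  Z-scored features by default — an explicit correlation-PCA choice, since
  covariance vs correlation is otherwise left open.
* **HCA** defaults to correlation distance (1 − Pearson) with average
  linkage on Z-scored features — the common metabolomics convention; both
  are configurable, and the dendrogram exports as Newick.

## What the simulator emulates — and what it does not

`sim_config()` defaults encode the study conditions: four berry colors over
66 varieties (17/16/16/17) with 3 biological replicates (198 samples),
Gaussian 5 ppm *m/z* jitter on every ion, 5 uniform noise peaks per
spectrum, 10% ladder dropout (the Y0+ terminus always survives), log-normal
base abundances (SD 1 log-unit around 1e4), per-sample injection factors
(log-SD 0.2) removed exactly by the IS feature, 20% replicate CV, and a
class-enrichment matrix planting the expected accumulation pattern: purple
berries 4× enriched in acylated flavonoid glycosides and triterpenoids, 2×
in diglycosides, with milder red/pink enrichment. Noise peaks avoid ±3×
tolerance windows around true peaks so that recovery failures measure
search behavior rather than label noise; a `hostile_noise` switch disables
the avoidance for stress testing. Fragment intensities decay exponentially
down the ladder; the engine ignores intensity (the annotation logic uses
only *m/z* differences), so the intensity model exists to validate future
intensity-aware scoring, not current behavior.

Passing tests on this simulator demonstrate the *mechanics*: ladder
recovery at realistic mass error, diagnostic-ion specificity, calibrated
type-I error, exact variance decompositions, planted-structure recovery.
They do not demonstrate performance on real chromatograms: co-eluting
isomers, in-source fragmentation, isotope envelopes, adducts other than
[M+H]+, and vendor peak-picking artifacts are all outside the simulation,
and population-level counts from the original study (signal counts,
variance fractions, per-color unique features) depend on raw data that was
never deposited, so they are not reproduction targets.

Problem sizes in the shipped tests and scripts (300–500 spectra for
recovery and oracle-equivalence checks, 10,000 features for the null
calibration, 150–400 compounds in the pipeline rehearsals) were chosen so
each check has enough resolution for the thresholds it asserts.

## Known limitations

* C-glycosides (cross-ring 0,2X cleavages) and lactonization rules are not
  modeled: no diagnostic masses are specified for them.
* Oleanolic vs ursolic acid are isomeric and spectrally indistinguishable
  here; only a standard's retention time separates them.
* The search is exact only up to the configured depth (4 modifications);
  heavily decorated glycosides beyond that are reported as `partial`.
* Quantitation assumes a linear calibration; weighting and saturation are
  out of scope.
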