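---
title: "Annotating CID fragments in full MS/AIF data: methods and design"
author: "aifrag authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating CID fragments in full MS/AIF data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aifrag)
```

## The measurement model

A full MS/AIF experiment alternates two scan types on one chromatographic
time axis: an unfragmented MS¹ scan and an all-ion-fragmentation (AIF)
MS² scan in which *every* ion is collisionally dissociated, with no
precursor isolation.  Two physical facts carry the whole annotation
method:

* **Shared elution.** Fragmentation happens after the column, so a true
  CID fragment inherits its precursor's elution profile exactly.  The
  precursor's profile is best read from the MS¹ channel (no
  fragmentation losses), the fragment's from the AIF channel (highest
  fragment intensity).
* **Conserved atoms.** A fragment ion is a sub-multiset of its
  precursor's atoms.  Any element or count exceeding the precursor's
  rules the candidate out.

`aifrag` operationalizes both, plus a third evidence source — the
isotopologue envelope, which fingerprints the elemental composition —
into a per-precursor pipeline: precursor formula from MS¹, fragment
candidates from the AIF scans at the precursor apex, shape filter,
fragment formula prediction, subformula filter, neutral losses, and a
quasi-isolated MS² spectrum.

## Peak-shape similarity

Two traces are compared by the area between their normalized forms,

$$A(x_1, x_2) = \frac{1}{T}\int_{t_0}^{t_0+T}
  \left|\hat x_1(t) - \hat x_2(t)\right|\,\mathrm{d}t,$$

where $\hat x$ is the trace scaled to unit apex height and $T$ the
retention-time window length.  Choices the metric needs (none of which
are dictated by the underlying idea, so they are fixed here as package
conventions):

* **Normalization is max→1**, not unit area: the comparison is of
  *shapes* at a glance, and an intensity-scaled copy of a trace must
  compare identical (the metric is invariant to uniform scaling of
  either input).
* **Shared grid.** MS¹ and AIF scans interleave, so their time stamps
  never coincide; both traces are linearly interpolated onto 200 uniform
  grid points spanning the window and integrated by the trapezoid rule.
  Outside a trace's sampled range its boundary value is held.
* **Division by $T$** makes the threshold independent of the window
  length and scan rate.  $A \in [0, 2]$; identical shapes give 0,
  non-overlapping unit peaks approach the summed peak areas over $T$.
* **Threshold.** Default 0.15, configurable — the right value depends on
  the XIC noise of the instrument.  For reference: two equal-width
  Gaussians 3σ apart in a 1-min window with σ = 0.05 min score ≈ 0.22
  and are rejected.

The window (`rt_window`, default ±0.5 min around the peak-list entry) is
also used, centered between two precursors, when deciding whether two
peak-list entries co-elute indistinguishably; keeping the window length
equal to the fragment filter's preserves the threshold's meaning.  An
earlier draft compared co-elution over the union of both windows, which
dilutes $A$ by a larger $T$ and let fully separated peaks pass — a trap
worth documenting.

## Fragment candidates

Candidate fragment masses are read from the AIF scan nearest the
precursor's apex plus its two neighbors (not from every scan — early
rejection is what makes the pipeline fast), keeping centroids above
`min_fragment_intensity` (default 1000 counts) and at or below the
precursor m/z.  Duplicates within the extraction tolerance merge to
their intensity-weighted mean.  Two classes of centroids are removed
because they are not independent fragment masses:

* the precursor's own residual peak (it gets the `precursor` role in the
  quasi-MS² instead), and
* **isotopologue satellites**: centroids one or two isotope spacings
  above a stronger candidate.  The spacing intervals
  $[0.9960, 1.0055]$ and $[1.9930, 2.0100]$ u cover ¹⁵N through ¹³C and
  ³⁴S through ¹³C₂ but deliberately stop short of the one- and
  two-hydrogen spacings (1.0078, 2.0157 u), so genuine fragment pairs
  differing by H or H₂ — common in CID — are never conflated with
  isotope peaks.

The shape filter runs *before* any formula work; only shape-passing
masses are ever enumerated.

## Formula prediction and the second-isotopologue rule

For a measured m/z, all formulas within ±15 ppm over the element ranges
C 0–50, H 0–100, N 0–5, O 0–20, S 0–3, I 0–2 (P available but disabled
by default) are enumerated; the ranges cover typical ESI(−)
organic-aerosol constituents below m/z 400 while keeping enumeration
instantaneous.  All ions are treated as singly charged; in negative mode
formulas are [M−H]⁻ *ion* formulas and one electron mass is added to the
atomic sum.  XIC extraction uses a tighter 5 ppm, since extraction works
on measured masses rather than candidate theory.

Each candidate is scored by three clamped linear terms minus the
optional penalty:

$$S = w_m\max\!\left(0, 1-\tfrac{|\delta_\text{ppm}|}{15}\right)
    + w_i\max\!\left(0, 1-\tfrac{e_\text{iso}}{0.5}\right)
    + w_s\max\!\left(0, 1-\tfrac{A_\text{iso}}{0.3}\right) - P,$$

with unit weights by default.  $e_\text{iso}$ is the relative deviation
of the measured second-isotopologue/monoisotopic apex ratio from theory;
$A_\text{iso}$ the area between the second-isotopologue XIC and the
reference (precursor) trace.  The functional form and weights are this
package's own convention — simple, monotone in each error, and
penalty-additive.  Apex intensities (not peak areas) feed the ratio;
areas would average over the tails where noise dominates.

The decisive rule is rejection: **a candidate without a found second
isotopologue is discarded, and if no candidate survives the prediction
is "none"** — exact mass alone produces too many false positives to be
reported.  "Found" is quantitative, in three parts:

1. the isotopologue trace's apex must exceed `iso_detection_k` (3) times
   the median absolute deviation of that trace in the window,
2. the measured intensity ratio must lie within ±50 % of theory
   (`iso_ratio_max = 0.5`) — with a relative error, a near-zero
   measurement always has error just below 1, so a clamp of 1 could
   never reject an *absent* isotopologue; 50 % agreement is the usual
   isotope-pattern-matching practice, and
3. the trace must co-elute with the reference
   ($A_\text{iso} \le$ `iso_shape_max` = 0.3; twice the fragment
   threshold, since isotopologue traces are an order of magnitude
   weaker and noisier).

Without parts 2 and 3, about 1 % of simulated runs with the second
isotopologue deleted still produced a formula through a lone noise
centroid at a candidate's +1 m/z; with them, the no-prediction behavior
is exact across all tested seeds.

Formulas built only of monoisotopic elements (I, P) have no second
isotopologue to verify; they are scored on mass error alone.  This is
what lets a bare iodide fragment of an iodinated aromatic acid be
annotated at all.  Ties break by score, then smaller |ppm|, then fewer
heteroatoms.

Theoretical envelopes come from convolving per-element natural-abundance
distributions (values pinned in the package for offline
reproducibility), aggregated into nominal-mass-offset bins whose fine
structure (¹³C vs ²H vs ¹⁷O…) is centroided by abundance weighting — the
same collapse a centroiding instrument performs at moderate resolution.

## Plausibility heuristics

An optional punishment score adds a fixed weight per violated
composition rule: RDBE ∈ [−0.5, 40] (RDBE = C − H/2 + N/2 + 1;
half-integers are normal for even-electron anions), H/C ∈ [0.1, 3.1],
O/C ≤ 3, N/C ≤ 2, S/C ≤ 1, P/O ≤ 1/3.  Carbon-ratio rules are skipped
for carbon-free ions (e.g. the SO₃⁻ fragment of sulfonic acids).  The
check is off by default: the isotopologue gates already control false
positives, and hard heuristics would bias against unusual but real
aerosol constituents.

## The simulator: what it emulates and what it does not

`simulate_run()` is the package's ground-truth generator, not a physics
model.  It emulates exactly the features the pipeline relies on:
alternating MS¹/AIF scans (one scan per second by default, so each
channel samples every 2 s), Gaussian elution (default σ = 0.05 min,
apex height 10⁶ counts for precursors), isotopologue envelopes planted
from the same pinned abundances, fragments sharing the precursor profile
with configurable yields, a residual precursor in the AIF channel (30 %),
retention-shifted decoys, optional +O/+2O co-eluting artifacts, 1 ppm
Gaussian mass jitter, a Gaussian intensity-noise floor with a
shot-noise-like $\sqrt{I}$ term, and ~10 random noise centroids per
scan with exponentially distributed intensities (mean 50 counts).

It does **not** model peak tailing or fronting, gradient-dependent
retention, detector saturation, ion suppression, or chimeric
fragmentation chemistry.  Passing tests on simulated data therefore
demonstrate that the *algorithmic* chain — extraction, shape metric,
enumeration, isotopologue gates, subformula logic — is correct under the
stated measurement model; they do not certify performance on real
chromatography, where the shape threshold and noise-dependent gates must
be tuned to the instrument (the configuration is designed to be set once
per instrument and reused).

A built-in fixture, `standard_mix_compounds()`, encodes the ion formulas
and observed AIF fragment sets of a 28-compound ESI(−) standard mixture
(nitroaromatics, aromatic and aliphatic acids, methoxyphenols, sulfonic
acids, an iodinated acid; one compound has no assignable formula and is
skipped, leaving 27 simulated ions).  Its simulated re-annotation is the
package's desk-scale re-enactment of a standard-mixture validation; the
problem sizes used throughout the tests and the acceptance script —
2-minute single-compound runs, an 11-minute 27-compound run, 100-seed
trial loops — were chosen so the full validation completes in well under
a minute on a laptop while still exercising every code path.

## Numerical and degenerate-input conventions

* Retention times are minutes everywhere, converted on mzML read.
* Centroided data only; profile spectra are an error, never silently
  centroided — the shape and intensity semantics assume centroids.
* All MS-level-2 scans are AIF; isolation windows, if present, are
  ignored with a warning.  Stepped collision energies are pooled into
  one channel and kept as metadata.
* An all-zero XIC cannot be normalized (error); a precursor absent from
  MS¹ yields a flagged result, not an exception; a run without AIF scans
  yields zero fragments plus a flag.
* Enumeration output is deterministically ordered (ascending |ppm|,
  ties by lexicographic counts); summary tables are byte-identical
  across reruns — the pipeline itself has no randomness.
* Shape-passing masses that fail formula prediction are *retained* in
  the results as unannotated and appear in the quasi-MS² in the
  unannotated role: information preservation over strictness.
* Coeluting precursors with indistinguishable shapes sharing a
  compatible fragment get the fragment annotated on **both** results
  with `ambiguous = TRUE` — no intensity-ratio deconvolution is
  attempted; good chromatography is the real fix.
* The quasi-MS² uses the single apex AIF scan, not an average over the
  peak: averaging would blend in neighbors' fragments at the peak edges.
* Van Krevelen / OSc summaries neutralize [M−H]⁻ formulas by adding one
  H (configurable off); OSc = 2·O/C − H/C.

## Known limitations

* Only singly charged ions and ±H adducts; no multimers, no Na/K/Cl
  adducts, no multiply charged species.
* No database or spectral-library lookup, by design: results stay
  unbiased toward catalogued chemistry, at the cost of leaving
  low-intensity ions (second isotopologue below the gates) without a
  formula.
* The candidate de-isotoping windows assume spacings characteristic of
  C/H/N/O/S/I chemistry; exotic elements would need new intervals.
* Coelution ambiguity is detected between peak-list entries only;
  an unlisted coeluting compound can still contribute foreign fragment
  masses (they survive only if they also pass the subformula test
  against the listed precursor).
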