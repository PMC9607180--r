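---
title: "Quantifying deviations between CBCT facial shells and smartphone depth-sensor scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying deviations between CBCT facial shells and smartphone depth-sensor scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Facially driven orthodontic planning needs accurate 3D models of the
facial soft tissue. Structured-light depth sensors on consumer
smartphones promise cheap, non-ionizing face scans, but their clinical
accuracy must be judged against a reference geometry — typically an
open "face shell" segmented from cone beam CT (CBCT) of the same
patient. `facedev` implements the full measurement chain for such
paired-mesh studies:

1. **Superimposition** — rigid registration of the scan onto the shell,
   seeded by expression-stable landmarks and refined by trimmed ICP
   restricted to expression-stable surface regions (forehead, temples,
   nasal bridge and tip, cheekbones).
2. **Deviation mapping** — per-vertex *absolute* distance between the
   aligned surfaces, displayed with a 3 mm cap, exported as PLY/CSV
   heatmaps.
3. **Regional classification** — aggregation over a 23-region facial
   atlas, a four-interval clinical scale, and a strict `> 3 mm`
   clinical-relevance flag per region and subject.
4. **Cohort statistics** — sex-stratified 2x2 contingency tables with a
   self-contained two-sided Fisher's exact test, and a Friedman rank
   comparison of seven lateral-profile sites.

Because no mesh data ship with studies of this kind, the package also
contains a first-class synthetic-face generator that produces paired
shell/scan meshes with *known* ground truth, so every stage — and the
pipeline end to end — is validated by parameter recovery rather than by
eyeballing.

## The measurement model

Let $S$ be the scan mesh and $R$ the reference shell, both in mm. The
deviation at scan vertex $p$ is

$$ d(p) = \min_{q \in R} \lVert T p - q \rVert $$

where $T$ is the rigid transform estimated by registration. Sign
(inside/outside) is deliberately discarded; the clinical question is the
magnitude of disagreement, not its direction. Two validity rules guard
against non-overlap artifacts: a vertex is *invalid* when its closest
point lies on the shell's open boundary (the shell is cropped at the
forehead and jaw; distances to a cut edge measure missing data, not
anatomy) or when $d > 10$ mm (far above any plausible soft-tissue
difference). The raw distance feeds classification; the 3 mm cap applies
only to display values, because a capped statistic could never
distinguish 3.1 mm from 30 mm while the clinical scale is open-ended
above 3 mm.

The clinical scale partitions $[0, \infty)$ into $\{0\}$, $(0,1]$,
$(1,3]$ and $(3,\infty)$ with approximation values 0, 0.5, 2 and 4 mm.
Boundaries belong to the lower interval: "greater than 3 mm" is strict,
so a deviation of exactly 3 mm is *not* clinically relevant.

A region's statistic is the **95th percentile** of raw deviations over
its valid vertices. The underlying study records only whether a
deviation "was present" per region; a mean would dilute focal defects
and a maximum is a one-vertex spike detector, so the 95th percentile is
the robust middle ground (exposed as `flag_prob` in `run_config()`).
Regions with fewer than 20 valid vertices are *unassessable* and are
excluded pairwise from cohort statistics rather than imputed — cropped
foreheads are the common cause, mirroring practice where artifact-laden
forehead data is simply missing.

## Registration

Coarse alignment is a Kabsch fit on six landmarks (glabella, left/right
temple, pronasale, left/right zygion) — a deterministic replacement for
the manual pre-positioning a human operator performs. Refinement is
trimmed ICP:

* correspondences run from the scan vertices lying in the alignment-mask
  regions to closest points on the full shell surface;
* correspondences whose closest point lies on the shell's boundary are
  rejected (edge suction is the classic open-shell ICP failure, and also
  the signature of crop non-overlap);
* the worst 10% by distance are trimmed, emulating the exclusion of
  marginal/artifact areas;
* the rigid update minimizes the **point-to-plane** error of the
  survivors (Gauss–Newton on the linearized motion, rotation rebuilt by
  Rodrigues' formula), while convergence and reporting use the
  point-to-point RMS (tolerance 1e-4 mm, at most 100 iterations). An
  iteration that would increase the RMS is rolled back, so the reported
  RMS sequence is non-increasing by construction.

The point-to-plane step is a deliberate design choice: point-to-point
updates have almost no gradient against tangential sliding on smooth
facial surfaces, and in testing they stalled millimetres apart from
jittered starts after 100 iterations. Point-to-plane converges in a
handful of iterations and passes all recovery tolerances
(noise-free misalignments of up to 10 degrees / 10 mm recovered to
< 0.05 mm mean surface displacement at default resolution). The
least-squares step uses an SVD pseudo-inverse so that degenerate
directions (a rotationally symmetric target) receive *no* update
instead of an unstable one.

`dual_operator_check()` emulates the study design in which two
independent operators repeat the superimposition: ICP is re-run from
jittered initializations and the spread of the results is reported.
Agreement requires both (a) per-region 95th-percentile deviations to
agree within 0.1 mm across restarts and (b) the converged transforms to
agree within 1 mm of surface displacement. Criterion (b) exists because
for a rotationally symmetric surface every rotation yields the *same*
deviation field — (a) alone would happily declare agreement while the
alignments disagree by many millimetres; the transform-spread check
flags exactly this degeneracy.

## The synthetic world

The generator (`generate_face()`, `derive_pair()`, `simulate_cohort()`)
emulates the features of real shell/scan pairs that drive the analysis,
and nothing more:

* **Geometry** — a height field over an ellipsoidal base (140 x 180 x
  60 mm) with Gaussian bumps and depressions for the nose, lips, chin,
  brow, cheekbones, orbital sockets, temporal fossae and the
  nasolabial/mentolabial grooves. It is *not* anatomically realistic;
  what matters is that all 23 named regions exist with controllable
  convexity class, because scan error is modelled as
  concavity-dependent.
* **Resolution mismatch** — the shell keeps the full grid (default 140
  vertices per axis); the scan resamples the same surface at half the
  axis resolution, i.e. ~25% of the faces, mirroring the visibly coarser
  polygon resolution of app-exported scans.
* **Scan error** — per-vertex displacement along the normal,
  zero-mean Gaussian with sd `0.15 + 0.3 * concavity` mm (concavity =
  normalized positive part of the height-field Laplacian). The range
  matches reported smartphone-scan accuracies of roughly 0.5–1.4 mm and
  encodes the observation that concave structures (orbits, mentolabial
  sulcus) scan worse than prominences.
* **Injected defects** — per-region offsets along vertex normals,
  recorded exactly in the returned ground truth. Defect amplitudes are
  drawn from U(4, 8) mm, non-defect regions from U(0, 1) mm, so the
  `> 3 mm` flag is unambiguous. Offsets above 10 mm are rejected
  (self-intersection risk).
* **Artifacts** — optional removal of the top fraction of the frontal
  region (the cropped, artifact-laden upper forehead of CBCT shells) and
  an eyelid-mismatch toggle that adds a 4 mm orbital offset (closed eyes
  during CBCT vs open eyes during scanning — the dominant cause of
  orbital disagreement).
* **Cohort** — defaults to 19 men and 41 women; per-region defect
  probabilities default to the published reference cohort's observed
  rates (`reference_cohort_rates()`). Scan intervals are sampled on 0–10
  days and expression/artifact QC flags at 95% pass rates so that the
  `interval < 7 days` / neutral-expression / artifact-free filter has
  genuine exclusions to perform. Each subject uses seed substream
  `seed + index`, so growing the cohort never reshuffles existing
  subjects. Because R initializes the Mersenne–Twister state from the
  seed with an LCG, streams from consecutive seeds are correlated in
  their first draws; every substream is therefore re-seeded from one
  tempered MT output before use (and replicate cohorts should still
  space their master seeds by more than the cohort size so substream
  ranges never overlap).

What a green recovery test establishes: the measurement chain is
unbiased at the ~0.1 mm level and flags exactly the regions whose true
offset exceeds 3 mm. What it cannot establish: behaviour on real
anatomy, texture-driven scanner failure modes, or non-rigid expression
change — those are outside the simulator's vocabulary by construction.

## Statistics

`fisher_exact_two_sided()` computes the exact min-likelihood two-sided
p-value (sum of hypergeometric probabilities of tables no more probable
than the observed one, with a 1e-7 relative slack at ties), in log space
via `lchoose`. `friedman_test()` uses within-subject mean ranks and the
standard tie-corrected chi-square on $k-1$ degrees of freedom; subjects
with any unassessable site are dropped listwise (complete blocks). Both
are cross-checked in the test suite against independent enumeration
oracles and against the corresponding `stats` implementations. The
per-site value ranked by the Friedman comparison is the same
95th-percentile statistic used for flagging — the source material never
states which per-site quantity was ranked, so the package declares one
and uses it consistently. No multiple-testing correction is applied
across the 23 regions by default (mirroring unadjusted reporting at
alpha = 0.05); a Holm option exists.

A note on reproducing published p-values: the printed Fisher column of
the reference study is internally inconsistent (a region with zero flags
in both sexes prints p = 0.365, where any exact test gives 1.0), so the
package's validation targets are the reconstructed counts and
percentages, which do reproduce exactly, and property-based checks of
the test implementations — not the printed p-values.

## Numerical choices

* STL welding tolerance 1e-6 mm (grid rounding; far below sensor
  precision). STL coordinates are float32, so a write/read roundtrip
  quantizes at ~1e-5 mm for head-sized coordinates — irrelevant at
  clinical scales, but the reason bundle atlases are renumbered to the
  post-roundtrip vertex order.
* Closest-point queries use a longest-axis median-split AABB hierarchy
  with deterministic tie-breaks; the test suite proves equality with
  exhaustive per-triangle minimization to 1e-9 mm.
* Kabsch rejects reflections by sign-correcting the smallest singular
  vector and refuses collinear configurations.
* Degenerate (zero-area) faces are dropped with a message rather than
  an error — segmentation-derived shells commonly contain slivers.
* Quantiles are type-7 (R default). Determinism everywhere: a fixed
  seed yields byte-identical cohort tables.

## Known limitations

* The synthetic face is a smooth parametric stand-in; regional
  vertex counts, not likeness, are calibrated.
* Rigid registration only — by design, as the procedure under study is
  rigid; non-rigid residuals (expression drift) appear as deviation.
* The aesthetic/harmony-line analysis mentioned in the source material
  has no stated procedure and is intentionally not implemented.
* At coarse test resolutions (grid 60) decimation faceting biases
  registration by ~0.15 mm; the default resolution (140) keeps it below
  0.01 mm. Scaled-down tests state this where it matters.
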