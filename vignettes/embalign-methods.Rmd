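---
title: "Ensemble co-optimization for naming embryonic nuclei across imaging modalities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble co-optimization for naming embryonic nuclei across imaging modalities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embalign)
```

## The problem

A *C. elegans* embryo at late developmental stages contains several hundred
nuclei whose identities are known, cell by cell, from the invariant lineage.
Fluorescence microscopy (FM) time series can be lineage-traced, so every
nuclear centroid in an FM embryo carries a name.  A volume electron
microscopy (EM) dataset of an embryo at the same stage shows the same nuclei
as anonymous points.  `embalign` transfers the names: given a few labeled
clouds ("ensemble members") and one anonymous cloud, it returns an identity
and a confidence flag for every anonymous landmark.

Both kinds of data enter the pipeline as `landmark_cloud` objects — 3D
centroid positions in micrometres, with names and a time stamp (minutes
post first cleavage) when available.

## The model

Three ideas carry the method.

**Structural constraints from an ensemble.**  Cell contacts are approximated
by the Gabriel graph of the nuclear centroids: two landmarks are adjacent
iff the open ball having their connecting segment as diameter contains no
third landmark (a subgraph of the Delaunay graph, and a standard contact
proxy when membranes are not segmented).  An adjacency present in *every*
labeled member — a *consistent adjacency* — is treated as a structural
constraint that a correct labeling of the anonymous cloud should reproduce.
`consistency_profile()` reports the full edge-frequency spectrum; the
consistent set is its frequency-1 slice.

**Inconsistent landmarks and co-optimization.**  Samples at nominally the
same stage differ in developmental timing (heterochrony), so cells that
divide or die near the stage time may be present in one sample and absent
in another.  These cells are compiled from a lineage-event table within the
model's temporal window (13 min by default, centered on the stage time).
Each such event generates explicit hypotheses about the anonymous sample:
a dying cell may already be gone (*remove-death*), an observed division may
not have happened yet (*merge-daughters*, placing the parent at the
daughters' midpoint), a pending division may have already happened
(*split-parent*, two daughters at the parent's exact position — no
division-axis prior, which would add complexity without preventing the
cascading errors the modification is meant to stop).  A greedy sweep tries
the hypotheses in a fixed order (divisions before deaths, each group in
lexicographic subject order) and keeps a modification iff it lowers the
total number of missing consistent adjacencies by at least the acceptance
threshold (3 by default).

**Matching with iterative error correction.**  Given a (possibly modified)
labeled cloud and the pre-aligned anonymous cloud, matching is a linear
assignment problem minimizing total Euclidean distance (a hand-written
shortest-augmenting-path solver in C++; rectangular instances leave the
excess side unmatched).  The resulting labeling is scored by counting
missing consistent adjacencies; each missing edge is charged to both
endpoint identities.  The individually worst identity — the one with the
most missing expected adjacencies — is then made impossible (its current
pair is given effectively infinite cost) and the LAP is re-solved.  After
200 such iterations per hypothesis (1400 after the final sweep), the
assignment with the lowest violation total seen is kept, ties broken by
smaller total distance.

Per-member answers are combined by a plain vote; a landmark is *confident*
when the winner reaches a 75% supermajority of the votes cast (abstentions
from unmatched landmarks leave the denominator, otherwise confidence would
be unreachable whenever members differ in size).  No uniqueness is enforced
across landmarks — forcing unique names was found to reduce accuracy, and
duplicated names are themselves a useful error signal.  One *reiteration*
round follows: a fresh thin-plate-spline alignment is fitted from the
confident matches in place of the original pre-alignment, and matching plus
co-optimization is repeated for the uncertain landmarks only, with
confident identities frozen and reinserted during constraint evaluation.

## Pre-alignment

The anonymous cloud is warped into each member's frame in two steps:

1. a landmark fit from a small manual correspondence table — affine least
   squares (at least 4 pairs) or a 3D thin-plate spline with the
   biharmonic kernel $U(r) = r$ (at least 5 pairs; `prealign_mode` in the
   configuration);
2. correspondence-free coherent point drift (CPD): a Gaussian-mixture EM in
   which the source points move through a kernel-regularized displacement
   field, so nearby points move similarly.

Two numerical points deserve a note.  For the 3D kernel $U(r) = r$, the
kernel matrix projected onto the complement of the affine polynomials is
negative definite, so the smoothing ridge must be *subtracted*
($K - \lambda I$); the textbook $K + \lambda I$ form crosses a singularity
at intermediate $\lambda$ and produces exploding warps.  The fit is solved
in the null-space (QR) form, which stays well conditioned for any
$\lambda$, interpolates exactly at $\lambda = 0$, and converges to the
affine least-squares fit as $\lambda \to \infty$ (both limits are asserted
in the test suite).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `window_minutes` | 13 | temporal window of the ensemble model (min) |
| `accept_threshold` | 3 | minimum violation drop to keep a modification |
| `correction_iters_inner` | 200 | correction iterations per hypothesis |
| `correction_iters_final` | 1400 | correction iterations after the sweep |
| `supermajority` | 0.75 | vote fraction for a confident identity |
| `reiteration_rounds` | 1 | confident-match TPS re-alignment rounds |
| `tps_lambda` | 0.1 | TPS smoothing (unitless, kernel-scaled) |
| `cpd_beta`, `cpd_lambda` | 3, 10 | CPD kernel width / stiffness |
| `cpd_outlier_weight` | 0.1 | CPD uniform-component weight |

The first six are the standard settings of the pipeline.  The last three are this
package's own design choices: the confident matches that seed the
reiteration TPS carry positional noise at the per-nucleus jitter scale, so
the spline smooths (`tps_lambda = 0.1`) instead of interpolating them —
interpolation demonstrably warps the neighborhood of every slightly-wrong
control point; likewise the CPD field is kept stiff (width 3, regularization
10 in the normalized frame) because the deformations it must absorb are
body-scale, and a more flexible field starts fitting per-nucleus noise.
Costs are raw Euclidean distances; a squared-distance switch exists purely
for sensitivity checks.

## The synthetic embryo generator

Real EM/FM data are large, external and partly manual; every stage of the
pipeline is therefore exercised on synthetic embryos with known ground
truth (`synthetic_spec()`, `make_benchmark()`).  The generator emulates:

* an embryo-shaped reference: `n_landmarks` (150) points quasi-uniformly
  dart-thrown into a 50 × 25 × 25 µm ellipsoid (2:1:1 axis ratio, roughly a
  bean-stage embryo), with a minimum separation of 0.3× the expected
  nearest-neighbor distance;
* per-sample positional jitter: isotropic Gaussian noise with per-axis SD
  `jitter_sigma` (0.02) × cloud diameter;
* per-sample smooth deformation: a sum of five Gaussian-bump displacement
  fields with length scale `warp_smoothness` (0.35) × diameter, normalized
  to a maximum displacement of `warp_amplitude` (0.03) × diameter;
* heterochrony: `frac_inconsistent` (0.05) of cells carry a division or
  death event with a time drawn inside the 13-min window; each sample draws
  a developmental clock offset (SD `clock_sd` = 3 min) and realizes exactly
  the events whose time lies behind its clock.  Samples therefore agree on
  events far from the stage time and disagree near it, which is the
  mechanism that makes landmarks "inconsistent" in the first place;
  realized divisions offset each daughter by half the local
  nearest-neighbor distance from the parent;
* a modality distortion on the anonymous sample: anisotropic axis scaling
  (default 1, 1, 0.8, standing in for section compression) plus a random
  global rotation, followed by name stripping and index permutation.  Six
  well-spread stable cells form the simulated manual correspondence table.

**What the generator does not emulate** — and hence what passing synthetic
tests does and does not show.  Real inter-embryo variation is spatially
correlated (neighborhoods shift together), whereas the generator's jitter
is independent per nucleus; independent jitter destabilizes Gabriel edges
much more aggressively at equal magnitude.  Real EM distortion is not an
exact affine map, and real manual correspondences carry identification
error, whereas the synthetic distortion is exactly affine and the
correspondences are exact.  Both gaps push the synthetic benchmark into a
regime where distance-only matching after pre-alignment is close to its
theoretical ceiling while the adjacency constraints are noisy: measured on
the default benchmark, roughly one in six consistent adjacencies is
violated by the ground-truth labeling itself.  Synthetic results therefore
validate correctness and determinism of every component, and the
end-to-end behavior in a *constraint-noisy, alignment-easy* regime; they do
not reproduce the relative component contributions seen on real data,
which sit in the opposite (alignment-hard, constraint-reliable) regime.

Two measured consequences on the default benchmark (150 landmarks, 3
members, 5 seeds) are worth stating plainly, because the package's own
diagnostics expose them.  First, minimizing missing consistent adjacencies
and maximizing accuracy decouple: iterative correction reliably lowers the
violation total, yet the per-member accuracy change is slightly negative,
and because all members share the anonymous cloud's (noisy) Gabriel graph,
correction errors repeat across members and survive the vote, while plain
LAP errors from independent member jitter are outvoted.  Second, the
reiteration round re-decides exactly the landmarks where constraints and
distance disagreed in round 1 — under a noisy constraint set this is the
subset where the constraints mislead, so re-running constraint-guided
correction there can lose accuracy that the round-1 vote had already
secured.  Both effects shrink as constraint quality rises; on the
noise-free fixture the full pipeline is exact.

## Numerical and degenerate-input choices

* Gabriel test: strict open-ball criterion via the sign of
  $(u-w)\cdot(v-w)$; boundary witnesses (right angles, cocircularity) do
  not delete an edge.  Coincident points raise an error rather than being
  silently perturbed.
* Forbidden LAP pairs use a finite sentinel cost ($10^7$) rather than
  $10^{12}$: dual potentials on the sentinel scale would otherwise erode
  micrometre-level precision in double arithmetic.  A matching forced
  through a sentinel pair is detected and reported as infeasible; inside
  the correction loop the offending ban is dropped, the identity is locked
  out of further banning, and the run continues with a warning.
* Worst-identity ties in the correction loop: the identity with the larger
  matched distance is banned first, remaining ties lexicographic — a
  deterministic rule targeting the least spatially plausible match.
* Vote ties favor the identity proposed by the member alignment with the
  fewest violations, then lexicographic order.
* For a division event, merge is tried before split and an accepted merge
  skips the split hypothesis, preventing oscillation; modifications
  accumulate greedily on the current best cloud.
* Constraint edges follow accepted modifications: edges to a removed cell
  leave the constraint set (the death hypothesis *explains* their
  absence), edges to merged daughters remap to the parent, edges to a
  split parent are satisfied by either daughter.  Without remapping, every
  modification would spuriously change the constraint-set size.  Edges
  whose identity is present in the labeled cloud but unmatched still count
  as missing.
* Reiteration skips with a warning when fewer than 5 confident landmarks
  exist (the TPS would be underdetermined), and skips modification
  hypotheses that touch a frozen identity.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on generated data:
oracle comparisons use 30-point clouds (Gabriel, 20 seeds) and up-to-7-a-
side assignment instances (50 seeds, against exhaustive enumeration); the
end-to-end noise-free fixture uses 120 landmarks; the identity-recovery
benchmark uses the generator defaults (150 landmarks, 3 members) over 5
seeds, with the standard iteration counts (200/1400) unchanged.  These
sizes keep a complete run within a few minutes on one CPU while exercising
every code path at the study's default conditions.

## Known limitations

* Accuracy on the default synthetic benchmark is bounded near 0.85–0.90 by
  the independent-jitter floor (two jittered samples of the same embryo
  admit no better matching), and the constraint-guided stages do not add
  accuracy in this regime, for the reasons measured above.
* The Gabriel graph is a geometric proxy; no membrane or contact-area
  information is used, and no weighted-adjacency variant is provided.
* Temporal staging is an input (`stage_time`), not an optimization; the
  violation-vs-time curve can be swept by scoring assignments at different
  stage choices, but no automatic stage search is implemented.
* StarryNite/AceTree archives are not parsed natively; clouds enter as
  plain CSV.
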