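---
title: "Methods: quantifying fly aggression and its descending circuitry"
author: "flyaggr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying fly aggression and its descending circuitry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flyaggr)
```

This vignette explains what the package computes and why its defaults are
what they are: the measurement chain from video to ethogram, the
statistical procedures layered on top, the resistor-circuit connectome
model, and what the synthetic generators do and do not emulate.

## The behavioural measurement chain

### Video foreground by pixel statistics

A fly moving over a static arena makes its pixels vary a lot *relative to
their brightness*. The per-pixel log coefficient of variation
LCV = log10(sigma/mu), computed over a (background-subtracted) frame
stack, is therefore large on the animal and small on the arena; an
absolute ceiling on log10(sigma) additionally rejects saturated flicker.
Defaults are LCV > 0.25 and log10(sigma) < 0.45, with base-10 logarithms
throughout. Pixels with mu <= 0 or sigma = 0 have no defined LCV and are
classified background rather than raising errors, so dead pixels and
empty borders are harmless. The module's contract deliberately ends at
the boolean mask: contrast equalization, sharpening and the recombination
of mask fragments are compositing choices of the caller.

### Triangulation

Both rigs are calibrated by moving a fluorescent microbead through a box
of known positions and fitting, per camera, the standard 11-parameter
direct linear transformation, i.e. the projective camera without lens
distortion. The homogeneous system is solved after Hartley normalisation
(centroid to origin, mean radius sqrt(2) and sqrt(3)) purely for
conditioning; coefficients are reported in the rig's declared units
(millimetres for the free-walking chamber, micrometres for the
head-fixed rig — declared in configuration, never inferred from data).
Configurations with fewer than six correspondences, or coplanar ones, are
rejected as degenerate: a coplanar calibration leaves a multi-dimensional
null space that the solver detects through a vanishing second singular
value.

A 3D point is reconstructed by stacking each valid view's two DLT ray
equations and solving the 3-unknown least-squares system. Parts seen by
fewer than two cameras are *flagged invalid rather than erroring*: missing
views are a normal data condition, and validity propagates downstream.

### From tracks to observables

Detections with 2D confidence below 0.7 are treated as unseen. After
triangulation, interior runs of invalid frames strictly shorter than
500 ms are filled by per-coordinate linear interpolation; longer runs and
leading/trailing runs are left invalid (no extrapolation). Every derived
signal is then invalid at exactly the frames where any body part it
depends on is invalid — the dependency sets are explicit in the code and
covered by a dependency-oracle test on random dropout patterns.

Angles are in degrees everywhere, because every threshold of the
classification rules is stated in degrees.

* **Body vector**: the first principal axis of head, thorax and abdomen
  (a total-least-squares line), oriented abdomen-to-head. For the
  head-fixed rig the thorax-to-first-abdominal-stripe vector plays the
  role of the negative body vector, reflecting that the abdomen tip of a
  tethered fly is often curled.
* **Wing pitch**: the unsigned angle between the negative body vector and
  the thorax-to-wingtip vector, computed as atan2(|v x u|, v.u) — the
  numerically stable form of the plain vector angle in [0, 180]. A signed
  variant would need a reference normal; after the absolute value that
  reference is irrelevant, which is how the implementation treats it.
* **Wing offset angle**: |45 - atan2(R, L)| in degrees — the angular
  deviation of the (left, right) pitch point from the identity line, in
  [0, 45]. It measures bilateral asymmetry and cleanly separates the
  symmetric threat posture from unilateral extension. The degenerate
  L = R = 0 case is defined as 0.
* **Elevation**: each wall's unit normal is the third right-singular
  vector of the zero-centred wall points; the fly's distance to a wall is
  the mean perpendicular distance of the two body-axis endpoints (the
  perpendicular projections of head and abdomen onto the body axis); the
  nearest wall wins, ties broken by configuration order; the elevation is
  the unsigned angle between body vector and that wall's plane, in
  [0, 90].
* **Wing plane angles**: the frontal plane is spanned by head, thorax and
  abdomen with its normal oriented to the fly's left via the cross-product
  order (head - thorax) x (abdomen - thorax); the medial plane is
  perpendicular to it, contains the body axis, and has its normal facing
  upward in the canonical upright pose. Points are translated by the
  thorax before projecting — a plane projection formula through the origin
  is only meaningful if the plane actually contains the body points — and
  each wing's elevation (azimuth) is the planar angle between its
  projection and the projected abdomen direction in the frontal (medial)
  plane.

### Classification rules

All inequalities are strict, exactly at the stated thresholds; boundary
frames carry no label. This is a reproducibility choice: a strict rule
set has no hidden smoothing and two implementations can agree bit for
bit. The low-wing-threat offset bound is read as 10 degrees, consistent
with the offset-angle definition used by the other two wing rules. Alert
stance is scored independently of the wing labels and may co-occur with
them — the rules share no observable, and nothing in the definitions
forbids a slow, pitched-up fly from also displaying; the ethogram keeps
the three wing labels mutually exclusive and alert separate.

Frames where a required observable is invalid get an indeterminate (NA)
label per action, and the per-frame `unknown` mask is their union.

### Temporal statistics

Bouts are maximal runs of a label, terminated by unknown frames. The
first-bout latency counts the first bout that *begins after* light onset
and lasts more than 30 ms — a bout already in progress at onset is not an
evoked response. Per-fly action probabilities are the fraction of trials
performing the action at each time point, with unknown trials excluded
from numerator and denominator alike (exclusion is a package decision;
counting unknowns as non-performing would bias proportions down in
noisier flies), smoothed by a centred 250 ms moving mean whose window
shrinks at the edges. Group comparisons average each fly over 500 ms
non-overlapping bins and apply a two-sided Wilcoxon rank-sum test per bin
at alpha = 0.01, with no multiplicity correction across bins (the
per-bin cutoff is already strict; consecutive-bin significance is
interpreted jointly by the analyst). For small samples the test
enumerates the exact permutation distribution of the midrank statistic,
which remains exact under ties; larger samples use the tie-corrected
normal approximation.

### Wing-pitch mixtures

During stimulation flies hold their wings slightly ajar even between
displays, so the pitch distribution in a window is modelled as a mixture:
a single Gaussian on the 0.5 s pre-onset baseline, then a two-component
Gaussian mixture (unequal variances) on 1.5 s windows sliding by 0.5 s.
A window falls back to one component when the two-component BIC is worse
or the fitted means are closer than 5 degrees — two means within the
measurement jitter do not constitute evidence of a second posture. BIC is
the standard -2 logL + k log n with k = 3G - 1 (mean, sd, weight per
component). The EM fit is delegated to `mclust`, whose deterministic
model-based hierarchical initialisation makes the whole analysis
reproducible without restart heuristics; windows with fewer than 10 valid
samples are skipped and flagged rather than fitted.

### Wingspan metrics and estimation statistics

On baseline-subtracted wingspan traces (baseline: mean over the 10 s
before each light onset), the first response peak is the first local
maximum — a sign change of the first difference, with no smoothing before
detection — exceeding 0.22 mm for males and 0.25 mm for females: female
wings are longer, so the same relative response is a larger absolute
wingspan change. The baseline shift is the mean over 20–30 s after light
offset minus the pre-onset mean; within-bout habituation is the mean over
the first 2 s of the stimulus minus the mean over its last 2 s.

Group effects are summarised by estimation statistics: bias-corrected and
accelerated (BCa) bootstrap confidence intervals of mean differences,
10,000 resamples by default, stratified within groups (or resampling
per-pair differences when paired), built on the `boot` package and
deterministic under a fixed seed. All-equal degenerate inputs yield a
width-zero interval instead of an error.

## The resistor-circuit connectome model

Edges are synapse counts between neurons, thresholded at 10 synapses
before any path computation — the same cutoff for all connectivity
analysis, a conventional range for proofread whole-brain data, chosen
over 5 because the intermediate-partner explosion below that makes the
computation impractical. Treating counts as conductances, a two-edge path
through an intermediate carries the series weight W1·W2/(W1+W2) — the
inverse of the sum of inverses, never exceeding either edge — and
parallel paths add. The package evaluates direct paths and paths with
exactly one intermediate; longer paths are out of scope.

Any node except source and target may serve as intermediate by default,
including members of the source's or target's own class: nothing in the
model restricts relays, and a restricted variant is one configuration
flag away (`excludeIntermediates`) for sensitivity checks.

Per-synapse neurotransmitter predictions (GABA, acetylcholine, glutamate,
octopamine, serotonin, dopamine; one most-confident label per synapse)
split each edge weight into six channels, and each one-intermediate path
into a 6 x 6 permutation cell W1^i · W2^j / (W1+W2). Because the six
channels sum to the edge weight, the 36 cells sum exactly to the scalar
path weight — conservation is enforced as a class invariant. Direct
edges, having one edge and one NT per synapse, sit on the tensor
diagonal by convention, and both marginals (by first-edge NT and by
terminal-edge NT) are exposed since either aggregation can be the
quantity of interest (e.g. "GABAergic input onto the target" is the
terminal-edge marginal).

### Modularity of the weight matrix

Source rows are Euclidean-normalised and compared by cosine similarity;
zero rows cannot be normalised and are dropped with a warning.
Agglomerative clustering runs on the distance 1 - cosine with average
linkage — a middle ground between the chaining of single and the
compactness bias of complete linkage; the linkage is configurable since
the choice is genuinely open. k = 3 clusters is the default of the
analysis this package supports, not an estimate: choosing k automatically
is a non-goal. Cluster-to-DN profiles are the mean member weight per DN,
binarized at a strict > 20 (an elbow of the weight distribution), and a
DN's multiplicity counts the clusters it is strong for.

For the biplot, rows with total equivalent weight below 300 are removed
(weakly DN-connected neurons carry almost no profile information and the
analysis is reported robust for thresholds up to about 1,100), the
remaining rows are Euclidean-normalised, and PCA is computed on the
mean-centred rows by default. Whether to centre is a real ambiguity —
centring changes variance fractions — so an uncentred variant is exposed
(`center = FALSE`) and the choice is recorded in the result object. The
top-3 scores are rescaled by (max loading radius)/(max |score|) so scores
and loadings share one plotting scale; loadings stay unscaled. Two linear
SVMs in the 3D score space separate hemisphere and class; a hard margin
is preferred (large penalty), falling back to a soft margin with penalty
1 when the training data are inseparable, and 10-fold cross-validation
with deterministic, seed-derived stratified folds yields the reported
losses. The angle between the two plane normals is folded into [0, 90].

## What the synthetic generators emulate

The pose generator realises the free-walking assay's structure — 15
trials of 30.5 s at 100 Hz with light on from 0.5 to 15.5 s — with
minimal piecewise templates: a circular walking path (3 mm/s default), a
resting wing pitch of 10 degrees, threat bouts raising both wings to a
50–70 degree plateau, extension bouts raising one wing to 40–70 degrees,
alert bouts pitching the body to 25–40 degrees at 0.2 mm/s, and thrust
bouts as a rise-then-drop elevation excursion (peaking below the alert
threshold) with a speed transient. Plateaus switch on and off within one
frame, so the intended label is exact ground truth away from single
transition frames. Gaussian angular noise and per-frame single-part
dropout emulate tracking error. These are threshold-logic exercises, not
biomechanics: real flies have smooth transitions, correlated tracking
failures, wing deformation and camera-specific confidence structure, so
passing recovery tests here demonstrates correctness of the pipeline's
logic, not field performance on any particular video.

The connectome generator plants 8 sources per hemisphere split into 3
modules, each module strongly wired (40–80 synapses) to its own DN pairs,
one DN shared between two modules (the multiplicity-2 motif), a
GABAergic and a glutamatergic relay realising indirect
source-to-pC1d-like inhibitory motifs with closed-form expected NT
weights, and a sparse Erdős–Rényi background (density 0.05, 3–12
synapses) straddling the cutoff. Sizes mirror the real system's scale at
the source side while keeping DN counts small; real connectomes have
heavy-tailed degree and weight distributions the generator does not
attempt.

## Numerical choices and edge cases

* Degenerate geometry returns invalid frames (coincident body points,
  zero wing vectors, collinear frontal-plane points) — never errors.
* Gap interpolation is strictly-less-than the 500 ms bound; a gap of
  exactly 500 ms stays invalid.
* Moving means use shrinking centred windows at the series edges.
* The rank-sum test switches from exact enumeration to the normal
  approximation when the number of group assignments exceeds 1e5.
* Clustering, PCA and SVM consume finite matrices only; zero-norm rows
  are dropped before normalisation with a warning.
* All generators and analyses are bit-deterministic given their seed;
  per-stage seeds are derived from one master seed in configurations.

## Problem sizes used in the checks

The property checks run at deliberately chosen sizes: 200 random graphs
of up to 30 nodes against exhaustive path enumeration; 10,000 random
poses against closed-form angle oracles; full 15-trial sessions for
behavioural recovery; 20 seeds for mixture recovery and for
reduced-separation clustering (planted weights 20–32 against a denser
5–16 background, a regime where recovery is good but no longer trivial);
and 500 replicates of 50-versus-50 samples for BCa coverage at 1,999
resamples per interval — a standard resample count for a 95% interval,
while the analysis-facing default stays at 10,000.

## Known limitations

* Only one intermediate per path; multi-hop effective connectivity needs
  a different algorithm (and different normalisation questions).
* The LCV module stops at the mask; recombining "noise" pixels into the
  processed foreground is left to the caller.
* The DLT model has no lens distortion; rigs with wide-angle optics
  should undistort upstream.
* Ethogram rules are fixed thresholds; they inherit any bias of the
  upstream tracking and do not adapt per fly.
* The synthetic generators validate logic, not realism (see above).
* Thrust classification is external to this package; thrust appears only
  as ground truth in synthetic scripts.
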