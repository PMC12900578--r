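---
title: "Coarse-to-fine localization of palatal gingival-margin landmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-to-fine localization of palatal gingival-margin landmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Morphometric analysis of the palate starts from twelve anatomical points:
for each maxillary tooth from the right first molar (FDI 16) to the left
first molar (FDI 26), the most apical point of the palatal gingival margin —
the deepest point of the small concavity where the gum line meets the
palatal mucosa. Placing these by hand on a scanned dental cast
(a triangular surface mesh of 60,000–120,000 vertices, in millimetres) is
slow and operator-dependent. `palatemark` localizes all twelve points
automatically with a two-stage point-cloud network: a global *coarse* stage
proposes candidate locations anywhere on the cast, and a local *refinement*
stage sharpens each proposal within a small surface patch.

## Pipeline overview

1. **Mesh to cloud.** Each vertex becomes a 6-channel point: position plus
   a unit normal (area-weighted average of incident face cross products,
   orientation from the face winding; no global re-orientation pass).
2. **Canonical orientation and normalization.** A principal-component
   rotation brings every cast into a common anatomical frame (below), the
   cloud is centered on its bounding box and scaled isotropically by
   2 / (longest extent), so the longest axis spans exactly [-1, 1].
3. **Farthest-point sampling** to a fixed budget (24,000 points at full
   scale) gives even spatial coverage.
4. **Coarse stage.** A three-level set-abstraction encoder (query radii
   0.025 / 0.1 / 0.2 in normalized units) with feature propagation back to
   full resolution feeds two parallel per-point heads: a non-negative
   distance-to-nearest-landmark regressor and a 3-vector offset regressor.
   The n points with the smallest predicted distance, displaced by their
   offsets, form the candidate set (256 at full scale).
5. **Clustering.** DBSCAN groups the candidates; the grouping is resolved
   to exactly 12 centroids (merging duplicate clusters, promoting isolated
   candidates, splitting as a last resort — see below).
6. **Refinement.** A 6 mm *geodesic* ball (shortest paths on a k-NN graph
   over the sampled cloud, k = 8) around each centroid is standardized to a
   fixed patch size and scored by an encoder–decoder network that outputs a
   per-point probability map; the landmark is the argmax point.
7. **Identity assignment.** Because refined points snap onto
   gingival-margin concavities, FDI identities are assigned *after*
   refinement: near-duplicate refined points are merged, coverage gaps are
   re-aimed with one further patch at the midpoint of the largest angular
   gap along the arch, and the 12 distinct points are labelled 16 … 26 by
   their angular order around the arch center.

Geodesic rather than Euclidean patches matter on the palate: two points on
opposite gingival walls can be close in space but far along the surface, and
a Euclidean ball would mix them into one patch.

## Canonical orientation

Orientation must be annotation-free, deterministic, and stable across
casts. The package uses the principal axes of the vertex positions with
shape-derived sign rules:

* **z** is the smallest-variance axis, signed so the mean vertex normal
  points along +z (occlusal surface up).
* Of the two in-plane axes, the **antero-posterior axis is the one with the
  larger absolute skewness** of its vertex projections. A dental arch is
  nearly mirror-symmetric transversely but strongly asymmetric front-to-back
  (a single anterior apex against a broad posterior edge), so skewness
  separates the two robustly even when the antero-posterior extent exceeds
  the transverse width — for typical cast proportions it does, so variance
  *order* alone cannot identify the transverse axis. The axis is signed so
  the farthest point along it (the incisor apex) lies at negative y.
* **x** completes a right-handed frame.

Applying the same composed transform to the ground-truth landmarks puts the
training targets in normalized space; every reported error is computed after
inverting the transform, in millimetres.

## Networks and losses

Both networks share the same machinery, written in base R with explicit
backward passes (verified against central finite differences to 1e-3
relative in the test suite) and Rcpp kernels for sampling, grouping and
pooling. A set-abstraction level samples centers by farthest-point
sampling, groups neighbours inside a query ball (nearest-first, capped, a
center with an empty ball falls back to its nearest point), applies a
shared per-point perceptron, and max-pools per group. Feature propagation
interpolates coarser features with inverse-distance weights over the three
nearest centers and concatenates the skip features. Grouping structure
depends only on geometry, so it is computed once per cast and reused across
epochs.

The coarse loss is a weighted sum (defaults 1 / 1 / 1 / 0.1):

* **distance loss** — Huber (delta = 1 normalized unit) on the predicted
  distance to the nearest landmark, averaged over points;
* **offset supervision** — Huber on the 3-vector offset residual, folded
  into the distance supervision with its own weight;
* **chamfer loss** — symmetric squared chamfer between the candidate set
  and the 12 landmarks: mean over candidates of the squared distance to the
  nearest landmark plus mean over landmarks of the squared distance to the
  nearest candidate;
* **separation loss** — mean over unordered candidate pairs of
  `max(0, margin - d)^2` (margin 0.05), discouraging candidate collapse.

Predicted distances pass through a softplus rather than a clamp so the
gradient never dies. Candidate selection (top-n by predicted distance) and
the grouping structure are treated as fixed during backpropagation.

The refinement target is a Gaussian heatmap: `exp(-d^2 / (2 sigma^2))` with
d the distance in mm from each patch point to the true landmark
(sigma = 1 mm), normalized to sum to 1, trained with softmax cross-entropy.
The output head specifies only a probability map, so the supervision form is
the package's choice; a Gaussian heatmap is the standard one for landmark
regression and makes the Bayes-optimal argmax the patch point nearest the
true landmark. The final coordinate snaps to an existing cloud point
(argmax); a probability-weighted centroid mode exists behind a flag for
ablation, but sub-point interpolation is deliberately not the default.

## Training

Adam (beta 0.9/0.999), 50 epochs per stage by default, learning rate 0.001
for the coarse stage and 0.002 with global gradient-norm clipping at 0.5
for the refinement stage; batch size 1 cast (coarse) or one cast's twelve
patches (refine): with a few dozen training casts the extra optimizer steps
from single-cast batches outweigh the gradient noise, and validation loss is
the arbiter through best-checkpoint selection. The best-validation checkpoint is retained. Refinement
patches are centered on the ground-truth landmarks *plus an isotropic
Gaussian jitter of 1.5 mm* during training (oracle-patch mode) by default.
Exact ground-truth centering stabilizes training but teaches the scorer the
degenerate shortcut "the landmark is at the patch center"; the jitter forces
it to recognize the concavity feature itself, which is what inference-time
patches — centered on imperfect cluster centroids — require. Centering on
coarse centroids is a config option. All randomness (split, initialization, batch order,
simulation) derives from a single root seed through fixed offsets, making a
run bit-reproducible on one platform; cross-platform reproducibility is
approximate (BLAS summation order).

Splits use fractions 251/377, 63/377, 63/377 (floor for train and
validation, remainder to test), reproducing a 251/63/63 partition at
n = 377.

## Resolving the clustering to 12 landmarks

DBSCAN needs two parameters that the method itself does not fix; the
defaults are eps = 3 mm at full scale and 1.5 mm in the scaled profile
(converted to normalized units per cast through the stored scale) with
min_samples = 4 — at 64 candidates the clumps around each tooth hold only
about five points and adjacent incisors are ~4 mm apart, so a tighter
radius is needed to keep them separate. DBSCAN does not guarantee 12
clusters, so a deterministic resolution policy is applied, designed around
how candidate sets actually fail: well-detected teeth attract several
clusters while sparsely detected teeth leave only isolated (noise)
candidates. First, clusters whose centroids are closer than 2.5 mm — below
the smallest inter-tooth pitch, hence necessarily duplicates of one tooth —
are merged. While fewer than 12 clusters remain, the noise point farthest
from the existing centroids is *promoted* to a new cluster (it is typically
the only coverage of a missed tooth); splitting the largest non-coincident
cluster by deterministic 2-means (Lloyd from the two farthest members) is
used only when no noise remains. With more than 12, the 12 largest are kept
(ties by compactness), and remaining noise finally joins its nearest
centroid. Fewer than 12 candidates in total is reported as a detection
failure rather than guessed around. The alternative policy of splitting
before promoting was tried and discarded: it subdivides well-covered teeth
while ignoring the isolated candidates that cover the missed ones.

Tooth identity uses the canonical frame: points are ordered by the signed
angle `atan2(-x, -y)` around their mean, which increases monotonically from
the most posterior-right tooth through the anterior apex to the most
posterior-left tooth, and are labeled 16 … 26 in that order. A template-free
angular sweep was chosen over nearest-to-template matching because no
population template exists without training data. Crucially, the final
assignment operates on the *refined* points, not the cluster centroids:
centroids carry millimetres of scatter and occasionally double up on one
tooth, and a single duplicated or missing position shifts the angular order
of every tooth in between. Refined points sit on actual concavities, so
duplicates are detectable (two points closer than 2 mm, half the smallest
tooth pitch) and a missed tooth appears as a double-width angular gap; the
predictor merges duplicates, extracts one extra patch at each gap midpoint,
and only then assigns labels.

## The synthetic generator

No cast data ships with the package, so a parametric generator provides
train/test material with analytically known ground truth. The surface is a
height field over scaled elliptical coordinates (rho, theta): a gum ridge at
rho = 1 carries one Gaussian bump per tooth (first molars 1.6x wider
mesiodistally than incisors, premolars intermediate, reproducing the
clinically reported difficulty gradient at molars), a smooth palatal dome
descends toward the arch center, and an explicit gingival-margin dimple of
1.2 mm sits on the palatal side of each tooth at (theta_k, rho = 0.88). The
twelve landmarks are the dimple centers — exact surface points by
construction, so no annotation step exists and landmark error can be
measured against an exact reference. Defaults: arch width 36 mm, depth
42 mm, palate depth 14 mm, bump height 5 mm, Gaussian surface roughness
0.05 mm, 12,000 vertices for tests (80,000 emulates scanner resolution).
Datasets jitter each length parameter by Uniform(0.9, 1.1) and pose each
cast with rotations within ±20° per axis and ±10 mm translations — large
enough to exercise canonical orientation, small enough that "occlusal up"
stays meaningful.

What the generator does *not* emulate: rugae and soft-tissue texture,
crowding, rotation or absence of individual teeth, gingival inflammation or
recession, scanner artefacts beyond isotropic roughness, and mixed
dentition. Passing tests on synthetic casts therefore demonstrate that the
pipeline machinery is correct and that the networks can learn a
well-structured geometry; they do not certify clinical accuracy on real
casts.

Repeat-annotation noise for reliability studies defaults to sd = 0.1507 mm
per coordinate, calibrated so two independently perturbed sessions differ by
about 0.34 mm on average (the scale of reported intraexaminer landmarking
error); the chi(3) expectation is verified by Monte-Carlo in the tests.

## Numerical choices

* Farthest-point sampling starts from the point farthest from the centroid
  (ties to the lowest index) — deterministic preprocessing; a seeded random
  start is available.
* STL welding uses exact bit-wise coordinate equality (hex-float keys), not
  tolerance welding, to avoid collapsing fine gingival detail.
* k-NN graphs are symmetrized; disconnected components are bridged
  iteratively by the single shortest inter-component edge so geodesics stay
  finite.
* Patches are standardized to a fixed size (1,024 points at full scale):
  larger patches are farthest-point downsampled, smaller ones padded by
  cyclic repetition with duplicate flags; duplicate probabilities are merged
  by mean at extraction, which provably never changes the argmax relative to
  the unpadded patch.
* Argmax ties break to the lowest parent index; cross-entropy guards
  `log(p + 1e-12)` and the guard is differentiated exactly so gradient
  checks pass at machine precision.
* ICC uses the two-way absolute-agreement single-measures form ICC(A,1),
  the standard choice for intra-examiner coordinate reliability; a
  consistency variant is available. Outliers are flagged at
  error > mean + 3 SD per landmark, with a 1.5 IQR boxplot rule as an
  alternative.

## Problem sizes

The `scaled_down` profile — 2,048 sampled points, 64 candidates, 256-point
patches, halved channel widths, query radii widened in proportion to the
sparser sampling — is the package's test and example configuration; it
trains both stages on 48 synthetic casts in minutes on one CPU core. The
`full` profile (24,000 / 256 / 1,024, full widths) matches the method's
stated operating point for real casts. The acceptance checks train the
scaled profile on a 48/8/8 split for 30 + 30 epochs and require the mean
test error to fall below 5% of the arch width with refinement beating the
coarse centroids alone.

## Known limitations

* Orientation assumes an intact permanent-dentition arch; severely
  asymmetric or partially edentulous casts could defeat the skewness rule.
* Cluster identity assumes all twelve teeth are present; missing teeth
  would shift the angular ordering.
* Geodesics are graph approximations on the sampled cloud, not exact
  polyhedral geodesics on the original mesh.
* The final landmark is a cloud point: accuracy is floored by the sampling
  density (about the nearest-sample distance, verified by the
  oracle-supervision tests).
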