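# palatemark

Automatic localization of the 12 palatal gingival-margin landmarks on 3D
maxillary dental-cast meshes.

## The problem

Palatal morphometrics starts from one anatomical point per maxillary tooth,
first molar to first molar (FDI 16, 15, …, 26): the most apical point of
the palatal gingival margin — the deepest point of the concavity where the
gum line meets the palate. Annotating these twelve points by hand on
scanned casts (60,000–120,000-vertex STL meshes, in mm) is slow and
operator-dependent; `palatemark` localizes them automatically and provides
the statistics used to evaluate such annotations (per-landmark Euclidean
error, per-axis MAE, success detection rates, repeatability, ICC).

## The method

A two-stage coarse-to-fine point-cloud pipeline:

1. **Preprocess.** The mesh becomes a 6-channel cloud (vertex positions +
   area-weighted unit normals), is rotated into a canonical anatomical
   frame by principal components with shape-derived sign rules, scaled into
   the normalized box [-1, 1] along its longest axis, and farthest-point
   sampled to N = 24,000 points.
2. **Coarse stage.** A hierarchical set-abstraction encoder (query radii
   0.025 / 0.1 / 0.2) with feature propagation feeds two parallel per-point
   heads predicting, for every point *p*, the distance
   d(p) = min_k ||l_k − p|| to the nearest landmark and the offset vector
   o(p) = l_k − p reaching it. The 256 points with smallest predicted
   distance, displaced by their offsets, are the candidate set. Training
   minimizes a composite loss: Huber distance/offset supervision +
   symmetric squared chamfer between candidates and landmarks + a pairwise
   hinge separation penalty.
3. **Refinement.** Candidates are grouped by DBSCAN and resolved to 12
   cluster centroids; a 6 mm geodesic ball (shortest paths on a k-NN graph)
   around each centroid is scored by a patch encoder–decoder that outputs a
   per-point probability map (supervised as a Gaussian heatmap, sigma =
   1 mm, with softmax cross-entropy); the landmark is the argmax point,
   mapped back to cast-frame mm. FDI identities follow from the angular
   order of the refined points around the dental arch.

Both networks are trained with Adam (50 epochs each; learning rate 0.001
coarse, 0.002 with gradient clipping at 0.5 for refinement) on 251/63/63
train/validation/test splits. No framework is used: forward and backward
passes are explicit base-R linear algebra over Rcpp geometry kernels, with
gradients verified against finite differences in the test suite.

Because no cast data ships with the package, a parametric synthetic-cast
generator (parabolic dental arch, palatal dome, per-tooth gingival-margin
concavities with analytically known landmark positions, mm scale, random
rigid pose, surface noise) provides training and test material; the
`scaled_down` profile (2,048 points, 64 candidates, 256-point patches,
halved channels) makes the whole pipeline trainable on one CPU in minutes.

## Worked example

Simulate 64 casts, train both stages at the scaled-down profile (48/8/8
split, 30 + 30 epochs; about 10 minutes on one CPU core), and evaluate on
the held-out test casts:

```r
library(palatemark)

cfg <- pm_config("scaled_down", coarse_epochs = 30L, refine_epochs = 30L,
                 split_fractions = c(48, 8, 8) / 64)
res <- run_experiment(n_casts = 64, config = cfg, seed = 0)

print(res$model)
#> Two-stage palatal landmark localization model
#>   profile: scaled_down (2048 points, 64 candidates, 256-point patches)
#>   casts: 64 (train 48 / val 8 / test 8)
#>   coarse net: 211364 parameters, best epoch 20
#>   refine net: 51409 parameters, best epoch 29

print(res$report)
#> Landmark localization over 8 casts (mm):
#>  landmark mean   sd sdr0.5   sdr1 sdr1.5   sdr2
#>        16 0.62 0.29  50.00  87.50 100.00 100.00
#>        15 0.89 0.37  12.50  62.50  87.50 100.00
#>        ...
#>   Overall 0.93 1.23  43.75  78.12  88.54  91.67
```

Each row gives, for one tooth's landmark, the mean and SD of the Euclidean
error in mm over the test casts and the success detection rate (SDR): the
percentage of predictions within 0.5 / 1 / 1.5 / 2 mm of the ground truth.
Here the overall mean error is 0.93 mm — about half the mean spacing of the
2,048-point sampled cloud, i.e. close to the resolution floor of snapping
to a cloud point — and 92% of landmarks land within 2 mm. The coarse stage
alone (cluster centroids, `res$coarse_errors`) averages 2.97 mm on the same
casts, so the refinement stage recovers roughly a factor three.

Predict on a new cast and write a MeshLab PickPoints file:

```r
cast <- generate_cast(cast_shape_params(seed = 99))
pred <- predict(res$model, cast$mesh)
euclidean_errors(pred, cast$landmarks)
write_pickpoints(pred, "predicted.pp")
```

A thin command-line front end with `simulate`, `run`, `predict`, and
`evaluate` subcommands lives in `inst/scripts/palatemark`.

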