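---
title: "Ensemble facial landmarking and twin heritability: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble facial landmarking and twin heritability: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the models it
implements, the assumptions behind them, the tunable parameters and their
defaults, what the synthetic data generator does and does not emulate, and
the choices made where several reasonable designs existed. The worked
numbers cited here are the ones the test suite and `scripts/acceptance.R`
compute; nothing else is asserted.

## 1. From mesh to aligned rasters

A facial scan arrives as a triangle mesh in mm with optional per-vertex
grayscale color. `fit_ellipsoid()` fits a general ellipsoid by minimizing
the algebraic quadric residual under the ellipsoid-specific constraint
`4J − I² = 1` on the quadratic form (the 3D analogue of the direct
least-squares ellipse fit). The constraint matters: a frontal face covers
perhaps a quarter of a closed surface, and the unconstrained algebraic fit
then frequently returns a hyperboloid. The fit is solved as a reduced 6×6
generalized eigenproblem after centering and scaling.

`project_mercator()` parameterizes space by the ellipsoid's normalized
sphere, builds a pole/meridian frame there from configurable world "up" and
"front" directions (defaults +y, +z: faces are assumed roughly upright and
frontal in scanner coordinates), and applies the standard Mercator forward
map `X = lon`, `Y = asinh(tan lat)`. The region of interest is a square of
side 1.6 radians (configurable) centered by default on the forward
projection of the mesh centroid direction, rasterized at 200×200. Pixels
are 0-based, x rightward, y downward, pixel `(i, j)` centered at
`(i + 0.5, j + 0.5)`.

Rasterization interpolates per-triangle (barycentric) the signed radial
height over the ellipsoid, the texture, and the 3D position (the
*back-map*). Where several surface sheets cross a pixel's radial ray the
outermost — the sheet visible from outside — is kept; for the star-shaped
relief surfaces this pipeline targets there is only one. Uncovered ROI
pixels are flagged in a hole mask and filled by iterative nearest-neighbour
inpainting; the count is recorded. Ground resolution (~0.7 mm/px for the
synthetic faces) is measured from the back-map, and all mm errors are
computed in 3D through the back-map rather than by a global scale.

**Curvature.** Per edge `(i, j)` the normal curvature along the edge is
estimated as `(n_j − n_i)·(p_j − p_i)/|p_j − p_i|²` with area-weighted
vertex normals oriented away from the mesh centroid. Averaged over a
patch's edge directions this approximates the mean curvature
`H = (k1 + k2)/2`: the tests verify 1/r within 5% on a projected sphere and
1/(2r) for the per-triangle mean on a cylinder. Within each triangle the
three edge values are interpolated linearly through the edge-midpoint
(Crouzeix–Raviart) basis and carried to pixels by the projection's
triangle/barycentric buffers. Boundary edges use one-sided vertex normals.
An earlier candidate estimator based on adjacent-triangle centroids was
rejected: on right-triangle grids the two triangles of a quad share a
circumcenter and the estimate degenerates.

## 2. Feature bank

Three main maps × five variants (unfiltered, x/y central-difference
derivatives, Laplacian-of-Gaussian, Sobel gradient magnitude) give 15
channels in a fixed, documented order (`tex.ori` … `crv.sob`). Choices the
method description leaves open, fixed here: LoG scale σ = 2 px; Sobel
output is the gradient magnitude of the classic unnormalized 3×3 kernels;
convolution boundaries are reflective; and every channel is z-score
standardized. Standardization is what makes the channel-summed jets of
landmarker 16 comparable across channels; without it the curvature channels
(units 1/mm, range ~0.2) would vanish next to texture. Pixel
correspondence across channels is exact, so manual landmarks placed on one
channel serve all fifteen.

## 3. Gabor jets and the bunch-graph search

The wavelet bank follows the classic bunch-graph parameterization: 5
log-spaced frequency levels from `k_max = π/2` at ratio √2, 8 orientations
in [0, π), envelope width ratio σ = 2π, kernels DC-corrected (analytically
and then exactly, by subtracting the discrete mean) and truncated at 2.5
envelope SDs. A *jet* is the 40-vector of complex responses at one pixel.

Similarity between jets is the normalized inner product of magnitude
vectors — phase-insensitive, in [0, 1], with zero-norm jets scoring 0. A
phase-sensitive variant exists behind a flag but is not used by the
searches: magnitude similarity varies smoothly over several pixels, which
suits a coarse template search initialized at the population mean.

Training (`train_bunch_graph()`) stores, per landmark × channel, the jets
of all training subjects plus the mean position and per-axis SDs of the
training coordinates. The search window is the mean ± max(10 px, 2×training
SD) per axis — the initialization is prescribed by the method, the extent
is a choice here. A pixel's score is the *maximum* over the bunch of its
similarity to a training jet (the classic bunch rule; mean-over-bunch is a
configuration away). Ties are broken by distance to the mean position, then
row-major order, making the argmax deterministic; the winning pixel is then
refined to sub-pixel precision by a parabolic fit through its axis
neighbours' scores (clamped to half a pixel, skipped at window borders and
ties) — the standard refinement for quantized template matching, without
which any averaging predictor would gain a spurious sub-pixel advantage
over single searches. On a training image the
true landmark scores exactly 1.0 on every channel (its own jet is in the
bunch), which the acceptance suite asserts.

Responses are computed by FFT over the whole image but only materialized at
the union of all landmarks' search windows; the convolution engine is
compiled (RcppArmadillo) because the 600 inverse transforms per subject
dominate runtime. The R and C++ engines agree to 1e-10 and both match
direct spatial-domain jet extraction, including at image borders (zero
padding, wrap-free).

## 4. PC-guided global search (landmarker 18)

Five anatomy-based sub-graphs of 4–6 landmarks (right eye/brow, left
eye/brow, upper nose, lower nose, mouth/chin; membership overridable) are
fitted in order. Per group, PCA of the stacked training coordinates gives a
mean and two leading components; a 21×21 grid over scores in ±2 score-SDs
is searched for the maximal objective

> Σ over group landmarks Σ over 15 channels (bunch similarity at the
> reconstructed pixel) − λ · Σ over overlap landmarks (pixel distance to
> the earlier fit),

with λ = 0.01 per pixel, and only configurations keeping every landmark
inside its per-axis mean ± 1 SD training rectangle (and the image) are
admissible. If nothing is admissible the group falls back to its mean with
a warning. Reconstructed positions are rounded to the nearest pixel for
similarity lookup (jets are pixel-sampled). Overlapping landmarks keep the
earliest-fitted group's coordinates. Grid resolution, the ±2 SD range, λ,
and the per-axis (rather than radial) reading of the 1 SD bound are
decisions documented here; the returned-inside-the-box property is a hard
invariant the acceptance suite checks over 100 group fits.

## 5. Ensembles

**Bagging** draws bags with replacement from the training subjects (bags
with fewer than two unique subjects are redrawn) and averages per-bag
predictions. A per-bag model is the bunch graph restricted to the bag's
multiset — identical to retraining, since jets are per-subject — so the
expensive convolutions are shared across bags. The benchmark's bagging
experiment bags the *deployable* landmarker — the template-based base
landmarker with the best training-set out-of-fold error (bags re-extract
its templates, which is what bagging means for a template matcher) — at 20
bags; the original experiment ran at cluster scale, and the package
reproduces the *finding*, not the scale. For such a working landmarker,
bagging changes the error by well under 15%: training-sample composition
has little impact on a landmarker whose score surface has a clear peak. The
picture is different for noise-dominated searches (e.g. the texture
x-derivative channel, whose argmax is nearly random within its window):
there bag-averaging regresses predictions toward the window mean and
"improves" them by 20-30% — a variance reduction on a predictor one would
never deploy alone, not a useful gain, and the reason the experiment is
defined on the deployable landmarker.

**Stacking** collects out-of-fold predictions: each training subject is
predicted by all 18 landmarkers from models trained on the other n−1 (the
held-out subject's jets and coordinates enter nothing — a mutation test
asserts this). Per landmark, predictions and truth are centered per axis
and pooled across axes; one no-intercept least-squares fit of truth on the
18 predictions, on SD-standardized columns, ranks the landmarkers by
absolute coefficient; the top 3 are refitted and their weights applied at
prediction time as `Σ wᵢ pᵢ`.

Two numerical realities shaped the final combiner. First, the 18-column
design is *structurally* rank-deficient — landmarker 17 is exactly the mean
of landmarkers 1–15 — and several good landmarkers are near-duplicates, so
a plain (or nearly unregularized) first pass produces huge
opposite-signed coefficients on collinear subsets and corrupts the
ranking. The ridge fallback therefore triggers on a condition test
(smallest eigenvalue below 1% of the mean diagonal of X'X) with a penalty
of 1% of the mean diagonal. Second, normalizing refit coefficients to sum
to 1 *after* an unconstrained fit explodes when the coefficients nearly
cancel, which happens at landmarks whose population coordinate variance is
below pixel quantization; during development this produced 30 mm test
errors from weights like (4.7, 10.7, −14.3). The refit is therefore least
squares *constrained* to sum-to-one weights (as in Breiman's stacked
regressions), which yields the relative weights directly and degrades
gracefully to a minimum-variance mix when the target is noise. The model
object still records the full 18-coefficient vector, the 3 selected ids,
weights summing to 1, and whether the ridge was used.

## 6. Evaluation

`run_loo()` is a generic leave-one-out harness over method functions;
`run_benchmark()` is the standard experiment: train everything on n_train
subjects, stack via out-of-fold collection, evaluate all 18 bases plus the
stacked predictor on held-out subjects. Errors are 3D mm distances obtained
by backprojecting both predicted and manual pixel coordinates; the grand
mean weights the 21 per-landmark means equally. Report files flag means
below 2 mm and above 4 mm.

## 7. Twin heritability

Landmark configurations are aligned by generalized Procrustes
(translation, unit centroid-size scaling — togglable — and best-fit
rotations to the evolving consensus until it moves < 1e-8). Features are
the aligned coordinates, all C(21,2) = 210 pairwise distances, and the
area plus three interior angles of each triangle of a Delaunay
triangulation of the *symmetrized* mean shape (the consensus averaged with
its mirrored, relabeled copy; Delaunay is brute-force empty-circumcircle,
adequate at 21 points and verified against the 2n−2−h count). Angle labels
a/b/c refer to the first/second/third listed landmark id — a positional
convention adopted here.

The trait model is `y = β0 + β_age·age + g + ε` with within-pair genetic
covariance σg² (MZ) or 0.5·σg² (DZ) — the additive-kinship reading of
narrow-sense heritability, with no shared-environment term, so
`h² = σg²/(σg²+σe²)` exactly. Fixed effects are profiled by GLS over the
2×2 pair blocks; (σg², σe²) maximize the REML likelihood by L-BFGS-B on the
log-variance scale. The per-block closed forms make a 1000-pair fit take
milliseconds. On MZ-only cohorts the model reduces to a random pair
intercept, which provides an independent oracle (lme4) in the tests; the
acceptance suite verifies |mean ĥ² − h²_true| < 0.05 at h²_true ∈ {0.2,
0.5, 0.8} over 50 cohorts of 500+500 pairs. The reported σ's are SDs; the
published table this mirrors labels its columns "variances", but its
printed h² values satisfy the SD reading row by row (e.g. 1.01²/(0.76² +
1.01²) = 0.64), so SDs are what the package reports.

**Importance maps** summarize per-feature h² at each pixel as
`Σ wᵢ hᵢ / Σ wᵢ` with `wᵢ = hᵢ/(ε + d(p, cᵢ))`, ε = 1 px. Feature centers
are the landmark position (coordinates), segment midpoint (distances),
triangle centroid (areas) and the angle's vertex (angles) — the last is a
choice; a centroid convention would also be defensible. Display rescaling
to [0, max h²] is optional so the raw weighted average remains testable
(at a feature center the value approaches that feature's h²).

## 8. The synthetic study population

The generator defines the conditions under which all package-level results
are computed. A face is an ellipsoid patch (semi-axes 90/115/95 mm,
longitude ±0.95 rad, latitude −0.85..0.75) plus fixed anisotropic Gaussian
relief (nose ridge and tip, brows, cheekbones, lips, chin boss, eye
sockets), so there are structure-rich landmarks (nose) and structure-poor
ones (forehead, chin) — the distinction the PC landmarker exists for.
Texture is a deterministic shading of the relief with dark patches at
eyes, brows, mouth and nostrils, plus per-vertex Gaussian noise
(SD 0.02 intensity units). Ground-truth landmarks are evaluated from the
same closed-form surface, so they are exact.

Shape variation is low-rank by construction: six smooth displacement
fields (face width, face height, nose prominence, midface lateral shift,
mouth width, midface vertical shift) with score SDs (2, 1.5, 1.2, 1, 0.8,
0.8) mm; positions are affine in the scores, which makes the ±1 SD
antisymmetry and closed-form population SDs testable. The basis initially
comprised only the three symmetric modes; that left every midline
landmark's x-coordinate exactly constant across the population — a
degeneracy no real cohort exhibits, which made the PC landmarker exact to
machine precision and fed zero-variance targets to the stacking
regression. The six-mode basis is the fix and is the definition of the
study population used by every benchmark number.

What the generator deliberately does *not* emulate: annotation error (truth
is exact, so absolute errors are optimistic relative to a manual-rater
ground truth), scanner artifacts and holes, hair/eyelash texture clutter,
non-frontal pose, and non-additive twin effects (no dominance or shared
environment). Passing benchmarks therefore demonstrate the machinery —
correct correspondence, search, combination and inference — under known
truth, not field accuracy on clinical scans.

## 9. Problem sizes and numerical choices

The standard benchmark uses 30 training and 10 test subjects at 200×200 px
(the training-size regime the method targets), 21×21 PC grids, 20 bags,
and 50-rep twin recovery at 500+500 pairs — sizes chosen so the full suite
runs on a desktop core in minutes. Degenerate inputs are handled
explicitly: zero-variance PC groups collapse to the mean with a flag;
constant feature channels standardize to zero; zero-norm jets score 0;
landmarks outside the ROI are flagged, never clamped; bags must contain two
unique subjects. All randomness flows from user-supplied seeds through a
seed-restoring wrapper, so every pipeline stage is reproducible.

Known limitations: grayscale texture only; the Mercator parameterization
and ROI side are defaults not validated against any particular scanner
protocol; the ellipsoid fit assumes a roughly upright, frontal face for its
pole/meridian frame; heritability point estimates come without likelihood
confidence intervals (a convergence flag is reported instead).
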