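---
title: "Individualized cortical parcellation with masked graph convolutions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individualized cortical parcellation with masked graph convolutions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcnparcel)
```

# The problem

Connectivity-based group atlases assign every cortical vertex a parcel label
on a registered template surface, but individual brains deviate from the
group layout — modestly in primary sensory and motor cortex, substantially
in association cortex. An individualized parcellation method must (i) keep
the global topographic organization of the atlas, (ii) move parcel borders
to follow each subject's own functional connectivity, (iii) do so reliably,
i.e. reproduce the same individual map from independent sessions of the same
subject, and (iv) produce parcels whose vertices have more homogeneous
signals than the atlas's. `gcnparcel` implements a semi-supervised graph
convolutional approach to this problem along with the full evaluation
battery.

# Model and procedure

## Brain graph and spectral operators

The cortical sheet is represented as the 1-skeleton of the registered
surface mesh: vertices are nodes, and two cortical vertices are connected
iff they co-occur in a mesh triangle (`build_adjacency()`). Medial-wall
vertices (cortex mask `FALSE`) are removed with compact re-indexing rather
than kept as isolated nodes, so every graph vertex has degree at least one;
disconnected components are allowed (two hemispheres would form two), but an
isolated single vertex is treated as a data error.

The symmetric normalized Laplacian `L = I − D^{−1/2} A D^{−1/2}`
(`normalized_laplacian()`) has spectrum in [0, 2]. Chebyshev filtering needs
the rescaled operator `L̃ = 2L/λ_max − I` with spectrum in [−1, 1]
(`scale_laplacian()`). `λ_max` is computed by plain power iteration on `L`
(`estimate_lambda_max()`, relative tolerance 1e−6, cap 10,000 iterations,
seeded start vector, Rayleigh-quotient estimate); since `L` is positive
semidefinite its largest-magnitude eigenvalue is `λ_max`, so no shift is
needed. The universal bound `λ_max = 2` can be passed instead
(`scale_laplacian(lap, lambda_max = 2)`); exact scaling keeps the Chebyshev
argument inside [−1, 1], which is why the estimate is the default.

## Connectivity fingerprints

Raw vertex time series are nuisance-regressed (`regress_nuisance()`,
ordinary least squares against an intercept plus confound columns, e.g.
mean white-matter and CSF signals) and band-pass filtered to 0.01–0.1 Hz
(`bandpass_filter()`, zero-phase forward–backward Butterworth of section
order 2; the mean is removed first so constant series map to exact zeros).
The fingerprint of a vertex is its Pearson correlation with the mean series
of each atlas ROI (`connectivity_fingerprint()`), giving the N × F signal
matrix on the graph. Fingerprints are kept as raw correlations — the
conventional choice, preserving sign — rather than being converted to
assignment probabilities; vertices with zero-variance series get an all-zero
row, are flagged, and are labeled 0 downstream rather than silently imputed.

## Confidence mask

The similarity-based initial parcellation (`initial_parcellation()`) assigns
each vertex to the parcel whose *centroid fingerprint* (mean fingerprint of
the parcel's atlas vertices, computed from the same session) correlates best
with the vertex's fingerprint — profile-to-profile similarity, not the
single own-ROI entry, because the borderline vertices that matter are
precisely those whose own-ROI correlations are ambiguous. Exact ties break
to the lowest parcel index.

A vertex enters the subject's binary confidence mask
(`build_confidence_mask()`) iff in **every** session (1) its initial label is
assigned, (2) the label equals the group atlas, and (3) the label agrees
across sessions. One mask per subject is built from all sessions and shared
by them during training; the training target at masked vertices is the
group-atlas label (inside the mask the initial labels and the atlas agree by
construction). Weights are binary — the mask is an in/out vertex exclusion,
not a graded weighting.

## Network and training

Two Chebyshev convolution layers (default F → 64 → K+1 channels, order
K = 3 each) with a rectifier between them, dropout 0.5 on the hidden
features during training only, and a row-wise softmax output
(`msgcn_model()`, `msgcn_forward()`). Third-order filters make each layer
3-hop localized; the stacked receptive field is exactly 6 hops
(`receptive_field_check()` verifies this empirically). Higher orders are
configurable but over-smooth. The output dimension is `n_parcels + 1`, class
1 being the unassigned/background label 0.

The loss is the confidence-masked Kullback–Leibler divergence to the one-hot
group prior, `−Σ_v w_v log p_{v,y_v}` (`masked_kl_loss()`), i.e. the negated
masked log-likelihood, so that minimization maximizes the probability of the
atlas label at confident vertices; probabilities are floored at 1e−12 before
the log. Training (`train_msgcn()`) iterates subject-sessions with batch
size one subject, adaptive moment estimation (learning rate 0.001, β 0.9 /
0.999), l2 weight decay 0.0005 added to the weight gradients (biases are not
decayed), dropout reseeded deterministically per epoch and sample, and a
seeded per-epoch shuffle. Early stopping monitors the mean masked loss over
the validation subjects — the trained objective — and restores the best
validation epoch after 10 epochs without improvement. Gradients are computed
by exact backpropagation through the Chebyshev recursion (the layer-1 basis
is cached per session, since it never changes across epochs). The defaults
(100 epochs, patience 10, 40/10-style train/validation split scaled to the
cohort) follow the published protocol for this family of models.

Inference (`predict_parcellation()`) is dropout-free and deterministic:
`label(v) = argmax_k p_{v,k}` with ties to the lower class index.

## Evaluation battery

* `dice_parcellation()` — per-parcel Dice `2|A∩B|/(|A|+|B|)`, label 0
  excluded, unweighted mean over parcels present in either map.
* `cohens_d()` — `(μ_inter − μ_intra)/sqrt(σ²_inter + σ²_intra)` with
  population (denominator-n) variances, matching the plain `σ²` of the
  defining equation; sample variance by flag.
* `variability_maps()` — per parcel, Cohen's d between the intersubject and
  intrasubject collections of `1 − Dice` (a dissimilarity, so larger d =
  more intersubject variability), summarized by parcel class.
* `connectivity_variability()` — the same construction on per-vertex
  fingerprint correlations between runs, averaged within parcels.
* `functional_homogeneity()` — mean within-parcel pairwise correlation;
  the global value is parcel-size weighted ("adjusted for parcel size" is
  read as vertex-count weighting, the cited convention; a regression
  adjustment would be an alternative reading).
* `task_alignment()` — per-parcel standard deviation (variability) and mean
  (homogeneity) of an activation beta map; whole-brain variability is the
  size-weighted mean of per-parcel standard deviations.
* `correlate_maps()` — Pearson r and two-sided p across parcels, pairwise
  NA dropping, for associating variability maps with covariates
  (connectivity variability, myelin ratio, laminar class).
* Paired comparisons (intra vs inter Dice, homogeneity of two parcellation
  schemes) use the standard two-sided paired t-test from `stats`.

## Behavior prediction

`fit_behavior()` implements the topography–behavior model
`y ≈ Σ_i Dice(l, l_i) y_i` as kernel ridge regression in dual form — the
raw weighted sum is scale-inconsistent once an l2 penalty and
cross-validation enter, so scores are mean-centered, dual weights solve
`(G + λI)a = y_c` with `G` the pairwise mean-Dice Gram matrix, and λ is
selected from a 15-point logarithmic grid (1e−4…1e3) by seeded five-fold
cross-validation. The empirical Dice kernel is not guaranteed positive
semidefinite; a diagonal jitter up to 1e−6 is added when the smallest
eigenvalue is negative, and a larger defect is an error. The unfitted
normalized Dice-weighted average remains available as a baseline
(`predict_behavior(..., baseline = TRUE)`).

# The synthetic cohort generator

Real individualized-parcellation studies need restricted-access fMRI; the
generator (`make_cohort()`) emulates the *statistical structure* such data
exhibit, at desk scale, so that every pipeline property is testable.

* **Cortex** — an icosphere (`make_mesh()`): an icosahedron subdivided
  `s` times (level 4 = 2,562 vertices), radius 100 mm, with an optional
  south-polar cap standing in for the medial wall. A sphere rather than two
  hemisphere sheets: none of the implemented operators depend on topology,
  and a two-component variant only changes the graph's component count.
* **Atlas** — farthest-point-seeded multi-source breadth-first-search
  partition (`make_group_atlas()`): parcels are connected, non-empty, and
  exhaustive; a contiguous block (default 40% of parcels) is tagged
  `"association"`, the rest `"primary"`.
* **Subject truths** — one canonical *deformation trajectory* per cohort
  (`warp_trajectory()`): an ordered sequence of guarded boundary-vertex
  label flips in which association parcels flip more often than primary
  ones (expected flip rounds 0.7 vs 0.2 at the far end). Each subject
  replays a prefix of this sequence, of length set by a per-subject
  severity drawn uniform on [0.15, 1] (`make_subject_truth()`). Severity 0
  reproduces the atlas; Dice to the atlas decreases with severity; parcels
  never empty. Intersubject variability is thus a shared, low-dimensional
  deformation mode with a sensory-fugal gradient — deliberately so: scores
  that are a fixed function of parcellation topography are then learnable
  through whole-map Dice similarity, which is the working assumption of the
  Dice-kernel behavior model. Fully independent per-subject border noise
  would make any parcel-specific topography–behavior coupling invisible to
  that kernel (we verified this: held-out prediction collapses to chance),
  so it is not the default; independence enters instead through session
  noise and the behavioral noise term.
* **Sessions** — each parcel draws an independent latent series (white
  noise band-passed to 0.01–0.1 Hz at TR 0.72 s, standardized); each vertex
  gets its parcel's latent plus independent Gaussian noise of standard
  deviation `1/snr` (`make_session()`). Sessions of a subject share the
  truth but not the draws.
* **Behavior** — `score_s = effect · Σ_k c_k · dice_k(truth_s, atlas) +
  noise` with per-parcel contrasts `c_k ~ N(0,1)` fixed per cohort
  (`make_behavior()`).
* **Task betas** — piecewise-constant levels on the subject's true parcels
  plus vertex noise (`make_task_betas()`), so activation changes follow the
  true borders.

All generators are bit-reproducible from the config seed; every random
draw uses a named substream derived from it, so adding subjects or sessions
never perturbs earlier ones.

## Default study conditions

| parameter | default | rationale |
|---|---|---|
| mesh subdivisions | 4 (2,562 vertices) | desk-scale stand-in for a 32k surface |
| parcels K | 50 | ≈50 vertices per parcel, matching the vertex-per-parcel ratio of a 400-parcel atlas on 59k vertices |
| subjects × sessions | 20 × 2 | scaled-down training cohort; evaluation adds 10 held-out subjects |
| timepoints, TR | 400, 0.72 s | ~5 min of acquisition at the standard fast TR |
| snr | 0.4 | within-parcel vertex-pair correlation `snr²/(1+snr²) ≈ 0.14`, the magnitude of resting-state parcel homogeneity reported for high-quality surface fMRI |
| warp (primary / association) | 0.2 / 0.7 | cohort-mean Dice(truth, atlas) ≈ 0.89, the reported scale of group-vs-individual topographic similarity |
| severity range | uniform [0.15, 1] | every subject deviates somewhat; none is atlas-identical |
| behavior effect / noise | 1 / 0.1 | recoverable but noisy topography–behavior link |

What passing tests on these cohorts *do* show: the end-to-end ordering
properties — individualized maps beat the atlas in Dice-to-truth and
homogeneity, intrasubject reliability exceeds intersubject similarity,
association parcels vary more than primary ones, task variability drops
under individualized borders, and noiseless topography-linked scores are
recovered. What they do *not* show: performance under real fMRI noise
(motion, physiology, spatially correlated noise, vascular artifacts),
real cortical geometry and registration error, or high-dimensional
idiosyncratic border variability; parcel latents are independent, so
fingerprints are cleaner and initial parcellations more accurate than on
real data (synthetic confidence masks cover ~85–90% of the cortex versus
roughly half on real data).

# Numerical choices

* Power iteration: tolerance 1e−6 on successive Rayleigh quotients, cap
  10,000; failure suggests the `λ_max = 2` fallback.
* Probabilities floored at 1e−12 inside the loss; softmax computed with
  row-max subtraction.
* Ties (initial parcellation, prediction argmax) break to the lowest index;
  this is asserted by tests, not incidental.
* Dice of a parcel absent from both maps is NA (excluded from means), never
  0; an all-absent parcel in variability maps is flagged missing.
* Cohen's d with both variances zero is 0 when the means agree and an error
  otherwise (undefined effect size).
* Dice-kernel PSD repair: jitter up to 1e−6; beyond that, error.
* Parameter initialization: zero-mean normal scaled by
  `sqrt(2/(fan_in·(K+1)))`, seeded; biases start at zero.
* Training determinism: dropout masks, shuffles, and fold splits are all
  derived from the run seed through named substreams.
* Degenerate inputs error early with the offending vertex/parcel named:
  empty cortex masks, isolated vertices, zero-variance parcels, masked
  label-0 vertices, rank-deficient confounds.

# Scaled problem sizes

The test suite and the acceptance script train for 40 epochs (patience 10)
on the 2,562-vertex default cohort — the validation loss is still falling
gently at that point, but the orderings under study are stable from roughly
epoch 25 — and use 16/4 train/validation subjects within the 20-subject
training set, mirroring the 4:1 split of the full-scale protocol. The
behavior experiment uses 60 subjects (40 train / 20 test) without session
data, since scores depend only on the ground-truth maps.

# Known limitations

* Dropout uses inverted scaling at train time; quantitative loss values are
  therefore not comparable between runs with different dropout rates.
* The Dice kernel treats parcellations as unordered label sets; it cannot
  distinguish *which* border moved, only how much overlap remains — hence
  the generator's shared-deformation design.
* GIFTI support covers the ASCII encoding (read and write); binary/gzip
  GIFTI from other tools must be converted first.
* The CLI's `evaluate` groups sessions by the filename prefix before the
  first underscore; files not following `<subject>_<session>` naming fall
  back to a pooled pairwise-Dice summary.
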