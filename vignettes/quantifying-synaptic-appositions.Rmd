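---
title: "Quantifying synaptic appositions and subcellular protein localization in confocal images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying synaptic appositions and subcellular protein localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synappose)
```

## The measurement problem

Counting synapses in tissue from light microscopy is done indirectly: a
presynaptic marker (GAD65, GAD67, CB1R, Syt2, VGlut1) or postsynaptic marker
(Gephyrin, PSD95) is immunolabeled, small fluorescent puncta are segmented,
and a punctum is accepted as a synaptic contact onto a target structure —
a pyramidal-cell soma, an axon initial segment (AIS), or a labeled axon —
when the *area of mask overlap* between punctum and structure exceeds a
criterion. `synappose` implements this apposition-based workflow end to
end, together with a soma-versus-neuropil scoring of tagged proteins and
the hierarchical statistics used to compare genotypes or electroporation
conditions, and a synthetic-scene generator that makes every stage testable
against known ground truth.

The apposition criteria, in µm² of mask colocalization (all inclusive,
`>=`):

| call                                    | criterion |
|-----------------------------------------|-----------|
| presynaptic bouton contacting a soma/AIS | 0.04      |
| postsynaptic cluster contained in a soma | 0.04      |
| pre/post pair forming a synapse          | 0.03      |
| synapse originating from a labeled axon  | 0.025     |

Minimum particle sizes are per marker class: 0.06 µm² for GAD67/GAD65/CB1R
boutons and 0.05 µm² for Syt2/VGlut1 boutons and Gephyrin/PSD95 clusters.
Particle circularity (4πA/P²) is filtered on the range [0.00, 1.00], i.e.
unconstrained by default.

All physical thresholds are compared against **exact pixel counts times the
pixel area** — no threshold is rounded to a whole number of pixels. A guard
of 1e-12 absorbs floating-point representation error in products such as
`4 * 0.1^2`; it is far below any physically meaningful area. The pixel size
(µm/px) is a required user input throughout: objective magnification and
digital zoom do not determine it unambiguously, so the package deliberately
offers no default.

## Channel conditioning

`condition_channel()` applies, in order: background subtraction, Gaussian
blur, mean-filter smoothing, and saturated contrast rescaling to the full
bit range. The four steps follow the usual ImageJ macro chain for synaptic
channels; their parameters (`preproc_params()`) default to macro-typical
values — background disc radius 50 px, blur σ = 1 px, 3×3 mean filter,
0.3 % tail saturation — and every value is echoed into the run log.
Background is estimated as the grayscale morphological opening with a disc
structuring element, which removes any plateau narrower than the disc (the
same idea as the rolling-ball estimator); a constant image therefore maps
to zero. Before the final rescale the chain is linear, so intensity
rescaling commutes with it — a property the test suite checks directly.
Whether the original macros used saturated rescaling or histogram
equalization for "contrast enhancement" is not recorded anywhere we could
find; rescaling is the default and equalization is available via
`method = "equalize"`.

For the subcellular-localization analysis, images from one experiment are
first normalized to a shared reference frame with `match_histogram()` —
classic integer-level histogram specification with a monotone mapping.
Matching an image to itself is the identity and the operation is
idempotent. Matching is applied to whole frames, not per ROI, because
normalization exists to make one experiment-wide threshold meaningful.

## Thresholding and segmentation

Thresholds are **fixed per experiment**: selected once (e.g. with
`threshold_isodata()`, the classic iterative intensity threshold
`T <- (mean below + mean above) / 2` run to its fixed point) and applied to
every image of the experiment. Foreground is `>= threshold`.

* **Somata** (`segment_somata()`): 8-connected components of the
  thresholded surface-reporter channel, kept when their area is at least
  `min_soma_area_um2` (default 50 µm²). The size gate — not the threshold —
  is what separates cell bodies from neuropil texture. Perimeter is the
  marching-squares contour length at the 0.5 iso-level; regions of ≥ 20 px
  are lightly smoothed first, which brings the estimate within 1 % on
  digital discs of radius ≥ 5 px (the raw binary contour overestimates a
  disc's perimeter by ~7 %). The estimator rounds sharp corners slightly,
  a bias irrelevant for convex cell bodies.
* **Neuropil** (`segment_neuropil()`): foreground at a second (higher)
  threshold minus all soma pixels.
* **AIS** (`segment_ais()`): connected components whose length is the
  longest geodesic path along the morphological skeleton (Zhang–Suen
  thinning; 8-connected path with √2 diagonal steps, double-sweep
  shortest-path search). Components shorter than `min_length_um` are
  dropped.
* **Puncta** (`detect_puncta()`): binarize, split touching blobs with a
  watershed on the Euclidean distance transform (basin-merging tolerance
  h = 1 px by default, which avoids oversplitting single discs), label,
  then apply the class size minimum and circularity range. Circularity is
  capped at 1: the contour perimeter of very small (1–3 px) particles is
  shorter than the area implies, which would otherwise push 4πA/P² above
  1 and silently discard legitimate diffraction-limited puncta. Puncta
  touching the frame border are kept by default (`exclude_border = TRUE`
  reverses this).

Connectivity is 8-connected everywhere, matching the ImageJ lineage of the
workflow.

## Apposition calls and densities

`overlap_area()` is an exact pixel-intersection count times the pixel
area; every apposition operator reduces to it. `call_contacts()` assigns
each punctum to at most one structure (largest overlap, then lowest
structure label). `pair_synapses()` matches pre and post puncta one-to-one,
greedily by descending overlap (ties: lower pre label, then lower post
label) — whether one bouton may serve two clusters is not specified
anywhere in the source workflow, and one-to-one matching is the
conservative choice. `assign_pairs_to_process()` keeps pairs whose
presynaptic punctum overlaps the labeled-process mask by ≥ 0.025 µm²; the
criterion's phrase "their area" is ambiguous between the pre member, the
pair union, and either member, so the other two readings are available via
`mode = "union"` / `"either"`.

`linear_density()` divides contact counts by the soma perimeter or AIS
length. Published figures label the quantity only as "density", so the
unit is a reporting choice: the package reports per µm and per 10 µm side
by side and writes the unit into every output header.

## Hierarchical statistics

The **animal is the unit of analysis** for group comparisons: cell values
are averaged per animal (`animal_means()`) before testing; cumulative
frequency plots (`ecdf_table()`) use cell-level values. `compare_groups()`
implements the test-selection logic: Shapiro–Wilk per group at α = 0.05;
two groups → equal-variance Student's t (Welch via `var_equal = FALSE`) or
Mann–Whitney U; more than two → one-way ANOVA with Tukey's range post hoc,
or Kruskal–Wallis. Groups whose normality cannot be assessed (fewer than
3 animals, or constant values) fail the gate and route to the
non-parametric branch. If every group is constant the report carries
statistic 0, p = 1 and a `degenerate` flag rather than an error, so batch
runs survive pathological inputs. Whether the original analyses gated
normality per group or on pooled residuals is not recorded; per-group
gating is the stricter and more common reading. Two-way designs are out of
scope: no reported result exercises them.

```{r stats-example}
co <- generate_cohort(scene_spec(seed = 1), c(control = 1, mutant = 0.6),
                      n_animals = 5, n_cells_per_animal = 15, seed = 42)
compare_groups(animal_means(co$measurements))
```

## The synthetic-scene generator

`generate_scene()` renders multichannel frames emulating the measurement
situations: bright soma discs on a dimmer smooth neuropil texture,
elongated AIS bars, diffraction-limited puncta planted tangent to structure
boundaries, postsynaptic partner clusters at a controlled overlap fraction,
labeled-process patches over a chosen fraction of pairs, and a tag channel
restricted to soma, neuropil, or a mixture. Channels are blurred with a
Gaussian PSF (σ = 0.1 µm default) and degraded with Poisson shot noise plus
additive Gaussian read noise; **ground truth is recorded pre-noise**.

Defaults are the conditions the pipeline targets: 1024×1024 frames,
0.1 µm/px (a typical 100× confocal calibration — the true value is always
a user input), somata of radius 6 ± 0.5 µm (≈ 12 µm diameter pyramidal
cell bodies), ~12 perisomatic boutons per soma (≈ 0.38 boutons/µm of
perimeter, the scale seen for basket-cell innervation), punctum radii
0.2–0.3 µm, and read noise at 8 % of full range, giving SNR ≈ 8 at the
punctum amplitude. Two constructions guarantee that planted truth clears
the criteria *by construction*: boutons are centred on the structure
boundary (half the disc inside, so soma overlap ≥ 0.04 µm² for all default
radii; `near_miss_px` plants them 1–2 px off to exercise the threshold
instead), and soma radii are truncated at mean − 2 sd so no planted soma
falls under the 50 µm² size gate. Determinism: all draws run on R's
Mersenne–Twister with per-entity derived sub-seeds, so adding somata does
not shift the bouton placement of earlier ones and scenes are reproducible
across platforms.

What the generator does **not** emulate: realistic confocal PSF shape
(Airy rings, axial extent), bleaching and chromatic shifts, tissue
autofluorescence structure, and the full morphological variety of real
neurons. Passing recovery tests therefore demonstrates that the
*quantification chain* is correct and robust at realistic SNR — not that
segmentation would be error-free on arbitrary tissue.

`generate_cohort()` adds the study design on top: animals within groups
(lognormal between-animal rate multipliers, CV 10 % by default), cells
within animals (Poisson bouton counts at a planted group multiplier). By
default it simulates at the measurement level — cell densities from the
same soma-radius and bouton-rate model — which is what makes 100-repetition
calibration and power studies run in seconds; `render = TRUE` additionally
rasterizes every cell as a single-soma scene for end-to-end runs.

## Validation and problem sizes

The test suite validates each stage against independent oracles:
brute-force pixel enumeration for all overlap and apposition operators,
analytic discs and bars for areas/perimeters/lengths, hand-iterated
IsoData fixed points, hand-computed t/U/ECDF/s.e.m. fixtures, and planted
ground truth for end-to-end recovery. Recovery runs use 384×384 frames
with 3 somata × 10 boutons (noise-free: exact recovery required; SNR ≈ 8:
recall and precision ≥ 0.9), and the statistical calibration uses 100
simulated cohorts of 5 animals × 15 cells per group — sizes chosen so the
full suite runs in well under a minute while keeping ≥ 90 planted objects
per noisy check. The type-I rate of the full pipeline is expected within
binomial noise of the nominal 5 %, and a planted 40 % density reduction
must be detected in ≥ 80 % of runs, mirroring the loss-of-function effect
sizes the workflow was designed to resolve.

One validation target cannot be computed self-contained: reproducing the
published per-animal one-way ANOVA statistics (F = 11.100, F = 22.120,
F = 0.679) requires the per-animal source tables distributed as
supplementary files with the original study, which are not redistributable
here. The corresponding check looks for user-supplied CSVs under
`inst/extdata/source_data/` and fails with a clear message until they are
provided.

## Known limitations

* Strictly 2D: no z-stacks, no 3D objects, no projection logic.
* No image registration and no proprietary microscope formats — TIFF only.
* Apposition is binary mask overlap; intensity-weighted colocalization
  (Manders, Pearson) is deliberately out of scope.
* Laminar compartment labels (e.g. stratum pyramidale vs radiatum) are
  user-supplied ROI annotations; the package does not infer them.
* The Mann–Whitney branch uses the exact null distribution only where
  `stats::wilcox.test` does (no ties, small n); with ties it falls back to
  the normal approximation, as in standard R practice.
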