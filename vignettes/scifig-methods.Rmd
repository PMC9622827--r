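---
title: "Methods: copy-move detection, image ranking and provenance graphs for scientific figures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy-move detection, image ranking and provenance graphs for scientific figures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and of the
design choices that were genuinely open: what each stage computes, which
parameters matter and why their defaults are what they are, what the
synthetic phantoms emulate, and what the passing test suite does and
does not demonstrate about real figures.

## The copy-move model

Copy-move manipulation duplicates a region within one figure, either to
multiply an object (a band, a group of cells) or to paint background over
unwanted content. Scientific figures differ from natural photographs in
three ways that drive the design: they are compound (multiple panels plus
lettering), they have large uniform backgrounds and a compressed
intensity range, and the same lettering legitimately recurs across
panels. The detector therefore (1) splits the figure into panels,
(2) erases detected text and excludes flat regions from matching, and
(3) searches for near-exact patch correspondences *within* each panel and
*across* every unordered panel pair.

### Dense features

Each pixel is described by one of two complementary feature vectors:

* **Zernike magnitudes** (d = 12): `|Z_nm|` for `n <= 5`, `m >= 0`,
  `n - m` even, computed over the circular patch of radius
  `zernike_radius_px = 8` on luma. The moment is the projection of the
  (mean-centered, except for `n = m = 0`) patch onto the complex Zernike
  polynomial `V_nm`; rotating or mirroring the patch multiplies `Z_nm`
  by a unit complex factor or conjugates it, so the magnitudes are
  exactly invariant. Mean-centering all higher-order kernels makes a
  constant patch map to a single nonzero feature, and makes the
  invariance exact on the discrete grid for 90-degree rotations and
  mirrorings (the disk grid maps onto itself). The implementation
  evaluates all twelve projections by FFT correlation; the unit tests
  check it against an independent direct double-summation oracle at
  `1e-6`.
* **Raw RGB patches** (d = 192): the `8 x 8 x 3` block around the pixel,
  raveled row-fastest. This is deliberately *not* invariant to anything:
  it is the discriminative branch that separates visually similar but
  non-identical content (e.g. two different blots), and it carries a
  component permutation realizing a horizontal mirror so the search can
  match a patch against mirrored copies.

Pixels whose patch support leaves the panel, or whose local standard
deviation (luma for the Zernike branch, best channel for the RGB branch)
falls below `min_patch_sd = 2.5` intensity levels, are excluded:
*exactly* uniform regions — erased text boxes, constant-luma fills —
match anything at zero cost and would otherwise generate
bidirectionally-consistent false regions. The threshold sits below the
noise level of any real scan, so ordinary noisy background remains
valid.

### Randomized nearest-neighbor field

The search approximates, for every valid pixel `p`, the offset `f(p)` to
the most similar other patch under squared Euclidean feature distance,
subject to `|f(p)| >= min_offset_px = 16` (suppressing trivial
near-self matches). It is the classic randomized scheme: seeded uniform
initialization over admissible offsets; alternating raster/anti-raster
sweeps that propagate the causal neighbors' offsets; and a random search
whose window halves from the image extent down to one pixel. Three
package-specific strengthenings matter:

* propagation also proposes the neighbor's offset adjusted by plus or
  minus 2 along the scan axis — the offset field of a mirrored or
  180-degree-rotated clone is affine with slope -2, which plain
  propagation cannot track;
* in the RGB branch every candidate is evaluated both plainly and
  through the mirror permutation, and the winning flag is carried with
  the offset;
* each random-search scale draws three samples plus one uniform restart,
  which speeds convergence on weakly coherent (noise-floor) regions.

Convergence is verified against exhaustive search. Two regimes are
distinguished deliberately. On fields derived from phantom panels the
production setting (8 sweeps) lands within about 5% of the exhaustive
mean cost in aggregate; run to convergence (128 sweeps on 48x48 fields)
every individual field is within 5%. On i.i.d. random feature fields
no propagation-based search can approach exhaustive cost — there is no
spatial coherence to exploit — so the near-exactness claim is stated,
and tested, for image-derived fields. Ninety-degree-rotated clones are
reachable only through the random-search stage (propagation does not
transpose axes) and are not a tested detection condition; this is a
known limitation.

### From matches to a clone mask

Four filters turn the raw field into a mask, in order:

1. **Bidirectionality**: keep `p` only if
   `max|f(p + f(p)) + f(p)| <= bidir_tol_px = 2` (and, in the RGB
   branch, both directions agree on the mirror flag). A region is
   declared a clone of another only when each maps onto the other.
2. **Noise-floor rejection**: keep `p` only if its match cost is at most
   `max_cost_frac = 0.25` of the field's median cost. A genuine clone
   copies the pixel noise along with the signal, so its cost is near
   zero; coincidental matches between unrelated content cannot beat the
   noise floor. This is what keeps pristine blot backgrounds — weakly
   textured, highly self-similar — from alarming.
3. **Dense linear fitting**: offsets are median-filtered over the kept
   pixels (window `median_window_px = 7`), then each pixel's offset is
   compared with a local least-squares affine model over its
   `(2 * 7 + 1)^2` neighborhood; squared residuals above
   `dlf_error_thresh = 4 px^2` (or neighborhoods with under 6 kept
   pixels) are dropped. Affine, not constant, because mirrored clones
   have linearly varying offsets. Plain and mirrored matches are
   filtered separately, as they follow different local models.
4. **Morphology**: connected regions under `min_region_px = 50` are
   removed, every surviving pixel's partner `p + f(p)` is marked so both
   source and destination appear, and the mask is dilated by
   `dilation_radius_px = 3`. Partner marking precedes dilation so that
   the pre-dilation mask is exactly partner-symmetric — the suite
   asserts this bit-exactly.

The two branch masks are fused by pixelwise union (`fusion = "or"`):
each branch catches clones the other misses (mirrored blots are
invisible to raw RGB without the mirror augmentation; iso-luminant color
clones are invisible to luma-based Zernike), so union maximizes recall.
Intersection is available as a configuration alternative for
precision-critical screening. None of the numeric defaults above is
prescribed by theory; they follow the dense-field copy-move literature
and are all exposed in `copymove_config()`.

## Image ranking

The retrieval engine answers "which indexed figures share content with
this one". Interest points are scale-space maxima of the
scale-normalized determinant of the Hessian over a Gaussian stack
(`sigma = 1.6 * 2^(k/3)`, k = 0..7 — the third-octave spacing keeps
descriptors stable across the moderate 0.8-1.2x rescaling typical of
figure reuse). Descriptors are upright SIFT-style gradient histograms
(4x4 cells x 8 orientations, Gaussian-weighted, clipped at 0.2 and
renormalized) mapped through RootSIFT, so Euclidean distance emulates
the Hellinger kernel. Orientation normalization is deliberately absent:
figure reuse rarely rotates content, and an upright descriptor is both
cheaper and more discriminative for this material. Mirroring, however,
is common, so every figure is additionally described on its horizontal
mirror and the index records the flag.

The index is flat and exact; at case scale (hundreds of figures, under a
million descriptors) approximate indexing buys nothing. Voting is
uniform — each of the 8 nearest entries per query descriptor casts one
vote; distance-weighted voting is a possible refinement that was
considered and not adopted, to keep the vote count interpretable as "how
many local structures agree". Entries pointing back to the query's own
figure are skipped without consuming a neighbor slot, since ranking a
figure against itself is uninformative. Ties break by ascending summed
neighbor distance, then id, making ranks fully deterministic.

## Provenance graphs

Pairwise evidence is the inlier count of a geometric verification:
mutual-nearest-neighbor descriptor matches filtered by Lowe's ratio test
(0.8), then a seeded RANSAC affine fit (tolerance 5 px, 1000 draws, with
a least-squares refit on the consensus set). Counts below
`min_inliers = 8` are zeroed — below that, a spanning forest would
happily chain figures on descriptor noise. The adjacency matrix is
symmetric by construction (match counts have no direction), so direction
comes entirely from metadata: Kruskal's maximum spanning forest is
extracted (ties broken by lexicographic id pair for determinism), and
each chosen edge is oriented from the earlier publication date to the
later. Equal or missing dates orient by ascending id; only the
*later-to-earlier* direction is forbidden, because publication order is
the one thing the pixels cannot contradict. The suite fuzz-tests 100
random adjacency/date instances and asserts zero date violations and
acyclicity, and cross-checks the forest weight against an independent
minimum-spanning-tree implementation on negated weights.

Two evaluation-condition notes. The keypoint budget for adjacency
construction is 1000 per figure in the tests and the acceptance script:
measurements showed that a larger budget (the `match_pair()` API default
of 2000) *reduces* chain-recovery accuracy, because the extra fine-scale
points match between any two related figures and dilute the
adjacent-versus-skip ordering that the spanning forest depends on. And
chain recovery is not seed-proof: on some generated chains a
grandparent's *net* scale ratio to a figure lands nearer 1 than the
parent's (two resize steps can cancel), and since multi-scale upright
descriptors degrade with net rescale, the skip edge can narrowly
out-score the true edge, costing one edge of EO. This mirrors how
provenance systems degrade on real data and is reported, not patched.

## The synthetic phantoms

The generator provides the study conditions: western-blot-like panels
(light background 220-240, dark Gaussian-blurred elliptical bands in
lanes, additive Gaussian noise sd 3), micrograph-like panels (textured
dark background, bright Gaussian blobs of radius 5-15 px under
Poisson noise), iso-luminant chroma panels (smooth chroma noise at
constant luminance 128 — constructed so only a color-sensitive branch
can see clones there), glyph labels from a built-in 5x7 bitmap font,
planted clones with exact ground-truth masks, and reuse chains (crop
retaining at least half the area per side-scale 0.75-0.92, resize
0.8-1.2x, brightness within 10 levels, optional mirror; strictly
increasing dates). All appearance constants are fixture choices made
once to resemble the imagery class at realistic noise levels; they are
not claims about real blots or micrographs. Everything is a
deterministic function of its seed, and test problem sizes (panels of
roughly 100-200 px per side, chains of up to 7 figures, indexes of up to
40 figures) were chosen as the smallest sizes at which every stage's
behavior is non-trivial.

What passing tests show: the implementation is correct against
independent oracles, convergent, deterministic, and able to recover
planted manipulations under the stated conditions with high F1 and exact
ranks/chains. What they do not show: performance on real retracted-paper
figures, which have JPEG artifacts, rescans, annotation overlays, and
laxly annotated ground truth — on such data, published dense-field
detectors report far lower F1, and nothing here contradicts that. The
synthetic numbers are upper bounds under clean conditions, not forecasts.

## Numerical and interface choices

* 8-bit internal representation; grayscale stays single-channel until a
  stage needs three channels; high-bit-depth input is min-max stretched.
* All coordinates are 0-based, row-major, half-open — including in every
  JSON interface; R's 1-based indexing appears only at the point of use.
* Dates parse as ISO-8601, with bare years read as January 1st.
* Degenerate inputs have defined behavior throughout: empty masks
  compare as 1.0 in IoU/F1 (so pristine evaluations are well defined),
  featureless images yield empty keypoint sets and empty ranks, panels
  smaller than the feature support are skipped with a warning.
* The CLI writes a manifest (parameters, seed, versions) next to every
  output; identical manifests reproduce bit-identical outputs. Config
  files are YAML, the natural serialization for R tooling in this stack.
* The panel segmenter is a deterministic stand-in with the same
  interface a learned detector would have; its single-glyph aspect
  limit (width at most twice height) is deliberately stricter than a
  generic text heuristic so that blot bands are not mistaken for
  lettering and erased.
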