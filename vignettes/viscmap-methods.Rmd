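---
title: "Methods: models, parameters and design choices in viscmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in viscmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viscmap)
```

# Scope

`viscmap` analyses volumetric two-photon calcium imaging of brainstem
interoceptive neurons — nucleus-of-the-solitary-tract (NTS) populations whose
nuclei carry a red genetically encoded calcium indicator and which respond to
visceral stimuli: graded balloon distensions of gastrointestinal sites and
chemical perfusions of the larynx or duodenum. The pipeline runs from an
image stack to biological summaries: nucleus detection, fluorescence
extraction, ΔF/F, response calling, adaptation-kinetics classification,
organ-tuning profiles, spatial segregation statistics and paired-stimulus
suppression. Because raw recordings of this kind are rarely shared, the
package ships a synthetic-experiment generator with complete ground truth;
every stage is validated against it.

# The measurement model

## From pixels to ΔF/F

Nuclei are detected on a time-averaged image by normalized cross-correlation
against a Gaussian kernel sized like an average nucleus
(`detect_nuclei()`); the correlation map is thresholded, connected
components are filtered by area, and adjacent detections are resolved by
keeping the higher-correlation peak. The correlation threshold (default
0.5) and area bounds (default 20–400 px) are not dictated by any published
value; they are exposed as arguments, and manual mask curation is replaced
by the area filter plus an optional exclusion list so that runs are exactly
reproducible.

Raw fluorescence `F[i, t]` is the mean over each mask's pixels
(`extract_fluorescence()`), and

$$\frac{\Delta F}{F} = \frac{F_t - F_0}{F_0},$$

with `F0` averaged over a 24-s pre-stimulus window (30 frames at the
default 1.25 volumes/s). Traces are then detrended by subtracting a linear
fit to the stimulus-free frames, which removes photobleaching-like drift;
duodenal chemical perfusion runs are exempted (`exclude = TRUE`), because
their genuinely slow responses would be absorbed into the trend. A linear
model was chosen as the least structured option consistent with
"detrending"; a running-percentile alternative can be substituted by
detrending traces externally before calling.

## Units of the response threshold

The response threshold is `theta = F0 + 2.5 * s0`, with `F0`/`s0` the mean
and SD of the pre-stimulus baseline. `viscmap` computes these statistics on
the ΔF/F trace itself (post-detrending), so `theta` lives in ΔF/F units and
`F0 ≈ 0`. This is the only reading under which comparing in-window ΔF/F
against `theta` is dimensionally coherent, and it is applied uniformly.

## Response criteria

A mechanical (distension) response requires, within the stimulation window:
ΔF/F above `theta` for **more than three** continuous frames (strict: a
3-frame run fails, a 4-frame run passes), and above both
`F0' + 2 s0'` (statistics of the 7 pre-onset frames) and `theta` for at
least two continuous frames. A chemical response is evaluated over the
stimulation window **plus the 20 frames after offset**, with the first
requirement strengthened to more than four continuous frames and the local
bound computed from the 25 pre-onset frames. Both boundary readings are
pinned by tests.

Response magnitude is the maximum of the 5-frame moving-averaged ΔF/F over
the same window, minus `theta`. The moving average is centred and shrinks
at trace edges (alignment is not externally specified); it is computed by
shifted-column means rather than cumulative sums so that identical response
shapes anywhere in a recording produce bit-identical magnitudes — this
matters for the suppression classifier, whose criteria are strict
inequalities between repeated measurements.

## Adaptation kinetics

Responders are clustered on onset-aligned, peak-normalized response windows
with k-means (k = 2, Euclidean distance, 10 restarts under a fixed seed;
none of these are externally specified). The cluster whose mean trace has
the larger late-window/early-window ratio is labelled *slowly adapting*
(sustained); the other *rapidly adapting* (onset transient). Fewer than two
traces yield `"none"`; indistinguishable traces collapse to a single
effective cluster and are all labelled `"slow"`.

# Spatial statistics

## Segregation index

For two labelled groups of somata $X$ ($n \ge 2$) and $Y$ ($m \ge 2$), each
point contributes its mean distance to the other group minus its mean
distance to its own group (self excluded); the average over all $n + m$
points is the numerator. The denominator is the label-permutation null: for
each random permutation of the pooled positions the same construction is
evaluated with a "+" sign (mean cross-distance plus mean within-distance,
halved), and averaged over 1,000 permutations. SI ≈ 0 for intermingled
groups, > 0 for segregated domains, < 0 for interleaved lattices.

Numerical notes:

* The implementation reduces each permutation to two submatrix sums over a
  precomputed distance matrix; a literal $O((n+m)^2)$ transcription of the
  defining sums is kept in the test suite and must agree to at least ten
  significant digits on shared permutation draws.
* When $(n+m)! \le 10{,}000$ the permutation average is enumerated exactly,
  so small instances are deterministic; otherwise permutations are drawn
  uniformly with replacement under a caller-supplied seed.
* In the defining expression the final within-group sum is written with an
  index range whose literal bounds would address elements beyond the pooled
  vector; the only coherent reading — within-group distances of the
  permuted second group — is implemented in both the fast path and the
  test-suite transcription.
* SI is computed on in-plane (x, y) coordinates by default, matching
  per-plane analysis; `dims = 3` enables volumetric distances.
* Pooling across fields of view divides the mean of per-FOV numerators by
  the mean of per-FOV denominators (`pool_segregation()`), not the mean of
  per-FOV ratios.

## Shuffle tests, density maps, enrichment

`pairwise_distance_shuffle_test()` compares within- and cross-label
pairwise distances against label reassignments that preserve per-FOV label
frequencies, controlling for regional density variation; neuron-to-bouton
comparisons reuse the identical contract with structure classes as labels.
Density maps are Gaussian kernel densities normalized per label
(`MASS::kde2d`, with the bandwidth argument expressed directly as the
kernel SD in μm). The enrichment index
$(P_{+} - P_{-}) / (P_{+} + P_{-})$ contrasts response frequencies of a
Cre-labelled class and its complement and is undefined (NA) only when both
frequencies are zero.

Bouton centroids are recovered by Canny edge detection (Gaussian smoothing,
Sobel gradients, non-maximum suppression, two-threshold hysteresis —
implemented in `canny_edges()`, as no installed R package provides it),
followed by morphological closing of the thinned edge rings, hole filling,
and area-filtered connected components.

# Suppression classification

With trials measured in the fixed order stomach, duodenum, mix, stomach,
duodenum, mix, a duodenal response is *suppressed* only if
$d_{M1} < d_{D1}$, $d_{M2} < d_{D2}$ and $(d_{M1} + d_{M2})/2 < d_{D2}$
(stomach responses: the same with $d_S$ substituted). All inequalities are
strict, so exact ties — including the third criterion's boundary — are not
suppressed. The third criterion compares the mix average against the
*second* single trial only; whether that asymmetry is intentional is not
stated where the criteria are defined, and the literal form is implemented.

Two behaviours of these criteria are worth knowing when interpreting
fractions. First, a neuron whose mixture response truly equals its single
response sits exactly at the tie point, and symmetric measurement noise
satisfies the three strict inequalities in roughly a sixth to a third of
such neurons (the eligibility requirement of responding in both single
trials skews the single-trial magnitudes upward, raising the rate); called
suppression fractions therefore overestimate small true fractions. Second,
multiplicative signal loss over the session (photobleaching) biases every
mix-vs-single comparison because mixes are measured later; linear
detrending removes additive drift but cannot undo a gain change. The test
suite therefore validates the classifier as exact on noiseless data and as
a strong discriminator (sensitivity ≥ 0.9, wide margin over the tie-break
rate) under noise with drift disabled.

# The synthetic experiment generator

`generate_experiment()` emulates the target preparation: a
509.12 × 509.12 × 320 μm field imaged as five 512 × 512 planes at 1.25
volumes/s with ~2,800 nuclear-labelled neurons. Defaults are fixed once and
are the conditions under which all recovery tests run:

| parameter | default | meaning |
|---|---|---|
| `frac_selective` / `frac_multi` | 0.54 / 0.06 | fractions of **all** neurons tuned to one / several organs; the remainder never respond. Together they give 60% responders with 90% single-organ selectivity among responders |
| organ domains | stomach and duodenum centroids 60 μm apart, 40 μm spread | Gaussian spatial domains at the documented centroid-segregation scale |
| `frac_rapid` | 0.5 | responders with rapidly adapting kinetics |
| `kernel_rise_s` / `kernel_decay_s` | 0.3 s / 1.5 s | indicator rise/decay (difference-of-exponentials) |
| `adapt_tau_s` | 8 s | within-stimulus exponential relaxation of the rapid class |
| amplitude | lognormal, median 1.0 ΔF/F, sdlog 0.35, floor 0.4 | per-neuron peak response; no published amplitude distribution exists for this preparation, so this is the package's own choice of a realistic nuclear-indicator response range, stated here and not presented as a literature value |
| dose response | Hill, exponent 1.5, per-organ EC50 (stomach 300 μl, duodenum 100 μl) | saturating amplitude scaling with distension volume |
| `noise_sd` | 0.1 ΔF/F | per-frame trace noise |
| `drift_rate` | 0.02 / min | multiplicative photobleaching of raw fluorescence |
| suppression | duodenum by stomach, fraction 0.3, strength 0.7 | multiplicative amplitude loss during simultaneous presentation, scaled by the suppressor's Hill dose factor |

Each stimulus's unit response shape is peak-normalized before scaling, so a
configured amplitude is exactly the trace maximum within that stimulus
window. Slowly adapting shapes plateau for the stimulus duration; rapidly
adapting shapes relax during it; both decay with the indicator time
constant after offset and are clamped to zero below 10⁻⁴ so stimulus-free
stretches are exactly quiet.

Rendering (`render_movie()`) draws each neuron as a 2D Gaussian nucleus on
its nearest plane — no axial PSF blur, chosen for test simplicity — with
additive pixel noise, and writes multi-page TIFF. The generator can enforce
a minimum in-plane separation between somata and an FOV edge margin; the
end-to-end recovery tests use that *well-separated regime* because they
validate the round trip, not the crowded-field limit.

What the generator does **not** emulate: brain motion (motion correction is
out of scope; real movies must be registered first), vascular artefacts and
occlusions, anaesthesia-state drift, correlated network activity, overlap
of somata in depth, and trial-to-trial response variability beyond additive
noise. Passing recovery tests therefore demonstrate correctness of the
analysis on data obeying the stated model, not robustness to every failure
mode of real recordings.

# Problem sizes and determinism

Recovery tests run at 2,000 neurons (response calling, tuning structure),
500 (suppression under noise), 200 replicates of 50 + 50 points (SI null
calibration), and a 30-neuron single-plane movie for the full imaging round
trip — sizes at which every check completes quickly on one CPU while
keeping binomial confidence intervals tight enough to be informative. All
randomness flows from explicit seeds: the generator seeds its own stream
(`withr::with_seed`) and leaves the caller's RNG untouched; k-means
restarts and permutation draws take seed arguments. Fixed seeds reproduce
experiments bit-identically.

# Known limitations

* FOV inclusion filters and per-FOV pooling assume the caller supplies
  per-FOV tables; the package does not manage multi-animal cohorts.
* Group-level hypothesis tests (Mann–Whitney, Kruskal–Wallis and similar)
  are left to standard tools; the package produces the per-neuron and
  per-FOV quantities those tests consume.
* The suppression dose-series is summarized as a magnitude-vs-co-intensity
  table without a model fit, as no functional form is established.
* Bleed-through removal for two-channel bouton imaging is reduced to the
  caller's upstream unmixing; only the geometry analysis is provided.
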