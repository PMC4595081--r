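---
title: "Coarse-to-fine statistical detection of complex worm postures"
author: "wormtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-to-fine statistical detection of complex worm postures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormtrace)
```

## The problem

Automated trackers reconstruct the midline of *C. elegans* from video to
quantify posture and locomotion. Most single-frame methods segment the
animal by thresholding against the background, which fails whenever the
body touches or overlaps itself — exactly the coiled, spooled and
omega-shaped ("complex", non-self-avoiding) postures that dominate the
behavior of severe coiler mutants. `wormtrace` implements a generative
statistical detector that works from one grayscale frame at a time, with
no temporal initialization: the detection problem is embarrassingly
parallel and detection errors cannot propagate between frames.

## The model

### Edges and mid-level features

Eight binary edge types (four orientations of the edge line x two
polarities) are extracted by comparing adjacent pixel intensity
differences against a threshold, with non-maximum suppression along the
difference direction. Because only differences are compared, the edge map
is invariant to affine intensity changes, which is what makes the
detector robust to contrast rescaling and moderate blur with no parameter
changes. Our suppression window extends two pixel pairs to each side but
only same-polarity differences compete: a blurred boundary ramp collapses
to a single edge line, while the closely spaced *inverse*-polarity pair
produced by the brighter interior of the head is preserved.

Mid-level features are likelihood-ratio count tests on the edge arrays,
evaluated at the centers of a coarse grid whose cell is a quarter of the
worm width. A *body* feature expects two inversely polarized edge bands
one worm width apart (the two sides of the dark body); a *head* feature
additionally expects an inner inversely polarized pair from the lighter
anterior interior; a *double-body* feature places the bands two worm
widths apart and detects two body segments pressed together, registering
at the hypothesized centers of both segments. Bands rather than lines
give invariance to the exact edge position. Three details matter in
practice and are our own design choices: diagonal-orientation bands are
half as thick as axis-aligned ones (axis-aligned boundaries also produce
diagonal pixel-pair differences, and the thinner band keeps that
cross-talk below threshold); each band's count is capped at the number of
lattice steps a single ideal boundary can contribute (duplicate parallel
edges add no evidence); and body-type masks require each band to pass a
per-area threshold individually, so a single curved boundary sweeping
through both bands cannot imitate the two-sided geometry.

### The coarse model

A posture is a sequence of coarse-grid points in which consecutive points
are 8-neighbors, the direction changes by at most 45 degrees per step
(bounded body curvature), and the midline is self-avoiding. We add one
further admissibility rule: non-consecutive points may not be 8-adjacent.
At quarter-width resolution two distinct stretches of midline are always
several cells apart — even tightly pressed segments keep their midlines a
body width apart — and without this hard core the search can profitably
loop back alongside itself to harvest the same image evidence twice.

The data model assigns a correctly oriented feature probability `p_high`
on the midline, `p_med` at the two orthogonal neighbor cells, and `p_low`
anywhere else (defaults 0.80 / 0.70 / 0.01, estimated once from labelled
synthetic scenes and frozen). The likelihood is a product over grid
*locations*: every location contributes exactly once, and a location
claimed as an orthogonal neighbor is upgraded if the path later passes
through it. This set-based accounting is essential — scoring each step
independently double-counts shared locations and rewards self-adjacent
paths.

The length prior is `exp(-A (n - lambda)^2)` with `lambda` the expected
midline length. We measure `n` as lattice arc length (diagonal steps
count `sqrt(2)`), which makes the prior independent of body orientation;
`A = 0.15` was calibrated once against the generator, where the body
length is known exactly, and reflects the assumption that length is known
per developmental stage. The prior applies to the body search only: the
head sub-instantiation is a short prefix scored by likelihood alone
(a prior pulling it toward full body length would reward arbitrary
growth).

### The search

Detection is head-first: head features are sparse, so their connected
clusters yield a handful of candidate start pairs (in hard cases two or
three clusters are kept and all are tried — avoiding an all-or-none
decision at the head stage). From each head sub-instantiation a beam
search grows the body one point at a time from either end, keeping every
candidate whose log posterior is within `DIFF` of the best, one candidate
per endpoint, and stopping after a fixed number of non-improving
iterations (2 for the head, 3 for the body) so it can cross short feature
gaps. `DIFF` is `alpha = 3` times the log-likelihood-ratio gap between a
perfect and a worst-case additional point. The body stage scores against
the union of body and double-body features. A final pass re-runs the body
search from the head end of the winning instantiation, which otherwise
stays frozen where head features stop. If no head feature fires anywhere
(e.g. heavy blur erases the interior head structure), a body-only search
seeded at the strongest body cell is used and the result is flagged
`low_confidence`.

The beam inner loop is implemented in C++; with an unbounded beam
(`DIFF = Inf`) the per-endpoint reduction is bypassed and the search
enumerates exhaustively, which is how the test suite verifies exact
equivalence with brute force on small grids.

### The fine model

The coarse midline is lightly smoothed, extended at both ends (the coarse
search stops short of the featureless tapered tail and overruns under
blur; the extension adapts to the length budget `lambda` implies, up to
3/4 width per end), and offset by half a width on both sides to
hypothesize the boundary: a point sequence running from the left side of
the tail, around the head tip, to the right side of the tail. Each point
is restricted to a corridor of pixels around its hypothesis; each segment
has an expected 45-degree-quantized orientation and an expected edge type
determined by which side of the dark body it bounds. The objective sums,
over rasterized segment pixels, the log-likelihood ratio of the expected
edge type (`p_obj` vs `p_bg`, defaults 0.40 / 0.01) and subtracts `B`
(default 1.5) per 45-degree step of deviation from the expected
orientation. Because the objective is a sum over consecutive pairs, the
global maximum over all corridor assignments is found exactly by a
chain-structured dynamic program (also C++). The midline is the midpoint
polyline of opposite boundary points, resampled to 21 points equally
spaced in arc length; the paper-level source does not prescribe the
midline construction, and midpoint pairing was chosen for simplicity and
testability.

## Posture analytics

The midline is divided into 20 equal intervals and the 18 signed relative
angles between next-nearest-neighbor intervals represent the posture
(tail-to-head order; positive = counter-clockwise in image coordinates
with the row axis pointing down). Anterior (posterior) coils are frames
where the head (tail) comes within 5% of the midline length of a body
point at least 15% of the arc length away; the exclusion zone is a
configurable design choice since the proximity rule alone would fire on
the endpoint's own neighborhood. Locomotion states come from a lagged
correlation between each angle and its anterior neighbor over a sliding
window — coherent propagation toward the tail is forward, toward the head
backward, incoherent windows are dwelling and windows with almost no
angle change are quiescent; this explicit, testable classifier stands in
for the external tracker-suite heuristics used in the original analyses.
Eigenworms are the principal components of the centered angle vectors;
spools are postures whose two leading amplitudes satisfy `a1 * a2 > 1`
(severe above 4, figure-eight-like below -4). K-means clustering with a
redundancy of restarts (defaults k = 50, 5 restarts; MacQueen updates,
which converge on the near-duplicate posture sets recordings produce)
summarizes posture space. Coil events are maximal runs of coil-positive
frames; their durations are fitted by maximum-likelihood Weibull (profile
likelihood: closed-form scale given shape, 1-D search over shape, so the
exponential special case is exact), with durations under 2 frames
censored. Transition summaries align state probabilities at coil-event
entries and exits, report the fraction of coil events within 5 s of a
locomotion initiation, and compare directed-state propensities during
coiling against their baselines.

## The synthetic generator

Postures are curvature profiles built from the first six members of an
orthonormal cosine basis over arc length (so the leading eigenmodes of a
generated ensemble are band-limited by construction), integrated into a
midline and swept as a tapered tube: flat dark body on a uniform brighter
background, a lighter interior band over the anterior 15% of the body
producing the head's inner edge pair, sharper tapering at the tail than
at the head. Perturbations emulate the documented operating envelope:
contrast scaling in [0.5, 1.5] about the background level, Gaussian blur
of sigma 0, 2 or 3 px, and additive sensor noise (sd 2 intensity units).
The default geometry is a 180 px body of width 12 px in a 288 x 288
frame. The width was fixed from a physical-consistency argument: at much
smaller widths a 3 px blur erases the interior head structure entirely,
contradicting the premise that head features are detectable under the
documented conditions (real recordings of this kind resolve the worm at
tens of pixels wide).

Families: `straight`, `sinuous` (moderate random low-order bends),
`omega` (deep bend scaled until the head approaches mid-body within the
coil threshold), `spool` (inward spiral whose successive turns lie about
one body width apart — bodies pressed, outer boundaries two widths apart,
the double-body geometry; certified to satisfy `a1 * a2 > 1` in a fixed
reference eigenbasis), `figure8` (opposite-signed end curvatures) and
`random`. All families respect a curvature cap of one worm width of bend
radius and keep the midline simple. `simulate_behavior()` generates
traveling-wave angle dynamics with regime-specific coil injection
(wildtype-like: rare brief omega turns, under 5% of frames;
static-coiler: locking into a frozen spool posture for
Weibull-distributed durations, dwelling throughout; loopy-mover:
continuous high-amplitude waves with coiling during directed motion),
with ground-truth states and coil flags for validating the analytics.

What the generator does *not* emulate: bacterial lawns and debris,
illumination gradients, multi-animal scenes, true 3-D body overlap
photometry, and width variation between individuals. Passing tests on
synthetic scenes therefore demonstrate correctness of the algorithms
under the stated imaging model, not performance on any particular real
recording.

## Numerical choices and limitations

* Coordinates are (row, column), 1-based, origin top-left — the native R
  matrix convention.
* Ties in non-maximum suppression resolve toward the earlier pixel; ties
  between equal-posterior beam candidates keep the earlier-created one;
  all stages are deterministic given the configuration.
* Segment rasterization is classic integer Bresenham, endpoints
  inclusive, join pixels counted once (first segment keeps both ends).
* Reported log posteriors are relative to the all-background model; the
  background constant cancels in all comparisons.
* The head/tail identity is inherited from the head-first coarse stage.
  Under heavy blur the interior head structure is physically
  unresolvable, head features vanish, and the body-only fallback cannot
  identify the head; such frames are flagged `low_confidence`.
* Detected midlines are pixel-quantized with ~2 px boundary spacing, so
  relative angles round-trip to a few tenths of a radian for coiled
  postures (and to ~0.02 rad for straight ones); the angles at the two
  ends are the least reliable.
* Problem sizes used in the shipped tests and the acceptance script: a
  200-frame corpus for detection success, a 10,000-posture ensemble for
  the eigenmode variance target, 500 events for Weibull recovery,
  exhaustive-oracle comparisons on grids of up to 12 x 12 cells. These
  sizes were chosen so that every check reruns from scratch in a few
  minutes on one CPU.

## A worked example

```{r example, eval = FALSE}
cfg <- worm_config()
scene <- render_scene(scene_spec(sample_posture("omega", seed = 2)))
fit <- detect_posture(scene$image, cfg)
summary(fit)
plot(fit, image = scene$image)

# behavior analytics on a simulated recording
sim <- simulate_behavior(120, fps = 10, regime = "static-coiler", seed = 1)
states <- classify_locomotion(sim$angles, fps = 10)
events <- coil_event_stats(list(anterior = sim$anterior,
                                posterior = sim$posterior), fps = 10)
events$fits$anterior$characteristic_duration
```
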