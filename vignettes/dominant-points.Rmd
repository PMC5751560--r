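---
title: "Dominant-point contour extraction: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dominant-point contour extraction: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 5)
library(kdomseg)
```

## The problem

A connected component of edge pixels from a microscopy image — say the
outline of a Drosophila embryo — is an unordered cloud of 2-D points. To
reason about the object it traces (measure it, compare it, or split it from
a neighbor it touches), the cloud must be reduced to an ordered polygon
whose vertices sit at the geometrically meaningful locations of the
contour: corners, extremities, inflections, and the junctions where two
touching objects meet. `kdomseg` fits such a polygon by *k-dominant point
extraction*: a recursive, tolerance-driven growth of a cyclic vertex
sequence, followed by subdivision of the sequence at nonsmooth vertices to
separate touching objects.

## The extraction model

Throughout, the central primitive is the *point-line-segment sum distance*
$\|p-a\|+\|p-b\|$. It is minimal — equal to $\|a-b\|$ — exactly when $p$
lies on the closed segment $ab$, so "$p$ lies on $ab$ up to distortion
$\varepsilon$" is the single relative inequality
$\|p-a\|+\|p-b\| \le (1+\varepsilon)\,\|a-b\|$.

The fitted object is a cyclic sequence of **dominant points**
$\langle v_1,\dots,v_k\rangle$ in which every consecutive pair (including
the closing pair $(v_k, v_1)$) carries a **closed tag**: a closed pair is
a segment already verified to be covered by input points, and no further
vertex may be inserted between its endpoints.

Growth proceeds as follows (`kdp()`):

1. **Initialization.** The first two vertices are the farthest pair of the
   point set. The two cyclic pairs of this 2-vertex sequence are the two
   traversal directions of one segment — the two sides of the eventual
   polygon — and both start open. If the points already cover the segment,
   the set is a 1-piece polyline and extraction stops.
2. **Third point.** The point maximizing the sum of distances to the first
   two is inserted unconditionally. This is the base case of the
   3-dominant-point scheme the method generalizes; no tolerance can be
   satisfied by a genuine corner at this stage (a rectangle's corner is
   nowhere near the diagonal chord), so gating the third point on
   insertability would stall every non-degenerate shape.
3. **Candidates.** Each subsequent round scores every remaining point by
   $f(p)=\sum_i \|p-v_i\|$ over the current vertices and considers up to
   three candidates: the **max**-sum point (hull extremities and corners),
   the **min**-sum point (the discrete analogue of the geometric median;
   on the merged contour of two touching objects it sits at the waist,
   which is why a Fermat-point/geometric-median view motivates it), and
   the **median**-sum point (the lower median order statistic of the
   scores; it can respond to inflections that are neither extremal nor
   central). Each candidate is assigned its best insertion slot among the
   open pairs, and a **balance ratio** — min/max of its distances to the
   prospective neighbors. The candidate with the largest ratio wins
   (ties: max > min > median).
4. **Insertion or reduction.** If the selected candidate is *insertable*
   (within the $(1+\varepsilon)$ bound of at least one open pair) it is
   inserted; the two pairs created by the split are immediately tested for
   closedness, and pairs that close shed the points covering them.
   Otherwise the point set is *reduced*: every open pair is tested for
   closedness, the survivors are partitioned among the open pairs, and the
   extractor recurses on each subset, splicing each child sequence back
   into its parent slot. This divide-and-conquer step is what handles
   concave shapes.

### Slot choice

The insertion slot is the open pair maximizing the confidence of the
derived sequence. Two confidence criteria exist: the number of points the
polyline covers, and the total polyline length. For the length criterion
the *most confident* insertion is the one adding the **least** detour:
among cyclic orders of the same vertices, orders that cross themselves are
strictly longer, so minimal length is maximal geometric consistency. For
max-sum candidates (hull extremal) the detour rule is cheap and reliable
and is the default (`confidence = "length"`). Min- and median-sum
candidates live inside concavities, where a candidate can lie close to the
*line* of a long unrelated chord and the detour rule misplaces it; their
slots are therefore always chosen by the *support* criterion — the number
of points within a small lateral band of the two segments the insertion
would create. An insertion that makes the polyline hug the data scores
high; one that cuts across empty interior scores near zero.

### Closedness

A pair $(v, w)$ is closed when the points near the segment $vw$ cover it:
after projecting the nearby points onto the segment and sorting, no gap
may exceed `gap_tol` pixels. Two deliberate choices differ from a naive
reading of the tolerance machinery:

* **Nearness is absolute, not relative.** A point is "near $vw$" when its
  lateral distance is at most `lateral_tol` pixels. A relative
  $(1+\varepsilon)$ band would grow with the segment: a 200-px chord would
  accept points 20 px away, so a long chord spanning the waist of two
  touching objects would be witnessed as "covered" by the very points that
  dip away from it, sealing the concavity. The relative band is the right
  notion for *insertability* (a property of the polyline's shape); for
  *coverage* (a property of the sampling) the resolution is the pixel
  scale of the edge map, not the chord length.
* **Evidence is the whole level's point set.** Points spent by one pair
  still witness the coverage of a neighboring pair: the two bands overlap
  near a shared vertex, and forgetting spent points would leave every
  corner with a systematic hole. For the same reason, a gap adjacent to a
  segment endpoint (the bite a neighboring pair's removal takes out of a
  shared corner) is forgiven up to `2 * gap_tol`, while interior gaps —
  the signature of an uncovered corner or concavity — never are.

### Recursion bookkeeping

Each recursive call receives its subset *plus* the two bracket vertices of
the parent pair it subdivides, so the child's sequence normally begins
with them as its farthest pair. The reverse side of the child's initial
segment coincides with the parent's chord; it starts closed, so no vertex
can be inserted on a side of the cycle the parent polyline already
accounts for, and splicing the child back is unambiguous (the vertex path
between the brackets replaces the parent slot, carrying the child's tags).
Points are partitioned among open pairs by the sum-distance *excess*
(sum distance minus segment length — a collinearity defect), gated so a
point is only assigned to a pair whose segment span contains its
projection; the degenerate initial 2-vertex cycle is split by side.

### Consolidation

Three deterministic passes run after growth; all operate with the same
tolerances as the growth itself and none introduces new parameters.

* **Duplicate merge.** Sibling subtrees cannot see each other's
  insertions, so two children occasionally contribute near-coincident
  vertices for the same feature. Consecutive vertices closer than
  `gap_tol` are merged, keeping the one whose removal would shorten the
  cycle more (the actual apex).
* **2-opt uncrossing.** A valid geometric sequence is a *simple* cyclic
  polyline. Among cyclic orders of a fixed vertex set the simple orders
  are strictly shorter, so reversing any sub-path whose reversal shortens
  the cycle — classic 2-opt — repairs local order damage; closed tags are
  then recomputed as plain coverage facts.
* **Straight-run removal and corner snap.** A vertex deviating from the
  chord between its own neighbors by less than `lateral_tol` encodes no
  feature the tolerances can resolve and is removed (this is the familiar
  requirement that a non-vertex point of a rectangle must not survive as
  a dominant point). Finally, each max-origin vertex is re-estimated as
  the intersection of total-least-squares lines through its two adjacent
  coverage bands, snapped to the nearest input point. A single extremal
  sample under jitter can slide several pixels along the flat ridge of
  the score function; averaging over the two adjacent runs is limited
  only by the jitter itself. Moves beyond `gap_tol` (ill-conditioned,
  near-collinear intersections) are rejected, and min/median-origin
  vertices — junctions and inflections, which are not corner-like — are
  left untouched.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `eps` | 0.02 | relative | distortion tolerated when a point is tested against a segment (insertability); meaningful range about 0.01–0.05 |
| `confidence` | `"length"` | — | slot criterion for max-sum candidates (`"count"` selects coverage support for them too) |
| `measure` | `"max_min_median"` | — | candidate scheme; `"max_only"` suffices for convex shapes and is cheapest |
| `gap_tol` | 5 | px | maximal projected gap in a covered segment; also the duplicate-merge radius and corner-snap guard |
| `lateral_tol` | 3 | px | how far off a segment a point may sit and still cover it; also the straight-run removal threshold |
| `max_depth` | 4 | — | reduction recursion limit |
| `min_subset` | 5 | points | subsets smaller than this are represented by their farthest pair only |

`gap_tol` and `lateral_tol` are pixel-scale resolutions tied to the kind
of edge map the method consumes: 1-px sample spacing with sub-pixel jitter
gives projected-gap noise whose tail crosses 3 px routinely (about 400
gaps are tested per shape), hence 5 px for gaps along a segment; lateral
deviation is bounded by edge thickness plus jitter, hence 3 px across it.
Both are far below the span that a genuinely missed corner leaves
uncovered, which is what the closedness test must detect.

## Subdivision of touching objects

On a smooth closed contour — even a concave one with inflections — the
cross angle at every dominant point (between the direction vectors to its
cyclic neighbors) is obtuse. Where the contours of two touching objects
meet, the angle is acute. `label_vertices()` classifies vertices by this
dichotomy (threshold `pi/2` by default — the literal acute/obtuse
boundary, configurable because junction wedges vary),
`split_at_nonsmooth()` cuts the cycle at the acute vertices (each shared
by its two adjacent arcs), and `longest_smooth_subsequence()` returns the
dominant arc. The pipeline closes each arc into a polygon, by default by
least-squares ellipse fitting — appropriate for ellipsoidal objects such
as embryos — with a chord fallback for degenerate vertex sets.

## The synthetic generator

`shape_spec()` / `sample_boundary()` / `render_image()` produce the four
geometric situations the extractor targets, with exact ground truth and
bit-reproducible output: convex polygons (piecewise-linear contours),
ellipses (smooth convex contours), *bean* shapes, and *touching* ellipse
pairs. Defaults: 1-px boundary sampling, Gaussian jitter of 0.5 px,
grayscale noise 0.02 on filled renders — the texture of a thin edge map
from a clean micrograph.

* The **bean** is an ellipse whose polar radius is dented by a cosine
  term, $r(\theta) = 1 - w\sin\theta$ before anisotropic scaling; for
  $w \in (0.5, 1)$ the curve has exactly two inflection points. The dent
  sits on a long flank (a kidney profile); its radius of curvature is
  $(1-w)^2/(2w-1)$ times the shape scale, so the default $w = 0.55$ keeps
  the dent gentle and the inflection angles clearly obtuse, as they are on
  a concave-but-smooth embryo. Depths much beyond 0.6 sharpen the dent
  toward the acute regime and would blur the very dichotomy the
  subdivision relies on.
* The **touching** pair lies side by side, flanks overlapping, the way
  adjacent embryos actually touch: centers offset along the minor axis by
  $0.85\,(b_1+b_2)$. This yields a union contour whose two junctions are
  deep V-notches with wedge angles of roughly 50–70 degrees — comfortably
  acute at the sequence's own vertex spacing, and an order of magnitude
  deeper than the coverage tolerances. (A tip-to-tip arrangement instead
  produces a waist dip of a few pixels spread under a very long chord —
  below any reasonable tolerance, and not how touching embryos look.)
  Touching frames default to 320 x 400 px with semi-axes near (88, 52):
  junction structure has an absolute pixel scale, so the pair is rendered
  at the resolution of a full micrograph rather than a thumbnail. Both
  members are filled at the same gray level, like equally stained tissue;
  the only edges are then on the union contour.

What the generator does **not** emulate: texture and staining gradients
inside the objects, out-of-focus blur, debris and broken edges beyond the
additive noise, multi-object clutter, and junctions of more than two
objects. Passing the packaged tests therefore demonstrates the geometric
behavior of the method on clean edge maps, not robustness to every
artifact of real micrographs.

## The image pipeline

`extract_contours()` chains a Canny-style edge detector (Gaussian
smoothing, Sobel gradients, non-maximum suppression, hysteresis with an
absolute gradient floor), 8-connected component labeling, component
selection (`largest` or `center`), a merge of fragments lying within
`gap_tol` of the selected component (edge response weakens exactly at
junctions, where one contour can break into pieces — harmless, since the
extractor consumes unordered points), the extractor, subdivision, closing
and even-odd rasterization. `evaluate_contours()` scores each ground-truth
object by the best intersection-over-union among the extracted contours
and calls an image a successful detection when every object exceeds 0.9 —
IoU being the standard symmetric choice of overlap measure.

```{r example, eval = FALSE}
sp  <- shape_spec("touching", seed = 3)
img <- render_image(sp)
res <- extract_contours(img$image)
plot(res$fit)
mask_overlap(res$contours[[1]]$mask, img$masks[[1]])
```

## Numerical choices and degenerate inputs

All argmax/argmin ties break toward the lowest point or slot index, so
every result is deterministic; there is no randomness anywhere in the
fitting chain. Duplicate input points are collapsed on construction. A
candidate coinciding with — or within `gap_tol` of — an existing vertex is
degenerate (balance ratio 0) and can never be selected; a round offering
only degenerate candidates falls through to reduction. Point sets smaller
than `min_subset` are represented by their farthest pair. Zero-length
segments, collinear triangles (for the Fermat point), sequences with
fewer than 2 vertices, and insertion into closed pairs are errors.

The problem sizes used throughout the tests — boundaries of 300–1300
points, images of 160 x 200 to 320 x 400 px, and 50–200 trials per
property — were chosen so the full suite exercises every code path at the
generator's study conditions while remaining comfortable to run
interactively.

## Known limitations

* Junctions are found through the min-sum candidate and the reduction
  recursion; a junction whose notch is shallower than `lateral_tol` is
  below the method's resolution and will be smoothed over.
* The recursion depth default (4) is ample for one or two concavities per
  contour; pathological shapes with many nested concavities need a larger
  `max_depth`.
* The polygon is inscribed in the point cloud, so its mask systematically
  under-covers a smooth region by the chord sagitta the tolerances
  permit; with the defaults this costs a few percent of IoU on smooth
  shapes.
* Contour closing by ellipse fitting presumes roughly ellipsoidal
  objects; for strongly non-elliptical touching objects use
  `close_method = "chord"`.
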