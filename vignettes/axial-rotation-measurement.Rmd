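---
title: "Measuring axial vertebral rotation from AP radiograph landmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring axial vertebral rotation from AP radiograph landmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avrot)
```

## The measurement problem

In scoliosis, vertebrae rotate about their cranio-caudal axis, and tracking
that axial rotation matters for bracing and surgical decisions. On an
antero-posterior (AP) radiograph the rotation is only visible indirectly:
the paired pedicle shadows, which sit posterior to the vertebral body at a
transverse-plane radius $x$ from its centre, displace laterally as the
vertebra turns. `avrot` implements a graphical method that converts that
displacement into degrees using nothing but landmarks a clinician can mark
with pencil and ruler, together with a synthetic "rotation device" that
makes the method's accuracy checkable end to end without any imaging data.

The geometric idea: when the vertebra rotates by $\alpha$, the projected
midpoint of the inter-pedicle distance separates from the projected centre
of the vertebral body width by a distance

$$d = x \tan\alpha,$$

so $\alpha$ can be recovered if $x$ is known. $x$ itself is not visible on
an AP film, but it is strongly proportional to the vertebral body height
$z$, which is visible. The method therefore replaces $x$ by $k\,z$ with a
fixed per-region ratio: $x = 0.75\,z$ for thoracic vertebrae and L5, and
$x = 0.5\,z$ for L1--L4. Reading the rotation then reduces to a
construction performed entirely on the film:

1. outline the vertebral body and mark its centre $A$ as the crossing of
   the outline quadrilateral's diagonals;
2. drop perpendiculars (always to the *bottom edge of the body*, never the
   image axes) through each pedicle's inner contour point; their
   intersections with the bottom and top edges form a quadrangle whose
   diagonal crossing is the inter-pedicle centre $B$;
3. drop the perpendicular through $A$; its foot on the base edge is $C$;
4. for L1--L4, $\alpha$ is the angle at $C$ between that perpendicular and
   the line $CB$ ($B$ lies at half the body height, matching $k = 0.5$);
5. for thoracic levels and L5, first find $D$ halfway between $B$ and the
   top edge (i.e. at $\tfrac{3}{4}$ of the body height, matching
   $k = 0.75$) and use the line $CD$ instead.

Because every element is defined relative to the base edge, the reading is
invariant to the film's absolute size, position and in-plane orientation —
the property tests verify all three to $10^{-9}$ degrees, and the mirror
image of a film yields the negated angle.

### Exact angle versus linearised reading

`measure_rotation()` returns the exact arctangent of the constructed
triangle, which is what a protractor on the film measures. The relation
$d = x\tan\alpha$ is sometimes linearised ($\tan\alpha \approx \alpha$ in
radians); the discrepancy of that shortcut is exposed separately as
`small_angle_error()`:

```{r}
error_table()
```

The discrepancy is negligible to 20 degrees and acceptable to 30, which is
one of the two reasons the method carries a 30 degree validity limit. The
other is anatomical: beyond roughly 30 degrees the concave-side pedicle
shadow merges with the body contour and can no longer be marked.

### Sign convention

The original description reports unsigned protractor readings. `avrot`
signs the angle: positive when the inter-pedicle centre displaces toward
+x of $A$'s perpendicular in the base-edge frame. The magnitude is the
protractor reading; mirroring the film flips the sign.

## The digital rotation device

The physical verification mounted dry vertebrae on a device that sets
rotation from 0 to 45 degrees in 3 degree steps. `vertebra_model()` and
`project_ap()` reproduce that experiment synthetically: a parametric solid
(body height $z$, width, pedicle radius $x$, inter-pedicle gap, optional
wedge angle) is projected to an AP landmark set at a known rotation.

Two forward models are provided. `"tan"` displaces the pedicle points by
$d = x\tan\alpha$ — the relation the method itself assumes. `"sin"`
displaces them by $d = x\sin\alpha$, which is what an orthographic
projection of a point rotating at radius $x$ about the body centre gives.
The source geometry behind the published relation is not recoverable from
its description, so the simulator offers both and the measurement side is
agnostic; the two agree at 0 and diverge slowly (at 30 degrees the sin
model reads $\arctan(\sin 30^\circ) = 26.57^\circ$ on a criterion-exact
phantom). `"tan"` is the default because it is the method's stated
relation.

Default dimensions are round, realistic adult values: thoracic
$z = 20$ mm, width 30 mm, gap 16 mm; lumbar $z = 28$ mm, width 42--46 mm,
gap 24--26 mm. The pedicle radius defaults to the anatomical ratios
$x/z = 1.21$ (thoracic) and $0.86$ (L1--L4). L5 is anatomically lumbar, so
its radius also defaults to $0.86\,z$, while its *measurement rule* is the
thoracic one ($k = 0.75$) — the method's own convention. The silhouette
width is held constant under rotation (the true decrease is slight and
does not observably change the width/height ratio), and the pedicle inner
points sit at half the body height.

Two phantom flavours matter:

- **Criterion-exact** (`criterion_phantom()`): $x$ set to exactly $k z$.
  Projection followed by measurement recovers every angle of the 0--45
  degree series to $10^{-9}$ degrees — the round-trip identity that
  validates the construction code itself.
- **Anatomical ratios**: with $x/z = 1.21$ or $0.86$ the method's rounded
  criteria ($0.75$, $0.5$) no longer match the generating radius, and the
  reading carries the deterministic bias
  $\arctan\!\big(\tfrac{x}{k z}\tan\alpha\big) - \alpha$. The
  implementation reproduces that closed form through the full construction
  to $10^{-9}$ degrees. This bias is a property of the published criteria
  on idealised anatomy, characterised here empirically rather than
  reconciled; on the real films used to calibrate the criteria the
  verification recovered the set angles closely, suggesting the effective
  radiographic lever arm is nearer $k z$ than the anatomical tables imply
  (source-film perspective, which magnifies posterior structures, is one
  plausible contributor and is deliberately not modelled).

### Hidden pedicles

`project_ap()` flags the concave-side pedicle as
`concave_pedicle_missing` when the rotation exceeds the visibility limit
(default 30 degrees) *or* when the projected inner point leaves the body
silhouette — the geometric version of the merge. The simulator always
records the true coordinates (it is a digital device and knows its ground
truth); `drop_hidden = TRUE` blanks them, emulating a human annotator who
can only mark what is visible. `measure_rotation()` applies the fallback —
substitute the lateral body contour at the visible pedicle's height
fraction — only when the flagged coordinate is actually absent. This keeps
the noiseless round trip exact across the whole series while still
exercising the fallback path on demand; measurements above 30 degrees are
always returned *and* flagged, never refused.

### Wedged vertebrae

Severe structural curves present wedged vertebral bodies. The graphical
centre of a wedged outline drifts toward the wedge apex by $d'$, biasing
the reading even at zero rotation (about 7 degrees for a 10 degree wedge
on the default thoracic phantom). The remedy is the compromise
rectangle/rhomboid of `wedge_substitute()`: base parallel to the pedicle
suture, height equal to the convex (undeformed) side, width preserved.
`apply_wedge()` adds the deformity to a phantom, and the tests verify that
substitution strictly reduces the absolute error at every angle of the
series for 5--15 degree wedges. When the two lateral heights are equal
within tolerance the convex side is undefined; the minimal-area bounding
parallelogram is returned with an `ambiguous` attribute.

### Rater noise and the recovery study

`generate_series()` emulates repeated readings: independent Gaussian
jitter (SD in mm) on every landmark coordinate, one observation per
(angle, rater). Each record's noise is seeded by an explicit function of
(seed, rater, angle index), so any single observation is reproducible in
isolation, and the same standard normal draws are scaled by the noise SD —
making measurement spread exactly monotone in the noise level at a fixed
seed. This is the simplest defensible model of annotation jitter; it does
not emulate film contrast, observer systematic error, or inter-landmark
error correlation, so passing recovery tests demonstrate correctness of
the geometry under idealised noise, not clinical inter-rater performance.

`recovery_stats()` groups residuals (measured − defined) by the rule
regions (`Thoracic`, `L1-L4`, `L5`, `All`) and reports bias and residual
SD. Whether a rater study's dispersion should be summarised on raw
readings or residuals is a genuine choice; residual SD is reported because
it is the error the clinician cares about and is invariant to the angle
grid. At 0.5 mm noise with 10 raters on criterion-exact phantoms (the
deterministic ratio bias is a separate, closed-form effect, so the noise
study removes it by construction), group biases stay well under 1 degree:

```{r}
df <- do.call(rbind, lapply(c("Th6", "L2", "L5"), function(lv)
  measure_series(generate_series(criterion_phantom(lv),
                                 n_raters = 10, noise_sd_mm = 0.5,
                                 seed = 2014))))
recovery_stats(df)
```

### Nash-Moe comparator

`nash_moe_grade()` implements the classical five-level grading as a
comparator: the convex hemivertebra (lateral edge to midline) is divided
into thirds; grade 0 is a symmetric pedicle pair, grades 1--3 place the
convex pedicle in successive thirds toward the midline, and grade 4 is at
or past the midline (the at-midline tie resolves to 4). The thirds
convention is the standard one from the orthopaedic literature, external
to this package's own method. The displacement threshold for "symmetric"
defaults to 2 % of the body width — continuous coordinates are never
exactly symmetric. On a noiseless rotation series the grade is
nondecreasing, illustrating how coarse a 5-level scale is next to the
continuous reading.

## Numerical choices and degenerate inputs

- The base edge is the segment between the two designated bottom corners,
  extended infinitely for foot points; a perpendicular/edge intersection
  further than 2x the quad diagonal from the quad centroid is declared
  degenerate rather than extrapolated.
- A quadrilateral is degenerate when its area is below $10^{-9}$ mm² or a
  diagonal-intersection parameter falls outside $[-10, 10]$.
- Point $D$ uses exact midpoint arithmetic (on film it may be estimated;
  there is no reason to emulate that imprecision).
- The angle is computed with `atan2` in the base-edge frame, so vertical
  constructions are exact and no quadrant issues arise; degrees at every
  interface, radians only internally.
- Landmark files may use y-down pixel frames with a `pixel_spacing_mm`;
  conversion happens once at the I/O boundary. Unknown fields in a file
  are rejected, not ignored: silent acceptance of misspelled keys is how
  measurement provenance gets corrupted.
- The pedicle reference point is the inner contour, the recommended
  choice; outer contours or pedicle middles work identically (the
  construction is unchanged — only the landmark semantics differ, which
  the property tests demonstrate by shifting both pedicle points
  symmetrically).

## Problem sizes in the test suite

The invariance properties are checked over 1000 randomised landmark sets,
the recovery study uses 3 phantoms x 16 angles x 10 raters = 480
observations, and the wedge study 2 levels x 3 wedges x 16 angles; these
sizes give stable statistics while keeping the default test run fast.

## Known limitations

- No pixel-level processing: landmarks must be provided, not detected.
- Orthographic projection only; source--film divergence (which magnifies
  the posteriorly located pedicles) is unmodelled, so the simulator cannot
  arbitrate the tan-vs-sin question empirically.
- The anatomical-ratio bias above means absolute accuracy on real,
  anatomically proportioned vertebrae rests on the published criteria
  having been calibrated on real films — the package quantifies the
  sensitivity but cannot resolve it.
- Readings above 30 degrees are returned but flagged; both the
  linearisation error and pedicle visibility argue against trusting them.
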