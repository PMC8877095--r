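---
title: "Reconstructing round bowls from a single top-view ruler image"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing round bowls from a single top-view ruler image}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bowlrecon)
```

## The problem

Estimating how much food or drink a person consumed from a photograph
requires a metric 3D reference in the scene.  For meals served in round
bowls — the dominant food container in much of Asia and Africa — the bowl
itself is the natural reference: once its interior shape is known, the
visible food level pins down the food volume, and the *fullness*
(volume / capacity, in percent) is a robust, unit-free serving measure.

`bowlrecon` implements a single-image bowl pre-measurement: an adhesive
paper ruler with markers every half inch is taped centrally across the
bowl's bottom and sides, and one roughly top-down photograph is taken.
Because the ruler has constant physical width and marker spacing, the
apparent narrowing of its width and the apparent crowding of its markers
in the image encode the distance and slope of every surface patch the
tape crosses.  The package turns those distortions into a metric
surface-of-revolution model of the bowl interior, and then uses that model
to estimate liquid/food volume in later meal images.

## Camera model and measurements

All image-plane arithmetic is metric.  A pixel coordinate $(x, y)$
(centred, $y$ down) maps to image-plane millimetres through the pixel
pitch $s_x, s_y$ and principal-point offset $(o_x, o_y)$:
$x' = s_x (x + o_x)$, $y' = s_y (y + o_y)$.  A camera-frame point
$(X, Y, Z)$ projects to $(f X / Z,\; f Y / Z)$ with focal length $f$ (mm).
Lenses are assumed rectified upstream; the intrinsics record carries an
`undistorted` flag.

From the labelled marker pairs (one point on each ruler border per
marker), the pipeline measures, per marker $i$:

* $W_i$ — the observed ruler width (mm on the image plane), read as the
  vertical chord between two degree-$\le 5$ polynomial border fits
  (valid because the ruler is imaged parallel to the image's bottom edge);
* $V_i$ — the signed offset of the pair's midpoint from the image centre,
  positive in the left half-plane, so the ray angle is
  $\alpha_i = \arctan(V_i / f)$ and the angle between neighbouring rays is
  $\theta_i = \alpha_i - \alpha_{i+1}$.

With ruler width $D$, similar triangles give the initial ray lengths
$r^0_i = f D / W_i$.

## Constrained ray optimization

The unknowns are the ray lengths $r_i$ from the optical centre to the
tape centreline at each marker.  Neighbouring markers are a known arc
length $C_i$ apart (12.7 mm except at the cut tape ends), and the law of
cosines predicts the chord between neighbouring surface points, giving
the objective

$$J(r) = \sum_i \left(\sqrt{r_i^2 + r_{i+1}^2 - 2 r_i r_{i+1}
\cos\theta_i} - C_i\right)^2 .$$

Markers annotated as lying on the flat bottom (the contiguous index set
$\beta$) must share one vertical depth: $r_k \cos\alpha_k$ constant over
$\beta$.  Rather than carrying these equality constraints into a
general-purpose solver, the implementation eliminates them exactly — all
flat-bottom rays are expressed through a single bottom-depth parameter
$d$ as $r_k = d / \cos\alpha_k$ — and solves the reduced bound-constrained
problem ($r_i \in [0.2, 5] \cdot r^0_i$, relative tolerance $10^{-10}$,
at most 500 iterations) with `stats::nlminb` and an analytic gradient.
The constraints therefore hold to machine precision at any iterate.

## Why a refinement loop is needed

Three approximations in the raw formulation are individually small but
are amplified by the geometry:

1. **Tape wrap.**  On the wall the tape bends around the horizontal
   circle of radius $\rho$; the midpoint between the two border landmarks
   images the point at radius $\rho\cos(D/2\rho)$, not $\rho$.  For a
   19 mm tape on a 60–100 mm-wide flat bottom this shifts $V_i$ and $W_i$
   by several percent near the bottom corner.
2. **Arc vs chord.**  $C_i$ is an arc length while $J$ compares chords.
   Along a smooth wall the difference is negligible, but the interval
   that straddles the bottom–wall corner bends sharply, and its chord is
   up to ~15 % shorter than its arc.
3. **A flat objective valley.**  Neighbouring rays are nearly parallel
   (about 2° apart), so coherent radial shifts of a whole wall chain
   barely change any chord.  The optimizer can therefore absorb the
   corner mismatch by sliding one wall several millimetres along its
   rays, reaching $J \approx 0$ at a visibly kinked, wrong cross-section.
   Because the bowl depth (40–70 mm) is small compared to the camera
   distance (~400 mm), a 1 % coherent ray error becomes an ~8 % depth
   error.

`reconstruct_bowl()` therefore iterates a *measurement rectification*
against the current reconstruction: wall offsets and widths are un-warped
($V' = V/\cos\phi$, $W' = W\,\phi/\sin\phi$, $\phi = D/2\hat\rho$), each
interval's chord target becomes $C_i$ times the chord/arc ratio of the
current curve (exactly 1 between flat-bottom markers), and the
corner-straddling interval's target is computed from an explicit local
wall model — a circle through the three innermost wall points (a line if
they are collinear) extrapolated to the known bottom plane.  The
optimization is re-run from the previous solution until the rays are
stable, at most six passes.  Every correction is a deterministic function
of the annotation itself; no tuning constants are involved.  With
oracle-supplied (true) corrections the estimator recovers simulated rays
to machine precision, which is the design argument for the loop; the test
suite verifies that the self-estimated corrections recover capacity,
diameter and depth of nine simulated bowls within 2 % without noise and
keep median capacity error within 5 % at 0.5 px landmark noise.
`refine_iterations = 0` disables the loop and reproduces the raw
original single-pass pipeline, whose depth bias the acceptance tests document.

## Symmetrization and revolution

The optimized rays give cross-section points
$(u_i, w_i) = (r_i \sin\alpha_i,\; r_i \cos\alpha_i)$ in the ruler's
vertical plane.  A round bowl's cross-section must be symmetric, so the
point set is interpolated with a parametric natural cubic spline (in
cumulative chord length, so vertical walls are representable), shifted so
the midpoint of its two rim endpoints lies on the axis, rotated about
that midpoint so both rim endpoints share one depth (the rotation angle
is reduced modulo $\pi$), and the two halves are averaged on a uniform
501-point height grid.  The bowl depth is measured between the polygon
vertices (deepest marker vs rim) rather than on the dense spline, whose
natural-spline overshoot between markers otherwise inflates depth by
about 1 %.  A cross-section whose rim endpoints disagree in depth by more
than 20 % of the bowl depth before rotation triggers an asymmetry
warning (ruler not taped centrally, or camera far off-centre).

Revolving the half-profile $\rho(z)$ about the vertical axis gives
capacity $\pi\int_0^{H}\rho(z)^2\,dz$ by trapezoidal quadrature on the
grid (accurate to well under 0.1 % for cylinders, hemispheres and cones
at the default grid), the rim diameter $2\rho(H)$, and the monotone
level-to-volume table used for meal-image work.  A degenerate all-flat
annotation collapses to a zero-depth plate with zero capacity.

## Locating the bowl in a meal image and estimating volume

The bowl's circular rim appears as an ellipse.  Five or more clicked rim
points are fitted with the direct (conic-constrained) least-squares
ellipse method in its numerically stable partitioned form.  The viewing
rays through the ellipse form an elliptic cone $x^\top Q x = 0$; with
eigenvalues $\lambda_1 \ge \lambda_2 > 0 > \lambda_3$ of $Q$ and the
known rim radius $R$, the circle pose has the closed form used in
`estimate_circle_pose()`.  Every ellipse admits exactly two circle poses,
and both re-project onto the *identical* ellipse, so the ambiguity is
irreducible from the rim alone; the package returns the more upright
solution (the sensible prior for a container standing below a roughly
overhead camera) and reports both candidates in the diagnostics.  Both
branches agree on depth to well under 0.1 %, so distances and level
projections are insensitive to the choice.

Volume is then estimated one of two ways:

* **Level matching** (`match_surface()`): the level-to-volume table is
  swept in fixed volume increments, each level's circle is projected to
  an image ellipse, and the level minimizing the mean squared distance to
  the clicked liquid-surface points wins; a second pass with ten-fold
  finer increments refines the estimate.
* **Food area ratio** (`compute_far()`, `build_far_regression()`,
  `volume_from_far()`): the FAR is the segmented liquid pixel count over
  the within-rim pixel count.  Simulated fills of the reconstructed bowl
  give (FAR, volume) support points, an ordinary least-squares line
  `volume ~ FAR` is fitted, and an observed FAR is looked up on the line
  (clamped to $[0, \text{capacity}]$).  The line is what the original method prescribes;
  for bowls whose FAR–volume relation is visibly convex (dome-like
  profiles) the line misfits the extreme fills by several percent of
  capacity even with $R^2 \ge 0.95$ — the acceptance suite documents this
  honestly as a failing bound rather than papering over it with a
  nonlinear fit the method does not prescribe.

`fullness()` converts a volume to percent of capacity (values above
100 % warn but are returned — mounded foods overfill the rim), and
`density_ground_truth()` implements the weighing-based reference
($\rho = w_c / v_c$, $v_f = w_f / \rho$) used to validate amorphous-food
estimates.

## The synthetic world

All tests run against the forward simulator, which emulates the physical
measurement end to end:

* parametric bowls (cylinder, flat-bottomed spherical cap, power wall
  $\rho(z) = R_b + (R_r - R_b)(z/H)^p$, cone frustum) with closed-form
  capacities; the validation grid spans diameters 100–156 mm, depths
  42–65 mm and capacities roughly 210–850 mL, the ranges of common
  household bowls;
* a phone-like camera (f = 4 mm, 1.5 µm pixels, 4000×3000) about 400 mm
  above the bowl bottom, looking straight down;
* the tape centreline following the central cross-section, markers at
  12.7 mm arc spacing (0.5 in ticks) plus the cut tape end with its
  shorter interval, border points half a tape width (19 mm total) along
  the circumferential surface direction, and i.i.d. Gaussian pixel noise
  (default 0.5 px) on every landmark coordinate;
* simulated liquid fills: the level circle at the table height for the
  requested volume, projected exactly, with surface sample points and
  exact ellipse areas.

What the simulator does **not** model — and what a green test therefore
does not establish — includes segmentation errors in real liquid
boundaries (the shallow-edge under-detection the original experiments
report), lens distortion residuals, off-centre or rotated rulers
(assumptions the method itself makes), rim occlusion of the liquid
surface, non-circular bowls, and outward-curled rims (a known
worst case; the rim is defined as the profile endpoint, with no curl
handling).

## Numerical choices and degenerate inputs

* Border polynomials: degree $\min(5, I - 2)$, with a warning when
  reduced; duplicate abscissae and near-vertical rulers are errors.
* Landmarks are ordered by decreasing $V$ (left to right); a reversed
  annotation is flipped consistently, non-monotone offsets are an error.
* Profile grid: 501 samples; quadrature: trapezoid; level lookup:
  monotone linear interpolation of the cumulative table.
* Optimizer bounds $[0.2, 5] r^0$, relative tolerance $10^{-10}$, 500
  iterations; failure to improve on $J(r^0)$ is an error.
* Corner chord targets are clamped to $[0.7, 1] \cdot C_i$; refinement
  stops early if wrap correction breaks offset monotonicity (noisy,
  extreme annotations) and falls back to the last stable pass.
* Fewer than two flat-bottom markers yield no flatness constraint
  (warning); an all-flat annotation reconstructs as a plate.

## Files and interfaces

Annotations are a CSV point list (`index`, `border`, `x_px`, `y_px`,
top-left origin) with a JSON sidecar (spacing, tape width, flat-bottom
range, image size); intrinsics and bowl models are JSON; meshes export to
OBJ for inspection.  The `bowl_cli()` entry point (installed script in
`inst/cli/bowlrecon`) wires the subcommands `simulate`, `reconstruct`,
`estimate-volume` and `report`.
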