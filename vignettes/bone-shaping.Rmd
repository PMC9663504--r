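---
title: "Morphomechanics of long-bone shaping: model, assumptions and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphomechanics of long-bone shaping: model, assumptions and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bulkybone)
```

## The biological question

Salamander limbs regenerate fully, but the regenerated long bones come out
*bulkier* than bones shaped by normal development: micro-CT comparisons of
regenerated versus contralateral zeugopodial elements show increased diameter
and more ossified volume, and heat maps of shape deviation localize the
difference along the shaft. Two cellular observations motivate a mechanical
explanation. First, chondrocyte divisions in the growing rod-shaped cartilage
are predominantly transversal (division axis nearly perpendicular to the bone
axis), so proliferation pushes tissue outward as well as lengthwise. Second,
the timing of ossification differs: during development, cortical bone is laid
down in the mid-shaft *while* the cartilage is still growing, mechanically
limiting further transversal expansion there, whereas during regeneration the
whole element remains cartilaginous until it has reached roughly its final
size, so nothing restrains radial expansion anywhere along the rod.

`bulkybone` casts this argument as a quantitative morphomechanical model and
supplies the measurement tools (surface-deviation maps, diameter profiles,
division-orientation statistics, labeled-volume quantification) needed to
read out its predictions, exercisable end to end on synthetic data.

## The mechanical model

Growth is slow compared to any viscoelastic relaxation time of the tissue, so
the growing element is approximated as a homogeneous, isotropic,
linear-elastic cylinder (length $L$, radius $R$, Young's modulus $E$,
Poisson's ratio $\nu$). Dividing cells push their neighbours; we model this
as a *body force density* $\mathbf{f}$ (kPa/mm, force per unit volume) with
an axial component $f_a \hat{z}$ and a radial component
$f_r \hat{r}$ pointing away from the bone axis. The cylinder is divided into
$K$ contiguous axial regions (default five:
epiphysis--metaphysis--diaphysis--metaphysis--epiphysis at fractions
0, 0.15, 0.35, 0.65, 0.85, 1), each with its own $(f_a, f_r)$:

* **regeneration** — all regions share the same moduli: growth by uniform
  cartilage expansion;
* **development** — the radial moduli ramp symmetrically from a fraction
  $c$ (default 0.2) at the central region up to 1 at the two end regions,
  encoding the suppression of transversal expansion by early mid-shaft
  cortical ossification. The ramp is linear in region index by default (a
  geometric ramp is available); $c = 1$ degenerates to the uniform case.

Static equilibrium $\nabla\cdot\sigma + \mathbf{f} = 0$ with Hooke's law
$\sigma = \lambda\,\mathrm{tr}(\varepsilon) I + 2\mu\varepsilon$ is solved by
the finite element method on a tetrahedral mesh; vertices are then advected
by the displacement field to produce the grown shape. Repeating
(solve-and-advect) yields growth snapshots; a single step is the default,
keeping the model a single linear-elasticity problem.

Comparing scenarios requires a matched radial "budget": the development
radial moduli are rescaled so that the total radial impulse
$\sum_k |f_r(k)| V_k$ equals the regeneration scenario's. Both runs then
share one load scale, chosen so that the regeneration run's maximum
displacement is 20% of the radius (small-strain guard). The readouts are the
**bulge index** (mean effective radius over the central 20% of the shaft
divided by the averaged end-band radii, a dimensionless bulky-versus-tapered
scalar) and the **signed deviation map** between the two deformed surfaces.

## What the model is *not*

Small-strain linear elasticity with additive advection is the simplest
possible growth kinematics: there is no multiplicative growth decomposition,
no residual stress accumulation across steps, no separate cortical shell
material, and no coupling of the load field to simulated ossification. The
load moduli are phenomenological stand-ins for division-driven pressure, not
measured quantities. The model's claim is qualitative: *uniform* radial
growth yields a cylindrical, bulky rod, whereas *centrally suppressed*
radial growth yields a tapered one.

## Parameters, units and defaults

| parameter | default | units | why |
|---|---|---|---|
| $L$, $R$ | 10, 1 | mm | zeugopod-like aspect ratio for a larval salamander long bone |
| $E$ | 1 | kPa | soft growing cartilage; in linear elasticity $E$ only scales displacements and cancels from all shape ratios |
| $\nu$ | 0.40 | — | nearly incompressible soft tissue; values $\ge 0.49$ trigger a volumetric-locking warning for linear tetrahedra |
| $f_a$, $f_r$ | 0.1, 1 | kPa/mm | axial response scales as $f_a L^2/E$ and radial as $f_r R^2/E$; with $L/R = 10$ these defaults make one normalized step both elongate and thicken the rod by a few percent, so the two scenarios produce shapes of similar length that differ in their thickness profiles -- the readout of interest. The development-versus-regeneration contrast is independent of $f_a$ (identical axial loading cancels between scenarios) |
| center fraction $c$ | 0.2 | — | strength of mid-shaft suppression; the linear ramp and $c$ are this package's operationalization of radial moduli that increase gradually from the center toward the ends |
| normalization | 0.2 | fraction of $R$ | keeps max displacement inside the small-strain regime |
| mesh | 48 × 10 × 24 | layers × rings × sectors | 65,664 tetrahedra; convergence checks show shape ratios are stable at this resolution |

## Numerical choices

**Mesh.** A structured mesher avoids any external meshing dependency:
nodes on concentric rings at each axial layer; the resulting triangular
prisms are split into three tetrahedra each with quad-face diagonals chosen
through the face's smallest global vertex index, which makes adjacent prisms
conform and the mesh watertight by construction. The cross-section is the
inscribed polygon, so the mesh volume is strictly below $\pi R^2 L$ with
relative deficit $1 - \sin(x)/x$, $x = 2\pi/n_{\rm angular}$ (1.1% at the
default 24 sectors), converging as resolution grows. `n_angular` must be
even so the vertex set is mirror-symmetric about the two axial coordinate
planes. External meshes are accepted via the VTU/legacy-VTK readers.

**Element and solver.** Linear (P1) tetrahedra with exact closed-form
stiffness $K_{(a,i),(b,j)} = V(\lambda g_{a,i}g_{b,j} + \mu g_{a,j}g_{b,i} +
\mu\,\delta_{ij}\, g_a \cdot g_b)$; assembly is fully vectorized into sparse
triplets. The constrained system is factorized with a sparse Cholesky
decomposition (`Matrix`); a failed factorization is reported as missing
rigid-body constraints. Relative residuals are checked against $10^{-8}$.

**Body loads.** Consistent P1 integration with the force density evaluated
at each element centroid: every tetrahedron spreads $\mathbf{f}V$ equally
over its four vertices. On the axis the radial direction is zero.

**Boundary conditions.** Growth of a free-standing rod does not dictate a unique constraint set.
The default set here lets the proximal face roll ($u_z = 0$) and enforces
the two mirror symmetries of the loading: $u_y = 0$ on the $y = 0$ plane and
$u_x = 0$ on the $x = 0$ plane. These are satisfied *exactly* by the
axisymmetric growth solutions and by the uniaxial verification fields, kill
all six rigid modes redundantly, and leave radial expansion free everywhere.
A minimal alternative (roller base, one fully fixed near-axis node, one
tangential pin) is available but not recommended: the centroid-sampled
radial load on an unavoidably asymmetric tet decomposition carries a tiny
(~3×10⁻⁴ relative) net lateral resultant, and with only two pinned nodes
resisting it the whole rod deflects visibly sideways.

**Verification problems.** Two closed forms anchor the solver. (i) *Patch
test*: a roller-based cylinder under uniform end traction $\sigma = 0.01E$
has the linear exact solution $u = (-\nu\sigma x/E, -\nu\sigma y/E,
\sigma z/E)$, so mean tip displacement $\sigma L/E$ and lateral contraction
$-\nu\sigma R/E$ are reproduced to solver precision at *any* resolution —
this validates assembly, loads and constraints but cannot show convergence.
(ii) *Body-force case*: a uniform axial force density $f$ with the exact
(quadratic) field
$u_z = f(Lz - z^2/2)/E - \nu f (x^2+y^2)/(2E)$,
$u_{x,y} = -\nu f (L-z)\{x,y\}/E$, prescribed on the base, has a genuine
$O(h^2)$ discretization error; the RMS tip error decreases monotonically
under uniform refinement (measured: 6.1×10⁻³ → 1.4×10⁻³ → 3.6×10⁻⁴ mm over
the three default levels).

**Deviation maps.** Exact point-to-triangle-set distances (face, edge and
vertex cases) per test vertex, cross-checked in the tests against an
independent region-case implementation to 10⁻¹². The map is one-sided
(actual → nominal) and *signed* by the side of the closest triangle's
outward normal, matching industrial nominal/actual comparison conventions;
the headline localization statistic is the peak of the signed map (the
largest outward deviation). At matched impulse the unsigned field has
near-equal magnitudes mid-shaft (where the regenerate is thicker) and at the
ends (where the rescaled development loading is stronger), so the unsigned
peak position is numerically fragile, whereas the positive band is
unambiguously mid-shaft.

**Orientation statistics.** Doublet angles are axial data folded into
[0°, 90°]; a doublet and its reverse give identical angles. The 45°
transversal threshold is the quadrant midpoint (configurable). Group
comparison uses Welch's unequal-variance two-tailed t-test (via
`stats::t.test`; pooled-variance assumptions are avoided by default) or a
seeded permutation test on the Welch statistic with the add-one correction
$(b+1)/(m+1)$ — note the correction bounds attainable p at $1/(m+1)$, so
resolving p below 10⁻⁶ needs more than 10⁶ resamples. Two-dimensional
section data are accepted by zero-padding the third coordinate with an
in-plane axis.

**Degenerate inputs.** Inverted tetrahedra abort assembly naming the
elements; advection that inverts elements aborts naming the step; empty
diameter-profile bins are flagged, never interpolated; zero-variance groups
under Welch are redirected to the permutation test.

## The synthetic-data generators

Every pipeline input can be generated with a seed, alongside its analytic
ground truth, so all tests run without any acquisition:

* `gen_doublets()` — division doublets with polar angle from a
  normal(mean, sd) truncated to [0°, 90°] (closed-form moments), uniform
  azimuth, midpoints uniform in the cylinder; byte-identical under a fixed
  seed.
* `gen_profile_volume()` — labeled voxel volumes of solids of revolution
  $r(z)$ (constant, Gaussian bulge/waist, linear taper) with the
  voxel-center-in-solid rule, the analytic volume $\int \pi r(z)^2 dz$, and
  a matching watertight surface. Voxel counting is not monotone between
  arbitrary resolutions (a lattice-counting effect), but the documented
  halving 0.02 mm → 0.01 mm reduces the error.
* `gen_surface_pair()` — concentric cylinders (known offset everywhere) and
  bulge-versus-straight pairs (known peak) for deviation-map oracles.

These emulate controlled geometry and angular structure only: no imaging
noise, no partial-volume effects, no segmentation error, no biological
variability in the force fields. Passing tests therefore validate the
*computational machinery*, not the model's fidelity to any particular
animal.

## Problem sizes used by the tests

Unit tests run on small cylinders (hundreds to a few thousand elements); the
verification and contrast checks use the default 65,664-element mesh, a
three-level refinement study up to ~46k elements, 500 random points against
200 triangles for the deviation oracle, voxel volumes at 0.02/0.01 mm, and
orientation studies with n = 100 per group, 2×10⁶ permutation resamples for
the separated groups and 1,000 null replicates (10⁴ resamples each) for
type-I calibration.

## Known limitations

* One material for the whole rod; ossified regions are represented only
  through reduced growth forces, not increased stiffness.
* Additive advection accumulates no residual stress; multi-step runs are
  snapshots, not a finite-growth theory.
* The structured mesher only builds cylinders; arbitrary geometries must be
  imported.
* P1 elements lock as $\nu \to 0.5$; the packaged default 0.40 is safe, and
  a warning fires at 0.49.
* One-sided deviation maps are asymmetric between test and reference
  surfaces of very different resolution (documented 20% agreement bound for
  comparable resolutions).

## A minimal run

```{r, eval = FALSE}
cfg <- run_config()                      # default study conditions
s <- run_pipeline(cfg, "bulkybone-out")  # ~2 min on one CPU
s$bulge_index
#  regeneration > development, ratio ~ 1.02 under matched radial impulse
s$deviation$peak_axial_fraction
#  ~ 0.46: the regenerate bulges outward mid-shaft
```
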