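---
title: "Suture mechanics on a skull phantom: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Suture mechanics on a skull phantom: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`suturefe` asks a focused biomechanical question at desk scale: how do
patent cranial sutures — thin, compliant fibrocellular joints between
skull bones — change the strain field a skull experiences under bite
loading, compared with the same geometry after the sutures have fused
to bone? The package answers it the way a cranial finite-element study
would: a multi-tissue tetrahedral model, muscle forces derived from
architecture, a static bite equilibrium, two analyses per load case
(sutured and fused), and principal-strain post-processing with virtual
strain gauges. The crucial difference is the geometry: instead of a
specimen micro-CT mesh, the package generates a parametric "skull
phantom" whose tissue topology — suture bands splitting bones, tooth
pegs with periodontal-ligament (PDL) sleeves, a trabecular core —
preserves the features the question depends on while staying small
enough to solve in minutes.

## The phantom

The phantom is a plate, by default 30 × 15 × 4 mm, meshed on a
structured hexahedral grid (0.5 mm cells) and split into six tetrahedra
per cell. The same Freudenthal split — six tets sharing each cell's
main diagonal — is used in every cell; because every face diagonal then
joins the locally lowest- and highest-indexed corner of that face,
neighbouring cells triangulate shared faces identically and the mesh is
conforming by construction. (A design note: an alternating-diagonal
pattern achieves the same; the uniform pattern was chosen because its
conformity is immediate and it keeps the generator branch-free.)

Onto this grid the generator paints tissue labels at element centroids,
with precedence tooth > pulp > pdl > suture > trabecular > cortical:

* **Suture bands.** A longitudinal "sagittal" band (default: 1 mm wide,
  sinusoidally interdigitated with amplitude 1 mm and wavelength 3 mm)
  and two straight transverse "coronal"/"lambdoid" bands at one and two
  thirds of the plate length. An element is suture if its centroid lies
  within half the band width of the centreline **curve** — the distance
  is measured to the sampled sinusoid, not vertically, so interdigitated
  bands keep constant thickness and (as in real skulls) more
  interdigitation means more suture tissue. Bands are at least 0.2 mm
  wide and resolved by at least two cells at the default grid.
* **Tooth pegs.** Two anterior "incisor" and two posterior "molar"
  pegs: vertical cylinders (radius 0.75 mm, length 3 mm) rooted in the
  ventral surface, with a pulp core, a dentine/enamel shell and a PDL
  sleeve. The PDL is nominally 0.2 mm; since a centroid-labelled sleeve
  cannot be thinner than one cell, the default phantom uses 0.5 mm
  (one cell) and the 0.2 mm default applies on finer grids.
* **Trabecular core.** A mid-thickness layer (40% of the thickness)
  inside bones, kept one cell clear of suture bands and pegs — how
  trabecular bone should interface with sutures has no canonical
  answer, so the phantom simply keeps the two apart.

The plate can be bent into an arch about the longitudinal axis
(`curvature`, radians); labelling and landmark snapping always use the
flat parametric coordinates kept alongside the deformed geometry, so
regions stay well defined. An interior-node jitter (`distortion`, as a
fraction of cell size, seeded) supplies the distorted meshes that
verification problems such as the patch test require. The default
phantom is flat and unjittered, hence bit-reproducible.

Named node sets mirror the experimental apparatus: single bite nodes at
the peg tips, single temporomandibular-joint (TMJ) nodes at the
posterior corners, lateral muscle-attachment patches, three gauge sites
(IFS-analog on a transverse band, SGS-analog on the sagittal band,
PB-analog on bone at least 3 mm from any suture), and per-bone surface
sets. "Bone surface" is taken literally: surface nodes adjacent only
to cortical or trabecular elements. Tooth-, PDL- and suture-adjacent
nodes are excluded, because the bite reaction acts at a tooth tip and
its local strain concentration would otherwise contaminate bone
averages.

## Materials

All six tissues are homogeneous, isotropic and linear elastic, in a
consistent mm–N–MPa system: cortical bone E = 19 920 MPa, ν = 0.3;
trabecular bone 56 MPa, 0.3; suture 20 MPa, 0.49; PDL 50 MPa, 0.49;
tooth (dentine and enamel combined, assigned enamel properties)
62 370 MPa, 0.33; pulp 2 MPa, 0.45. The "fused" experimental variant
rewrites the suture entry to the cortical values and touches nothing
else, so the sutured and fused analyses share the identical mesh — the
comparison isolates the material effect of patency. ν = 0.5 is
rejected (the Lamé conversion λ = Eν/((1+ν)(1−2ν)) diverges); the
suture's ν = 0.49 is legal but near-incompressible, which matters for
the element choice below.

## Muscle loading

Muscle forces follow the standard architecture chain: physiological
cross-sectional area PCSA = mass·cos(pennation)/(fibre length·density)
with density 1.06 g cm⁻³, and maximal isometric force PCSA × 25 N cm⁻².
Parallel-fibred muscles record pennation 0, so that path is exact.
No specimen-specific muscle architecture is bundled with the package,
so the default set is an explicit placeholder chosen once at rat
scale: a "masseter-analog" of 1.3 g,
15° pennation, 1.0 cm fibres per side (≈29.6 N each, applied as four
strands from the lateral attachment patch toward a ventral insertion)
and a "temporalis-analog" of 0.9 g, parallel-fibred, 1.2 cm fibres per
side (≈17.7 N). These values give a total muscle force of ≈95 N and
predicted bite forces of ≈31 N (incisor) and ≈37 N (molar) — the same
tens-of-newtons regime as an adult rat, which is the only anchor the
defaults claim.

The temporalis-analog is applied as a frictionless wrapped path: a
polyline from an anchor near the sagittal band, over the lateral edge,
to a distal point on the side face. Each interior via point receives
T(t̂₊ − t̂₋), the distal node −T t̂ (full tension pulling along the
path), the proximal anchor +T t̂. Segment by segment these forces are
equal-and-opposite pairs along a common line, so the emitted system has
zero net force *and* zero net moment: the wrap loads the vault locally
(pressing the edges down and pulling the anchors laterally, which puts
the sagittal band in transverse tension) without altering the
rigid-body balance. Tension is clamped at zero — a muscle cable cannot
push.

## Bite statics and the FE cross-check

The mandible itself is not modelled; its role is reduced to a static,
rigid, massless force balance, which is all the maximal-bite question
needs. Given the full set of applied nodal forces, the bilateral solver
uses the sagittal-plane equilibrium (3 equations) for the total
vertical bite force and a joint reaction at the TMJ-axis midpoint; the
unilateral solver solves the full 6 × 6 wrench balance for the bite
force, a 3-component balancing-side TMJ reaction and a 2-component
(anterior-posterior and dorsoventral) working-side reaction. That
unknown set deliberately mirrors the FE constraint scheme — one
vertical constraint per biting tooth, the balancing TMJ clamped in all
three directions, the working TMJ in two — so the two modules check
each other: for the unilateral case the reactions are statically
determinate and the FE bite reaction must match the statics prediction
to solver precision; for the bilateral case symmetry makes the summed
incisor reaction determinate as well. The package's acceptance surface
requires 5% agreement; in practice the match is ~10 significant digits,
because both solve the same equilibrium.

## The solver

The element is the 4-node constant-strain tetrahedron, assembled from
the closed-form isotropic entry
K[(a,i),(b,j)] = V(λ g_{ai} g_{bj} + μ g_{aj} g_{bi} + δ_{ij} μ g_a·g_b),
vectorised over all elements, into a symmetric sparse matrix
(`Matrix::dsCMatrix`). Constraints are imposed by row/column
elimination — prescribed values are honoured, which is how the patch
test drives affine boundary displacements; the experiment itself only
ever prescribes zeros. The reduced system is factorised with CHOLMOD's
sparse Cholesky; there is no randomness anywhere in the chain, so runs
are bit-reproducible. Reactions are recovered as (K u − f) at
constrained DOFs, and global equilibrium (Σ applied + Σ reactions = 0
per axis, to 1e-8 of the load) is asserted in the test suite on every
solve.

Strain recovery uses relative nodal displacements,
ε = sym(Σ_{a≥2} ∇N_a ⊗ (u_a − u₁)) with ∇N₁ ≡ −Σ∇N_a, which makes
rigid translations produce *exactly* zero strain in floating point and
keeps the rotation null-space error at machine roundoff (~1e-10
microstrain per unit displacement on structured meshes; heavy node
jitter roughly doubles it — 1e-10 µε is 1e-16 strain, i.e. the double-
precision floor, not a modelling error).

Numerical behaviour to know about:

* **Bending stiffness.** Constant-strain tets are stiff in bending. The
  cantilever verification (100 × 10 × 10 mm, tip-loaded) converges
  monotonically to Euler–Bernoulli-plus-shear theory and is within 15%
  at an 80 × 8 × 8 grid — adequate for the comparative question, but
  absolute strain magnitudes on coarse grids are underestimates.
* **Near-incompressibility.** Sutures and PDL at ν = 0.49 invite
  volumetric locking in TET4, again biasing suture strain low. A
  10-node quadratic element would mitigate both effects; this build
  deliberately implements TET4 only (a `tet10` request in the config is
  answered with an explicit "not implemented") because every headline
  contrast survives the TET4 bias with an order of magnitude to spare.

## Post-processing

Per-element principal strains come from a vectorised closed-form
(Cardano/trigonometric) symmetric-eigenvalue routine, cross-checked in
the tests against dense `eigen()`; ε₁ is the most tensile, ε₃ the most
compressive principal strain, reported in microstrain. The |ε₁:ε₃|
dominance ratio classifies each element's regime; when |ε₃| falls below
1e-3 µε the ratio is undefined and reported as a sentinel (`NA` plus a
`tension_dominated` flag) rather than a spurious number. Nodal fields
are volume-weighted averages of adjacent element values — deterministic
and guaranteed to stay inside the adjacent elements' range.

The sutured-vs-fused comparison produces, per element and principal
component, the absolute difference |ε|_fused − |ε|_sutured (positive
where fusing raises strain) and a relative difference with the sutured
magnitude as denominator, floored at 1 µε so near-zero strains cannot
manufacture huge ratios. Virtual gauges average the nodal field over
the surface nodes within a disc of area 1 mm² (the footprint of a
rosette strain gauge); gauge orientation is not modelled since
principal strains are orientation-free. Whether such averages should be
taken over nodes or elements is not fixed by the source material; this
package averages nodal values and says so in its outputs. Everything is
exported as legacy ASCII VTK (readable in ParaView) with tissue,
principal strains, dominance and difference fields as cell data and
displacements and nodal strains as point data; a write/read round trip
preserves connectivity exactly and values to better than 1e-6.

## What a green run establishes — and what it does not

On the default phantom, both load cases reproduce the qualitative
contrasts that motivate suture modelling: strain inside suture elements is tens of times
the level in adjacent bone (the acceptance surface demands ≥5×;
measured ≈60–80×); the suture-site gauges respond to fusion orders of
magnitude more strongly than the far-field PB-analog gauge; and the
far-field picture is stable — the parietal-analog bones' surface-mean
ε₁ and ε₃ change by ≤6% between variants (criterion: <20%).

Two caveats define the edge of that claim. First, "far-field" here
means the parietal-analog bones, which host the PB gauge and contain
no bite-point or joint singularity. The anterior (frontal-analog)
bones are *not* far-field in any useful sense: they are loaded almost
entirely through the coronal band and the tooth pegs, and their
surface means shift by up to ~30% between variants — the same kind of
nonlocal strain redistribution over the anterior dorsal cranium that
specimen-level cranial FE studies report during incisor biting. The pipeline
reports all six bones so that this is visible, but the stability
criterion is asserted only where "far from sutures" is true.

Second, the phantom is a topology, not an anatomy. It preserves what
the comparison needs — near-suture vs far-from-suture sites,
anterior/posterior bite points, compliant bands between stiff plates,
a PDL decoupling teeth from bone — and nothing else: no curvature of
real calvaria (unless switched on), no heterogeneous bone, no realistic
muscle wrapping geometry, no contact at the TMJ, no dynamics. Green
tests therefore establish that the *mechanical logic* of the
sutured-vs-fused contrast is implemented correctly and behaves as the
field expects; they do not reproduce, and cannot be compared against,
any specimen-specific strain or bite-force value.

## Reproducibility

Every stage is deterministic given the configuration: the phantom from
its spec (the seed only feeds the optional jitter), the solver from the
mesh and loads, the report from the run. Rerunning `run_experiment()`
with the same config produces byte-identical CSV/JSON artifacts; for
that reason the report carries the config echo and package version but
no wall-clock timestamps.
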