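---
title: "hemomesh: model, synthetic world, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hemomesh: model, synthetic world, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Patient-specific hemodynamic simulation of the pulmonary artery from 3D
cardiac MRI normally requires three slow, expert-driven steps: manual
segmentation, CFD-suitable volume meshing, and a Navier-Stokes solve.
`hemomesh` implements, end to end and at desk scale, the alternative: a
single hybrid image/graph convolutional network that deforms a
point-correspondent tetrahedral *template* mesh of a bifurcating vessel into
the patient's anatomy, and simultaneously regresses gauge pressure (Pa) and
velocity (m/s) at every node, conditioned on a scalar inlet velocity. The
output is a simulation-ready volume mesh with a flow field attached — one
forward pass instead of a pipeline.

Everything here runs on synthetic data generated by the package itself, so
every claim the test suite makes is reproducible on one CPU with no
downloads.

## The model

**Image encoding arm.** Five convolutional levels; each level is two
residual blocks (three 3x3x3 convolutions, each followed by instance
normalization and LeakyReLU, then spatial channel dropout and a residual
connection) followed by 2x2x2 max-pooling. Filter counts increase per level:
16/48/96/192/384 at full scale (128^3 input), 8/16/32/64/128 at the
CPU-sized `small` scale (32^3 input). Level *k* features live on a
`D/2^(k-1)` grid.

**Graph transformation arm.** The template mesh is treated as a graph with
seven node features (x-y-z, pressure, three velocity components). All graph
convolutions are first-order Chebyshev layers `X W0 + L~ X W1 + b`, where
`L~ = L - I` is the symmetric-normalized graph Laplacian rescaled with
`lambda_max` fixed at its upper bound 2 (the standard first-order practice;
it avoids a per-graph eigensolve and keeps the operator's spectrum in
[-1, 1]). An initial graph convolution sees the template coordinates
(divided by the image edge length, a pure conditioning choice) and the inlet
velocity broadcast to every node. Three sequential transformation branches
then each: adapt the graph feature width, sample encoder features from two
pyramid levels at the current node positions by trilinear interpolation
(gradients flow through the sample positions), concatenate graph features,
image features and the inlet velocity, pass through three graph residual
blocks, and emit a 7-channel per-node **delta** through a zero-initialized
bottleneck. Deltas are added to the running coordinates/fields, so the
untrained network is exactly the identity on the template — a stable start.
Branch *i* samples encoder levels (5,4), (4,3), (3,2): coarse context first,
finer detail as geometry converges.

Design points the source architecture leaves open, decided here: branch
outputs are deltas rather than absolute positions; graph hidden widths
default to the finer paired encoder level's channel count; graph instance
normalization is over nodes per channel; dropout rate 0.1, disabled at
inference; optimizer Adam with learning rate 1e-3, batch size 1 (one
anatomy per step).

One decision deserves emphasis. Instance normalization over nodes removes
any feature that is constant across nodes — and the broadcast inlet
velocity is exactly such a feature, so a naive concatenation is annihilated
before it can influence anything (we observed exactly this: a trained model
whose inlet-velocity sweep was flat to four digits). The inlet velocity is
therefore re-injected at each branch's unnormalized bottleneck as
`[h, v_in * h, v_in]`: the plain channel restores a direct linear path, and
the gated `v_in * h` block makes the truth's multiplicative structure
(every synthetic field is exactly linear in the inlet velocity) linearly
expressible. This is the package's own design choice where the source
architecture is silent on injection points.

## Losses

Per branch, with empirical weights `lambda = (1, 0.1, 0.5, 0.05, 30)`:

* **Point (Chamfer)**: symmetric squared nearest-neighbour distance between
  predicted and true node sets, once for all nodes, once for surface nodes.
  The reduction is a **mean** over each set (a sum, as the formula is
  usually printed, differs only by the constant node count, which the
  weights absorb; a flag restores sum-reduction). Gradients use the
  envelope theorem: differentiate at the fixed argmin assignment.
* **Edge-length deviation**: population standard deviation over mean of the
  edge lengths, for all edges and for surface edges; scale-invariant, 0 for
  perfectly uniform meshes.
* **Aspect ratio**: mean over tets of longest/shortest edge; floor 1.
* **Cap coplanarity**: summed squared deviation of each inlet/outlet cap
  face normal from its cap's mean normal; rigid-motion invariant. Cap
  faces are identified by template labels carried through the deformation,
  never re-detected geometrically.
* **Flow MAE**: sum over the four standardized channels of the per-node
  mean absolute error, where pressure is signed-cube-root transformed and
  all channels standardized by global training statistics (below). The
  pressure and velocity groups are weighted equally within the sum.

The total loss is the sum of the weighted branch losses over the three
branches. The whole objective — including the losses — is differentiated by
a small reverse-mode tape built for this package (no deep-learning framework
exists in the target R environment); conv3d/maxpool/trilinear kernels are
C++ with hand-written adjoints, and every term passes finite-difference
checks in the test suite.

## Field normalization

Gauge pressure is heavily right-skewed across and within cases, so it is
transformed by a **signed** cube root (`sign(x)|x|^(1/3)` — gauge pressure
can be locally negative with a 0 Pa outlet reference) before standardizing;
velocity components are standardized directly. Statistics are means and
**population** standard deviations pooled over all nodes of all training
fields — global rather than per-case, since per-case statistics would be
unavailable at inference. Predictions are cubed back to Pa on the way out.
Round-trip exactness is tested to 1e-9 relative.

## The synthetic world

The generator replaces scanner data and a Navier-Stokes solver with a world
whose ground truth is exact, while keeping the two structures the model must
learn: geometry -> resistance -> pressure, and inlet velocity -> field
scaling.

**Anatomy and meshing.** A Y-shaped vessel (one inlet, two outlets) is
meshed on a fixed (segment, station, ring, sector) lattice: disk
cross-sections (centre node + `rings x sectors`) along centerlines, disk
triangulations extruded to prisms between stations, each prism split into
three tets by the index-ordered (Dompierre) rule, giving identical
connectivity — point-point correspondence — for every parameter draw.
Branch 1 continues conformally off the trunk-end (junction) disk; branch 2
is welded to the junction wall ring and duplicates the disk interior as a
thin internal septum, because an interior disk can bound only two cell
layers — a full three-way disk weld is inherently non-manifold. The
full-scale lattice (5 rings, 28 sectors, 26 trunk + 2x26 branch stations)
has 11,111 nodes, within the ~11,000-node working range typical of
pulmonary-artery volume meshes at this density; the small-scale lattice has
641. Disk orientations rotate linearly from the trunk-end tangent to the
branch direction along each branch so no prism inverts at the weld, and all
orientation decisions are topological, so connectivity is draw-independent
by construction (and validated: any folding draw raises an error rather
than silently flipping cells).

Population defaults (small scale): trunk radius 4.5 mm, trunk length 10 mm,
branch radii 3.2/3.0 mm, branch lengths 9 mm, half-angles 35 degrees; paper
scale is the same anatomy at about 4x (trunk radius 14 mm) in a 128 mm box.
Draws vary radii and lengths by +/-15%, half-angles by +/-7 degrees,
centreline bow up to 2x default, and radial bumpiness up to 8% — moderate
anatomical diversity in the spirit of a mixed congenital-heart-disease
population. These ranges were fixed before any end-to-end testing and are
not tuned. A consequence worth knowing when reading the tests: the
average-anatomy template alone already overlaps held-out cases at Dice ~0.89,
so the geometric criterion mostly certifies that training does not *damage*
geometry; the genuinely learned content is the flow field and its
inlet-velocity response.

**Flow.** Steady laminar Hagen-Poiseuille flow per segment (blood:
viscosity 0.04 Pa s, density 1060 kg/m^3): inlet flow
`Q = v_in * pi * r_trunk^2`; the branch split is proportional to inverse
resistances `8 mu L / (pi r^4)` (exactly conserving Q); pressure drops
linearly along each segment's stations to exactly 0 Pa gauge at both
outlets; velocity follows the parabolic profile `2 v_mean (1 - (rho/r)^2)`
along the local centreline tangent with no-slip walls. Velocity direction
and mean blend linearly across the first quarter of each branch (a
deterministic stand-in for the junction's secondary flow, which Poiseuille
theory does not describe). Every field is exactly linear in the inlet
velocity. Flow tangents are computed from station-centre differences by the
same rule whether the lattice is exact or re-fitted from node positions, so
the oracle applied to a predicted mesh reproduces the generating field to
well under 1% on the true geometry.

What the toy physics deliberately lacks: turbulence, pulsatility, secondary
junction vortices, pressure recovery, and realistic bSSFP contrast. A green
end-to-end test therefore establishes that the pipeline learns the stated
geometry->pressure and inlet->scaling structures from images — not that it
would match Navier-Stokes on a real PA.

**Images.** `image = 0.3 + 0.5 * mask`, plus smooth Gaussian "tissue" blobs,
a low-frequency multiplicative bias field, Gaussian noise (sigma 0.05), all
clipped to [0, 1]; bit-reproducible from the case seed. Inlet velocities
are drawn from N(0.2, 0.05) m/s (truncated at 0.02 m/s — a draw four sigma
below the mean would otherwise be nonphysical), four per training case;
test cases add a fixed 0.1/0.2/0.3 m/s sweep.

## Training regime

110/10/15 case splits at full scale, 40/8/8 at small scale. At each epoch
every training case contributes **one** of its four inlet-velocity fields,
drawn from a dedicated augmentation RNG stream (stable across architecture
edits); validation always evaluates all four. The template is the node-wise
average of the training meshes; normalization statistics are fitted on all
training fields. Early stopping tracks validation total loss; the
best-validation parameters are retained. All randomness (weights, dropout,
augmentation, data) derives from one master seed, and a repeated 2-epoch
run is byte-identical.

## Evaluation

Dice on voxelized masks (two empty masks define Dice 1, with a warning);
ASSD and Hausdorff distance on extracted surfaces via exact point-to-triangle
distances (HD defaults to the true maximum; a 95th-percentile variant is
available by flag). Flow accuracy uses the node-wise normalized absolute
error `NAE = 100 |pred - truth| / (max(truth) - min(truth))` with the range
taken **per subject and per channel** — a documented choice; the upstream
definition is cited, not restated, in the source literature. It reproduces
the known behaviour that percentage errors inflate when a subject's fields
are small (low inlet velocities). MNAE_s averages NAE over nodes per
subject, MNAE_n over subjects per node (their grand means coincide, which is
tested exactly). Bland-Altman bias and 1.96-sigma limits of agreement use
the population standard deviation.

The error-decomposition report contrasts the network's direct fields with
the flow oracle run on the network's own predicted geometry — the
desk-scale analogue of running conventional CFD on a deep-learning
segmentation. On synthetic data the "CFD" on a predicted mesh means:
re-fit the anatomy parameters from the predicted lattice landmarks (radii
from mean wall-ring distance, lengths from centreline arclength, half-angles
from end-to-junction directions) and evaluate the analytic solution. The
identity case is therefore only approximately zero (the re-fit is a fit);
the tests bound it below 1% rather than asserting exact zero.

## Numerical choices and limitations

* Coordinates are stored in mm in the image frame; with 1 mm spacing, mm
  equals voxel index. Voxel (i,j,k) centres sit at `origin + spacing*(i,j,k)`
  (0-based); out-of-bounds feature samples clamp to the boundary voxel,
  since meshes may transiently exit the grid during training.
* Point-in-tet tests use barycentric coordinates with tolerance 1e-9,
  boundary inclusive; containing-tet lookups break ties toward the lowest
  tet index; edges/faces are canonicalized by sorted indices and all set
  outputs are sorted — everything deterministic.
* Subnormal floats are flushed to zero at package load: deep backward
  passes otherwise produce vanishing gradients in the 1e-310 range that
  run 50-100x slower on x86 without changing any tested quantity.
* The full-scale configuration trains in principle but is far outside a
  single-CPU test budget; the test suite trains the small scale and keeps
  epoch counts modest. The end-to-end acceptance run additionally narrows
  the image encoder (filters 4/8/16/32/64, one block per level) while
  keeping the graph arm at full width (48/32/24) — the encoder dominates
  CPU cost while the graph arm, which carries the flow prediction, is
  nearly free at 641 nodes. Wall-clock inference time is reported, never
  asserted.
* The MAE flow term has constant-magnitude gradients; under Adam its
  per-branch value decays with a time-constant of roughly 125 steps on
  single-case fixtures. Rapid-overfit demonstrations therefore reach about
  a 6x total-loss reduction in 200 steps, not more — the mesh-quality terms
  additionally put a hard floor (3 x lambda3 x aspect of the target
  anatomy, about 3.5) under the total loss.
* Known limitations: 0 Pa outlet conditions for both outlets (not
  physiological), steady flow only, single image contrast model, and the
  junction septum described above.
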