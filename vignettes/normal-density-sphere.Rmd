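---
title: "The Normal Density Sphere and Feature Prominence scoring"
author: "ndshape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Normal Density Sphere and Feature Prominence scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ndshape)
```

## The problem

Craniosynostosis — premature fusion of one or more cranial sutures — deforms
the infant skull in stereotyped ways: sagittal fusion produces the long,
narrow scaphocephalic head (vertex depression, occipital pinching, frontal
bossing), metopic fusion the triangular trigonocephalic forehead (wedging,
metopic ridge, temporal hollowing). Clinical severity assessment has
traditionally been subjective. `ndshape` implements a quantitative pipeline:
a 3D head surface is reduced to a low-dimensional, anonymized shape
descriptor; a small fully connected network classifies the phenotype; and the
network's raw pre-softmax output — the *Feature Prominence* (FP) score — acts
as a continuous severity proxy, explained by integrated-gradients attention
maps projected back onto the head surface.

## The descriptor: a kernel density estimate of unit normals

Every vertex of a (registered) triangle mesh carries an outward unit normal
$\hat N_i$, computed as the area-weighted average of its incident face
normals. The set $\{\hat N_i\}_{i=1}^n$ lives on the unit sphere: flat
regions of the head concentrate normals in one direction, curved regions
spread them. The *Normal Density Sphere* (NDS) is the kernel density estimate
of this set evaluated at a fixed lattice of points $s$ on the sphere,

$$\hat f(s) \;=\; \frac{1}{nh}\sum_{i=1}^{n}
  \frac{1}{\sqrt{2\pi}}\, e^{-\frac{1}{2}\left(\frac{\lVert s - \hat N_i
  \rVert}{h}\right)^2},$$

with $\lVert\cdot\rVert$ the Euclidean (chord) distance between unit vectors
and $h$ the bandwidth from Scott's rule, $h = \hat\sigma\, n^{-1/(d+4)}$,
where $\hat\sigma$ is the mean per-coordinate standard deviation of the
normals and $d = 3$ their ambient dimension (both configurable). The
$1/(nh)$ prefactor is kept verbatim even though the estimator is then not a
normalized density on the sphere: the classifier consumes relative density
patterns, and keeping the closed form fixed keeps descriptors comparable. A
von Mises–Fisher kernel ($\hat f(s) = \frac1n \sum_i C(\kappa)
e^{\kappa\langle s,\hat N_i\rangle}$, $C(\kappa) = \kappa/(4\pi\sinh\kappa)$,
a proper spherical density) is available as an option, with
$\kappa = 1/h^2$ by default so the two kernels agree in the small-angle
limit; the chord-Gaussian is the default because, at the concentrations
typical of cranial normal fields, the chord/geodesic distortion is
negligible and the simpler kernel trains better.

The evaluation lattice is a deterministic spherical Fibonacci lattice,
near-uniform in area, of 4515 points by default — the classifier's input
width. No standard lattice family yields exactly 4515 points, so the count
is simply a configurable parameter whose default matches the network
architecture. Each grid carries a fingerprint (`gridHash`) stored with every
descriptor, model and attribution so that artifacts from different lattices
can never be mixed silently.

Because unit normals ignore position and size, the NDS is exactly invariant
to translation and uniform scaling of the mesh, and *equivariant* to
rotation: rotating the mesh is equivalent to inversely rotating the
evaluation lattice. Upstream rigid alignment (three-point Procrustes on the
nasion and tragus landmarks) therefore makes the full pipeline invariant to
how a scan happens to sit in space; the test suite verifies end-to-end FP
and attention changes below $10^{-6}$ across random similarity transforms.

## Pre-processing and correspondence

Scans are clipped at the plane through the nasion and both tragus points,
keeping the cranial side; the side is determined by the right-handed normal
of the landmark triangle ordered (nasion, left tragus, right tragus), with a
`flip` argument to override. Faces crossing the plane are split 1→2 or 1→3
so the cut boundary lies exactly on the plane; new intersection vertices are
appended after the retained originals, and originals that lose all their
faces are dropped (keeping them would leave isolated vertices with undefined
normals).

For cross-dataset comparability every scan is brought onto a shared template
topology by a stiffness-annealed non-rigid ICP: each template vertex carries
its own affine transform, the data term pulls transformed vertices toward
their closest points on the target surface (point-to-triangle, with a
distance cutoff rejecting far correspondences), and a stiffness term
penalizes differences between neighbouring vertices' transforms. Each
annealing step (default stiffness schedule 50, 20, 5, 2, 0.8; at most 10
iterations per step; convergence at 0.1 µm maximum vertex motion) solves one
sparse normal-equations system. This is the annealed core of the standard
per-vertex-affine formulation; landmark energy terms and normal-compatibility
rejection are omitted — the distance cutoff suffices at desk scale on
pre-aligned meshes. The fitted mesh keeps the template's face array, which
is what gives vertex-level correspondence across a collection. Templates are
expected at desk scale (a few thousand vertices); no decimation is applied
to oversized templates.

## The classifier and the FP score

The NDS vector feeds a fully connected network, 4515–256–128–64–32–3 by
default, with ReLU hidden activations, trained with mini-batch Adam
(learning rate $10^{-3}$, batch 16, at most 200 epochs) on softmax
cross-entropy over the classes (normocephalic, trigonocephalic,
scaphocephalic — the fixed class order, which also breaks argmax ties).
These optimizer settings are not prescribed by the descriptor; they are a
standard small-MLP recipe and all exposed in `trainConfig()`. An 80/10/10
random split (train floor, validation floor, test remainder; unstratified,
so per-class counts drift as in a plain random draw) provides validation for
early stopping: training stops after 20 epochs without validation
improvement, and the best-validation weights are retained. Because a
30-sample validation set saturates accuracy almost immediately, best-model
selection breaks accuracy ties by validation cross-entropy loss — otherwise
the retained model is the first epoch that happens to hit the plateau,
visibly undertrained. Inputs are fed raw by default (FP values are only
meaningful relative to a fixed input scale); a per-feature z-scoring switch
exists and its statistics travel with the model.

The *FP score* of a head is the pre-softmax output of the class of interest
— by default the predicted class, overridable (e.g. score a post-operative
scan against the scaphocephalic node). Its absolute value depends on the
training set and architecture, so it is reported together with its empirical
percentile within the scored class's training FP distribution (linear
interpolation between order statistics, clamped to [0, 100]; per class, not
pooled, because severity scales are class-specific).

## Attribution

Integrated gradients attribute the *pre-softmax* class output (not the
probability, for coherence with the FP score) along the straight path from a
baseline to the input, using an $m$-step right-endpoint Riemann sum
(default 128; the completeness gap $|\sum_i \mathrm{IG}_i - (F(x) -
F(x'))|$ is reported and falls below 1% of the output difference at 512
steps). The default baseline is the all-zeros descriptor — the attribution
convention; a uniform-density baseline (the density a uniform normal field
would produce) is available as the domain-meaningful null. Grid-point
attributions are traced back to the surface by hard assignment: every vertex
receives the attribution of the lattice point nearest (by angle) to its
normal. This is the simplest invertible reading of the descriptor's
construction; kernel-weighted spreading is deliberately not implemented.
Per-class mean maps average the per-head vertex maps over a class, which
presumes the shared template topology.

## The synthetic generator

Real craniosynostosis datasets cannot ship with a package, so `ndshape`
generates its own validation data: a deterministic half-ellipsoid
neurocranium template (semi-axes 90 × 70 × 65 mm — a realistic infant head —
meshed pole-and-rings, 2049 vertices at the default subdivision, base rim
exactly on the landmark plane) deformed by class-specific smooth fields
scaled by a severity dial $s \in [0,1]$:

* **scaphocephalic** — anteroposterior stretch $\times(1+0.25s)$, biparietal
  narrowing $\times(1-0.15s)$, plus Gaussian-bump vertex depression (9 mm·s),
  occipital pinching (6 mm·s each side) and frontal bossing (5 mm·s);
* **trigonocephalic** — forehead wedging (anterior lateral compression up to
  45%·s), a metopic midline ridge (3.5 mm·s) and bilateral temple hollowing
  (7 mm·s);
* **normocephalic** — the template unchanged.

Amplitudes were chosen once so that severity 1 caricatures a severe clinical
phenotype (cephalic index falling from ≈0.78 to ≈0.53 across the
scaphocephalic dial) and severity near 0 is indistinguishable from normal.
All classes receive smooth correlated noise — 12 random Gaussian bumps with
15–35 mm extent and amplitude SD `noiseSD` (0.5 mm default), not per-vertex
jitter, which would shred the normal field in a way photogrammetry artifacts
do not. Displacements fade to zero at the base rim so generated heads remain
clipped at the landmark plane. Two measurable dials validate the generator
itself: the cephalic index (width/length, strictly decreasing in
scaphocephalic severity) and the forehead wedge angle (interior angle
between planes fitted to the left/right forehead walls, strictly decreasing
in trigonocephalic severity). Grades 0–3 for rank-correlation checks come
from quartile-binning the drawn severities, mimicking a 4-point expert
photoscore without experts.

What the generator does *not* emulate: statistical-shape-model variation of
real populations, age-driven size variation (irrelevant to the descriptor by
scale invariance), facial features, hair or reconstruction artifacts, and
adaptive (anisotropic) mesh refinement. Passing tests therefore demonstrate
the pipeline's internal correctness and its behaviour under controlled
phenotype strength — not clinical performance on raw patient scans.

## Numerical choices and degenerate inputs

* KDE sums run in compiled code; tests pin them to a literal double-loop
  evaluation of the estimator within $10^{-12}$.
* Scott's rule refuses a zero-spread normal field (all normals identical)
  and asks for an explicit bandwidth instead.
* Clipping treats vertices within $10^{-9}\cdot$scale of the plane as on it,
  making the operation idempotent; a mesh entirely below the plane is an
  error, and a clip that removes nothing returns the input object unchanged.
* Argmax ties in classification resolve to the first class in the fixed
  order; a constant attribution field min-max-normalizes to zeros with a
  warning rather than dividing by a zero range.
* Non-rigid ICP warns (and flags the result) if any stiffness step exhausts
  its iteration cap; an empty correspondence set within the cutoff is an
  error.
* All randomness (generator, splits, training initialization and batching)
  is driven by explicit integer seeds; identical seeds reproduce identical
  artifacts bit for bit.

## Problem sizes used in validation

The packaged validation suite trains on 100 heads per class (severities
drawn uniformly from [0.3, 1.0], 0.5 mm noise — clearly expressed phenotypes,
matching the public synthetic cohort the method was designed around),
extracts 4515-point descriptors from 2049-vertex meshes, and evaluates on
the 30-sample test partition; severity–FP rank correlations use 30 heads per
class spanning the full [0, 1] dial. Registration checks run on the
subdivision-3 (513-vertex) template. These sizes were chosen as the smallest
that exercise every stage at full descriptor width.

## Known limitations

The FP score is relative to its training distribution — models trained on
different cohorts yield incomparable absolute scores (the percentile scale
is the portable one). The classifier presumes consistent mesh topology;
meshes with adaptive refinement should be resampled before descriptor
extraction. The attention-map projection is hard-assigned and therefore
piecewise constant across vertices whose normals share a nearest lattice
point. And the registration module implements the annealed core of
per-vertex-affine ICP, not the full landmark-weighted formulation — for
badly mis-posed scans, run the rigid landmark alignment first (the pipeline
does).
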