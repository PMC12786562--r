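---
title: "Crimping biomechanics of stapedotomy prostheses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crimping biomechanics of stapedotomy prostheses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crimpsim)
```

## The problem

In stapes surgery for otosclerosis, a piston prosthesis is crimped onto the
long (lenticular) process of the incus. The crimping step is the critical
surgical act: insufficient closure lets the loop slip and the conductive
hearing loss recur, while excessive closure loads the incudal cortical bone
beyond what it tolerates, promoting erosion and necrosis. The quantity this
package computes is the mechanical load the loop places on the incus — the
interface pressure and the resulting von Mises stress field — as a function
of prosthesis material (titanium versus PTFE), loop geometry (band width,
loop outer diameter) and crimping force (300–500 mN, the upper segment of
clinically reported forces). Stresses are judged against 60 MPa, the
commonly used von Mises strength proxy for cortical bone, which serves here
as the necrosis-risk criterion.

All computations use the mm–MPa–N unit system (1 MPa × 1 mm² = 1 N);
forces from the surgical literature are quoted in mN (1 mN = 0.001 N).

## Analytical open-ring model

A self-crimping PTFE loop is an open elastic ring that grips the incus by
elastic recovery. Modelling the lenticular process as a rigid cylinder of
diameter 0.8 mm and the loop as a thick ring with inner diameter `ID`,
outer diameter `OD`, mean radius $r_m = (ID + OD)/4$, wall thickness
$t = (OD - ID)/2$ and radial interference $\Delta r$, the closed-ring
interface pressure follows the thick-ring reduction of the Lamé solution:

$$ p \;=\; \frac{E\,\Delta r}{r_m\,(r_m/t + \nu)} $$

An open ring is more compliant than a closed one: its circumferential
stiffness scales approximately with the covered arc $\theta$, so the loop
pressure carries the coverage fraction as a multiplicative factor,

$$ p_{loop} \;=\; p \cdot \phi(\theta), \qquad \phi(\theta)=\theta/360^\circ ,$$

the inverse of the closed-to-open stiffness *ratio* $360^\circ/\theta$.
The covered arc is not a printed datum of the configurations this package
models; it is calibrated once. $\theta = 216^\circ$ ($\phi = 0.6$) is the
unique value that reproduces all three reference PTFE pressures
(0.405 / 0.476 / 0.524 MPa for OD 1.2 / 1.4 / 1.8 mm at
$\Delta r = 2\,\mu m$) simultaneously under 3-decimal rounding, and it is
exposed as a parameter (`coverage_angle`) rather than hard-coded.

```{r analytical}
pressure_table(c(1.2, 1.4, 1.8))
```

For manually crimped titanium bands the pressure is imposed by the clamp
rather than by material elasticity; the link between crimping force and
mean interface pressure is purely geometric:
$F = p \cdot A_c$, $A_c = w \cdot L_c$, $L_c = (\theta/360)\,2\pi r_i$,
with $w$ the axial band width and $r_i$ the loop inner radius.
`pressure_from_force()` and `force_from_pressure()` are exact inverses.

## Synthetic geometry and meshing

No external data enter the analysis: `build_assembly()` generates the
assembly parametrically. The lenticular process is a cortical-bone cylinder
(diameter 0.8 mm; modelled length 3.0 mm, a free parameter chosen so the
crimp site 1.3 mm from the tip is interior to the model). The loop is an
annular sector over the coverage arc; the shaft (body diameter 0.4 mm,
functional length 3.4 mm) is a straight arm extruded radially from the
outer band surface at mid-arc, which is where a piston's shaft joins its
loop. The titanium band's radial wall is not a datum of the configurations
modelled here; it defaults to 0.1 mm and is exposed
(`ti_band_thickness`).

Meshes are structured: planar cross-sections are triangulated, extruded
into prisms, and every prism is split into three tetrahedra using the
minimum-global-vertex-index rule, which makes shared quadrilateral faces
split along the same diagonal everywhere — the mesh is conforming by
construction, including across the loop/shaft junction. Quadratic (10-node)
tetrahedra are the default, inferred from the node-to-element ratio of the
reference discretization; a linear mode exists for fast experiments.
Midside nodes stay at straight-edge midpoints (affine elements), so the
cylinder surfaces are faceted; the incus angular and axial grids are
aligned with the coverage-arc and band edges so the tagged contact patch
area matches the analytical $A_c$ to within about 1%.

The generator maps a nominal "average element size" to its grid step with
a single calibration factor of 1.25, reflecting that structured grids pack
denser than the average-size convention of general-purpose tetrahedral
meshers; with it, the 0.05 mm reference-scale profile yields ~113k nodes,
within ~7% of the reference discretization's 105,403. The working profile
for tests and sweeps is 0.15 mm (about 3,500 nodes per assembly), at which
the full 12-case sweep runs in ~3 minutes on one CPU; all meshing is
deterministic, so identical inputs give byte-identical meshes.

What the generator deliberately does **not** emulate: real incudal
curvature, surface roughness and inter-individual variability; the loop's
fillets and tip profile; ligament and tympanic-membrane compliance (the
posterior incus is rigidly clamped instead, as in the reference setup).
Passing tests therefore validate the solver and the model logic on the
idealized geometry, not patient-specific stress magnitudes.

## Finite-element solver and contact

The solver is small-strain isotropic linear elasticity on TET4/TET10
meshes, assembled region-by-region (bone E = 14 GPa, ν = 0.30; titanium
E = 110 GPa, ν = 0.30; PTFE E = 0.5 GPa, ν = 0.46) with sparse direct
factorizations from the Matrix package. A geometrically nonlinear mode is
not implemented: at µm-scale closure displacements the corotational
correction would be far below the discretization error, and requesting it
raises an explicit error rather than silently differing from the reference
setup, which activated large-deformation effects.

Contact between the loop's inner surface and the incus is node-to-surface
with small-sliding kinematics: pairings, normals and gaps are fixed from
the initial geometry, and the two-pass (symmetric) option — each surface
acting once as slave — is the default. The normal condition is enforced by
an augmented Lagrangian: penalty solves (penalty
$50\,E_{soft}/h$, with $E_{soft}$ the softer contacting modulus and $h$
the local element size) with Uzawa multiplier updates until the residual
penetration falls below $10^{-3}h$. Friction (µ = 0.25 at both interfaces,
the conservative choice for PTFE) uses a tangential penalty spring for
every active pair plus a return-map correction for sliding pairs whose
magnitude is tied to the frozen augmented multiplier, so the Coulomb
condition $|t_t| \le \mu\,p_n$ holds pointwise by construction and the
stiff normal coupling never appears explicitly on the right-hand side
(which would destabilize the fixed-point iteration).

Because the faceted surfaces polygonize the nominal cylinders with sagitta
errors of a few µm — the same order as the 2 µm interference — contact
gaps use the *nominal* analytic geometry ("adjust to touch") rather than
the faceted one; without this, contact localizes at spurious discrete
spots. Ambiguous closest-facet ties resolve to the smallest facet index,
keeping the pairing deterministic.

### Load cases

* **`crimp_force`** (titanium): the total crimping force is spread as a
  uniform radial traction over the loop's outer band surface (the shaft
  window is excluded), with integrated traction *magnitude* equal to `F`
  exactly, and transmitted to the incus through the frictional interface.
  This matches the averaging behind $p = F/A_c$; a concentrated pinch would
  be an alternative worth a sensitivity study, but the distributed form is
  the default because the force-to-pressure bookkeeping of the analytical
  model assumes it.
* **`self_crimp_pressure`** (PTFE): the analytically computed loop pressure
  is applied as the mutual interface condition — compressing the incus
  beneath the band and, as the reaction, pushing the loop's incus-facing
  surface outward. The pressure *is* the contact solution of the
  interference fit, so the contact coupling is disabled in this mode:
  enforcing the 2 µm overlap on top of the applied pressure would count the
  self-crimp action twice. (Applying the pressure on the loop's inner
  surface alone would push the loop off the incus and leave the interface
  unloaded; applying it on the outer surface would overload the interface
  by the ratio of outer to inner radius, 1.5–2.3×.)

Boundary conditions fix the posterior incus end face and the distal shaft
tip in all degrees of freedom. With a clamped incus, part of the crimping
load necessarily flows through the stiff shaft anchor (~25–30% for
titanium), so the contact-resultant-equals-applied-load identity is exact
only for two-body problems without an alternative load path — it is
verified on the press-fit oracle below, while assembly solves verify global
reaction balance instead.

### Verification

Three closed-form oracles gate the solver:

1. **Patch test** — a uniaxially loaded box reproduces the uniform stress
   state exactly (quadratic elements represent linear displacement fields).
2. **Lamé thick-walled cylinder** — a pressurized 90° sector with symmetry
   boundary conditions matches the plane-stress Lamé hoop/radial stresses
   within 3% at the 0.1 mm profile (element-centroid comparison — centroids
   are the accurate sampling points; nodal averages smear one-sided
   boundary information), converging under refinement.
3. **Coaxial press-fit** — a solid cylinder with an interfering outer ring
   under frictionless augmented-Lagrangian contact reproduces the classical
   press-fit interface force within 5% (2% in practice).

## Safety metrics

`summarize_solution()` reduces a converged field to the reported
quantities. The peak incus von Mises stress is taken over the contact
region: the axial slab under the band widened by half a local element
size. The restriction matters — the clamped-incus idealization produces
cantilever bending stresses that grow toward the posterior support and
would otherwise be reported as "peaks" even though they are artifacts of
the rigid anchorage, not of the crimp. The contact-surface mean is
reported both area-weighted and as a plain nodal mean (whether the
reference post-processing weighted by area is unknowable, so both are
kept). The dominant stress mode at the peak comes from the principal
decomposition ($\sigma_3 < 0$ dominant → compressive, as found beneath the
band). The risk class compares the peak against the 60 MPa bone limit with
a near-threshold band at 85–100% of the limit, motivated by treating
~53 MPa as "approaching" the threshold; PTFE prosthesis-body stresses are
additionally compared against the 25 MPa tensile limit of the material.

Peak stresses from an independent commercial contact simulation of the
same twelve configurations are shipped as *indicative references* with a
±30% reporting band (`reference_peaks()`), never as assertion targets:
absolute peak values in contact FE depend strongly on mesh density,
element type and contact settings, and the reference discretization and
contact details are not reproducible from published information. Entries
whose band straddles 60 MPa — all 500 mN titanium cases and the 400 mN
wide-band case — carry a `threshold_sensitive` flag, because whether they
cross the limit is within the reproduction uncertainty. At this package's
test-profile mesh with distributed crimp tractions the computed peaks are
an order of magnitude below those references; the *orderings* (force
monotonicity, OD monotonicity, PTFE below titanium, compressive peak
state) are the reproducible content and are what the test suite asserts.

## Force-window risk layer

The titanium stress–force relation is monotone; its inverse defines the
admissible crimping-force window. `max_safe_force()` bisects a (verified
monotone) response for the largest force whose peak stress stays below the
limit. Surgeon force variability is modelled as a normal distribution
truncated to [0, 1300] mN — non-negative, bounded by the short-term
maximum admissible force at the incus — with reported junior
(433 ± 334 mN) and senior (182 ± 169 mN) parameters built in.
`exceedance_probability()` propagates draws through a monotone
piecewise-linear interpolation of the FE stress–force map (a full FE solve
per draw would add nothing at three support points) and reports the
binomial standard error; all draws are inverse-CDF transforms of seeded
uniforms, so every estimate is exactly reproducible from its seed. The
micro-rupture force range reported for the incudomalleolar joint
(406–568 mN) concerns a different loading path and is deliberately not a
second limit; it appears only as context in reports.

## Numerical choices and limitations

* Tie-breaks: closest-facet ties and quad-diagonal choices resolve by
  smallest index; the pipeline contains no unseeded randomness.
* Degenerate inputs fail loudly: zero wall thickness, empty patches,
  non-monotone responses, unconverged contact and under-constrained models
  all raise errors rather than propagate.
* The penalty scale and $10^{-3}h$ penetration tolerance are standard
  robust defaults; halving or doubling the penalty moves verified
  interface pressures by far less than the discretization error.
* Linear elasticity throughout: bone anisotropy, PTFE viscoelasticity and
  plastic deformation of the titanium band during forming are out of
  scope; trends between materials are expected to be robust to these
  simplifications, absolute magnitudes less so.
* Problem sizes: verification oracles run at 0.1–0.15 mm element size,
  sweeps at 0.15 mm, and the 0.05 mm reference-scale profile is available for
  mesh studies (`mesh_profile: reference` in configs).
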