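---
title: "Volume-conductor modelling of deep brain stimulation with dbsvcm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volume-conductor modelling of deep brain stimulation with dbsvcm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dbsvcm)
```

## The physical model

During deep brain stimulation (DBS) a lead delivers brief current or
voltage pulses into deep grey-matter nuclei. The electric field that
spreads from the contacts is governed, at stimulation frequencies, by the
electro-quasistatic (EQS) approximation of Maxwell's equations: magnetic
induction is negligible and the complex potential $\underline\varphi$
satisfies

$$\nabla\cdot\big[(\sigma(\mathbf r,\omega) +
  j\omega\varepsilon(\mathbf r,\omega))\,\nabla\underline\varphi\big]=0,$$

with conductivity $\sigma$ and permittivity $\varepsilon$ of the tissue.
Brain tissue is strongly dispersive: both parameters change by orders of
magnitude between the pulse repetition rate (~130 Hz) and the upper edge
of the pulse spectrum (~1 MHz). `dbsvcm` therefore works in the frequency
domain (Fourier finite elements): the stimulus is expanded in its Fourier
series, the EQS problem is solved per retained harmonic, and the
time-dependent potential on neuron compartments is recovered by the
inverse transform. Because every per-frequency problem is linear and
independent, solves parallelize trivially and amplitude changes reduce to
scaling.

The quasistatic (QS) simplification drops the capacitive term
($\varepsilon \to 0$) and makes the response separable — the potential is
then the static profile times the waveform. The package keeps both
formulations switchable (`qs_mode`), which is the standard way to judge
whether tissue capacitance matters for a given protocol; for
current-controlled pulses the capacitive path visibly distorts the pulse
plateau (charging), which the acceptance suite checks qualitatively.

## Tissue dielectrics

Dispersion is modelled with the standard 4-term Cole-Cole fit

$$\varepsilon^*(\omega)=\varepsilon_\infty+
  \sum_{n=1}^{4}\frac{\Delta\varepsilon_n}{1+(j\omega\tau_n)^{1-\alpha_n}}
  +\frac{\sigma_i}{j\omega\varepsilon_0},$$

with the literature (Gabriel-type) constants for grey matter, white
matter and CSF embedded as named parameter sets
(`tissue_table()`). Effective conductivity follows as
$\sigma(\omega)=\omega\varepsilon_0(-\mathrm{Im}\,\varepsilon^*)$. The
vacuum permittivity is fixed at the rounded engineering value
$\varepsilon_0 = 8.854\times10^{-12}$ F/m; with it the shipped constants
reproduce their published 520 Hz reference values digit-for-digit
(`scripts/acceptance.R` recomputes them).

The fibrotic encapsulation sheath that forms around an implanted lead is
modelled as grey matter with conductivity scaled by a configurable factor
(default 0.5, applied at every frequency) and unchanged permittivity.
Anisotropy enters as a symmetric weighting tensor $D_{ij}$ on the
conductive part only — permittivity stays isotropic, and encapsulation,
electrode metal and floating conductors are never anisotropic. Tensors
come from a voxel field (DTI-like), optionally normalized to unit trace
so the weights average to one.

## Domain, electrode and mesh

The computational domain is a sphere or ellipsoid of tissue. Electrode
geometry is deliberately parametric (a cylindrical lead with ring
contacts; a coaxial tip/ring preset for rodent work) rather than CAD:
vendor-faithful lead geometry is a non-goal of this package. The
insulating shaft is carved out of the mesh, leaving a hole with a
homogeneous Neumann condition; contact rings stay in the mesh as metal
cell regions so the same mesh serves driven, grounded and floating roles.
Energized contacts are Dirichlet-constrained over their whole region
(assigned values real, imaginary part zero); floating and inactive
contacts use the virtual-permittivity method with
$\varepsilon_r = 10^9$, which makes them near-equipotential passive
conductors above ~100 Hz. At DC the permittivity path vanishes, so a DC
solve substitutes a virtual conductivity of the magnitude the virtual
permittivity path would have at 130 Hz (configurable); the DC harmonic is
always solved as a purely conductive problem.

The background mesh is a Kuhn-triangulated structured grid, clipped to
the domain and graded towards per-region target edge lengths
(defaults for a 10 mm toy domain: ROI 0.5 mm, contact vicinity 0.1 mm,
rest-of-tissue 2.0 mm; all overridable, and tests use coarser settings).
The region partition — encapsulation shell, contact vicinity (contacts
dilated by twice the encapsulation thickness), ROI (bounding sphere of
the neuron population plus 1 mm) and ROT — controls both meshing targets
and the refinement sweep order. One caveat of the structured carve-out:
contacts closer along the lead than one grid cell would share mesh
nodes, which would tie a floating contact to its neighbour's Dirichlet
data; the builder warns in that case and the gap or `base_edge` should be
adjusted.

A second mesh family, a radially extruded icosphere between two
concentric spherical contacts, exists because it admits the closed-form
solution $\varphi(r)=V\,(1/r-1/R)/(1/r_0-1/R)$; all its boundary nodes
lie exactly on the spheres (refined nodes are snapped back), making it
the verification vehicle for solver accuracy and flux conservation.

Voxel volumes map onto cells by majority vote of the voxel centres inside
each cell, with a nearest-voxel fallback for cells smaller than a voxel
and a default label outside the covered box (local mapping). The vote is
deterministic (ties break to the smaller label code), and the mapping is
idempotent. This choice matters: the current-convergence criterion reacts
to mapping errors near contacts, so the mapping rule is part of the
convergence behaviour.

## Refinement

Mesh adaptation is driven by the quantity that actually matters for
activation estimates: the potential on the neuron compartments. It runs
in two stages at the lowest retained frequency, and the adapted mesh is
reused for the whole spectrum.

Stage 1 resolves CSF near the neurons. CSF is an order of magnitude more
conductive than grey or white matter, so unresolved CSF pockets dominate
the error budget. Cells containing CSF voxel centres within a vicinity
radius of any compartment are bisected until none exceeds a target edge
(default: the voxel size — the stopping size is a convention, exposed as
`csf_max_edge`). The solution on that maximally refined mesh is the aim
$\varphi_{\text{aim}}$; intermediate iterates stop once
$\max_i |\,|\varphi_{\text{aim},i}|-|\varphi_{k,i}|\,|/V_{\text{drop}}
\le \Theta_{\text{CSF}}$. Comparing successive iterates against the aim
(rather than against each other) makes the stage terminate at zero
deviation by construction once the target edge is reached everywhere.

Stage 2 sweeps contact vicinity + encapsulation, then ROI, then ROT. Each
probe uniformly bisects the region and checks the same max-norm deviation
against $\Theta_\varphi$; a passing probe is by construction a
verification against uniform refinement, closing the local-convergence
loophole. A failing probe marks cells on the coarser mesh whose midpoint
field changed by more than $\Theta_E$ in relative $L_2$ (cells with
vanishing new field are never marked, since the criterion divides by
$\|E_{\text{new}}\|$), plus — in current mode — parents whose integrated
$|J|$ disagrees with the sum over their bisection children by more than
$\Theta_J$, skipping parents below a small-current fraction. Defaults
($\Theta_{\text{CSF}}=\Theta_\varphi=0.01$ of the voltage drop,
$\Theta_E=0.05$, $\Theta_J=0.01$, skip fraction $10^{-3}$, 8 iterations
per region) are package conventions, exposed in `refinement_config()`;
the thresholds themselves are standard but their values are not fixed by
any reference. Refinement never coarsens, and with infinite thresholds
the mesh passes through unchanged.

## Solvers and flux evaluation

P1 and P2 Lagrange tetrahedra are implemented; current evaluation always
uses P2, because boundary flux needs a non-constant gradient per cell.
The complex system is kept as two real stiffness matrices (conductive,
possibly tensor-weighted; capacitive, isotropic). Real/QS problems are
solved with a supernodal sparse Cholesky factorization. Complex problems
use a conjugate-orthogonal CG iteration (the complex-symmetric variant of
CG) preconditioned by the Cholesky factor of $K_\sigma+K_\varepsilon$,
which is definite on the free unknowns even where floating conductors
make one part vanish; the iteration is run to a relative residual of
$10^{-10}$ and errors out if it fails to converge. This is algebraically
equivalent to the mixed real/imaginary two-block formulation, and a test
asserts that QS equals EQS exactly when all permittivities are zero.

Two flux evaluators coexist deliberately. `contact_current()` integrates
the normal admittivity flux over contact facets (the definitional surface
integral). `contact_current_residual()` sums the weak residual over a
contact's constrained dofs; it is discretely conservative (two-contact
balance to machine precision, floating regions carry exactly zero net
current) and much more accurate on coarse or stair-stepped interfaces.
The multicontact current-controlled mode — one solve per driven contact
with the others floating, then Ohm's-law rescaling plus superposition of
the floating potentials — uses the residual flux, because the middle
contact's small prescribed current is a difference of large coupled
fluxes and amplifies any flux error. The two evaluators cross-check each
other in the test suite.

In voltage-controlled runs with an electrode-tissue interface, the
double layer is a lumped constant-phase element
$Z_{\text{CPE}}=K_S/(j\omega)^\alpha$ in series with the tissue on each
active contact; $K_S$ is given per unit area and divided by the actual
contact area, so contact size matters. The corrected Dirichlet values
subtract each contact's own CPE drop and the field problem is re-solved;
Kirchhoff consistency of the divider is tested to machine precision. In
current-controlled runs the series interface cannot change the field and
is ignored. Faradaic (charge-transfer) conduction is out of scope.

## Stimulus spectrum

Three pulse shapes are supported (rectangular, centered triangular,
ramp), with closed-form Fourier coefficients. The phase parameter shifts
the pulse within the period (not the train start). The spectrum is
one-sided: weight 1 for DC, 2 for positive harmonics; the identity
round-trip (unit transfer reproduces the band-limited waveform) is the
test of that convention. The default band edge of 1 MHz is truncated to
the nearest harmonic of the repetition rate.

Truncation either keeps the first $n$ harmonics, the $n$ largest by
coefficient magnitude, or — above a start frequency — solves one
representative harmonic per geometric octave band $[f, 2f)$ (the
harmonic closest to the geometric band centre) while every band member
keeps its own coefficient and reuses the representative's transfer. With
an identity transfer the octave scheme reproduces the untruncated
reconstruction exactly, which pins down the bookkeeping.

## Axons and activation

Axon geometry follows the double-cable myelinated fibre convention:
nodes of Ranvier separated by a fixed internodal pattern
(MYSA, FLUT, 3×STIN mirrored), with node spacing and segment lengths
tabulated for fibre diameters 5.7–16.0 µm. Only geometry is modelled — no
membrane dynamics. A generated axon with $n$ nodes has exactly
$n + 10(n-1)$ compartments. Populations are ordered arrays (grid ×
orientations, x-fastest ordering) or imported point sequences, whose
arc-length spacing is trusted as given.

An axon is excluded if any compartment leaves the domain, lands in the
encapsulation sheath, in electrode metal, or in a voxel with an excluded
tissue label (CSF by default) — such fibres are anatomically implausible
or electrically shielded. Filtering is idempotent and monotone in the
excluded-label set, and is tested against an exhaustive per-compartment
oracle.

Activation is estimated by thresholds, not simulated: either peak $|E|$
over the compartments, or the activating function — the second spatial
difference of the potential along the nodes of Ranvier with the actual
internode spacing (all-compartment evaluation is an option). Thresholds
are mandatory user inputs; no defaults are shipped, because defensible
values depend on pulse width, fibre diameter and the membrane model one
has in mind. Time courses come from the inverse transform of the probed
per-frequency potentials; in current mode each per-frequency solution is
first rescaled to the prescribed current.

## Pipeline, determinism and artifacts

`run_simulation()` chains mesh build → tissue/tensor mapping → axon
placement and filtering → refinement → per-frequency solves → optional
CPE correction → scaling → time courses → activation. Every step writes
a JSON metadata record plus a state file keyed by a hash of its inputs;
re-running an unchanged configuration skips completed steps, and a
failed step leaves a resumable record. Frequency solves can be
dispatched to forked workers (`workers` in the config); the contract is
bitwise identity with the serial run, which a test enforces. Artifacts
are plain formats: VTK for meshes and fields, CSV for populations,
impedances, activation and time courses, JSON for reports and configs.

The synthetic phantoms (`make_synthetic_tissue_volume()`) stand in for
segmented MRI: uniform tissue, concentric grey/white/CSF shells, a grey
background with an ellipsoidal CSF pocket, and a half-space split, plus
an axis-aligned constant tensor field. They are deterministic given the
seed and reproduce the geometric features the algorithms key on (label
interfaces, a conductive inclusion near the lead) — but not partial
voluming, segmentation noise, convoluted CSF geometry or realistic DTI
fields, so green tests demonstrate algorithmic correctness, not clinical
validity on real imaging data.

## Problem sizes and numerical conventions

The shipped tests and the acceptance script run at desk scale by choice:
toy domains of 7–10 mm with $10^4$–$6\times10^4$ tetrahedra, P2 spaces up
to roughly $10^5$ unknowns, spectra truncated to 3–40 retained
harmonics. The concentric-spheres verification uses a subdivision-3
icosphere with ten geometrically graded layers plus one bisection pass
near the inner contact. Bisection uses deterministic longest-edge
selection (ties broken by the smallest global node pair, so neighbouring
cells agree), and point location breaks boundary ties towards the best
barycentric fit. Degenerate inputs are errors, not silent repairs:
zero-current scaling, zero total impedance in the CPE divider, missing
transfer values, and points outside the mesh all name the offending
quantity; the two benign exceptions are clamping an over-long truncation
(with a warning) and clipping negative tensor eigenvalues to zero (with
a warning), both of which have one sensible interpretation.

## Known limitations

No membrane dynamics (threshold approximations only); no Faradaic
interface processes; no transient (time-domain) solves; no CAD lead
geometries; anisotropy is cell-wise constant and never applied to
permittivity; the structured carve-out approximates the lead surface to
within one local edge length; imported axon populations are not
resampled. The multicontact pipeline path drives one source contact —
multi-source current steering is available at the API level
(`multicontact_current_mode`) but not wired into the JSON config.
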