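---
title: "QuenchBind: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QuenchBind: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(QuenchBind)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, the
numerical choices, and the known limitations.

## The inference chain

### Stern–Volmer quenching

A quencher at concentration $[Q]$ reduces the protein's intrinsic
fluorescence from $F_0$ to $F$ according to

$$\frac{F_0}{F} = 1 + K_{sv}[Q] = 1 + K_q \tau_0 [Q],$$

where $K_{sv}$ (L/mol) is the quenching constant, $\tau_0$ the fluorophore
lifetime without quencher, and $K_q = K_{sv}/\tau_0$ the bimolecular
quenching rate constant. `fitSternVolmer()` reads the peak intensity of
each spectrum (`extractPeak()`), forms $F_0/F$, and fits ordinary least
squares against $[Q]$.

Two assumptions matter. First, the model is linear only for a single
dominant quenching mode; curvature in $F_0/F$ indicates mixed static and
dynamic quenching and will show up in the fit's $R^2$ and intercept.
Second, the intercept should be 1; the default fit leaves it **free** as a
normalisation diagnostic (a constrained mode, `constrainedIntercept =
TRUE`, regresses $F_0/F - 1$ through the origin for the literal law). A
free intercept surfaces blank-subtraction or inner-filter faults that a
constrained fit silently absorbs.

Mechanism classification compares $K_q$ with the maximum
diffusion-collision quenching constant, $2.0 \times 10^{10}$ L/(mol·s):
above it, quenching cannot be purely collisional and is called *static*;
below, *dynamic*. Within one standard error of the threshold the verdict
is *indeterminate* — a band of our own choosing, since the underlying rule
is stated only as an inequality; real casein-ligand systems sit 2 orders
of magnitude above the threshold, so the band never matters in practice.
$\tau_0$ defaults to $10^{-8}$ s, the customary biopolymer lifetime scale.

### Double-logarithmic binding fit

For $m$ equivalent binding sites,

$$\log_{10}\frac{F_0 - F}{F} = \log_{10} K_b + n \log_{10} [Q],$$

fitted by `fitDoubleLog()` over the nonzero concentrations. The slope $n$
is the apparent binding-site number (stoichiometry is `round(n)`), the
intercept gives $K_b$ in L/mol. Logarithm base 10 is used here, as is
standard in this literature, while the van't Hoff analysis below uses the
natural log — the two conventions are deliberate and independent.

A point of honesty about precision: with a titration covering
$2\times10^{-6}$–$10^{-5}$ mol/L, $\log_{10}[Q]$ spans only
$[-5.7, -5]$, while the intercept lives at $\log_{10}[Q] = 0$. The fit
therefore extrapolates about five decades beyond the data, and any noise
in the intensities is amplified into the intercept by more than an order
of magnitude. Measured over 200 seeded replicates, Gaussian noise with SD
equal to 1% of the $F_0$ peak leaves the *slope* of the Stern–Volmer fit
accurate to about 1% (median), but inflates the median relative error of
$K_b$ to roughly 80%. This is a property of the functional form, not of
the implementation; the test suite asserts the 5% median-recovery bound
for $K_{sv}$ at 1% noise, and for $K_b$ asserts recovery at
proportionally tighter noise plus monotone error scaling. Users fitting
real data should report $\log_{10} K_b$ with its standard error rather
than trusting the leading digits of $K_b$.

### Van't Hoff thermodynamics

$$\ln K_b = -\frac{\Delta H}{RT} + \frac{\Delta S}{R}, \qquad
  \Delta G = \Delta H - T\Delta S,$$

with $R = 8.314$ J/(mol·K). `fitVantHoff()` regresses $\ln K_b$ on $1/T$;
$\Delta H = -R \cdot \mathrm{slope}$ is reported in kJ/mol and
$\Delta S = R \cdot \mathrm{intercept}$ in J/(mol·K), the units this
literature prints. The assumption is that $\Delta H$ and $\Delta S$ are
temperature-independent over the fitted range (no $\Delta C_p$ term) —
reasonable for the narrow 298–312 K windows typical of these studies, and
unfalsifiable from three points anyway.

`gibbsEnergy()` harmonises the mixed units explicitly:
$\Delta G = \Delta H - T \Delta S / 1000$ (kJ/mol). The division by 1000
is easy to lose when tables carry $\Delta H$ in kJ and $\Delta S$ in J;
published tables in this area sometimes print what is numerically
$-T\Delta S$ (in kJ) in a column labelled $\Delta G$, which the explicit
harmonisation here avoids. All internal arithmetic is in J.

The driving-force call follows the Ross–Subramanian sign heuristic with
**strict** inequalities; a zero on either axis means the sign is not
established and the class is `unclassified` rather than a guess.

### Docking energy to dissociation constant

`ebToKd()` implements $K_d = \exp(E_b / R'T)$ with
$R' = 1.987207\times10^{-3}$ kcal/(mol·K), the convention by which docking
tools relate a score in kcal/mol to a dissociation constant. The map is
strictly increasing and multiplicative
($K_d(a+b) = K_d(a)K_d(b)$ at fixed $T$); energies near $-7$ kcal/mol land
on the $10^{-6}$–$10^{-5}$ mol/L scale at 298.15 K, the default
temperature (docking scores rarely state one).

## The synthetic-data generator

`generateEmissionTitration()` emits one Gaussian emission band per
quencher concentration, with peak amplitude following one of the two
quenching laws exactly:

* Stern–Volmer mode: $F = F_0 / (1 + K_{sv}[Q])$
* binding mode: $F = F_0 / (1 + K_b [Q]^n)$

The defaults encode a casein–curcumin-style experiment: concentrations
$\{0, 2, 4, 6, 8, 10\}\times10^{-6}$ mol/L, a 300–450 nm grid at 1 nm,
emission centre 337 nm (334 nm is the typical centre at acidic pH), band
width $\sigma = 25$ nm. The band width is a cosmetic choice — the fits
read only the peak amplitude, so $\sigma$ is irrelevant to every
downstream number as long as the band fits the grid. The peak position is
held fixed across concentrations, matching the observed behaviour of
casein quenching; a concentration-dependent spectral shift is *not*
modelled. Noise is additive Gaussian per grid point under a caller-
supplied seed (seeds are mandatory arguments; there is no hidden global
state, and the session RNG is restored after each call). With
`noiseSD = 0` output is bit-reproducible and seed-independent.

Not emulated: inner-filter absorption (a real titration at high quencher
absorbance underestimates $F$ and biases $K_{sv}$ upward), photobleaching,
FRET, scattering baselines, instrument wavelength error. Passing tests on
this generator therefore demonstrates correctness of the *fitting
chain*, not robustness to every artefact of real spectra; the blank-
subtraction hook and the free-intercept diagnostic are the package's
handles for the most common real-data deviations.

`generateKbSeries()` inverts the van't Hoff law exactly, so
generator→fitter round trips recover $(\Delta H, \Delta S)$ to $10^{-9}$
relative — used as an exactness oracle in the tests.

On the structural side, `buildIdealChain()` constructs poly-alanine
backbones (N, H, CA, C, O) by internal-to-Cartesian placement with
standard geometry (N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å, C=O 1.231 Å;
angles 111.2°/116.2°/121.7°), every residue at the requested
$(\phi, \psi, \omega)$; `applyRigidMotion()` and `makeHbondFixture()`
complete the fixture kit. Dihedral conventions were cross-checked against
two independent structural libraries; built chains reproduce their input
torsions to $10^{-6}$ degrees.

## Structural metrics

**RMSD.** `backboneRmsd()` matches atoms by (chain, residue, name),
superposes with the closed-form Kabsch algorithm (SVD of the covariance,
determinant guard against reflections), and reports the post-alignment
RMSD. The tests verify symmetry, rigid-motion invariance, and agreement
within $10^{-3}$ Å with both a rotation-grid search oracle and an
established reference aligner.

**Hydrogen bonds.** `detectHbonds()` uses geometric criteria: donor–
acceptor distance $\le 3.5$ Å and, when the donor hydrogen is present,
D–H···A angle $\ge 120°$ (vertex at H). Both cutoffs are exposed because
no single criterion is canonical across analysis engines; counts from
different tools (energy-based criteria especially) are not expected to
match ours bond-for-bond. Structures without hydrogens fall back to the
distance criterion alone, flagged `heavyOnly`.

**Secondary structure.** `assignSecondaryStructure()` is a four-class
simplification of the Kabsch–Sander scheme. Backbone H-bonds are scored
by the electrostatic energy
$E = 0.084\,(1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN}) \times 332$
kcal/mol (bond iff $E < -0.5$), with missing amide hydrogens
reconstructed in-plane opposite the bisector of the two N bonds at
1.01 Å. Helices (H) need two consecutive $i\!\to\!i{+}4$ turns; strands
(E) come from parallel/antiparallel bridge patterns (inter-chain bridges
included); $i\!\to\!i{+}3$ turns give T; the rest is coil. The four
classes {H, E, T, C} mirror the helix/sheet/turn/coil accounting used by
MD analysis tools; 3₁₀- and π-helices are not distinguished from H.
Chains under 5 residues are all-coil with a warning. Fractions always sum
to 100.

**Ramachandran summary.** `ramachandranSummary()` classifies each
residue's $(\phi, \psi)$ against a shipped, deliberately coarse rectangle
map (`ramachandranMap()`) with four levels — core, additional, generous,
disallowed — and a widened map for glycine. The map is an owned,
versioned artefact: it contains the canonical $\alpha$ and $\beta$ basins
as core and is validated by construction tests (an ideal helix is 100%
core; $(\phi,\psi) = (60°, 60°)$ is disallowed for non-glycine). It does
not reproduce any particular validation program's grids, so percentages
on real structures will differ from, e.g., PROCHECK's — the summary is
for internal consistency checks and coarse triage, not model validation.

## Numerical choices

* **Peak extraction**: centred moving average (default half-width 2 nm),
  grid maximum (lowest wavelength wins exact ties), then 3-point
  parabolic refinement. Peaks on the grid edge are returned unrefined and
  flagged. Flat spectra raise a degenerate-peak error rather than return
  an arbitrary position. Smoothing is linear, so $F_0/F$ ratios — and
  hence every fitted constant — are invariant under uniform intensity
  scaling.
* **Intensities are never renormalised**; the ratios in both fitted laws
  cancel units.
* **Blank handling**: `subtractBlank()` is elementwise and linear;
  omitted blanks warn instead of failing.
* **Titration file format**: long-format delimited text
  (`wavelength_nm,intensity,quencher_conc_M,temperature_K,pH`) with the
  blank under a sentinel concentration of −1; numerics are written at 12
  significant digits, so write→load round trips are lossless at that
  precision. Long format was chosen over wide (one column per
  concentration) because it is self-describing and order-independent.
* **PDB I/O** delegates parsing and record formatting to bio3d;
  multi-model files become `StructureEnsemble` objects with a
  configurable frame spacing (default 20 ps, a common trajectory write
  interval). Coordinates survive round trips at the format's 3-decimal
  precision.
* **Determinism**: `runPipeline()` output is byte-identical for identical
  configurations; reports carry md5 hashes of file inputs.

## Problem sizes in the test suite

The suite runs on synthetic material sized for seconds-scale execution:
6-concentration titrations on 151-point grids; 200 seeded replicates for
the noise-robustness regression; chains of 6–20 residues; ensembles of up
to 21 frames; rotation-grid oracles on 4-point toy sets. These sizes are
the package's choice of smallest material that exercises every code path
with meaningful statistics.

## Known limitations

* No inner-filter correction, modified (Lehrer) Stern–Volmer plot, or
  time-resolved lifetime analysis.
* The double-log $K_b$ is intrinsically noise-amplifying (see above); the
  package reports standard errors so users can judge.
* Secondary-structure and Ramachandran outputs are simplified,
  self-consistent schemes — not drop-in replacements for DSSP or
  PROCHECK on experimental structures.
* Hydrogen-bond counts depend on the chosen geometric cutoffs and will
  not numerically match energy-criterion engines.
* Docking and molecular-dynamics engines themselves are out of scope; the
  package consumes their outputs (energies, trajectories) only.
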