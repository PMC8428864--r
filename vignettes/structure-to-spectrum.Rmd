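---
title: "From pigment geometry to absorption spectra: methods and choices"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psiexciton)
```

This vignette documents the model implemented by psiexciton, the numerical
choices behind it, and what the synthetic generators do and do not emulate.
It follows the pipeline order: coordinates → transition charges → couplings
→ exciton Hamiltonian → simulated spectra → experimental workup →
conservation profiles.

## 1. Structures and pigment labels

`read_structure()` wraps bio3d's PDB/mmCIF readers into a single
`structure_model` with one explicit policy decision: alternate locations
are resolved by keeping the highest-occupancy record per atom, first
record on ties. Pigments are addressed through `pigment_label_map()`
objects (stable label → chain + residue number), because residue numbering
is structure-specific and the pipeline refuses to guess it.

`cofactor_inventory()` classifies residues into chlorophyll / carotenoid /
phylloquinone / iron–sulfur / protein / other by residue name
(`default_cofactor_classes()`); unknown names are counted under "other"
and reported, never dropped, so the per-class counts always sum to the
residue total.

Inter-ring contacts use `min_ring_distance()`: the minimum over all
heavy-atom pairs between two named atom subsets ("indole" for tryptophan,
"macrocycle" for chlorins). This closest-heavy-atom definition matches how
contact distances between a tryptophan and a chlorophyll ring are usually
quoted, and is symmetric by construction.

## 2. Transition charges and dipoles

A TrESP charge set is a named vector of atom-centered charges with zero
net monopole; `transition_charges()` enforces `|sum q| <= 1e-3 e` because
the transition dipole `mu = sum_i q_i r_i` is origin-independent only for
a traceless set. Units: charges in e, coordinates in Angstrom, so `mu` is
in e·Angstrom; 1 e·Angstrom = 4.80320 D.

Every pigment is rescaled (`rescale_charges()`, or the `target_dipole`
argument of `pigment_site()`) so `|mu| = 4.3` D, the effective in-protein
Q~y~ dipole strength of chlorophyll a. This choice absorbs environmental
screening into the dipole magnitude, which is why the Coulomb sum below
carries no screening factor — a deliberate modelling convention, not an
omission.

## 3. Couplings

`coupling_tresp()` evaluates the unscreened Coulomb sum

$$V = f \sum_{i \in a, j \in b} \frac{q_i q_j}{r_{ij}}, \qquad
f = 1.16140 \times 10^5\ \mathrm{cm^{-1}\,\mathring{A}\,e^{-2}},$$

erroring below 1 Angstrom minimum separation (overlapping sites — the
point-charge picture is meaningless) and warning below 3.5 Angstrom
(contact range — TrESP degrades where orbital overlap matters).

`coupling_point_dipole()` implements the far-field closed form
$V = 5.034\times 10^3\, \kappa\, \mu_a \mu_b / R^3$ (Debye, Angstrom) with
the orientation factor
$\kappa = \hat\mu_a\cdot\hat\mu_b - 3(\hat\mu_a\cdot\hat n)(\hat\mu_b\cdot\hat n)$.
It serves as an independent oracle: the test suite checks that the TrESP
sum converges to it to better than 1% at 50 Angstrom separation.

Cross-structure geometry changes are quantified by
`dipole_rotation_angle()`: a Kabsch superposition (base-R SVD) on shared
anchor-pigment macrocycle atoms brings the comparison structure into the
reference frame, and the rotation of a chosen pigment's dipole is then
decomposed into in-plane and out-of-plane parts relative to the
least-squares plane of a reference macrocycle (plane normal = third right
singular vector of the centered anchor coordinates). Collinear anchors are
rejected as degenerate rather than silently producing an arbitrary axis.

## 4. Exciton Hamiltonian and simulated spectra

`build_hamiltonian()` assembles the symmetric matrix from named site
energies and a coupling matrix (labels are matched by name, never by
position). `diagonalize()` returns ascending-energy states, orthonormal
coefficients, per-state dipoles $\mu_k = \sum_m c_{mk}\mu_m$ and dipole
strengths $|\mu_k|^2$; two invariants — trace conservation and the
oscillator-strength sum rule — are exercised continuously by the tests.

`simulate_absorption()` performs Monte-Carlo disorder averaging:

- diagonal perturbed with i.i.d. Gaussian noise of FWHM 300 cm^-1
  (`disorder_model()`; sigma = FWHM / (2 sqrt(2 ln 2)));
- default 10^6 iterations, the study-scale value; the test suite uses
  10^5, this package's own choice of a quick-but-converged size;
- each state deposits $|\mu_k|^2$ into the 1 cm^-1 bin containing its
  energy on a 12000–16000 cm^-1 grid (`line_shape()`); binning is an
  explicit per-state loop because two states can land in the same bin;
- the averaged histogram is convolved with a normalized discrete Gaussian
  of 10 cm^-1 FWHM (display smoothing only);
- the grid must cover all mean site energies ± 5 sigma, enforced up
  front, so no intensity is silently clipped;
- intensities carry no frequency prefactor and `as_wavelength()`
  (lambda = 10^7 / E) applies no Jacobian: across the narrow Q~y~ band
  both are near-constant and would cancel in normalized comparisons.

Linewidths are best read off with `spectrum_fwhm(spec, "moments")` (the
intensity-weighted second moment, exact for a Gaussian): the half-maximum
crossing estimator is biased low on Monte-Carlo spectra because the noisy
peak maximum is biased high.

`simulated_difference()` normalizes each simulated spectrum to unit area
over its full band before subtracting. In the paired pipeline
(`run_spectrum_compare()`) both structures are simulated with *common
random numbers* — the identical disorder draw — so the difference reflects
couplings and dipoles only, and is identically zero for identical
structures rather than zero-mean noise.

## 5. Experimental workup

The experimental side mirrors standard absorbance-difference practice:

- `normalize_area()`: unit trapezoidal area over 550–775 nm (the
  Q-band region), with the window edges included by interpolation;
  idempotent, scale recorded in metadata.
- `difference_spectrum()`: linear interpolation of one spectrum onto the
  other's axis, subtraction over the overlap only; warns if either input
  was not area-normalized.
- `spectral_features()`: extrema refined by a three-point parabola through
  the extreme sample and neighbours (recovers off-grid peak positions to
  well under a tenth of the grid step); probe intensities and intensity
  ratios by linear interpolation.
- `fit_gaussians()`: bounded Levenberg–Marquardt (minpack.lm) of k
  Gaussians in the *wavelength* domain — difference features are reported
  and compared in nm, so fitting in nm avoids a domain conversion of the
  fitted widths. The multistart is deterministic: 16 phase-shifted
  equispaced center layouts plus one start anchored at the strongest
  observed feature; centers are bounded to the fit region and FWHMs to
  [1, 40] nm (narrower than the grid is meaningless; wider than the
  region is a baseline, not a band). The best-RMS converged start wins;
  a width pinned at its bound is flagged (`width_at_bound`), and
  non-convergence is reported honestly instead of raising. The default
  fit region for far-red difference features is 680–730 nm with 3
  components.

## 6. Conservation profiles

`anchor_column()` maps an ungapped residue position of a reference
sequence to its alignment column (cumulative non-gap count), so a
structural position can be located in any alignment that contains the
reference. `column_profile()` reports per-residue fractions over the
*non-gap* entries and aggregates them into charge classes (D/E negative;
K/R/H positive; N; other); the gap fraction uses the full sequence count
as denominator and is reported separately, so heavily gapped columns are
conspicuous rather than inflating class percentages.

## 7. Synthetic generators

The generators exist so every pipeline stage can be tested against known
ground truth without external data; each returns its planted parameters
alongside the data.

- `chlorin_template()` / `make_chlorin()`: a rigid, planar, idealized
  chlorin (Mg, four pyrrole nitrogens at canonical names, ring carbons,
  methine bridges) placed by a recorded rotation + translation + optional
  seeded jitter. It emulates the geometry and atom naming a chlorophyll
  macrocycle contributes to coupling calculations — not a real conformer,
  no phytyl tail, no ring pucker.
- `toy_chlorin_charges()`: ±q on N~B~/N~D~ — the minimal zero-monopole set
  polarized along the Q~y~ axis.
- `make_pigment_pair()`: two placed chlorins with the analytic
  point-dipole coupling of the planted geometry as an oracle value.
- `make_spectrum()` / `default_red_components()`: Gaussian mixtures
  (defaults: centers 699/704/711 nm, FWHMs 5/7/9 nm, amplitudes
  −0.6/−1.0/−0.5) with additive i.i.d. Gaussian noise — adequate for
  fit-recovery testing, not a physical spectrum model.
- `make_alignment()`: uniform background columns with one planted column
  drawn from class probabilities (defaults 0.48/0.30/0.22); no
  phylogenetic correlation structure is emulated.
- `write_pigments_pdb()` writes generated pigments through the real PDB
  writer so tests exercise the real readers.

Generator defaults are study-scale conditions, fixed once; tests compare
against each generator's returned truth, never against re-derived values.

## 8. Limitations

- The exciton model is point-charge electrostatics over a handful of
  pigments: no charge-transfer states, no dynamic (homogeneous)
  broadening, no vibronic structure, no full-antenna (96-pigment)
  simulation.
- TrESP couplings at van der Waals contact (< 3.5 Angstrom) are flagged
  but still computed; treat them as order-of-magnitude.
- The shipped charge table is synthetic (see the README); quantitative
  coupling reproduction requires a published charge set and deposited
  coordinates, supplied by the user.
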