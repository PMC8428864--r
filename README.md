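# psiexciton

Tools for connecting chlorophyll geometry in photosystem I (PSI) to its
Q<sub>y</sub> absorption spectroscopy, built around the question: *how do a
few long-wavelength ("red") chlorophylls shift absorption beyond 700 nm when
their geometry or environment changes?*

## The model

A cluster of `n` chlorophylls is described by a Frenkel exciton Hamiltonian

```
H_mm = E_m          (site energy of pigment m, cm^-1)
H_mn = V_mn         (excitonic coupling between pigments m and n, cm^-1)
```

Couplings are computed from atomic coordinates with the transition-charge
(TrESP) method: each pigment's Q<sub>y</sub> transition density is a set of
atom-centered point charges `q_i` (zero net monopole), and

```
V_mn = f * sum_ij  q_i q_j / r_ij,   f = 1.16140e5 cm^-1 * Angstrom / e^2
```

with all charge sets rescaled so each pigment carries an effective
transition dipole of 4.3 D (environmental screening is absorbed into that
effective value, so the Coulomb sum itself is unscreened). The point-dipole
approximation `V = 5.034e3 * kappa * mu_a mu_b / R^3` (dipoles in Debye, R
in Angstrom, kappa the orientation factor) is provided as an independent
far-field check.

Diagonalizing `H` gives exciton states with energies `E_k` and dipole
strengths `|mu_k|^2`. Absorption spectra are simulated by Monte-Carlo
averaging over static disorder: the diagonal is perturbed with independent
Gaussian noise (FWHM 300 cm^-1 by default), each state deposits its dipole
strength into the wavenumber bin at its energy, and the averaged histogram
is convolved with a narrow (10 cm^-1) Gaussian for display.

Around that core the package implements the matching experimental workup
(area normalization over 550–775 nm, difference spectra, parabola-refined
peak positions, multi-Gaussian band deconvolution), structure handling
(PDB/mmCIF reading, cofactor inventories, pigment extraction by stable
labels, Kabsch superposition and dipole-rotation decomposition,
closest-ring-atom distances), residue-conservation profiles on protein
alignments, and seed-deterministic synthetic-data generators (idealized
planar chlorins with planted rigid transforms, Gaussian-mixture spectra
and toy alignments, each carrying its generator truth for recovery tests).

The shipped charge table `inst/extdata/chla_qy_tresp_synthetic.csv` is a
*synthetic* chlorophyll-a Q<sub>y</sub> charge set (zero monopole, dipole
along the N<sub>B</sub>–N<sub>D</sub> axis); because every workflow rescales
to a target dipole, its absolute scale never matters. Substitute a published
TrESP set via `read_charge_table()` for production work.

## Worked example

Build the three-pigment red-chlorophyll cluster of the reference trimer
from its printed site energies and couplings, diagonalize, and simulate
its absorption:

```r
library(psiexciton)

E <- c(B18 = 14600, B19 = 14950, B40 = 14950)
V <- matrix(c(0, -71, -20,
              -71, 0, -106,
              -20, -106, 0), 3, 3, byrow = TRUE,
            dimnames = list(names(E), names(E)))
ham <- build_hamiltonian(E, V)
ham
#> <exciton_hamiltonian> 3 pigments (cm-1)
#>       B18   B19   B40
#> B18 14600   -71   -20
#> B19   -71 14950  -106
#> B40   -20  -106 14950

mu <- rbind(c(4.3, 0, 0), c(0, 4.3, 0), c(3.0, 3.0, 0.5))  # site dipoles, D
states <- diagonalize(ham, mu)
states
#> <exciton_states>
#>   energy_cm1 wavelength_nm dipole_strength
#> 1    14581.5         685.8          22.040
#> 2    14859.6         673.0          26.160
#> 3    15059.0         664.1           7.027

spec <- simulate_absorption(ham, mu, disorder_model(n_samples = 1e5),
                            line_shape())
as_wavelength(spec)
#> <spectrum> 4001 points, 625-833.333 nm

spectral_features(as_wavelength(spec), region = c(640, 720))$argmax
#> [1] 674.2
```

The lowest exciton state lands at 685.8 nm — a low-energy state pushed
~20 nm past the mean site energy by the couplings alone.

For structure-driven runs, `run_config()` + `run_coupling_report()` /
`run_spectrum_compare()` take two coordinate files, per-structure label
maps (YAML) and a charge table, and return dipoles, TrESP coupling
matrices, the cross-structure dipole-rotation decomposition, and
common-random-number simulated difference spectra; see the vignette
(`vignettes/structure-to-spectrum.Rmd`) for the full tour, including the
synthetic generators.

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "psiexciton", load_package = "installed")'
```

Most tests run on synthetic data with generator-truth bookkeeping. A few
acceptance-level tests require published experimental spectra and deposited
coordinate files that cannot be shipped with the package; they fail with a
message naming the file(s) to place under `tests/testthat/data/`.

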