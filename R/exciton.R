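#' Assemble a Frenkel exciton Hamiltonian
#'
#' Diagonal entries are the pigment site energies E_m; off-diagonal entries
#' the excitonic couplings V_mn, all in cm^-1.
#'
#' @param site_energies Named numeric vector of site energies (cm^-1),
#'   names are the pigment labels and define the ordering.
#' @param couplings A `coupling_matrix` (labels must match, any order) or a
#'   symmetric numeric matrix with matching dimnames; omit for uncoupled
#'   pigments.
#' @return Object of class `exciton_hamiltonian`: list with `labels` and
#'   the symmetric matrix `H`.
#' @export
build_hamiltonian <- function(site_energies, couplings = NULL) {
  labels <- names(site_energies)
  if (is.null(labels)) stop("site_energies must be named by pigment label")
  if (any(!is.finite(site_energies)) || any(site_energies <= 0)) {
    stop("all site energies must be set and positive")
  }
  n <- length(labels)
  H <- matrix(0, n, n, dimnames = list(labels, labels))
  diag(H) <- site_energies
  if (!is.null(couplings)) {
    V <- if (inherits(couplings, "coupling_matrix")) couplings$V else couplings
    if (is.null(dimnames(V)[[1]])) {
      if (!all(dim(V) == n)) stop("coupling matrix dimension mismatch")
      dimnames(V) <- list(labels, labels)
    }
    if (!setequal(rownames(V), labels)) {
      stop("coupling labels do not match site-energy labels")
    }
    V <- V[labels, labels]
    if (!isSymmetric(unname(V))) stop("coupling matrix must be symmetric")
    H[upper.tri(H)] <- V[upper.tri(V)]
    H[lower.tri(H)] <- V[lower.tri(V)]
  }
  structure(list(labels = labels, H = H), class = "exciton_hamiltonian")
}

#' @export
print.exciton_hamiltonian <- function(x, digits = 1, ...) {
  cat("<exciton_hamiltonian>", length(x$labels), "pigments (cm-1)\n")
  print(round(x$H, digits))
  invisible(x)
}

#' Diagonalize an exciton Hamiltonian
#'
#' Eigen-decomposition of H with per-state transition dipoles
#' mu_k = sum_m c_mk mu_m and dipole strengths d_k = |mu_k|^2. States are
#' returned in ascending energy order; the coefficient matrix is orthonormal
#' and the dipole strengths obey the oscillator-strength sum rule
#' sum_k d_k = sum_m |mu_m|^2.
#'
#' @param ham An `exciton_hamiltonian`.
#' @param site_dipoles n x 3 matrix of site transition dipoles (rows in the
#'   Hamiltonian's label order; any consistent unit -- Debye in typical use).
#' @return Object of class `exciton_states`: list with `energies` (cm^-1,
#'   ascending), `coefficients` (columns are states), `state_dipoles`
#'   (n x 3), and `dipole_strengths`.
#' @export
diagonalize <- function(ham, site_dipoles) {
  H <- ham$H
  if (!isSymmetric(unname(H))) stop("Hamiltonian must be symmetric")
  site_dipoles <- as.matrix(site_dipoles)
  if (nrow(site_dipoles) != nrow(H)) stop("one dipole row per pigment required")
  es <- eigen(H, symmetric = TRUE)
  ord <- order(es$values)
  vals <- es$values[ord]
  C <- es$vectors[, ord, drop = FALSE]
  mu_k <- t(C) %*% site_dipoles
  structure(list(labels = ham$labels, energies = vals, coefficients = C,
                 state_dipoles = mu_k, dipole_strengths = rowSums(mu_k^2)),
            class = "exciton_states")
}

#' @export
print.exciton_states <- function(x, ...) {
  cat("<exciton_states>\n")
  print(data.frame(energy_cm1 = round(x$energies, 1),
                   wavelength_nm = round(1e7 / x$energies, 1),
                   dipole_strength = signif(x$dipole_strengths, 4)))
  invisible(x)
}

#' Static-disorder model for site energies
#'
#' Pigment-to-pigment and complex-to-complex variation of site energies is
#' modeled as independent Gaussian perturbations of the Hamiltonian
#' diagonal, averaged by Monte Carlo.
#'
#' @param site_fwhm Full width at half maximum of the site-energy
#'   distribution in cm^-1 (default 300).
#' @param n_samples Monte-Carlo iterations (default 1e6; scale down for
#'   quick runs).
#' @param seed RNG seed making the average reproducible.
#' @return Object of class `disorder_model`.
#' @export
disorder_model <- function(site_fwhm = 300, n_samples = 1e6, seed = 1L) {
  stopifnot(site_fwhm >= 0, n_samples >= 1)
  structure(list(site_fwhm = site_fwhm, n_samples = as.integer(n_samples),
                 seed = as.integer(seed), sigma = fwhm_to_sigma(site_fwhm)),
            class = "disorder_model")
}

#' Line-shape / grid settings for simulated spectra
#'
#' @param conv_fwhm FWHM in cm^-1 of the Gaussian the averaged stick
#'   histogram is convolved with for visualization (default 10).
#' @param grid Uniform, strictly increasing wavenumber grid (cm^-1);
#'   default 12000:16000 in 1 cm^-1 steps.
#' @return Object of class `line_shape`.
#' @export
line_shape <- function(conv_fwhm = 10, grid = seq(12000, 16000, by = 1)) {
  stopifnot(conv_fwhm >= 0, length(grid) > 1, all(diff(grid) > 0))
  step <- diff(grid)
  if (max(step) - min(step) > 1e-9 * step[1]) stop("grid must be uniform")
  structure(list(conv_fwhm = conv_fwhm, grid = grid, step = step[1]),
            class = "line_shape")
}

#' Simulate a disorder-averaged Qy absorption spectrum
#'
#' For each Monte-Carlo iteration the Hamiltonian diagonal is perturbed by
#' independent Gaussian noise (sigma from the disorder FWHM), the
#' Hamiltonian is diagonalized, and each exciton state deposits its dipole
#' strength |mu_k|^2 into the wavenumber bin containing its energy. The
#' iteration-averaged histogram is then convolved with a normalized Gaussian
#' of FWHM `shape$conv_fwhm`. Stick intensity carries no frequency
#' prefactor, and conversion to wavelength (see [as_wavelength()]) applies
#' no Jacobian: over the narrow Qy band both are near-constant factors.
#'
#' @param ham An `exciton_hamiltonian`.
#' @param site_dipoles n x 3 site dipole matrix (Debye).
#' @param disorder A [disorder_model()].
#' @param shape A [line_shape()].
#' @return A [new_spectrum()] in wavenumber units; metadata records seed,
#'   sample count and widths.
#' @export
simulate_absorption <- function(ham, site_dipoles,
                                disorder = disorder_model(),
                                shape = line_shape()) {
  H <- ham$H
  n <- nrow(H)
  site_dipoles <- as.matrix(site_dipoles)
  stopifnot(nrow(site_dipoles) == n)
  grid <- shape$grid
  step <- shape$step
  E0 <- diag(H)
  cover <- 5 * max(disorder$sigma, fwhm_to_sigma(shape$conv_fwhm))
  if (min(E0) - cover < grid[1] || max(E0) + cover > grid[length(grid)]) {
    stop("simulation grid does not cover mean site energies +/- 5 sigma")
  }
  nb <- length(grid)
  acc <- numeric(nb)
  nit <- disorder$n_samples
  set.seed(disorder$seed)
  noise <- matrix(stats::rnorm(n * nit, sd = disorder$sigma), nrow = n)
  if (n == 1) {
    # single pigment: eigenvalue is the perturbed site energy itself
    e <- E0 + noise[1, ]
    d <- sum(site_dipoles[1, ]^2)
    idx <- round((e - grid[1]) / step) + 1
    idx <- idx[idx >= 1 & idx <= nb]
    acc <- tabulate(idx, nbins = nb) * d
  } else {
    Hd <- H
    for (it in seq_len(nit)) {
      diag(Hd) <- E0 + noise[, it]
      es <- eigen(Hd, symmetric = TRUE)
      mu <- crossprod(es$vectors, site_dipoles)
      d <- rowSums(mu^2)
      idx <- round((es$values - grid[1]) / step) + 1
      for (k in seq_len(n)) {  # explicit loop: states may share a bin
        if (idx[k] >= 1 && idx[k] <= nb) acc[idx[k]] <- acc[idx[k]] + d[k]
      }
    }
  }
  acc <- acc / nit
  if (shape$conv_fwhm > 0) {
    sg <- fwhm_to_sigma(shape$conv_fwhm) / step
    half <- ceiling(6 * sg)
    kern <- stats::dnorm(seq(-half, half), sd = sg)
    kern <- kern / sum(kern)
    acc <- stats::convolve(c(numeric(half), acc, numeric(half)), rev(kern),
                           type = "filter")
  }
  new_spectrum(grid, acc, unit = "wavenumber",
               metadata = list(seed = disorder$seed,
                               n_samples = nit,
                               site_fwhm_cm1 = disorder$site_fwhm,
                               conv_fwhm_cm1 = shape$conv_fwhm))
}

#' Convert a wavenumber spectrum to the wavelength axis
#'
#' lambda[nm] = 1e7 / E[cm^-1]; intensities are carried over with no
#' Jacobian reweighting.
#'
#' @param spec A `spectrum` in wavenumber units.
#' @return A `spectrum` in nm with an ascending axis.
#' @export
as_wavelength <- function(spec) {
  stopifnot(inherits(spec, "spectrum"))
  if (spec$unit == "nm") return(spec)
  new_spectrum(rev(1e7 / spec$axis), rev(spec$intensity), unit = "nm",
               metadata = spec$metadata)
}

#' Difference of two simulated spectra
#'
#' Each spectrum is first normalized to unit integrated (trapezoidal) area
#' over its full simulation band, then subtracted pointwise (`a - b`).
#' Grids must be identical.
#'
#' @param spec_a,spec_b `spectrum` objects on the same grid and unit.
#' @return A `spectrum` holding the normalized difference.
#' @export
simulated_difference <- function(spec_a, spec_b) {
  if (!identical(spec_a$unit, spec_b$unit) ||
      length(spec_a$axis) != length(spec_b$axis) ||
      max(abs(spec_a$axis - spec_b$axis)) > 1e-9) {
    stop("simulated spectra must share an identical grid")
  }
  norm1 <- function(s) {
    area <- trapz(s$axis, s$intensity)
    if (area <= 0) stop("cannot normalize: nonpositive area")
    s$intensity / area
  }
  new_spectrum(spec_a$axis, norm1(spec_a) - norm1(spec_b), unit = spec_a$unit,
               metadata = list(operands = c(a = spec_a$metadata$seed,
                                            b = spec_b$metadata$seed)))
}
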