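test_that("Hamiltonian assembly places energies and couplings correctly", {
  H <- wt_triad_hamiltonian()
  expect_equal(diag(H$H), c(B18 = 14600, B19 = 14950, B40 = 14950))
  expect_equal(H$H["B19", "B40"], -106)
  expect_equal(H$H["B18", "B40"], H$H["B40", "B18"])
  expect_equal(sum(diag(H$H)), sum(c(14600, 14950, 14950)))

  # permuting inputs and permuting back yields the identical matrix
  e <- c(B40 = 14950, B18 = 14600, B19 = 14950)
  V <- H$H; diag(V) <- 0
  H2 <- build_hamiltonian(e, V[names(e), names(e)])
  expect_equal(H2$H[H$labels, H$labels], H$H)

  # 1x1 Hamiltonian
  H1 <- build_hamiltonian(c(P = 15000))
  expect_equal(dim(H1$H), c(1L, 1L))
  expect_error(build_hamiltonian(c(A = 15000, B = -1)), "positive")
})

test_that("homodimer diagonalization gives the closed-form splitting and dipoles", {
  mu <- rbind(c(2, 0, 0), c(2, 0, 0))  # parallel site dipoles
  for (V in c(-100, -37.5, 60)) {
    H <- build_hamiltonian(c(P1 = 15000, P2 = 15000),
                           matrix(c(0, V, V, 0), 2, 2))
    st <- diagonalize(H, mu)
    expect_equal(diff(st$energies), 2 * abs(V))
    expect_equal(st$energies, sort(c(15000 - abs(V), 15000 + abs(V))))
  }
  # V < 0, parallel dipoles: the lower state is symmetric and carries all
  # the dipole strength (2|mu|^2), the upper is dark
  H <- build_hamiltonian(c(P1 = 15000, P2 = 15000),
                         matrix(c(0, -100, -100, 0), 2, 2))
  st <- diagonalize(H, mu)
  expect_equal(st$energies, c(14900, 15100))
  expect_equal(st$dipole_strengths, c(2 * 4, 0), tolerance = 1e-10)
})

test_that("eigen-decomposition satisfies orthonormality and both sum rules", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(2:6, 1)
    A <- matrix(stats::rnorm(n * n, sd = 80), n, n)
    V <- (A + t(A)) / 2; diag(V) <- 0
    E <- stats::runif(n, 14000, 16000)
    H <- build_hamiltonian(stats::setNames(E, paste0("P", 1:n)), V)
    mu <- matrix(stats::rnorm(3 * n), n, 3)
    st <- diagonalize(H, mu)
    expect_lt(max(abs(crossprod(st$coefficients) - diag(n))), 1e-8)
    expect_equal(sum(st$energies), sum(diag(H$H)), tolerance = 1e-6)
    expect_equal(sum(st$dipole_strengths), sum(mu^2), tolerance = 1e-8)
    expect_false(is.unsorted(st$energies))
  }
  H1 <- build_hamiltonian(c(P = 15000))
  st1 <- diagonalize(H1, matrix(c(1, 2, 2), 1))
  expect_equal(st1$energies, 15000)
  expect_equal(st1$dipole_strengths, 9)
})

test_that("disorder-free single-pigment spectrum is the convolution Gaussian", {
  H <- build_hamiltonian(c(P = 14000))
  mu <- matrix(c(4.3, 0, 0), 1)
  sp <- simulate_absorption(H, mu, disorder_model(0, 10, seed = 1), line_shape())
  expect_equal(sp$axis[which.max(sp$intensity)], 14000)
  expect_equal(spectrum_fwhm(sp, "halfmax"), 10, tolerance = 0.05)
  # area in grid measure equals the dipole strength
  expect_equal(sum(sp$intensity), 4.3^2, tolerance = 1e-6)
})

test_that("disorder adds in quadrature with the convolution width", {
  H <- build_hamiltonian(c(P = 14000))
  mu <- matrix(c(4.3, 0, 0), 1)
  sp <- simulate_absorption(H, mu, disorder_model(300, 2e4, seed = 5),
                            line_shape())
  expect_equal(spectrum_fwhm(sp, "moments"), sqrt(300^2 + 10^2),
               tolerance = 0.02)
})

test_that("simulation is seed-reproducible and integrates independently of coupling", {
  H <- wt_triad_hamiltonian()
  mu <- rbind(c(4.3, 0, 0), c(0, 4.3, 0), c(3, 3, 0.4))
  d1 <- disorder_model(300, 3000, seed = 11)
  s1 <- simulate_absorption(H, mu, d1, line_shape())
  s2 <- simulate_absorption(H, mu, d1, line_shape())
  expect_identical(s1$intensity, s2$intensity)

  # oscillator strength: integral identical with couplings switched off
  H0 <- build_hamiltonian(stats::setNames(diag(H$H), H$labels))
  s0 <- simulate_absorption(H0, mu, d1, line_shape())
  expect_equal(sum(s0$intensity), sum(s1$intensity), tolerance = 1e-8)
  expect_equal(sum(s1$intensity), sum(mu^2), tolerance = 1e-6)
})

test_that("zero-coupling spectrum equals the analytic sum of site Gaussians", {
  E <- c(P1 = 14300, P2 = 14700, P3 = 15100)
  mu <- rbind(c(2, 0, 0), c(0, 3, 0), c(1, 1, 1))
  H0 <- build_hamiltonian(E)
  sp <- simulate_absorption(H0, mu, disorder_model(300, 5e4, seed = 3),
                            line_shape())
  sig <- sqrt(fwhm_to_sigma <- (300 / (2 * sqrt(2 * log(2))))^2 +
                (10 / (2 * sqrt(2 * log(2))))^2)
  d <- rowSums(mu^2)
  analytic <- rowSums(vapply(1:3, function(i)
    d[i] * stats::dnorm(sp$axis, E[i], sig), numeric(length(sp$axis))))
  # max-abs bound sized from the binomial binning noise at 5e4 samples
  expect_lt(max(abs(sp$intensity - analytic)), 0.1 * max(analytic))
})

test_that("per-sample trace conservation holds under diagonal disorder", {
  set.seed(7)
  H <- wt_triad_hamiltonian()$H
  for (i in 1:20) {
    Hd <- H
    diag(Hd) <- diag(H) + stats::rnorm(3, sd = 127)
    ev <- eigen(Hd, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sum(ev), sum(diag(Hd)), tolerance = 1e-10)
  }
})

test_that("grid coverage and symmetry contracts are enforced", {
  H <- build_hamiltonian(c(P = 11000))  # below the default grid
  expect_error(simulate_absorption(H, matrix(c(1, 0, 0), 1),
                                   disorder_model(300, 10)), "grid")
  Hbad <- wt_triad_hamiltonian()
  Hbad$H[1, 2] <- Hbad$H[1, 2] + 1  # break symmetry
  expect_error(diagonalize(Hbad, matrix(0, 3, 3)), "symmetric")
})

test_that("wavelength conversion flips the axis without reweighting", {
  sp <- new_spectrum(c(14000, 14500, 15000), c(1, 2, 3), unit = "wavenumber")
  wl <- as_wavelength(sp)
  expect_equal(wl$axis, rev(1e7 / sp$axis))
  expect_equal(wl$intensity, rev(sp$intensity))
})

test_that("simulated difference is zero for identical inputs, derivative-like for shifts", {
  H <- build_hamiltonian(c(P = 14400))
  mu <- matrix(c(4.3, 0, 0), 1)
  d <- disorder_model(200, 2000, seed = 2)
  a <- simulate_absorption(H, mu, d, line_shape())
  expect_true(all(simulated_difference(a, a)$intensity == 0))

  # two offset single-Gaussian (disorder-free) spectra: antisymmetric lobes
  # with the zero crossing at the midpoint
  g1 <- simulate_absorption(build_hamiltonian(c(P = 14400)), mu,
                            disorder_model(0, 1, seed = 1), line_shape())
  g2 <- simulate_absorption(build_hamiltonian(c(P = 14500)), mu,
                            disorder_model(0, 1, seed = 1), line_shape())
  dd <- simulated_difference(g2, g1)
  mid <- which(dd$axis == 14450)
  expect_lt(abs(dd$intensity[mid]), 1e-12)
  expect_gt(dd$intensity[which(dd$axis == 14500)], 0)
  expect_lt(dd$intensity[which(dd$axis == 14400)], 0)
})
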