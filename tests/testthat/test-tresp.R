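test_that("transition dipole of a two-point charge pair is q*d along the axis", {
  s <- two_point_site("A", q = 0.2)
  # +0.2 e at origin, -0.2 e at (1,0,0) scaled by d=2: use explicit coords
  coords <- rbind(P = c(0, 0, 0), Q = c(2, 0, 0))
  td <- transition_dipole(coords, c(P = 0.2, Q = -0.2))
  expect_equal(td$vector, c(-0.4, 0, 0))
  expect_equal(td$debye, 0.4 * 4.80320)
  expect_error(transition_dipole(coords[1, , drop = FALSE], c(P = 0.2, Q = -0.2)),
               "Q")
})

test_that("degenerate and monopole-bearing charge sets are rejected at load", {
  expect_error(transition_charges(c(A = 0, B = 0)), "degenerate")
  expect_error(transition_charges(c(A = 0.3, B = -0.1)), "monopole")
})

test_that("transition dipole is origin-independent when the monopole vanishes", {
  ch <- read_charge_table(shipped_charge_table())
  coords <- chlorin_template()
  td1 <- transition_dipole(coords, ch)
  td2 <- transition_dipole(sweep(coords, 2, c(123, -45, 9), "+"), ch)
  expect_lt(max(abs(td1$vector - td2$vector)), 1e-9)
})

test_that("the shipped chlorophyll charge set polarizes along the NB-ND axis", {
  ch <- read_charge_table(shipped_charge_table())
  coords <- chlorin_template()
  mu <- transition_dipole(coords, ch)$vector
  axis <- coords["NB", ] - coords["ND", ]
  cosang <- sum(mu * axis) / sqrt(sum(mu^2) * sum(axis^2))
  expect_lt(acos(abs(cosang)) * 180 / pi, 25)
})

test_that("rescaling hits the target dipole, preserves the monopole, idempotent", {
  coords <- rbind(P = c(0, 0, 0), Q = c(1, 0, 0))
  q0 <- 5.0 / 4.80320  # gives exactly 5.0 D
  s <- pigment_site("A", coords, c(P = q0, Q = -q0))
  expect_equal(s$dipole_debye, 5.0)
  r <- rescale_charges(s, 4.3)
  expect_equal(r$dipole_debye, 4.3)
  expect_equal(r$charges$applied_scale, 0.86)
  expect_lt(abs(sum(r$charges$charges)), 1e-3)
  r2 <- rescale_charges(r, 4.3)
  expect_equal(r2$charges$charges, r$charges$charges)
  # already at target: identity
  expect_equal(rescale_charges(r, 4.3)$dipole_debye, 4.3)
})

test_that("TrESP coupling reproduces the hand Coulomb sum for point pairs", {
  sa <- two_point_site("A", c(0, 0, 0))
  sb <- two_point_site("B", c(10, 0, 0))
  hand <- 1.16140e5 * (0.01 / 10 - 0.01 / 11 - 0.01 / 9 + 0.01 / 10)
  expect_equal(coupling_tresp(sa, sb), hand, tolerance = 1e-12)
  expect_equal(coupling_tresp(sa, sb), coupling_tresp(sb, sa))
  # point-dipole closed form on the same collinear fixture: kappa = -2
  pd <- coupling_point_dipole(sa, sb, "dipole-weighted")
  kappa_form <- tresp_constants()$coulomb_cm1_A * (-2) * 0.1 * 0.1 / 10^3
  expect_equal(pd, kappa_form, tolerance = 1e-12)
  expect_lt(abs(pd - coupling_tresp(sa, sb)) / abs(pd), 0.02)
})

test_that("overlapping sites error and near-contact warns", {
  sa <- two_point_site("A", c(0, 0, 0))
  expect_error(coupling_tresp(sa, two_point_site("B", c(0.5, 0, 0))), "1 A")
  expect_warning(coupling_tresp(sa, two_point_site("B", c(3, 0, 0))), "contact")
})

test_that("coupling is invariant under joint rigid motion and bilinear in scale", {
  pp <- make_pigment_pair(18, rotation_axis = c(0, 1, 0), rotation_deg = 37)
  v0 <- coupling_tresp(pp$site_a, pp$site_b)
  for (seed in 1:5) {
    R <- random_rotation(seed)
    shift <- c(100, -40, 9) * seed
    va <- coupling_tresp(apply_rigid(pp$site_a, R, shift),
                         apply_rigid(pp$site_b, R, shift))
    expect_equal(va, v0, tolerance = 1e-9)
  }
  scale_site <- function(s, f) {
    s$charges <- transition_charges(s$charges$charges * f,
                                    applied_scale = s$charges$applied_scale * f)
    s
  }
  v_scaled <- coupling_tresp(scale_site(pp$site_a, 2), scale_site(pp$site_b, 3))
  expect_equal(v_scaled, 6 * v0, tolerance = 1e-12)
})

test_that("two parallel 4.3 D dipoles broadside at 20 A couple at +11.6 cm-1", {
  pp <- make_pigment_pair(20, target_dipole = 4.3)
  # dipoles along y, separation along x: kappa = 1
  expected <- 5.034e3 * 4.3^2 / 20^3
  expect_equal(pp$oracle_cm1, expected, tolerance = 1e-3)
  # perpendicular in-plane orientations: kappa = 0
  pk0 <- make_pigment_pair(20, rotation_axis = c(1, 0, 0), rotation_deg = 90,
                           target_dipole = 4.3)
  expect_lt(abs(pk0$oracle_cm1), 1e-9)
})

test_that("TrESP converges to the point-dipole value in the far field", {
  pp <- make_pigment_pair(50)
  v_tresp <- coupling_tresp(pp$site_a, pp$site_b)
  expect_lt(abs(v_tresp - pp$oracle_cm1) / abs(pp$oracle_cm1), 0.01)
})

test_that("Kabsch superposition recovers planted transforms", {
  P <- chlorin_template()
  R <- rotation_matrix(c(1, 2, 3), 47)
  Q <- sweep(P %*% R, 2, c(10, -5, 3), "+")
  # note kabsch maps Q back onto P
  fit <- kabsch(P, Q)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(fit$R, t(R), tolerance = 1e-9)
  # collinear anchors are degenerate
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch(line, line), "collinear")
})

test_that("dipole rotation between structures reports planted angles", {
  ch <- toy_chlorin_charges()
  p_ref <- make_chlorin()
  s_ref <- pigment_site("P", p_ref$coords, ch)
  # identical structures: zero rotation
  same <- dipole_rotation_angle(s_ref, s_ref, p_ref$coords, p_ref$coords)
  expect_lt(same$angle_deg, 1e-4)

  # pigment rotated 25 degrees about x (out of the z=0 macrocycle plane),
  # anchors untouched
  p_cmp <- make_chlorin(rotation_axis = c(1, 0, 0), rotation_deg = 25)
  s_cmp <- pigment_site("P", p_cmp$coords, ch)
  anch <- chlorin_template()
  r <- dipole_rotation_angle(s_ref, s_cmp, anch, anch)
  expect_equal(r$angle_deg, 25, tolerance = 0.01)
  expect_gt(r$out_of_plane_deg, r$in_plane_deg)

  # in-plane rotation about z stays in plane
  p_in <- make_chlorin(rotation_axis = c(0, 0, 1), rotation_deg = 25)
  s_in <- pigment_site("P", p_in$coords, ch)
  r_in <- dipole_rotation_angle(s_ref, s_in, anch, anch)
  expect_equal(r_in$angle_deg, 25, tolerance = 0.01)
  expect_gt(r_in$in_plane_deg, r_in$out_of_plane_deg)

  expect_error(dipole_rotation_angle(s_ref, s_cmp, anch[1:4, ], anch),
               "anchor")
})
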