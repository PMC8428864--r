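# Shared fixtures, all generated in code at test time.

shipped_charge_table <- function() {
  system.file("extdata", "chla_qy_tresp_synthetic.csv", package = "psiexciton")
}

# Two-point-charge site at given origin along +x: +q at origin, -q at
# origin + (1, 0, 0). Dipole magnitude q e*Angstrom.
two_point_site <- function(label, origin = c(0, 0, 0), q = 0.1) {
  coords <- rbind(P = origin, Q = origin + c(1, 0, 0))
  pigment_site(label, coords, c(P = q, Q = -q))
}

# A three-pigment synthetic "structure" written as PDB: two fixed pigments
# (the anchors) plus a third whose orientation about x can be planted.
write_triad_pdb <- function(path, third_rot_deg = 0) {
  p1 <- make_chlorin(translation = c(0, 0, 0))
  p2 <- make_chlorin(translation = c(12, 0, 0))
  p3 <- make_chlorin(rotation_axis = c(1, 0, 0), rotation_deg = third_rot_deg,
                     translation = c(12, 12, 3))
  write_pigments_pdb(list(p1, p2, p3), path)
}

triad_label_map <- function() {
  pigment_label_map(
    data.frame(label = c("B18", "B19", "B40"), chain = "X", resno = 1:3),
    structure_id = "synthetic-triad")
}

# The three-pigment Hamiltonian printed for the reference (wild-type)
# structure: site energies on the diagonal, couplings off it, cm^-1.
wt_triad_hamiltonian <- function() {
  V <- matrix(c(0, -71, -20,
                -71, 0, -106,
                -20, -106, 0), 3, 3, byrow = TRUE,
              dimnames = list(c("B18", "B19", "B40"), c("B18", "B19", "B40")))
  build_hamiltonian(c(B18 = 14600, B19 = 14950, B40 = 14950), V)
}

random_rotation <- function(seed) {
  set.seed(seed)
  ax <- stats::rnorm(3)
  rotation_matrix(ax, stats::runif(1, 0, 360))
}

apply_rigid <- function(site, R, shift) {
  site$coords <- sweep(site$coords %*% R, 2, shift, "+")
  site$dipole <- as.numeric(site$dipole %*% R)
  site
}
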