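#' Idealized planar chlorin template
#'
#' A rigid, planar, chlorin-like pigment geometry used by the synthetic
#' generators: central Mg, four pyrrole nitrogens at the canonical names
#' NA-ND, the alpha-carbon ring and the four methine bridges, all in the
#' z = 0 plane at a ~1.4-2.1 Angstrom bond scale. It is an idealization for
#' controlled-geometry tests, not a real chlorophyll a conformer.
#'
#' @return Numeric matrix (atoms x 3) with atom-name rownames.
#' @export
chlorin_template <- function() {
  rn <- 2.05   # Mg-N distance
  rc <- 3.45   # ring-carbon radius
  ang <- function(deg) deg * pi / 180
  atoms <- list(MG = c(0, 0, 0))
  ncoord <- list(`NA` = 0, NB = 90, NC = 180, ND = 270)
  for (nm in names(ncoord)) {
    a <- ang(ncoord[[nm]])
    atoms[[nm]] <- c(rn * cos(a), rn * sin(a), 0)
  }
  # alpha carbons C1X/C4X flank each nitrogen; methine bridges between rings
  ring <- c(A = 0, B = 90, C = 180, D = 270)
  for (r in names(ring)) {
    base <- ring[[r]]
    for (off in c(-24, 24)) {
      idx <- if (off < 0) "1" else "4"
      a <- ang(base + off)
      atoms[[paste0("C", idx, r)]] <- c(rc * cos(a), rc * sin(a), 0)
    }
    for (off in c(-14, 14)) {
      idx <- if (off < 0) "2" else "3"
      a <- ang(base + off)
      atoms[[paste0("C", idx, r)]] <- c(4.35 * cos(a), 4.35 * sin(a), 0)
    }
  }
  bridges <- c(CHA = 315, CHB = 45, CHC = 135, CHD = 225)
  for (nm in names(bridges)) {
    a <- ang(bridges[[nm]])
    atoms[[nm]] <- c(3.4 * cos(a), 3.4 * sin(a), 0)
  }
  do.call(rbind, atoms)
}

#' Rotation matrix about an axis
#'
#' Rodrigues rotation by `angle_deg` degrees about the unit vector `axis`,
#' for row-vector use: `coords %*% rotation_matrix(...)` rotates row points.
#'
#' @param axis Length-3 axis (normalized internally; must be nonzero).
#' @param angle_deg Rotation angle in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_matrix <- function(axis, angle_deg) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("rotation axis must be nonzero")
  u <- axis / n
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  t(R)  # transposed so that rows %*% R rotates row vectors
}

#' Place a chlorin template by rotation, translation and jitter
#'
#' The template is rotated about its centroid, translated, then optionally
#' jittered with i.i.d. Gaussian noise per coordinate. The exact planted
#' transform is returned alongside the coordinates so recovery tests can
#' check against the generator's bookkeeping instead of re-deriving it.
#'
#' @param rotation_axis Length-3 rotation axis (default z).
#' @param rotation_deg Rotation angle in degrees.
#' @param translation Length-3 translation in Angstrom.
#' @param jitter_sd Per-coordinate Gaussian jitter sigma (Angstrom).
#' @param seed RNG seed used when `jitter_sd > 0`.
#' @param template Atom coordinate matrix; default [chlorin_template()].
#' @return List with `coords` (named matrix) and `transform`
#'   (list `R`, `axis`, `angle_deg`, `translation`, `jitter_sd`, `seed`).
#' @export
make_chlorin <- function(rotation_axis = c(0, 0, 1), rotation_deg = 0,
                         translation = c(0, 0, 0), jitter_sd = 0, seed = 1L,
                         template = chlorin_template()) {
  stopifnot(jitter_sd >= 0)
  R <- rotation_matrix(rotation_axis, rotation_deg)
  coords <- template %*% R
  coords <- sweep(coords, 2, translation, "+")
  if (jitter_sd > 0) {
    set.seed(seed)
    coords <- coords + matrix(stats::rnorm(length(coords), sd = jitter_sd),
                              nrow = nrow(coords))
  }
  rownames(coords) <- rownames(template)
  list(coords = coords,
       transform = list(R = R, axis = rotation_axis, angle_deg = rotation_deg,
                        translation = translation, jitter_sd = jitter_sd,
                        seed = seed))
}

#' Toy transition charge set for the synthetic chlorin
#'
#' Charges +q on NB and -q on ND (zero monopole), giving a transition
#' dipole of magnitude `q * |NB - ND|` e*Angstrom along the NB-ND axis of
#' the template -- the axis the chlorophyll Qy transition is polarized
#' along.
#'
#' @param q Charge magnitude in e (default 0.1).
#' @return A [transition_charges()] object.
#' @export
toy_chlorin_charges <- function(q = 0.1) {
  transition_charges(c(NB = q, ND = -q), pigment_type = "toy-chlorin",
                     provenance = "synthetic two-point Qy charge set")
}

#' Generate a pigment pair with a known point-dipole coupling
#'
#' Places one chlorin at the origin and a second, optionally re-oriented,
#' copy at `separation` Angstrom along +x, assigns toy charges, and also
#' returns the analytic point-dipole coupling for the planted geometry as
#' an oracle value.
#'
#' @param separation Center separation in Angstrom (> 1).
#' @param rotation_axis,rotation_deg Orientation of the second pigment
#'   relative to the first.
#' @param q Toy charge magnitude in e.
#' @param target_dipole Optional Debye value to rescale both sites to.
#' @return List with `site_a`, `site_b` (class `pigment_site`) and
#'   `oracle_cm1`, the closed-form point-dipole coupling.
#' @export
make_pigment_pair <- function(separation, rotation_axis = c(0, 0, 1),
                              rotation_deg = 0, q = 0.1,
                              target_dipole = NULL) {
  if (separation <= 1) stop("separation must exceed 1 Angstrom")
  a <- make_chlorin()
  b <- make_chlorin(rotation_axis = rotation_axis, rotation_deg = rotation_deg,
                    translation = c(separation, 0, 0))
  site_a <- pigment_site("SYN1", a$coords, toy_chlorin_charges(q),
                         target_dipole = target_dipole)
  site_b <- pigment_site("SYN2", b$coords, toy_chlorin_charges(q),
                         target_dipole = target_dipole)
  list(site_a = site_a, site_b = site_b,
       oracle_cm1 = coupling_point_dipole(site_a, site_b))
}

#' Generate a synthetic spectrum as a sum of Gaussians plus noise
#'
#' @param components Data frame with columns `center`, `fwhm`, `amplitude`
#'   (nm domain); zero rows give an identically zero baseline.
#' @param axis Strictly increasing nm grid.
#' @param noise_sd Additive i.i.d. Gaussian noise sigma (intensity units).
#' @param seed RNG seed.
#' @return A [new_spectrum()] whose metadata stores the true generator
#'   parameters (`truth`) for recovery tests.
#' @export
make_spectrum <- function(components, axis = seq(650, 750, by = 1),
                          noise_sd = 0, seed = 1L) {
  stopifnot(is.data.frame(components), noise_sd >= 0)
  y <- numeric(length(axis))
  for (i in seq_len(nrow(components))) {
    y <- y + gauss_eval(axis, components$center[i], components$fwhm[i],
                        components$amplitude[i])
  }
  if (noise_sd > 0) {
    set.seed(seed)
    y <- y + stats::rnorm(length(axis), sd = noise_sd)
  }
  new_spectrum(axis, y, unit = "nm",
               metadata = list(truth = components, noise_sd = noise_sd,
                               seed = seed))
}

#' Default component set mirroring the far-red difference-band structure
#'
#' Three negative Gaussians at 699, 704 and 711 nm -- the band positions
#' resolved by deconvolution of the far-red absorbance-difference feature.
#'
#' @return Data frame with columns `center`, `fwhm`, `amplitude`.
#' @export
default_red_components <- function() {
  data.frame(center = c(699, 704, 711), fwhm = c(5, 7, 9),
             amplitude = c(-0.6, -1.0, -0.5))
}

.aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
           "Q", "R", "S", "T", "V", "W", "Y")

#' Generate a toy alignment with a planted column composition
#'
#' Background columns are uniform over the 20 amino acids; at the planted
#' column each sequence's residue class is drawn from `class_probs`
#' (classes: `neg` -> D/E, `pos` -> K/R/H, `asn` -> N, `gap` -> `-`,
#' `other` -> remaining amino acids). The drawn class counts are returned
#' as generator truth.
#'
#' @param n_sequences Number of sequences.
#' @param length Aligned length.
#' @param planted_column Column index to plant.
#' @param class_probs Named probabilities over
#'   `c("neg", "pos", "asn", "gap", "other")` subsets; must sum to 1.
#' @param seed RNG seed.
#' @return List with `aln` (an [alignment()]) and `truth` (list with
#'   `column`, drawn `class_counts`, and the planted `class_probs`).
#' @export
make_alignment <- function(n_sequences, length, planted_column,
                           class_probs = c(neg = 0.48, asn = 0.30,
                                           other = 0.22),
                           seed = 1L) {
  stopifnot(planted_column >= 1, planted_column <= length,
            abs(sum(class_probs) - 1) < 1e-9)
  pools <- list(neg = c("D", "E"), pos = c("K", "R", "H"), asn = "N",
                gap = "-",
                other = setdiff(.aa20, c("D", "E", "K", "R", "H", "N")))
  if (!all(names(class_probs) %in% names(pools))) {
    stop("unknown class in class_probs")
  }
  set.seed(seed)
  mat <- matrix(sample(.aa20, n_sequences * length, replace = TRUE),
                nrow = n_sequences)
  cls_draw <- sample(names(class_probs), n_sequences, replace = TRUE,
                     prob = class_probs)
  mat[, planted_column] <- vapply(cls_draw, function(cl) {
    p <- pools[[cl]]
    if (length(p) == 1) p else sample(p, 1)
  }, "")
  seqs <- apply(mat, 1, paste, collapse = "")
  aln <- alignment(sprintf("seq%04d", seq_len(n_sequences)), seqs)
  truth <- list(column = planted_column,
                class_counts = table(factor(cls_draw,
                                            levels = names(class_probs))),
                class_probs = class_probs)
  list(aln = aln, truth = truth)
}

#' Write placed pigments as a PDB fixture
#'
#' Wraps a list of placed pigment coordinate sets into a `structure_model`
#' (residue name CLA, chain X, consecutive residue numbers) and writes it
#' with [write_structure_pdb()], so tests exercise the real reader.
#'
#' @param pigments List of coordinate matrices (rownames = atom names), or
#'   of [make_chlorin()] results.
#' @param path Output PDB path.
#' @param resname Residue name to assign (default `"CLA"`).
#' @param chain Chain id (default `"X"`).
#' @return The `structure_model` that was written, invisibly.
#' @export
write_pigments_pdb <- function(pigments, path, resname = "CLA", chain = "X") {
  rows <- list()
  for (i in seq_along(pigments)) {
    p <- pigments[[i]]
    coords <- if (is.list(p) && !is.null(p$coords)) p$coords else p
    rows[[i]] <- data.frame(
      chain = chain, resno = i, insert = "", resname = resname,
      atom = rownames(coords),
      element = ifelse(substr(rownames(coords), 1, 1) %in% c("N", "M"),
                       ifelse(rownames(coords) == "MG", "MG",
                              substr(rownames(coords), 1, 1)), "C"),
      x = coords[, 1], y = coords[, 2], z = coords[, 3],
      occ = 1, stringsAsFactors = FALSE)
  }
  model <- new_structure_model("synthetic", do.call(rbind, rows))
  write_structure_pdb(model, path)
  invisible(model)
}
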