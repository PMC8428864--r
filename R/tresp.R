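#' Transition charge sets
#'
#' A transition charge set represents a pigment's Qy transition density as
#' atom-centered point charges (in units of the elementary charge). The
#' transition monopole must vanish: |sum q_i| <= 1e-3 e is enforced at
#' construction and after every rescaling, which is what makes the derived
#' transition dipole origin-independent.
#'
#' @param charges Named numeric vector, atom name -> charge in e.
#' @param pigment_type Free-text pigment type, e.g. `"CLA"`.
#' @param provenance Citation or description of where the charges come from.
#' @param applied_scale Positive multiplier already applied to the raw set.
#' @return Object of class `transition_charges`.
#' @export
transition_charges <- function(charges, pigment_type = "CLA",
                               provenance = "", applied_scale = 1) {
  stopifnot(is.numeric(charges), !is.null(names(charges)), applied_scale > 0)
  if (anyDuplicated(names(charges))) stop("duplicate atom names in charge set")
  if (abs(sum(charges)) > 1e-3) {
    stop(sprintf("charge set has non-zero transition monopole (%.2e e)",
                 sum(charges)))
  }
  if (all(charges == 0)) stop("degenerate charge set: all charges zero")
  structure(list(pigment_type = pigment_type, charges = charges,
                 provenance = provenance, applied_scale = applied_scale),
            class = "transition_charges")
}

#' Read a transition-charge table from CSV
#'
#' Expects columns `atom_name,charge_e`; leading `#` lines are treated as a
#' provenance header and stored verbatim.
#'
#' @param path CSV path.
#' @param pigment_type Pigment type tag.
#' @return A `transition_charges` object.
#' @export
read_charge_table <- function(path, pigment_type = "CLA") {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  # na.strings disabled: "NA" is a legitimate atom name (pyrrole nitrogen A)
  tab <- utils::read.csv(text = lines[!grepl("^#", lines)],
                         stringsAsFactors = FALSE, na.strings = character())
  stopifnot(all(c("atom_name", "charge_e") %in% names(tab)))
  transition_charges(stats::setNames(tab$charge_e, tab$atom_name),
                     pigment_type = pigment_type,
                     provenance = paste(sub("^#\\s*", "", hdr), collapse = "; "))
}

#' Transition dipole from coordinates and transition charges
#'
#' mu = sum_i q_i r_i, in e*Angstrom; the magnitude is also reported in
#' Debye (1 e*Angstrom = 4.80320 D). With a vanishing monopole the result is
#' independent of the coordinate origin.
#'
#' @param coords Numeric matrix of atom positions (Angstrom), rows named by
#'   atom name and covering every charged atom.
#' @param charges A `transition_charges` object or named numeric vector.
#' @return List with `vector` (e*Angstrom, length 3) and `debye` (scalar).
#' @export
transition_dipole <- function(coords, charges) {
  q <- if (inherits(charges, "transition_charges")) charges$charges else charges
  missing <- setdiff(names(q), rownames(coords))
  if (length(missing)) {
    stop("coordinates missing for charged atoms: ",
         paste(missing, collapse = ", "))
  }
  r <- coords[names(q), , drop = FALSE]
  mu <- as.numeric(crossprod(r, q))
  list(vector = mu,
       debye = sqrt(sum(mu^2)) * tresp_constants()$debye_per_eA)
}

#' Pigment sites
#'
#' A pigment site binds a charge set to one pigment's coordinates, together
#' with its site energy (the diagonal Hamiltonian entry) and the derived Qy
#' transition dipole. If `target_dipole` is given the charges are rescaled
#' at construction so that |mu| equals it (the study convention is an
#' effective 4.3 D Qy dipole, which absorbs dielectric screening).
#'
#' @param label Pigment label, e.g. `"B40"`.
#' @param coords Matrix of atom coordinates, rows named by atom name.
#' @param charges `transition_charges` or named numeric vector.
#' @param site_energy Site energy in cm^-1 (may be `NA` until assigned).
#' @param target_dipole Optional dipole strength in Debye to rescale to.
#' @return Object of class `pigment_site`.
#' @export
pigment_site <- function(label, coords, charges, site_energy = NA_real_,
                         target_dipole = NULL) {
  if (!inherits(charges, "transition_charges")) {
    charges <- transition_charges(charges)
  }
  if (!is.na(site_energy) && site_energy <= 0) stop("site_energy must be positive")
  td <- transition_dipole(coords, charges)
  site <- structure(list(label = label, coords = coords, charges = charges,
                         site_energy = site_energy, dipole = td$vector,
                         dipole_debye = td$debye),
                    class = "pigment_site")
  if (!is.null(target_dipole)) site <- rescale_charges(site, target_dipole)
  site
}

#' @export
print.pigment_site <- function(x, ...) {
  cat(sprintf("<pigment_site> %s: %d charged atoms, |mu| = %.4f D, E = %s cm-1\n",
              x$label, length(x$charges$charges), x$dipole_debye,
              ifelse(is.na(x$site_energy), "unset",
                     format(x$site_energy))))
  invisible(x)
}

#' Rescale a site's transition charges to a target dipole strength
#'
#' All charges are multiplied by `target / |mu|_D`, so the operation is
#' idempotent and preserves the zero-monopole invariant.
#'
#' @param site A `pigment_site`.
#' @param target Target dipole strength in Debye (default 4.3).
#' @return The rescaled `pigment_site`; `charges$applied_scale` accumulates
#'   the factor.
#' @export
rescale_charges <- function(site, target = 4.3) {
  stopifnot(inherits(site, "pigment_site"), target > 0)
  if (site$dipole_debye <= 0) stop("degenerate (zero) transition dipole; cannot rescale")
  s <- target / site$dipole_debye
  q <- site$charges
  site$charges <- transition_charges(q$charges * s, q$pigment_type,
                                     q$provenance, q$applied_scale * s)
  site$dipole <- site$dipole * s
  site$dipole_debye <- target
  site
}

site_distmat <- function(site_a, site_b) {
  ra <- site_a$coords[names(site_a$charges$charges), , drop = FALSE]
  rb <- site_b$coords[names(site_b$charges$charges), , drop = FALSE]
  d2 <- outer(rowSums(ra^2), rowSums(rb^2), "+") - 2 * ra %*% t(rb)
  sqrt(pmax(d2, 0))
}

#' Excitonic coupling by the TrESP Coulomb sum
#'
#' V = f * sum_ij q_i q_j / r_ij over the two sites' charged atoms, with
#' f = e^2/(4 pi eps0) in cm^-1 Angstrom (vacuum; no dielectric screening
#' factor -- screening is implicit in the effective 4.3 D dipole the
#' charges are rescaled to). Exactly symmetric in its arguments.
#'
#' @param site_a,site_b Rescaled `pigment_site` objects sharing no atoms.
#' @return Coupling in cm^-1.
#' @export
coupling_tresp <- function(site_a, site_b) {
  d <- site_distmat(site_a, site_b)
  if (min(d) < 1) {
    stop(sprintf("sites overlap: minimum interatomic separation %.2f A < 1 A",
                 min(d)))
  }
  if (min(d) < 3.5) {
    warning(sprintf("sites in contact (min separation %.2f A < 3.5 A); point-charge Coulomb may be unreliable", min(d)))
  }
  qa <- site_a$charges$charges
  qb <- site_b$charges$charges
  tresp_constants()$coulomb_cm1_A * as.numeric(t(qa) %*% (1 / d) %*% qb)
}

site_center <- function(site, rule = c("Mg", "dipole-weighted")) {
  rule <- match.arg(rule)
  coords <- site$coords
  if (rule == "Mg" && "MG" %in% rownames(coords)) {
    return(as.numeric(coords["MG", ]))
  }
  q <- abs(site$charges$charges)
  r <- coords[names(site$charges$charges), , drop = FALSE]
  as.numeric(crossprod(r, q) / sum(q))
}

#' Excitonic coupling in the point-dipole approximation
#'
#' V = f * (mu_a . mu_b - 3 (mu_a . n)(mu_b . n)) / R^3 with dipoles in
#' e*Angstrom and the center separation R in Angstrom; equivalently
#' 5.034e3 * kappa * mu_a[D] mu_b[D] / R^3 with the orientation factor
#' kappa = mu_a_hat . mu_b_hat - 3 (mu_a_hat . n)(mu_b_hat . n). Serves as
#' the far-field oracle for [coupling_tresp()].
#'
#' @param site_a,site_b `pigment_site` objects.
#' @param center_rule `"Mg"` (the central Mg atom if present, else the
#'   |q|-weighted centroid) or `"dipole-weighted"`.
#' @return Coupling in cm^-1.
#' @export
coupling_point_dipole <- function(site_a, site_b,
                                  center_rule = c("Mg", "dipole-weighted")) {
  center_rule <- match.arg(center_rule)
  ca <- site_center(site_a, center_rule)
  cb <- site_center(site_b, center_rule)
  dR <- cb - ca
  R <- sqrt(sum(dR^2))
  if (R < 1e-9) stop("coincident site centers")
  n <- dR / R
  ma <- site_a$dipole
  mb <- site_b$dipole
  tresp_constants()$coulomb_cm1_A *
    (sum(ma * mb) - 3 * sum(ma * n) * sum(mb * n)) / R^3
}

#' Pairwise coupling matrix over a set of pigment sites
#'
#' @param sites List of `pigment_site` objects (rescaled).
#' @param method `"tresp"` (full Coulomb sum) or `"point_dipole"`.
#' @return Object of class `coupling_matrix`: list with `labels`, symmetric
#'   `V` (cm^-1, zero diagonal), and `method`.
#' @export
couplings_from_sites <- function(sites, method = c("tresp", "point_dipole")) {
  method <- match.arg(method)
  labels <- vapply(sites, function(s) s$label, "")
  n <- length(sites)
  V <- matrix(0, n, n, dimnames = list(labels, labels))
  fun <- if (method == "tresp") coupling_tresp else coupling_point_dipole
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        V[i, j] <- V[j, i] <- fun(sites[[i]], sites[[j]])
      }
    }
  }
  structure(list(labels = labels, V = V, method = method),
            class = "coupling_matrix")
}

#' @export
print.coupling_matrix <- function(x, digits = 1, ...) {
  cat("<coupling_matrix> method =", x$method, "(cm-1)\n")
  print(round(x$V, digits))
  invisible(x)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Returns the rotation matrix `R` and translation such that
#' `sweep(Q, 2, cq) %*% R + rep(cp)` best fits `P` in the least-squares
#' sense, with a proper rotation guaranteed (reflections corrected).
#'
#' @param P,Q n x 3 coordinate matrices of paired points (n >= 3).
#' @return List with `R` (3 x 3), `center_p`, `center_q`, and `rmsd`.
#' @export
kabsch <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3, ncol(Q) == 3, nrow(P) >= 3)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- t(Qc) %*% Pc
  sv <- svd(H)
  if (min(sv$d) < 1e-10 && sum(sv$d > 1e-10) < 2) {
    stop("degenerate (collinear) anchor configuration")
  }
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- Qc %*% R
  list(R = R, center_p = cp, center_q = cq,
       rmsd = sqrt(mean(rowSums((fitted - Pc)^2))))
}

# Unit normal of the least-squares plane through points (rows of X).
ls_plane_normal <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc)
  n <- sv$v[, 3]
  n / sqrt(sum(n^2))
}

#' Rotation of a pigment's transition dipole between two structures
#'
#' Superposes structure 2 onto structure 1 by a Kabsch fit of paired anchor
#' atoms (typically the ring atoms of neighbouring pigments common to both
#' structures), transforms the comparison dipole into the reference frame,
#' and reports the angle between the two dipole directions together with an
#' in-plane / out-of-plane decomposition relative to a reference macrocycle
#' plane.
#'
#' @param site_ref,site_cmp `pigment_site` objects in structures 1 and 2.
#' @param anchors_ref,anchors_cmp Paired n x 3 anchor coordinate matrices
#'   (n >= 3) in structures 1 and 2.
#' @param plane_coords Coordinates (>= 3 x 3) in structure 1 defining the
#'   reference macrocycle plane; defaults to `anchors_ref`.
#' @return List with `angle_deg` (in [0, 180]), `in_plane_deg`,
#'   `out_of_plane_deg`, `anchor_rmsd`, and the transformed comparison
#'   dipole direction `dipole_cmp_aligned`.
#' @export
dipole_rotation_angle <- function(site_ref, site_cmp, anchors_ref, anchors_cmp,
                                  plane_coords = NULL) {
  if (nrow(anchors_ref) != nrow(anchors_cmp)) {
    stop("anchor atom counts differ between structures")
  }
  fit <- kabsch(anchors_ref, anchors_cmp)
  u <- site_ref$dipole / sqrt(sum(site_ref$dipole^2))
  v0 <- site_cmp$dipole / sqrt(sum(site_cmp$dipole^2))
  v <- as.numeric(v0 %*% fit$R)
  ang <- acos(max(-1, min(1, sum(u * v)))) * 180 / pi
  if (is.null(plane_coords)) plane_coords <- anchors_ref
  nrm <- ls_plane_normal(plane_coords)
  elev <- function(w) asin(max(-1, min(1, sum(w * nrm)))) * 180 / pi
  proj <- function(w) {
    p <- w - sum(w * nrm) * nrm
    p / sqrt(sum(p^2))
  }
  out_pl <- abs(elev(v) - elev(u))
  in_pl <- acos(max(-1, min(1, sum(proj(u) * proj(v))))) * 180 / pi
  list(angle_deg = ang, in_plane_deg = in_pl, out_of_plane_deg = out_pl,
       anchor_rmsd = fit$rmsd, dipole_cmp_aligned = v)
}
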