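#' Run configuration for the structure-to-spectrum pipeline
#'
#' Validates and normalizes the inputs of [run_coupling_report()] and
#' [run_spectrum_compare()]. Label maps must be explicit for both
#' structures: the pipeline never guesses structure-specific residue
#' numbering.
#'
#' @param reference,comparison Paths to the reference and comparison
#'   coordinate files (PDB/mmCIF).
#' @param label_map_ref,label_map_cmp `pigment_label_map` objects (or YAML
#'   paths) for the two structures.
#' @param charge_table Path to the transition-charge CSV, or a
#'   `transition_charges` object.
#' @param labels Pigment labels of the modeled cluster
#'   (default `c("B18", "B19", "B40")`).
#' @param site_energies Named site energies in cm^-1 for `labels`
#'   (default `c(B18 = 14600, B19 = 14950, B40 = 14950)`).
#' @param target_dipole Qy dipole strength each pigment is rescaled to, in
#'   Debye (default 4.3).
#' @param rotation_pigment Label whose dipole rotation is reported
#'   (default `"B40"`).
#' @param anchor_labels Labels whose macrocycle atoms anchor the
#'   cross-structure superposition (default `c("B18", "B19")`).
#' @param disorder A [disorder_model()].
#' @param shape A [line_shape()].
#' @return Object of class `run_config`.
#' @export
run_config <- function(reference, comparison, label_map_ref, label_map_cmp,
                       charge_table,
                       labels = c("B18", "B19", "B40"),
                       site_energies = c(B18 = 14600, B19 = 14950, B40 = 14950),
                       target_dipole = 4.3,
                       rotation_pigment = "B40",
                       anchor_labels = c("B18", "B19"),
                       disorder = disorder_model(),
                       shape = line_shape()) {
  for (p in c(reference, comparison)) {
    if (!file.exists(p)) stop("structure file not found: ", p)
  }
  if (is.character(label_map_ref)) label_map_ref <- read_label_map(label_map_ref)
  if (is.character(label_map_cmp)) label_map_cmp <- read_label_map(label_map_cmp)
  if (is.character(charge_table)) charge_table <- read_charge_table(charge_table)
  for (lm in list(label_map_ref, label_map_cmp)) {
    missing <- setdiff(labels, lm$entries$label)
    if (length(missing)) {
      stop("label map for structure '", lm$structure_id,
           "' does not resolve label(s): ", paste(missing, collapse = ", "))
    }
  }
  stopifnot(setequal(names(site_energies), labels), target_dipole > 0,
            rotation_pigment %in% labels,
            all(anchor_labels %in% labels))
  structure(list(reference = reference, comparison = comparison,
                 label_map_ref = label_map_ref, label_map_cmp = label_map_cmp,
                 charge_table = charge_table, labels = labels,
                 site_energies = site_energies[labels],
                 target_dipole = target_dipole,
                 rotation_pigment = rotation_pigment,
                 anchor_labels = anchor_labels,
                 disorder = disorder, shape = shape),
            class = "run_config")
}

build_sites <- function(model, labelmap, config) {
  lapply(config$labels, function(lab) {
    pig <- extract_pigment(model, labelmap, lab)
    pigment_site(lab, pig$coords, config$charge_table,
                 site_energy = config$site_energies[[lab]],
                 target_dipole = config$target_dipole)
  })
}

anchor_coords <- function(model, labelmap, config) {
  mats <- lapply(config$anchor_labels, function(lab) {
    pig <- extract_pigment(model, labelmap, lab)
    select_subset(pig$coords, "macrocycle")
  })
  nm <- unlist(lapply(seq_along(mats), function(i)
    paste(config$anchor_labels[i], rownames(mats[[i]]))))
  out <- do.call(rbind, mats)
  rownames(out) <- nm
  out
}

#' Dipoles, couplings and dipole-geometry comparison for two structures
#'
#' For each structure: the per-pigment Qy dipoles after rescaling to the
#' target strength and the full TrESP coupling matrix over the configured
#' cluster. Across structures: per-pair coupling differences and the
#' rotation of the configured pigment's dipole after anchoring on the
#' shared macrocycle atoms. Fully deterministic.
#'
#' @param config A [run_config()].
#' @return List with `reference` and `comparison` (each: `sites`, `dipoles`
#'   data frame, `couplings`), `coupling_delta` (comparison - reference),
#'   and `rotation` (see [dipole_rotation_angle()]).
#' @export
run_coupling_report <- function(config) {
  stopifnot(inherits(config, "run_config"))
  mdl_r <- read_structure(config$reference)
  mdl_c <- read_structure(config$comparison)
  sites_r <- build_sites(mdl_r, config$label_map_ref, config)
  sites_c <- build_sites(mdl_c, config$label_map_cmp, config)
  dip_tab <- function(sites) {
    data.frame(label = vapply(sites, `[[`, "", "label"),
               dipole_debye = vapply(sites, `[[`, 0, "dipole_debye"),
               mx = vapply(sites, function(s) s$dipole[1], 0),
               my = vapply(sites, function(s) s$dipole[2], 0),
               mz = vapply(sites, function(s) s$dipole[3], 0))
  }
  V_r <- couplings_from_sites(sites_r)
  V_c <- couplings_from_sites(sites_c)
  rot_i <- match(config$rotation_pigment, config$labels)
  anch_r <- anchor_coords(mdl_r, config$label_map_ref, config)
  anch_c <- anchor_coords(mdl_c, config$label_map_cmp, config)
  common <- intersect(rownames(anch_r), rownames(anch_c))
  plane_lab <- config$anchor_labels[length(config$anchor_labels)]
  plane_sel <- common[startsWith(common, paste0(plane_lab, " "))]
  rotation <- dipole_rotation_angle(
    sites_r[[rot_i]], sites_c[[rot_i]],
    anch_r[common, , drop = FALSE], anch_c[common, , drop = FALSE],
    plane_coords = anch_r[plane_sel, , drop = FALSE])
  list(reference = list(sites = sites_r, dipoles = dip_tab(sites_r),
                        couplings = V_r),
       comparison = list(sites = sites_c, dipoles = dip_tab(sites_c),
                         couplings = V_c),
       coupling_delta = V_c$V - V_r$V,
       rotation = rotation,
       charge_provenance = config$charge_table$provenance)
}

#' Simulated spectra for both structures plus the experimental workup
#'
#' Runs the disorder-averaged absorption simulation for the reference and
#' comparison structures (shared site energies; couplings and dipoles from
#' each structure's geometry) and forms their normalized simulated
#' difference. If experimental spectra are supplied, additionally runs the
#' standard workup: area normalization, difference spectrum, extremum /
#' probe features, and multi-Gaussian deconvolution of the configured
#' region.
#'
#' @param config A [run_config()].
#' @param experimental Optional list with `a` and `b` (paths or `spectrum`
#'   objects, sample vs control), `window` (normalization window, default
#'   `c(550, 775)` nm), `fit_region` (default `c(680, 730)` nm), and
#'   `n_components` (default 3).
#' @return List with `report` (the coupling report), `sim_ref`, `sim_cmp`,
#'   `sim_difference` (all wavenumber-domain `spectrum` objects), plus,
#'   when experimental data are given, `exp_difference`, `exp_features`,
#'   and `exp_fit`.
#' @export
run_spectrum_compare <- function(config, experimental = NULL) {
  rep <- run_coupling_report(config)
  dip <- function(sites) do.call(rbind, lapply(sites, function(s)
    s$dipole * tresp_constants()$debye_per_eA))
  ham <- function(sites, V) build_hamiltonian(config$site_energies, V)
  sim_r <- simulate_absorption(ham(rep$reference$sites, rep$reference$couplings),
                               dip(rep$reference$sites),
                               disorder = config$disorder, shape = config$shape)
  # common random numbers: the same disorder draw for both structures, so
  # the simulated difference reflects couplings/dipoles only (and vanishes
  # identically for identical structures)
  sim_c <- simulate_absorption(ham(rep$comparison$sites, rep$comparison$couplings),
                               dip(rep$comparison$sites),
                               disorder = config$disorder, shape = config$shape)
  out <- list(report = rep, sim_ref = sim_r, sim_cmp = sim_c,
              sim_difference = simulated_difference(sim_c, sim_r))
  if (!is.null(experimental)) {
    getspec <- function(s) if (inherits(s, "spectrum")) s else read_spectrum(s)
    win <- if (is.null(experimental$window)) c(550, 775) else experimental$window
    reg <- if (is.null(experimental$fit_region)) c(680, 730) else experimental$fit_region
    k <- if (is.null(experimental$n_components)) 3L else experimental$n_components
    sa <- normalize_area(getspec(experimental$a), win)
    sb <- normalize_area(getspec(experimental$b), win)
    d <- difference_spectrum(sa, sb)
    out$exp_difference <- d
    out$exp_features <- spectral_features(d, region = reg)
    out$exp_fit <- fit_gaussians(d, region = reg, n_components = k)
  }
  out
}
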