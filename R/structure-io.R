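#' Read a macromolecular structure from PDB or mmCIF
#'
#' Parses a coordinate file (via bio3d) into a flat atom table, keeping
#' hetero residues (cofactors) and resolving alternate locations by the
#' highest-occupancy policy (ties broken by the first alt-loc identifier in
#' file order).
#'
#' @param path Path to a PDB or mmCIF file.
#' @param format One of `"auto"` (default; decided by file extension),
#'   `"pdb"`, or `"cif"`.
#' @param structure_id Identifier stored on the returned model; defaults to
#'   the file name without extension.
#' @return An object of class `structure_model`: a list with `structure_id`
#'   and `atoms`, a data frame with columns `chain`, `resno`, `insert`,
#'   `resname`, `atom`, `element`, `x`, `y`, `z`, `occ`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           structure_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  parsed <- if (format == "cif") {
    bio3d::read.cif(path)
  } else {
    bio3d::read.pdb(path)
  }
  at <- parsed$atom
  if (is.null(at) || nrow(at) == 0L) stop("empty structure: no atoms in ", path)
  atoms <- data.frame(
    chain = as.character(at$chain),
    resno = as.integer(at$resno),
    insert = ifelse(is.na(at$insert) | at$insert == "", "", as.character(at$insert)),
    resname = as.character(at$resid),
    atom = as.character(at$elety),
    element = as.character(at$elesy),
    x = as.numeric(at$x), y = as.numeric(at$y), z = as.numeric(at$z),
    occ = ifelse(is.na(at$o), 1, as.numeric(at$o)),
    alt = ifelse(is.na(at$alt) | at$alt == "", "", as.character(at$alt)),
    stringsAsFactors = FALSE
  )
  atoms$chain[is.na(atoms$chain)] <- ""
  # the literal atom name "NA" (pyrrole nitrogen A, sodium) survives parsing
  # as a missing value in some readers; restore it
  atoms$atom[is.na(atoms$atom)] <- "NA"
  atoms$element[is.na(atoms$element)] <- ""
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("non-finite coordinates in ", path)
  }
  atoms <- resolve_altloc(atoms)
  if (is.null(structure_id)) {
    structure_id <- sub("\\.[A-Za-z.]+$", "", basename(path))
  }
  new_structure_model(structure_id, atoms)
}

new_structure_model <- function(structure_id, atoms) {
  structure(list(structure_id = structure_id, atoms = atoms),
            class = "structure_model")
}

# Highest occupancy wins within (chain, resno, insert, resname, atom);
# ties go to the alt-loc id seen first in file order.
resolve_altloc <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$resname,
               atoms$atom, sep = "\r")
  if (!anyDuplicated(key)) {
    atoms$alt <- NULL
    return(atoms)
  }
  idx <- seq_len(nrow(atoms))
  ord <- order(key, -atoms$occ, idx)
  keep <- ord[!duplicated(key[ord])]
  atoms <- atoms[sort(keep), , drop = FALSE]  # keep original file order
  rownames(atoms) <- NULL
  atoms$alt <- NULL
  atoms
}

#' @export
print.structure_model <- function(x, ...) {
  res <- structure_residues(x)
  cat("<structure_model> ", x$structure_id, "\n", sep = "")
  cat("  ", nrow(x$atoms), " atoms, ", nrow(res), " residues, ",
      length(unique(x$atoms$chain)), " chains\n", sep = "")
  invisible(x)
}

#' Residue table of a structure model
#'
#' @param model A `structure_model`.
#' @return Data frame with one row per residue: `chain`, `resno`, `insert`,
#'   `resname`.
#' @export
structure_residues <- function(model) {
  a <- model$atoms
  key <- paste(a$chain, a$resno, a$insert, sep = "\r")
  first <- !duplicated(key)
  out <- a[first, c("chain", "resno", "insert", "resname")]
  rownames(out) <- NULL
  out
}

# Three-letter codes treated as protein residues for the inventory.
.amino3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
             "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
             "TYR", "VAL", "MSE", "SEC", "PYL")

#' Default residue-name classification for PSI cofactor inventories
#'
#' Maps wwPDB chemical-component ids onto the cofactor classes of a
#' cyanobacterial photosystem I model: chlorophylls (CLA = Chl a, CL0 = the
#' C13 epimer Chl a' of P700), carotenoids (beta-carotene and echinenone),
#' phylloquinone, and the Fe4S4 iron-sulfur clusters. Standard amino acids
#' map to `"protein"`. Extend or replace entries to cover other dictionaries.
#'
#' @return Named character vector: residue name -> class.
#' @export
default_cofactor_classes <- function() {
  cls <- c(
    stats::setNames(rep("protein", length(.amino3)), .amino3),
    CLA = "chlorophyll", CL0 = "chlorophyll",
    BCR = "carotenoid", ECN = "carotenoid", CAN = "carotenoid",
    PQN = "phylloquinone",
    SF4 = "iron-sulfur cluster", FES = "iron-sulfur cluster"
  )
  cls
}

#' Count cofactors and protein content of a structure
#'
#' Every residue of the model is assigned to exactly one class via the
#' classification table; residue names absent from the table are counted as
#' `"other"` and reported (never dropped). Protein subunits are additionally
#' counted as chains containing at least one amino-acid residue.
#'
#' @param model A `structure_model`.
#' @param classification Named character vector residue name -> class; see
#'   [default_cofactor_classes()].
#' @return Object of class `cofactor_inventory`: list with `counts` (named
#'   integer vector over classes incl. `"other"`), `protein_chains`,
#'   `unclassified` (residue names that fell into `"other"`), and
#'   `total_residues`.
#' @export
cofactor_inventory <- function(model, classification = default_cofactor_classes()) {
  res <- structure_residues(model)
  cls <- unname(classification[res$resname])
  unknown <- is.na(cls)
  cls[unknown] <- "other"
  classes <- unique(c(unname(classification), "other"))
  counts <- stats::setNames(integer(length(classes)), classes)
  tab <- table(cls)
  counts[names(tab)] <- as.integer(tab)
  prot_chains <- unique(res$chain[res$resname %in% .amino3])
  unclassified <- sort(unique(res$resname[unknown]))
  if (length(unclassified)) {
    message("cofactor_inventory: residues counted as 'other': ",
            paste(unclassified, collapse = ", "))
  }
  structure(list(counts = counts, protein_chains = length(prot_chains),
                 unclassified = unclassified, total_residues = nrow(res)),
            class = "cofactor_inventory")
}

#' @export
print.cofactor_inventory <- function(x, ...) {
  cat("<cofactor_inventory> ", x$total_residues, " residues, ",
      x$protein_chains, " protein chains\n", sep = "")
  print(x$counts[x$counts > 0 | names(x$counts) %in%
                   c("chlorophyll", "carotenoid", "phylloquinone")])
  invisible(x)
}

#' Write a cofactor inventory as CSV
#'
#' @param inv A `cofactor_inventory`.
#' @param path Output path; columns `class,count`.
#' @export
write_inventory_csv <- function(inv, path) {
  utils::write.csv(data.frame(class = names(inv$counts),
                              count = unname(inv$counts)),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Pigment label maps
#'
#' Canonical pigment labels (the field's "B40"/"A31"-style names) are not
#' stored in deposited coordinate files; a label map records, per structure,
#' which (chain, residue number) each label refers to. Maps are supplied as
#' a data frame or loaded from YAML of the form
#' `structure_id: ...` / `labels: {B40: {chain: B, resno: 1140, resname: CLA}}`.
#'
#' @param entries Data frame with columns `label`, `chain`, `resno`, and
#'   optionally `resname`.
#' @param structure_id Identifier of the structure the map describes.
#' @return Object of class `pigment_label_map`.
#' @export
pigment_label_map <- function(entries, structure_id = "") {
  stopifnot(is.data.frame(entries),
            all(c("label", "chain", "resno") %in% names(entries)))
  if (anyDuplicated(entries$label)) {
    stop("duplicate pigment labels in label map")
  }
  if (is.null(entries$resname)) entries$resname <- NA_character_
  structure(list(structure_id = structure_id,
                 entries = entries[, c("label", "chain", "resno", "resname")]),
            class = "pigment_label_map")
}

#' @rdname pigment_label_map
#' @param path YAML file path.
#' @export
read_label_map <- function(path) {
  y <- yaml::read_yaml(path)
  labs <- y$labels
  entries <- data.frame(
    label = names(labs),
    chain = vapply(labs, function(e) as.character(e$chain), ""),
    resno = vapply(labs, function(e) as.integer(e$resno), 1L),
    resname = vapply(labs, function(e)
      if (is.null(e$resname)) NA_character_ else as.character(e$resname), ""),
    stringsAsFactors = FALSE
  )
  pigment_label_map(entries, structure_id = if (is.null(y$structure_id)) "" else y$structure_id)
}

.chl_resnames <- c("CLA", "CL0")

#' Extract the atoms of a labelled pigment
#'
#' @param model A `structure_model`.
#' @param labelmap A `pigment_label_map` resolving labels in this model.
#' @param label Canonical pigment label, e.g. `"B40"`.
#' @return List with `label`, `chain`, `resno`, `resname`, and `coords`, a
#'   numeric matrix (rows named by atom name) of the residue's heavy atoms.
#' @export
extract_pigment <- function(model, labelmap, label) {
  e <- labelmap$entries
  i <- match(label, e$label)
  if (is.na(i)) {
    stop("unknown pigment label '", label, "'; known labels: ",
         paste(e$label, collapse = ", "))
  }
  a <- model$atoms
  sel <- a$chain == e$chain[i] & a$resno == e$resno[i]
  if (!any(sel)) {
    stop("label '", label, "' maps to chain ", e$chain[i], " residue ",
         e$resno[i], " which is absent from structure ", model$structure_id)
  }
  resname <- a$resname[sel][1]
  if (!is.na(e$resname[i]) && !identical(resname, e$resname[i])) {
    stop("label '", label, "' expected residue ", e$resname[i],
         " but found ", resname)
  }
  sel <- sel & toupper(a$element) != "H"
  coords <- as.matrix(a[sel, c("x", "y", "z")])
  rownames(coords) <- a$atom[sel]
  list(label = label, chain = e$chain[i], resno = e$resno[i],
       resname = resname, coords = coords)
}

# Named atom subsets used for ring-to-ring distance queries.
.atom_subsets <- list(
  indole = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  macrocycle = c("MG", "NA", "NB", "NC", "ND",
                 "C1A", "C2A", "C3A", "C4A", "C1B", "C2B", "C3B", "C4B",
                 "C1C", "C2C", "C3C", "C4C", "C1D", "C2D", "C3D", "C4D",
                 "CHA", "CHB", "CHC", "CHD"),
  all = NULL
)

select_subset <- function(coords, subset) {
  if (identical(subset, "all") || is.null(subset)) return(coords)
  wanted <- .atom_subsets[[subset]]
  if (is.null(wanted)) {
    if (!is.character(subset)) stop("unknown atom subset")
    wanted <- subset  # explicit atom-name vector
  }
  sel <- rownames(coords) %in% wanted
  if (!any(sel)) {
    stop("atom subset selected no atoms; wanted: ",
         paste(utils::head(wanted, 12), collapse = ", "))
  }
  coords[sel, , drop = FALSE]
}

#' Minimum heavy-atom distance between two residue ring systems
#'
#' Distance is the minimum Euclidean distance over all pairs of selected
#' heavy atoms; it is symmetric in its arguments. Subsets: `"indole"` (the
#' nine tryptophan indole ring atoms), `"macrocycle"` (the chlorin ring
#' heavy atoms incl. Mg), `"all"`, or an explicit atom-name vector.
#'
#' @param model A `structure_model`.
#' @param residue_a,residue_b Lists `list(chain=, resno=, subset=)`; `subset`
#'   defaults to `"all"`. Either may instead be the result of
#'   [extract_pigment()] with an added `subset` element.
#' @return Distance in Angstrom.
#' @export
min_ring_distance <- function(model, residue_a, residue_b) {
  get_coords <- function(r) {
    if (!is.null(r$coords)) {
      coords <- r$coords
    } else {
      a <- model$atoms
      sel <- a$chain == r$chain & a$resno == r$resno & toupper(a$element) != "H"
      if (!any(sel)) stop("residue not found: chain ", r$chain, " resno ", r$resno)
      coords <- as.matrix(a[sel, c("x", "y", "z")])
      rownames(coords) <- a$atom[sel]
    }
    select_subset(coords, if (is.null(r$subset)) "all" else r$subset)
  }
  ca <- get_coords(residue_a)
  cb <- get_coords(residue_b)
  d2 <- outer(rowSums(ca^2), rowSums(cb^2), "+") - 2 * ca %*% t(cb)
  sqrt(max(0, min(d2)))
}

#' Write a structure model to a PDB file
#'
#' Minimal fixed-width ATOM/HETATM writer used for fixtures and round-trip
#' checks; hetero residues (anything not a standard amino acid) are written
#' as HETATM records.
#'
#' @param model A `structure_model`.
#' @param path Output file path.
#' @export
write_structure_pdb <- function(model, path) {
  a <- model$atoms
  rec <- ifelse(a$resname %in% .amino3, "ATOM  ", "HETATM")
  name <- vapply(a$atom, function(nm) {
    if (nchar(nm) >= 4) substr(nm, 1, 4) else sprintf(" %-3s", nm)
  }, "")
  lines <- sprintf("%s%5d %s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rec, seq_len(nrow(a)), name, a$resname,
                   substr(paste0(a$chain, " "), 1, 1), a$resno,
                   substr(paste0(a$insert, " "), 1, 1),
                   a$x, a$y, a$z, a$occ, 0, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
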