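test_that("a minimal hand-written PDB parses into one residue of three atoms", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "END"), path)
  m <- read_structure(path)
  expect_s3_class(m, "structure_model")
  expect_equal(nrow(m$atoms), 3L)
  expect_equal(nrow(structure_residues(m)), 1L)
  expect_equal(m$atoms$atom, c("N", "CA", "C"))
  expect_equal(m$atoms$x[2], 1.458)
})

test_that("alt-loc resolution keeps the highest occupancy, first id on ties", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      2  CA BALA A   1       2.000   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CB AALA A   1       3.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CB BALA A   1       4.000   0.000   0.000  0.50  0.00           C",
    "END"), path)
  m <- read_structure(path)
  expect_equal(nrow(m$atoms), 2L)
  expect_equal(m$atoms$x[m$atoms$atom == "CA"], 1.0)  # occ 0.6 wins
  expect_equal(m$atoms$x[m$atoms$atom == "CB"], 3.0)  # tie: first id wins
  # atom names unique within the residue after resolution
  expect_false(anyDuplicated(m$atoms$atom) > 0)
})

test_that("write -> read round trip preserves counts, names and coordinates", {
  path <- withr::local_tempfile(fileext = ".pdb")
  placed <- list(make_chlorin(rotation_deg = 33, translation = c(5, -2, 7)),
                 make_chlorin(translation = c(-4, 9, 0)))
  m0 <- write_pigments_pdb(placed, path)
  m1 <- read_structure(path)
  expect_equal(nrow(m1$atoms), nrow(m0$atoms))
  expect_equal(m1$atoms$atom, m0$atoms$atom)
  expect_lt(max(abs(as.matrix(m1$atoms[, c("x", "y", "z")]) -
                    as.matrix(m0$atoms[, c("x", "y", "z")]))), 1e-3)
})

test_that("reading a structure with no atoms fails loudly", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", path)
  expect_error(read_structure(path))
})

test_that("cofactor inventory counts synthetic chlorophylls and flags unknowns", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pigments_pdb(lapply(1:5, function(i)
    make_chlorin(translation = c(20 * i, 0, 0))), path)
  m <- read_structure(path)
  inv <- cofactor_inventory(m)
  expect_equal(unname(inv$counts[["chlorophyll"]]), 5L)
  expect_equal(unname(inv$counts[["phylloquinone"]]), 0L)
  expect_equal(sum(inv$counts), inv$total_residues)

  # unknown residue names fall into "other" and are reported, not dropped
  m$atoms$resname[m$atoms$resno == 5] <- "XYZ"
  expect_message(inv2 <- cofactor_inventory(m), "XYZ")
  expect_equal(unname(inv2$counts[["chlorophyll"]]), 4L)
  expect_equal(unname(inv2$counts[["other"]]), 1L)
  expect_equal(sum(inv2$counts), inv2$total_residues)
})

test_that("inventory is invariant under atom/chain reordering", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pigments_pdb(lapply(1:3, function(i)
    make_chlorin(translation = c(20 * i, 0, 0))), path)
  m <- read_structure(path)
  m_rev <- m
  m_rev$atoms <- m$atoms[rev(seq_len(nrow(m$atoms))), ]
  expect_equal(cofactor_inventory(m_rev)$counts, cofactor_inventory(m)$counts)
})

test_that("extract_pigment round-trips placed atoms and rejects unknown labels", {
  path <- withr::local_tempfile(fileext = ".pdb")
  placed <- make_chlorin(rotation_deg = 12, translation = c(3, 4, 5))
  write_pigments_pdb(list(placed), path)
  m <- read_structure(path)
  lm <- pigment_label_map(data.frame(label = "S1", chain = "X", resno = 1))
  pig <- extract_pigment(m, lm, "S1")
  expect_setequal(rownames(pig$coords), rownames(placed$coords))
  expect_lt(max(abs(pig$coords[rownames(placed$coords), ] - placed$coords)),
            1e-3)
  expect_error(extract_pigment(m, lm, "Z99"), "S1")
  lm_bad <- pigment_label_map(data.frame(label = "S9", chain = "X", resno = 99))
  expect_error(extract_pigment(m, lm_bad, "S9"), "absent")
})

test_that("label maps reject duplicate labels and load from YAML", {
  expect_error(pigment_label_map(
    data.frame(label = c("B1", "B1"), chain = "A", resno = 1:2)), "duplicate")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("structure_id: demo", "labels:",
               "  B40: {chain: B, resno: 1140, resname: CLA}",
               "  B19: {chain: B, resno: 1119}"), path)
  lm <- read_label_map(path)
  expect_equal(sort(lm$entries$label), c("B19", "B40"))
  expect_equal(lm$entries$resno[lm$entries$label == "B40"], 1140L)
})

test_that("min_ring_distance is symmetric and matches a brute-force minimum", {
  path <- withr::local_tempfile(fileext = ".pdb")
  p1 <- make_chlorin()
  p2 <- make_chlorin(rotation_deg = 30, translation = c(7.5, 0, 0))
  write_pigments_pdb(list(p1, p2), path)
  m <- read_structure(path)
  ra <- list(chain = "X", resno = 1, subset = "macrocycle")
  rb <- list(chain = "X", resno = 2, subset = "macrocycle")
  d_ab <- min_ring_distance(m, ra, rb)
  d_ba <- min_ring_distance(m, rb, ra)
  expect_identical(d_ab, d_ba)

  # brute force over all pairs of the same (file-round-tripped) coordinates
  lm <- pigment_label_map(data.frame(label = c("A", "B"), chain = "X",
                                     resno = 1:2))
  ca <- extract_pigment(m, lm, "A")$coords
  cb <- extract_pigment(m, lm, "B")$coords
  bf <- min(sqrt(outer(rowSums(ca^2), rowSums(cb^2), "+") - 2 * ca %*% t(cb)))
  expect_equal(d_ab, bf, tolerance = 1e-9)
})

test_that("min_ring_distance handles shared positions and bad subsets", {
  path <- withr::local_tempfile(fileext = ".pdb")
  p1 <- make_chlorin()
  p2 <- make_chlorin()  # identical position: distance 0
  write_pigments_pdb(list(p1, p2), path)
  m <- read_structure(path)
  expect_equal(min_ring_distance(m,
                                 list(chain = "X", resno = 1, subset = "macrocycle"),
                                 list(chain = "X", resno = 2, subset = "macrocycle")),
               0)
  # chlorins have no indole atoms: selection must fail, naming the subset
  expect_error(min_ring_distance(m,
                                 list(chain = "X", resno = 1, subset = "indole"),
                                 list(chain = "X", resno = 2, subset = "macrocycle")),
               "subset")
})
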