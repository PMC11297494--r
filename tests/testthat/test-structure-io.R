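pdb_lines <- function(...) {
  c(..., "END")
}
ca_line <- function(serial, resname, chain, resno, x, y, z, alt = " ",
                    type = "ATOM  ") {
  sprintf("%s%5d  CA %s%s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          type, serial, alt, resname, chain, resno, x, y, z)
}

test_that("a hand-written three-residue PDB reads as three unit-weight points", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb_lines(
    ca_line(1, "ALA", "A", 1, 0, 0, 0),
    ca_line(2, "GLY", "A", 2, 3.8, 0, 0),
    ca_line(3, "LYS", "A", 3, 7.6, 1, 0)), path)
  cl <- read_point_cloud(path)
  expect_equal(nrow(cl$coords), 3L)
  expect_equal(cl$weights, c(1, 1, 1))
  expect_equal(cl$coords[, 1], c(0, 3.8, 7.6))
  # reading twice is deterministic
  cl2 <- read_point_cloud(path)
  expect_identical(cl$coords, cl2$coords)
  expect_identical(cl$weights, cl2$weights)
})

test_that("residue-mass weighting uses the standard masses with a mean fallback", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb_lines(
    ca_line(1, "GLY", "A", 1, 0, 0, 0),
    ca_line(2, "TRP", "A", 2, 3.8, 0, 0),
    ca_line(3, "XYZ", "A", 3, 7.6, 0, 0)), path)
  cl <- read_point_cloud(path, weight_mode = "residue_mass")
  expect_equal(cl$weights[1], 57.0519, tolerance = 1e-6)
  expect_equal(cl$weights[2], 186.2132, tolerance = 1e-6)
  expect_equal(cl$weights[3], mean(zernike3d:::RESIDUE_MASS), tolerance = 1e-6)
})

test_that("alternate locations beyond 'A' and HETATM records are excluded", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb_lines(
    ca_line(1, "ALA", "A", 1, 0, 0, 0, alt = "A"),
    ca_line(2, "ALA", "A", 1, 0.5, 0, 0, alt = "B"),
    ca_line(3, "GLY", "A", 2, 3.8, 0, 0),
    ca_line(4, "HOH", "A", 90, 9, 9, 9, type = "HETATM"),
    ca_line(5, " CA", "A", 91, 8, 8, 8, type = "HETATM")), path)
  cl <- read_point_cloud(path)
  expect_equal(nrow(cl$coords), 2L)
  expect_equal(cl$coords[, 1], c(0, 3.8))
})

test_that("chain filtering selects the chain or fails as an empty selection", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb_lines(
    ca_line(1, "ALA", "A", 1, 0, 0, 0),
    ca_line(2, "GLY", "B", 1, 5, 0, 0)), path)
  expect_equal(nrow(read_point_cloud(path, chain_filter = "B")$coords), 1L)
  expect_error(read_point_cloud(path, chain_filter = "Z"),
               class = "zernike3d_validation_error")
})

test_that("unreadable or contentless files raise I/O errors naming the path", {
  err <- tryCatch(read_point_cloud("/no/such/file.pdb"), error = identity)
  expect_s3_class(err, "zernike3d_io_error")
  expect_match(conditionMessage(err), "file.pdb")
  junk <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("this is", "not a structure"), junk)
  expect_error(read_point_cloud(junk), class = "zernike3d_error")
})

test_that("mmCIF input gives the same cloud as equivalent PDB input", {
  cif <- withr::local_tempfile(fileext = ".cif")
  writeLines(c(
    "data_test", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 C CA . ALA A 1 1 ? 0.000 0.000 0.000 1.00 0.00 ? 1 ALA A CA 1",
    "ATOM 2 C CA . GLY A 1 2 ? 3.800 0.000 0.000 1.00 0.00 ? 2 GLY A CA 1",
    "ATOM 3 C CA . LYS A 1 3 ? 7.600 1.000 0.000 1.00 0.00 ? 3 LYS A CA 1"),
    cif)
  cl <- suppressWarnings(read_point_cloud(cif))
  expect_equal(nrow(cl$coords), 3L)
  expect_equal(cl$coords[, 1], c(0, 3.8, 7.6))
})

test_that("fixture clouds survive a PDB write/read round trip", {
  cl <- make_asymmetric_cloud(15, seed = 2)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_point_cloud_pdb(cl, path)
  back <- read_point_cloud(path)
  expect_equal(nrow(back$coords), 15L)
  expect_lt(max(abs(back$coords - cl$coords)), 1e-3)  # 3-decimal PDB fields
})

test_that("transform documents round-trip bit-exactly", {
  tr <- diag(4)
  tr[1:3, 1:3] <- random_rotation(5)
  tr[1:3, 4] <- c(pi, -sqrt(2), 1 / 3)
  res <- structure(list(transform = tr, score = exp(1),
                        best_pair = c(moving = 2L, fixed = 3L),
                        moving = "a.pdb", fixed = "b.pdb"),
                   class = "superposition_result")
  path <- withr::local_tempfile(fileext = ".json")
  write_transform(res, path)
  back <- read_transform(path)
  expect_identical(back$transform, tr)
  expect_identical(back$score, res$score)
  expect_equal(back$best_pair, unname(res$best_pair))

  # identity transform writes the identity matrix block
  res$transform <- diag(4)
  write_transform(res, path)
  expect_identical(read_transform(path)$transform, diag(4))
})

test_that("invalid transforms and unwritable paths are refused", {
  bad <- structure(list(transform = matrix(NaN, 4, 4), score = 0,
                        best_pair = c(1L, 1L), moving = "", fixed = ""),
                   class = "superposition_result")
  expect_error(write_transform(bad, tempfile()),
               class = "zernike3d_validation_error")
  ok <- structure(list(transform = diag(4), score = 0,
                       best_pair = c(1L, 1L), moving = "", fixed = ""),
                  class = "superposition_result")
  expect_error(write_transform(ok, "/no/such/dir/x.json"),
               class = "zernike3d_io_error")
  expect_error(read_transform("/no/such/file.json"),
               class = "zernike3d_io_error")
})
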