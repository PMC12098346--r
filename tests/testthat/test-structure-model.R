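test_that("a minimal single-atom PDB record parses to one chain/residue/atom", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1      11.104   6.134  -6.504  1.00  0.00           C",
    "END"), f)
  m <- read_structure(f)
  expect_s3_class(m, "struct_model")
  expect_equal(nrow(m$atoms), 1L)
  expect_equal(m$atoms$chain, "A")
  expect_equal(m$atoms$resno, 1L)
  expect_equal(m$atoms$elety, "CA")
  expect_equal(m$atoms$x, 11.104)
})

test_that("unreadable and empty inputs raise explicit errors", {
  expect_error(read_structure(tempfile()), "not found")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", f)
  expect_error(read_structure(f), "no atoms|parse")
  expect_error(structure_model(data.frame(chain = character(),
                                          resno = integer(),
                                          icode = character(),
                                          resid = character(),
                                          elety = character(),
                                          element = character(),
                                          x = numeric(), y = numeric(),
                                          z = numeric())),
               "no atoms")
})

test_that("write/read round-trip preserves residue keys exactly and coordinates to 1e-3 A", {
  man <- make_complex(seed = 11, n_res_a = 8, n_res_b = 6, n_contacts = 4)
  m1 <- man$model
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m1, f)
  m2 <- read_structure(f)
  k1 <- format_residue_key(m1$atoms$chain, m1$atoms$resno, m1$atoms$icode)
  k2 <- format_residue_key(m2$atoms$chain, m2$atoms$resno, m2$atoms$icode)
  expect_identical(k1, k2)
  expect_identical(m1$atoms$elety, m2$atoms$elety)
  expect_lt(max(abs(as.matrix(m1$atoms[, c("x", "y", "z")]) -
                      as.matrix(m2$atoms[, c("x", "y", "z")]))), 1e-3)
  # second pass is coordinate-stable: the values are already at format
  # precision
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m2, f2)
  m3 <- read_structure(f2)
  expect_identical(m2$atoms[, c("x", "y", "z")],
                   m3$atoms[, c("x", "y", "z")])
})

test_that("altloc conformers resolve to highest occupancy, ties to smallest letter", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       5.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CB AALA A   1       1.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CB BALA A   1       9.000   0.000   0.000  0.50  0.00           C",
    "ATOM      5  N   GLY A   2       2.000   2.000   0.000  1.00  0.00           N",
    "END"), f)
  m <- read_structure(f)
  # residue count unchanged by altloc resolution, only the atom set
  expect_equal(length(unique(format_residue_key(m$atoms$chain,
                                                m$atoms$resno,
                                                m$atoms$icode))), 2L)
  ca <- m$atoms[m$atoms$elety == "CA", ]
  expect_equal(ca$x, 5.0)    # higher occupancy wins
  cb <- m$atoms[m$atoms$elety == "CB", ]
  expect_equal(cb$x, 1.0)    # occupancy tie -> altloc 'A'
})

test_that("mmCIF input is read with author numbering", {
  f <- withr::local_tempfile(fileext = ".cif")
  writeLines(c(
    "data_fixture",
    "loop_",
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
    "ATOM 1 N N . LEU A 1 1 ? 1.0 2.0 3.0 1.00 0.00 ? 95 LEU B N 1",
    "ATOM 2 C CA . LEU A 1 1 ? 2.4 2.0 3.0 1.00 0.00 ? 95 LEU B CA 1"),
    f)
  m <- read_structure(f)
  expect_equal(m$source_format, "mmcif")
  expect_equal(unique(m$atoms$chain), "B")     # auth asym id
  expect_equal(unique(m$atoms$resno), 95L)     # auth seq id
  expect_equal(unique(m$atoms$resid), "LEU")
})

test_that("selection restricts chains, drops waters, and is idempotent", {
  man <- make_complex(seed = 4, n_res_a = 6, n_res_b = 5, n_contacts = 3)
  m <- man$model
  wat <- data.frame(chain = "A", resno = 999L, icode = "", resid = "HOH",
                    elety = "O", element = "O", x = 50, y = 50, z = 50,
                    het = TRUE)
  m2 <- structure_model(rbind(m$atoms[, names(wat)], wat), id = "withwater")

  all_sel <- select_structure(m, chain_ids = c("A", "B"))
  expect_identical(all_sel$atoms[, c("chain", "resno", "elety")],
                   m$atoms[, c("chain", "resno", "elety")])

  a_only <- select_structure(m, chain_ids = "A")
  expect_setequal(unique(a_only$atoms$chain), "A")
  expect_equal(nrow(a_only$atoms), sum(m$atoms$chain == "A"))

  nowat <- select_structure(m2, include_waters = FALSE)
  expect_false(any(nowat$atoms$water))

  twice <- select_structure(select_structure(m, chain_ids = "A"),
                            chain_ids = "A")
  expect_identical(twice$atoms, a_only$atoms)

  expect_error(select_structure(m, chain_ids = "Z"), "available")
})

test_that("write_structure rejects residue numbers outside PDB columns", {
  a <- hand_ala("A", 1, c(0, 0, 0))
  a$resno <- 123456L
  m <- structure_model(a)
  expect_error(write_structure(m, tempfile(fileext = ".pdb")),
               "fixed-column range")
})
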