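test_that("side-chain templates exist for all 20 residues with sane geometry", {
  aas <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
           "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
           "TYR", "VAL")
  N <- c(-0.525, 1.362, 0); CA <- c(0, 0, 0); C <- c(1.525, 0, 0)
  for (aa in aas) {
    t <- sidechain_template(aa, N, CA, C)
    expect_true(all(is.finite(as.matrix(t[, c("x", "y", "z")]))),
                info = aa)
    if (aa == "GLY") {
      expect_equal(nrow(t), 0L)
    } else {
      cb <- as.numeric(t[t$elety == "CB", c("x", "y", "z")])
      expect_equal(sqrt(sum((cb - CA)^2)), 1.53, tolerance = 0.01,
                   info = aa)
    }
  }
  # proline ring approximately closes: CD within bonding distance of N
  pro <- sidechain_template("PRO", N, CA, C)
  cd <- as.numeric(pro[pro$elety == "CD", c("x", "y", "z")])
  expect_lt(sqrt(sum((cd - N)^2)), 2.0)
  expect_error(sidechain_template("XXX"), "no side-chain template")
})

test_that("identity substitution leaves backbone coordinates bit-exact", {
  man <- make_complex(seed = 41, n_contacts = 3)
  focal <- parse_residue_key(man$truth$focal)
  mut <- substitute_residue(man$model,
                            mutation_spec("A", focal$resno, "LEU",
                                          from_aa = "LEU"))
  bb <- c("N", "CA", "C", "O", "CB")
  w <- man$model$atoms
  m <- mut$atoms
  for (at in bb) {
    wi <- w[w$resno == focal$resno & w$chain == "A" & w$elety == at, ]
    mi <- m[m$resno == focal$resno & m$chain == "A" & m$elety == at, ]
    expect_identical(as.numeric(wi[, c("x", "y", "z")]),
                     as.numeric(mi[, c("x", "y", "z")]), info = at)
  }
})

test_that("Leu-to-Pro substitution renames, applies the template atom set, and touches nothing else", {
  man <- make_complex(seed = 43, n_contacts = 4)
  focal <- parse_residue_key(man$truth$focal)
  wt <- man$model
  mut <- substitute_residue(wt, mutation_spec("A", focal$resno, "PRO",
                                              from_aa = "LEU"))
  mres <- mut$atoms[mut$atoms$chain == "A" &
                      mut$atoms$resno == focal$resno, ]
  expect_true(all(mres$resid == "PRO"))
  expect_setequal(mres$elety, c("N", "CA", "C", "O", "CB", "CG", "CD"))
  # backbone (and shared CB) bit-exact
  for (at in c("N", "CA", "C", "O", "CB")) {
    expect_identical(
      as.numeric(wt$atoms[wt$atoms$chain == "A" &
                            wt$atoms$resno == focal$resno &
                            wt$atoms$elety == at, c("x", "y", "z")]),
      as.numeric(mres[mres$elety == at, c("x", "y", "z")]), info = at)
  }
  # all other residues bit-identical
  other_wt <- wt$atoms[!(wt$atoms$chain == "A" &
                           wt$atoms$resno == focal$resno), ]
  other_mut <- mut$atoms[!(mut$atoms$chain == "A" &
                             mut$atoms$resno == focal$resno), ]
  rownames(other_wt) <- rownames(other_mut) <- NULL
  expect_identical(other_wt, other_mut)
  # atom-count bookkeeping: n_mut = n_wt - |old side chain| + |new one|
  n_old_side <- sum(wt$atoms$chain == "A" &
                      wt$atoms$resno == focal$resno &
                      !wt$atoms$elety %in% c("N", "CA", "C", "O"))
  n_new_side <- sum(!mres$elety %in% c("N", "CA", "C", "O"))
  expect_equal(nrow(mut$atoms),
               nrow(wt$atoms) - n_old_side + n_new_side)
  # mutant file round-trips
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(mut, f)
  back <- read_structure(f)
  expect_equal(nrow(back$atoms), nrow(mut$atoms))
})

test_that("Leu-to-Gly strips the side chain entirely", {
  man <- make_complex(seed = 44, n_contacts = 2)
  focal <- parse_residue_key(man$truth$focal)
  mut <- substitute_residue(man$model,
                            mutation_spec("A", focal$resno, "GLY"))
  mres <- mut$atoms[mut$atoms$chain == "A" &
                      mut$atoms$resno == focal$resno, ]
  expect_setequal(mres$elety, c("N", "CA", "C", "O"))
  expect_true(all(mres$resid == "GLY"))
})

test_that("substitution guards fire: wrong from_aa, absent residue, missing backbone", {
  man <- make_complex(seed = 45, n_contacts = 2)
  focal <- parse_residue_key(man$truth$focal)
  expect_error(substitute_residue(man$model,
                                  mutation_spec("A", focal$resno, "PRO",
                                                from_aa = "TRP")),
               "found LEU")
  expect_error(substitute_residue(man$model,
                                  mutation_spec("A", 999, "PRO")),
               "not found")
  expect_error(mutation_spec("A", 1, "ZZZ"), "not a standard residue")
  broken <- man$model
  broken$atoms <- broken$atoms[!(broken$atoms$chain == "A" &
                                   broken$atoms$resno == focal$resno &
                                   broken$atoms$elety == "CA"), ]
  expect_error(substitute_residue(broken,
                                  mutation_spec("A", focal$resno, "PRO")),
               "backbone")
})

test_that("clash report finds exactly the planted overlap and respects the threshold", {
  atoms <- rbind(
    hand_ala("A", 1, c(0, 0, 0)),
    hand_ala("A", 2, c(20, 0, 0)),
    hand_ala("B", 1, c(0, 0, 30)))
  # plant a 2.0 A overlap: B:1 gets an atom 2.0 A from A:1 CB
  extra <- hand_residue("B", 2, "ALA", list(CB = c(-0.6, -1.2, 2.8)))
  m <- structure_model(rbind(atoms, extra))
  rep0 <- clash_report(m, "A:2")
  expect_equal(nrow(rep0), 0L)
  rep1 <- clash_report(m, "A:1")
  expect_equal(nrow(rep1), 1L)
  expect_equal(rep1$key_other, "B:2")
  expect_equal(rep1$atom_focus, "CB")
  expect_equal(rep1$distance, 2.0)
  expect_equal(nrow(clash_report(m, "A:1", threshold = 0)), 0L)
})
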