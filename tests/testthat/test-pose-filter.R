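test_that("self-superposition has zero RMSD and a recoverable random transform realigns to 1e-6 A", {
  man <- make_pose_ensemble(seed = 61, n_poses = 1)
  ref <- read_structure(man$paths$reference)
  s0 <- superpose(ref, ref)
  expect_lt(s0$rmsd, 1e-9)
  expect_equal(s0$rotation, diag(3), tolerance = 1e-9)

  moved <- rigid_move(ref, angle = 1.2, axis = c(2, -1, 3),
                      shift = c(12, -7, 4))
  s1 <- superpose(moved, ref)
  expect_lt(s1$rmsd, 1e-6)
  expect_lt(max(abs(as.matrix(s1$model$atoms[, c("x", "y", "z")]) -
                      as.matrix(ref$atoms[, c("x", "y", "z")]))), 1e-6)
  # cross-check the fitted coordinates against an independent
  # least-squares fit
  sel <- bio3d::atom.select(bio3d::read.pdb(man$paths$reference),
                            elety = "CA")
  ref_b <- bio3d::read.pdb(man$paths$reference)
  xyz_fit <- bio3d::fit.xyz(ref_b$xyz,
                            as.numeric(t(as.matrix(
                              moved$atoms[, c("x", "y", "z")]))),
                            fixed.inds = sel$xyz, mobile.inds = sel$xyz)
  expect_equal(as.numeric(t(as.matrix(
    s1$model$atoms[, c("x", "y", "z")]))),
    as.numeric(xyz_fit), tolerance = 1e-4)
})

test_that("superposition preconditions: too few or collinear points fail", {
  man <- make_pose_ensemble(seed = 62, n_poses = 1)
  ref <- read_structure(man$paths$reference)
  expect_error(superpose(ref, ref, keys = c("R:1", "R:2")), "at least 3")
  expect_error(superpose(ref, ref, keys = c("R:1", "R:2", "R:99")),
               "missing")
  # collinear C-alpha set
  atoms <- do.call(rbind, lapply(1:4, function(i)
    hand_ala("R", i, c(3 * i, 0, 0))))
  lin <- structure_model(atoms)
  expect_error(superpose(lin, lin), "collinear")
})

test_that("gamma C-terminus is the C-alpha of the last residue by (resno, icode)", {
  atoms <- rbind(hand_ala("G", 1, c(0, 0, 0)),
                 hand_ala("G", 2, c(6, 0, 0)),
                 hand_ala("G", 3, c(12, 0, 0)))
  ct <- gamma_cterm(structure_model(atoms), "G")
  expect_equal(ct$resno, 3L)
  expect_equal(ct$elety, "CA")
  # insertion-code-bearing terminal residue sorts after its parent number
  atoms2 <- rbind(atoms, hand_ala("G", 3, c(18, 0, 0), icode = "A"))
  ct2 <- gamma_cterm(structure_model(atoms2), "G")
  expect_equal(ct2$icode, "A")
  expect_error(gamma_cterm(structure_model(atoms), "Q"), "not found")
})

test_that("pose rules follow the stated strict inequalities at their boundaries", {
  frame <- membrane_frame(15, -15)
  crit <- filter_criteria("G", c("B", "G"), "R")
  base <- function(cterm_z, extra = NULL) {
    atoms <- rbind(hand_ala("B", 1, c(0, 0, -40)),
                   hand_ala("G", 1, c(10, 0, -40)),
                   hand_residue("G", 2, "ALA",
                                list(N = c(20, 0, -40),
                                     CA = c(21, 0, cterm_z),
                                     C = c(22, 0, -40))))
    if (!is.null(extra)) atoms <- rbind(atoms, extra)
    structure_model(atoms)
  }
  # both rules satisfied
  v <- filter_pose(base(-25), frame, crit)
  expect_true(v$retained)
  expect_equal(v$reason, "none")
  # one atom 0.1 A above the lower leaflet -> excluded
  v2 <- filter_pose(base(-25, hand_residue("B", 2, "ALA",
                                           list(CB = c(0, 0, -14.9)))),
                    frame, crit)
  expect_false(v2$retained)
  expect_equal(v2$reason, "atom_above_lower_leaflet")
  expect_equal(v2$worst_z, -14.9)
  # C-terminal CA exactly 30.0 A below the leaflet -> retained (strict
  # "more than")
  v3 <- filter_pose(base(-45), frame, crit)
  expect_true(v3$retained)
  expect_equal(v3$gamma_cterm_distance, 30)
  # 30.1 A -> excluded
  v4 <- filter_pose(base(-45.1), frame, crit)
  expect_false(v4$retained)
  expect_equal(v4$reason, "gamma_cterm_too_far")
  expect_error(filter_pose(structure_model(hand_ala("R", 1, c(0, 0, 0))),
                           frame, crit), "absent")
})

test_that("triage recovers the planted verdicts, conserves counts, and keeps input order", {
  for (seed in c(71, 72)) {
    man <- make_pose_ensemble(seed = seed, n_poses = 20,
                              frac_above_leaflet = 0.3,
                              frac_cterm_far = 0.2)
    ref <- read_structure(man$paths$reference)
    poses <- read_pose_table(man$paths$pose_table)
    tri <- triage_ensemble(poses, man$frame, ref, man$criteria)
    expect_equal(nrow(tri$verdicts), nrow(poses))
    expect_identical(tri$verdicts$model_id, poses$model_id)
    expect_identical(tri$retained$model_id,
                     poses$model_id[poses$model_id %in%
                                      man$truth$retained_ids])
    lab <- man$truth$labels
    expect_equal(
      tri$verdicts$reason[match(lab$model_id, tri$verdicts$model_id)],
      unname(c(pass = "none", above_leaflet = "atom_above_lower_leaflet",
               cterm_far = "gamma_cterm_too_far")[lab$label]))
  }
})

test_that("an unreadable pose is recorded as an error verdict and the run continues", {
  man <- make_pose_ensemble(seed = 73, n_poses = 5,
                            frac_above_leaflet = 0, frac_cterm_far = 0)
  poses <- read_pose_table(man$paths$pose_table)
  poses$path[2] <- file.path(dirname(poses$path[2]), "missing.pdb")
  ref <- read_structure(man$paths$reference)
  tri <- triage_ensemble(poses, man$frame, ref, man$criteria)
  expect_equal(nrow(tri$verdicts), 5L)
  expect_match(tri$verdicts$reason[2], "^error")
  expect_equal(sum(tri$verdicts$retained), 4L)
})

test_that("raising the C-terminus bound retains a superset", {
  man <- make_pose_ensemble(seed = 74, n_poses = 12,
                            frac_above_leaflet = 0.25,
                            frac_cterm_far = 0.5)
  ref <- read_structure(man$paths$reference)
  poses <- read_pose_table(man$paths$pose_table)
  tight <- triage_ensemble(poses, man$frame, ref, man$criteria)
  loose_crit <- filter_criteria("G", c("B", "G"), "R",
                                max_gamma_cterm_distance = 60)
  loose <- triage_ensemble(poses, man$frame, ref, loose_crit)
  expect_true(all(tight$retained$model_id %in% loose$retained$model_id))
  expect_gte(nrow(loose$retained), nrow(tight$retained))
})

test_that("verdicts are invariant under a rigid transform of the pose", {
  man <- make_pose_ensemble(seed = 75, n_poses = 6)
  ref <- read_structure(man$paths$reference)
  poses <- read_pose_table(man$paths$pose_table)
  crit <- man$criteria
  for (k in c(1L, 4L)) {
    pose <- read_structure(poses$path[k])
    v1 <- filter_pose(superpose(pose, ref)$model, man$frame, crit)
    moved <- rigid_move(pose, angle = 2.1, axis = c(-1, 4, 2),
                        shift = c(33, -21, 8))
    v2 <- filter_pose(superpose(moved, ref)$model, man$frame, crit)
    expect_equal(v1$retained, v2$retained)
    expect_equal(v1$reason, v2$reason)
    expect_equal(v1$worst_z, v2$worst_z, tolerance = 1e-6)
    expect_equal(v1$gamma_cterm_distance, v2$gamma_cterm_distance,
                 tolerance = 1e-6)
  }
})

test_that("model selection matches the exhaustive-scan oracle and its documented tie rules", {
  # definition case: largest cluster A, best score B
  tb <- data.frame(model_id = c("a", "b"), cluster_id = c(1L, 2L),
                   cluster_size = c(10L, 3L), score = c(-50, -80),
                   score_type = "balanced", is_centroid = TRUE,
                   path = "x.pdb", stringsAsFactors = FALSE)
  sel <- select_models(tb)
  expect_equal(sel$model_id[sel$role == "largest_cluster"], "a")
  expect_equal(sel$model_id[sel$role == "best_score"], "b")
  # single cluster: one model, both roles
  sel1 <- select_models(tb[1, ])
  expect_equal(nrow(sel1), 1L)
  expect_equal(sel1$role, "largest_cluster+best_score")
  # size tie broken by better score; score tie by lower cluster id
  tb2 <- data.frame(model_id = c("a", "b", "c"),
                    cluster_id = c(3L, 1L, 2L),
                    cluster_size = c(5L, 5L, 2L),
                    score = c(-70, -70, -70),
                    score_type = "balanced", is_centroid = TRUE,
                    path = "x.pdb", stringsAsFactors = FALSE)
  sel2 <- select_models(tb2)
  expect_equal(sel2$model_id[1], "b")   # cluster_id 1 wins both ties
  # randomized tables against the oracle
  set.seed(99)
  for (r in 1:20) {
    n <- sample(2:10, 1)
    tbr <- data.frame(
      model_id = sprintf("m%02d", 1:n), cluster_id = seq_len(n),
      cluster_size = sample(1:30, n, replace = TRUE),
      score = round(stats::runif(n, -100, -10), 1),
      score_type = "balanced", is_centroid = TRUE, path = "x.pdb",
      stringsAsFactors = FALSE)
    selr <- select_models(tbr)
    orc <- oracle_select(tbr)
    lc <- selr$model_id[grepl("largest_cluster", selr$role)]
    bs <- selr$model_id[grepl("best_score", selr$role)]
    expect_equal(lc, orc$largest)
    expect_equal(bs, orc$best_score)
    # permutation invariance
    perm <- tbr[sample(n), , drop = FALSE]
    selp <- select_models(perm)
    expect_setequal(selp$model_id, selr$model_id)
  }
  expect_error(select_models(tb[0, ]), "no retained")
})

test_that("leaflet planes derive from DUM pseudo-atom layers", {
  dum <- function(resno, z) data.frame(
    chain = "X", resno = resno, icode = "", resid = "DUM", elety = "O",
    element = "O", x = resno, y = 0, z = z, het = TRUE,
    stringsAsFactors = FALSE)
  atoms <- rbind(hand_ala("R", 1, c(0, 0, 0)),
                 do.call(rbind, lapply(1:5, function(i) dum(i, 14.8 + 0.1 * i))),
                 do.call(rbind, lapply(6:10, function(i) dum(i, -15.2 + 0.1 * (i - 6)))))
  m <- structure_model(atoms)
  fr <- membrane_frame_from_dum(m)
  expect_equal(fr$z_upper, mean(14.8 + 0.1 * (1:5)))
  expect_equal(fr$z_lower, mean(-15.2 + 0.1 * (0:4)))
  expect_error(membrane_frame_from_dum(
    structure_model(hand_ala("R", 1, c(0, 0, 0)))), "DUM")
  expect_error(membrane_frame(-5, 5), "greater")
})
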