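# --- synthetic fixtures with planted ground truth ---------------------------
#
# All generators are deterministic for a given seed and emit a manifest
# holding the planted truth, so every downstream stage can be scored exactly.
# Geometric placement is solved by direct construction (not sampling), so
# planted contact distances are exact. Fixtures are deliberately small
# (hundreds of atoms) so all-pairs oracles run instantly; they emulate the
# bookkeeping of a channel / G-beta-gamma complex, not the WD40 fold.

ideal_backbone <- function(center) {
  list(N = center + c(-0.525, 1.362, 0),
       CA = center,
       C = center + c(1.525, 0, 0),
       O = center + c(2.153, 1.062, 0))
}

# one residue (backbone + ideal side chain) centered at `center`
synth_residue <- function(chain, resno, aa, center) {
  bb <- ideal_backbone(center)
  sc <- sidechain_template(aa, N = bb$N, CA = bb$CA, C = bb$C)
  df <- data.frame(
    chain = chain, resno = resno, icode = "", resid = aa,
    elety = c("N", "CA", "C", "O", sc$elety),
    element = c("N", "C", "C", "O", sc$element),
    x = c(bb$N[1], bb$CA[1], bb$C[1], bb$O[1], sc$x),
    y = c(bb$N[2], bb$CA[2], bb$C[2], bb$O[2], sc$y),
    z = c(bb$N[3], bb$CA[3], bb$C[3], bb$O[3], sc$z),
    stringsAsFactors = FALSE)
  df
}

# coarse helix of residue centers: consecutive centers ~23 A apart so that
# planted cross-chain contacts cannot leak onto neighbouring residues
helix_centers <- function(n, radius = 14, rise = 8, step_deg = 100) {
  i <- seq_len(n) - 1L
  th <- i * step_deg * pi / 180
  cbind(radius * cos(th), radius * sin(th), rise * i)
}

#' Synthetic two-chain complex with planted contacts
#'
#' Builds a two-chain structure in which exactly `n_contacts` cross-chain
#' residue pairs have minimum heavy-atom distance equal to
#' `contact_distance` (by construction, to machine precision) and every
#' other cross-chain residue pair is farther than `background_min_distance`.
#' All planted contacts involve the designated focal LEU residue of chain A,
#' mirroring a focal-position contact-list analysis. The planted truth is
#' returned and written alongside the structure.
#'
#' @param seed integer RNG seed; the same seed reproduces byte-identical
#'   files.
#' @param n_res_a,n_res_b residues in chain A / chain B.
#' @param n_contacts planted cross-chain contact pairs (all at the focal
#'   residue; must be <= `n_res_b` and <= 12 for well-separated directions).
#' @param contact_distance planted minimum distance, Angstrom; must be below
#'   the 5.5 contact cutoff.
#' @param background_min_distance guaranteed clearance of all non-planted
#'   cross-chain pairs, Angstrom; must exceed the cutoff.
#' @param dir output directory (created); default a fresh temp directory.
#' @return list of class `fixture_manifest`: `seed`, `fixture_kind`,
#'   `truth` (planted contact pairs, focal key), `paths`, and `model`.
#' @export
make_complex <- function(seed, n_res_a = 12, n_res_b = 10, n_contacts = 7,
                         contact_distance = 4.0,
                         background_min_distance = 8.0,
                         dir = tempfile("complex_")) {
  if (!(contact_distance < 5.5 && 5.5 < background_min_distance))
    stop("need contact_distance < 5.5 < background_min_distance")
  if (n_contacts > n_res_b)
    stop("infeasible geometry: ", n_contacts, " contacts but only ",
         n_res_b, " residues in chain B")
  if (n_contacts > 12)
    stop("infeasible geometry: at most 12 well-separated contact ",
         "directions are supported")
  set.seed(seed)
  cen <- helix_centers(n_res_a)
  focal_i <- ceiling(n_res_a / 2)
  rows_a <- lapply(seq_len(n_res_a), function(i)
    synth_residue("A", i, if (i == focal_i) "LEU" else "ALA", cen[i, ]))
  atoms_a <- do.call(rbind, rows_a)
  focal_key <- format_residue_key("A", focal_i)

  fa <- atoms_a[atoms_a$resno == focal_i, , drop = FALSE]
  fxyz <- as.matrix(fa[, c("x", "y", "z")])
  radial <- c(cos((focal_i - 1) * 100 * pi / 180),
              sin((focal_i - 1) * 100 * pi / 180), 0)
  # fan of well-separated directions around the outward radial axis
  spread <- if (n_contacts > 1L)
    seq(-55, 55, length.out = n_contacts) else 0
  tilt <- stats::runif(n_contacts, -0.25, 0.25)
  which_b <- sort(sample.int(n_res_b, n_contacts))
  rows_b <- vector("list", n_res_b)
  truth_contacts <- NULL
  ci <- 0L
  for (j in seq_len(n_res_b)) {
    if (j %in% which_b) {
      ci <- ci + 1L
      ang <- spread[ci] * pi / 180
      u <- c(cos(ang) * radial[1] - sin(ang) * radial[2],
             sin(ang) * radial[1] + cos(ang) * radial[2], tilt[ci])
      u <- u / sqrt(sum(u^2))
      proj <- fxyz %*% u
      astar <- fxyz[which.max(proj), ]
      d <- contact_distance
      # string of atoms receding along u: the first (CB) realizes the
      # planted minimum exactly, the rest are strictly farther from every
      # chain-A atom by the projection argument; small lateral offsets on
      # C/O keep the backbone frame non-degenerate
      latbase <- pracma_cross(u, c(0, 0, 1))
      latbase <- latbase / sqrt(sum(latbase^2))
      pos <- list(N = astar + (d + 2.9) * u,
                  CA = astar + (d + 1.5) * u,
                  C = astar + (d + 2.6) * u + 0.8 * latbase,
                  O = astar + (d + 3.8) * u + 0.8 * latbase,
                  CB = astar + d * u)
      xyz <- do.call(rbind, pos[c("N", "CA", "C", "O", "CB")])
      rows_b[[j]] <- data.frame(
        chain = "B", resno = j, icode = "", resid = "ALA",
        elety = c("N", "CA", "C", "O", "CB"),
        element = c("N", "C", "C", "O", "C"),
        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
        stringsAsFactors = FALSE)
      truth_contacts <- rbind(truth_contacts, data.frame(
        key_a = focal_key, key_b = format_residue_key("B", j),
        distance = contact_distance, stringsAsFactors = FALSE))
    } else {
      rows_b[[j]] <- synth_residue("B", j, "ALA",
                                   c(0, 0, -200 - 12 * j))
    }
  }
  atoms <- rbind(atoms_a, do.call(rbind, rows_b))
  model <- structure_model(atoms, id = sprintf("synthetic_complex_s%d",
                                               seed))
  # direct verification of the planted geometry (all-pairs, tiny fixture):
  # exactly the planted pairs within the cutoff, everything else beyond the
  # background clearance
  av <- model$atoms[model$atoms$chain == "A", , drop = FALSE]
  bv <- model$atoms[model$atoms$chain == "B", , drop = FALSE]
  dm <- sqrt(outer(rowSums(as.matrix(av[, c("x", "y", "z")])^2),
                   rowSums(as.matrix(bv[, c("x", "y", "z")])^2), "+") -
               2 * as.matrix(av[, c("x", "y", "z")]) %*%
               t(as.matrix(bv[, c("x", "y", "z")])))
  ka <- residue_key_of(av); kb <- residue_key_of(bv)
  for (ia in unique(ka)) for (ib in unique(kb)) {
    md <- min(dm[ka == ia, kb == ib])
    planted <- ia == focal_key && ib %in% truth_contacts$key_b
    if (planted && abs(md - contact_distance) > 1e-9)
      stop("infeasible geometry: planted contact ", ia, "-", ib,
           " realized at ", signif(md, 6), " A")
    if (!planted && md <= background_min_distance)
      stop("infeasible geometry: unplanted pair ", ia, "-", ib,
           " at ", signif(md, 4),
           " A violates the background clearance")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pdb_path <- file.path(dir, "complex.pdb")
  write_structure(model, pdb_path)
  truth <- list(focal = focal_key, n_contacts = n_contacts,
                contact_distance = contact_distance,
                contacts = truth_contacts,
                n_res_a = n_res_a, n_res_b = n_res_b,
                n_atoms = nrow(atoms))
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  structure(list(seed = seed, fixture_kind = "complex", truth = truth,
                 paths = list(structure = pdb_path, truth = truth_path),
                 model = model),
            class = "fixture_manifest")
}

# random proper rotation matrix (deterministic under the session RNG)
random_rotation <- function() {
  q <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(q)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

apply_rigid <- function(model, R, t) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  moved <- xyz %*% t(R) + matrix(t, nrow(xyz), 3, byrow = TRUE)
  model$atoms$x <- moved[, 1]
  model$atoms$y <- moved[, 2]
  model$atoms$z <- moved[, 3]
  model
}

synth_chain <- function(chain, n, aa, origin, spacing = c(6, 0, 0)) {
  rows <- lapply(seq_len(n), function(i)
    synth_residue(chain, i, aa, origin + (i - 1) * spacing))
  do.call(rbind, rows)
}

#' Synthetic docked-pose ensemble with planted triage labels
#'
#' Emits a membrane-embedded reference receptor plus `n_poses` docked
#' G-beta-gamma poses: a planted fraction have one ligand atom strictly
#' above the lower leaflet, another fraction have the G-gamma C-terminal
#' C-alpha strictly more than 30 Angstrom below it, and the remainder pass
#' both rules. Every pose is written after a random rigid transform, so the
#' triage must superpose it back onto the reference. A cluster/score table
#' with distinct sizes and scores is emitted, and the truth records each
#' pose's label plus the correct largest-cluster / best-score selection.
#'
#' @param seed integer RNG seed.
#' @param n_poses ensemble size.
#' @param frac_above_leaflet,frac_cterm_far planted failure fractions (sum
#'   <= 1); counts are rounded down.
#' @param frame a [membrane_frame()].
#' @param dir output directory; default a fresh temp directory.
#' @return list of class `fixture_manifest` with `truth` (`labels`,
#'   `retained_ids`, `largest_cluster_id`, `best_score_id`), `paths`
#'   (`reference`, `pose_table`, `truth`), and the criteria used.
#' @export
make_pose_ensemble <- function(seed, n_poses = 40, frac_above_leaflet = 0.3,
                               frac_cterm_far = 0.2,
                               frame = membrane_frame(15, -15),
                               dir = tempfile("poses_")) {
  stopifnot(frac_above_leaflet >= 0, frac_cterm_far >= 0,
            frac_above_leaflet + frac_cterm_far <= 1)
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  # receptor: transmembrane chain R spanning the bilayer; residue centers
  # on a coarse helix so the C-alpha set is never collinear
  rc <- helix_centers(10, radius = 8, rise = 4, step_deg = 80)
  rc[, 3] <- rc[, 3] + frame$z_lower - 10
  ref_atoms <- do.call(rbind, lapply(seq_len(10), function(i)
    synth_residue("R", i, "ALA", rc[i, ])))
  reference <- structure_model(ref_atoms, id = "synthetic_receptor")
  ref_path <- file.path(dir, "reference.pdb")
  write_structure(reference, ref_path)

  empty_table <- data.frame(model_id = character(), cluster_id = integer(),
                            cluster_size = integer(), score = numeric(),
                            score_type = character(),
                            is_centroid = logical(), path = character(),
                            stringsAsFactors = FALSE)
  if (n_poses == 0L) {
    table_path <- file.path(dir, "poses.tsv")
    write.table(empty_table, table_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    truth <- list(labels = data.frame(model_id = character(),
                                      label = character()),
                  retained_ids = character(0),
                  largest_cluster_id = character(0),
                  best_score_id = character(0),
                  frame = list(z_upper = frame$z_upper,
                               z_lower = frame$z_lower))
    truth_path <- file.path(dir, "truth.json")
    jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
    return(structure(list(seed = seed, fixture_kind = "pose_ensemble",
                          truth = truth,
                          paths = list(reference = ref_path,
                                       pose_table = table_path,
                                       truth = truth_path),
                          frame = frame,
                          criteria = filter_criteria("G", c("B", "G"), "R")),
                     class = "fixture_manifest"))
  }
  n_above <- floor(n_poses * frac_above_leaflet)
  n_far <- floor(n_poses * frac_cterm_far)
  labels <- c(rep("above_leaflet", n_above), rep("cterm_far", n_far),
              rep("pass", n_poses - n_above - n_far))
  labels <- sample(labels)

  pose_rows <- vector("list", n_poses)
  sizes <- sample(seq_len(n_poses) * 3L)           # distinct cluster sizes
  scores <- round(-sample(seq(20, 20 + 2 * n_poses, by = 2), n_poses), 1)
  score_types <- sample(c("balanced", "electrostatic", "hydrophobic",
                          "vdw"), n_poses, replace = TRUE)
  for (k in seq_len(n_poses)) {
    # ligand built below the inner leaflet: beta chain B and gamma chain G
    base_z <- frame$z_lower - 12
    beta <- synth_chain("B", 4, "ALA", c(20, 5 * k %% 7, base_z))
    gamma <- synth_chain("G", 3, "ALA", c(20, -8, base_z - 3))
    lab <- labels[k]
    if (lab == "above_leaflet") {
      # push one beta CB strictly above the lower leaflet plane
      i <- which(beta$elety == "CB")[1]
      beta$z[i] <- frame$z_lower + stats::runif(1, 0.5, 3)
    } else if (lab == "cterm_far") {
      # sink the whole gamma chain so its terminal CA is > 30 A deep
      depth <- stats::runif(1, 31.5, 45)
      ca3 <- which(gamma$resno == 3 & gamma$elety == "CA")
      gamma$z <- gamma$z - (gamma$z[ca3] - (frame$z_lower - depth))
    } else {
      depth <- stats::runif(1, 5, 25)
      ca3 <- which(gamma$resno == 3 & gamma$elety == "CA")
      gamma$z <- gamma$z - (gamma$z[ca3] - (frame$z_lower - depth))
    }
    pose <- structure_model(rbind(ref_atoms, beta, gamma),
                            id = sprintf("pose_%03d", k))
    pose <- apply_rigid(pose, random_rotation(), stats::runif(3, -30, 30))
    p <- file.path(dir, sprintf("pose_%03d.pdb", k))
    write_structure(pose, p)
    pose_rows[[k]] <- data.frame(
      model_id = sprintf("pose_%03d", k), cluster_id = k,
      cluster_size = sizes[k], score = scores[k],
      score_type = score_types[k], is_centroid = TRUE,
      path = basename(p), stringsAsFactors = FALSE)
  }
  pose_table <- do.call(rbind, pose_rows)
  table_path <- file.path(dir, "poses.tsv")
  write.table(pose_table, table_path, sep = "\t", quote = FALSE,
              row.names = FALSE)

  retained_ids <- pose_table$model_id[labels == "pass"]
  ret <- pose_table[labels == "pass", , drop = FALSE]
  truth <- list(
    labels = data.frame(model_id = pose_table$model_id, label = labels,
                        stringsAsFactors = FALSE),
    retained_ids = retained_ids,
    largest_cluster_id =
      if (nrow(ret) > 0L) ret$model_id[which.max(ret$cluster_size)] else
        character(0),
    best_score_id =
      if (nrow(ret) > 0L) ret$model_id[which.min(ret$score)] else
        character(0),
    frame = list(z_upper = frame$z_upper, z_lower = frame$z_lower))
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  criteria <- filter_criteria(gamma_chain = "G",
                              ligand_chains = c("B", "G"),
                              receptor_chains = "R")
  structure(list(seed = seed, fixture_kind = "pose_ensemble", truth = truth,
                 paths = list(reference = ref_path,
                              pose_table = table_path, truth = truth_path),
                 frame = frame, criteria = criteria),
            class = "fixture_manifest")
}

#' Synthetic delta-delta-G table with planted classes
#'
#' Emits a stability/affinity delta-delta-G table whose values are sampled
#' strictly inside each class interval (significant: (1.05, 3]; above noise:
#' (0.65, 0.95]; within noise: [0, 0.55] kcal/mol in magnitude, random
#' sign), so the classifier must recover the planted classes exactly.
#'
#' @param seed integer RNG seed.
#' @param n_rows table rows.
#' @param class_mix named numeric vector over
#'   `c("significant", "above_noise", "within_noise")`, summing to 1; counts
#'   are apportioned largest-remainder.
#' @param dir output directory; default a fresh temp directory.
#' @return list of class `fixture_manifest` with the emitted `table` and
#'   planted per-row classes in `truth`.
#' @export
make_ddg_table <- function(seed, n_rows = 30,
                           class_mix = c(significant = 1 / 3,
                                         above_noise = 1 / 3,
                                         within_noise = 1 / 3),
                           dir = tempfile("ddg_")) {
  classes <- c("significant", "above_noise", "within_noise")
  stopifnot(all(names(class_mix) %in% classes),
            abs(sum(class_mix) - 1) < 1e-9)
  mix <- setNames(numeric(3), classes)
  mix[names(class_mix)] <- class_mix
  set.seed(seed)
  counts <- floor(mix * n_rows)
  rem <- n_rows - sum(counts)
  if (rem > 0) {
    frac <- mix * n_rows - counts
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[add] <- counts[add] + 1L
  }
  draw <- function(cls, n) {
    if (n == 0L) return(numeric(0))
    m <- switch(cls,
                significant = stats::runif(n, 1.05, 3.0),
                above_noise = stats::runif(n, 0.65, 0.95),
                within_noise = stats::runif(n, 0.0, 0.55))
    m * sample(c(-1, 1), n, replace = TRUE)
  }
  cls_stab <- sample(rep(classes, counts))
  cls_aff <- sample(rep(classes, counts))
  stab <- numeric(n_rows); aff <- numeric(n_rows)
  for (cl in classes) {
    stab[cls_stab == cl] <- draw(cl, sum(cls_stab == cl))
    aff[cls_aff == cl] <- draw(cl, sum(cls_aff == cl))
  }
  tb <- data.frame(
    complex_id = sprintf("complex_%02d", seq_len(n_rows)),
    mutation = "L95P",
    ddg_stability = round(stab, 3), ddg_affinity = round(aff, 3),
    stringsAsFactors = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv_path <- file.path(dir, "ddg.tsv")
  write.table(tb, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(class_stability = cls_stab, class_affinity = cls_aff,
                counts = as.list(counts))
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  structure(list(seed = seed, fixture_kind = "ddg_table", truth = truth,
                 paths = list(table = tsv_path, truth = truth_path),
                 table = tb),
            class = "fixture_manifest")
}

#' @export
print.fixture_manifest <- function(x, ...) {
  cat(sprintf("<fixture_manifest> kind %s, seed %d\n  files: %s\n",
              x$fixture_kind, x$seed,
              paste(unlist(x$paths), collapse = ", ")))
  invisible(x)
}
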