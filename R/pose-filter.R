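#' Membrane frame from leaflet planes
#'
#' Two z-planes in the OPM convention: +z points toward the extracellular
#' side, `z_upper` is the outer leaflet and `z_lower` the inner (cytoplasmic)
#' leaflet. "Above the lower leaflet" therefore means z strictly greater
#' than `z_lower`, i.e. inside or beyond the bilayer as seen from the
#' cytosol — the side a membrane-anchored G-beta-gamma must not cross.
#'
#' @param z_upper,z_lower leaflet plane z-coordinates, Angstrom;
#'   `z_upper > z_lower`.
#' @return list of class `membrane_frame`.
#' @export
membrane_frame <- function(z_upper = 15, z_lower = -15) {
  stopifnot(is.numeric(z_upper), is.numeric(z_lower))
  if (!(z_upper > z_lower))
    stop("z_upper must be greater than z_lower")
  structure(list(normal = "+z extracellular", z_upper = z_upper,
                 z_lower = z_lower), class = "membrane_frame")
}

#' Membrane frame from OPM DUM pseudo-atoms
#'
#' OPM-embedded reference structures carry the leaflets as layers of DUM
#' pseudo-atoms (HETATM, residue `DUM`). The atoms are split into the two
#' layers at the mid z and each leaflet plane is set to the mean z of its
#' layer.
#'
#' @param model a [structure_model()] read with waters/hetero retained, or
#'   any model containing DUM residues.
#' @return A [membrane_frame()].
#' @export
membrane_frame_from_dum <- function(model) {
  stopifnot(inherits(model, "struct_model"))
  dum <- model$atoms[model$atoms$resid == "DUM", , drop = FALSE]
  if (nrow(dum) == 0L)
    stop("no DUM pseudo-atoms found; supply explicit leaflet planes")
  mid <- (max(dum$z) + min(dum$z)) / 2
  membrane_frame(z_upper = mean(dum$z[dum$z >= mid]),
                 z_lower = mean(dum$z[dum$z < mid]))
}

# Kabsch optimal rotation: rotate P (n x 3, centered) onto Q (centered)
kabsch_rotation <- function(P, Q) {
  H <- t(P) %*% Q
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  s$v %*% diag(c(1, 1, d)) %*% t(s$u)
}

#' Rigid-body superposition by matched C-alpha atoms
#'
#' Least-squares (Kabsch) fit of the mobile model onto the reference using
#' C-alpha atoms matched by residue key. Used to carry docked poses into the
#' membrane frame of an OPM-embedded reference before geometric triage.
#'
#' @param mobile,reference [structure_model()]s.
#' @param keys residue keys to match on the receptor; `NULL` uses every
#'   residue key present in both models with a C-alpha atom.
#' @return list of class `superposition`: `rotation` (3x3), `translation`
#'   (length 3; transform is `x %*% t(R) + t`), `rmsd` (Angstrom), `n_atoms`,
#'   and `model`, the transformed mobile structure.
#' @export
superpose <- function(mobile, reference, keys = NULL) {
  stopifnot(inherits(mobile, "struct_model"),
            inherits(reference, "struct_model"))
  ca <- function(m) {
    a <- m$atoms[m$atoms$elety == "CA" & !m$atoms$het, , drop = FALSE]
    a[!duplicated(residue_key_of(a)), , drop = FALSE]
  }
  ma <- ca(mobile); ra <- ca(reference)
  mk <- residue_key_of(ma); rk <- residue_key_of(ra)
  if (is.null(keys)) {
    keys <- intersect(mk, rk)
  } else {
    miss <- c(setdiff(keys, mk), setdiff(keys, rk))
    if (length(miss) > 0L)
      stop("residue keys missing a matched C-alpha: ",
           paste(unique(miss), collapse = ", "))
  }
  if (length(keys) < 3L)
    stop("need at least 3 matched C-alpha pairs, got ", length(keys))
  P <- as.matrix(ma[match(keys, mk), c("x", "y", "z")])
  Q <- as.matrix(ra[match(keys, rk), c("x", "y", "z")])
  cP <- colMeans(P); cQ <- colMeans(Q)
  Pc <- sweep(P, 2, cP); Qc <- sweep(Q, 2, cQ)
  if (qr(Pc)$rank < 2L)
    stop("selected C-alpha atoms are collinear; superposition is degenerate")
  R <- kabsch_rotation(Pc, Qc)
  fitted <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Qc)^2)))
  translation <- cQ - as.numeric(R %*% cP)
  xyz <- as.matrix(mobile$atoms[, c("x", "y", "z")])
  moved <- xyz %*% t(R) + matrix(translation, nrow(xyz), 3, byrow = TRUE)
  out <- mobile
  out$atoms$x <- moved[, 1]; out$atoms$y <- moved[, 2]
  out$atoms$z <- moved[, 3]
  list(rotation = R, translation = translation, rmsd = rmsd,
       n_atoms = length(keys), model = out)
}

#' C-terminal C-alpha of the G-gamma chain
#'
#' The geranylgeranyl anchor sits at the G-gamma C-terminus, so the terminal
#' C-alpha is the reference point for the membrane-proximity rule. The last
#' residue is taken by `(resno, icode)` ordering.
#'
#' @param model a [structure_model()].
#' @param gamma_chain chain id of G-gamma.
#' @return one-row data.frame (the atom record).
#' @export
gamma_cterm <- function(model, gamma_chain) {
  a <- model$atoms
  g <- a[a$chain == gamma_chain & !a$het & !a$water, , drop = FALSE]
  if (nrow(g) == 0L) stop("gamma chain '", gamma_chain, "' not found")
  last <- g[order(g$resno, g$icode), , drop = FALSE]
  lk <- residue_key_of(last)[nrow(last)]
  res <- last[residue_key_of(last) == lk, , drop = FALSE]
  caa <- res[res$elety == "CA", , drop = FALSE]
  if (nrow(caa) == 0L)
    stop("terminal residue ", lk, " of chain ", gamma_chain,
         " has no C-alpha atom")
  caa[1, , drop = FALSE]
}

#' Pose filter criteria
#'
#' The two conjunctive exclusion rules for docked poses, applied in the
#' membrane frame: (1) no ligand (G-beta-gamma) heavy atom may lie strictly
#' above the lower leaflet plane; (2) the G-gamma C-terminal C-alpha may not
#' lie more than `max_gamma_cterm_distance` (strictly) below the lower
#' leaflet.
#'
#' @param gamma_chain chain id of G-gamma.
#' @param ligand_chains chain ids of the docked ligand (G-beta-gamma).
#' @param receptor_chains chain ids of the receptor (channel), used for
#'   superposition.
#' @param max_gamma_cterm_distance Angstrom, default 30.
#' @param exclude_above_lower_leaflet apply rule (1)?
#' @return list of class `filter_criteria`.
#' @export
filter_criteria <- function(gamma_chain, ligand_chains, receptor_chains,
                            max_gamma_cterm_distance = 30,
                            exclude_above_lower_leaflet = TRUE) {
  stopifnot(max_gamma_cterm_distance > 0)
  structure(list(gamma_chain = gamma_chain, ligand_chains = ligand_chains,
                 receptor_chains = receptor_chains,
                 max_gamma_cterm_distance = max_gamma_cterm_distance,
                 exclude_above_lower_leaflet = exclude_above_lower_leaflet),
            class = "filter_criteria")
}

#' Membrane-geometry verdict for one pose
#'
#' The pose must already be in the reference membrane frame (see
#' [superpose()]). Both rule quantities are always reported.
#'
#' @param model a [structure_model()] in the membrane frame.
#' @param frame a [membrane_frame()].
#' @param criteria a [filter_criteria()].
#' @return one-row data.frame: `retained`, `reason` (`"none"`,
#'   `"atom_above_lower_leaflet"` or `"gamma_cterm_too_far"`), `worst_z`
#'   (highest ligand heavy-atom z), `gamma_cterm_distance` (depth of the
#'   G-gamma C-terminal C-alpha below the lower leaflet).
#' @export
filter_pose <- function(model, frame, criteria) {
  stopifnot(inherits(frame, "membrane_frame"),
            inherits(criteria, "filter_criteria"))
  a <- model$atoms
  lig <- a[a$chain %in% criteria$ligand_chains & !a$hydrogen & !a$water, ,
           drop = FALSE]
  if (nrow(lig) == 0L)
    stop("ligand chain(s) ", paste(criteria$ligand_chains, collapse = ","),
         " absent from pose")
  worst_z <- max(lig$z)
  ct <- gamma_cterm(model, criteria$gamma_chain)
  cterm_dist <- frame$z_lower - ct$z
  reason <- "none"
  if (isTRUE(criteria$exclude_above_lower_leaflet) &&
      worst_z > frame$z_lower) {
    reason <- "atom_above_lower_leaflet"
  } else if (cterm_dist > criteria$max_gamma_cterm_distance) {
    reason <- "gamma_cterm_too_far"
  }
  data.frame(retained = reason == "none", reason = reason,
             worst_z = worst_z, gamma_cterm_distance = cterm_dist,
             stringsAsFactors = FALSE)
}

#' Read a docking pose table
#'
#' Documented TSV with columns `model_id`, `cluster_id`, `cluster_size`,
#' `score`, `score_type`, `is_centroid`, `path`.
#'
#' @param path TSV file path.
#' @param base_dir directory against which relative `path` entries are
#'   resolved; defaults to the table's own directory.
#' @return data.frame of pose records.
#' @export
read_pose_table <- function(path, base_dir = dirname(path)) {
  tb <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("model_id", "cluster_id", "cluster_size", "score",
            "score_type", "is_centroid", "path")
  miss <- setdiff(need, names(tb))
  if (length(miss) > 0L)
    stop("pose table is missing column(s): ", paste(miss, collapse = ", "))
  rel <- !grepl("^(/|[A-Za-z]:)", tb$path)
  tb$path[rel] <- file.path(base_dir, tb$path[rel])
  tb$is_centroid <- as.logical(tb$is_centroid)
  tb
}

#' Triage a docked pose ensemble against the membrane frame
#'
#' Each pose is read, superposed onto the reference by its receptor
#' C-alpha atoms, and passed through [filter_pose()]. An unreadable pose is
#' recorded as an `error` verdict and the run continues. The retained list
#' preserves input order.
#'
#' @param poses data.frame of pose records (see [read_pose_table()]).
#' @param frame a [membrane_frame()].
#' @param reference reference [structure_model()] in the membrane frame.
#' @param criteria a [filter_criteria()].
#' @return list of class `triage_result`: `retained` (pose records),
#'   `verdicts` (one row per input pose).
#' @export
triage_ensemble <- function(poses, frame, reference, criteria) {
  n <- nrow(poses)
  if (n == 0L) {
    verdicts <- data.frame(model_id = character(), retained = logical(),
                           reason = character(), worst_z = numeric(),
                           gamma_cterm_distance = numeric(),
                           stringsAsFactors = FALSE)
    return(structure(list(retained = poses, verdicts = verdicts,
                          frame = frame, criteria = criteria),
                     class = "triage_result"))
  }
  verdicts <- vector("list", n)
  for (k in seq_len(n)) {
    v <- tryCatch({
      pose <- read_structure(poses$path[k])
      sup <- superpose(pose, reference)
      filter_pose(sup$model, frame, criteria)
    }, error = function(e) {
      data.frame(retained = FALSE, reason = paste0("error: ",
                                                   conditionMessage(e)),
                 worst_z = NA_real_, gamma_cterm_distance = NA_real_,
                 stringsAsFactors = FALSE)
    })
    v$model_id <- poses$model_id[k]
    verdicts[[k]] <- v[, c("model_id", "retained", "reason", "worst_z",
                           "gamma_cterm_distance")]
  }
  verdicts <- do.call(rbind, verdicts)
  rownames(verdicts) <- NULL
  structure(list(retained = poses[verdicts$retained, , drop = FALSE],
                 verdicts = verdicts, frame = frame, criteria = criteria),
            class = "triage_result")
}

#' @export
print.triage_result <- function(x, ...) {
  cat(sprintf("<triage_result> %d/%d poses retained\n",
              nrow(x$retained), nrow(x$verdicts)))
  invisible(x)
}

#' Select the largest-cluster and best-score centroid models
#'
#' From the retained pose records, returns (at most) two representatives:
#' the centroid of the cluster with the greatest membership and the centroid
#' of the cluster with the lowest (best) energy score. When one model fills
#' both roles it is returned once with both role tags. Ties: the larger
#' cluster wins by better score, a score tie by lower `cluster_id`.
#'
#' @param retained data.frame of retained pose records.
#' @return data.frame of selected records with a `role` column
#'   (`"largest_cluster"`, `"best_score"`, or
#'   `"largest_cluster+best_score"`).
#' @export
select_models <- function(retained) {
  if (is.null(retained) || nrow(retained) == 0L)
    stop("no retained poses to select from")
  # one representative record per cluster: its centroid when flagged,
  # otherwise the lowest-score member
  reps <- lapply(split(retained, retained$cluster_id), function(cl) {
    cand <- if (any(cl$is_centroid)) cl[cl$is_centroid, , drop = FALSE]
    else cl
    cand[order(cand$score), , drop = FALSE][1, , drop = FALSE]
  })
  reps <- do.call(rbind, reps)
  lc <- reps[order(-reps$cluster_size, reps$score, reps$cluster_id), ,
             drop = FALSE][1, , drop = FALSE]
  bs <- reps[order(reps$score, reps$cluster_id), ,
             drop = FALSE][1, , drop = FALSE]
  if (identical(lc$model_id, bs$model_id)) {
    lc$role <- "largest_cluster+best_score"
    out <- lc
  } else {
    lc$role <- "largest_cluster"
    bs$role <- "best_score"
    out <- rbind(lc, bs)
  }
  rownames(out) <- NULL
  out
}
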