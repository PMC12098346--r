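# Independent all-pairs oracles. These deliberately avoid the package's
# spatial-grid code path: distances come from a full atom-atom distance
# matrix, and eligibility filtering is re-derived from the raw atom flags.

oracle_atoms <- function(model, cutoff = 5.5, heavy_only = TRUE,
                         no_waters = TRUE, no_hetero = TRUE) {
  a <- model$atoms
  keep <- rep(TRUE, nrow(a))
  if (heavy_only) keep <- keep & !(a$element %in% c("H", "D"))
  if (no_waters) keep <- keep & !(a$resid %in% c("HOH", "WAT", "DOD"))
  if (no_hetero) keep <- keep & (!a$het | a$resid %in% c("HOH", "WAT", "DOD"))
  a[keep, , drop = FALSE]
}

oracle_key <- function(a) {
  ifelse(nzchar(a$icode), paste(a$chain, a$resno, a$icode, sep = ":"),
         paste(a$chain, a$resno, sep = ":"))
}

# min heavy-atom distance for every residue pair across two atom subsets
oracle_residue_mins <- function(aa, ab) {
  dm <- as.matrix(stats::dist(rbind(as.matrix(aa[, c("x", "y", "z")]),
                                    as.matrix(ab[, c("x", "y", "z")]))))
  dm <- dm[seq_len(nrow(aa)), nrow(aa) + seq_len(nrow(ab)), drop = FALSE]
  ka <- oracle_key(aa); kb <- oracle_key(ab)
  out <- expand.grid(key_a = unique(ka), key_b = unique(kb),
                     stringsAsFactors = FALSE)
  out$min_distance <- mapply(function(x, y)
    min(dm[ka == x, kb == y]), out$key_a, out$key_b)
  out
}

# brute-force interface contacts (unsorted residue pair set)
oracle_interface <- function(model, group_a, group_b, cutoff = 5.5) {
  at <- oracle_atoms(model, cutoff)
  aa <- at[at$chain %in% group_a, , drop = FALSE]
  ab <- at[at$chain %in% group_b, , drop = FALSE]
  mm <- oracle_residue_mins(aa, ab)
  mm[mm$min_distance <= cutoff, , drop = FALSE]
}

# brute-force focal environment
oracle_environment <- function(model, focal, cutoff = 5.5,
                               scope = "all") {
  at <- oracle_atoms(model, cutoff)
  keys <- oracle_key(at)
  fa <- at[keys == focal, , drop = FALSE]
  oth <- at[keys != focal, , drop = FALSE]
  fchain <- fa$chain[1]
  if (scope == "inter_chain") oth <- oth[oth$chain != fchain, , drop = FALSE]
  if (scope == "intra_chain") oth <- oth[oth$chain == fchain, , drop = FALSE]
  mm <- oracle_residue_mins(fa, oth)
  mm <- mm[mm$min_distance <= cutoff, , drop = FALSE]
  mm[order(mm$min_distance, mm$key_b), , drop = FALSE]
}

# exhaustive-scan oracle for largest-cluster / best-score selection,
# reproducing the documented tie rules by explicit ordering
oracle_select <- function(retained) {
  reps <- do.call(rbind, lapply(split(retained, retained$cluster_id),
                                function(cl) {
    cand <- if (any(cl$is_centroid)) cl[cl$is_centroid, , drop = FALSE]
    else cl
    cand[which.min(cand$score), , drop = FALSE]
  }))
  best <- function(ord) reps[ord, , drop = FALSE][1, "model_id"]
  list(largest = best(order(-reps$cluster_size, reps$score,
                            reps$cluster_id)),
       best_score = best(order(reps$score, reps$cluster_id)))
}

# rigid transform applied to a structure model (test-side twin of the
# generator's internal helper)
rigid_move <- function(model, angle = 0.7, axis = c(1, 2, 3),
                       shift = c(5, -4, 9)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  moved <- xyz %*% t(R) + matrix(shift, nrow(xyz), 3, byrow = TRUE)
  model$atoms$x <- moved[, 1]
  model$atoms$y <- moved[, 2]
  model$atoms$z <- moved[, 3]
  model
}
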