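#' Contact criteria
#'
#' The contact criterion used throughout: two residues are in contact when
#' any heavy atom of one lies at 5.5 Angstrom or below from any heavy atom of
#' the other (the PRODIGY interface convention; the comparison is `<=`,
#' "5.5 and below"). Waters and hydrogens are excluded by default, as are
#' non-water hetero groups, so counts are over amino-acid heavy atoms.
#'
#' @param cutoff distance cutoff in Angstrom (> 0).
#' @param heavy_atoms_only restrict to non-hydrogen atoms?
#' @param exclude_waters drop water residues?
#' @param exclude_self_residue drop the focal residue itself from
#'   environments?
#' @param include_hetero include non-water HETATM groups?
#' @return list of class `contact_criteria`.
#' @export
contact_criteria <- function(cutoff = 5.5, heavy_atoms_only = TRUE,
                             exclude_waters = TRUE,
                             exclude_self_residue = TRUE,
                             include_hetero = FALSE) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, cutoff > 0)
  structure(list(cutoff = cutoff, heavy_atoms_only = heavy_atoms_only,
                 exclude_waters = exclude_waters,
                 exclude_self_residue = exclude_self_residue,
                 include_hetero = include_hetero),
            class = "contact_criteria")
}

# Uniform spatial grid neighbour search: all (i, j) atom pairs with
# dist(A[i, ], B[j, ]) <= cutoff. Cell edge = cutoff, so every pair within
# cutoff falls into the same or an adjacent (27-neighbourhood) cell.
# Correctness is pinned to an all-pairs oracle in the test suite.
grid_pairs <- function(A, B, cutoff) {
  empty <- data.frame(i = integer(), j = integer(), d = numeric())
  if (nrow(A) == 0L || nrow(B) == 0L) return(empty)
  cell <- function(M) {
    ix <- floor(M / cutoff)
    paste(ix[, 1], ix[, 2], ix[, 3], sep = ",")
  }
  keyB <- cell(B)
  bmap <- split(seq_len(nrow(B)), keyB)
  cA <- floor(A / cutoff)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out <- vector("list", 0L)
  cells_a <- paste(cA[, 1], cA[, 2], cA[, 3], sep = ",")
  for (ck in unique(cells_a)) {
    ia <- which(cells_a == ck)
    base <- as.integer(strsplit(ck, ",", fixed = TRUE)[[1]])
    nb_keys <- paste(base[1] + offs[, 1], base[2] + offs[, 2],
                     base[3] + offs[, 3], sep = ",")
    jb <- unlist(bmap[nb_keys], use.names = FALSE)
    if (is.null(jb) || length(jb) == 0L) next
    d2 <- outer(rowSums(A[ia, , drop = FALSE]^2),
                rowSums(B[jb, , drop = FALSE]^2), "+") -
      2 * (A[ia, , drop = FALSE] %*% t(B[jb, , drop = FALSE]))
    d2[d2 < 0] <- 0
    hit <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
    if (nrow(hit) > 0L)
      out[[length(out) + 1L]] <- data.frame(
        i = ia[hit[, 1]], j = jb[hit[, 2]],
        d = sqrt(d2[hit]))
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

# minimum heavy-atom distance per residue pair, from an atom-pair table
pair_min_by_residue <- function(pairs, atoms_a, atoms_b) {
  if (nrow(pairs) == 0L)
    return(data.frame(key_a = character(), key_b = character(),
                      min_distance = numeric()))
  ka <- residue_key_of(atoms_a)[pairs$i]
  kb <- residue_key_of(atoms_b)[pairs$j]
  grp <- paste(ka, kb, sep = "\r")
  md <- tapply(pairs$d, grp, min)
  parts <- strsplit(names(md), "\r", fixed = TRUE)
  data.frame(key_a = vapply(parts, `[`, "", 1L),
             key_b = vapply(parts, `[`, "", 2L),
             min_distance = as.numeric(md), stringsAsFactors = FALSE)
}

residue_table <- function(atoms, keys) {
  ak <- residue_key_of(atoms)
  idx <- match(keys, ak)
  data.frame(key = keys, chain = atoms$chain[idx], resno = atoms$resno[idx],
             icode = atoms$icode[idx], resid = atoms$resid[idx],
             stringsAsFactors = FALSE)
}

#' Inter-group interface residues and contacts
#'
#' A residue of group A is an interface residue iff any of its (heavy) atoms
#' lies at `cutoff` or below from any (heavy) atom of any residue of group B,
#' and vice versa. Contacts are unordered residue pairs with their minimum
#' heavy-atom distance.
#'
#' @param model a [structure_model()].
#' @param group_a,group_b disjoint, non-empty chain-id sets.
#' @param criteria a [contact_criteria()].
#' @return An `interface_report`: list with `partner_a`, `partner_b`,
#'   `interface_residues_a`, `interface_residues_b` (residue tables) and
#'   `contacts` (one row per residue pair, sorted by distance then key).
#' @export
find_interface <- function(model, group_a, group_b,
                           criteria = contact_criteria()) {
  stopifnot(inherits(model, "struct_model"))
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("both chain groups must be non-empty")
  if (length(intersect(group_a, group_b)) > 0L)
    stop("chain groups overlap: ",
         paste(intersect(group_a, group_b), collapse = ", "))
  have <- unique(model$atoms$chain)
  unknown <- setdiff(c(group_a, group_b), have)
  if (length(unknown) > 0L)
    stop("unknown chain id(s): ", paste(unknown, collapse = ", "),
         "; available: ", paste(have, collapse = ", "))
  at <- criteria_atoms(model, criteria)
  aa <- at[at$chain %in% group_a, , drop = FALSE]
  ab <- at[at$chain %in% group_b, , drop = FALSE]
  pr <- grid_pairs(as.matrix(aa[, c("x", "y", "z")]),
                   as.matrix(ab[, c("x", "y", "z")]), criteria$cutoff)
  contacts <- pair_min_by_residue(pr, aa, ab)
  contacts$same_chain <- rep(FALSE, nrow(contacts))
  contacts <- contacts[order(contacts$min_distance, contacts$key_a,
                             contacts$key_b), , drop = FALSE]
  rownames(contacts) <- NULL
  structure(list(
    partner_a = group_a, partner_b = group_b,
    interface_residues_a = residue_table(aa, sort(unique(contacts$key_a))),
    interface_residues_b = residue_table(ab, sort(unique(contacts$key_b))),
    contacts = contacts, criteria = criteria
  ), class = "interface_report")
}

#' @export
print.interface_report <- function(x, ...) {
  cat(sprintf(
    "<interface_report> %s | %s: %d contacts, %d + %d interface residues (cutoff %.2f A)\n",
    paste(x$partner_a, collapse = ","), paste(x$partner_b, collapse = ","),
    nrow(x$contacts), nrow(x$interface_residues_a),
    nrow(x$interface_residues_b), x$criteria$cutoff))
  invisible(x)
}

#' Contact environment of a focal residue
#'
#' Every residue with any heavy atom at `cutoff` or below from any heavy atom
#' of the focal residue (an INTAA-style contact list), with exact minimum
#' distances, sorted by distance ascending then residue key. Sequence
#' neighbours (i +/- 1) are included by default; set
#' `exclude_backbone_neighbors` to drop them.
#'
#' @param model a [structure_model()].
#' @param focal residue key string (e.g. `"B:95"`).
#' @param criteria a [contact_criteria()].
#' @param partner_scope `"all"`, `"intra_chain"` or `"inter_chain"`.
#' @param exclude_backbone_neighbors drop residues at sequence positions
#'   focal resno +/- 1 on the focal chain?
#' @return data.frame with one row per environment residue: `key`, `chain`,
#'   `resno`, `icode`, `resid`, `min_distance`, `same_chain`.
#' @export
residue_environment <- function(model, focal, criteria = contact_criteria(),
                                partner_scope = c("all", "intra_chain",
                                                  "inter_chain"),
                                exclude_backbone_neighbors = FALSE) {
  stopifnot(inherits(model, "struct_model"))
  partner_scope <- match.arg(partner_scope)
  fk <- parse_residue_key(focal)
  if (length(residue_rows(model, fk)) == 0L) {
    all_keys <- unique(residue_key_of(model$atoms))
    same_chain <- all_keys[startsWith(all_keys, paste0(fk$chain, ":"))]
    near <- same_chain[order(abs(
      vapply(same_chain, function(k) parse_residue_key(k)$resno, 1L) -
        fk$resno))]
    stop("focal residue '", focal, "' not found; nearest keys on chain ",
         fk$chain, ": ",
         paste(utils::head(near, 5L), collapse = ", "))
  }
  at <- criteria_atoms(model, criteria)
  keys <- residue_key_of(at)
  fkey <- format_residue_key(fk$chain, fk$resno, fk$icode)
  fa <- at[keys == fkey, , drop = FALSE]
  oth <- at
  if (isTRUE(criteria$exclude_self_residue))
    oth <- oth[residue_key_of(oth) != fkey, , drop = FALSE]
  if (partner_scope == "intra_chain")
    oth <- oth[oth$chain == fk$chain, , drop = FALSE]
  if (partner_scope == "inter_chain")
    oth <- oth[oth$chain != fk$chain, , drop = FALSE]
  if (exclude_backbone_neighbors)
    oth <- oth[!(oth$chain == fk$chain & !nzchar(oth$icode) &
                   abs(oth$resno - fk$resno) == 1L), , drop = FALSE]
  pr <- grid_pairs(as.matrix(fa[, c("x", "y", "z")]),
                   as.matrix(oth[, c("x", "y", "z")]), criteria$cutoff)
  res <- pair_min_by_residue(pr, fa, oth)
  env <- residue_table(oth, res$key_b)
  env$min_distance <- res$min_distance
  env$same_chain <- env$chain == fk$chain
  env <- env[order(env$min_distance, env$key), , drop = FALSE]
  rownames(env) <- NULL
  env
}

#' Wild-type versus mutant environment difference
#'
#' Set arithmetic on the residue keys of two contact environments computed
#' with identical criteria: which contacts are retained, lost or gained
#' after, e.g., a Leu-to-Pro substitution at the focal position.
#'
#' @param env_wt,env_mut data.frames from [residue_environment()].
#' @return list of class `environment_delta` with key vectors `retained`,
#'   `lost`, `gained` and the corresponding counts.
#' @export
environment_delta <- function(env_wt, env_mut) {
  kw <- env_wt$key
  km <- env_mut$key
  out <- list(retained = sort(intersect(kw, km)),
              lost = sort(setdiff(kw, km)),
              gained = sort(setdiff(km, kw)))
  out$n_wt <- length(kw); out$n_mut <- length(km)
  out$n_retained <- length(out$retained)
  out$n_lost <- length(out$lost)
  out$n_gained <- length(out$gained)
  structure(out, class = "environment_delta")
}

#' @export
print.environment_delta <- function(x, ...) {
  cat(sprintf(
    "<environment_delta> WT %d -> mutant %d: %d retained, %d lost, %d gained\n",
    x$n_wt, x$n_mut, x$n_retained, x$n_lost, x$n_gained))
  invisible(x)
}
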