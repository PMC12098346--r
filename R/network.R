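#' Default geometric rules for non-covalent interaction typing
#'
#' Residue interaction networks classify residue pairs into edge types by
#' conventional geometric rules, applied in a fixed precedence order (ionic >
#' hbond > hydrophobic > vdw > generic) so exactly one kind is assigned per
#' pair:
#'
#' * `ionic`: side-chain charged N/O of ARG/LYS (and HIS when
#'   `his_chargeable`) against side-chain carboxylate O of ASP/GLU at <=
#'   `ionic_cutoff`.
#' * `hbond`: donor-capable N/O against acceptor-capable N/O at <=
#'   `hbond_cutoff`. Hydrogens are excluded from the model by default, so no
#'   angle term is applied.
#' * `hydrophobic`: side-chain carbon against side-chain carbon of apolar
#'   residues at <= `hydrophobic_cutoff`.
#' * `vdw`: any heavy-atom pair at <= sum of van der Waals radii +
#'   `vdw_slack`.
#' * `generic`: any heavy-atom pair at <= `generic_cutoff` (the contact
#'   cutoff fallback).
#'
#' These thresholds are conventional values and are fully user-editable; the
#' network module's contract is reproducibility of this rule table, not
#' byte-agreement with any external annotation server.
#'
#' @param ionic_cutoff,hbond_cutoff,hydrophobic_cutoff,generic_cutoff
#'   distance cutoffs, Angstrom.
#' @param vdw_slack additive slack over the summed vdW radii, Angstrom.
#' @param his_chargeable treat histidine as protonatable (part of the ionic
#'   rule)?
#' @return list of class `interaction_rules`.
#' @export
interaction_rules <- function(ionic_cutoff = 4.0, hbond_cutoff = 3.5,
                              hydrophobic_cutoff = 5.0, vdw_slack = 0.5,
                              generic_cutoff = 5.5, his_chargeable = TRUE) {
  structure(list(ionic_cutoff = ionic_cutoff, hbond_cutoff = hbond_cutoff,
                 hydrophobic_cutoff = hydrophobic_cutoff,
                 vdw_slack = vdw_slack, generic_cutoff = generic_cutoff,
                 his_chargeable = his_chargeable),
            class = "interaction_rules")
}

# vdW radii (Angstrom), Bondi-style; default for unlisted elements
.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90)
vdw_radius <- function(element) {
  r <- .vdw_radii[element]
  r[is.na(r)] <- 1.70
  unname(r)
}

.backbone_atoms <- c("N", "CA", "C", "O", "OXT")
.apolar_residues <- c("ALA", "VAL", "LEU", "ILE", "PRO", "PHE", "MET", "TRP")

# charged side-chain atoms per residue
positive_atoms <- function(resid, elety, his_chargeable) {
  (resid == "ARG" & elety %in% c("NE", "NH1", "NH2")) |
    (resid == "LYS" & elety == "NZ") |
    (his_chargeable & resid == "HIS" & elety %in% c("ND1", "NE2"))
}
negative_atoms <- function(resid, elety) {
  (resid == "ASP" & elety %in% c("OD1", "OD2")) |
    (resid == "GLU" & elety %in% c("OE1", "OE2"))
}
# donor-capable: any nitrogen, plus hydroxyl/thiol-free oxygens of SER/THR/TYR
donor_atoms <- function(resid, elety, element) {
  element == "N" |
    (resid == "SER" & elety == "OG") |
    (resid == "THR" & elety == "OG1") |
    (resid == "TYR" & elety == "OH")
}
# acceptor-capable: any oxygen, plus histidine ring nitrogens
acceptor_atoms <- function(resid, elety, element) {
  element == "O" | (resid == "HIS" & elety %in% c("ND1", "NE2"))
}

# all heavy-atom pair distances between two residue atom tables
atom_pair_grid <- function(ra, rb) {
  d2 <- outer(rowSums(as.matrix(ra[, c("x", "y", "z")])^2),
              rowSums(as.matrix(rb[, c("x", "y", "z")])^2), "+") -
    2 * as.matrix(ra[, c("x", "y", "z")]) %*%
    t(as.matrix(rb[, c("x", "y", "z")]))
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Classify the interaction between two residues
#'
#' Applies the rule table of [interaction_rules()] in precedence order and
#' returns the first matching kind, together with the closest atom pair that
#' realizes it, or `NULL` when no rule fires.
#'
#' @param model a [structure_model()].
#' @param key_a,key_b residue key strings.
#' @param rules an [interaction_rules()].
#' @param criteria a [contact_criteria()] (controls atom eligibility).
#' @return `NULL` or a one-row data.frame: `key_a`, `key_b`, `kind`,
#'   `atom_a`, `atom_b`, `distance`.
#' @export
classify_pair <- function(model, key_a, key_b, rules = interaction_rules(),
                          criteria = contact_criteria()) {
  at <- criteria_atoms(model, criteria)
  keys <- residue_key_of(at)
  ra <- at[keys == key_a, , drop = FALSE]
  rb <- at[keys == key_b, , drop = FALSE]
  if (nrow(ra) == 0L || nrow(rb) == 0L)
    stop("residue pair not found in model: ", key_a, " / ", key_b)
  d <- atom_pair_grid(ra, rb)

  hit <- function(mask_a, mask_b, cutmat) {
    # role symmetry is handled by invoking this in both directions
    ok <- outer(mask_a, mask_b, "&") & d <= cutmat
    if (!any(ok)) return(NULL)
    dm <- d; dm[!ok] <- Inf
    ij <- which(dm == min(dm), arr.ind = TRUE)[1, , drop = TRUE]
    list(atom_a = ra$elety[ij[1]], atom_b = rb$elety[ij[2]],
         distance = d[ij[1], ij[2]])
  }
  edge <- function(kind, h) data.frame(
    key_a = key_a, key_b = key_b, kind = kind,
    atom_a = h$atom_a, atom_b = h$atom_b, distance = h$distance,
    stringsAsFactors = FALSE)

  pos_a <- positive_atoms(ra$resid, ra$elety, rules$his_chargeable)
  neg_a <- negative_atoms(ra$resid, ra$elety)
  pos_b <- positive_atoms(rb$resid, rb$elety, rules$his_chargeable)
  neg_b <- negative_atoms(rb$resid, rb$elety)
  h <- hit(pos_a, neg_b, rules$ionic_cutoff)
  if (is.null(h)) h <- hit(neg_a, pos_b, rules$ionic_cutoff)
  if (!is.null(h)) return(edge("ionic", h))

  don_a <- donor_atoms(ra$resid, ra$elety, ra$element)
  acc_a <- acceptor_atoms(ra$resid, ra$elety, ra$element)
  don_b <- donor_atoms(rb$resid, rb$elety, rb$element)
  acc_b <- acceptor_atoms(rb$resid, rb$elety, rb$element)
  h <- hit(don_a, acc_b, rules$hbond_cutoff)
  if (is.null(h)) h <- hit(acc_a, don_b, rules$hbond_cutoff)
  if (!is.null(h)) return(edge("hbond", h))

  apc_a <- ra$element == "C" & !(ra$elety %in% .backbone_atoms) &
    ra$resid %in% .apolar_residues
  apc_b <- rb$element == "C" & !(rb$elety %in% .backbone_atoms) &
    rb$resid %in% .apolar_residues
  h <- hit(apc_a, apc_b, rules$hydrophobic_cutoff)
  if (!is.null(h)) return(edge("hydrophobic", h))

  vcut <- outer(vdw_radius(ra$element), vdw_radius(rb$element), "+") +
    rules$vdw_slack
  h <- hit(rep(TRUE, nrow(ra)), rep(TRUE, nrow(rb)), vcut)
  if (!is.null(h)) return(edge("vdw", h))

  h <- hit(rep(TRUE, nrow(ra)), rep(TRUE, nrow(rb)), rules$generic_cutoff)
  if (!is.null(h)) return(edge("generic", h))
  NULL
}

#' Build the interaction network around a focal residue
#'
#' Nodes are the focal residue plus its contact environment (per
#' [residue_environment()]); edges are [classify_pair()] over all node pairs.
#' Every edge is also a contact pair at the environment cutoff.
#'
#' @param model a [structure_model()].
#' @param focal residue key string.
#' @param criteria a [contact_criteria()].
#' @param rules an [interaction_rules()].
#' @param partner_scope passed to [residue_environment()].
#' @return list of class `interaction_network`: `focal`, `nodes` (residue
#'   table), `edges` (data.frame), `environment`.
#' @export
build_network <- function(model, focal, criteria = contact_criteria(),
                          rules = interaction_rules(),
                          partner_scope = "all") {
  env <- residue_environment(model, focal, criteria,
                             partner_scope = partner_scope)
  node_keys <- c(focal, env$key)
  edges <- list()
  if (length(node_keys) > 1L) {
    cmb <- utils::combn(node_keys, 2L)
    for (k in seq_len(ncol(cmb))) {
      # only node pairs that are themselves within the contact cutoff
      e <- classify_pair(model, cmb[1, k], cmb[2, k], rules, criteria)
      if (!is.null(e) && e$distance <= criteria$cutoff + 1e-12)
        edges[[length(edges) + 1L]] <- e
    }
  }
  edges <- if (length(edges) > 0L) do.call(rbind, edges) else
    data.frame(key_a = character(), key_b = character(), kind = character(),
               atom_a = character(), atom_b = character(),
               distance = numeric())
  at <- criteria_atoms(model, criteria)
  nodes <- residue_table(at, intersect(unique(residue_key_of(at)),
                                       node_keys))
  structure(list(focal = focal, nodes = nodes, edges = edges,
                 environment = env, criteria = criteria, rules = rules),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network> focal %s: %d nodes, %d edges\n",
              x$focal, nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Summarize an interaction network
#'
#' @param net an `interaction_network` from [build_network()].
#' @return list with `n_nodes`, `n_edges`, per-kind edge counts
#'   (`counts`), and `focal_degree` (edges incident to the focal residue).
#' @export
network_summary <- function(net) {
  kinds <- c("ionic", "hbond", "hydrophobic", "vdw", "generic")
  counts <- setNames(integer(length(kinds)), kinds)
  if (nrow(net$edges) > 0L) {
    tb <- table(factor(net$edges$kind, levels = kinds))
    counts[names(tb)] <- as.integer(tb)
  }
  list(n_nodes = nrow(net$nodes), n_edges = nrow(net$edges),
       counts = counts,
       focal_degree = sum(net$edges$key_a == net$focal |
                            net$edges$key_b == net$focal))
}
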