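# --- internal-coordinate side-chain builder ---------------------------------
#
# Side chains are generated from ideal internal coordinates (bond length,
# bond angle, dihedral) relative to the backbone frame N-CA-C, by the
# standard NeRF placement. This is a deliberately SIMPLIFIED rigid-template
# builder: no rotamer search, no repacking, no energy minimization. Mutant
# contact counts derived from it are rigid-template estimates.

# place atom D given positions A, B, C and internal coordinates of D w.r.t.
# the chain A-B-C (bond C-D, angle B-C-D, dihedral A-B-C-D)
nerf_place <- function(A, B, C, bond, angle_deg, dihedral_deg) {
  ang <- angle_deg * pi / 180
  dih <- dihedral_deg * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  n <- pracma_cross(B - A, bc)
  n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(dih),
          bond * sin(ang) * sin(dih))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# z-matrix rows: atom, ref1, ref2, ref3 (placement chain ref1-ref2-ref3 ->
# atom), bond (A), angle (deg), dihedral (deg). CB is defined for every
# non-GLY residue from the C-N-CA chain; chi dihedrals default to trans.
.sidechain_zmat <- local({
  z <- function(...) {
    m <- matrix(c(...), ncol = 7, byrow = TRUE)
    data.frame(atom = m[, 1], r1 = m[, 2], r2 = m[, 3], r3 = m[, 4],
               bond = as.numeric(m[, 5]), angle = as.numeric(m[, 6]),
               dihedral = as.numeric(m[, 7]), stringsAsFactors = FALSE)
  }
  cb <- c("CB", "C", "N", "CA", "1.530", "110.5", "-122.6")
  list(
    GLY = data.frame(atom = character(), r1 = character(),
                     r2 = character(), r3 = character(), bond = numeric(),
                     angle = numeric(), dihedral = numeric(),
                     stringsAsFactors = FALSE),
    ALA = z(cb),
    SER = z(cb, "OG",  "N", "CA", "CB", "1.417", "110.8", "180"),
    CYS = z(cb, "SG",  "N", "CA", "CB", "1.808", "113.8", "180"),
    THR = z(cb, "OG1", "N", "CA", "CB", "1.433", "109.6", "180",
                "CG2", "N", "CA", "CB", "1.521", "110.5", "-60"),
    VAL = z(cb, "CG1", "N", "CA", "CB", "1.521", "110.5", "180",
                "CG2", "N", "CA", "CB", "1.521", "110.5", "-60"),
    LEU = z(cb, "CG",  "N", "CA", "CB", "1.530", "116.3", "180",
                "CD1", "CA", "CB", "CG", "1.521", "110.7", "180",
                "CD2", "CA", "CB", "CG", "1.521", "110.7", "60"),
    ILE = z(cb, "CG1", "N", "CA", "CB", "1.530", "110.4", "180",
                "CG2", "N", "CA", "CB", "1.521", "110.5", "-60",
                "CD1", "CA", "CB", "CG1", "1.513", "113.8", "180"),
    MET = z(cb, "CG",  "N", "CA", "CB", "1.520", "114.1", "180",
                "SD",  "CA", "CB", "CG", "1.803", "112.7", "180",
                "CE",  "CB", "CG", "SD", "1.791", "100.6", "180"),
    PRO = z(c("CB", "C", "N", "CA", "1.530", "103.0", "-120.0"),
            "CG", "N", "CA", "CB", "1.495", "104.5", "30",
            "CD", "CA", "CB", "CG", "1.507", "105.5", "-35"),
    PHE = z(cb, "CG",  "N", "CA", "CB", "1.502", "113.8", "180",
                "CD1", "CA", "CB", "CG", "1.384", "120.8", "90",
                "CD2", "CA", "CB", "CG", "1.384", "120.8", "-90",
                "CE1", "CB", "CG", "CD1", "1.382", "120.8", "180",
                "CE2", "CB", "CG", "CD2", "1.382", "120.8", "180",
                "CZ",  "CG", "CD1", "CE1", "1.372", "120.1", "0"),
    TYR = z(cb, "CG",  "N", "CA", "CB", "1.512", "113.9", "180",
                "CD1", "CA", "CB", "CG", "1.389", "120.8", "90",
                "CD2", "CA", "CB", "CG", "1.389", "120.8", "-90",
                "CE1", "CB", "CG", "CD1", "1.382", "121.1", "180",
                "CE2", "CB", "CG", "CD2", "1.382", "121.1", "180",
                "CZ",  "CG", "CD1", "CE1", "1.378", "119.5", "0",
                "OH",  "CD1", "CE1", "CZ", "1.376", "119.8", "180"),
    TRP = z(cb, "CG",  "N", "CA", "CB", "1.498", "113.6", "180",
                "CD1", "CA", "CB", "CG", "1.365", "126.9", "90",
                "CD2", "CA", "CB", "CG", "1.433", "126.7", "-90",
                "NE1", "CB", "CG", "CD1", "1.374", "110.2", "180",
                "CE2", "CB", "CG", "CD2", "1.409", "107.2", "180",
                "CE3", "CB", "CG", "CD2", "1.398", "133.9", "0",
                "CZ2", "CG", "CD2", "CE2", "1.394", "122.4", "180",
                "CZ3", "CG", "CD2", "CE3", "1.382", "118.6", "180",
                "CH2", "CD2", "CE2", "CZ2", "1.368", "117.5", "0"),
    HIS = z(cb, "CG",  "N", "CA", "CB", "1.492", "113.8", "180",
                "ND1", "CA", "CB", "CG", "1.380", "122.7", "90",
                "CD2", "CA", "CB", "CG", "1.354", "131.1", "-90",
                "CE1", "CB", "CG", "ND1", "1.326", "109.3", "180",
                "NE2", "CB", "CG", "CD2", "1.373", "107.2", "180"),
    ASP = z(cb, "CG",  "N", "CA", "CB", "1.516", "112.6", "180",
                "OD1", "CA", "CB", "CG", "1.249", "118.4", "0",
                "OD2", "CA", "CB", "CG", "1.249", "118.4", "180"),
    ASN = z(cb, "CG",  "N", "CA", "CB", "1.516", "112.6", "180",
                "OD1", "CA", "CB", "CG", "1.231", "120.8", "0",
                "ND2", "CA", "CB", "CG", "1.328", "116.4", "180"),
    GLU = z(cb, "CG",  "N", "CA", "CB", "1.520", "114.1", "180",
                "CD",  "CA", "CB", "CG", "1.516", "112.6", "180",
                "OE1", "CB", "CG", "CD", "1.249", "118.4", "0",
                "OE2", "CB", "CG", "CD", "1.249", "118.4", "180"),
    GLN = z(cb, "CG",  "N", "CA", "CB", "1.520", "114.1", "180",
                "CD",  "CA", "CB", "CG", "1.516", "112.6", "180",
                "OE1", "CB", "CG", "CD", "1.231", "120.8", "0",
                "NE2", "CB", "CG", "CD", "1.328", "116.4", "180"),
    LYS = z(cb, "CG",  "N", "CA", "CB", "1.520", "114.1", "180",
                "CD",  "CA", "CB", "CG", "1.520", "111.3", "180",
                "CE",  "CB", "CG", "CD", "1.520", "111.3", "180",
                "NZ",  "CG", "CD", "CE", "1.489", "111.9", "180"),
    ARG = z(cb, "CG",  "N", "CA", "CB", "1.520", "114.1", "180",
                "CD",  "CA", "CB", "CG", "1.520", "111.3", "180",
                "NE",  "CB", "CG", "CD", "1.461", "112.0", "180",
                "CZ",  "CG", "CD", "NE", "1.329", "124.2", "180",
                "NH1", "CD", "NE", "CZ", "1.326", "120.0", "0",
                "NH2", "CD", "NE", "CZ", "1.326", "120.0", "180")
  )
})

#' Side-chain template coordinates for a residue type
#'
#' Builds the ideal side-chain atoms of a standard residue from internal
#' coordinates, anchored to the supplied backbone atom positions (N, CA, C).
#' Used by [substitute_residue()]; exported so the template geometry is
#' inspectable.
#'
#' @param aa_name 3-letter residue name (one of the 20 standard residues).
#' @param N,CA,C numeric length-3 backbone atom positions, Angstrom.
#' @return data.frame with `elety`, `element`, `x`, `y`, `z` for the
#'   side-chain atoms (CB onward; empty for GLY).
#' @export
sidechain_template <- function(aa_name,
                               N = c(-0.525, 1.362, 0),
                               CA = c(0, 0, 0),
                               C = c(1.525, 0, 0)) {
  aa_name <- toupper(aa_name)
  zmat <- .sidechain_zmat[[aa_name]]
  if (is.null(zmat))
    stop("no side-chain template for residue '", aa_name,
         "'; available: ", paste(names(.sidechain_zmat), collapse = ", "))
  pos <- list(N = N, CA = CA, C = C)
  if (nrow(zmat) == 0L)
    return(data.frame(elety = character(), element = character(),
                      x = numeric(), y = numeric(), z = numeric()))
  for (k in seq_len(nrow(zmat))) {
    pos[[zmat$atom[k]]] <- nerf_place(pos[[zmat$r1[k]]], pos[[zmat$r2[k]]],
                                      pos[[zmat$r3[k]]], zmat$bond[k],
                                      zmat$angle[k], zmat$dihedral[k])
  }
  nm <- zmat$atom
  xyz <- do.call(rbind, pos[nm])
  data.frame(elety = nm, element = substr(nm, 1, 1),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

#' Specify a point mutation
#'
#' @param chain_id chain identifier.
#' @param number author residue number.
#' @param to_aa target residue, 3-letter code.
#' @param from_aa expected current residue (3-letter) or `NULL` to skip the
#'   guard; supplying it protects against residue-numbering drift.
#' @param icode insertion code (`""` when absent).
#' @return list of class `mutation_spec`.
#' @export
mutation_spec <- function(chain_id, number, to_aa, from_aa = NULL,
                          icode = "") {
  to_aa <- toupper(to_aa)
  if (!to_aa %in% names(.sidechain_zmat))
    stop("'", to_aa, "' is not a standard residue")
  structure(list(chain_id = chain_id, number = as.integer(number),
                 icode = icode, from_aa = if (is.null(from_aa)) NULL else
                   toupper(from_aa), to_aa = to_aa),
            class = "mutation_spec")
}

#' In-place point substitution of one residue
#'
#' Replaces the side chain of one residue with the ideal rigid template of
#' the target residue. Backbone atoms (N, CA, C, O, and CB when both source
#' and target have one) keep their original coordinates bit-exactly; all
#' other residues are untouched. No repacking or energy minimization is
#' performed: downstream contact comparisons are rigid-template estimates,
#' and the output model id records this.
#'
#' @param model a [structure_model()].
#' @param spec a [mutation_spec()].
#' @return The mutated [structure_model()].
#' @export
substitute_residue <- function(model, spec) {
  stopifnot(inherits(model, "struct_model"), inherits(spec, "mutation_spec"))
  rows <- residue_rows(model, list(chain = spec$chain_id,
                                   resno = spec$number, icode = spec$icode))
  if (length(rows) == 0L)
    stop("residue ", format_residue_key(spec$chain_id, spec$number,
                                        spec$icode), " not found")
  a <- model$atoms
  res <- a[rows, , drop = FALSE]
  found <- res$resid[1]
  if (!is.null(spec$from_aa) && found != spec$from_aa)
    stop("expected ", spec$from_aa, " at ",
         format_residue_key(spec$chain_id, spec$number, spec$icode),
         " but found ", found)
  bb_need <- c("N", "CA", "C")
  if (!all(bb_need %in% res$elety))
    stop("missing backbone atom(s) ",
         paste(setdiff(bb_need, res$elety), collapse = ", "),
         " at the mutation site")
  keep_names <- c("N", "CA", "C", "O", "OXT")
  tmpl_atoms <- .sidechain_zmat[[spec$to_aa]]$atom
  # CB is shared whenever both source and target residues have one
  if ("CB" %in% res$elety && "CB" %in% tmpl_atoms)
    keep_names <- c(keep_names, "CB")
  kept <- res[res$elety %in% keep_names, , drop = FALSE]
  at_pos <- function(nm) as.numeric(res[match(nm, res$elety),
                                        c("x", "y", "z")])
  tmpl <- sidechain_template(spec$to_aa, N = at_pos("N"), CA = at_pos("CA"),
                             C = at_pos("C"))
  tmpl <- tmpl[!tmpl$elety %in% kept$elety, , drop = FALSE]
  new_side <- if (nrow(tmpl) > 0L) data.frame(
    chain = spec$chain_id, resno = spec$number, icode = spec$icode,
    resid = spec$to_aa, elety = tmpl$elety, element = tmpl$element,
    x = tmpl$x, y = tmpl$y, z = tmpl$z, occ = 1, altloc = "",
    het = FALSE, water = FALSE, hydrogen = FALSE,
    stringsAsFactors = FALSE
  ) else kept[0, ]
  kept$resid <- spec$to_aa
  # canonical atom order: backbone, then template side-chain order
  ord_names <- c("N", "CA", "C", "O", "OXT", "CB", tmpl_atoms)
  new_res <- rbind(kept, new_side)
  new_res <- new_res[order(match(new_res$elety, ord_names)), , drop = FALSE]
  before <- a[seq_len(nrow(a)) < min(rows), , drop = FALSE]
  after <- a[seq_len(nrow(a)) > max(rows), , drop = FALSE]
  out <- rbind(before, new_res, after)
  m <- structure_model(out, id = paste0(model$id, "_", found, spec$number,
                                        spec$to_aa, "_rigid_template"),
                       source_format = model$source_format)
  m
}

#' Steric clash report around a residue
#'
#' A sanity check standing in for energy-based relaxation: lists heavy-atom
#' pairs between the focus residue and any other residue closer than
#' `threshold` (strict `<`), sorted ascending.
#'
#' @param model a [structure_model()].
#' @param focus residue key string.
#' @param threshold Angstrom; pairs strictly closer are reported.
#' @param criteria a [contact_criteria()] (atom eligibility).
#' @return data.frame: `atom_focus`, `key_other`, `atom_other`, `distance`.
#' @export
clash_report <- function(model, focus, threshold = 2.5,
                         criteria = contact_criteria()) {
  stopifnot(inherits(model, "struct_model"))
  if (threshold <= 0)
    return(data.frame(atom_focus = character(), key_other = character(),
                      atom_other = character(), distance = numeric()))
  at <- criteria_atoms(model, criteria)
  keys <- residue_key_of(at)
  fa <- at[keys == focus, , drop = FALSE]
  if (nrow(fa) == 0L) stop("focus residue '", focus, "' not found")
  oth <- at[keys != focus, , drop = FALSE]
  pr <- grid_pairs(as.matrix(fa[, c("x", "y", "z")]),
                   as.matrix(oth[, c("x", "y", "z")]), threshold)
  pr <- pr[pr$d < threshold, , drop = FALSE]
  out <- data.frame(atom_focus = fa$elety[pr$i],
                    key_other = residue_key_of(oth)[pr$j],
                    atom_other = oth$elety[pr$j],
                    distance = pr$d, stringsAsFactors = FALSE)
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}
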