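#' Construct a structure model from an atom table
#'
#' A `struct_model` is the coordinate substrate for every geometric stage in
#' the package: a flat atom table plus bookkeeping flags. Residues are
#' addressed by AUTHOR numbering, i.e. the key `(chain, resno, icode)`, which
#' is how positions such as "L95 of the G-beta chain" are referred to in the
#' literature.
#'
#' @param atoms data.frame with columns `chain` (character), `resno`
#'   (integer), `icode` (character, `""` when absent), `resid` (3-letter
#'   residue name), `elety` (atom name), `element` (element symbol), `x`,
#'   `y`, `z` (Angstrom), and optionally `occ` (occupancy, default 1),
#'   `altloc` (default `""`), `het` (HETATM flag, default `FALSE`).
#' @param id label for the model.
#' @param source_format `"pdb"`, `"mmcif"` or `"r"` (built in code).
#'
#' @return An object of class `struct_model`. Water (`HOH`/`WAT`/`DOD`) and
#'   hydrogen/deuterium atoms are flagged, not dropped; distance computations
#'   exclude them by default via [contact_criteria()].
#' @export
structure_model <- function(atoms, id = "model", source_format = "r") {
  need <- c("chain", "resno", "icode", "resid", "elety", "element",
            "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0L)
    stop("atom table is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L)
    stop("no atoms: refusing to build an empty structure model")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$altloc)) atoms$altloc <- ""
  if (is.null(atoms$het)) atoms$het <- FALSE
  atoms$chain  <- as.character(atoms$chain)
  atoms$resno  <- as.integer(atoms$resno)
  atoms$icode  <- as.character(atoms$icode)
  atoms$elety  <- as.character(atoms$elety)
  atoms$resid  <- toupper(as.character(atoms$resid))
  atoms$element <- toupper(as.character(atoms$element))
  if (any(!nzchar(atoms$element)))
    stop("empty element symbol; supply an element for every atom")
  if (any(atoms$occ < 0 | atoms$occ > 1))
    stop("occupancy outside [0, 1]")
  atoms$water <- atoms$resid %in% c("HOH", "WAT", "DOD")
  atoms$hydrogen <- atoms$element %in% c("H", "D")
  rownames(atoms) <- NULL
  structure(
    list(atoms = atoms, id = id, source_format = source_format),
    class = "struct_model"
  )
}

#' @export
print.struct_model <- function(x, ...) {
  a <- x$atoms
  keys <- unique(residue_key_of(a))
  cat(sprintf("<struct_model '%s'> %d atoms, %d residues, chains: %s\n",
              x$id, nrow(a), length(keys),
              paste(unique(a$chain), collapse = " ")))
  invisible(x)
}

# canonical residue key string: "B:95" or "B:95:A" with an insertion code
residue_key_of <- function(atoms) {
  ifelse(nzchar(atoms$icode),
         paste(atoms$chain, atoms$resno, atoms$icode, sep = ":"),
         paste(atoms$chain, atoms$resno, sep = ":"))
}

#' Parse a residue key string
#'
#' Keys look like `"B:95"` or `"B:95:A"` (chain, author residue number,
#' optional insertion code).
#'
#' @param key character scalar.
#' @return list with `chain`, `resno`, `icode`.
#' @export
parse_residue_key <- function(key) {
  parts <- strsplit(as.character(key), ":", fixed = TRUE)[[1]]
  if (length(parts) < 2L || length(parts) > 3L)
    stop("malformed residue key '", key, "'; expected chain:resno[:icode]")
  resno <- suppressWarnings(as.integer(parts[2]))
  if (is.na(resno)) stop("malformed residue key '", key, "': non-integer resno")
  list(chain = parts[1], resno = resno,
       icode = if (length(parts) == 3L) parts[3] else "")
}

#' Format a residue key
#' @param chain chain id
#' @param resno author residue number
#' @param icode insertion code (`""` when absent)
#' @return character key, e.g. `"B:95"`.
#' @export
format_residue_key <- function(chain, resno, icode = "") {
  ifelse(nzchar(icode), paste(chain, resno, icode, sep = ":"),
         paste(chain, resno, sep = ":"))
}

# rows of model$atoms belonging to one residue key (list or string form)
residue_rows <- function(model, key) {
  k <- if (is.character(key)) parse_residue_key(key) else key
  a <- model$atoms
  which(a$chain == k$chain & a$resno == k$resno & a$icode == k$icode)
}

# resolve altlocs: per (residue, atom name) keep the conformer with the
# highest occupancy, ties broken by the lexicographically smallest altloc
resolve_altloc <- function(atoms) {
  if (all(!nzchar(atoms$altloc))) return(atoms)
  grp <- paste(residue_key_of(atoms), atoms$elety, sep = "|")
  ord <- order(grp, -atoms$occ, atoms$altloc)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(grp[ord]), , drop = FALSE]
  atoms[order(as.integer(rownames(atoms))), , drop = FALSE]
}

from_bio3d <- function(pdb, id, source_format) {
  a <- pdb$atom
  ins <- a$insert; ins[is.na(ins)] <- ""
  alt <- a$alt;    alt[is.na(alt)] <- ""
  ele <- a$elesy;  ele[is.na(ele)] <- ""
  occ <- a$o;      occ[is.na(occ)] <- 1
  # fall back to the first letter of the atom name when the element column
  # is blank (common in minimal or hand-written PDB files)
  blank <- !nzchar(ele)
  ele[blank] <- sub("^[0-9]*", "", a$elety[blank])
  ele[blank] <- substr(ele[blank], 1L, 1L)
  ch <- a$chain; ch[is.na(ch)] <- " "
  atoms <- data.frame(
    chain = ch, resno = a$resno, icode = ins, resid = a$resid,
    elety = a$elety, element = ele, x = a$x, y = a$y, z = a$z,
    occ = pmin(pmax(occ, 0), 1), altloc = alt,
    het = a$type == "HETATM", stringsAsFactors = FALSE
  )
  atoms <- resolve_altloc(atoms)
  atoms$altloc <- ""
  structure_model(atoms, id = id, source_format = source_format)
}

#' Read a macromolecular structure (PDB or mmCIF)
#'
#' Loads every ATOM/HETATM record. Alternate locations are resolved per atom
#' to the highest-occupancy conformer (ties: lexicographically smallest
#' altloc). Waters and hydrogens are kept but flagged, so downstream distance
#' stages can exclude them (the default). Only the first model of a
#' multi-model (NMR-style) file is used, with a warning.
#'
#' @param path file path.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by file extension;
#'   `.cif`/`.mmcif` is mmCIF, anything else PDB).
#' @return A [structure_model()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "mmcif")
      suppressWarnings(bio3d::read.cif(path, multi = FALSE))
    else
      suppressWarnings(bio3d::read.pdb(path, multi = FALSE,
                                       rm.alt = FALSE)),
    error = function(e)
      stop("could not parse ", path, " as ", format, ": ",
           conditionMessage(e), call. = FALSE)
  )
  if (is.null(pdb$atom) || nrow(pdb$atom) == 0L)
    stop("no atoms found in ", path)
  if (!is.null(pdb$xyz) && is.matrix(unclass(pdb$xyz)) &&
      nrow(unclass(pdb$xyz)) > 1L)
    warning("multi-model file: using the first model only")
  from_bio3d(pdb, id = sub("\\.[^.]*$", "", basename(path)),
             source_format = format)
}

#' Write a structure model as PDB text
#'
#' Round-trips with [read_structure()]: residue keys are preserved exactly
#' and coordinates to the PDB format precision (1e-3 Angstrom).
#'
#' @param model a [structure_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "struct_model"))
  a <- model$atoms
  if (nrow(a) == 0L) stop("refusing to write an empty model")
  if (any(a$resno > 9999L | a$resno < -999L))
    stop("residue number outside the PDB fixed-column range (-999..9999)")
  ins <- a$icode; ins[!nzchar(ins)] <- ""
  bio3d::write.pdb(
    pdb = NULL, file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = ifelse(a$het, "HETATM", "ATOM"),
    resno = a$resno, resid = a$resid, eleno = seq_len(nrow(a)),
    elety = a$elety, chain = a$chain, insert = ins,
    o = a$occ, b = rep(0, nrow(a)), elesy = a$element
  )
  invisible(path)
}

#' Restrict a model to chains and atom classes
#'
#' Isolates e.g. the G-beta-gamma chains versus the channel chains before an
#' interface computation. By default waters, hydrogens and non-water hetero
#' groups are dropped, matching the package-wide convention that contact
#' counting is over amino-acid heavy atoms.
#'
#' @param model a [structure_model()].
#' @param chain_ids character vector of chain ids to keep; `NULL` keeps all.
#' @param include_hetero keep non-water HETATM groups (ligands, ions)?
#' @param include_waters keep water residues?
#' @param include_hydrogens keep hydrogen/deuterium atoms?
#' @return A restricted [structure_model()].
#' @export
select_structure <- function(model, chain_ids = NULL, include_hetero = FALSE,
                             include_waters = FALSE,
                             include_hydrogens = FALSE) {
  stopifnot(inherits(model, "struct_model"))
  a <- model$atoms
  if (!is.null(chain_ids)) {
    unknown <- setdiff(chain_ids, unique(a$chain))
    if (length(unknown) > 0L)
      stop("unknown chain id(s): ", paste(unknown, collapse = ", "),
           "; available: ", paste(unique(a$chain), collapse = ", "))
    a <- a[a$chain %in% chain_ids, , drop = FALSE]
  }
  if (!include_waters)    a <- a[!a$water, , drop = FALSE]
  if (!include_hydrogens) a <- a[!a$hydrogen, , drop = FALSE]
  if (!include_hetero)    a <- a[!a$het | a$water, , drop = FALSE]
  if (nrow(a) == 0L) stop("selection removed every atom")
  structure_model(a, id = model$id, source_format = model$source_format)
}

# atoms eligible for distance computations under the given criteria
criteria_atoms <- function(model, criteria) {
  a <- model$atoms
  keep <- rep(TRUE, nrow(a))
  if (isTRUE(criteria$heavy_atoms_only)) keep <- keep & !a$hydrogen
  if (isTRUE(criteria$exclude_waters))   keep <- keep & !a$water
  if (!isTRUE(criteria$include_hetero))  keep <- keep & (!a$het | a$water)
  a[keep, , drop = FALSE]
}
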