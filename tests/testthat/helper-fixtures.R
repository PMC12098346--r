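# Hand-built miniature structures for unit tests.

# a residue from explicit atom placements: pos is a named list of
# length-3 coordinates, names are atom labels
hand_residue <- function(chain, resno, resid, pos, icode = "",
                         het = FALSE) {
  nm <- names(pos)
  xyz <- do.call(rbind, pos)
  data.frame(chain = chain, resno = resno, icode = icode, resid = resid,
             elety = nm, element = substr(sub("^[0-9]+", "", nm), 1, 1),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], het = het,
             stringsAsFactors = FALSE)
}

# standard backbone + CB around a center, axis-aligned
hand_ala <- function(chain, resno, center, resid = "ALA", icode = "") {
  c0 <- center
  hand_residue(chain, resno, resid, icode = icode, pos = list(
    N = c0 + c(-0.5, 1.4, 0), CA = c0, C = c0 + c(1.5, 0, 0),
    O = c0 + c(2.1, 1.1, 0), CB = c0 + c(-0.6, -1.2, 0.8)))
}

# two chains whose nearest heavy atoms are ~separation apart along x
two_chain_model <- function(separation = 10) {
  atoms <- rbind(hand_ala("A", 1, c(0, 0, 0)),
                 hand_ala("A", 2, c(0, 8, 0)),
                 hand_ala("B", 1, c(separation + 3, 0, 0)),
                 hand_ala("B", 2, c(separation + 3, 8, 0)))
  structure_model(atoms, id = "two_chain")
}
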