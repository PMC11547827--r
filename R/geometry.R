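# Coarse ideal-geometry builders. Downstream analyses only need
# self-consistent coordinates with controlled contacts, not refined
# stereochemistry, so residues are laid out with near-ideal backbone
# spacing (3.8 A CA-CA) and schematic zigzag side chains.

# heavy side-chain atoms beyond the backbone, in growth order
SIDE_ATOMS <- list(
  GLY = character(0),
  ALA = "CB",
  VAL = c("CB", "CG1", "CG2"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  PRO = c("CB", "CG", "CD"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  MET = c("CB", "CG", "SD", "CE"),
  SER = c("CB", "OG"),
  THR = c("CB", "OG1", "CG2"),
  CYS = c("CB", "SG"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  ASN = c("CB", "CG", "OD1", "ND2"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  ASP = c("CB", "CG", "OD1", "OD2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"))

side_chain_offsets <- function(n) {
  # zigzag growing along +z from CB; CB itself is offset 0
  if (n == 0L) return(matrix(numeric(0), 0, 3))
  out <- matrix(0, n, 3)
  for (j in seq_len(n)) {
    if (j == 1L) next
    out[j, ] <- c(0, 0.75 * ifelse(j %% 2 == 0, 1, -1), 1.25 * (j - 1))
  }
  out
}

residue_atom_block <- function(res3, res_id, chain_id, n_pos, ca_pos, c_pos,
                               o_pos, side_dir = c(0, 0, 1),
                               side_lat = c(0, 1, 0)) {
  names_bb <- c("N", "CA", "C", "O")
  xyz <- rbind(n_pos, ca_pos, c_pos, o_pos)
  side <- SIDE_ATOMS[[res3]]
  if (is.null(side)) stop("no template for residue ", res3, call. = FALSE)
  if (length(side) > 0) {
    cb <- ca_pos + 1.53 * side_dir
    off <- side_chain_offsets(length(side))
    sxyz <- t(apply(off, 1, function(o)
      cb + o[2] * side_lat + o[3] * side_dir))
    xyz <- rbind(xyz, sxyz)
  }
  nm <- c(names_bb, side)
  data.frame(serial = seq_along(nm), name = nm,
             res_name = res3, chain = chain_id,
             auth_seq = res_id, res_id = res_id,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             element = guess_element(nm), het = FALSE,
             stringsAsFactors = FALSE)
}

#' Build an extended chain from a one-letter sequence
#'
#' Backbone runs along +x (or -x when `reverse`), side chains point along
#' `side_dir`. Schematic ideal geometry; intended for toy complexes and as
#' a start point for ring relaxation.
#'
#' @param seq one-letter sequence string.
#' @param chain_id chain id.
#' @param origin 3-vector origin of the first residue's N.
#' @param reverse build antiparallel (along -x).
#' @param side_dir unit 3-vector for side-chain growth.
#' @return a `molstruct` with one chain.
#' @export
build_extended_chain <- function(seq, chain_id = "A", origin = c(0, 0, 0),
                                 reverse = FALSE, side_dir = c(0, 0, 1)) {
  aa <- strsplit(seq, "")[[1]]
  stopifnot(length(aa) >= 1L)
  dirx <- if (reverse) c(-1, 0, 0) else c(1, 0, 0)
  blocks <- list()
  for (i in seq_along(aa)) {
    res3 <- aa_one_to_three(aa[i])
    if (res3 == "UNK") stop("unknown residue code: ", aa[i], call. = FALSE)
    base <- origin + (i - 1) * 3.8 * dirx
    yoff <- 0.4 * ifelse(i %% 2 == 0, 1, -1)   # slight backbone pleat
    blocks[[i]] <- residue_atom_block(
      res3, i, chain_id,
      n_pos = base + c(0, yoff, 0),
      ca_pos = base + 1.46 * dirx + c(0, yoff, 0),
      c_pos = base + 2.47 * dirx + c(0, yoff, 0),
      o_pos = base + 2.47 * dirx + c(0, yoff + 1.23, 0),
      side_dir = side_dir)
  }
  atoms <- do.call(rbind, blocks)
  atoms$serial <- seq_len(nrow(atoms))
  new_molstruct(atoms, source_tag = sprintf("built:%s", chain_id))
}

#' Build a head-to-tail ring from a one-letter sequence
#'
#' Residues are placed on a circle in the xy-plane with 3.8 A of arc per
#' residue and the backbone N/CA/C at arc offsets 0/1.46/2.47, so the
#' closing C(n)->N(1) gap is ~1.33 A by construction; side chains grow
#' outward along +z.
#'
#' @param seq one-letter sequence string (>= 3 residues).
#' @param chain_id chain id.
#' @return a `molstruct` ring.
#' @export
build_ring_chain <- function(seq, chain_id = "P") {
  aa <- strsplit(seq, "")[[1]]
  n <- length(aa)
  stopifnot(n >= 3L)
  circ <- 3.8 * n
  R <- circ / (2 * pi)
  at_arc <- function(s, radius = R, z = 0) {
    th <- 2 * pi * s / circ
    c(radius * cos(th), radius * sin(th), z)
  }
  blocks <- list()
  for (i in seq_along(aa)) {
    res3 <- aa_one_to_three(aa[i])
    if (res3 == "UNK") stop("unknown residue code: ", aa[i], call. = FALSE)
    s0 <- (i - 1) * 3.8
    th <- 2 * pi * (s0 + 1.46) / circ
    radial <- c(cos(th), sin(th), 0)
    blocks[[i]] <- residue_atom_block(
      res3, i, chain_id,
      n_pos = at_arc(s0),
      ca_pos = at_arc(s0 + 1.46),
      c_pos = at_arc(s0 + 2.47),
      o_pos = at_arc(s0 + 2.47, radius = R + 1.23),
      side_dir = c(0, 0, 1), side_lat = radial)
  }
  atoms <- do.call(rbind, blocks)
  atoms$serial <- seq_len(nrow(atoms))
  new_molstruct(atoms, source_tag = sprintf("ring:%s", chain_id))
}
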