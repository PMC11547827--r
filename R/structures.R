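#' @useDynLib pepcycle, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd median coef nls optim setNames uniroot dist
#' @importFrom utils read.csv write.csv head tail
NULL

# three-letter <-> one-letter residue code tables (20 standard amino acids)
AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
         GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
         LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
         SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
AA1 <- setNames(names(AA3), unname(AA3))

#' Convert residue codes
#'
#' @param x character vector of three-letter (`aa_three_to_one`) or
#'   one-letter (`aa_one_to_three`) residue codes.
#' @return character vector of converted codes; `"X"` / `"UNK"` for
#'   nonstandard residues.
#' @export
aa_three_to_one <- function(x) {
  out <- AA3[toupper(x)]
  out[is.na(out)] <- "X"
  unname(out)
}

#' @rdname aa_three_to_one
#' @export
aa_one_to_three <- function(x) {
  out <- AA1[toupper(x)]
  out[is.na(out)] <- "UNK"
  unname(out)
}

guess_element <- function(atom_name) {
  nm <- gsub("[^A-Za-z]", "", atom_name)
  # two-letter elements occurring in proteins/ligands we care about
  first <- toupper(substr(nm, 1, 1))
  ifelse(first %in% c("C", "N", "O", "S", "H", "P"), first,
         toupper(substr(nm, 1, 2)))
}

new_molstruct <- function(atoms, source_tag = "") {
  stopifnot(is.data.frame(atoms))
  atoms$is_heavy <- atoms$element != "H"
  s <- list(atoms = atoms, source_tag = source_tag)
  class(s) <- "molstruct"
  s
}

#' @export
print.molstruct <- function(x, ...) {
  ch <- chain_ids(x)
  nres <- vapply(ch, function(cc)
    length(unique(x$atoms$res_id[x$atoms$chain == cc])), integer(1))
  cat(sprintf("<molstruct> %d atoms, %d chain(s): %s\n",
              nrow(x$atoms), length(ch),
              paste(sprintf("%s(%d res)", ch, nres), collapse = ", ")))
  invisible(x)
}

#' Chain identifiers of a structure
#' @param s a `molstruct`.
#' @return character vector of chain ids in order of first appearance.
#' @export
chain_ids <- function(s) unique(s$atoms$chain)

#' One-letter sequence of one chain
#' @param s a `molstruct`.
#' @param chain chain id.
#' @return single string of one-letter codes.
#' @export
chain_sequence <- function(s, chain) {
  a <- s$atoms[s$atoms$chain == chain & !s$atoms$het, , drop = FALSE]
  if (nrow(a) == 0L) return("")
  res <- a[!duplicated(a$res_id), , drop = FALSE]
  res <- res[order(res$res_id), , drop = FALSE]
  paste(aa_three_to_one(res$res_name), collapse = "")
}

parse_pdb_atom_lines <- function(lines, lineno, path) {
  # fixed-width PDB v3.3 coordinate record layout
  num <- function(txt, what, ln) {
    v <- suppressWarnings(as.numeric(txt))
    bad <- is.na(v) & nzchar(trimws(txt))
    bad <- bad | !nzchar(trimws(txt))
    if (any(bad))
      stop(sprintf("malformed %s field in '%s' at line %d", what,
                   basename(path), ln[bad][1]), call. = FALSE)
    v
  }
  rec    <- substr(lines, 1, 6)
  serial <- suppressWarnings(as.integer(trimws(substr(lines, 7, 11))))
  serial[is.na(serial)] <- seq_along(lines)[is.na(serial)]
  name   <- trimws(substr(lines, 13, 16))
  altloc <- substr(lines, 17, 17)
  resn   <- trimws(substr(lines, 18, 20))
  chain  <- substr(lines, 22, 22)
  chain[chain == " "] <- "A"
  seqn   <- suppressWarnings(as.integer(trimws(substr(lines, 23, 26))))
  if (any(is.na(seqn)))
    stop(sprintf("malformed residue number in '%s' at line %d",
                 basename(path), lineno[is.na(seqn)][1]), call. = FALSE)
  icode  <- substr(lines, 27, 27)
  x <- num(substr(lines, 31, 38), "x-coordinate", lineno)
  y <- num(substr(lines, 39, 46), "y-coordinate", lineno)
  z <- num(substr(lines, 47, 54), "z-coordinate", lineno)
  elem <- toupper(trimws(substr(lines, 77, 78)))
  elem[!nzchar(elem)] <- guess_element(name[!nzchar(elem)])
  data.frame(serial = serial, name = name, altloc = altloc,
             res_name = resn, chain = chain, auth_seq = seqn,
             icode = icode, x = x, y = y, z = z, element = elem,
             het = rec == "HETATM",
             stringsAsFactors = FALSE)
}

#' Read a PDB coordinate file
#'
#' Parses ATOM and HETATM records of the first MODEL block (use
#' [read_ensemble()] for all models). Alternate locations other than
#' blank/'A' are dropped; insertion codes are collapsed into a sequential
#' 1-based `res_id` per chain while the author numbering is kept in
#' `auth_seq`.
#'
#' @param path path to a PDB file.
#' @return a `molstruct`: list with `atoms` data frame (columns `serial`,
#'   `name`, `res_name`, `chain`, `res_id`, `auth_seq`, `x`, `y`, `z`,
#'   `element`, `het`, `is_heavy`) and `source_tag`.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L)
    stop("empty PDB file: ", path, call. = FALSE)
  # keep only first MODEL
  m_start <- grep("^MODEL", lines)
  if (length(m_start) > 1L) {
    m_end <- grep("^ENDMDL", lines)
    if (length(m_end) >= 1L) lines <- lines[seq_len(m_end[1])]
  }
  sel <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(sel))
    stop("no ATOM records in ", path, call. = FALSE)
  atoms <- parse_pdb_atom_lines(lines[sel], which(sel), path)
  atoms <- atoms[atoms$altloc %in% c(" ", "", "A"), , drop = FALSE]
  atoms$altloc <- NULL
  atoms <- assign_sequential_res_id(atoms)
  new_molstruct(atoms, source_tag = basename(path))
}

assign_sequential_res_id <- function(atoms) {
  atoms$res_id <- NA_integer_
  for (cc in unique(atoms$chain)) {
    idx <- which(atoms$chain == cc)
    key <- paste(atoms$auth_seq[idx], atoms$icode[idx], atoms$res_name[idx])
    atoms$res_id[idx] <- match(key, unique(key))
  }
  atoms$icode <- NULL
  atoms
}

#' Write a structure as a PDB file
#'
#' Standard ATOM/HETATM records with 3-decimal coordinates and TER records
#' between chains.
#'
#' @param s a `molstruct`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write: ", path,
                                           call. = FALSE))
  on.exit(close(con))
  writeLines(format_pdb_lines(s), con)
  invisible(path)
}

format_pdb_lines <- function(s) {
  a <- s$atoms
  out <- character(0)
  serial <- 0L
  for (cc in chain_ids(s)) {
    ai <- a[a$chain == cc, , drop = FALSE]
    for (i in seq_len(nrow(ai))) {
      serial <- serial + 1L
      nm <- ai$name[i]
      # atom-name column convention: element right-aligned into cols 13-14
      nm_fmt <- if (nchar(nm) < 4L) sprintf(" %-3s", nm) else nm
      out <- c(out, sprintf(
        "%-6s%5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        if (ai$het[i]) "HETATM" else "ATOM", serial, nm_fmt,
        ai$res_name[i], cc, ai$auth_seq[i],
        ai$x[i], ai$y[i], ai$z[i], 1, 0, ai$element[i]))
    }
    out <- c(out, "TER")
  }
  c(out, "END")
}

#' Select chains from a structure
#'
#' @param s a `molstruct`.
#' @param ids character vector of chain ids; all must exist.
#' @return a `molstruct` containing exactly the named chains, input chain
#'   order preserved.
#' @export
select_chains <- function(s, ids) {
  avail <- chain_ids(s)
  missing <- setdiff(ids, avail)
  if (length(missing) > 0L)
    stop(sprintf("unknown chain id(s) %s; available: %s",
                 paste(missing, collapse = ","),
                 paste(avail, collapse = ",")), call. = FALSE)
  keep <- avail[avail %in% ids]
  atoms <- s$atoms[s$atoms$chain %in% keep, , drop = FALSE]
  atoms$chain <- factor(atoms$chain, levels = keep)
  atoms <- atoms[order(atoms$chain), , drop = FALSE]
  atoms$chain <- as.character(atoms$chain)
  rownames(atoms) <- NULL
  new_molstruct(atoms, source_tag = s$source_tag)
}

#' Extract a (possibly spliced) fragment of one chain
#'
#' Residues from the listed `res_id` intervals are concatenated in interval
#' order into a single new chain renumbered from 1 — the sequence-level
#' analogue of truncating a peptide out of a larger protein, including
#' non-contiguous splices.
#'
#' @param s a `molstruct`.
#' @param chain chain id to cut from.
#' @param ranges list of 2-vectors `c(start, end)` in sequential `res_id`
#'   numbering (a single 2-vector is accepted).
#' @param new_chain chain id for the output fragment (default `"P"`).
#' @return list with `structure` (the fragment as a `molstruct`) and
#'   `sequence` (its one-letter sequence).
#' @export
extract_fragment <- function(s, chain, ranges, new_chain = "P") {
  if (!chain %in% chain_ids(s))
    stop("unknown chain: ", chain, call. = FALSE)
  if (is.numeric(ranges)) ranges <- list(ranges)
  a <- s$atoms[s$atoms$chain == chain & !s$atoms$het, , drop = FALSE]
  max_id <- max(a$res_id)
  parts <- list()
  for (r in ranges) {
    stopifnot(length(r) == 2L)
    if (r[1] > r[2] || r[1] < 1L || r[2] > max_id)
      stop(sprintf("interval [%d,%d] outside chain %s (1..%d)",
                   r[1], r[2], chain, max_id), call. = FALSE)
    parts[[length(parts) + 1L]] <-
      a[a$res_id >= r[1] & a$res_id <= r[2], , drop = FALSE]
  }
  frag <- do.call(rbind, parts)
  # renumber residues 1..n in listed order
  old <- unlist(lapply(parts, function(p) unique(p$res_id)))
  frag$res_id <- match(frag$res_id, old)
  # careful: duplicated res_id across intervals is an error of the caller
  frag$auth_seq <- frag$res_id
  frag$chain <- new_chain
  frag <- frag[order(frag$res_id), , drop = FALSE]
  rownames(frag) <- NULL
  out <- new_molstruct(frag, source_tag = paste0(s$source_tag, ":frag"))
  list(structure = out, sequence = chain_sequence(out, new_chain))
}

#' Coordinate matrix of a structure
#' @param s a `molstruct`.
#' @param heavy_only keep heavy atoms only.
#' @return numeric n x 3 matrix.
#' @export
coords <- function(s, heavy_only = FALSE) {
  a <- s$atoms
  if (heavy_only) a <- a[a$is_heavy, , drop = FALSE]
  m <- as.matrix(a[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

set_coords <- function(s, xyz) {
  stopifnot(nrow(xyz) == nrow(s$atoms))
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}
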