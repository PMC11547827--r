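# Design layer: truncation candidates over key residues, head-to-tail
# GP (amide) / CC (disulfide) cyclization, the R1/alpha_GP/CCX naming
# scheme, enumeration, and 3-D ring building.

ALPHA <- "\u03b1"

#' Linear peptide candidate
#'
#' @param sequence one-letter sequence.
#' @param source `"R1"` (receptor-derived) or `"alpha"` (ligand-derived).
#' @param serial user-assigned serial number (>= 0; 0 is reserved for
#'   literature controls).
#' @param region free-text region label.
#' @param ranges list of source `res_id` intervals the sequence was cut
#'   from (optional).
#' @param key_covered number of key residues covered (optional).
#' @param external_control literature-control flag.
#' @return a `linear_candidate`.
#' @export
linear_candidate <- function(sequence, source = c("R1", "alpha"),
                             serial = 0L, region = "", ranges = NULL,
                             key_covered = NA_integer_,
                             external_control = FALSE) {
  source <- match.arg(source)
  stopifnot(nchar(sequence) >= 1L, serial >= 0L)
  if (!is.null(ranges)) {
    len <- sum(vapply(ranges, function(r) r[2] - r[1] + 1L, numeric(1)))
    if (len != nchar(sequence))
      stop("sequence length does not match interval lengths", call. = FALSE)
  }
  structure(list(sequence = toupper(sequence), source = source,
                 serial = as.integer(serial), region = region,
                 ranges = ranges, key_covered = key_covered,
                 external_control = external_control),
            class = "linear_candidate")
}

#' The packaged linear peptide candidates
#'
#' The 11 truncation candidates (7 receptor-derived, 4 ligand-derived)
#' plus two literature-control sequences flagged `external_control`.
#'
#' @param include_controls include the two serial-0 controls (FALSE).
#' @return list of `linear_candidate` objects.
#' @export
packaged_candidates <- function(include_controls = FALSE) {
  path <- system.file("extdata", "peptide_sequences.csv",
                      package = "pepcycle", mustWork = TRUE)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!include_controls) tab <- tab[!tab$external_control, , drop = FALSE]
  lapply(seq_len(nrow(tab)), function(i)
    linear_candidate(tab$sequence[i], tab$source[i], tab$serial[i],
                     tab$region[i],
                     external_control = tab$external_control[i]))
}

#' Propose truncation windows covering key residues
#'
#' Contiguous windows over the chain are ranked by (key residues covered
#' descending, window length ascending, start ascending). Non-contiguous
#' splices are accepted only as explicit user ranges via
#' [extract_fragment()].
#'
#' @param key_residues integer vector of key `res_id`s.
#' @param chain_res_ids integer vector of the chain's available `res_id`s
#'   (assumed contiguous).
#' @param window_lengths integer vector of window lengths to scan.
#' @param top keep the best `top` windows (default all).
#' @return data frame with `start`, `end`, `length`, `covered`, ranked.
#' @export
propose_truncations <- function(key_residues, chain_res_ids,
                                window_lengths, top = Inf) {
  if (length(key_residues) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), covered = integer(0)))
  if (!all(key_residues %in% chain_res_ids))
    stop("key residues outside the chain", call. = FALSE)
  lo <- min(chain_res_ids); hi <- max(chain_res_ids)
  out <- list()
  for (L in window_lengths) {
    if (L > hi - lo + 1L) next
    starts <- lo:(hi - L + 1L)
    covered <- vapply(starts, function(s)
      sum(key_residues >= s & key_residues <= s + L - 1L), integer(1))
    out[[length(out) + 1L]] <-
      data.frame(start = starts, end = starts + L - 1L, length = L,
                 covered = covered)
  }
  res <- do.call(rbind, out)
  res <- res[order(-res$covered, res$length, res$start), , drop = FALSE]
  rownames(res) <- NULL
  head(res, top)
}

#' Cyclize a linear candidate head-to-tail
#'
#' CC strategy: a cysteine is prepended and appended ("C" + base + "C")
#' and the ring closes through a disulfide between residues 1 and n; GP
#' strategy: glycine then proline are appended at the C-terminus and the
#' ring closes through a backbone amide from the proline carboxyl to the
#' residue-1 amine. The full sequence is renumbered from 1.
#'
#' @param candidate a `linear_candidate` or a bare sequence string.
#' @param strategy `"GP"` or `"CC"`.
#' @return a `cyclic_design`: base candidate, strategy, `sequence` (with
#'   added residues), `closure` descriptor, and `name`.
#' @export
cyclize <- function(candidate, strategy = c("GP", "CC")) {
  strategy <- match.arg(strategy)
  if (is.character(candidate)) candidate <- linear_candidate(candidate)
  base <- candidate$sequence
  if (strategy == "CC") {
    if (substr(base, 1, 1) == "C" ||
        substr(base, nchar(base), nchar(base)) == "C")
      warning("terminal cysteine in base sequence: CC cyclization will ",
              "add another; check this is intended")
    full <- paste0("C", base, "C")
    closure <- list(type = "disulfide", atoms = c("SG", "SG"),
                    residues = c(1L, nchar(full)), target = 2.05)
  } else {
    full <- paste0(base, "GP")
    closure <- list(type = "amide", atoms = c("C", "N"),
                    residues = c(nchar(full), 1L), target = 1.33)
  }
  d <- structure(list(base = candidate, strategy = strategy,
                      sequence = full, closure = closure),
                 class = "cyclic_design")
  d$name <- name_design(d)
  d
}

#' @export
print.cyclic_design <- function(x, ...) {
  cat(sprintf("<cyclic_design> %s: %s (%d res, %s closure)\n",
              x$name, x$sequence, nchar(x$sequence), x$closure$type))
  invisible(x)
}

#' Name a cyclic design / parse a design name
#'
#' The scheme is `{R1|α}_{GP|CC}{serial}`: origin (receptor- or
#' ligand-derived), cyclization strategy, serial number.
#'
#' @param d a `cyclic_design`.
#' @return the name string.
#' @export
name_design <- function(d) {
  src <- if (d$base$source == "R1") "R1" else ALPHA
  sprintf("%s_%s%d", src, d$strategy, d$base$serial)
}

#' @rdname name_design
#' @param name a design name like `"R1_CC4"` or `"\u03b1_GP8"` (ASCII
#'   `"a"`/`"alpha"` accepted for the ligand prefix).
#' @return for `parse_design_name`, list with `source`, `strategy`,
#'   `serial`.
#' @export
parse_design_name <- function(name) {
  m <- regmatches(name, regexec(
    paste0("^(R1|", ALPHA, "|a|alpha)_(GP|CC)([0-9]+)$"), name))[[1]]
  if (length(m) != 4L) stop("cannot parse design name: ", name,
                            call. = FALSE)
  list(source = if (m[2] == "R1") "R1" else "alpha",
       strategy = m[3], serial = as.integer(m[4]))
}

#' Enumerate both cyclizations of every candidate
#'
#' @param candidates list of `linear_candidate`s.
#' @return list of `cyclic_design`s, ordered by serial with GP before CC
#'   (2 x input count).
#' @export
enumerate_designs <- function(candidates) {
  if (length(candidates) == 0L) return(list())
  ord <- order(vapply(candidates, `[[`, integer(1), "serial"))
  out <- list()
  for (cand in candidates[ord]) {
    out[[length(out) + 1L]] <- suppressWarnings(cyclize(cand, "GP"))
    out[[length(out) + 1L]] <- suppressWarnings(cyclize(cand, "CC"))
  }
  out
}

closure_atom_indices <- function(s, d) {
  a <- s$atoms
  i1 <- which(a$res_id == d$closure$residues[1] &
                a$name == d$closure$atoms[1])
  i2 <- which(a$res_id == d$closure$residues[2] &
                a$name == d$closure$atoms[2])
  c(i1[1], i2[1])
}

#' Closure-bond residual of a built design
#' @param s built `molstruct` ring.
#' @param d the `cyclic_design`.
#' @return |distance - target| in Angstrom.
#' @export
closure_residual <- function(s, d) {
  ij <- closure_atom_indices(s, d)
  x <- coords(s)
  abs(sqrt(sum((x[ij[1], ] - x[ij[2], ])^2)) - d$closure$target)
}

relax_closure <- function(xyz, i, j, target, movable, steps = 200,
                          step_size = 0.05, trace = FALSE) {
  # steepest descent on (d_ij - target)^2, moving `movable` atoms
  path <- numeric(0)
  for (s in seq_len(steps)) {
    dv <- xyz[i, ] - xyz[j, ]
    dist <- sqrt(sum(dv^2))
    resid <- dist - target
    if (trace) path <- c(path, abs(resid))
    if (abs(resid) < 1e-3) break
    g <- 2 * resid * dv / dist
    if (i %in% movable) xyz[i, ] <- xyz[i, ] - step_size * g
    if (j %in% movable) xyz[j, ] <- xyz[j, ] + step_size * g
  }
  list(xyz = xyz, trace = path)
}

#' Build 3-D coordinates for a cyclic design
#'
#' Without a template the full sequence is laid on a circular backbone
#' (3.8 A of arc per residue) so the ring is closed by construction, then
#' up to 200 steepest-descent steps refine the closure bond (amide C-N
#' 1.33 A, disulfide S-S 2.05 A) by moving the closure atoms. With a
#' template the base residues take the template's coordinates, added
#' residues are grown from the termini, and the same relaxation must pull
#' the closure within tolerance or an error is raised.
#'
#' @param d a `cyclic_design`.
#' @param template optional `molstruct` of the base fragment (single
#'   chain, residues 1..n matching the base sequence).
#' @param chain_id output chain id.
#' @param tol acceptable closure residual (0.2 A).
#' @return a `molstruct`; attributes `"closure_residual"` and
#'   `"closure_trace"` (per-step residuals).
#' @export
build_cyclic_geometry <- function(d, template = NULL, chain_id = "P",
                                  tol = 0.2) {
  if (is.null(template)) {
    s <- build_ring_chain(d$sequence, chain_id)
  } else {
    s <- splice_template_ring(d, template, chain_id)
  }
  ij <- closure_atom_indices(s, d)
  if (anyNA(ij)) stop("closure atoms missing from built ring",
                      call. = FALSE)
  movable <- if (d$closure$type == "disulfide") ij else ij
  rx <- relax_closure(coords(s), ij[1], ij[2], d$closure$target, movable,
                      trace = TRUE)
  s <- set_coords(s, rx$xyz)
  resid <- closure_residual(s, d)
  if (resid > tol)
    stop(sprintf("ring closure failed for %s: residual %.2f A > %.2f A",
                 d$name, resid, tol), call. = FALSE)
  attr(s, "closure_residual") <- resid
  attr(s, "closure_trace") <- rx$trace
  s
}

splice_template_ring <- function(d, template, chain_id) {
  tch <- chain_ids(template)[1]
  tseq <- chain_sequence(template, tch)
  base <- d$base$sequence
  if (tseq != base)
    stop("template sequence does not match the base candidate",
         call. = FALSE)
  # ideal ring for the full sequence, then overwrite base residues with
  # template coordinates superposed CA-wise onto the ring positions
  ring <- build_ring_chain(d$sequence, chain_id)
  off <- if (d$strategy == "CC") 1L else 0L
  ring_ca <- ring$atoms$name == "CA" &
    ring$atoms$res_id %in% (seq_len(nchar(base)) + off)
  tmpl_ca <- template$atoms$name == "CA"
  # map template atoms residue-by-residue into the ring frame
  sp <- superpose(coords(template)[tmpl_ca, , drop = FALSE],
                  coords(ring)[ring_ca, , drop = FALSE])
  txyz <- sp$transform(coords(template))
  a <- ring$atoms
  x <- coords(ring)
  ta <- template$atoms
  for (r in seq_len(nchar(base))) {
    rows_t <- which(ta$res_id == r)
    for (ri in rows_t) {
      tgt <- which(a$res_id == r + off & a$name == ta$name[ri])
      if (length(tgt) == 1L) x[tgt, ] <- txyz[ri, ]
    }
  }
  set_coords(ring, x)
}

#' Write designs as FASTA
#'
#' One record per design; the description line records the cyclization
#' strategy and closure type
#' (`cyclization=GP|CC closure=amide|disulfide`).
#'
#' @param designs list of `cyclic_design`s.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_designs_fasta <- function(designs, path) {
  lines <- unlist(lapply(designs, function(d)
    c(sprintf(">%s cyclization=%s closure=%s", d$name, d$strategy,
              d$closure$type), d$sequence)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read designs from a FASTA written by [write_designs_fasta()]
#' @param path FASTA path.
#' @return list of `cyclic_design`s.
#' @export
read_designs_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  hdr <- grep("^>", lines)
  lapply(seq_along(hdr), function(k) {
    h <- sub("^>", "", lines[hdr[k]])
    name <- strsplit(h, " ")[[1]][1]
    to <- if (k < length(hdr)) hdr[k + 1] - 1L else length(lines)
    seqs <- paste(lines[(hdr[k] + 1L):to], collapse = "")
    info <- parse_design_name(name)
    base <- if (info$strategy == "CC")
      substr(seqs, 2, nchar(seqs) - 1) else substr(seqs, 1, nchar(seqs) - 2)
    suppressWarnings(
      cyclize(linear_candidate(base, info$source, info$serial),
              info$strategy))
  })
}

#' Write a built cyclic structure as PDB with its closure record
#'
#' Disulfide closures get an SSBOND header record.
#'
#' @param s built `molstruct` from [build_cyclic_geometry()].
#' @param d the `cyclic_design`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cyclic_pdb <- function(s, d, path) {
  lines <- format_pdb_lines(s)
  if (d$closure$type == "disulfide") {
    ch <- chain_ids(s)[1]
    ss <- sprintf("SSBOND   1 CYS %s %4d    CYS %s %4d", ch,
                  d$closure$residues[1], ch, d$closure$residues[2])
    lines <- c(ss, lines)
  }
  writeLines(lines, path)
  invisible(path)
}
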