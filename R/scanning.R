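# Computational alanine scanning and virtual point mutation with
# re-scoring. Single-trajectory protocol: mutants are built by side-chain
# truncation/replacement on the existing frames, never re-sampled, so an
# alanine scanned to alanine gives ddG = 0 exactly.

unit3 <- function(v) v / sqrt(sum(v^2))

ideal_cb <- function(n_pos, ca_pos, c_pos) {
  # tetrahedral-ish direction away from the N-CA-C plane bisector
  d <- -(unit3(n_pos - ca_pos) + unit3(c_pos - ca_pos))
  if (sqrt(sum(d^2)) < 1e-6) d <- c(0, 0, 1)
  ca_pos + 1.53 * unit3(d)
}

residue_rows <- function(s, chain, res_id) {
  which(s$atoms$chain == chain & s$atoms$res_id == res_id)
}

#' Mutate one residue to alanine (side-chain truncation)
#'
#' Side-chain atoms beyond C-beta are removed and the residue renamed ALA;
#' glycine gets a C-beta added at ideal geometry. Parameters are
#' reassigned when the input was parameterized.
#'
#' @param s a `molstruct`.
#' @param chain,res_id the residue to mutate.
#' @return list with `structure` and `removed` (atom indices of `s`
#'   dropped) and `added` (number of atoms appended).
#' @export
mutate_to_alanine <- function(s, chain, res_id) {
  rows <- residue_rows(s, chain, res_id)
  if (length(rows) == 0L) stop("residue not found", call. = FALSE)
  res3 <- s$atoms$res_name[rows[1]]
  if (!res3 %in% names(SIDE_ATOMS))
    stop("nonstandard residue: ", res3, call. = FALSE)
  keep_names <- c("N", "CA", "C", "O", "CB", "OXT")
  drop <- rows[!s$atoms$name[rows] %in% keep_names &
                 s$atoms$is_heavy[rows]]
  # hydrogens of the removed side chain are also dropped (if any)
  a <- s$atoms
  added <- 0L
  if (!"CB" %in% a$name[rows]) {
    gi <- function(nm) rows[a$name[rows] == nm][1]
    cb <- ideal_cb(unlist(a[gi("N"), c("x", "y", "z")]),
                   unlist(a[gi("CA"), c("x", "y", "z")]),
                   unlist(a[gi("C"), c("x", "y", "z")]))
    newrow <- a[gi("CA"), ]
    newrow$name <- "CB"; newrow$element <- "C"
    newrow$x <- cb[1]; newrow$y <- cb[2]; newrow$z <- cb[3]
    a <- rbind(a[seq_len(max(rows)), ], newrow,
               if (max(rows) < nrow(a)) a[(max(rows) + 1):nrow(a), ])
    added <- 1L
  }
  a$res_name[a$chain == chain & a$res_id == res_id] <- "ALA"
  if (length(drop) > 0L) a <- a[-drop, , drop = FALSE]
  a$serial <- seq_len(nrow(a))
  rownames(a) <- NULL
  out <- new_molstruct(a, source_tag = s$source_tag)
  if (is_parameterized(s)) out <- assign_parameters(out)
  list(structure = out, removed = drop, added = added)
}

scan_entry <- function(chain, res_id, res_name, dg_wild, dg_mut, flag = "") {
  data.frame(chain = chain, res_id = res_id, res_name = res_name,
             dg_wild = dg_wild, dg_mut = dg_mut, ddg = dg_wild - dg_mut,
             flag = flag, stringsAsFactors = FALSE)
}

#' Computational alanine scan over an ensemble
#'
#' For each residue the mutant coordinates are rebuilt frame by frame
#' (side-chain truncation, no re-sampling), the binding free energy is
#' recomputed, and ddG = dG(wild) - dG(mutant) reported; a stabilizing
#' wild-type side chain gives ddG < 0 under this sign convention. Glycine
#' is skipped with a warning (no side chain to truncate); proline is
#' scanned but flagged.
#'
#' @inheritParams binding_energy
#' @param residues data frame with `chain` and `res_id` columns (e.g. from
#'   [interface_residues()]).
#' @param threshold hot-spot threshold passed to [classify_hotspots()].
#' @return data frame of scan entries with `ddg` and `is_hotspot`,
#'   in input residue order.
#' @export
alanine_scan <- function(e, receptor, ligand, residues,
                         settings = pb_settings(), trailing_fraction = 0.25,
                         pb = TRUE, threshold = 2.0) {
  topo <- require_parameters(e$topology)
  e <- new_ensemble(topo, e$frames)
  idx_rec <- resolve_selection(topo, receptor)
  idx_lig <- resolve_selection(topo, ligand)
  wild <- binding_energy(e, receptor, ligand, settings,
                         trailing_fraction, pb = pb)
  entries <- list()
  for (i in seq_len(nrow(residues))) {
    ch <- residues$chain[i]; rid <- residues$res_id[i]
    rows <- residue_rows(topo, ch, rid)
    if (length(rows) == 0L) stop("scan residue not found: ", ch, rid,
                                 call. = FALSE)
    if (!any(c(rows %in% idx_rec, rows %in% idx_lig)))
      stop("scan residue outside both partners: ", ch, rid, call. = FALSE)
    res3 <- topo$atoms$res_name[rows[1]]
    if (res3 == "GLY") {
      warning("skipping GLY ", ch, rid, ": no side chain to truncate")
      next
    }
    if (res3 == "ALA") {
      entries[[length(entries) + 1L]] <-
        scan_entry(ch, rid, res3, wild$g_bind, wild$g_bind)
      next
    }
    mut <- mutate_to_alanine(topo, ch, rid)
    keep <- setdiff(seq_len(nrow(topo$atoms)), mut$removed)
    frames_m <- lapply(e$frames, function(f) f[keep, , drop = FALSE])
    em <- new_ensemble(mut$structure, frames_m)
    bm <- binding_energy(em, receptor, ligand, settings,
                         trailing_fraction, pb = pb)
    entries[[length(entries) + 1L]] <-
      scan_entry(ch, rid, res3, wild$g_bind, bm$g_bind,
                 flag = if (res3 == "PRO") "PRO_backbone" else "")
  }
  out <- do.call(rbind, entries)
  if (is.null(out)) return(data.frame())
  out$is_hotspot <- out$ddg <= -threshold
  rownames(out) <- NULL
  out
}

#' Classify hot-spot residues from scan entries
#'
#' Under the convention ddG = dG(wild) - dG(alanine), a wild-type side
#' chain that stabilizes binding by at least `threshold` kcal/mol gives
#' ddG <= -threshold.
#'
#' @param entries data frame from [alanine_scan()].
#' @param threshold kcal/mol (default 2).
#' @param direction `"stabilizing"` (ddg <= -threshold, default) or
#'   `"destabilizing"` (ddg >= threshold); exposed because published
#'   hot-spot rules state the inequality both ways.
#' @return subset of `entries` classified as hot spots.
#' @export
classify_hotspots <- function(entries, threshold = 2.0,
                              direction = c("stabilizing",
                                            "destabilizing")) {
  direction <- match.arg(direction)
  if (nrow(entries) == 0L) return(entries)
  keep <- if (direction == "stabilizing") entries$ddg <= -threshold
          else entries$ddg >= threshold
  entries[keep, , drop = FALSE]
}

#' Parse a point-mutation label like "L16R"
#' @param label text `"<from><res_id><to>"` in one-letter codes.
#' @return list with `from`, `res_id`, `to`.
#' @export
parse_mutation <- function(label) {
  m <- regmatches(label, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", label))[[1]]
  if (length(m) != 4L) stop("cannot parse mutation label: ", label,
                            call. = FALSE)
  list(from = toupper(m[2]), res_id = as.integer(m[3]), to = toupper(m[4]))
}

relieve_clashes <- function(xyz, movable, steps = 50, contact = 2.0,
                            step_size = 0.1) {
  # steepest descent on sum over close pairs of (contact - d)^2,
  # moving only `movable` rows
  for (s in seq_len(steps)) {
    grad <- matrix(0, nrow(xyz), 3)
    pen <- 0
    for (i in movable) {
      dv <- sweep(xyz, 2, xyz[i, ], "-")
      d <- sqrt(rowSums(dv^2))
      close <- which(d < contact & d > 1e-9 & seq_len(nrow(xyz)) != i)
      for (j in close) {
        pen <- pen + (contact - d[j])^2
        g <- 2 * (contact - d[j]) * dv[j, ] / d[j]   # d(pen)/d(xyz_i)
        grad[i, ] <- grad[i, ] + g
      }
    }
    if (pen < 1e-8) break
    gn <- sqrt(sum(grad^2))
    if (gn < 1e-9) break
    xyz <- xyz - step_size * grad / gn
  }
  xyz
}

#' Virtual point mutation with idealized side-chain placement
#'
#' The wild-type side chain is replaced by an extended template grown
#' along the existing CA->CB direction, followed by 50 steps of
#' steepest-descent clash relief moving only the new atoms. Deterministic;
#' a `clash` attribute flags unresolved contacts (< 1.5 A).
#'
#' @param s a `molstruct`.
#' @param label mutation label like `"L16R"` (one-letter codes).
#' @param chain chain id (default the first chain).
#' @return the mutated `molstruct`; attribute `"clash"` is TRUE if a
#'   heavy-atom contact below 1.5 A remains.
#' @export
point_mutation <- function(s, label, chain = chain_ids(s)[1]) {
  spec <- parse_mutation(label)
  rows <- residue_rows(s, chain, spec$res_id)
  if (length(rows) == 0L) stop("residue not found: ", chain, spec$res_id,
                               call. = FALSE)
  a <- s$atoms
  res3_old <- a$res_name[rows[1]]
  if (aa_three_to_one(res3_old) != spec$from)
    stop(sprintf("mutation %s: residue %d is %s, not %s", label,
                 spec$res_id, res3_old, aa_one_to_three(spec$from)),
         call. = FALSE)
  res3_new <- aa_one_to_three(spec$to)
  if (res3_new == "UNK") stop("unknown target residue: ", spec$to,
                              call. = FALSE)
  if (res3_new == res3_old) return(s)
  gi <- function(nm) rows[a$name[rows] == nm][1]
  npos <- unlist(a[gi("N"), c("x", "y", "z")])
  capos <- unlist(a[gi("CA"), c("x", "y", "z")])
  cb_row <- gi("CB")
  cbpos <- if (!is.na(cb_row)) unlist(a[cb_row, c("x", "y", "z")])
           else ideal_cb(npos, capos, unlist(a[gi("C"), c("x", "y", "z")]))
  dir <- unit3(cbpos - capos)
  # lateral direction perpendicular to dir
  lat <- unit3(pracma_nullvec(dir))
  side <- SIDE_ATOMS[[res3_new]]
  keep <- rows[a$name[rows] %in% c("N", "CA", "C", "O", "OXT") |
                 !a$is_heavy[rows]]
  tmpl <- a[rows[1], ]
  new_rows <- do.call(rbind, lapply(seq_along(side), function(j) {
    r <- tmpl
    r$name <- side[j]
    r$element <- guess_element(side[j])
    pos <- if (j == 1L) cbpos else {
      off <- side_chain_offsets(length(side))[j, ]
      cbpos + off[2] * lat + off[3] * dir
    }
    r$x <- pos[1]; r$y <- pos[2]; r$z <- pos[3]
    r
  }))
  # rebuild: atoms before residue, kept backbone, new side chain, rest
  pre <- a[seq_len(nrow(a)) < min(rows), , drop = FALSE]
  bb <- a[keep, , drop = FALSE]
  post <- a[seq_len(nrow(a)) > max(rows), , drop = FALSE]
  if (!is.null(new_rows))
    new_rows <- new_rows[, names(pre), drop = FALSE]
  a2 <- rbind(pre, bb, new_rows, post)
  a2$res_name[a2$chain == chain &
                a2$res_id == spec$res_id] <- res3_new
  a2$serial <- seq_len(nrow(a2))
  rownames(a2) <- NULL
  out <- new_molstruct(a2, source_tag = s$source_tag)
  # clash relief on the new atoms only
  if (length(side) > 0L) {
    movable <- which(a2$chain == chain & a2$res_id == spec$res_id &
                       a2$name %in% setdiff(side, "CB"))
    if (length(movable) > 0L) {
      xyz2 <- relieve_clashes(coords(out), movable)
      out <- set_coords(out, xyz2)
    }
  }
  if (is_parameterized(s)) out <- assign_parameters(out)
  # clash flag: new side-chain atoms vs heavy atoms of other residues
  a3 <- out$atoms
  new_idx <- which(a3$chain == chain & a3$res_id == spec$res_id &
                     a3$name %in% side)
  other <- which(a3$is_heavy &
                   !(a3$chain == chain & a3$res_id == spec$res_id))
  dmin <- Inf
  if (length(new_idx) > 0L && length(other) > 0L) {
    d <- pairwise_dist(as.matrix(a3[new_idx, c("x", "y", "z")]),
                       as.matrix(a3[other, c("x", "y", "z")]))
    dmin <- min(d)
  }
  attr(out, "clash") <- is.finite(dmin) && dmin < 1.5
  if (isTRUE(attr(out, "clash")))
    warning(sprintf("unresolved steric contact (%.2f A) after mutation %s",
                    dmin, label))
  out
}

pracma_nullvec <- function(v) {
  # any unit vector perpendicular to v
  ax <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  w <- c(v[2] * ax[3] - v[3] * ax[2],
         v[3] * ax[1] - v[1] * ax[3],
         v[1] * ax[2] - v[2] * ax[1])
  w
}
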