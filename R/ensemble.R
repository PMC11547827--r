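# Ensemble container (an ordered set of coordinate frames over one
# topology; the desk-scale stand-in for an MD trajectory) and the
# trajectory-style analyses: Kabsch superposition, RMSD/RMSF series,
# interface residues, hydrogen-bond occupancy, DCCM.

#' Create an ensemble from a topology and coordinate frames
#'
#' @param topology a `molstruct`.
#' @param frames list of n_atoms x 3 coordinate matrices (Angstrom).
#' @return a `molensemble`.
#' @export
new_ensemble <- function(topology, frames) {
  stopifnot(inherits(topology, "molstruct"), length(frames) >= 1L)
  na <- nrow(topology$atoms)
  ok <- vapply(frames, function(f) is.matrix(f) && nrow(f) == na &&
                 ncol(f) == 3L, logical(1))
  if (!all(ok)) stop("all frames must be n_atoms x 3 matrices congruent ",
                     "with the topology", call. = FALSE)
  e <- list(topology = topology, frames = frames)
  class(e) <- "molensemble"
  e
}

#' @export
print.molensemble <- function(x, ...) {
  cat(sprintf("<molensemble> %d frames x %d atoms\n",
              length(x$frames), nrow(x$topology$atoms)))
  invisible(x)
}

#' Number of frames
#' @param e a `molensemble`.
#' @return integer frame count.
#' @export
n_frames <- function(e) length(e$frames)

#' Write an ensemble as a multi-MODEL PDB file
#' @param e a `molensemble`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(e, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(e$frames)) {
    writeLines(sprintf("MODEL     %4d", k), con)
    sk <- set_coords(e$topology, e$frames[[k]])
    lines <- format_pdb_lines(sk)
    writeLines(lines[lines != "END"], con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-MODEL PDB file as an ensemble
#' @param path PDB path; files without MODEL records yield 1 frame.
#' @return a `molensemble`.
#' @export
read_ensemble <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0L) {
    s <- read_pdb(path)
    return(new_ensemble(s, list(coords(s))))
  }
  ends <- grep("^ENDMDL", lines)
  stopifnot(length(ends) == length(starts))
  topo <- NULL
  frames <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    blk <- lines[(starts[k] + 1):(ends[k] - 1)]
    sel <- grepl("^(ATOM  |HETATM)", blk)
    atoms <- parse_pdb_atom_lines(blk[sel], which(sel) + starts[k], path)
    if (k == 1L) {
      atoms <- atoms[atoms$altloc %in% c(" ", "", "A"), , drop = FALSE]
      atoms$altloc <- NULL
      atoms <- assign_sequential_res_id(atoms)
      topo <- new_molstruct(atoms, source_tag = basename(path))
      frames[[k]] <- coords(topo)
    } else {
      m <- as.matrix(atoms[, c("x", "y", "z")])
      dimnames(m) <- NULL
      frames[[k]] <- m
    }
  }
  new_ensemble(topo, frames)
}

resolve_selection <- function(s, selection) {
  # selection: NULL (all heavy), "heavy", "all", "calpha", logical/integer
  # vector, or list(chain=, res_id=) filter; returns atom indices
  a <- s$atoms
  if (is.null(selection) || identical(selection, "heavy"))
    return(which(a$is_heavy & !a$het))
  if (identical(selection, "all")) return(seq_len(nrow(a)))
  if (identical(selection, "calpha"))
    return(which(a$name == "CA" & !a$het))
  if (is.logical(selection)) return(which(selection))
  if (is.numeric(selection)) return(as.integer(selection))
  if (is.list(selection)) {
    keep <- a$is_heavy & !a$het
    if (!is.null(selection$chain)) keep <- keep & a$chain %in% selection$chain
    if (!is.null(selection$res_id)) keep <- keep & a$res_id %in% selection$res_id
    return(which(keep))
  }
  stop("unsupported selection", call. = FALSE)
}

#' Optimal least-squares superposition (Kabsch)
#'
#' Returns the rotation and translation minimizing the coordinate RMSD of
#' `mobile[selection, ]` onto `reference[selection, ]`, with determinant
#' correction so reflections are never returned.
#'
#' @param mobile,reference n x 3 coordinate matrices with equal row count.
#' @param selection optional row indices to fit on (default all rows).
#' @return list with `rotation` (3x3), `translation` (length-3), `rmsd`
#'   (Angstrom, over the selection), and `transform(x)` applying the fit.
#' @export
superpose <- function(mobile, reference, selection = NULL) {
  if (is.null(selection)) selection <- seq_len(nrow(mobile))
  m <- mobile[selection, , drop = FALSE]
  r <- reference[selection, , drop = FALSE]
  if (nrow(m) != nrow(r)) stop("selection size mismatch", call. = FALSE)
  if (nrow(m) < 3L) stop("degenerate selection: need >= 3 atoms",
                         call. = FALSE)
  cm <- colMeans(m); cr <- colMeans(r)
  mc <- sweep(m, 2, cm); rc <- sweep(r, 2, cr)
  if (qr(mc)$rank < 2L) stop("degenerate selection: collinear atoms",
                             call. = FALSE)
  H <- crossprod(mc, rc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  transform <- function(x) sweep(sweep(x, 2, cm) %*% t(R), 2, cr, "+")
  fitted <- transform(mobile)
  rmsd <- sqrt(mean(rowSums((fitted[selection, , drop = FALSE] - r)^2)))
  list(rotation = R, translation = cr - as.numeric(R %*% cm),
       rmsd = rmsd, transform = transform)
}

#' Plain coordinate RMSD (no fitting)
#' @param a,b n x 3 matrices.
#' @return RMSD in Angstrom.
#' @export
coord_rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' RMSD time series over an ensemble
#'
#' Each frame is superposed on the reference frame over `selection` (fit
#' and measure on the same selection) before the RMSD is taken. The mean
#' over the trailing fraction of frames emulates averaging over the
#' equilibrated tail of a trajectory.
#'
#' @param e a `molensemble`.
#' @param reference_frame index of the reference frame (default 1).
#' @param selection atom selection (see details in [rmsf()]); default all
#'   heavy atoms.
#' @param trailing_fraction fraction of trailing frames averaged into
#'   `trailing_mean` (default 0.25).
#' @return list with `kind = "rmsd"`, `values` (per frame, Angstrom),
#'   `trailing_mean`.
#' @export
rmsd_series <- function(e, reference_frame = 1L, selection = NULL,
                        trailing_fraction = 0.25) {
  sel <- resolve_selection(e$topology, selection)
  ref <- e$frames[[reference_frame]]
  vals <- vapply(e$frames, function(f) {
    if (identical(dim(f), dim(ref)) && all(f == ref)) return(0)
    superpose(f, ref, sel)$rmsd
  }, numeric(1))
  k <- max(1L, ceiling(trailing_fraction * length(vals)))
  list(kind = "rmsd", values = vals,
       trailing_mean = mean(tail(vals, k)))
}

#' Per-residue root-mean-square fluctuation
#'
#' Fluctuation of each selected atom about its ensemble-mean position
#' (after optional superposition of every frame on the first), averaged
#' over the atoms of each residue.
#'
#' @param e a `molensemble`.
#' @param selection atom selection; default all heavy atoms; `"calpha"`
#'   restricts to C-alpha.
#' @param align superpose frames on frame 1 first (default TRUE).
#' @return list with `kind = "rmsf"`, `residues` (chain/res_id data
#'   frame), `values` (Angstrom per residue), `atom_values`.
#' @export
rmsf <- function(e, selection = NULL, align = TRUE) {
  sel <- resolve_selection(e$topology, selection)
  frames <- e$frames
  if (align && length(frames) > 1L) {
    ref <- frames[[1]]
    frames <- lapply(frames, function(f) superpose(f, ref, sel)$transform(f))
  }
  arr <- array(unlist(lapply(frames, function(f) f[sel, , drop = FALSE])),
               dim = c(length(sel), 3, length(frames)))
  mu <- apply(arr, c(1, 2), mean)
  dev2 <- apply((arr - array(mu, dim(arr)))^2, c(1, 3), sum)
  atom_vals <- sqrt(rowMeans(dev2))
  a <- e$topology$atoms[sel, , drop = FALSE]
  key <- paste(a$chain, a$res_id)
  uk <- unique(key)
  res_vals <- as.numeric(tapply(atom_vals, factor(key, uk), mean))
  u <- !duplicated(key)
  list(kind = "rmsf",
       residues = data.frame(chain = a$chain[u], res_id = a$res_id[u],
                             res_name = a$res_name[u],
                             stringsAsFactors = FALSE),
       values = res_vals, atom_values = atom_vals)
}

#' Interface residues of a two-chain complex
#'
#' A residue belongs to the interface iff any of its heavy atoms lies
#' within `cutoff` (inclusive) of any heavy atom of the other chain.
#'
#' @param s a `molstruct`.
#' @param chain_a,chain_b chain ids.
#' @param cutoff distance cutoff in Angstrom (default 5).
#' @return list with residue-id vectors `a` and `b`.
#' @export
interface_residues <- function(s, chain_a, chain_b, cutoff = 5.0) {
  for (cc in c(chain_a, chain_b))
    if (!cc %in% chain_ids(s)) stop("chain not found: ", cc, call. = FALSE)
  aa <- s$atoms[s$atoms$chain == chain_a & s$atoms$is_heavy & !s$atoms$het, ]
  ab <- s$atoms[s$atoms$chain == chain_b & s$atoms$is_heavy & !s$atoms$het, ]
  xa <- as.matrix(aa[, c("x", "y", "z")])
  xb <- as.matrix(ab[, c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  hit <- d2 <= cutoff^2 + 1e-12
  list(a = sort(unique(aa$res_id[rowSums(hit) > 0])),
       b = sort(unique(ab$res_id[colSums(hit) > 0])))
}

#' Hydrogen-bond occupancy over an ensemble
#'
#' Candidate donors and acceptors are N/O atoms identified by name. When
#' the topology carries hydrogens (an H within 1.2 A of the donor), the
#' criterion is donor-acceptor distance <= `dist_cutoff` and D-H...A angle
#' >= `angle_cutoff`; otherwise distance-only. Same-residue pairs are
#' excluded; `cross_chain_only` restricts to inter-chain pairs.
#'
#' @param e a `molensemble`.
#' @param dist_cutoff donor-acceptor distance cutoff, Angstrom (3.5).
#' @param angle_cutoff D-H...A angle cutoff, degrees (135).
#' @param cross_chain_only only pairs across chains (default TRUE).
#' @param min_occupancy drop records below this percent (default 1).
#' @return data frame (donor/acceptor chain, res_id, res_name, atom,
#'   occupancy percent), sorted by occupancy descending.
#' @export
hydrogen_bonds <- function(e, dist_cutoff = 3.5, angle_cutoff = 135,
                           cross_chain_only = TRUE, min_occupancy = 1) {
  a <- e$topology$atoms
  cand <- which(a$element %in% c("N", "O") & !a$het)
  if (length(cand) < 2L)
    return(data.frame())
  pairs <- expand.grid(d = cand, ac = cand)
  pairs <- pairs[pairs$d != pairs$ac, ]
  same_res <- a$chain[pairs$d] == a$chain[pairs$ac] &
    a$res_id[pairs$d] == a$res_id[pairs$ac]
  pairs <- pairs[!same_res, ]
  if (cross_chain_only)
    pairs <- pairs[a$chain[pairs$d] != a$chain[pairs$ac], ]
  if (nrow(pairs) == 0L) return(data.frame())
  # attached hydrogens of each donor candidate (topology frame 1)
  x0 <- e$frames[[1]]
  hyd <- which(a$element == "H")
  h_of <- rep(NA_integer_, nrow(a))
  for (h in hyd) {
    d2 <- rowSums(sweep(x0[cand, , drop = FALSE], 2, x0[h, ])^2)
    j <- which.min(d2)
    if (d2[j] < 1.2^2) h_of[cand[j]] <- h
  }
  nf <- length(e$frames)
  counts <- numeric(nrow(pairs))
  for (f in e$frames) {
    dv <- f[pairs$d, , drop = FALSE] - f[pairs$ac, , drop = FALSE]
    dist <- sqrt(rowSums(dv^2))
    ok <- dist <= dist_cutoff
    hidx <- h_of[pairs$d]
    ang_ok <- rep(TRUE, nrow(pairs))
    with_h <- !is.na(hidx)
    if (any(with_h & ok)) {
      ii <- which(with_h & ok)
      v1 <- f[pairs$d[ii], , drop = FALSE] - f[hidx[ii], , drop = FALSE]
      v2 <- f[pairs$ac[ii], , drop = FALSE] - f[hidx[ii], , drop = FALSE]
      cosang <- rowSums(v1 * v2) /
        (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
      ang_ok[ii] <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi >= angle_cutoff
    }
    counts <- counts + (ok & ang_ok)
  }
  occ <- 100 * counts / nf
  out <- data.frame(
    donor_chain = a$chain[pairs$d], donor_res_id = a$res_id[pairs$d],
    donor_res = a$res_name[pairs$d], donor_atom = a$name[pairs$d],
    acceptor_chain = a$chain[pairs$ac], acceptor_res_id = a$res_id[pairs$ac],
    acceptor_res = a$res_name[pairs$ac], acceptor_atom = a$name[pairs$ac],
    occupancy = occ, stringsAsFactors = FALSE)
  out <- out[out$occupancy >= min_occupancy, , drop = FALSE]
  out <- out[order(-out$occupancy), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dynamic cross-correlation matrix
#'
#' Entry (i, j) is the normalized covariance of the displacement vectors
#' of atoms i and j about their ensemble means: symmetric, unit diagonal,
#' in [-1, 1]. Frames are superposed on frame 1 over the selection first.
#'
#' @param e a `molensemble`.
#' @param selection atom selection (default C-alpha; `"heavy"` for all
#'   heavy atoms).
#' @param align superpose first (default TRUE).
#' @return correlation matrix over selected atoms.
#' @export
dccm <- function(e, selection = "calpha", align = TRUE) {
  sel <- resolve_selection(e$topology, selection)
  frames <- e$frames
  if (align && length(frames) > 1L) {
    ref <- frames[[1]]
    frames <- lapply(frames, function(f) superpose(f, ref, sel)$transform(f))
  }
  nf <- length(frames)
  n <- length(sel)
  arr <- array(unlist(lapply(frames, function(f) f[sel, , drop = FALSE])),
               dim = c(n, 3, nf))
  mu <- apply(arr, c(1, 2), mean)
  dev <- arr - array(mu, dim(arr))
  # <dri . drj> = sum over xyz of covariances
  cov <- matrix(0, n, n)
  for (k in 1:3) cov <- cov + tcrossprod(matrix(dev[, k, ], n, nf)) / nf
  d <- sqrt(diag(cov))
  d[d == 0] <- 1
  cm <- cov / outer(d, d)
  cm[cm > 1] <- 1; cm[cm < -1] <- -1
  diag(cm) <- 1
  cm
}
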