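# Synthetic-data generators: every input the pipeline needs, built in
# code. The trajectory stand-in is Gaussian positional noise (optionally
# with shared group displacements), not physical dynamics: the downstream
# statistics (RMSD/RMSF, occupancy, DCCM, end-state averaging) only need
# controlled statistical structure, and parameter recovery is then exact
# in expectation.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  code
}

random_sequence <- function(n) {
  # toy sequences drawn from a fixed palette; uncharged-biased like a
  # typical interface core
  paste(sample(c("A", "L", "V", "S", "T", "N", "G", "Y", "F", "R", "E"),
               n, replace = TRUE), collapse = "")
}

#' Generate a toy two-chain complex with a designed interface
#'
#' Two extended chains are placed antiparallel, chain B translated along y
#' until the closest heavy-atom cross-chain distance equals `gap` (within
#' 0.1 A). Deterministic for a given seed.
#'
#' @param n_res_a,n_res_b residue counts per chain (>= 2).
#' @param gap closest heavy-atom distance between the chains, Angstrom.
#' @param seed RNG seed (used for random sequences when none given).
#' @param seq_a,seq_b optional one-letter sequences overriding the random
#'   ones (lengths must match the counts).
#' @return a parameter-free `molstruct` with chains `"A"` and `"B"`.
#' @export
make_toy_complex <- function(n_res_a, n_res_b, gap = 4.5, seed = 1,
                             seq_a = NULL, seq_b = NULL) {
  stopifnot(n_res_a >= 2L, n_res_b >= 2L, gap > 0)
  with_seed(seed, {
    if (is.null(seq_a)) seq_a <- random_sequence(n_res_a)
    if (is.null(seq_b)) seq_b <- random_sequence(n_res_b)
  })
  stopifnot(nchar(seq_a) == n_res_a, nchar(seq_b) == n_res_b)
  sa <- build_extended_chain(seq_a, "A", origin = c(0, 0, 0))
  # antiparallel partner; side chains away from the interface
  sb <- build_extended_chain(seq_b, "B",
                             origin = c(3.8 * (n_res_b - 1), -20, 0),
                             reverse = TRUE, side_dir = c(0, 0, 1))
  xa <- coords(sa, heavy_only = TRUE)
  xb0 <- coords(sb, heavy_only = TRUE)
  mind <- function(shift) {
    xb <- sweep(xb0, 2, c(0, shift, 0), "+")
    d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
    sqrt(max(0, min(d2)))
  }
  f <- function(shift) mind(shift) - gap
  shift <- uniroot(f, lower = 0, upper = 19, tol = 1e-4)$root
  sb$atoms$y <- sb$atoms$y + shift
  atoms <- rbind(sa$atoms, sb$atoms)
  atoms$serial <- seq_len(nrow(atoms))
  new_molstruct(atoms, source_tag = sprintf("toy_complex(seed=%d)", seed))
}

#' Generate a Gaussian-fluctuation ensemble around a reference structure
#'
#' Frame k = reference + independent per-atom isotropic Gaussian
#' displacements + shared per-group displacements (one Gaussian 3-vector
#' per group per frame added to every atom of the group). The expected
#' per-atom RMSF of an isotropic displacement of scale sigma is
#' sigma * sqrt(3).
#'
#' @param s reference `molstruct`.
#' @param n_frames number of frames (>= 1).
#' @param per_atom_sigma scalar sigma (Angstrom), an unnamed per-atom
#'   vector, or a vector named by `res_id` giving a per-residue profile
#'   (unlisted residues get 0).
#' @param correlated_groups list of atom-index vectors sharing one
#'   displacement stream per group.
#' @param group_sigma sigma of each shared displacement (recycled).
#' @param seed RNG seed (mandatory, never global state).
#' @param first_frame_reference make frame 1 the unperturbed reference.
#' @return a `molensemble`.
#' @export
make_ensemble <- function(s, n_frames, per_atom_sigma = 0.3,
                          correlated_groups = list(), group_sigma = 1.0,
                          seed = 1, first_frame_reference = FALSE) {
  stopifnot(n_frames >= 1L, all(per_atom_sigma >= 0))
  ref <- coords(s)
  na <- nrow(ref)
  if (!is.null(names(per_atom_sigma))) {
    sig <- rep(0, na)
    m <- match(as.character(s$atoms$res_id), names(per_atom_sigma))
    sig[!is.na(m)] <- per_atom_sigma[m[!is.na(m)]]
  } else if (length(per_atom_sigma) == 1L) {
    sig <- rep(per_atom_sigma, na)
  } else {
    stopifnot(length(per_atom_sigma) == na)
    sig <- per_atom_sigma
  }
  gs <- rep(group_sigma, length.out = length(correlated_groups))
  frames <- with_seed(seed, {
    lapply(seq_len(n_frames), function(k) {
      if (k == 1L && first_frame_reference) return(ref)
      f <- ref + matrix(rnorm(na * 3), na, 3) * sig
      for (gi in seq_along(correlated_groups)) {
        dv <- rnorm(3) * gs[gi]
        idx <- correlated_groups[[gi]]
        f[idx, ] <- sweep(f[idx, , drop = FALSE], 2, dv, "+")
      }
      f
    })
  })
  new_ensemble(s, frames)
}

#' Generate an ensemble with hydrogen-bond occupancy by construction
#'
#' A two-chain glycine pair whose backbone N (chain A, donor) and backbone
#' O (chain B, acceptor) sit at 2.9 A in exactly
#' `round(occupancy_true * n_frames)` frames and at 7.9 A otherwise; no
#' other N/O cross pair ever satisfies the 3.5 A criterion.
#'
#' @param occupancy_true target occupancy fraction in [0, 1].
#' @param n_frames number of frames.
#' @param seed RNG seed (shuffles which frames are bonded).
#' @return a `molensemble`.
#' @export
make_hbond_ensemble <- function(occupancy_true, n_frames, seed = 1) {
  stopifnot(occupancy_true >= 0, occupancy_true <= 1, n_frames >= 1L)
  mk <- function(nm, res, ch, xyz, rid)
    data.frame(serial = NA_integer_, name = nm, res_name = res, chain = ch,
               auth_seq = rid, res_id = rid, x = xyz[1], y = xyz[2],
               z = xyz[3], element = guess_element(nm), het = FALSE,
               stringsAsFactors = FALSE)
  atoms <- rbind(
    mk("N", "GLY", "A", c(0, 0, 0), 1L),
    mk("CA", "GLY", "A", c(1.46, 0, 0), 1L),
    mk("C", "GLY", "A", c(2.47, 0, 0), 1L),
    mk("O", "GLY", "A", c(2.47, 1.23, 0), 1L),
    mk("O", "GLY", "B", c(0, -2.9, 0), 1L),
    mk("C", "GLY", "B", c(0, -4.13, 0), 1L),
    mk("CA", "GLY", "B", c(-1.2, -4.8, 0), 1L),
    mk("N", "GLY", "B", c(-2.4, -5.5, 0), 1L))
  atoms$serial <- seq_len(nrow(atoms))
  topo <- new_molstruct(atoms, source_tag = "hbond_toy")
  ref <- coords(topo)
  k <- round(occupancy_true * n_frames)
  bonded <- with_seed(seed, sample(n_frames) <= k)
  b_idx <- which(topo$atoms$chain == "B")
  frames <- lapply(seq_len(n_frames), function(i) {
    f <- ref
    if (!bonded[i])
      f[b_idx, 2] <- f[b_idx, 2] - 5
    f
  })
  new_ensemble(topo, frames)
}

#' Generate a noisy one-site saturation binding curve
#'
#' response = baseline + a_max * c / (kd_true + c) + N(0, noise_sd).
#' The default concentration series is a 5-fold dilution from 4 uM down
#' to 0.00128 uM.
#'
#' @param kd_true true dissociation constant, uM (> 0).
#' @param a_max saturating amplitude (absorbance units).
#' @param baseline response at zero concentration.
#' @param concentrations concentration vector, uM.
#' @param noise_sd Gaussian noise SD (absorbance units).
#' @param seed RNG seed.
#' @return data frame with `concentration_uM` and `response`.
#' @export
make_binding_curve <- function(kd_true, a_max = 1.0, baseline = 0.05,
                               concentrations = 4 / 5^(0:5),
                               noise_sd = 0, seed = 1) {
  stopifnot(kd_true > 0, all(concentrations >= 0))
  mu <- baseline + a_max * concentrations / (kd_true + concentrations)
  resp <- with_seed(seed, mu + rnorm(length(mu), 0, noise_sd))
  data.frame(concentration_uM = concentrations, response = resp)
}
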