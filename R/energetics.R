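# MM-PBSA engine: gas-phase cross terms (Coulomb, 12-6 Lennard-Jones),
# Shrake-Rupley SASA with the linear nonpolar model, finite-difference
# linearized PB polar solvation, single-trajectory aggregation with the
# standard identities
#   dG_bind = dE_MM + dG_solv,  dE_MM = dE_ele + dE_vdw + dE_int (= 0),
#   dG_solv = dG_PB + dG_nonp,  dG_nonp = gamma * SASA + beta,
# and per-residue decomposition.

KCOUL <- 332.0637   # kcal mol^-1 A e^-2

#' Poisson-Boltzmann / surface-area settings
#'
#' Defaults follow common end-state practice: internal dielectric 1,
#' external 80, 0.15 M ionic strength, 1.4 A probe, gamma 0.00542
#' kcal mol^-1 A^-2 and beta 0.92 kcal mol^-1 for the nonpolar term.
#'
#' @param eps_internal,eps_external solute/solvent dielectric constants.
#' @param ionic_strength molar ionic strength (1:1 salt).
#' @param grid_spacing PB grid spacing, Angstrom.
#' @param box_margin solvent margin around the solute, Angstrom.
#' @param probe_radius SASA probe radius, Angstrom.
#' @param gamma,beta nonpolar model coefficients.
#' @param coulomb_constant Coulomb constant, kcal mol^-1 A e^-2.
#' @param sasa_points sphere quadrature points per atom (>= 96).
#' @param pb_max_iter,pb_tol,pb_omega SOR solver controls.
#' @return a `pb_settings` list.
#' @export
pb_settings <- function(eps_internal = 1, eps_external = 80,
                        ionic_strength = 0.15, grid_spacing = 0.4,
                        box_margin = 8, probe_radius = 1.4,
                        gamma = 0.00542, beta = 0.92,
                        coulomb_constant = KCOUL, sasa_points = 960,
                        pb_max_iter = 5000, pb_tol = 1e-3,
                        pb_omega = 1.9) {
  stopifnot(eps_external >= eps_internal, eps_internal >= 1,
            grid_spacing > 0, probe_radius > 0, sasa_points >= 96)
  structure(list(eps_internal = eps_internal, eps_external = eps_external,
                 ionic_strength = ionic_strength,
                 grid_spacing = grid_spacing, box_margin = box_margin,
                 probe_radius = probe_radius, gamma = gamma, beta = beta,
                 coulomb_constant = coulomb_constant,
                 sasa_points = sasa_points, pb_max_iter = pb_max_iter,
                 pb_tol = pb_tol, pb_omega = pb_omega),
            class = "pb_settings")
}

#' Extract a parameterized atom set
#'
#' @param s a parameterized `molstruct`.
#' @param selection atom selection (see [rmsf()]); default all heavy atoms.
#' @param xyz optional replacement coordinate matrix for the whole
#'   structure (e.g. one ensemble frame).
#' @return data frame of atoms with coordinates and parameters.
#' @export
atom_set <- function(s, selection = NULL, xyz = NULL) {
  s <- require_parameters(s)
  if (!is.null(xyz)) s <- set_coords(s, xyz)
  idx <- resolve_selection(s, selection)
  a <- s$atoms[idx, , drop = FALSE]
  a$atom_index <- idx
  a
}

pairwise_dist <- function(xa, xb) {
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  sqrt(pmax(d2, 0))
}

#' Coulomb cross-interaction energy of two atom sets
#'
#' Sum over all cross pairs of k q_i q_j / (eps r_ij), no distance cutoff.
#'
#' @param set_a,set_b atom sets from [atom_set()] (need `x,y,z,charge`).
#' @param eps dielectric constant.
#' @param k Coulomb constant.
#' @return energy in kcal/mol.
#' @export
coulomb_energy <- function(set_a, set_b, eps = 1, k = KCOUL) {
  if (nrow(set_a) == 0L || nrow(set_b) == 0L) return(0)
  r <- pairwise_dist(as.matrix(set_a[, c("x", "y", "z")]),
                     as.matrix(set_b[, c("x", "y", "z")]))
  if (any(r < 1e-6))
    stop("coincident atoms (r < 1e-6 A) in Coulomb sum", call. = FALSE)
  sum(k * outer(set_a$charge, set_b$charge) / (eps * r))
}

#' Lennard-Jones 12-6 cross-interaction energy
#'
#' Lorentz-Berthelot-style combination: rmin_ij = rmin_half_i +
#' rmin_half_j, eps_ij = sqrt(eps_i eps_j);
#' E = sum eps_ij ((rmin/r)^12 - 2 (rmin/r)^6). No cutoff.
#'
#' @param set_a,set_b atom sets (need `x,y,z,lj_rmin_half,lj_epsilon`).
#' @return energy in kcal/mol.
#' @export
lj_energy <- function(set_a, set_b) {
  if (nrow(set_a) == 0L || nrow(set_b) == 0L) return(0)
  r <- pairwise_dist(as.matrix(set_a[, c("x", "y", "z")]),
                     as.matrix(set_b[, c("x", "y", "z")]))
  if (any(r < 1e-6))
    stop("coincident atoms (r < 1e-6 A) in LJ sum", call. = FALSE)
  rmin <- outer(set_a$lj_rmin_half, set_b$lj_rmin_half, "+")
  epsm <- sqrt(outer(set_a$lj_epsilon, set_b$lj_epsilon))
  s6 <- (rmin / r)^6
  sum(epsm * (s6^2 - 2 * s6))
}

unit_sphere_points <- function(n) {
  # deterministic golden-section spiral
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per atom, the fraction of `n_points` unit-sphere quadrature points at
#' radius (r_atom + probe) not buried inside any neighbour's expanded
#' sphere, times the expanded sphere area.
#'
#' @param s a parameterized `molstruct`, or a data frame with columns
#'   `x,y,z,solv_radius` (heavy atoms).
#' @param probe probe radius, Angstrom (default 1.4).
#' @param n_points quadrature points per atom (>= 96).
#' @return list with `per_atom` (A^2), `total`, `probe`, `n_points`.
#' @export
sasa <- function(s, probe = 1.4, n_points = 960) {
  stopifnot(n_points >= 96)
  a <- if (inherits(s, "molstruct")) atom_set(s) else s
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rad <- a$solv_radius + probe
  n <- nrow(xyz)
  pts <- unit_sphere_points(n_points)
  per <- numeric(n)
  for (i in seq_len(n)) {
    d <- sqrt(rowSums(sweep(xyz, 2, xyz[i, ])^2))
    nbr <- which(d < rad[i] + rad & seq_len(n) != i)
    p <- sweep(pts * rad[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in nbr) {
      dj2 <- rowSums(sweep(p, 2, xyz[j, ])^2)
      free <- free & dj2 >= rad[j]^2
      if (!any(free)) break
    }
    per[i] <- sum(free) / n_points * 4 * pi * rad[i]^2
  }
  list(per_atom = per, total = sum(per), probe = probe,
       n_points = n_points)
}

#' Nonpolar solvation free energy from SASA
#'
#' gamma * SASA + beta.
#'
#' @param sasa_total total SASA in A^2.
#' @param settings a [pb_settings()].
#' @return energy in kcal/mol.
#' @export
nonpolar_solvation <- function(sasa_total, settings = pb_settings()) {
  settings$gamma * sasa_total + settings$beta
}

#' Polar solvation free energy (finite-difference linearized PB)
#'
#' Reaction-field energy of moving the solute from a uniform
#' `eps_internal` medium into `eps_external` solvent with Debye screening,
#' solved by SOR on a 7-point stencil; the vacuum reference uses the
#' identical grid so the discrete self-energy cancels.
#'
#' @param s a parameterized `molstruct`, or a data frame with columns
#'   `x,y,z,charge,solv_radius`.
#' @param settings a [pb_settings()].
#' @return list with `total` (kcal/mol), `per_atom` shares, `spacing`,
#'   `dims`, `residual`.
#' @export
polar_solvation <- function(s, settings = pb_settings()) {
  a <- if (inherits(s, "molstruct")) atom_set(s) else s
  if (all(abs(a$charge) < 1e-12))
    return(list(total = 0, per_atom = rep(0, nrow(a)),
                spacing = settings$grid_spacing, dims = NA, residual = 0))
  .pb_solve_cpp(as.matrix(a[, c("x", "y", "z")]), a$charge, a$solv_radius,
                settings$grid_spacing, settings$box_margin,
                settings$eps_internal, settings$eps_external,
                settings$ionic_strength, settings$pb_max_iter,
                settings$pb_tol, settings$pb_omega)
}

#' Assemble an energy breakdown from its components
#'
#' Enforces the aggregation identities on unrounded inputs; used both by
#' [binding_energy()] and to run printed component tables through the
#' identities.
#'
#' @param e_ele,e_vdw,g_pb,g_nonp component energies, kcal/mol.
#' @param e_int internal-energy difference (0 under the single-trajectory
#'   protocol).
#' @param ts_term optional -T dS term (absent by default; entropy is
#'   conventionally neglected in end-state scoring).
#' @param se optional named list of standard errors per component.
#' @return an `energy_breakdown` list with `e_mm`, `g_solv`, `g_bind`.
#' @export
energy_breakdown <- function(e_ele, e_vdw, g_pb, g_nonp, e_int = 0,
                             ts_term = NULL, se = NULL) {
  e_mm <- e_ele + e_vdw + e_int
  g_solv <- g_pb + g_nonp
  g_bind <- e_mm + g_solv + if (is.null(ts_term)) 0 else ts_term
  structure(list(e_ele = e_ele, e_vdw = e_vdw, e_int = e_int,
                 g_pb = g_pb, g_nonp = g_nonp, e_mm = e_mm,
                 g_solv = g_solv, g_bind = g_bind, ts_term = ts_term,
                 se = se),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  fmt <- function(v) sprintf("%10.2f", v)
  cat("Binding free energy breakdown (kcal/mol)\n")
  for (t in c("e_ele", "e_vdw", "e_int", "g_pb", "g_nonp", "e_mm",
              "g_solv", "g_bind"))
    cat(sprintf("  %-7s %s%s\n", t, fmt(x[[t]]),
                if (!is.null(x$se) && !is.null(x$se[[t]]))
                  sprintf(" +/- %.2f", x$se[[t]]) else ""))
  invisible(x)
}

frame_terms <- function(s, idx_rec, idx_lig, settings, pb = TRUE) {
  a_all <- s$atoms
  set_r <- a_all[idx_rec, , drop = FALSE]
  set_l <- a_all[idx_lig, , drop = FALSE]
  e_ele <- coulomb_energy(set_r, set_l, eps = settings$eps_internal,
                          k = settings$coulomb_constant)
  e_vdw <- lj_energy(set_r, set_l)
  sas_c <- sasa(rbind(set_r, set_l), settings$probe_radius,
                settings$sasa_points)
  sas_r <- sasa(set_r, settings$probe_radius, settings$sasa_points)
  sas_l <- sasa(set_l, settings$probe_radius, settings$sasa_points)
  g_nonp <- nonpolar_solvation(sas_c$total, settings) -
    nonpolar_solvation(sas_r$total, settings) -
    nonpolar_solvation(sas_l$total, settings)
  if (pb) {
    pb_c <- polar_solvation(rbind(set_r, set_l), settings)
    pb_r <- polar_solvation(set_r, settings)
    pb_l <- polar_solvation(set_l, settings)
    g_pb <- pb_c$total - pb_r$total - pb_l$total
  } else {
    pb_c <- pb_r <- pb_l <- NULL
    g_pb <- 0
  }
  list(e_ele = e_ele, e_vdw = e_vdw, g_pb = g_pb, g_nonp = g_nonp,
       sas = list(complex = sas_c, rec = sas_r, lig = sas_l),
       pb = list(complex = pb_c, rec = pb_r, lig = pb_l))
}

trailing_idx <- function(n, trailing_fraction) {
  k <- max(1L, ceiling(trailing_fraction * n))
  seq.int(n - k + 1L, n)
}

#' MM-PBSA binding free energy over an ensemble (single-trajectory)
#'
#' For each frame of the trailing fraction, complex / receptor / ligand
#' terms are computed from the same coordinates, so bonded differences
#' vanish (e_int = 0) and the gas-phase deltas reduce to cross-chain
#' interactions; frame values are averaged with SEM error bars. Entropy
#' is omitted.
#'
#' @param e a `molensemble` of the complex (parameterized topology, or
#'   parameters are assigned from the packaged table).
#' @param receptor,ligand selections (e.g. `list(chain = "A")`) that
#'   partition the heavy atoms of the complex.
#' @param settings a [pb_settings()].
#' @param trailing_fraction fraction of trailing frames used (0.25).
#' @param pb compute the PB polar term (TRUE); FALSE leaves g_pb = 0 for
#'   gas+SASA-only screens.
#' @return an `energy_breakdown` with per-term SEM in `$se` and per-frame
#'   values in `$frames`.
#' @export
binding_energy <- function(e, receptor, ligand, settings = pb_settings(),
                           trailing_fraction = 0.25, pb = TRUE) {
  topo <- require_parameters(e$topology)
  idx_rec <- resolve_selection(topo, receptor)
  idx_lig <- resolve_selection(topo, ligand)
  if (length(intersect(idx_rec, idx_lig)) > 0L)
    stop("receptor and ligand selections overlap", call. = FALSE)
  if (length(idx_rec) == 0L || length(idx_lig) == 0L)
    stop("empty receptor or ligand selection", call. = FALSE)
  fidx <- trailing_idx(n_frames(e), trailing_fraction)
  vals <- lapply(fidx, function(k) {
    sk <- set_coords(topo, e$frames[[k]])
    frame_terms(sk, idx_rec, idx_lig, settings, pb = pb)
  })
  comp <- function(t) vapply(vals, `[[`, numeric(1), t)
  sem <- function(v) if (length(v) > 1L) sd(v) / sqrt(length(v)) else 0
  terms <- lapply(c(e_ele = "e_ele", e_vdw = "e_vdw", g_pb = "g_pb",
                    g_nonp = "g_nonp"), comp)
  out <- energy_breakdown(mean(terms$e_ele), mean(terms$e_vdw),
                          mean(terms$g_pb), mean(terms$g_nonp),
                          se = lapply(terms, sem))
  out$frames <- as.data.frame(terms)
  out$n_frames_used <- length(fidx)
  out
}

#' Per-residue decomposition of the binding free energy
#'
#' Gas-phase cross-pair energies are halved onto the two residues of each
#' pair (residue sums reproduce the complex totals exactly); the nonpolar
#' share is gamma times the per-atom SASA change on complexation (with
#' the beta offset spread proportionally), and the polar share is the
#' per-atom half-q-delta-phi reaction-field change. Shares are averaged
#' over the trailing frames.
#'
#' @inheritParams binding_energy
#' @return data frame with per-residue `e_ele`, `e_vdw`, `g_pb_share`,
#'   `g_nonp_share`, `total` (kcal/mol).
#' @export
per_residue_decomposition <- function(e, receptor, ligand,
                                      settings = pb_settings(),
                                      trailing_fraction = 0.25, pb = TRUE) {
  topo <- require_parameters(e$topology)
  idx_rec <- resolve_selection(topo, receptor)
  idx_lig <- resolve_selection(topo, ligand)
  fidx <- trailing_idx(n_frames(e), trailing_fraction)
  a <- topo$atoms
  rkey <- paste(a$chain, a$res_id)
  all_idx <- c(idx_rec, idx_lig)
  res_keys <- unique(rkey[all_idx])
  acc <- matrix(0, length(res_keys), 4,
                dimnames = list(res_keys,
                                c("e_ele", "e_vdw", "g_pb", "g_nonp")))
  for (k in fidx) {
    sk <- set_coords(topo, e$frames[[k]])
    ak <- sk$atoms
    xr <- as.matrix(ak[idx_rec, c("x", "y", "z")])
    xl <- as.matrix(ak[idx_lig, c("x", "y", "z")])
    r <- pairwise_dist(xr, xl)
    eel <- settings$coulomb_constant *
      outer(ak$charge[idx_rec], ak$charge[idx_lig]) /
      (settings$eps_internal * r)
    rmin <- outer(ak$lj_rmin_half[idx_rec], ak$lj_rmin_half[idx_lig], "+")
    epsm <- sqrt(outer(ak$lj_epsilon[idx_rec], ak$lj_epsilon[idx_lig]))
    s6 <- (rmin / r)^6
    evd <- epsm * (s6^2 - 2 * s6)
    fr <- factor(rkey[idx_rec], res_keys)
    fl <- factor(rkey[idx_lig], res_keys)
    half_ele <- 0.5 * (rowsum(rowSums(eel), fr)[, 1])
    acc[names(half_ele), "e_ele"] <- acc[names(half_ele), "e_ele"] + half_ele
    half_ele_l <- 0.5 * (rowsum(colSums(eel), fl)[, 1])
    acc[names(half_ele_l), "e_ele"] <-
      acc[names(half_ele_l), "e_ele"] + half_ele_l
    half_v <- 0.5 * (rowsum(rowSums(evd), fr)[, 1])
    acc[names(half_v), "e_vdw"] <- acc[names(half_v), "e_vdw"] + half_v
    half_v_l <- 0.5 * (rowsum(colSums(evd), fl)[, 1])
    acc[names(half_v_l), "e_vdw"] <- acc[names(half_v_l), "e_vdw"] + half_v_l
    # nonpolar: per-atom delta-SASA on complexation
    ft <- frame_terms(sk, idx_rec, idx_lig, settings, pb = pb)
    dsasa <- c(ft$sas$complex$per_atom[seq_along(idx_rec)] -
                 ft$sas$rec$per_atom,
               ft$sas$complex$per_atom[length(idx_rec) + seq_along(idx_lig)] -
                 ft$sas$lig$per_atom)
    np_atom <- settings$gamma * dsasa
    tot_np <- sum(np_atom)
    beta_share <- if (abs(tot_np) > 1e-12) {
      -settings$beta * np_atom / tot_np
    } else rep(-settings$beta / length(np_atom), length(np_atom))
    np_atom <- np_atom + beta_share
    fres <- factor(rkey[all_idx], res_keys)
    np_res <- rowsum(np_atom, fres)[, 1]
    acc[names(np_res), "g_nonp"] <- acc[names(np_res), "g_nonp"] + np_res
    if (pb) {
      pb_atom <- c(ft$pb$complex$per_atom[seq_along(idx_rec)] -
                     ft$pb$rec$per_atom,
                   ft$pb$complex$per_atom[length(idx_rec) +
                                            seq_along(idx_lig)] -
                     ft$pb$lig$per_atom)
      pb_res <- rowsum(pb_atom, fres)[, 1]
      acc[names(pb_res), "g_pb"] <- acc[names(pb_res), "g_pb"] + pb_res
    }
  }
  acc <- acc / length(fidx)
  u <- a[match(res_keys, rkey), c("chain", "res_id", "res_name")]
  out <- data.frame(u, acc, row.names = NULL, stringsAsFactors = FALSE)
  names(out)[4:7] <- c("e_ele", "e_vdw", "g_pb_share", "g_nonp_share")
  out$total <- out$e_ele + out$e_vdw + out$g_pb_share + out$g_nonp_share
  out
}
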