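# small settings used throughout: coarse grid keeps PB solves fast on toys
fast_pb <- pb_settings(grid_spacing = 0.8, box_margin = 5)

point_set <- function(xyz, charge = 0, rmin_half = 1.908, eps = 0.086,
                      rad = 1.7) {
  data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], charge = charge,
             lj_rmin_half = rmin_half, lj_epsilon = eps, solv_radius = rad)
}

test_that("coulomb energy matches hand arithmetic and scales with 1/eps", {
  a <- point_set(matrix(c(0, 0, 0), 1), charge = 1)
  b <- point_set(matrix(c(3.320637, 0, 0), 1), charge = 1)
  expect_equal(coulomb_energy(a, b, eps = 1), 100.00, tolerance = 1e-10)
  expect_equal(coulomb_energy(a, b, eps = 2),
               coulomb_energy(a, b, eps = 1) / 2)
  expect_equal(coulomb_energy(a[0, ], b), 0)
  expect_equal(coulomb_energy(a, b[0, ]), 0)
  b0 <- point_set(matrix(c(0, 0, 0), 1), charge = 1)
  expect_error(coulomb_energy(a, b0), "coincident")
})

test_that("LJ energy has its minimum and zero at the closed-form radii", {
  e1 <- 0.086; e2 <- 0.21
  rmin <- 1.908 + 1.661
  a <- point_set(matrix(c(0, 0, 0), 1), eps = e1, rmin_half = 1.908)
  b <- function(r) point_set(matrix(c(r, 0, 0), 1), eps = e2,
                             rmin_half = 1.661)
  expect_equal(lj_energy(a, b(rmin)), -sqrt(e1 * e2), tolerance = 1e-12)
  expect_equal(lj_energy(a, b(rmin / 2^(1/6))), 0, tolerance = 1e-10)
  # brute-force pair enumeration oracle on a 3x2 system
  set.seed(5)
  A <- point_set(matrix(rnorm(9, sd = 3), 3), eps = 0.1, rmin_half = 1.8)
  B <- point_set(matrix(rnorm(6, sd = 3) + 8, 2), eps = 0.2,
                 rmin_half = 1.9)
  manual <- 0
  for (i in 1:3) for (j in 1:2) {
    r <- sqrt(sum((as.numeric(A[i, 1:3]) - as.numeric(B[j, 1:3]))^2))
    rm <- A$lj_rmin_half[i] + B$lj_rmin_half[j]
    ep <- sqrt(A$lj_epsilon[i] * B$lj_epsilon[j])
    manual <- manual + ep * ((rm / r)^12 - 2 * (rm / r)^6)
  }
  expect_equal(lj_energy(A, B), manual, tolerance = 1e-10)
})

test_that("sasa matches closed forms and detects burial", {
  one <- point_set(matrix(c(0, 0, 0), 1), rad = 1.7)
  r1 <- sasa(one, probe = 1.4, n_points = 960)
  expect_equal(r1$total, 4 * pi * 3.1^2, tolerance = 0.01)
  expect_equal(r1$total, sum(r1$per_atom))

  # beyond r1 + r2 + 2 probe: no occlusion
  two <- point_set(matrix(c(0, 0, 0, 7.0, 0, 0), 2, byrow = TRUE),
                   rad = 1.7)
  expect_equal(sasa(two)$total, 2 * r1$total, tolerance = 1e-9)

  # caged central atom is fully buried
  sph <- pepcycle:::unit_sphere_points(60) * 2.0
  cage <- point_set(rbind(c(0, 0, 0), sph), rad = 1.5)
  expect_equal(sasa(cage)$per_atom[1], 0)

  # monotone decrease on approach (until burial)
  tot <- vapply(seq(6, 1, by = -0.5), function(d)
    sasa(point_set(matrix(c(0, 0, 0, d, 0, 0), 2, byrow = TRUE)))$total,
    numeric(1))
  expect_true(all(diff(tot) <= 1e-9))
})

test_that("nonpolar term is the linear SASA model", {
  st <- pb_settings()
  expect_equal(nonpolar_solvation(0, st), 0.92)
  expect_equal(nonpolar_solvation(1000, st), 6.34)
  S <- 537.3
  expect_equal(nonpolar_solvation(2 * S, st) - nonpolar_solvation(S, st),
               st$gamma * S)
})

test_that("PB solver approaches the Born energy with first-order spacing", {
  born <- -0.5 * 332.0637 * (1 - 1 / 80) / 2.0
  ion_free <- function(h) pb_settings(grid_spacing = h, box_margin = 6,
                                      ionic_strength = 0)
  sph <- point_set(matrix(c(0, 0, 0), 1), charge = 1, rad = 2.0)
  e1 <- polar_solvation(sph, ion_free(0.5))$total
  e2 <- polar_solvation(sph, ion_free(0.25))$total
  expect_lt(abs(e2 - born), abs(e1 - born))   # order >= linear
  expect_lt(abs(e2 - born) / abs(born), 0.05)

  # no charges, and no dielectric contrast, both give zero
  neutral <- point_set(matrix(c(0, 0, 0), 1), charge = 0, rad = 2.0)
  expect_equal(polar_solvation(neutral, ion_free(0.5))$total, 0)
  same_eps <- pb_settings(eps_internal = 80, eps_external = 80,
                          grid_spacing = 0.5, box_margin = 6,
                          ionic_strength = 0)
  expect_equal(polar_solvation(sph, same_eps)$total, 0, tolerance = 0.5)
})

test_that("binding_energy obeys the aggregation identities", {
  s <- salt_bridge_complex()
  e <- make_ensemble(s, 4, 0.1, seed = 2, first_frame_reference = TRUE)
  be <- binding_energy(e, list(chain = "A"), list(chain = "B"), fast_pb,
                       trailing_fraction = 0.5)
  expect_equal(be$e_int, 0)
  expect_equal(be$e_mm, be$e_ele + be$e_vdw + be$e_int)
  expect_equal(be$g_solv, be$g_pb + be$g_nonp)
  expect_equal(be$g_bind, be$e_mm + be$g_solv)
  expect_error(binding_energy(e, list(chain = "A"),
                              list(chain = c("A", "B")), fast_pb),
               "overlap")
})

test_that("gas terms are rigid-motion invariant but partner-motion sensitive", {
  s <- salt_bridge_complex()
  aset <- atom_set(s, list(chain = "A"))
  bset <- atom_set(s, list(chain = "B"))
  th <- 0.9
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  move <- function(set) {
    xyz <- as.matrix(set[, c("x", "y", "z")]) %*% t(R)
    set$x <- xyz[, 1] + 2; set$y <- xyz[, 2] - 1; set$z <- xyz[, 3]
    set
  }
  expect_equal(coulomb_energy(move(aset), move(bset)),
               coulomb_energy(aset, bset), tolerance = 1e-9)
  expect_equal(lj_energy(move(aset), move(bset)), lj_energy(aset, bset),
               tolerance = 1e-9)
  # moving only one partner changes the cross terms
  expect_gt(abs(coulomb_energy(aset, move(bset)) -
                  coulomb_energy(aset, bset)), 1e-3)
})

test_that("single-frame binding energy equals hand-assembled terms", {
  s <- lj_only_pair(4.0)
  e <- new_ensemble(s, list(coords(s)))
  st <- fast_pb
  be <- binding_energy(e, list(chain = "A"), list(chain = "B"), st,
                       trailing_fraction = 1)
  aset <- atom_set(s, list(chain = "A"))
  bset <- atom_set(s, list(chain = "B"))
  lj <- lj_energy(aset, bset)
  dS <- sasa(rbind(aset, bset), st$probe_radius)$total -
    sasa(aset, st$probe_radius)$total - sasa(bset, st$probe_radius)$total
  expect_equal(be$e_ele, 0)
  expect_equal(be$g_pb, 0)   # all charges zero
  expect_equal(be$g_bind, lj + st$gamma * dS - st$beta, tolerance = 1e-9)
  # averaging over one frame is exact: per-frame table equals the means
  expect_equal(nrow(be$frames), 1L)
  expect_equal(be$frames$e_vdw[1], be$e_vdw)
})

test_that("per-residue decomposition conserves the totals", {
  s <- salt_bridge_complex()
  e <- make_ensemble(s, 2, 0.05, seed = 6, first_frame_reference = TRUE)
  st <- fast_pb
  be <- binding_energy(e, list(chain = "A"), list(chain = "B"), st,
                       trailing_fraction = 1, pb = FALSE)
  dec <- per_residue_decomposition(e, list(chain = "A"),
                                   list(chain = "B"), st,
                                   trailing_fraction = 1, pb = FALSE)
  expect_equal(sum(dec$e_ele), be$e_ele, tolerance = 1e-6)
  expect_equal(sum(dec$e_vdw), be$e_vdw, tolerance = 1e-6)
  expect_equal(sum(dec$total), be$g_bind, tolerance = 1e-6)

  # with PB on, polar shares still sum to the complex-level polar term
  be2 <- binding_energy(e, list(chain = "A"), list(chain = "B"), st,
                        trailing_fraction = 1, pb = TRUE)
  dec2 <- per_residue_decomposition(e, list(chain = "A"),
                                    list(chain = "B"), st,
                                    trailing_fraction = 1, pb = TRUE)
  expect_equal(sum(dec2$g_pb_share), be2$g_pb, tolerance = 1e-6)
  expect_equal(sum(dec2$total), be2$g_bind, tolerance = 1e-6)
})

test_that("symmetric toys decompose into equal shares; pairs match direct", {
  # two single-atom residues per chain, mirror symmetric
  mk <- function(ch, res, x, q) data.frame(
    serial = NA_integer_, name = "CA", res_name = "GLY", chain = ch,
    auth_seq = res, res_id = res, x = x, y = if (ch == "A") 0 else 4,
    z = 0, element = "C", het = FALSE, stringsAsFactors = FALSE)
  atoms <- rbind(mk("A", 1, -2, 0), mk("A", 2, 2, 0),
                 mk("B", 1, -2, 0), mk("B", 2, 2, 0))
  atoms$serial <- seq_len(nrow(atoms))
  s <- pepcycle:::new_molstruct(atoms)
  s$atoms$charge <- c(0.5, 0.5, -0.5, -0.5)
  s$atoms$lj_rmin_half <- 1.9; s$atoms$lj_epsilon <- 0.1
  s$atoms$solv_radius <- 1.7
  e <- new_ensemble(s, list(coords(s)))
  dec <- per_residue_decomposition(e, list(chain = "A"),
                                   list(chain = "B"), fast_pb,
                                   trailing_fraction = 1, pb = FALSE)
  a_rows <- dec$chain == "A"
  # gas terms split exactly; the SASA share carries O(1/n_points)
  # quadrature asymmetry, so totals agree only to that level
  expect_equal(dec$e_ele[a_rows][1], dec$e_ele[a_rows][2])
  expect_equal(dec$e_vdw[a_rows][1], dec$e_vdw[a_rows][2])
  expect_equal(dec$total[a_rows][1], dec$total[a_rows][2],
               tolerance = 0.01)

  # single charged residue pair: decomposition equals the pair energies
  s1 <- pepcycle:::new_molstruct(rbind(mk("A", 1, 0, 0), mk("B", 1, 0, 0)))
  s1$atoms$charge <- c(1, -1)
  s1$atoms$lj_rmin_half <- 1.9; s1$atoms$lj_epsilon <- 0.1
  s1$atoms$solv_radius <- 1.7
  e1 <- new_ensemble(s1, list(coords(s1)))
  d1 <- per_residue_decomposition(e1, list(chain = "A"),
                                  list(chain = "B"), fast_pb,
                                  trailing_fraction = 1, pb = FALSE)
  aset <- atom_set(s1, list(chain = "A"))
  bset <- atom_set(s1, list(chain = "B"))
  expect_equal(sum(d1$e_ele), coulomb_energy(aset, bset), tolerance = 1e-9)
  expect_equal(sum(d1$e_vdw), lj_energy(aset, bset), tolerance = 1e-9)
  expect_equal(d1$e_ele[1], d1$e_ele[2])  # half to each residue
})

test_that("energy_breakdown enforces identities on arbitrary components", {
  eb <- energy_breakdown(-33.51, -88.74, 80.73, -9.28)
  expect_equal(eb$e_mm, -122.25)
  expect_equal(eb$g_solv, 71.45)
  expect_equal(eb$g_bind, -50.80)
  eb2 <- energy_breakdown(1, 2, 3, 4, e_int = 0, ts_term = -5)
  expect_equal(eb2$g_bind, 1 + 2 + 3 + 4 - 5)
})
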