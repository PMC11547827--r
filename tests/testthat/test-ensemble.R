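# independent oracle: planar point sets, minimum over a rotation grid at
# 1e-3 rad resolution (translation removed by centroids). For planar
# configurations every optimal 3-D rotation acts in-plane either as a
# rotation or as a reflection (a 180-degree flip about an in-plane axis
# is a proper rotation), so both one-parameter families are scanned.
grid_rmsd_2d <- function(mobile, ref) {
  mc <- sweep(mobile, 2, colMeans(mobile))
  rc <- sweep(ref, 2, colMeans(ref))
  best <- Inf
  for (th in seq(0, 2 * pi, by = 1e-3)) {
    Rrot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0,
                     0, 0, 1), 3, 3)
    Rflip <- matrix(c(cos(th), sin(th), 0, sin(th), -cos(th), 0,
                      0, 0, -1), 3, 3)
    r <- min(sqrt(mean(rowSums((mc %*% t(Rrot) - rc)^2))),
             sqrt(mean(rowSums((mc %*% t(Rflip) - rc)^2))))
    if (r < best) best <- r
  }
  best
}

test_that("superpose recovers rigid transforms and matches a grid oracle", {
  set.seed(10)
  x <- matrix(rnorm(30), 10, 3)
  expect_lt(superpose(sweep(x, 2, c(5, 0, 0), "+"), x)$rmsd, 1e-10)
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)  # 90 deg about z
  expect_lt(superpose(x %*% t(Rz), x)$rmsd, 1e-10)

  # 4-point planar toys vs brute-force rotation grid
  for (k in 1:3) {
    set.seed(k)
    ref <- cbind(matrix(rnorm(8), 4, 2), 0)
    mob <- cbind(matrix(rnorm(8), 4, 2), 0)
    expect_equal(superpose(mob, ref)$rmsd, grid_rmsd_2d(mob, ref),
                 tolerance = 1e-3)
  }

  # applying the returned transform reproduces the reported rmsd
  mob2 <- x %*% t(Rz) + 0.1 * matrix(rnorm(30), 10, 3)
  sp <- superpose(mob2, x)
  expect_equal(coord_rmsd(sp$transform(mob2), x), sp$rmsd,
               tolerance = 1e-8)

  expect_error(superpose(x[1:2, ], x[1:2, ]), "degenerate")
  lin <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(superpose(lin, lin), "collinear")
})

test_that("rmsd_series matches the isotropic-noise closed form", {
  s <- make_toy_complex(4, 4, 4.5, seed = 6)
  n_atoms <- sum(s$atoms$is_heavy)
  sigma <- 0.3
  e <- make_ensemble(s, 201, per_atom_sigma = sigma, seed = 8,
                     first_frame_reference = TRUE)
  rs <- rmsd_series(e)
  expect_equal(rs$values[1], 0)
  # E[RMSD] ~ sigma sqrt(3) sqrt((N - 2)/N) after removing 6 fit DOF
  expected <- sigma * sqrt(3) * sqrt((n_atoms - 2) / n_atoms)
  expect_equal(mean(rs$values[-1]), expected, tolerance = 0.1)

  e1 <- new_ensemble(s, e$frames[1])
  expect_equal(rmsd_series(e1)$values, 0)
})

test_that("rmsf recovers a designed per-residue profile", {
  s <- build_extended_chain("AAAA", "A")
  prof <- c("1" = 0.2, "2" = 1.0, "3" = 0.2, "4" = 0.2)
  e <- make_ensemble(s, 2000, per_atom_sigma = prof, seed = 12)
  rf <- rmsf(e, align = FALSE)
  expect_equal(rf$values[2] / rf$values[1], 5, tolerance = 0.1)
  # sigma -> rmsf linearity: doubling all sigmas doubles rmsf
  e2 <- make_ensemble(s, 2000, per_atom_sigma = 2 * prof, seed = 12)
  rf2 <- rmsf(e2, align = FALSE)
  expect_equal(rf2$values / rf$values, rep(2, 4), tolerance = 0.05)
  # static ensemble -> all zero
  e0 <- make_ensemble(s, 5, 0, seed = 1)
  expect_equal(rmsf(e0)$values, rep(0, 4))
})

test_that("rmsd and rmsf are invariant under rigid motion of every frame", {
  s <- make_toy_complex(3, 3, 4.5, seed = 4)
  e <- make_ensemble(s, 30, 0.25, seed = 3, first_frame_reference = TRUE)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- lapply(e$frames, function(f)
    sweep(f %*% t(R), 2, c(3, -2, 7), "+"))
  em <- new_ensemble(s, moved)
  expect_equal(rmsd_series(em)$values, rmsd_series(e)$values,
               tolerance = 1e-8)
  expect_equal(rmsf(em)$values, rmsf(e)$values, tolerance = 1e-8)
})

test_that("interface_residues matches a brute-force scan and is symmetric", {
  s <- make_toy_complex(5, 4, 4.2, seed = 21)
  ir <- interface_residues(s, "A", "B", 5)
  # O(n^2) oracle with explicit loops, no matrix algebra
  a <- s$atoms[s$atoms$is_heavy, ]
  oracle <- list(a = integer(0), b = integer(0))
  for (i in which(a$chain == "A")) for (j in which(a$chain == "B")) {
    d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
                (a$z[i] - a$z[j])^2)
    if (d <= 5) {
      oracle$a <- union(oracle$a, a$res_id[i])
      oracle$b <- union(oracle$b, a$res_id[j])
    }
  }
  expect_setequal_int(ir$a, oracle$a)
  expect_setequal_int(ir$b, oracle$b)
  rev <- interface_residues(s, "B", "A", 5)
  expect_equal(rev$a, ir$b)
  expect_equal(rev$b, ir$a)
  expect_error(interface_residues(s, "A", "Z"), "not found")
})

test_that("interface cutoff boundary is inclusive", {
  mk <- function(ch, y) data.frame(
    serial = 1L, name = "CA", res_name = "GLY", chain = ch, auth_seq = 1L,
    res_id = 1L, x = 0, y = y, z = 0, element = "C", het = FALSE,
    stringsAsFactors = FALSE)
  near <- pepcycle:::new_molstruct(rbind(mk("A", 0), mk("B", 4.9)))
  ir <- interface_residues(near, "A", "B", 5)
  expect_equal(ir$a, 1L); expect_equal(ir$b, 1L)
  far <- pepcycle:::new_molstruct(rbind(mk("A", 0), mk("B", 5.1)))
  ir2 <- interface_residues(far, "A", "B", 5)
  expect_equal(length(ir2$a), 0L)
})

test_that("hydrogen-bond occupancy is exact and order-invariant", {
  e <- make_hbond_ensemble(0.5, 100, seed = 2)
  hb <- hydrogen_bonds(e, min_occupancy = 0)
  target <- hb[hb$donor_chain == "A" & hb$donor_atom == "N" &
                 hb$acceptor_atom == "O", ]
  expect_equal(target$occupancy, 50)

  eall <- make_hbond_ensemble(1, 40, seed = 2)
  hb2 <- hydrogen_bonds(eall, min_occupancy = 0)
  expect_equal(max(hb2$occupancy), 100)
  expect_true(all(diff(hb2$occupancy) <= 0))  # sorted descending

  perm <- new_ensemble(e$topology, e$frames[sample(length(e$frames))])
  hbp <- hydrogen_bonds(perm, min_occupancy = 0)
  expect_equal(hbp$occupancy, hb$occupancy)
})

test_that("dccm reproduces constructed correlation structure", {
  mk2 <- function() {
    rows <- do.call(rbind, lapply(1:3, function(r) data.frame(
      serial = r, name = "CA", res_name = "GLY", chain = "A",
      auth_seq = r, res_id = r, x = 10 * r, y = 0, z = 0, element = "C",
      het = FALSE, stringsAsFactors = FALSE)))
    pepcycle:::new_molstruct(rows)
  }
  s <- mk2()
  ref <- coords(s)
  set.seed(31)
  shared <- lapply(1:400, function(k) {
    d <- rnorm(3)
    rbind(ref[1, ] + d, ref[2, ] + d, ref[3, ] - d)
  })
  cm <- dccm(new_ensemble(s, shared), selection = "calpha", align = FALSE)
  expect_equal(cm[1, 2], 1, tolerance = 1e-8)
  expect_equal(cm[1, 3], -1, tolerance = 1e-8)
  expect_equal(diag(cm), rep(1, 3))
  expect_equal(cm, t(cm))
  expect_true(all(cm >= -1 & cm <= 1))

  indep <- lapply(1:5000, function(k) ref + matrix(rnorm(9), 3, 3))
  ci <- dccm(new_ensemble(s, indep), selection = "calpha", align = FALSE)
  expect_lt(max(abs(ci[upper.tri(ci)])), 0.05)
})

test_that("shared-group ensembles drive dccm toward +1", {
  s <- build_extended_chain("GGGG", "A")
  ca <- which(s$atoms$name == "CA")
  e <- make_ensemble(s, 1500, per_atom_sigma = 0.05,
                     correlated_groups = list(seq_len(nrow(s$atoms))),
                     group_sigma = 1.0, seed = 17)
  cm <- dccm(e, selection = "calpha", align = FALSE)
  expect_gt(min(cm), 0.95)
})
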