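test_that("truncation windows are ranked by key coverage", {
  keys <- c(62, 65, 66, 67, 68, 71)
  # exhaustive scan oracle at window 10 over chain 60..75
  best <- propose_truncations(keys, 60:75, 10)[1, ]
  expect_equal(best$covered, 6L)
  oracle <- max(vapply(60:66, function(s)
    sum(keys >= s & keys <= s + 9), integer(1)))
  expect_equal(best$covered, oracle)

  # window shorter than the spacing of any two keys -> coverage 1
  sparse <- c(60, 70)
  w <- propose_truncations(sparse, 58:75, 5)
  expect_equal(max(w$covered), 1L)

  # single key, tie broken toward the lowest start containing it
  one <- propose_truncations(65, 60:75, 6)
  expect_equal(one$covered[1], 1L)
  expect_true(one$start[1] <= 65 && one$end[1] >= 65)
  full <- one[one$covered == 1L, ]
  expect_equal(one$start[1], min(full$start))

  expect_equal(nrow(propose_truncations(integer(0), 1:10, 5)), 0L)
  expect_error(propose_truncations(99, 1:10, 5), "outside")
})

test_that("CC cyclization indexes the added cysteines as 1 and n", {
  d <- cyclize(linear_candidate("TISRIAVSYQTKVNLLS", "alpha", 8), "CC")
  expect_equal(nchar(d$sequence), 19L)
  ch <- strsplit(d$sequence, "")[[1]]
  expect_equal(ch[c(1, 19)], c("C", "C"))
  expect_equal(ch[2], "T")    # Thr2
  expect_equal(ch[10], "Y")   # Tyr10
  expect_equal(ch[13], "K")   # Lys13
  expect_equal(ch[14], "V")   # Val14
  expect_equal(ch[15], "N")   # Asn15
  expect_equal(d$closure$type, "disulfide")
  expect_equal(d$closure$residues, c(1L, 19L))
  expect_equal(d$name, "α_CC8")
})

test_that("GP cyclization appends GP with an amide closure", {
  d <- cyclize(linear_candidate("FTASENH", "R1", 2), "GP")
  expect_equal(nchar(d$sequence), 9L)
  expect_equal(substr(d$sequence, 7, 9), "HGP")
  expect_equal(d$closure$type, "amide")
  expect_equal(d$closure$residues, c(9L, 1L))
  expect_equal(d$name, "R1_GP2")
  # base subsequence preserved verbatim in both strategies
  for (strat in c("GP", "CC")) {
    dd <- cyclize(linear_candidate("ASENHLRHCL", "R1", 1), strat)
    expect_true(grepl("ASENHLRHCL", dd$sequence, fixed = TRUE))
  }
})

test_that("re-cyclizing a CC product warns about terminal cysteines", {
  d <- cyclize("FTASENH", "CC")
  expect_warning(cyclize(d$sequence, "CC"), "terminal cysteine")
})

test_that("design names round-trip, including the ligand-source prefix", {
  expect_equal(parse_design_name("R1_CC4"),
               list(source = "R1", strategy = "CC", serial = 4L))
  expect_equal(parse_design_name("α_GP10"),
               list(source = "alpha", strategy = "GP", serial = 10L))
  expect_equal(parse_design_name("alpha_CC8")$source, "alpha")
  designs <- enumerate_designs(packaged_candidates())
  for (d in designs) {
    p <- parse_design_name(d$name)
    expect_equal(p$strategy, d$strategy)
    expect_equal(p$serial, d$base$serial)
    expect_equal(p$source, d$base$source)
  }
  expect_error(parse_design_name("R2_CC4"), "cannot parse")
})

test_that("enumeration doubles the candidate list deterministically", {
  cands <- packaged_candidates()
  expect_length(cands, 11L)
  designs <- enumerate_designs(cands)
  expect_length(designs, 22L)
  strategies <- vapply(designs, `[[`, character(1), "strategy")
  expect_equal(strategies, rep(c("GP", "CC"), 11))
  serials <- vapply(designs, function(d) d$base$serial, integer(1))
  expect_true(!is.unsorted(serials))
  expect_length(enumerate_designs(cands[1]), 2L)
  expect_length(enumerate_designs(list()), 0L)
  # controls ship flagged and separate
  all14 <- packaged_candidates(include_controls = TRUE)
  expect_length(all14, 13L)
  expect_equal(sum(vapply(all14, `[[`, logical(1), "external_control")), 2L)
})

test_that("built rings satisfy the closure contract", {
  dcc <- cyclize(linear_candidate("ASENH", "R1", 1), "CC")
  ring <- build_cyclic_geometry(dcc)
  expect_lte(attr(ring, "closure_residual"), 0.2)
  ij <- pepcycle:::closure_atom_indices(ring, dcc)
  x <- coords(ring)
  ss <- sqrt(sum((x[ij[1], ] - x[ij[2], ])^2))
  expect_equal(ss, 2.05, tolerance = 0.2)

  dgp <- cyclize(linear_candidate("FTASENH", "R1", 2), "GP")
  ring2 <- build_cyclic_geometry(dgp)
  ij2 <- pepcycle:::closure_atom_indices(ring2, dgp)
  x2 <- coords(ring2)
  cn <- sqrt(sum((x2[ij2[1], ] - x2[ij2[2], ])^2))
  expect_equal(cn, 1.33, tolerance = 0.2)

  # relaxation trace is monotone non-increasing on fixtures
  tr <- attr(ring, "closure_trace")
  if (length(tr) > 1) expect_true(all(diff(tr) <= 1e-9))
})

test_that("a built design feeds the scoring engine end to end", {
  d <- cyclize(linear_candidate("TISRIAVSYQTKVNLLS", "alpha", 8), "CC")
  ring <- build_cyclic_geometry(d)
  # pair the ring with a small receptor chain placed below it
  rec <- build_extended_chain("ANLV", "R", origin = c(-6, -14, 0))
  atoms <- rbind(rec$atoms, ring$atoms)
  atoms$serial <- seq_len(nrow(atoms))
  cplx <- assign_parameters(pepcycle:::new_molstruct(atoms))
  e <- new_ensemble(cplx, list(coords(cplx)))
  be <- binding_energy(e, list(chain = "R"), list(chain = "P"),
                       pb_settings(grid_spacing = 1.0, box_margin = 4),
                       trailing_fraction = 1, pb = FALSE)
  expect_true(is.finite(be$g_bind))
  expect_equal(be$e_int, 0)
})

test_that("FASTA round trip preserves designs and closures", {
  designs <- enumerate_designs(packaged_candidates())
  p <- tempfile(fileext = ".fasta")
  write_designs_fasta(designs, p)
  back <- read_designs_fasta(p)
  expect_length(back, 22L)
  expect_equal(vapply(back, `[[`, character(1), "sequence"),
               vapply(designs, `[[`, character(1), "sequence"))
  expect_equal(vapply(back, `[[`, character(1), "name"),
               vapply(designs, `[[`, character(1), "name"))
})

test_that("template-based ring building splices base coordinates", {
  base <- "ASENH"
  tmpl <- build_extended_chain(base, "T")
  d <- cyclize(linear_candidate(base, "R1", 1), "CC")
  ring <- build_cyclic_geometry(d, template = tmpl)
  expect_lte(attr(ring, "closure_residual"), 0.2)
  expect_equal(chain_sequence(ring, "P"), d$sequence)
  expect_error(
    build_cyclic_geometry(cyclize(linear_candidate("WWWW", "R1", 1), "CC"),
                          template = tmpl),
    "does not match")
})
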