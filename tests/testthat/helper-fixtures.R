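# Shared fixtures, built in code at test time.

# hand-written 3-atom single-residue PDB text
tiny_pdb_lines <- function() c(
  "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
  "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
  "TER",
  "END")

write_tiny_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(tiny_pdb_lines(), path)
  path
}

# two-MODEL ensemble text built from the tiny fixture
write_two_model_pdb <- function(path = tempfile(fileext = ".pdb")) {
  atom <- tiny_pdb_lines()[1:3]
  shifted <- sub("0\\.000   0\\.000   0\\.000", "1.000   0.000   0.000",
                 atom[1])
  writeLines(c("MODEL        1", shifted, atom[2:3], "ENDMDL",
               "MODEL        2", atom, "ENDMDL", "END"),
             path)
  path
}

# deterministic small two-chain complex with a salt bridge (Arg on A,
# Glu on B) used across energetics/scanning tests
salt_bridge_complex <- function(gap = 4.0) {
  assign_parameters(make_toy_complex(3, 3, gap = gap, seed = 1,
                                     seq_a = "ARA", seq_b = "AEA"))
}

# neutral two-atom-per-chain parameterized frame for LJ-only checks
lj_only_pair <- function(r = 4.0) {
  mk <- function(ch, x) data.frame(
    serial = NA_integer_, name = "CA", res_name = "ALA", chain = ch,
    auth_seq = 1L, res_id = 1L, x = x, y = c(0, 1.5), z = 0,
    element = "C", het = FALSE, stringsAsFactors = FALSE)
  atoms <- rbind(mk("A", 0), mk("B", r))
  atoms$serial <- seq_len(nrow(atoms))
  s <- pepcycle:::new_molstruct(atoms, "lj_toy")
  s$atoms$charge <- 0
  s$atoms$lj_rmin_half <- 1.908
  s$atoms$lj_epsilon <- 0.086
  s$atoms$solv_radius <- 1.7
  s
}

expect_setequal_int <- function(a, b) expect_setequal(as.integer(a),
                                                      as.integer(b))
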