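# End-to-end pipeline: simulate (or load) -> analyze interface -> score
# -> alanine scan -> design -> mutate + re-score, with a JSON config, a
# checksummed output manifest, and per-stage logging. Deterministic for a
# given config + seed.

default_config <- function() {
  list(
    out_dir = "pepcycle_run",
    seed = 1L,
    complex = list(pdb = NULL, n_res_a = 4L, n_res_b = 4L, gap = 4.5,
                   seq_a = "ARLA", seq_b = "AELA"),
    receptor = NULL, ligand = NULL,
    ensemble = list(n_frames = 8L, sigma = 0.15),
    pb = list(grid_spacing = 0.8, box_margin = 5),
    use_pb = TRUE,
    trailing_fraction = 0.5,
    scan = "interface", interface_cutoff = 5.0,
    design = list(packaged = TRUE, build = "first_cc"),
    mutation = NULL)
}

read_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- utils::modifyList(default_config(), config)
  # validate before any compute
  if (is.null(cfg$receptor) || is.null(cfg$ligand))
    stop("config error: receptor and ligand selections are required",
         call. = FALSE)
  if (!is.null(cfg$complex$pdb) && !file.exists(cfg$complex$pdb))
    stop("config error: complex PDB not found: ", cfg$complex$pdb,
         call. = FALSE)
  cfg
}

write_num_csv <- function(df, path) {
  # fixed formatting so reruns are byte-identical
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.6f", v))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the full design pipeline
#'
#' Stages: `simulate` (toy complex + Gaussian ensemble, or a user PDB),
#' `analyze` (RMSD, RMSF, interface, hydrogen bonds, DCCM), `mmpbsa`
#' (binding free energy + per-residue decomposition), `alascan`
#' (interface alanine scan), `design` (cyclization of the packaged or
#' user candidates, one built ring), `mutate` (optional point mutation of
#' a ligand residue and re-score). Identical config and seed give
#' byte-identical numeric CSVs.
#'
#' @param config a config list or path to a JSON config; see the vignette
#'   for the schema. Required: `receptor`, `ligand` chain ids.
#' @return the manifest (list), invisibly; written as `manifest.json` in
#'   `out_dir` with an md5 checksum per output file.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- read_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  stages <- character(0)
  t_all <- Sys.time()
  log_stage <- function(name, expr) {
    t0 <- Sys.time()
    v <- force(expr)
    message(sprintf("[pepcycle] stage %-8s done in %.1fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    stages <<- c(stages, name)
    v
  }
  out <- function(nm) file.path(cfg$out_dir, nm)

  # 1 simulate ------------------------------------------------------------
  sim <- log_stage("simulate", {
    s <- if (!is.null(cfg$complex$pdb)) read_pdb(cfg$complex$pdb)
    else make_toy_complex(cfg$complex$n_res_a, cfg$complex$n_res_b,
                          gap = cfg$complex$gap, seed = cfg$seed,
                          seq_a = cfg$complex$seq_a,
                          seq_b = cfg$complex$seq_b)
    s <- assign_parameters(s)
    e <- make_ensemble(s, n_frames = cfg$ensemble$n_frames,
                       per_atom_sigma = cfg$ensemble$sigma,
                       seed = cfg$seed, first_frame_reference = TRUE)
    write_pdb(s, out("complex.pdb"))
    write_ensemble(e, out("ensemble.pdb"))
    files <- c(files, out("complex.pdb"), out("ensemble.pdb"))
    list(s = s, e = e)
  })
  files <- c(files, out("complex.pdb"), out("ensemble.pdb"))
  s <- sim$s; e <- sim$e
  settings <- do.call(pb_settings, cfg$pb)

  # 2 analyze -------------------------------------------------------------
  log_stage("analyze", {
    rs <- rmsd_series(e, trailing_fraction = cfg$trailing_fraction)
    files <- c(files, write_num_csv(
      data.frame(frame = seq_along(rs$values), rmsd = rs$values),
      out("rmsd.csv")))
    rf <- rmsf(e)
    files <- c(files, write_num_csv(
      cbind(rf$residues, rmsf = rf$values), out("rmsf.csv")))
    ir <- interface_residues(s, cfg$receptor, cfg$ligand,
                             cutoff = cfg$interface_cutoff)
    files <- c(files, write_num_csv(
      data.frame(chain = c(rep(cfg$receptor, length(ir$a)),
                           rep(cfg$ligand, length(ir$b))),
                 res_id = c(ir$a, ir$b)), out("interface.csv")))
    hb <- hydrogen_bonds(e, min_occupancy = 0)
    files <- c(files, write_num_csv(hb, out("hbonds.csv")))
    dm <- dccm(e)
    files <- c(files, write_num_csv(as.data.frame(dm), out("dccm.csv")))
    ir
  })
  ir <- interface_residues(s, cfg$receptor, cfg$ligand,
                           cutoff = cfg$interface_cutoff)

  # 3 mmpbsa --------------------------------------------------------------
  be <- log_stage("mmpbsa", {
    be <- binding_energy(e, list(chain = cfg$receptor),
                         list(chain = cfg$ligand), settings,
                         cfg$trailing_fraction, pb = isTRUE(cfg$use_pb))
    terms <- c("e_ele", "e_vdw", "e_int", "g_pb", "g_nonp", "e_mm",
               "g_solv", "g_bind")
    files <- c(files, write_num_csv(
      data.frame(term = terms,
                 value = vapply(terms, function(t) be[[t]], numeric(1))),
      out("energy.csv")))
    dec <- per_residue_decomposition(e, list(chain = cfg$receptor),
                                     list(chain = cfg$ligand), settings,
                                     cfg$trailing_fraction,
                                     pb = isTRUE(cfg$use_pb))
    files <- c(files, write_num_csv(dec, out("decomposition.csv")))
    be
  })

  # 4 alascan -------------------------------------------------------------
  log_stage("alascan", {
    resdf <- data.frame(
      chain = c(rep(cfg$receptor, length(ir$a)),
                rep(cfg$ligand, length(ir$b))),
      res_id = c(ir$a, ir$b), stringsAsFactors = FALSE)
    sc <- suppressWarnings(
      alanine_scan(e, list(chain = cfg$receptor),
                   list(chain = cfg$ligand), resdf, settings,
                   cfg$trailing_fraction, pb = isTRUE(cfg$use_pb)))
    files <- c(files, write_num_csv(sc, out("alascan.csv")))
  })

  # 5 design --------------------------------------------------------------
  built_name <- log_stage("design", {
    cands <- if (isTRUE(cfg$design$packaged)) packaged_candidates()
    else lapply(seq_along(cfg$design$sequences), function(i)
      linear_candidate(cfg$design$sequences[[i]], serial = i))
    designs <- enumerate_designs(cands)
    files <- c(files, write_designs_fasta(designs, out("designs.fasta")))
    cc <- Filter(function(d) d$strategy == "CC", designs)[[1]]
    ring <- build_cyclic_geometry(cc)
    files <- c(files, write_cyclic_pdb(ring, cc, out("design_ring.pdb")))
    cc$name
  })

  # 6 mutate + re-score ---------------------------------------------------
  log_stage("mutate", {
    if (!is.null(cfg$mutation)) {
      sm <- point_mutation(s, cfg$mutation, chain = cfg$ligand)
      em <- make_ensemble(sm, n_frames = cfg$ensemble$n_frames,
                          per_atom_sigma = cfg$ensemble$sigma,
                          seed = cfg$seed, first_frame_reference = TRUE)
      bm <- binding_energy(em, list(chain = cfg$receptor),
                           list(chain = cfg$ligand), settings,
                           cfg$trailing_fraction, pb = isTRUE(cfg$use_pb))
      files <- c(files, write_num_csv(
        data.frame(variant = c("wild", cfg$mutation),
                   g_bind = c(be$g_bind, bm$g_bind)),
        out("rescore.csv")))
      files <- c(files, write_pdb(sm, out("mutant.pdb")))
    } else {
      files <- c(files, write_num_csv(
        data.frame(variant = "wild", g_bind = be$g_bind),
        out("rescore.csv")))
    }
  })

  files <- unique(files)
  manifest <- list(
    package_version = as.character(utils::packageVersion("pepcycle")),
    seed = cfg$seed,
    settings = unclass(settings),
    stages = stages,
    built_design = built_name,
    wall_time_s = as.numeric(Sys.time() - t_all, units = "secs"),
    outputs = data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Minimal command-line entry point
#'
#' Subcommands: `run` (full pipeline from a JSON config), `design`
#' (enumerate packaged designs to FASTA), `fit-kd` (one-site fit of a
#' 2-column CSV). Intended for `Rscript -e 'pepcycle::pep_cli()' ...`.
#'
#' @param argv argument vector (default `commandArgs(trailingOnly=TRUE)`).
#' @return exit status, invisibly.
#' @export
pep_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: pep_cli run <config.json> | design <out.fasta> | fit-kd <curve.csv>"
  if (length(argv) < 1L) { message(usage); return(invisible(1L)) }
  cmd <- argv[1]
  if (cmd == "run" && length(argv) >= 2L) {
    run_pipeline(argv[2])
  } else if (cmd == "design" && length(argv) >= 2L) {
    write_designs_fasta(enumerate_designs(packaged_candidates()), argv[2])
    message("wrote ", argv[2])
  } else if (cmd == "fit-kd" && length(argv) >= 2L) {
    fit <- fit_kd(read.csv(argv[2]))
    print(fit)
  } else {
    message(usage); return(invisible(1L))
  }
  invisible(0L)
}
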