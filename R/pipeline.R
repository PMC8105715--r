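# Pipeline front end: one entry point per analysis stage, writing TSV
# tables, JSON summaries and a run manifest into an output directory.
# Outputs are staged in a temporary directory and moved into place only
# on success, so a failing stage leaves no partial outputs.  The thin
# command-line wrapper in inst/cli/memfoot maps shell arguments onto
# run_pipeline().

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
}

.read_flat_config <- function(path) {
  # flat `key = value` document mirroring analysis_config()
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "\\s*=\\s*")[[1]]
    if (length(kv) != 2 || !nzchar(kv[1])) {
      stop("malformed config line: '", ln, "'")
    }
    val <- strsplit(kv[2], "[,\\s]+")[[1]]
    num <- suppressWarnings(as.numeric(val))
    out[[kv[1]]] <- if (anyNA(num)) val else num
  }
  out
}

.load_system <- function(inputs) {
  if (is.null(inputs$structure)) stop("missing input: structure")
  if (!file.exists(inputs$structure)) {
    stop("input file not found: ", inputs$structure)
  }
  st <- read_structure(inputs$structure)
  if (!is.null(inputs$trajectory)) {
    if (!file.exists(inputs$trajectory)) {
      stop("input file not found: ", inputs$trajectory)
    }
    traj <- read_trajectory(inputs$trajectory, st$topology)
  } else {
    traj <- trajectory(st$topology, list(st$frame))
  }
  list(structure = st, traj = traj)
}

.fit_for <- function(traj, config, reference_frame = traj$frames[[1]]) {
  sel <- if (config$fit_selection == "pore") {
    select_beads(traj$topology, category = "protein",
                 residue_range = config$pore_residue_range)
  } else {
    select_beads(traj$topology, category = "protein")
  }
  fit_trajectory(traj, sel, reference_frame)
}

#' Run one pipeline stage
#'
#' Executes a named analysis stage on file inputs and writes its
#' outputs (TSV/JSON) plus a run manifest (command, effective config,
#' input paths with MD5 hashes, seed, package version, timestamp) to
#' `out_dir`.  Deterministic stages are byte-reproducible given
#' identical inputs and configuration.
#'
#' @param command One of `"synth"`, `"fit"`, `"leaflets"`, `"depth"`,
#'   `"heightmap"`, `"density"`, `"contacts"`, `"preference"`,
#'   `"motifs"`.
#' @param inputs Named list of input paths and stage parameters:
#'   `structure` (GRO/PDB) and `trajectory` (multi-GRO) for analysis
#'   stages, `fasta` for `motifs`, `species` for `density`/`contacts`,
#'   `leaflet` for `heightmap`, `dome` (list of [dome_spec()]
#'   arguments) for `synth`.
#' @param config An [analysis_config()], or a named list / flat
#'   key-value file path of overrides.
#' @param out_dir Output directory (created; must not already contain
#'   a manifest).
#' @param seed Integer seed recorded in the manifest and applied to
#'   stochastic stages (`synth`).
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(command, inputs = list(),
                         config = analysis_config(), out_dir,
                         seed = 1L) {
  command <- match.arg(command, c("synth", "fit", "leaflets", "depth",
                                  "heightmap", "density", "contacts",
                                  "preference", "motifs"))
  if (is.character(config) && length(config) == 1) {
    config <- .read_flat_config(config)
  }
  if (!inherits(config, "analysis_config")) {
    config <- do.call(analysis_config, config)
  }
  stage <- file.path(tempfile("memfoot_stage_"))
  dir.create(stage, recursive = TRUE)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)

  run_stage(command, inputs, config, stage, seed)

  in_files <- unlist(inputs[vapply(inputs, function(x)
    is.character(x) && length(x) == 1 && file.exists(x), logical(1))])
  manifest <- list(
    command = command,
    config = unclass(config),
    inputs = if (length(in_files) > 0) {
      lapply(stats::setNames(as.list(in_files), names(in_files)),
             function(p) list(path = p,
                              md5 = unname(tools::md5sum(p))))
    } else list(),
    seed = seed,
    tool_version = as.character(utils::packageVersion("memfoot")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  .write_json(manifest, file.path(stage, "manifest.json"))

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (f in list.files(stage)) {
    file.copy(file.path(stage, f), file.path(out_dir, f),
              overwrite = TRUE)
  }
  invisible(out_dir)
}

run_stage <- function(command, inputs, config, stage, seed) {
  switch(
    command,
    synth = {
      args <- inputs$dome
      if (is.null(args)) args <- list()
      args$seed <- seed
      sys <- make_dome_trajectory(do.call(dome_spec, args))
      write_gro(sys$trajectory, file.path(stage, "system.gro"))
      .write_json(list(spec = sys$truth$spec[
        c("box", "lattice_spacing", "leaflet_separation", "depth_D",
          "width_sigma", "lobe_amplitude", "lobe_count",
          "noise_sigma_xy", "noise_sigma_z", "n_frames", "seed")],
        lipids = sys$truth$lipids),
        file.path(stage, "truth.json"))
    },
    fit = {
      sys <- .load_system(inputs)
      fitted <- .fit_for(sys$traj, config)
      write_gro(fitted, file.path(stage, "fitted.gro"))
      rmsd <- vapply(attr(fitted, "fits"), function(f) f$rmsd_nm,
                     numeric(1))
      .write_tsv(data.frame(frame = seq_along(rmsd), rmsd_nm = rmsd),
                 file.path(stage, "fit_rmsd.tsv"))
    },
    leaflets = {
      sys <- .load_system(inputs)
      hb <- select_beads(sys$traj$topology, category = "lipid",
                         headgroup_only = TRUE)
      ser <- assign_leaflets_series(sys$traj, hb,
                                    config$leaflet_cutoff_nm)
      tab <- do.call(rbind, lapply(seq_along(ser$assignments),
                                   function(i) {
        a <- ser$assignments[[i]]
        data.frame(frame = i, bead_index = a$bead_index,
                   leaflet = a$leaflet)
      }))
      .write_tsv(tab, file.path(stage, "leaflets.tsv"))
      .write_tsv(ser$flips, file.path(stage, "leaflet_flips.tsv"))
    },
    depth = {
      sys <- .load_system(inputs)
      fitted <- .fit_for(sys$traj, config)
      hb <- select_beads(fitted$topology, category = "lipid",
                         headgroup_only = TRUE)
      ser <- assign_leaflets_series(fitted, hb, config$leaflet_cutoff_nm)
      dep <- depth_series(fitted, ser,
                          exclude_first_ns = config$depth_exclusion_ns,
                          percentile = config$surface_percentile)
      .write_tsv(dep, file.path(stage, "depth.tsv"))
      .write_json(aggregate_depth(dep), file.path(stage, "depth_summary.json"))
    },
    heightmap = {
      sys <- .load_system(inputs)
      fitted <- .fit_for(sys$traj, config)
      hb <- select_beads(fitted$topology, category = "lipid",
                         headgroup_only = TRUE)
      ser <- assign_leaflets_series(fitted, hb, config$leaflet_cutoff_nm)
      lf <- if (is.null(inputs$leaflet)) "upper" else inputs$leaflet
      hm <- height_map(fitted, ser, lf, bins = config$heightmap_bins)
      utils::write.table(hm$mean_z,
                         file.path(stage, paste0("heightmap_", lf, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
      .write_json(list(leaflet = lf, bins = hm$bins,
                       x_edges = hm$x_edges, y_edges = hm$y_edges,
                       n_frames = hm$n_frames),
                  file.path(stage, "heightmap_meta.json"))
    },
    density = {
      sys <- .load_system(inputs)
      fitted <- .fit_for(sys$traj, config)
      top <- fitted$topology
      spc <- inputs$species
      if (is.null(spc)) stop("missing input: species")
      if (identical(spc, "protein")) {
        sel <- select_beads(top, category = "protein")
        n_mol <- length(unique(top$beads$chain_id[
          top$beads$category == "protein"]))
      } else {
        sel <- select_beads(top, species = spc, headgroup_only = TRUE)
        n_mol <- length(unique(top$beads$molecule_id[sel + 1L]))
      }
      dm <- density_map(fitted, sel, n_mol, bins = config$heightmap_bins,
                        species = spc)
      utils::write.table(dm$density_norm,
                         file.path(stage, paste0("density_", spc, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
      .write_json(list(species = spc, bins = dm$bins,
                       n_molecules = dm$n_molecules,
                       n_frames = dm$n_frames,
                       x_edges = dm$x_edges, y_edges = dm$y_edges),
                  file.path(stage, "density_meta.json"))
    },
    contacts = {
      sys <- .load_system(inputs)
      fitted <- .fit_for(sys$traj, config)
      spc <- inputs$species
      if (is.null(spc)) stop("missing input: species")
      prof <- contact_profile(fitted, spc, config)
      sig <- significant_residues(prof, config$significance_fraction)
      out <- as.data.frame(prof)
      out$significant <- out$residue_number %in% sig
      .write_tsv(out, file.path(stage, paste0("contacts_", spc, ".tsv")))
    },
    preference = {
      sys <- .load_system(inputs)
      fitted <- .fit_for(sys$traj, config)
      pref <- preference_analysis(fitted, config)
      .write_tsv(as.data.frame(pref), file.path(stage, "preference.tsv"))
    },
    motifs = {
      if (is.null(inputs$fasta)) stop("missing input: fasta")
      if (!file.exists(inputs$fasta)) {
        stop("input file not found: ", inputs$fasta)
      }
      seqs <- read_fasta(inputs$fasta)
      rows <- list()
      for (nm in names(seqs)) {
        for (ty in c("CRAC", "CARC")) {
          h <- scan_motifs(seqs[[nm]], ty)
          if (nrow(h) > 0) rows[[length(rows) + 1L]] <-
              cbind(record = nm, h)
        }
      }
      tab <- if (length(rows) > 0) do.call(rbind, rows) else
        data.frame(record = character(0), motif_type = character(0),
                   start = integer(0), end = integer(0),
                   center = integer(0), matched_sequence = character(0))
      .write_tsv(tab, file.path(stage, "motifs.tsv"))
    }
  )
  invisible(NULL)
}
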