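# Structure and trajectory I/O.
#
# GRO is the native dialect (fixed-width, nm, box on the last line); a
# multi-frame GRO file (concatenated blocks) is the portable trajectory
# format.  PDB files are read through bio3d and converted from Angstrom
# to nm.  Compressed binary trajectory formats (XTC/TRR) have no reader
# in this package's dependency set and are rejected with a clear error.

.parse_gro_block <- function(lines, offset) {
  # offset: 0-based index of the title line within the file
  if (length(lines) < 3) {
    stop("GRO parse error at line ", offset + 1,
         ": truncated file (need title, atom count, box)")
  }
  title <- lines[1]
  natoms <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(natoms) || natoms < 1) {
    stop("GRO parse error at line ", offset + 2,
         ": invalid atom count '", trimws(lines[2]), "'")
  }
  if (length(lines) < natoms + 3) {
    stop("GRO parse error at line ", offset + length(lines),
         ": expected ", natoms, " atom records plus box line")
  }
  atom_lines <- lines[3:(natoms + 2)]
  resnum <- suppressWarnings(as.integer(substr(atom_lines, 1, 5)))
  resname <- trimws(substr(atom_lines, 6, 10))
  beadname <- trimws(substr(atom_lines, 11, 15))
  x <- suppressWarnings(as.numeric(substr(atom_lines, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(atom_lines, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(atom_lines, 37, 44)))
  bad <- which(is.na(resnum) | !nzchar(resname) | !nzchar(beadname) |
                 is.na(x) | is.na(y) | is.na(z))
  if (length(bad) > 0) {
    stop("GRO parse error at line ", offset + 2 + bad[1],
         ": malformed fixed-width atom record")
  }
  box_fields <- suppressWarnings(
    as.numeric(strsplit(trimws(lines[natoms + 3]), "\\s+")[[1]])
  )
  if (length(box_fields) < 3 || any(is.na(box_fields[1:3]))) {
    stop("GRO parse error at line ", offset + natoms + 3,
         ": malformed box line")
  }
  time_ns <- NA_real_
  tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
  if (length(tm) == 1) {
    time_ns <- suppressWarnings(as.numeric(sub("t=\\s*", "", tm)))
  }
  list(natoms = natoms, resnum = resnum, resname = resname,
       beadname = beadname, coords = cbind(x, y, z),
       box = box_fields[1:3], time_ns = time_ns,
       n_lines = natoms + 3L)
}

# Assign category/species/headgroup from residue-name rules.  Standard
# amino-acid names are protein; unmatched names fall back to solvent
# (or error in strict mode).
.categorize_beads <- function(resname, beadname, resnum, rules,
                              strict = FALSE) {
  n <- length(resname)
  category <- rep("solvent", n)
  species <- rep("", n)
  is_head <- rep(FALSE, n)

  is_prot <- toupper(resname) %in% .aa3
  category[is_prot] <- "protein"

  idx <- match(toupper(resname), toupper(rules$residue_name))
  hit <- !is.na(idx) & !is_prot
  category[hit] <- rules$category[idx[hit]]
  species[hit] <- rules$species[idx[hit]]
  head_sets <- strsplit(rules$headgroup_beads, ",")
  for (i in which(hit & category == "lipid")) {
    is_head[i] <- toupper(beadname[i]) %in%
      toupper(trimws(head_sets[[idx[i]]]))
  }
  unknown <- !is_prot & is.na(idx)
  if (strict && any(unknown)) {
    stop("unknown residue name(s): ",
         paste(unique(resname[unknown]), collapse = ", "),
         " (strict mode; extend category_rules)")
  }

  # residue boundaries: change in file residue number or name
  new_res <- c(TRUE, resnum[-1] != resnum[-n] | resname[-1] != resname[-n])
  res_serial <- cumsum(new_res)

  # chains: a protein chain breaks where the residue number decreases
  chain_id <- rep("", n)
  residue_number <- rep(NA_integer_, n)
  if (any(is_prot)) {
    p <- which(is_prot)
    pres <- resnum[p]
    # chains restart their residue numbering, so a decrease marks the
    # next chain; repeated numbers are further beads of the same residue
    new_chain <- c(TRUE, diff(pres) < 0)
    chain_serial <- cumsum(new_chain)
    chain_id[p] <- LETTERS[(chain_serial - 1L) %% 26L + 1L]
    residue_number[p] <- pres
  }

  # molecule id: protein chain = one molecule; every other residue is
  # its own molecule
  mol_key <- ifelse(is_prot, paste0("P", chain_id), paste0("R", res_serial))
  molecule_id <- as.integer(factor(mol_key, levels = unique(mol_key)))

  data.frame(
    bead_index = 0:(n - 1L), bead_name = beadname, residue_name = resname,
    category = category, species = species, is_headgroup = is_head,
    molecule_id = molecule_id, chain_id = chain_id,
    residue_number = residue_number, stringsAsFactors = FALSE
  )
}

#' Read a coarse-grained structure (GRO or PDB)
#'
#' Parses a single-frame structure file, assigns bead categories from a
#' residue-name rule table, and returns the topology together with the
#' coordinate frame.  GRO coordinates are taken as nm; PDB coordinates
#' (Angstrom) are converted to nm on read.  Protein chains are detected
#' from the residue numbering (a decrease starts a new chain in GRO;
#' PDB chain ids are honoured).
#'
#' @param path Path to a `.gro` or `.pdb` file.
#' @param category_rules Rule table as returned by
#'   [default_category_rules()].
#' @param strict If `TRUE`, an unmatched non-protein residue name is an
#'   error instead of being categorised as solvent.
#' @param box Optional length-3 box override in nm (required for PDB
#'   files without a CRYST1 record).
#' @return `list(topology = , frame = )`.
#' @export
read_structure <- function(path, category_rules = default_category_rules(),
                           strict = FALSE, box = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xtc", "trr")) {
    stop("XTC/TRR are not supported; convert to multi-frame GRO")
  }
  if (ext == "pdb") {
    return(.read_pdb_structure(path, category_rules, strict, box))
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("empty structure file: ", path)
  blk <- .parse_gro_block(lines, 0L)
  beads <- .categorize_beads(blk$resname, blk$beadname, blk$resnum,
                             category_rules, strict)
  top <- topology(beads)
  fr <- traj_frame(blk$coords, blk$box,
                   if (is.na(blk$time_ns)) 0 else blk$time_ns)
  list(topology = top, frame = fr)
}

.read_pdb_structure <- function(path, category_rules, strict, box) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  coords <- cbind(at$x, at$y, at$z) / 10  # Angstrom -> nm
  if (is.null(box)) {
    # bio3d drops CRYST1; parse its fixed columns (a, b, c in Angstrom)
    cl <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
    cr <- if (length(cl) >= 1) {
      suppressWarnings(as.numeric(c(substr(cl[1], 7, 15),
                                    substr(cl[1], 16, 24),
                                    substr(cl[1], 25, 33))))
    } else NULL
    if (is.null(cr) || any(!is.finite(cr)) || any(cr <= 0)) {
      stop("PDB file has no usable CRYST1 record; pass box = c(Lx, Ly, Lz)")
    }
    box <- cr / 10
  }
  beads <- .categorize_beads(at$resid, at$elety, at$resno,
                             category_rules, strict)
  # PDB carries explicit chain ids; prefer them for protein beads
  has_chain <- !is.na(at$chain) & nzchar(at$chain)
  prot <- beads$category == "protein"
  beads$chain_id[prot & has_chain] <- at$chain[prot & has_chain]
  top <- topology(beads)
  list(topology = top, frame = traj_frame(coords, box, 0))
}

#' Read a multi-frame GRO trajectory
#'
#' Concatenated GRO blocks form the trajectory dialect.  Frame times are
#' taken from a `t=` token on each block's title line (interpreted in
#' ns); blocks without one are numbered 0, 1, 2, ... ns in file order.
#'
#' @param path Path to a multi-frame `.gro` file.
#' @param topology The [topology()] the frames must match.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, topology) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xtc", "trr")) {
    stop("XTC/TRR are not supported; convert to multi-frame GRO")
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("empty trajectory file: ", path)
  frames <- list()
  pos <- 1L
  k <- 0L
  while (pos <= length(lines)) {
    if (!nzchar(trimws(paste(lines[pos:min(pos + 2, length(lines))],
                             collapse = "")))) break
    blk <- .parse_gro_block(lines[pos:length(lines)], pos - 1L)
    k <- k + 1L
    if (blk$natoms != topology$n_beads) {
      stop(sprintf("frame %d has %d beads but topology has %d",
                   k, blk$natoms, topology$n_beads))
    }
    t_ns <- if (is.na(blk$time_ns)) k - 1 else blk$time_ns
    frames[[k]] <- traj_frame(blk$coords, blk$box, t_ns)
    pos <- pos + blk$n_lines
  }
  if (length(frames) == 0) stop("no frames found in ", path)
  trajectory(topology, frames)
}

#' Write a frame (or frames) as (multi-)GRO
#'
#' Writes fixed-width GRO records in nm with the box on the last line of
#' each block.  Frame times are recorded as `t= <ns>` on the title line.
#' Protein beads are written with their per-chain residue numbers (so a
#' number decrease marks the next chain on read-back); all other
#' molecules get a running residue serial.
#'
#' @param traj A [trajectory()], or a list with `topology` and `frame`
#'   entries as returned by [read_structure()].
#' @param path Output path.
#' @param title Title prefix for each block.
#' @return `path`, invisibly.
#' @export
write_gro <- function(traj, path, title = "memfoot system") {
  if (!inherits(traj, "trajectory")) {
    traj <- trajectory(traj$topology, list(traj$frame))
  }
  b <- traj$topology$beads
  n <- nrow(b)
  is_prot <- b$category == "protein"
  new_res <- c(TRUE, (b$molecule_id[-1] != b$molecule_id[-n]) |
                 (!is.na(b$residue_number[-1]) &
                    !is.na(b$residue_number[-n]) &
                    b$residue_number[-1] != b$residue_number[-n]))
  res_serial <- cumsum(new_res)
  file_resnum <- ifelse(is_prot, b$residue_number,
                        (res_serial - 1L) %% 99999L + 1L)
  atomnum <- (b$bead_index %% 99999L) + 1L
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in traj$frames) {
    writeLines(sprintf("%s t= %.6f", title, fr$time_ns), con)
    writeLines(sprintf("%5d", n), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       file_resnum, substr(b$residue_name, 1, 5),
                       substr(b$bead_name, 1, 5), atomnum,
                       fr$coords[, 1], fr$coords[, 2], fr$coords[, 3]),
               con)
    writeLines(sprintf("%10.5f%10.5f%10.5f",
                       fr$box[1], fr$box[2], fr$box[3]), con)
  }
  invisible(path)
}

#' Select beads from a topology
#'
#' Returns the sorted 0-based bead indices matching every given filter.
#' `residue_range` is a closed 1-based interval on the per-chain residue
#' number (protein beads only).  An empty selection is an error, which
#' guards against silent all-zero analyses.
#'
#' @param topology A [topology()].
#' @param category,species,chain Optional exact-match filters.
#' @param headgroup_only If `TRUE`, keep only lipid headgroup beads.
#' @param residue_range Optional closed interval `c(lo, hi)`.
#' @return Sorted integer vector of 0-based bead indices.
#' @export
select_beads <- function(topology, category = NULL, species = NULL,
                         headgroup_only = FALSE, chain = NULL,
                         residue_range = NULL) {
  b <- topology$beads
  keep <- rep(TRUE, nrow(b))
  if (!is.null(category)) keep <- keep & b$category %in% category
  if (!is.null(species)) keep <- keep & b$species %in% species
  if (isTRUE(headgroup_only)) keep <- keep & b$is_headgroup
  if (!is.null(chain)) keep <- keep & b$chain_id %in% chain
  if (!is.null(residue_range)) {
    stopifnot(length(residue_range) == 2,
              residue_range[1] <= residue_range[2])
    keep <- keep & !is.na(b$residue_number) &
      b$residue_number >= residue_range[1] &
      b$residue_number <= residue_range[2]
  }
  idx <- sort(b$bead_index[keep])
  if (length(idx) == 0) {
    stop("select_beads: selection is empty (refusing silent all-zero analysis)")
  }
  idx
}
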