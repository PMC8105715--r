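#' Bead topology of a coarse-grained system
#'
#' A `topology` is the static per-bead annotation shared by all frames of
#' a trajectory: bead and residue names, category (protein / lipid /
#' solvent / ion), lipid species, headgroup flag, molecule id, and for
#' protein beads the chain id and 1-based residue number.  Bead indices
#' are 0-based and contiguous, matching the on-disk atom order.
#'
#' @param beads A data.frame with columns `bead_index` (0-based int),
#'   `bead_name`, `residue_name`, `category` (one of `"protein"`,
#'   `"lipid"`, `"solvent"`, `"ion"`), `species` (lipid species, `""`
#'   otherwise), `is_headgroup` (logical), `molecule_id` (int),
#'   `chain_id` (`""` for non-protein), `residue_number` (1-based int
#'   within chain, `NA` for non-protein).
#' @return An object of class `topology`.
#' @export
topology <- function(beads) {
  required <- c("bead_index", "bead_name", "residue_name", "category",
                "species", "is_headgroup", "molecule_id", "chain_id",
                "residue_number")
  missing_cols <- setdiff(required, names(beads))
  if (length(missing_cols) > 0) {
    stop("topology beads missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  beads <- as.data.frame(beads)[required]
  beads$bead_index <- as.integer(beads$bead_index)
  beads$category <- as.character(beads$category)
  beads$species <- as.character(beads$species)
  beads$is_headgroup <- as.logical(beads$is_headgroup)
  beads$molecule_id <- as.integer(beads$molecule_id)
  beads$chain_id <- as.character(beads$chain_id)
  beads$residue_number <- as.integer(beads$residue_number)

  n <- nrow(beads)
  if (n == 0) stop("topology must contain at least one bead")
  if (!identical(beads$bead_index, 0:(n - 1L))) {
    stop("bead_index must be contiguous from 0")
  }
  bad_cat <- setdiff(unique(beads$category),
                     c("protein", "lipid", "solvent", "ion"))
  if (length(bad_cat) > 0) {
    stop("unknown bead category: ", paste(bad_cat, collapse = ", "))
  }
  is_lip <- beads$category == "lipid"
  if (any(is_lip & !nzchar(beads$species))) {
    stop("every lipid bead must have a nonempty species")
  }
  is_prot <- beads$category == "protein"
  if (any(is_prot & (!nzchar(beads$chain_id) |
                     is.na(beads$residue_number) |
                     beads$residue_number < 1))) {
    stop("every protein bead must have a chain_id and residue_number >= 1")
  }
  if (any(beads$is_headgroup & !is_lip)) {
    stop("headgroup flags are only allowed on lipid beads")
  }
  structure(list(beads = beads, n_beads = n), class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  b <- x$beads
  cat(sprintf("Topology: %d beads (%d protein, %d lipid, %d other)\n",
              x$n_beads, sum(b$category == "protein"),
              sum(b$category == "lipid"),
              sum(!b$category %in% c("protein", "lipid"))))
  sp <- table(b$species[b$category == "lipid" & b$is_headgroup])
  if (length(sp) > 0) {
    cat("  lipid molecules by species (headgroup beads): ",
        paste(sprintf("%s=%d", names(sp), as.integer(sp)), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Single trajectory frame
#'
#' @param coords Numeric n x 3 matrix of bead coordinates in nm.
#' @param box Numeric length-3 vector `(Lx, Ly, Lz)` in nm, all > 0.
#' @param time_ns Frame time in ns, >= 0.
#' @return An object of class `traj_frame`.
#' @export
traj_frame <- function(coords, box, time_ns = 0) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("coords must be an n x 3 matrix")
  storage.mode(coords) <- "double"
  box <- as.numeric(box)
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0)) {
    stop("box must be three positive lengths (nm)")
  }
  if (!is.finite(time_ns) || time_ns < 0) stop("time_ns must be >= 0")
  dimnames(coords) <- NULL
  structure(list(coords = coords, box = box, time_ns = as.numeric(time_ns)),
            class = "traj_frame")
}

#' Trajectory: a topology plus time-ordered frames
#'
#' @param topology A [topology()].
#' @param frames List of [traj_frame()] objects with strictly increasing
#'   times and bead counts matching the topology.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(topology, frames) {
  if (!inherits(topology, "topology")) stop("topology must be a topology")
  if (length(frames) == 0) stop("trajectory must contain at least one frame")
  times <- vapply(frames, function(f) f$time_ns, numeric(1))
  if (any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing")
  }
  for (i in seq_along(frames)) {
    if (!inherits(frames[[i]], "traj_frame")) {
      stop("frames must be traj_frame objects (frame ", i, ")")
    }
    if (nrow(frames[[i]]$coords) != topology$n_beads) {
      stop(sprintf("frame %d has %d beads but topology has %d",
                   i, nrow(frames[[i]]$coords), topology$n_beads))
    }
  }
  structure(list(topology = topology, frames = frames),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  times <- frame_times(x)
  cat(sprintf("Trajectory: %d frames, %d beads, t = %g..%g ns\n",
              length(x$frames), x$topology$n_beads,
              min(times), max(times)))
  invisible(x)
}

#' Frame times of a trajectory
#' @param traj A [trajectory()].
#' @return Numeric vector of frame times in ns.
#' @export
frame_times <- function(traj) {
  vapply(traj$frames, function(f) f$time_ns, numeric(1))
}

#' Default residue-name category rules (Martini-style names)
#'
#' Maps residue names found in coarse-grained structure files to a
#' category, a lipid species and the set of bead names treated as the
#' lipid headgroup.  The defaults cover the common Martini lipids of an
#' asymmetric plasma-membrane mix (POPC/POPE/POPS/PIP2/SM/cholesterol,
#' plus water and monovalent ions); the phosphate bead `PO4` is the
#' headgroup for phospholipids, the phosphodiester/phosphate beads
#' `PO4`/`P1`/`P2` for PIP2, and the hydroxyl bead `ROH` for
#' cholesterol.  Simulation setups differ in which beads they call the
#' headgroup (notably for PIP2 and cholesterol), so the table is a
#' starting point meant to be overridden: supply your own data.frame of
#' the same shape to [read_structure()].
#'
#' @return data.frame with columns `residue_name`, `category`,
#'   `species`, `headgroup_beads` (comma-separated bead names).
#' @export
default_category_rules <- function() {
  data.frame(
    residue_name = c("POPC", "POPE", "POPS", "POP2", "PIP2", "DPSM",
                     "PSM", "CHOL", "W", "WF", "NA+", "CL-", "NA", "CL",
                     "ION"),
    category = c(rep("lipid", 8), "solvent", "solvent",
                 "ion", "ion", "ion", "ion", "ion"),
    species = c("POPC", "POPE", "POPS", "PIP2", "PIP2", "SM", "SM",
                "CHOL", "", "", "", "", "", "", ""),
    headgroup_beads = c("PO4", "PO4", "PO4", "PO4,P1,P2", "PO4,P1,P2",
                        "PO4", "PO4", "ROH", "", "", "", "", "", "", ""),
    stringsAsFactors = FALSE
  )
}

# Standard amino-acid 3-letter names: residues matching these are
# categorised as protein by read_structure().
.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")
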