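# Two-dimensional density maps, per-residue protein-lipid contact
# profiles with significance cutoffs, and the preferential
# lipid-binding coefficient
#
#   delta_L = N_L - N_A * (n_L / n_A)
#
# where N_L is the protein contact count of the evaluated lipid, N_A
# the total protein-lipid contact count, n_L the molecule count of the
# evaluated lipid and n_A the total lipid molecule count.  A positive
# delta_L means the lipid contacts the protein more than its bulk
# fraction predicts.
#
# A contact is a (protein bead, lipid headgroup bead) pair at
# minimum-image distance strictly below the cutoff (0.55 nm by
# default); contacts use full xyz wrapping, unlike the in-plane-only
# wrapping of leaflet assignment.

#' 2D number-density map (z-summed)
#'
#' Histograms the selected beads on a fixed x/y grid per frame, sums
#' over frames, and normalizes by `n_molecules * n_frames`.  With one
#' counted bead per molecule and no bead leaving the grid, the
#' normalized density sums to exactly 1.  Beads outside the grid are
#' clipped to the edge bins and counted.
#'
#' @param fitted_traj A [trajectory()] fitted to the pore reference.
#' @param selection 0-based bead indices to count (e.g. one species'
#'   headgroup beads, or all protein beads).
#' @param n_molecules Number of molecules behind the selection (lipid
#'   molecule count for a lipid species; number of protein chains for
#'   protein density).
#' @param bins Bins per axis.
#' @param species Label stored with the map.
#' @param reference_frame Frame whose box fixes the grid extent.
#' @return Object of class `density_map`: `counts_raw` and
#'   `density_norm` (`bins x bins`, x along rows), edges and metadata.
#' @export
density_map <- function(fitted_traj, selection, n_molecules,
                        bins = 75L, species = "",
                        reference_frame = fitted_traj$frames[[1]]) {
  bins <- as.integer(bins)
  stopifnot(bins >= 1, n_molecules > 0)
  if (length(selection) == 0) stop("density selection is empty")
  lx <- reference_frame$box[1]
  ly <- reference_frame$box[2]
  counts <- matrix(0, bins, bins)
  rows <- selection + 1L
  for (fr in fitted_traj$frames) {
    xy <- fr$coords[rows, , drop = FALSE]
    ix <- pmin(bins, pmax(1L, floor(xy[, 1] / lx * bins) + 1L))
    iy <- pmin(bins, pmax(1L, floor(xy[, 2] / ly * bins) + 1L))
    cell <- (iy - 1L) * bins + ix
    tab <- tabulate(cell, nbins = bins * bins)
    counts <- counts + tab
  }
  n_frames <- length(fitted_traj$frames)
  structure(
    list(species = species, counts_raw = counts,
         density_norm = counts / (n_molecules * n_frames),
         x_edges = seq(0, lx, length.out = bins + 1L),
         y_edges = seq(0, ly, length.out = bins + 1L),
         n_molecules = n_molecules, n_frames = n_frames, bins = bins),
    class = "density_map"
  )
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf(
    "Density map%s: %dx%d bins, %d molecule(s), %d frame(s), total %.4f\n",
    if (nzchar(x$species)) paste0(" (", x$species, ")") else "",
    x$bins, x$bins, x$n_molecules, x$n_frames, sum(x$density_norm)))
  invisible(x)
}

#' Protein-lipid contacts in one frame
#'
#' Counts every (protein bead, lipid headgroup bead) pair within the
#' cutoff (strict `<`, minimum image in all three dimensions) and
#' attributes it to the protein bead's residue/chain and the lipid's
#' molecule.
#'
#' @param frame A [traj_frame()].
#' @param topology The matching [topology()].
#' @param protein_beads,lipid_beads 0-based bead index selections.
#' @param cutoff_nm Contact cutoff (nm).
#' @param method Neighbour-search backend, see [pairs_within()].
#' @return data.frame `residue_number`, `chain_id`, `molecule_id`,
#'   `count`, one row per (residue, chain, lipid molecule) with at
#'   least one contacting bead pair.
#' @export
contacts_frame <- function(frame, topology, protein_beads, lipid_beads,
                           cutoff_nm = 0.55,
                           method = c("cell", "brute")) {
  method <- match.arg(method)
  stopifnot(cutoff_nm > 0)
  a <- frame$coords[protein_beads + 1L, , drop = FALSE]
  b <- frame$coords[lipid_beads + 1L, , drop = FALSE]
  prs <- pairs_within(a, b, box = frame$box, cutoff = cutoff_nm,
                      pbc = "xyz", method = method)
  bd <- topology$beads
  if (nrow(prs) == 0) {
    return(data.frame(residue_number = integer(0),
                      chain_id = character(0),
                      molecule_id = integer(0), count = numeric(0)))
  }
  p_rows <- protein_beads[prs[, 1]] + 1L
  l_rows <- lipid_beads[prs[, 2]] + 1L
  key <- data.frame(residue_number = bd$residue_number[p_rows],
                    chain_id = bd$chain_id[p_rows],
                    molecule_id = bd$molecule_id[l_rows])
  agg <- stats::aggregate(list(count = rep(1, nrow(key))), key, sum)
  agg[order(agg$residue_number, agg$chain_id, agg$molecule_id), ,
      drop = FALSE]
}

# Shared frame retention and selection logic for contact analyses.
.retained_frames <- function(traj, exclude_first_ns) {
  keep <- which(frame_times(traj) >= exclude_first_ns)
  if (length(keep) == 0) {
    stop("all frames fall inside the ", exclude_first_ns,
         " ns exclusion window")
  }
  keep
}

#' Per-residue contact profile for one lipid species
#'
#' Drops the equilibration window, counts protein-lipid bead-pair
#' contacts per frame, sums them over frames and over the protein
#' chains at equal residue number, and normalizes by
#' `n_lipid_molecules * n_frames_used`.  All chains must span the same
#' residue numbers (the trimer is assumed symmetric); mismatching
#' chains are an error.
#'
#' @param fitted_traj A [trajectory()] fitted to the pore reference.
#' @param species Lipid species to profile (headgroup beads only).
#' @param config An [analysis_config()]; uses `contact_cutoff_nm` and
#'   `contact_exclusion_ns`.
#' @param method Neighbour-search backend.
#' @return Object of class `contact_profile`: data.frame with
#'   `residue_number`, `raw`, `norm` plus attributes `species`,
#'   `n_frames_used`, `n_lipid_molecules`, `max_norm`.
#' @export
contact_profile <- function(fitted_traj, species,
                            config = analysis_config(),
                            method = c("cell", "brute")) {
  method <- match.arg(method)
  top <- fitted_traj$topology
  bd <- top$beads
  chains <- sort(unique(bd$chain_id[bd$category == "protein"]))
  if (length(chains) == 0) stop("topology contains no protein beads")
  res_sets <- lapply(chains, function(ch) {
    sort(unique(bd$residue_number[bd$category == "protein" &
                                    bd$chain_id == ch]))
  })
  ref_set <- res_sets[[1]]
  for (i in seq_along(chains)[-1]) {
    if (!identical(res_sets[[i]], ref_set)) {
      bad <- c(setdiff(res_sets[[i]], ref_set),
               setdiff(ref_set, res_sets[[i]]))
      stop("chains ", chains[1], " and ", chains[i],
           " span different residue sets (mismatching residues: ",
           paste(utils::head(bad, 10), collapse = ", "), ")")
    }
  }
  prot <- select_beads(top, category = "protein")
  lip <- select_beads(top, species = species, headgroup_only = TRUE)
  n_lip <- length(unique(bd$molecule_id[lip + 1L]))
  keep <- .retained_frames(fitted_traj, config$contact_exclusion_ns)

  raw <- stats::setNames(numeric(length(ref_set)), ref_set)
  for (i in keep) {
    cf <- contacts_frame(fitted_traj$frames[[i]], top, prot, lip,
                         cutoff_nm = config$contact_cutoff_nm,
                         method = method)
    if (nrow(cf) == 0) next
    per_res <- tapply(cf$count, cf$residue_number, sum)
    raw[names(per_res)] <- raw[names(per_res)] + per_res
  }
  n_frames <- length(keep)
  norm <- raw / (n_lip * n_frames)
  out <- data.frame(residue_number = ref_set, raw = as.numeric(raw),
                    norm = as.numeric(norm))
  structure(out, species = species, n_frames_used = n_frames,
            n_lipid_molecules = n_lip, max_norm = max(norm),
            class = c("contact_profile", "data.frame"))
}

#' Residues with significant contacts
#'
#' Residues whose normalized contact value reaches `fraction` of the
#' profile maximum (e.g. 0.6 for sterols, 0.7 for PIP2).
#'
#' @param profile A [contact_profile()] (or data.frame with
#'   `residue_number` and `norm`).
#' @param fraction Significance fraction in (0, 1].
#' @return Integer vector of 1-based residue numbers.
#' @export
significant_residues <- function(profile, fraction = 0.6) {
  stopifnot(fraction > 0, fraction <= 1)
  mx <- max(profile$norm)
  if (mx == 0) {
    warning("all-zero contact profile; no significant residues")
    return(integer(0))
  }
  sort(profile$residue_number[profile$norm >= fraction * mx])
}

#' Preferential binding coefficient delta_L
#'
#' `delta_L = N_L - N_A * (n_L / n_A)`, in units of contacts.  Zero
#' means the lipid's contact share equals its bulk molecule fraction;
#' positive means enrichment at the protein.
#'
#' @param N_L Contact count of the evaluated lipid.
#' @param N_A Total contact count over all lipids.
#' @param n_L Molecule count of the evaluated lipid.
#' @param n_A Total lipid molecule count.
#' @return Numeric delta_L.
#' @export
delta_L <- function(N_L, N_A, n_L, n_A) {
  if (any(n_A <= 0)) stop("n_A must be > 0")
  if (any(n_L <= 0) || any(n_L > n_A)) stop("need 0 < n_L <= n_A")
  if (any(N_L < 0) || any(N_L > N_A)) stop("need 0 <= N_L <= N_A")
  N_L - N_A * (n_L / n_A)
}

#' Lipid binding preference per species
#'
#' Whole-protein contact analysis: after dropping the equilibration
#' window, each retained frame contributes per-species contact totals
#' (all protein beads vs. all lipid headgroup beads), from which
#' [delta_L()] is evaluated per frame and species.  The ensemble mean
#' and SEM over frames are reported.  Over the complete species
#' partition the per-frame delta_L values sum to zero by construction.
#'
#' @param fitted_traj A [trajectory()].
#' @param config An [analysis_config()].
#' @param method Neighbour-search backend.
#' @return Object of class `preference_result`: data.frame `species`,
#'   `delta_L`, `sem`, `n_molecules`, `n_frames`; the per-frame
#'   delta_L matrix (frames x species) is attached as attribute
#'   `"per_frame"`.
#' @export
preference_analysis <- function(fitted_traj, config = analysis_config(),
                                method = c("cell", "brute")) {
  method <- match.arg(method)
  top <- fitted_traj$topology
  bd <- top$beads
  lip_all <- select_beads(top, category = "lipid", headgroup_only = TRUE)
  species_of_bead <- bd$species[lip_all + 1L]
  mol_of_bead <- bd$molecule_id[lip_all + 1L]
  n_by_species <- vapply(split(mol_of_bead, species_of_bead),
                         function(m) length(unique(m)), integer(1))
  n_by_species <- n_by_species[n_by_species > 0]
  if (length(n_by_species) < 2) {
    stop("binding preference needs at least 2 lipid species")
  }
  species <- names(n_by_species)
  n_A <- sum(n_by_species)
  prot <- select_beads(top, category = "protein")
  keep <- .retained_frames(fitted_traj, config$contact_exclusion_ns)

  per_frame <- matrix(NA_real_, length(keep), length(species),
                      dimnames = list(NULL, species))
  for (fi in seq_along(keep)) {
    cf_pairs <- pairs_within(
      fitted_traj$frames[[keep[fi]]]$coords[prot + 1L, , drop = FALSE],
      fitted_traj$frames[[keep[fi]]]$coords[lip_all + 1L, , drop = FALSE],
      box = fitted_traj$frames[[keep[fi]]]$box,
      cutoff = config$contact_cutoff_nm, pbc = "xyz", method = method)
    n_sp <- stats::setNames(numeric(length(species)), species)
    if (nrow(cf_pairs) > 0) {
      tab <- table(species_of_bead[cf_pairs[, 2]])
      n_sp[names(tab)] <- as.numeric(tab)
    }
    N_A <- sum(n_sp)
    per_frame[fi, ] <- n_sp - N_A * (n_by_species / n_A)
  }
  sems <- apply(per_frame, 2, function(v) {
    if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  })
  out <- data.frame(species = species,
                    delta_L = colMeans(per_frame),
                    sem = sems,
                    n_molecules = as.integer(n_by_species),
                    n_frames = length(keep), row.names = NULL)
  structure(out, per_frame = per_frame,
            class = c("preference_result", "data.frame"))
}
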