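#' Analysis configuration
#'
#' Bundles the tunable constants of the footprint / lipid-fingerprint
#' pipeline.  Defaults follow the conventions of coarse-grained Piezo1
#' footprint analyses: a 2 nm flood-fill cutoff for leaflet detection
#' (smaller than the inter-leaflet headgroup separation), a 0.55 nm
#' protein-lipid contact cutoff, the 90th-percentile surface level for
#' dome depth, 75 x 75 bins for height and density maps, significance
#' cutoffs of 60% (sterols) and 70% (PIP2) of maximal contacts, and
#' equilibration exclusion windows of 1000 ns (depth) and 1500 ns
#' (contacts / binding preference).
#'
#' @param leaflet_cutoff_nm Flood-fill neighbour cutoff in nm.
#' @param contact_cutoff_nm Protein-lipid contact cutoff in nm; a bead
#'   pair at distance strictly below this counts as one contact.
#' @param surface_percentile Percentile of leaflet headgroup z defining
#'   the flat surface level (beads at or above it are averaged).
#' @param heightmap_bins Number of bins per axis for height/density maps.
#' @param significance_fraction Fraction of the maximal normalized
#'   contact value above which a residue is called significant.
#' @param depth_exclusion_ns Equilibration time dropped before depth
#'   analysis.
#' @param contact_exclusion_ns Equilibration time dropped before contact
#'   and binding-preference analysis.
#' @param pore_residue_range Closed 1-based residue interval defining the
#'   pore fitting reference.
#' @param fit_selection Fitting reference: `"whole_protein"` (depth and
#'   height maps) or `"pore"` (density and contact maps).
#' @return An object of class `analysis_config` (a validated list).
#' @examples
#' cfg <- analysis_config()
#' cfg$contact_cutoff_nm
#' @export
analysis_config <- function(leaflet_cutoff_nm = 2.0,
                            contact_cutoff_nm = 0.55,
                            surface_percentile = 90,
                            heightmap_bins = 75L,
                            significance_fraction = 0.6,
                            depth_exclusion_ns = 1000,
                            contact_exclusion_ns = 1500,
                            pore_residue_range = c(2105L, 2547L),
                            fit_selection = c("whole_protein", "pore")) {
  fit_selection <- match.arg(fit_selection)
  stopifnot(
    "leaflet_cutoff_nm must be > 0" = leaflet_cutoff_nm > 0,
    "contact_cutoff_nm must be > 0" = contact_cutoff_nm > 0,
    "surface_percentile must be in (0, 100)" =
      surface_percentile > 0 && surface_percentile < 100,
    "heightmap_bins must be a positive integer" = heightmap_bins >= 1,
    "significance_fraction must be in (0, 1]" =
      significance_fraction > 0 && significance_fraction <= 1,
    "depth_exclusion_ns must be >= 0" = depth_exclusion_ns >= 0,
    "contact_exclusion_ns must be >= 0" = contact_exclusion_ns >= 0,
    "pore_residue_range must be an increasing pair" =
      length(pore_residue_range) == 2 &&
        pore_residue_range[1] <= pore_residue_range[2]
  )
  structure(
    list(
      leaflet_cutoff_nm = leaflet_cutoff_nm,
      contact_cutoff_nm = contact_cutoff_nm,
      surface_percentile = surface_percentile,
      heightmap_bins = as.integer(heightmap_bins),
      significance_fraction = significance_fraction,
      depth_exclusion_ns = depth_exclusion_ns,
      contact_exclusion_ns = contact_exclusion_ns,
      pore_residue_range = as.integer(pore_residue_range),
      fit_selection = fit_selection
    ),
    class = "analysis_config"
  )
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, paste(x[[nm]], collapse = "-")))
  }
  invisible(x)
}
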