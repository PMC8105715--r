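# Membrane-dome depth statistic and leaflet height maps.
#
# Depth of the dome in one leaflet and frame = surface level minus
# bottom, where the surface level is the mean z of the headgroup beads
# at or above the 90th percentile of that leaflet's z values (the flat
# far field, averaged to damp thermal fluctuation) and the bottom is
# the single lowest headgroup z (stable because it sits on the protein,
# which is the fitting reference).

#' Dome depth of one leaflet in one frame
#'
#' @param frame A [traj_frame()] (from a trajectory fitted to the
#'   whole-protein reference).
#' @param assignment A [assign_leaflets()] result for this frame.
#' @param leaflet `"upper"` or `"lower"`.
#' @param percentile Surface-level percentile of leaflet headgroup z;
#'   beads with z at or above it are averaged (inclusive threshold,
#'   linearly interpolated percentile).
#' @return One-row data.frame: `frame_time_ns`, `leaflet`,
#'   `surface_z_nm`, `bottom_z_nm`, `depth_nm`.
#' @export
frame_depth <- function(frame, assignment, leaflet = c("upper", "lower"),
                        percentile = 90) {
  leaflet <- match.arg(leaflet)
  stopifnot(percentile > 0, percentile < 100)
  beads <- assignment$bead_index[assignment$leaflet == leaflet]
  if (length(beads) == 0) stop("leaflet '", leaflet, "' is empty")
  if (length(beads) < 10) {
    warning("leaflet '", leaflet, "' has fewer than 10 beads; ",
            "the surface percentile is unstable")
  }
  z <- frame$coords[beads + 1L, 3]
  thr <- stats::quantile(z, percentile / 100, names = FALSE, type = 7)
  surface <- mean(z[z >= thr])
  bottom <- min(z)
  data.frame(frame_time_ns = frame$time_ns, leaflet = leaflet,
             surface_z_nm = surface, bottom_z_nm = bottom,
             depth_nm = surface - bottom)
}

#' Per-frame dome depth over a trajectory
#'
#' Computes [frame_depth()] for each retained frame and leaflet.  The
#' initial equilibration window is dropped: frames with time below
#' `exclude_first_ns` are excluded.
#'
#' @param fitted_traj A [trajectory()] fitted to the whole-protein
#'   reference (see [fit_trajectory()]).
#' @param assignments A `leaflet_series` (per-frame assignments, same
#'   frame count) or a single `leaflet_assignment` used for all frames.
#' @param exclude_first_ns Equilibration time to drop (ns).
#' @param leaflets Which leaflets to report.
#' @inheritParams frame_depth
#' @return data.frame of depth records, one row per retained frame and
#'   leaflet.
#' @export
depth_series <- function(fitted_traj, assignments,
                         exclude_first_ns = 1000,
                         leaflets = c("upper", "lower"),
                         percentile = 90) {
  frames <- fitted_traj$frames
  per_frame <- inherits(assignments, "leaflet_series")
  if (per_frame &&
      length(assignments$assignments) != length(frames)) {
    stop("assignments cover ", length(assignments$assignments),
         " frames but trajectory has ", length(frames))
  }
  keep <- which(frame_times(fitted_traj) >= exclude_first_ns)
  if (length(keep) == 0) {
    stop("all frames fall inside the ", exclude_first_ns,
         " ns exclusion window")
  }
  out <- vector("list", length(keep) * length(leaflets))
  k <- 0L
  for (i in keep) {
    asg <- if (per_frame) assignments$assignments[[i]] else assignments
    for (lf in leaflets) {
      k <- k + 1L
      out[[k]] <- frame_depth(frames[[i]], asg, lf, percentile)
    }
  }
  do.call(rbind, out)
}

#' Pool depth records into a per-leaflet summary
#'
#' Merges depth series from one or more runs and reports the pooled
#' mean and standard error of the mean (sd/sqrt(N) over all pooled
#' per-frame depths) per leaflet.  Frames are treated as independent;
#' `block` > 1 averages consecutive blocks of that many frames first
#' (per run and leaflet) as a simple guard against autocorrelation.
#'
#' @param series A depth data.frame from [depth_series()], or a list of
#'   them (one per run).
#' @param block Block size for block-averaged SEM (1 = per-frame).
#' @return data.frame with `leaflet`, `mean_depth_nm`, `sem_nm`,
#'   `n_used`.
#' @export
aggregate_depth <- function(series, block = 1L) {
  if (is.data.frame(series)) series <- list(series)
  if (length(series) == 0 || all(vapply(series, nrow, 0L) == 0)) {
    stop("no depth records to aggregate")
  }
  leaflets <- unique(unlist(lapply(series, function(s) s$leaflet)))
  rows <- lapply(leaflets, function(lf) {
    vals <- unlist(lapply(series, function(s) {
      d <- s$depth_nm[s$leaflet == lf]
      if (block > 1L && length(d) >= block) {
        grp <- (seq_along(d) - 1L) %/% block
        d <- as.numeric(tapply(d, grp, mean))
      }
      d
    }))
    n <- length(vals)
    data.frame(leaflet = lf, mean_depth_nm = mean(vals),
               sem_nm = if (n > 1) stats::sd(vals) / sqrt(n) else NA_real_,
               n_used = n)
  })
  do.call(rbind, rows)
}

#' Leaflet height map
#'
#' Bins the leaflet's headgroup beads on a fixed x/y grid (extent =
#' the reference frame's box), computes the per-frame mean z in each
#' bin, and averages those matrices over frames.  Bins empty in a frame
#' are ignored in the average (zero-filling would drag the mean toward
#' 0); bins empty in every frame come out as `NA`.  Beads drifting
#' outside the grid are clipped to the edge bins and counted.
#'
#' @inheritParams depth_series
#' @param leaflet `"upper"` or `"lower"`.
#' @param bins Number of bins per axis.
#' @param reference_frame Frame whose box fixes the grid extent.
#' @return Object of class `height_map`: list with `mean_z`
#'   (`bins x bins` matrix, x along rows), `x_edges`, `y_edges`,
#'   `n_frames`, `leaflet`.
#' @export
height_map <- function(fitted_traj, assignments,
                       leaflet = c("upper", "lower"), bins = 75L,
                       reference_frame = fitted_traj$frames[[1]]) {
  leaflet <- match.arg(leaflet)
  bins <- as.integer(bins)
  stopifnot(bins >= 1)
  per_frame <- inherits(assignments, "leaflet_series")
  frames <- fitted_traj$frames
  lx <- reference_frame$box[1]
  ly <- reference_frame$box[2]
  sum_z <- matrix(0, bins, bins)
  n_occ <- matrix(0L, bins, bins)
  for (i in seq_along(frames)) {
    asg <- if (per_frame) assignments$assignments[[i]] else assignments
    beads <- asg$bead_index[asg$leaflet == leaflet]
    if (length(beads) == 0) next
    xy <- frames[[i]]$coords[beads + 1L, , drop = FALSE]
    ix <- pmin(bins, pmax(1L, floor(xy[, 1] / lx * bins) + 1L))
    iy <- pmin(bins, pmax(1L, floor(xy[, 2] / ly * bins) + 1L))
    cell <- (iy - 1L) * bins + ix
    zsum <- rowsum(xy[, 3], cell)
    zcnt <- rowsum(rep(1, length(cell)), cell)
    idx <- as.integer(rownames(zsum))
    sum_z[idx] <- sum_z[idx] + zsum[, 1] / zcnt[, 1]
    n_occ[idx] <- n_occ[idx] + 1L
  }
  if (all(n_occ == 0L)) stop("no occupied bins in any frame")
  mean_z <- sum_z / n_occ
  mean_z[n_occ == 0L] <- NA_real_
  structure(
    list(mean_z = mean_z,
         x_edges = seq(0, lx, length.out = bins + 1L),
         y_edges = seq(0, ly, length.out = bins + 1L),
         n_frames = length(frames), leaflet = leaflet, bins = bins),
    class = "height_map"
  )
}

#' @export
print.height_map <- function(x, ...) {
  occ <- sum(!is.na(x$mean_z))
  cat(sprintf(
    "Height map (%s leaflet): %dx%d bins, %d occupied, %d frame(s)\n",
    x$leaflet, x$bins, x$bins, occ, x$n_frames))
  cat(sprintf("  z range %.3f .. %.3f nm\n",
              min(x$mean_z, na.rm = TRUE), max(x$mean_z, na.rm = TRUE)))
  invisible(x)
}

#' Count angular minima of a height map around its centre
#'
#' Summarises the lobedness of a membrane footprint: occupied bins are
#' assigned to angular sectors about the grid centre, the minimum bin
#' height per sector forms a circular profile, and the number of local
#' minima of that profile (after circular moving-average smoothing and
#' plateau merging) is returned.  A three-bladed protein footprint
#' yields 3.
#'
#' @param hm A [height_map()].
#' @param n_sectors Number of angular sectors.
#' @param r_range Radial band (nm from the centre) of bins to include;
#'   default the full map.
#' @param smooth Odd circular moving-average window (1 = none).
#' @return Integer count of local minima; the sector profile is
#'   attached as attribute `"profile"`.
#' @export
angular_minima <- function(hm, n_sectors = 36L, r_range = c(0, Inf),
                           smooth = 3L) {
  n_sectors <- as.integer(n_sectors)
  stopifnot(n_sectors >= 3, smooth >= 1, smooth %% 2 == 1)
  xc <- (utils::head(hm$x_edges, -1) + utils::tail(hm$x_edges, -1)) / 2
  yc <- (utils::head(hm$y_edges, -1) + utils::tail(hm$y_edges, -1)) / 2
  cx <- mean(range(hm$x_edges))
  cy <- mean(range(hm$y_edges))
  g <- expand.grid(x = xc - cx, y = yc - cy)
  r <- sqrt(g$x^2 + g$y^2)
  theta <- atan2(g$y, g$x) %% (2 * pi)
  z <- as.vector(hm$mean_z)
  keep <- !is.na(z) & r >= r_range[1] & r <= r_range[2]
  if (!any(keep)) stop("no occupied bins in the requested radial band")
  sector <- pmin(n_sectors - 1L,
                 as.integer(floor(theta[keep] / (2 * pi) * n_sectors)))
  prof <- rep(NA_real_, n_sectors)
  mins <- tapply(z[keep], sector, min)
  prof[as.integer(names(mins)) + 1L] <- mins
  if (anyNA(prof)) {
    stop("empty angular sector(s); reduce n_sectors or widen r_range")
  }
  if (smooth > 1L) {
    half <- (smooth - 1L) %/% 2L
    ext <- c(utils::tail(prof, half), prof, utils::head(prof, half))
    prof <- as.numeric(stats::filter(ext, rep(1 / smooth, smooth),
                                     sides = 2))[half + seq_len(n_sectors)]
  }
  # merge circular plateaus, then count strict local minima
  v <- prof
  dup <- c(FALSE, diff(v) == 0)
  v <- v[!dup]
  if (length(v) > 1 && v[1] == v[length(v)]) v <- v[-length(v)]
  m <- length(v)
  if (m < 3) return(structure(if (m == 1) 1L else 0L, profile = prof))
  prev <- v[c(m, seq_len(m - 1))]
  nxt <- v[c(seq_len(m)[-1], 1)]
  count <- sum(v < prev & v < nxt)
  structure(as.integer(count), profile = prof)
}
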