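# Leaflet assignment by the branching-network (flood-fill) algorithm:
# starting from a single headgroup bead, repeatedly add every headgroup
# bead within a cutoff distance of any current member until closure;
# the complement is the other leaflet, and a confirmation pass seeded in
# the complement must reproduce it exactly.  Distances use the
# minimum-image convention in x and y only: the bilayer is periodic in
# the membrane plane but must not connect across the z boundary.

.flood_fill <- function(adj, seed, n) {
  visited <- logical(n)
  queue <- integer(n)
  queue[1] <- seed
  visited[seed] <- TRUE
  head <- 1L
  tail <- 1L
  while (head <= tail) {
    cur <- queue[head]
    head <- head + 1L
    for (nb in adj[[cur]]) {
      if (!visited[nb]) {
        visited[nb] <- TRUE
        tail <- tail + 1L
        queue[tail] <- nb
      }
    }
  }
  which(visited)
}

#' Assign headgroup beads to bilayer leaflets
#'
#' Flood fill from the headgroup bead with maximal z: beads within
#' `cutoff_nm` of any member join its leaflet until no more can be
#' added; the remaining beads form the other leaflet.  A confirmation
#' pass seeded at the highest-z bead of the complement must reproduce
#' the complement exactly — beads reachable from neither seed are an
#' error by default (they correspond to stray/flipped lipids, which the
#' upstream protocol removes by hand), or are attached to the leaflet
#' with the nearer mean z when `assign_strays_by_z = TRUE`.  The leaflet
#' with the greater mean z is labelled `"upper"`.
#'
#' @param frame A [traj_frame()].
#' @param headgroup_beads 0-based bead indices of the lipid headgroup
#'   beads (e.g. `select_beads(top, category = "lipid",
#'   headgroup_only = TRUE)`).
#' @param cutoff_nm Flood-fill neighbour cutoff (nm); must be smaller
#'   than the inter-leaflet separation and larger than the in-plane
#'   neighbour spacing.
#' @param method Neighbour-search backend, see [pairs_within()].
#' @param assign_strays_by_z Attach unreachable beads to the nearest
#'   leaflet (by mean-z distance) instead of erroring.
#' @return Object of class `leaflet_assignment`: data.frame-like list
#'   with `bead_index` (0-based), `leaflet` (`"upper"`/`"lower"`), and
#'   the two seed beads.
#' @export
assign_leaflets <- function(frame, headgroup_beads, cutoff_nm = 2.0,
                            method = c("cell", "brute"),
                            assign_strays_by_z = FALSE) {
  method <- match.arg(method)
  stopifnot(cutoff_nm > 0)
  hb <- as.integer(headgroup_beads)
  n <- length(hb)
  if (n < 2) stop("need at least 2 headgroup beads")
  coords <- frame$coords[hb + 1L, , drop = FALSE]
  z <- coords[, 3]

  prs <- pairs_within(coords, box = frame$box, cutoff = cutoff_nm,
                      pbc = "xy", method = method)
  adj <- vector("list", n)
  if (nrow(prs) > 0) {
    adj_all <- split(c(prs[, 2], prs[, 1]), c(prs[, 1], prs[, 2]))
    adj[as.integer(names(adj_all))] <- adj_all
  }
  adj[vapply(adj, is.null, logical(1))] <- list(integer(0))

  seed1 <- which.max(z)
  comp1 <- .flood_fill(adj, seed1, n)
  if (length(comp1) == n) {
    stop("flood fill absorbed all headgroup beads: leaflets are fused ",
         "at cutoff ", cutoff_nm, " nm (cutoff too large or bilayer ",
         "degenerate)")
  }
  rest <- setdiff(seq_len(n), comp1)
  seed2 <- rest[which.max(z[rest])]
  comp2 <- .flood_fill(adj, seed2, n)
  strays <- setdiff(rest, comp2)
  membership <- integer(n)
  membership[comp1] <- 1L
  membership[comp2] <- 2L
  if (length(strays) > 0) {
    if (!assign_strays_by_z) {
      stop("confirmation pass disagrees: ", length(strays),
           " headgroup bead(s) unreachable from either seed ",
           "(stray/flipped lipids?): bead indices ",
           paste(hb[utils::head(strays, 20)], collapse = ", "),
           if (length(strays) > 20) " ..." else "",
           ". Re-run with assign_strays_by_z = TRUE to attach them by ",
           "mean-plane distance.")
    }
    m1 <- mean(z[comp1])
    m2 <- mean(z[comp2])
    for (s in strays) {
      membership[s] <- if (abs(z[s] - m1) <= abs(z[s] - m2)) 1L else 2L
    }
  }
  mz <- c(mean(z[membership == 1L]), mean(z[membership == 2L]))
  if (mz[1] == mz[2]) {
    stop("leaflet mean z values tie exactly; cannot orient upper/lower")
  }
  upper_comp <- which.max(mz)
  leaflet <- ifelse(membership == upper_comp, "upper", "lower")
  seeds <- c(seed1, seed2)
  seed_upper <- hb[seeds[c(1L, 2L)[upper_comp]]]
  seed_lower <- hb[seeds[c(2L, 1L)[upper_comp]]]
  structure(
    list(bead_index = hb, leaflet = leaflet,
         seed_bead_upper = seed_upper, seed_bead_lower = seed_lower),
    class = "leaflet_assignment"
  )
}

#' @export
print.leaflet_assignment <- function(x, ...) {
  cat(sprintf("Leaflet assignment: %d upper / %d lower headgroup beads\n",
              sum(x$leaflet == "upper"), sum(x$leaflet == "lower")))
  invisible(x)
}

#' Per-frame leaflet assignment over a trajectory
#'
#' Runs [assign_leaflets()] independently on every frame and reports a
#' flip diagnostic: beads whose label changed between consecutive
#' frames.  With `static = TRUE` the first frame's assignment is reused
#' for all frames (no flips possible by construction).
#'
#' @inheritParams assign_leaflets
#' @param traj A [trajectory()].
#' @param static Reuse the first frame's assignment for all frames.
#' @return Object of class `leaflet_series`: list with `assignments`
#'   (one `leaflet_assignment` per frame) and `flips` (data.frame of
#'   `frame` index and 0-based `bead_index` of each label change).
#' @export
assign_leaflets_series <- function(traj, headgroup_beads,
                                   cutoff_nm = 2.0,
                                   method = c("cell", "brute"),
                                   assign_strays_by_z = FALSE,
                                   static = FALSE) {
  method <- match.arg(method)
  if (length(traj$frames) == 0) stop("trajectory has no frames")
  n_frames <- length(traj$frames)
  assignments <- vector("list", n_frames)
  errors <- character(0)
  for (i in seq_len(n_frames)) {
    if (static && i > 1L) {
      assignments[[i]] <- assignments[[1]]
      next
    }
    assignments[[i]] <- tryCatch(
      assign_leaflets(traj$frames[[i]], headgroup_beads, cutoff_nm,
                      method = method,
                      assign_strays_by_z = assign_strays_by_z),
      error = function(e) {
        errors <<- c(errors, sprintf("frame %d: %s", i,
                                     conditionMessage(e)))
        NULL
      }
    )
  }
  if (length(errors) > 0) {
    stop("leaflet assignment failed on ", length(errors), " frame(s):\n",
         paste(utils::head(errors, 5), collapse = "\n"))
  }
  flips <- data.frame(frame = integer(0), bead_index = integer(0))
  for (i in seq_len(n_frames)[-1]) {
    changed <- assignments[[i]]$leaflet != assignments[[i - 1]]$leaflet
    if (any(changed)) {
      flips <- rbind(flips, data.frame(
        frame = i, bead_index = assignments[[i]]$bead_index[changed]))
    }
  }
  structure(list(assignments = assignments, flips = flips),
            class = "leaflet_series")
}

#' @export
print.leaflet_series <- function(x, ...) {
  cat(sprintf("Leaflet series: %d frames, %d leaflet flip(s)\n",
              length(x$assignments), nrow(x$flips)))
  invisible(x)
}
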