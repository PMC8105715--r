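# Rigid-body superposition (Kabsch algorithm) and whole-trajectory
# fitting, replacing the external trajectory-fitting step of an MD
# toolchain.  Fits are unweighted: every selection bead counts equally.

#' Optimal rigid-body superposition of two point sets
#'
#' Computes the least-squares proper rotation and translation mapping
#' `mobile` onto `reference` (Kabsch algorithm via SVD, with the
#' determinant correction that excludes reflections).  The fitted
#' coordinates are `mobile %*% t(rotation) + translation` (rows).
#'
#' @param mobile,reference n x 3 coordinate matrices (nm), n >= 3, not
#'   all collinear.
#' @return Object of class `fit_result`: list with `rotation` (3 x 3,
#'   det +1), `translation` (length 3, nm), `rmsd_nm` (post-fit RMSD).
#' @export
kabsch <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3) {
    stop("mobile and reference must be equal-sized n x 3 matrices")
  }
  n <- nrow(mobile)
  if (n < 3) stop("kabsch needs at least 3 points")
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  mc <- sweep(mobile, 2, cm)
  rc <- sweep(reference, 2, cr)
  # collinear (or coincident) points leave the rotation about the line
  # axis undetermined
  if (svd(rc)$d[2] < 1e-9 || svd(mc)$d[2] < 1e-9) {
    stop("degenerate configuration: points are collinear or coincident")
  }
  h <- t(mc) %*% rc  # correlation matrix sum_i m_i r_i^T
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- as.numeric(cr - rot %*% cm)
  fitted <- mc %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - rc)^2)))
  structure(list(rotation = rot, translation = trans, rmsd_nm = rmsd),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Rigid-body fit: RMSD %.4f nm\n", x$rmsd_nm))
  invisible(x)
}

#' Apply a rigid-body fit to coordinates
#' @param coords n x 3 matrix.
#' @param fit A [kabsch()] result.
#' @return Transformed n x 3 matrix.
#' @export
apply_fit <- function(coords, fit) {
  sweep(as.matrix(coords) %*% t(fit$rotation), 2, fit$translation, "+")
}

#' Fit every trajectory frame to a reference selection
#'
#' Each frame gets its own rigid-body transform, computed on the
#' selection beads against the reference frame, and applied to all
#' beads.  Molecules are assumed whole (no periodic-image reassembly is
#' performed before fitting).  Box vectors and times are carried over
#' unchanged.
#'
#' @param traj A [trajectory()].
#' @param selection 0-based bead indices defining the fit reference
#'   (e.g. from [select_beads()]).
#' @param reference_frame Frame to fit against (default: first frame).
#' @return A fitted [trajectory()]; the per-frame [kabsch()] results are
#'   attached as attribute `"fits"`.
#' @export
fit_trajectory <- function(traj, selection,
                           reference_frame = traj$frames[[1]]) {
  if (length(selection) == 0) stop("fit selection is empty")
  if (nrow(reference_frame$coords) != traj$topology$n_beads) {
    stop("reference frame does not match trajectory topology")
  }
  rows <- selection + 1L
  ref <- reference_frame$coords[rows, , drop = FALSE]
  fits <- vector("list", length(traj$frames))
  frames <- traj$frames
  for (i in seq_along(frames)) {
    fit <- tryCatch(
      kabsch(frames[[i]]$coords[rows, , drop = FALSE], ref),
      error = function(e) stop("frame ", i, ": ", conditionMessage(e))
    )
    frames[[i]]$coords <- apply_fit(frames[[i]]$coords, fit)
    fits[[i]] <- fit
  }
  out <- trajectory(traj$topology, frames)
  attr(out, "fits") <- fits
  out
}
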