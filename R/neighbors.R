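# Pairwise neighbour search under periodic boundary conditions.
#
# Two interchangeable backends: a cell-list search (default) and a
# brute-force O(N^2) double loop kept as the reference oracle.  Leaflet
# assignment uses in-plane (x, y) minimum-image distances only, because
# a bilayer is periodic in the membrane plane but must not connect
# across the z boundary; contact counting uses all three dimensions.

.mi_wrap <- function(d, L) d - L * round(d / L)

# Minimum-image squared distances between one point and a coordinate
# block.  pbc_dims: logical length-3, which dimensions are periodic.
.mi_dist2 <- function(p, coords, box, pbc_dims) {
  d <- sweep(coords, 2, p)
  for (k in which(pbc_dims)) d[, k] <- .mi_wrap(d[, k], box[k])
  rowSums(d * d)
}

.pairs_brute <- function(a, b, box, cutoff, pbc_dims, self) {
  out_i <- integer(0)
  out_j <- integer(0)
  c2 <- cutoff^2
  for (i in seq_len(nrow(a))) {
    jmax <- if (self) i - 1L else nrow(b)
    if (jmax < 1L) next
    d2 <- .mi_dist2(a[i, ], b[seq_len(jmax), , drop = FALSE], box, pbc_dims)
    hit <- which(d2 < c2)
    out_i <- c(out_i, rep.int(i, length(hit)))
    out_j <- c(out_j, hit)
  }
  cbind(i = out_i, j = out_j)
}

.cell_index <- function(coords, box, cutoff, pbc_dims) {
  n <- nrow(coords)
  nc <- integer(3)
  id <- matrix(0L, n, 3)
  lo <- numeric(3)
  for (k in 1:3) {
    if (pbc_dims[k]) {
      nc[k] <- max(1L, as.integer(floor(box[k] / cutoff)))
      w <- box[k] / nc[k]
      ck <- coords[, k] %% box[k]
      id[, k] <- pmin(nc[k] - 1L, as.integer(floor(ck / w)))
    } else {
      lo[k] <- min(coords[, k])
      span <- max(coords[, k]) - lo[k]
      nc[k] <- max(1L, as.integer(floor(span / cutoff)) + 1L)
      id[, k] <- pmin(nc[k] - 1L, as.integer(floor((coords[, k] - lo[k]) /
                                                     cutoff)))
    }
  }
  list(id = id, nc = nc)
}

.pairs_cell <- function(a, b, box, cutoff, pbc_dims, self) {
  # a cell list only pays off when every periodic dimension holds at
  # least four cells (otherwise neighbour cells alias under wrapping)
  nc_p <- floor(box / cutoff)
  if (any(pbc_dims & nc_p < 4)) {
    return(.pairs_brute(a, b, box, cutoff, pbc_dims, self))
  }
  all_coords <- rbind(a, if (!self) b)
  ci <- .cell_index(all_coords, box, cutoff, pbc_dims)
  na <- nrow(a)
  idx_a <- seq_len(na)
  idx_b <- if (self) idx_a else (na + seq_len(nrow(b)))
  key <- function(id) {
    (id[, 1] * ci$nc[2] + id[, 2]) * ci$nc[3] + id[, 3] + 1L
  }
  kb <- key(ci$id[idx_b, , drop = FALSE])
  b_by_cell <- split(if (self) idx_a else seq_len(nrow(b)), kb)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  c2 <- cutoff^2
  out_i <- vector("list", na)
  out_j <- vector("list", na)
  bcoords <- if (self) a else b
  for (ii in idx_a) {
    id0 <- ci$id[ii, ]
    cand <- integer(0)
    for (o in seq_len(nrow(offs))) {
      id1 <- id0 + offs[o, ]
      ok <- TRUE
      for (k in 1:3) {
        if (pbc_dims[k]) {
          id1[k] <- id1[k] %% ci$nc[k]
        } else if (id1[k] < 0 || id1[k] >= ci$nc[k]) {
          ok <- FALSE
          break
        }
      }
      if (!ok) next
      hit <- b_by_cell[[as.character((id1[1] * ci$nc[2] + id1[2]) *
                                       ci$nc[3] + id1[3] + 1L)]]
      if (!is.null(hit)) cand <- c(cand, hit)
    }
    cand <- unique(cand)
    if (self) cand <- cand[cand < ii]
    if (length(cand) == 0) next
    d2 <- .mi_dist2(a[ii, ], bcoords[cand, , drop = FALSE], box, pbc_dims)
    hit <- cand[d2 < c2]
    out_i[[ii]] <- rep.int(ii, length(hit))
    out_j[[ii]] <- hit
  }
  cbind(i = unlist(out_i), j = unlist(out_j))
}

#' Bead pairs within a distance cutoff
#'
#' Finds all pairs of points closer than `cutoff` (strict inequality)
#' under the minimum-image convention in the chosen dimensions.  With
#' one coordinate set, self-pairs are returned once each (`i > j`);
#' with two sets, all cross pairs `(i, j)` are returned.
#'
#' @param a n x 3 coordinate matrix (nm).
#' @param b Optional second m x 3 coordinate matrix; `NULL` for
#'   self-pairs within `a`.
#' @param box Length-3 box vector (nm).
#' @param cutoff Distance cutoff in nm (pairs at exactly `cutoff` are
#'   excluded).
#' @param pbc `"xy"` (membrane-plane wrapping only) or `"xyz"` (full
#'   wrapping) or `"none"`.
#' @param method `"cell"` (cell list; falls back to brute force for
#'   boxes smaller than four cells per periodic dimension) or
#'   `"brute"` (reference double loop).
#' @return Two-column integer matrix of 1-based row indices (`i` into
#'   `a`, `j` into `b` or `a`).
#' @export
pairs_within <- function(a, b = NULL, box, cutoff,
                         pbc = c("xy", "xyz", "none"),
                         method = c("cell", "brute")) {
  pbc <- match.arg(pbc)
  method <- match.arg(method)
  stopifnot(cutoff > 0, length(box) == 3, all(box > 0))
  a <- as.matrix(a)
  self <- is.null(b)
  bm <- if (self) a else as.matrix(b)
  if (nrow(a) == 0 || nrow(bm) == 0) {
    return(cbind(i = integer(0), j = integer(0)))
  }
  pbc_dims <- switch(pbc,
                     xy = c(TRUE, TRUE, FALSE),
                     xyz = c(TRUE, TRUE, TRUE),
                     none = c(FALSE, FALSE, FALSE))
  res <- switch(method,
                brute = .pairs_brute(a, bm, box, cutoff, pbc_dims, self),
                cell = .pairs_cell(a, bm, box, cutoff, pbc_dims, self))
  if (is.null(res) || nrow(res) == 0) {
    return(cbind(i = integer(0), j = integer(0)))
  }
  res[order(res[, 1], res[, 2]), , drop = FALSE]
}
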