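# Independent brute-force oracles used across the suite.  Each is a
# deliberately naive re-implementation kept separate from the package
# code paths it checks.

# depth statistic: sort, slice, mean, min
brute_depth <- function(z, percentile = 90) {
  zs <- sort(z)
  thr <- stats::quantile(zs, percentile / 100, names = FALSE, type = 7)
  mean(zs[zs >= thr]) - zs[1]
}

# O(N^2) minimum-image pair list via nested loops
brute_pairs <- function(a, b = NULL, box, cutoff,
                        pbc_dims = c(TRUE, TRUE, FALSE)) {
  self <- is.null(b)
  if (self) b <- a
  hits <- NULL
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (self && j >= i) next
      d <- a[i, ] - b[j, ]
      for (k in 1:3) {
        if (pbc_dims[k]) d[k] <- d[k] - box[k] * round(d[k] / box[k])
      }
      if (sum(d^2) < cutoff^2) hits <- rbind(hits, c(i, j))
    }
  }
  if (is.null(hits)) {
    return(cbind(i = integer(0), j = integer(0)))
  }
  colnames(hits) <- c("i", "j")
  hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
}

# connected components of the cutoff graph via igraph (independent of
# the package's flood fill)
graph_components <- function(coords, box, cutoff) {
  prs <- brute_pairs(coords, box = box, cutoff = cutoff)
  g <- igraph::make_empty_graph(n = nrow(coords), directed = FALSE)
  if (nrow(prs) > 0) g <- igraph::add_edges(g, t(prs))
  igraph::components(g)$membership
}

# Monte-Carlo expected depth of a noise-jittered point set: applies
# the sort/slice/mean/min statistic to base_z plus fresh Gaussian
# noise, many times
mc_expected_depth <- function(base_z, sigma_z, n_mc = 200,
                              percentile = 90) {
  vals <- vapply(seq_len(n_mc), function(i) {
    brute_depth(base_z + stats::rnorm(length(base_z), 0, sigma_z),
                percentile)
  }, numeric(1))
  list(mean = mean(vals), sem = stats::sd(vals) / sqrt(n_mc))
}

# exhaustive anchor-triple motif enumeration via expand.grid
oracle_motif_triples <- function(seq_chars, first, center, last) {
  n <- length(seq_chars)
  fs <- which(seq_chars %in% first)
  cs <- which(seq_chars %in% center)
  ls <- which(seq_chars %in% last)
  if (!length(fs) || !length(cs) || !length(ls)) {
    return(data.frame(start = integer(0), center = integer(0),
                      end = integer(0)))
  }
  g <- expand.grid(start = fs, center = cs, end = ls)
  g <- g[g$center - g$start >= 2 & g$center - g$start <= 6 &
           g$end - g$center >= 2 & g$end - g$center <= 6, ]
  g <- g[order(g$start, g$end, g$center), ]
  rownames(g) <- NULL
  g
}

# greedy leftmost-shortest non-overlapping reduction of a triple table
oracle_greedy_reduce <- function(triples) {
  sel <- NULL
  pos <- 1L
  repeat {
    cand <- triples[triples$start >= pos, , drop = FALSE]
    if (nrow(cand) == 0) break
    cand <- cand[order(cand$start, cand$end, cand$center), , drop = FALSE]
    sel <- rbind(sel, cand[1, ])
    pos <- cand$end[1] + 1L
  }
  if (is.null(sel)) {
    return(data.frame(start = integer(0), center = integer(0),
                      end = integer(0)))
  }
  rownames(sel) <- NULL
  sel
}

# random amino-acid sequence rich in motif anchors
random_anchor_sequence <- function(n) {
  paste(sample(c("L", "V", "Y", "F", "R", "K", "A", "G", "S", "T"),
               n, replace = TRUE), collapse = "")
}

# leaflet assignment built directly from generator ground truth
truth_assignment <- function(sys) {
  lp <- sys$truth$lipids
  structure(list(bead_index = lp$bead_index, leaflet = lp$leaflet,
                 seed_bead_upper = NA_integer_,
                 seed_bead_lower = NA_integer_),
            class = "leaflet_assignment")
}

# small helper topology: n_lip single-bead lipids plus optional
# protein chains given as list(chain = residue count)
toy_topology <- function(n_lip = 4, species = "POPC", chains = NULL) {
  rows <- list()
  mol <- 0L
  if (!is.null(chains)) {
    for (ch in names(chains)) {
      mol <- mol + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        bead_name = "BB", residue_name = "ALA", category = "protein",
        species = "", is_headgroup = FALSE, molecule_id = mol,
        chain_id = ch, residue_number = seq_len(chains[[ch]]))
    }
  }
  if (n_lip > 0) {
    rows[[length(rows) + 1L]] <- data.frame(
      bead_name = ifelse(species == "CHOL", "ROH", "PO4"),
      residue_name = species, category = "lipid",
      species = species, is_headgroup = TRUE,
      molecule_id = mol + seq_len(n_lip), chain_id = "",
      residue_number = NA_integer_)
  }
  beads <- do.call(rbind, rows)
  beads$bead_index <- 0:(nrow(beads) - 1L)
  topology(beads)
}
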