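# Density maps, contact profiles, significance cutoffs and delta_L.

static_traj <- function(coords, box, n_frames, top) {
  frames <- lapply(seq_len(n_frames) - 1, function(t) {
    traj_frame(coords, box, t)
  })
  trajectory(top, frames)
}

test_that("density normalization is an identity for stationary lipids", {
  top <- toy_topology(1)
  traj <- static_traj(matrix(c(2.2, 3.3, 5), 1), c(10, 10, 10), 10, top)
  dm <- density_map(traj, 0L, n_molecules = 1, bins = 10)
  expect_equal(sum(dm$density_norm), 1)
  expect_equal(max(dm$density_norm), 1)

  top2 <- toy_topology(2)
  traj2 <- static_traj(rbind(c(1.5, 1.5, 5), c(8.5, 8.5, 5)),
                       c(10, 10, 10), 4, top2)
  dm2 <- density_map(traj2, 0:1, n_molecules = 2, bins = 10)
  expect_equal(sort(dm2$density_norm[dm2$density_norm > 0]),
               c(0.5, 0.5))
  expect_error(density_map(traj2, integer(0), 2), "empty")
})

test_that("normalized density sums to one per counted bead per molecule", {
  sys <- make_dome_trajectory(dome_spec(
    box = c(16, 16, 18), depth_D = 2, width_sigma = 3, n_frames = 3,
    noise_sigma_xy = 0.05, seed = 61))
  top <- sys$trajectory$topology
  sel <- select_beads(top, species = "POPC", headgroup_only = TRUE)
  n_mol <- length(unique(top$beads$molecule_id[sel + 1L]))
  dm <- density_map(sys$trajectory, sel, n_mol, bins = 30)
  expect_equal(sum(dm$density_norm), 1, tolerance = 1e-9)
})

test_that("a planted annulus enrichment is recovered by the density map", {
  ann_comp <- list(
    upper = c(POPC = 0.20, POPE = 0.10, SM = 0.50, CHOL = 0.20),
    lower = c(POPC = 0.10, POPE = 0.25, POPS = 0.15, PIP2 = 0.30,
              CHOL = 0.20))
  ratios <- vapply(1:6, function(seed) {
    sys <- make_dome_trajectory(dome_spec(
      box = c(40, 40, 14), depth_D = 0, protein = NULL,
      annulus = list(radius_nm = 8, composition = ann_comp),
      seed = seed))
    lp <- sys$truth$lipids
    low <- lp[lp$leaflet == "lower", ]
    r <- sqrt((low$base_x - 20)^2 + (low$base_y - 20)^2)
    realized <- (sum(low$species[r <= 8] == "PIP2") / sum(r <= 8)) /
      (sum(low$species[r > 8] == "PIP2") / sum(r > 8))

    top <- sys$trajectory$topology
    sel <- select_beads(top, species = "PIP2", headgroup_only = TRUE)
    n_mol <- length(unique(top$beads$molecule_id[sel + 1L]))
    dm <- density_map(sys$trajectory, sel, n_mol, bins = 40)
    xc <- (head(dm$x_edges, -1) + tail(dm$x_edges, -1)) / 2
    g <- expand.grid(x = xc - 20, y = xc - 20)
    rb <- sqrt(g$x^2 + g$y^2)
    in_ann <- rb <= 8
    far <- rb > 8 & rb <= 19
    measured <- mean(dm$density_norm[in_ann]) /
      mean(dm$density_norm[far])
    # the map must reproduce the realized draw almost exactly
    # (binning/edge effects only)
    expect_equal(measured, realized, tolerance = 0.08)
    realized
  }, numeric(1))
  # and the realized enrichment tracks the planted 3x across seeds
  expect_lt(abs(mean(ratios) - 3), 0.45)
})

test_that("contact counting respects the strict 0.55 nm cutoff", {
  top <- toy_topology(1, chains = list(A = 1))
  mk <- function(d) {
    traj_frame(rbind(c(5, 5, 5), c(5 + d, 5, 5)), c(10, 10, 10), 0)
  }
  cf <- contacts_frame(mk(0.50), top, 0L, 1L)
  expect_equal(cf$count, 1)
  expect_equal(nrow(contacts_frame(mk(0.60), top, 0L, 1L)), 0)
  # the inequality is strict: a pair exactly at the cutoff is excluded
  # (0.5 is exactly representable, unlike 0.55)
  expect_equal(nrow(contacts_frame(mk(0.5), top, 0L, 1L,
                                   cutoff_nm = 0.5)), 0)
  # minimum image: 9.7 apart in a 10 box is 0.3
  expect_equal(contacts_frame(mk(9.7), top, 0L, 1L)$count, 1)
})

test_that("cell-list contacts equal the brute-force oracle", {
  set.seed(62)
  for (rep in 1:20) {
    np <- sample(5:30, 1)
    nl <- sample(5:30, 1)
    box <- c(5, 5, 5)
    pc <- cbind(stats::runif(np, 0, 5), stats::runif(np, 0, 5),
                stats::runif(np, 0, 5))
    lc <- cbind(stats::runif(nl, 0, 5), stats::runif(nl, 0, 5),
                stats::runif(nl, 0, 5))
    got <- pairs_within(pc, lc, box = box, cutoff = 0.55, pbc = "xyz",
                        method = "cell")
    want <- brute_pairs(pc, lc, box = box, cutoff = 0.55,
                        pbc_dims = rep(TRUE, 3))
    expect_equal(unname(got), unname(want))
  }
})

test_that("planted contact schedules are recovered exactly", {
  # single chain, 1 lipid, contact at residue 7 in all 4 frames
  ps <- make_planted_contact_system(c("7" = 1), n_frames = 4,
                                    chains = "A")
  cfg <- analysis_config(contact_exclusion_ns = 0)
  prof <- contact_profile(ps$trajectory, "PIP2", cfg)
  expect_equal(prof$norm[prof$residue_number == 7], 1.0)
  expect_true(all(prof$norm[prof$residue_number != 7] == 0))

  # random schedules against the generator's bookkeeping
  set.seed(63)
  for (rep in 1:5) {
    res <- sort(sample(1:9, sample(2:4, 1)))
    sched <- stats::setNames(sample(1:3, length(res), replace = TRUE),
                             res)
    chains <- sample(list("A", c("A", "B"), c("A", "B", "C")), 1)[[1]]
    ps <- make_planted_contact_system(
      sched, n_frames = 3, chains = chains, n_residues = 10,
      extra_lipids = 5, seed = rep)
    prof <- contact_profile(ps$trajectory, "PIP2", cfg)
    expect_equal(prof$raw, ps$expected_profile$raw)
    expect_equal(prof$norm, ps$expected_profile$norm)
  }

  # empty schedule: all-zero profile
  ps0 <- make_planted_contact_system(stats::setNames(numeric(0),
                                                     character(0)),
                                     n_residues = 5, extra_lipids = 3)
  prof0 <- contact_profile(ps0$trajectory, "POPC", cfg)
  expect_true(all(prof0$raw == 0))
  expect_error(make_planted_contact_system(c("3" = 9)), "overcrowd")
})

test_that("chain summation adds equal-residue contacts across chains", {
  # three chains, residue-7 beads in a tight triangle around one lipid
  prot <- data.frame(
    bead_name = "BB", residue_name = "ALA", category = "protein",
    species = "", is_headgroup = FALSE,
    molecule_id = rep(1:3, each = 7), chain_id = rep(c("A", "B", "C"),
                                                     each = 7),
    residue_number = rep(1:7, 3))
  lip <- data.frame(bead_name = "PO4", residue_name = "POP2",
                    category = "lipid", species = "PIP2",
                    is_headgroup = TRUE, molecule_id = 4L,
                    chain_id = "", residue_number = NA_integer_)
  beads <- rbind(prot, lip)
  beads$bead_index <- 0:(nrow(beads) - 1L)
  top <- topology(beads)
  coords <- matrix(0, 22, 3)
  for (c_i in 1:3) {
    # residues 1-6 parked far away, residue 7 near the lipid
    rows <- (c_i - 1) * 7 + (1:7)
    coords[rows, ] <- cbind(3 * (1:7), 10 * c_i, 40)
    ang <- 2 * pi * c_i / 3
    coords[rows[7], ] <- c(20 + 0.3 * cos(ang), 20 + 0.3 * sin(ang), 5)
  }
  coords[22, ] <- c(20, 20, 5)
  fr <- traj_frame(coords, c(50, 50, 50), 0)
  prof <- contact_profile(trajectory(top, list(fr)), "PIP2",
                          analysis_config(contact_exclusion_ns = 0))
  expect_equal(prof$norm[prof$residue_number == 7], 3.0)
})

test_that("mismatching chain residue ranges are rejected", {
  top <- toy_topology(1, chains = list(A = 5, B = 4))
  coords <- cbind(seq_len(10), 1, 1)
  traj <- trajectory(top, list(traj_frame(coords, c(20, 20, 20), 0)))
  expect_error(contact_profile(traj, "POPC",
                               analysis_config(contact_exclusion_ns = 0)),
               "different residue sets")
})

test_that("contact profiles survive chain relabelling", {
  sched <- c("3" = 2, "6" = 1)
  ps <- make_planted_contact_system(sched, n_frames = 2,
                                    chains = c("A", "B"),
                                    n_residues = 8, seed = 5)
  cfg <- analysis_config(contact_exclusion_ns = 0)
  prof <- contact_profile(ps$trajectory, "PIP2", cfg)
  b <- ps$trajectory$topology$beads
  b$chain_id <- c(A = "C", B = "A", C = "B")[b$chain_id]
  b$chain_id[is.na(b$chain_id)] <- ""
  top2 <- topology(b)
  traj2 <- trajectory(top2, ps$trajectory$frames)
  prof2 <- contact_profile(traj2, "PIP2", cfg)
  expect_equal(prof2$norm, prof$norm)
})

test_that("significance cutoffs follow the fraction-of-maximum rule", {
  prof <- data.frame(residue_number = 1:3, raw = c(10, 7, 5),
                     norm = c(10, 7, 5))
  expect_equal(significant_residues(prof, 0.6), c(1, 2))
  expect_equal(significant_residues(prof, 1.0), 1)
  tie <- data.frame(residue_number = 1:3, raw = c(10, 10, 5),
                    norm = c(10, 10, 5))
  expect_equal(significant_residues(tie, 1.0), c(1, 2))
  zero <- data.frame(residue_number = 1:3, raw = 0, norm = 0)
  expect_warning(out <- significant_residues(zero, 0.6), "all-zero")
  expect_length(out, 0)
})

test_that("delta_L follows its algebraic identities", {
  expect_equal(delta_L(100, 400, 50, 500), 60)
  expect_equal(delta_L(N_L = 37, N_A = 37, n_L = 12, n_A = 12), 0)
  # proportional occupancy vanishes at any magnitude
  for (scale in c(1, 10, 1000)) {
    expect_equal(delta_L(3 * scale, 12 * scale, 5, 20), 0)
  }
  expect_error(delta_L(1, 2, 3, 0), "n_A")
  expect_error(delta_L(5, 2, 1, 2), "N_L")
})

test_that("binding preference recovers a planted PIP2 annulus", {
  ann_comp <- list(
    upper = c(POPC = 0.20, POPE = 0.10, SM = 0.50, CHOL = 0.20),
    lower = c(POPC = 0.10, POPE = 0.25, POPS = 0.15, PIP2 = 0.30,
              CHOL = 0.20))
  sys <- make_dome_trajectory(dome_spec(
    box = c(24, 24, 14), depth_D = 0, n_frames = 3,
    noise_sigma_xy = 0.03, noise_sigma_z = 0.03,
    protein = list(arrangement = "rings", n_chains = 3,
                   ring_radii = c(2.5, 3.3)),
    annulus = list(radius_nm = 6, composition = ann_comp), seed = 64))
  pref <- preference_analysis(sys$trajectory,
                              analysis_config(contact_exclusion_ns = 0))
  expect_gt(pref$delta_L[pref$species == "PIP2"], 0)
  expect_lt(pref$delta_L[pref$species == "POPC"], 0)
  # algebraic conservation per frame
  expect_true(all(abs(rowSums(attr(pref, "per_frame"))) < 1e-6))
})

test_that("two species with identical statistics give a null delta_L", {
  comp <- list(upper = c(POPC = 0.5, POPE = 0.5),
               lower = c(POPC = 0.5, POPE = 0.5))
  deltas <- vapply(1:5, function(seed) {
    sys <- make_dome_trajectory(dome_spec(
      box = c(20, 20, 14), depth_D = 0, composition = comp,
      n_frames = 4, noise_sigma_xy = 0.05, noise_sigma_z = 0.05,
      protein = list(arrangement = "rings", n_chains = 3,
                     ring_radii = 2.5), seed = seed))
    pref <- preference_analysis(sys$trajectory,
                                analysis_config(contact_exclusion_ns = 0))
    pref$delta_L[pref$species == "POPC"]
  }, numeric(1))
  sem <- stats::sd(deltas) / sqrt(length(deltas))
  expect_lt(abs(mean(deltas)), 3 * max(sem, 1e-9))
})
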