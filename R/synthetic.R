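# Synthetic ground-truth generators: a curved two-leaflet CG bilayer
# deformed by a parameterised trilobed dome, a planted-contact system
# with an exactly known contact profile, and motif-bearing protein
# sequences.  Each generator records the ground truth it planted, so
# every analysis in the package can be validated against construction
# rather than against itself.
#
# The dome deformation field applied to both leaflet lattices is
#
#   f(r, theta) = -D * exp(-r^2 / (2 sigma^2)) * g(theta),
#   g(theta)    = (1 + a cos(k theta)) / (1 + a),   f(0) := -D,
#
# with D the dome depth, sigma the dome width, a in [0, 1) the lobe
# amplitude and k the lobe count (3 for a trilobed footprint).

.species_resname <- c(POPC = "POPC", POPE = "POPE", POPS = "POPS",
                      PIP2 = "POP2", SM = "DPSM", CHOL = "CHOL")
.species_headbead <- c(POPC = "PO4", POPE = "PO4", POPS = "PO4",
                       PIP2 = "PO4", SM = "PO4", CHOL = "ROH")

#' Specification of a synthetic dome bilayer
#'
#' Defaults emulate an asymmetric plasma-membrane mix: sphingomyelin
#' only in the upper (extracellular) leaflet, PIP2 only in the lower
#' (cytosolic) leaflet, 20% cholesterol in both.
#'
#' @param box Box lengths `(Lx, Ly, Lz)` in nm.
#' @param lattice_spacing Headgroup lattice spacing (nm); must stay
#'   below the leaflet-assignment cutoff.
#' @param leaflet_separation Vertical headgroup-to-headgroup distance
#'   between leaflets (nm); must exceed the leaflet-assignment cutoff.
#' @param depth_D Dome depth D (nm, >= 0).
#' @param width_sigma Dome Gaussian width sigma (nm).
#' @param lobe_amplitude Angular modulation amplitude a in [0, 1).
#' @param lobe_count Number of lobes k.
#' @param noise_sigma_xy,noise_sigma_z Per-frame Gaussian jitter (nm).
#' @param composition Named fractions per leaflet,
#'   `list(upper = c(...), lower = c(...))`; each must sum to 1.
#' @param n_frames Number of frames.
#' @param dt_ns,t0_ns Frame spacing and first-frame time (ns).
#' @param seed RNG seed; species sampling and jitter flow from it.
#' @param cutoff_nm Leaflet-assignment cutoff the geometry must keep
#'   separable (checked at generation).
#' @param protein Protein stub: `NULL` for none, or a list with
#'   `arrangement` (`"column"` or `"rings"`), `n_chains`,
#'   `n_residues` (column) or `ring_radii` (rings), see
#'   [make_dome_trajectory()].
#' @param annulus Optional local composition override near the centre:
#'   `list(radius_nm = , composition = list(upper = , lower = ))`.
#' @param tail_beads 0 or 2 tail beads per lipid (non-headgroup).
#' @param translocate Optional planted leaflet flip:
#'   `list(from_frame = i)` moves one seeded-random lower-leaflet
#'   lipid to the upper surface from frame `i` on.
#' @return Object of class `dome_spec`.
#' @export
dome_spec <- function(box = c(24, 24, 16), lattice_spacing = 0.8,
                      leaflet_separation = 4.0, depth_D = 6,
                      width_sigma = 3, lobe_amplitude = 0,
                      lobe_count = 3L, noise_sigma_xy = 0,
                      noise_sigma_z = 0,
                      composition = list(
                        upper = c(POPC = 0.40, POPE = 0.10, SM = 0.30,
                                  CHOL = 0.20),
                        lower = c(POPC = 0.30, POPE = 0.25, POPS = 0.15,
                                  PIP2 = 0.10, CHOL = 0.20)),
                      n_frames = 1L, dt_ns = 1, t0_ns = 0, seed = 1L,
                      cutoff_nm = 2.0,
                      protein = list(arrangement = "column",
                                     n_chains = 3L, n_residues = 8L),
                      annulus = NULL, tail_beads = 0L,
                      translocate = NULL) {
  stopifnot(
    "box must be three positive lengths" =
      length(box) == 3 && all(box > 0),
    "depth_D must be >= 0" = depth_D >= 0,
    "width_sigma must be > 0" = width_sigma > 0,
    "lobe_amplitude must be in [0, 1)" =
      lobe_amplitude >= 0 && lobe_amplitude < 1,
    "lobe_count must be >= 1" = lobe_count >= 1,
    "noise sigmas must be >= 0" =
      noise_sigma_xy >= 0 && noise_sigma_z >= 0,
    "lattice_spacing must be below cutoff_nm" =
      lattice_spacing > 0 && lattice_spacing < cutoff_nm,
    "leaflet_separation must exceed cutoff_nm" =
      leaflet_separation > cutoff_nm,
    "n_frames must be >= 1" = n_frames >= 1,
    "tail_beads must be 0 or 2" = tail_beads %in% c(0L, 2L)
  )
  for (lf in c("upper", "lower")) {
    comp <- composition[[lf]]
    if (is.null(comp) || abs(sum(comp) - 1) > 1e-9) {
      stop("composition$", lf, " fractions must sum to 1")
    }
    if (!all(names(comp) %in% names(.species_resname))) {
      stop("unknown species in composition$", lf, ": ",
           paste(setdiff(names(comp), names(.species_resname)),
                 collapse = ", "))
    }
  }
  if (!is.null(annulus)) {
    stopifnot(is.list(annulus), annulus$radius_nm > 0)
    for (lf in c("upper", "lower")) {
      comp <- annulus$composition[[lf]]
      if (is.null(comp) || abs(sum(comp) - 1) > 1e-9) {
        stop("annulus composition$", lf, " fractions must sum to 1")
      }
    }
  }
  if (box[3] / 2 - leaflet_separation / 2 - depth_D -
        6 * noise_sigma_z <= 0) {
    stop("box z too small for dome depth ", depth_D,
         " nm below the lower leaflet")
  }
  structure(
    list(box = box, lattice_spacing = lattice_spacing,
         leaflet_separation = leaflet_separation, depth_D = depth_D,
         width_sigma = width_sigma, lobe_amplitude = lobe_amplitude,
         lobe_count = as.integer(lobe_count),
         noise_sigma_xy = noise_sigma_xy, noise_sigma_z = noise_sigma_z,
         composition = composition, n_frames = as.integer(n_frames),
         dt_ns = dt_ns, t0_ns = t0_ns, seed = as.integer(seed),
         cutoff_nm = cutoff_nm, protein = protein, annulus = annulus,
         tail_beads = as.integer(tail_beads), translocate = translocate),
    class = "dome_spec")
}

.dome_field <- function(x, y, spec) {
  cx <- spec$box[1] / 2
  cy <- spec$box[2] / 2
  r <- sqrt((x - cx)^2 + (y - cy)^2)
  theta <- atan2(y - cy, x - cx)
  g <- (1 + spec$lobe_amplitude * cos(spec$lobe_count * theta)) /
    (1 + spec$lobe_amplitude)
  f <- -spec$depth_D * exp(-r^2 / (2 * spec$width_sigma^2)) * g
  f[r == 0] <- -spec$depth_D
  f
}

.protein_stub_coords <- function(spec) {
  pr <- spec$protein
  if (is.null(pr)) return(NULL)
  mid <- spec$box[3] / 2
  z_top <- mid + spec$leaflet_separation / 2
  z_bot <- mid - spec$leaflet_separation / 2 - spec$depth_D
  cx <- spec$box[1] / 2
  cy <- spec$box[2] / 2
  n_chains <- if (is.null(pr$n_chains)) 3L else as.integer(pr$n_chains)
  if (identical(pr$arrangement, "rings")) {
    # beads on circles at both leaflet z levels, split into symmetric
    # chains: a contact-rich stub for binding-preference systems
    radii <- pr$ring_radii
    z_lower <- mid - spec$leaflet_separation / 2
    per_chain <- list()
    for (rr in radii) {
      arc <- 2 * pi * rr / n_chains
      nb <- max(3L, floor(arc / 0.5))
      ang <- (seq_len(nb) - 1) / nb * (2 * pi / n_chains)
      for (zz in c(z_lower, z_top)) {
        per_chain[[length(per_chain) + 1L]] <- cbind(ang, rr, zz)
      }
    }
    proto <- do.call(rbind, per_chain)
    coords <- list()
    chain_id <- character(0)
    residue <- integer(0)
    for (c_i in seq_len(n_chains)) {
      off <- 2 * pi * (c_i - 1) / n_chains
      coords[[c_i]] <- cbind(cx + proto[, 2] * cos(proto[, 1] + off),
                             cy + proto[, 2] * sin(proto[, 1] + off),
                             proto[, 3])
      chain_id <- c(chain_id, rep(LETTERS[c_i], nrow(proto)))
      residue <- c(residue, seq_len(nrow(proto)))
    }
    list(coords = do.call(rbind, coords), chain_id = chain_id,
         residue_number = residue)
  } else {
    n_res <- if (is.null(pr$n_residues)) 8L else as.integer(pr$n_residues)
    coords <- list()
    chain_id <- character(0)
    residue <- integer(0)
    for (c_i in seq_len(n_chains)) {
      ang <- 2 * pi * (c_i - 1) / n_chains
      zs <- seq(z_bot, z_top, length.out = n_res)
      coords[[c_i]] <- cbind(cx + 0.5 * cos(ang) + 0.05 * seq_len(n_res),
                             cy + 0.5 * sin(ang),
                             zs)
      chain_id <- c(chain_id, rep(LETTERS[c_i], n_res))
      residue <- c(residue, seq_len(n_res))
    }
    list(coords = do.call(rbind, coords), chain_id = chain_id,
         residue_number = residue)
  }
}

#' Generate a synthetic dome-deformed bilayer trajectory
#'
#' Builds two headgroup lattices separated by `leaflet_separation`,
#' displaces both by the trilobed Gaussian dome field, samples lipid
#' species per leaflet from the composition (optionally overridden
#' inside a central annulus), embeds a protein bead stub, and emits
#' `n_frames` frames with fresh Gaussian jitter each.  All randomness
#' flows from `spec$seed`.  The construction is checked against the
#' leaflet-separability preconditions (no cross-leaflet headgroup pair
#' within the cutoff, with a 6-sigma noise margin).
#'
#' @param spec A [dome_spec()].
#' @return Object of class `dome_system`: `list(trajectory, truth)`
#'   where `truth` records per-bead leaflet, species, base (noise-free)
#'   coordinates, the analytic deformation `f`, annulus membership and
#'   the planted translocation, plus the generating spec.
#' @export
make_dome_trajectory <- function(spec) {
  stopifnot(inherits(spec, "dome_spec"))
  sp <- spec$lattice_spacing
  nx <- floor(spec$box[1] / sp)
  ny <- floor(spec$box[2] / sp)
  # phase the lattice so the box centre is a lattice point: the dome
  # minimum then sits exactly at -D on a bead
  gx <- (seq_len(nx) - 1) * sp + (spec$box[1] / 2) %% sp
  gy <- (seq_len(ny) - 1) * sp + (spec$box[2] / 2) %% sp
  grid <- expand.grid(x = gx, y = gy)
  f <- .dome_field(grid$x, grid$y, spec)
  mid <- spec$box[3] / 2
  half <- spec$leaflet_separation / 2
  n_site <- nrow(grid)

  stub <- .protein_stub_coords(spec)
  n_prot <- if (is.null(stub)) 0L else nrow(stub$coords)

  set.seed(spec$seed)
  cx <- spec$box[1] / 2
  cy <- spec$box[2] / 2
  r_site <- sqrt((grid$x - cx)^2 + (grid$y - cy)^2)
  sample_species <- function(leaflet) {
    comp <- spec$composition[[leaflet]]
    out <- sample(names(comp), n_site, replace = TRUE, prob = comp)
    in_ann <- rep(FALSE, n_site)
    if (!is.null(spec$annulus)) {
      in_ann <- r_site <= spec$annulus$radius_nm
      acomp <- spec$annulus$composition[[leaflet]]
      if (any(in_ann)) {
        out[in_ann] <- sample(names(acomp), sum(in_ann), replace = TRUE,
                              prob = acomp)
      }
    }
    list(species = out, in_annulus = in_ann)
  }
  up <- sample_species("upper")
  lo <- sample_species("lower")

  lip <- data.frame(
    leaflet = rep(c("upper", "lower"), each = n_site),
    species = c(up$species, lo$species),
    in_annulus = c(up$in_annulus, lo$in_annulus),
    base_x = rep(grid$x, 2), base_y = rep(grid$y, 2),
    base_z = c(mid + half + f, mid - half + f),
    f = rep(f, 2)
  )
  n_lip <- nrow(lip)
  tails <- spec$tail_beads
  beads_per_lip <- 1L + tails

  # topology: protein stub first, then lipids leaflet by leaflet
  prot_beads <- if (n_prot > 0) data.frame(
    bead_name = "BB", residue_name = "ALA", category = "protein",
    species = "", is_headgroup = FALSE,
    molecule_id = match(stub$chain_id, unique(stub$chain_id)),
    chain_id = stub$chain_id, residue_number = stub$residue_number
  ) else NULL
  n_mol_prot <- if (n_prot > 0) max(prot_beads$molecule_id) else 0L
  lip_beads <- data.frame(
    bead_name = rep(ifelse(lip$species == "CHOL", "ROH", "PO4"),
                    each = beads_per_lip),
    residue_name = rep(.species_resname[lip$species],
                       each = beads_per_lip),
    category = "lipid",
    species = rep(lip$species, each = beads_per_lip),
    is_headgroup = rep(c(TRUE, rep(FALSE, tails)), n_lip),
    molecule_id = n_mol_prot + rep(seq_len(n_lip), each = beads_per_lip),
    chain_id = "", residue_number = NA_integer_
  )
  if (tails > 0) {
    tail_sel <- !lip_beads$is_headgroup
    lip_beads$bead_name[tail_sel] <- rep(c("C1A", "C2A"), n_lip)
  }
  beads <- rbind(prot_beads, lip_beads)
  beads$bead_index <- 0:(nrow(beads) - 1L)
  top <- topology(beads)

  head_rows <- n_prot + (seq_len(n_lip) - 1L) * beads_per_lip + 1L
  lip$bead_index <- head_rows - 1L  # 0-based

  # base (noise-free) coordinates for all beads
  base <- matrix(0, nrow(beads), 3)
  if (n_prot > 0) base[seq_len(n_prot), ] <- stub$coords
  base[head_rows, ] <- cbind(lip$base_x, lip$base_y, lip$base_z)
  if (tails > 0) {
    # tails point toward the bilayer midplane
    sgn <- ifelse(lip$leaflet == "upper", -1, 1)
    for (tb in seq_len(tails)) {
      base[head_rows + tb, ] <- cbind(lip$base_x, lip$base_y,
                                      lip$base_z + sgn * 0.5 * tb)
    }
  }

  # separability precondition: no cross-leaflet headgroup pair within
  # the cutoff (with a 6-sigma jitter margin)
  margin <- spec$cutoff_nm + 6 * spec$noise_sigma_z
  cross <- pairs_within(base[head_rows[lip$leaflet == "upper"], ,
                             drop = FALSE],
                        base[head_rows[lip$leaflet == "lower"], ,
                             drop = FALSE],
                        box = spec$box, cutoff = margin, pbc = "xy")
  if (nrow(cross) > 0) {
    stop("generated leaflets are not separable at cutoff ",
         spec$cutoff_nm, " nm (", nrow(cross), " cross-leaflet pair(s) ",
         "too close); reduce depth_D or widen width_sigma")
  }

  trans <- spec$translocate
  trans_bead <- NA_integer_
  if (!is.null(trans)) {
    lower_idx <- which(lip$leaflet == "lower")
    pick <- lower_idx[sample.int(length(lower_idx), 1)]
    trans_bead <- lip$bead_index[pick]
    trans$bead_index <- trans_bead
    trans$new_z <- mid + half + lip$f[pick]
  }

  lip_rows <- n_prot + seq_len(n_lip * beads_per_lip)
  frames <- vector("list", spec$n_frames)
  for (i in seq_len(spec$n_frames)) {
    coords <- base
    if (spec$noise_sigma_xy > 0) {
      coords[lip_rows, 1:2] <- coords[lip_rows, 1:2] +
        matrix(stats::rnorm(2 * length(lip_rows), 0, spec$noise_sigma_xy),
               ncol = 2)
    }
    if (spec$noise_sigma_z > 0) {
      coords[lip_rows, 3] <- coords[lip_rows, 3] +
        stats::rnorm(length(lip_rows), 0, spec$noise_sigma_z)
    }
    if (!is.null(trans) && i >= trans$from_frame) {
      row <- trans_bead + 1L
      coords[row, 3] <- trans$new_z +
        if (spec$noise_sigma_z > 0) stats::rnorm(1, 0, spec$noise_sigma_z)
        else 0
    }
    frames[[i]] <- traj_frame(coords, spec$box,
                              spec$t0_ns + (i - 1) * spec$dt_ns)
  }
  truth <- structure(
    list(lipids = lip, spec = spec, z_mid = mid,
         protein_beads = if (n_prot > 0) 0:(n_prot - 1L) else integer(0),
         translocation = trans,
         base_coords = base),
    class = "dome_truth"
  )
  structure(list(trajectory = trajectory(top, frames), truth = truth),
            class = "dome_system")
}

#' @export
print.dome_system <- function(x, ...) {
  sp <- x$truth$spec
  cat(sprintf(
    "Synthetic dome bilayer: D=%.1f nm, sigma=%.1f nm, a=%.2f, k=%d\n",
    sp$depth_D, sp$width_sigma, sp$lobe_amplitude, sp$lobe_count))
  print(x$trajectory)
  invisible(x)
}

#' Generate a planted-contact system with an exact expected profile
#'
#' Builds three identical protein chains (one bead per residue, 3 nm
#' apart) and places lipid headgroup beads 0.4 nm from the scheduled
#' residues' beads in every frame, with all other lipids parked more
#' than 1 nm from any protein bead.  The exact expected contact
#' profile is returned alongside.
#'
#' @param residue_schedule Named numeric vector: names are residue
#'   numbers, values are contacts per frame to plant (1-8).
#' @param species Lipid species of the planted beads.
#' @param n_frames Number of frames.
#' @param seed RNG seed (parking jitter).
#' @param chains Chain ids receiving planted contacts (subset of the
#'   stub's chains).
#' @param n_chains,n_residues Stub size; `n_residues` defaults to the
#'   largest scheduled residue.
#' @param extra_lipids Additional parked (never-contacting) lipids.
#' @param extra_species Species of the parked lipids.
#' @param t0_ns,dt_ns Frame times.
#' @return Object of class `planted_system`: `list(trajectory,
#'   expected_profile, n_lipid_molecules, n_frames)`; the expected
#'   profile has `residue_number`, `raw`, `norm`.
#' @export
make_planted_contact_system <- function(residue_schedule,
                                        species = "PIP2", n_frames = 4L,
                                        seed = 1L, chains = "A",
                                        n_chains = 3L,
                                        n_residues = NULL,
                                        extra_lipids = 0L,
                                        extra_species = "POPC",
                                        t0_ns = 0, dt_ns = 1) {
  sched_res <- as.integer(names(residue_schedule))
  sched_n <- as.integer(residue_schedule)
  if (length(sched_res) > 0) {
    stopifnot(all(sched_n >= 1), all(sched_res >= 1))
    if (any(sched_n > 8)) {
      stop("infeasible placement: more than 8 planted contacts per ",
           "residue would overcrowd the 0.4 nm shell")
    }
  }
  if (is.null(n_residues)) {
    n_residues <- max(c(sched_res, 4L))
  }
  if (length(sched_res) > 0 && max(sched_res) > n_residues) {
    stop("scheduled residue ", max(sched_res),
         " exceeds stub size ", n_residues)
  }
  chain_ids <- LETTERS[seq_len(n_chains)]
  if (!all(chains %in% chain_ids)) {
    stop("chains must be a subset of ", paste(chain_ids, collapse = ","))
  }
  z0 <- 5
  box <- c(3 * (n_residues + 1) + 6, 4 * (n_chains + 1) + 10, 10)

  prot <- expand.grid(residue = seq_len(n_residues), chain = chain_ids,
                      stringsAsFactors = FALSE)
  prot_xyz <- cbind(3 * prot$residue,
                    4 * match(prot$chain, chain_ids), z0)

  set.seed(seed)
  lip_xyz <- NULL
  lip_species <- character(0)
  owner <- list()  # (chain, residue) per planted lipid
  for (ch in chains) {
    for (si in seq_along(sched_res)) {
      r <- sched_res[si]
      cnt <- sched_n[si]
      bead <- prot_xyz[prot$residue == r & prot$chain == ch, ,
                       drop = FALSE]
      ang <- 2 * pi * (seq_len(cnt) - 1) / max(cnt, 1)
      pos <- cbind(bead[1, 1] + 0.4 * cos(ang),
                   bead[1, 2],
                   bead[1, 3] + 0.4 * sin(ang))
      lip_xyz <- rbind(lip_xyz, pos)
      lip_species <- c(lip_species, rep(species, cnt))
      owner <- c(owner, rep(list(c(ch, r)), cnt))
    }
  }
  n_planted <- length(lip_species)
  if (extra_lipids > 0) {
    # parking grid along the far y edge, > 1 nm from every protein bead
    py <- 4 * n_chains + 6
    park <- cbind(1 + (seq_len(extra_lipids) - 1) %% floor(box[1] - 2),
                  py + (seq_len(extra_lipids) - 1) %/%
                    floor(box[1] - 2),
                  z0 + stats::runif(extra_lipids, -0.2, 0.2))
    lip_xyz <- rbind(lip_xyz, park)
    lip_species <- c(lip_species, rep(extra_species, extra_lipids))
  }
  n_lip <- length(lip_species)
  if (n_lip == 0) {
    stop("schedule is empty and extra_lipids is 0: no lipids to place")
  }
  # guard: no unplanned contact (every non-owner protein-lipid pair
  # must be > 1 nm apart)
  d_ok <- pairs_within(prot_xyz, lip_xyz, box = box, cutoff = 1.0,
                       pbc = "xyz")
  for (rr in seq_len(nrow(d_ok))) {
    li <- d_ok[rr, 2]
    ow <- if (li <= n_planted) owner[[li]] else c("", -1L)
    pi_ <- d_ok[rr, 1]
    if (!(prot$chain[pi_] == ow[1] &&
          prot$residue[pi_] == as.integer(ow[2]))) {
      stop("infeasible placement: lipid ", li,
           " is within 1 nm of an unscheduled protein bead")
    }
  }

  beads <- rbind(
    data.frame(bead_name = "BB", residue_name = "ALA",
               category = "protein", species = "", is_headgroup = FALSE,
               molecule_id = match(prot$chain, chain_ids),
               chain_id = prot$chain, residue_number = prot$residue),
    data.frame(bead_name = ifelse(lip_species == "CHOL", "ROH", "PO4"),
               residue_name = .species_resname[lip_species],
               category = "lipid", species = lip_species,
               is_headgroup = TRUE,
               molecule_id = n_chains + seq_len(n_lip),
               chain_id = "", residue_number = NA_integer_)
  )
  beads$bead_index <- 0:(nrow(beads) - 1L)
  top <- topology(beads)
  coords <- rbind(prot_xyz, lip_xyz)
  frames <- lapply(seq_len(n_frames), function(i) {
    traj_frame(coords, box, t0_ns + (i - 1) * dt_ns)
  })

  raw <- stats::setNames(numeric(n_residues), seq_len(n_residues))
  if (length(sched_res) > 0) {
    raw[as.character(sched_res)] <-
      sched_n * n_frames * length(chains)
  }
  # the profile is normalized by the molecule count of the profiled
  # species only (per-lipid normalization)
  n_species_mol <- sum(lip_species == species)
  expected <- data.frame(
    residue_number = seq_len(n_residues), raw = as.numeric(raw),
    norm = if (n_species_mol > 0) {
      as.numeric(raw) / (n_species_mol * n_frames)
    } else rep(0, n_residues))
  structure(
    list(trajectory = trajectory(top, frames),
         expected_profile = expected,
         n_lipid_molecules = n_lip, n_frames = n_frames),
    class = "planted_system"
  )
}

.motif_background <- c("A", "C", "D", "E", "G", "H", "I", "M", "N",
                       "P", "Q", "S", "T", "W")

#' Generate a sequence with planted CRAC/CARC motifs
#'
#' The background alphabet excludes all anchor residues
#' (L, V, Y, F, R, K), so the planted motifs are the only matches; a
#' minimum gap of 7 background residues between motifs prevents
#' cross-motif anchor triples (anchors more than 6 apart cannot
#' combine).
#'
#' @param length Total sequence length.
#' @param planted List of `list(type = "CRAC"|"CARC",
#'   spacers = c(s1, s2))` with spacer lengths in 1-5.
#' @param seed RNG seed.
#' @param positions Optional explicit 1-based start positions (same
#'   length as `planted`); overlapping or too-close motifs are an
#'   error.
#' @param min_gap Minimum background residues between motifs (>= 7).
#' @return Object of class `motif_plant`: `list(sequence,
#'   expected_hits)` with the exact `all_matches` hit table.
#' @export
make_motif_sequence <- function(length, planted = list(), seed = 1L,
                                positions = NULL, min_gap = 7L) {
  stopifnot(length >= 5, min_gap >= 7)
  set.seed(seed)
  motifs <- lapply(planted, function(p) {
    stopifnot(p$type %in% c("CRAC", "CARC"),
              base::length(p$spacers) == 2,
              all(p$spacers >= 1), all(p$spacers <= 5))
    anc <- .motif_anchors(p$type, "YF")
    chars <- c(sample(anc$first, 1),
               sample(.motif_background, p$spacers[1], replace = TRUE),
               sample(anc$center, 1),
               sample(.motif_background, p$spacers[2], replace = TRUE),
               sample(anc$last, 1))
    list(type = p$type, chars = chars, len = base::length(chars),
         center_off = 1L + p$spacers[1])
  })
  k <- base::length(motifs)
  lens <- vapply(motifs, function(m) m$len, integer(1))
  if (is.null(positions)) {
    need <- sum(lens) + min_gap * (k + 1L)
    if (k > 0 && need > length) {
      stop("sequence length ", length, " too short for ", k,
           " motifs with min_gap ", min_gap)
    }
    slack <- length - sum(lens) - min_gap * (k + 1L)
    extras <- if (k > 0) {
      tabulate(sample.int(k + 1L, slack, replace = TRUE), k + 1L)
    } else integer(0)
    positions <- integer(k)
    pos <- 0L
    for (i in seq_len(k)) {
      pos <- pos + min_gap + extras[i] + 1L
      positions[i] <- pos
      pos <- pos + lens[i] - 1L
    }
  } else {
    stopifnot(base::length(positions) == k)
    ord <- order(positions)
    positions <- positions[ord]
    motifs <- motifs[ord]
    lens <- lens[ord]
    ends <- positions + lens - 1L
    if (k > 1 && any(positions[-1] <= ends[-k])) {
      stop("planted motifs overlap")
    }
    if (k > 1 && any(positions[-1] - ends[-k] - 1L < min_gap)) {
      stop("planted motifs closer than min_gap (", min_gap,
           "); cross-motif matches would form")
    }
    if (positions[1] < 1 || ends[k] > length) {
      stop("planted motif falls outside the sequence")
    }
  }
  s <- sample(.motif_background, length, replace = TRUE)
  rows <- list()
  for (i in seq_len(k)) {
    m <- motifs[[i]]
    idx <- positions[i]:(positions[i] + m$len - 1L)
    s[idx] <- m$chars
    rows[[i]] <- data.frame(
      motif_type = m$type, start = positions[i],
      end = positions[i] + m$len - 1L,
      center = positions[i] + m$center_off,
      matched_sequence = paste(m$chars, collapse = ""))
  }
  expected <- if (k > 0) do.call(rbind, rows) else
    data.frame(motif_type = character(0), start = integer(0),
               end = integer(0), center = integer(0),
               matched_sequence = character(0))
  structure(list(sequence = paste(s, collapse = ""),
                 expected_hits = expected[order(expected$start), ,
                                          drop = FALSE]),
            class = "motif_plant")
}
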