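# Dome depth statistic and height maps.

flat_assignment <- function(n_upper, n_lower) {
  structure(list(
    bead_index = 0:(n_upper + n_lower - 1L),
    leaflet = rep(c("upper", "lower"), c(n_upper, n_lower)),
    seed_bead_upper = 0L, seed_bead_lower = n_upper),
    class = "leaflet_assignment")
}

test_that("flat and constructed leaflets give the textbook depths", {
  # all beads at z = 4: depth 0
  coords <- cbind(stats::runif(50, 0, 10), stats::runif(50, 0, 10), 4)
  fr <- traj_frame(coords, c(10, 10, 10), 0)
  asg <- structure(list(bead_index = 0:49, leaflet = rep("upper", 50)),
                   class = "leaflet_assignment")
  d <- frame_depth(fr, asg, "upper")
  expect_equal(d$depth_nm, 0)

  # 90 beads at 0, 10 descending to -6: surface 0, bottom -6
  z <- c(rep(0, 90), seq(-0.6, -6, length.out = 10))
  fr2 <- traj_frame(cbind(stats::runif(100, 0, 10),
                          stats::runif(100, 0, 10), z),
                    c(10, 10, 20), 0)
  asg2 <- structure(list(bead_index = 0:99,
                         leaflet = rep("lower", 100)),
                    class = "leaflet_assignment")
  d2 <- frame_depth(fr2, asg2, "lower")
  expect_equal(d2$surface_z_nm, 0)
  expect_equal(d2$bottom_z_nm, -6)
  expect_equal(d2$depth_nm, 6)
})

test_that("frame_depth equals the sort/slice/mean/min oracle", {
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(20:200, 1)
    z <- stats::rnorm(n, sd = 2)
    fr <- traj_frame(cbind(stats::runif(n), stats::runif(n), z),
                     c(5, 5, 30), 0)
    asg <- structure(list(bead_index = 0:(n - 1L),
                          leaflet = rep("upper", n)),
                     class = "leaflet_assignment")
    p <- sample(c(80, 90, 95), 1)
    expect_equal(frame_depth(fr, asg, "upper", p)$depth_nm,
                 brute_depth(z, p))
  }
})

test_that("synthetic dome depth lands within the noise bound of D", {
  sys <- make_dome_trajectory(dome_spec(
    box = c(30, 30, 22), lattice_spacing = 1, depth_D = 6,
    width_sigma = 3, noise_sigma_z = 0.1, seed = 51))
  asg <- truth_assignment(sys)
  d <- frame_depth(sys$trajectory$frames[[1]], asg, "lower")
  expect_gt(d$depth_nm, 6 - 0.3)
  expect_lt(d$depth_nm, 6 + 0.3)
})

test_that("depth is invariant under rigid translation and z-rotation", {
  sys <- make_dome_trajectory(dome_spec(box = c(16, 16, 18),
                                        depth_D = 3, width_sigma = 3,
                                        seed = 52))
  fr <- sys$trajectory$frames[[1]]
  asg <- truth_assignment(sys)
  d0 <- frame_depth(fr, asg, "lower")$depth_nm
  shifted <- traj_frame(sweep(fr$coords, 2, c(1, -2, 3), "+"),
                        fr$box, 0)
  expect_equal(frame_depth(shifted, asg, "lower")$depth_nm, d0,
               tolerance = 1e-6)
  th <- 0.7
  rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  rotated <- traj_frame(fr$coords %*% t(rz), fr$box, 0)
  expect_equal(frame_depth(rotated, asg, "lower")$depth_nm, d0,
               tolerance = 1e-6)
})

test_that("depth grows monotonically with the generator depth D", {
  depths <- vapply(c(1, 2, 4, 6), function(D) {
    sys <- make_dome_trajectory(dome_spec(
      box = c(30, 30, 22), lattice_spacing = 1, depth_D = D,
      width_sigma = max(2.5, 0.8 * D), seed = 53))
    frame_depth(sys$trajectory$frames[[1]], truth_assignment(sys),
                "lower")$depth_nm
  }, numeric(1))
  expect_true(all(diff(depths) > 0))
})

test_that("time-constant domes reproduce frame 0 and honour exclusion", {
  sys <- make_dome_trajectory(dome_spec(box = c(16, 16, 18),
                                        depth_D = 3, width_sigma = 3,
                                        n_frames = 10, seed = 54))
  asg <- truth_assignment(sys)
  dep <- depth_series(sys$trajectory, asg, exclude_first_ns = 5)
  expect_equal(nrow(dep), 5 * 2)  # 5 retained frames x 2 leaflets
  d0 <- frame_depth(sys$trajectory$frames[[1]], asg, "lower")$depth_nm
  expect_true(all(dep$depth_nm[dep$leaflet == "lower"] == d0))
  expect_error(depth_series(sys$trajectory, asg,
                            exclude_first_ns = 100), "exclusion")
})

test_that("pooled depth summaries match hand arithmetic", {
  mk <- function(depths) {
    data.frame(frame_time_ns = seq_along(depths), leaflet = "lower",
               surface_z_nm = 0, bottom_z_nm = -depths,
               depth_nm = depths)
  }
  s <- aggregate_depth(mk(c(6, 6, 6)))
  expect_equal(s$mean_depth_nm, 6)
  expect_equal(s$sem_nm, 0)
  s2 <- aggregate_depth(mk(c(5, 7)))
  expect_equal(s2$mean_depth_nm, 6)
  expect_equal(s2$sem_nm, 1)
  pooled <- aggregate_depth(list(mk(c(5, 7)), mk(6)))
  expect_equal(pooled$n_used, 3)
  expect_error(aggregate_depth(list()), "no depth")
})

test_that("three seeded runs recover D within 3 SEM of the noise-corrected
          expectation", {
  # the depth estimator mixes a tail mean and a minimum, so its
  # distribution is right-skewed; a 3-SEM mean comparison needs a
  # sample large enough for the CLT to hold
  runs <- lapply(1:5, function(seed) {
    sys <- make_dome_trajectory(dome_spec(
      box = c(30, 30, 22), lattice_spacing = 1, depth_D = 4,
      width_sigma = 3, noise_sigma_z = 0.1, n_frames = 30, seed = seed))
    depth_series(sys$trajectory, truth_assignment(sys),
                 exclude_first_ns = 0, leaflets = "lower")
  })
  summ <- aggregate_depth(runs)
  expect_lt(abs(summ$mean_depth_nm - 4), 0.3)
  # noise-corrected expectation from the Monte-Carlo oracle on the
  # noise-free base z of the lower leaflet
  sys0 <- make_dome_trajectory(dome_spec(
    box = c(30, 30, 22), lattice_spacing = 1, depth_D = 4,
    width_sigma = 3, seed = 1))
  base_z <- sys0$truth$lipids$base_z[sys0$truth$lipids$leaflet == "lower"]
  set.seed(99)
  mc <- mc_expected_depth(base_z, 0.1, n_mc = 500)
  tol <- 3 * sqrt(summ$sem_nm^2 + mc$sem^2)
  expect_lt(abs(summ$mean_depth_nm - mc$mean), tol)
})

test_that("height maps reproduce flat fields and single beads", {
  coords <- cbind(stats::runif(200, 0, 10), stats::runif(200, 0, 10), 4)
  fr <- traj_frame(coords, c(10, 10, 10), 0)
  top <- toy_topology(200)
  asg <- structure(list(bead_index = 0:199,
                        leaflet = rep("upper", 200)),
                   class = "leaflet_assignment")
  hm <- height_map(trajectory(top, list(fr)), asg, "upper", bins = 10)
  expect_true(all(hm$mean_z[!is.na(hm$mean_z)] == 4))

  fr1 <- traj_frame(matrix(c(2.5, 7.5, 3.2), 1), c(10, 10, 10), 0)
  asg1 <- structure(list(bead_index = 0L, leaflet = "upper"),
                    class = "leaflet_assignment")
  hm1 <- height_map(trajectory(toy_topology(1), list(fr1)), asg1,
                    "upper", bins = 10)
  occ <- which(!is.na(hm1$mean_z), arr.ind = TRUE)
  expect_equal(nrow(occ), 1)
  expect_equal(unname(occ[1, ]), c(3, 8))  # bin of (2.5, 7.5)
  expect_equal(hm1$mean_z[occ], 3.2)
})

test_that("the count-weighted height-map average equals the mean z", {
  sys <- make_dome_trajectory(dome_spec(box = c(16, 16, 18),
                                        depth_D = 3, width_sigma = 3,
                                        seed = 55))
  asg <- truth_assignment(sys)
  hm <- height_map(sys$trajectory, asg, "lower", bins = 20)
  lower <- asg$bead_index[asg$leaflet == "lower"]
  xy <- sys$trajectory$frames[[1]]$coords[lower + 1L, ]
  ix <- pmin(20, pmax(1, floor(xy[, 1] / 16 * 20) + 1))
  iy <- pmin(20, pmax(1, floor(xy[, 2] / 16 * 20) + 1))
  w <- table(factor((iy - 1) * 20 + ix, levels = 1:400))
  wavg <- sum(hm$mean_z[as.integer(names(w))] * as.integer(w),
              na.rm = TRUE) / sum(w)
  expect_equal(wavg, mean(xy[, 3]), tolerance = 1e-9)
})

test_that("a trilobed dome produces exactly three angular minima", {
  sys <- make_dome_trajectory(dome_spec(
    box = c(24, 24, 16), depth_D = 3, width_sigma = 3.5,
    lobe_amplitude = 0.4, lobe_count = 3, seed = 56))
  hm <- height_map(sys$trajectory, truth_assignment(sys), "lower",
                   bins = 75)
  expect_equal(angular_minima(hm, n_sectors = 24, r_range = c(1.5, 7)),
               3L, ignore_attr = TRUE)
})
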