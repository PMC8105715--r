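# Structure/trajectory I/O and bead selection.

write_lines <- function(lines) {
  f <- tempfile(fileext = ".gro")
  writeLines(lines, f)
  f
}

test_that("a small GRO file is transcribed field by field", {
  f <- write_lines(c(
    "toy bilayer t= 2.5",
    "    3",
    "    1POPC  PO4    1   1.000   2.000   3.000",
    "    2POPC  PO4    2   4.000   5.000   6.000",
    "    3CHOL  ROH    3   7.000   8.000   9.500",
    "  10.00000  10.00000  10.00000"))
  st <- read_structure(f)
  expect_equal(st$topology$n_beads, 3)
  expect_equal(st$frame$box, c(10, 10, 10))
  expect_equal(st$frame$time_ns, 2.5)
  expect_equal(st$frame$coords[2, ], c(4, 5, 6))
  expect_equal(st$topology$beads$species, c("POPC", "POPC", "CHOL"))
  expect_true(all(st$topology$beads$is_headgroup))
  expect_equal(st$topology$beads$molecule_id, 1:3)
})

test_that("PDB coordinates are converted from Angstrom to nm", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1  100.000  100.000  100.000  90.00  90.00  90.00 P 1         1",
    paste0("ATOM      1  BB  ALA A   1      15.000  20.000  30.000",
           "  1.00  0.00"),
    paste0("ATOM      2  BB  ALA A   2      18.000  20.000  30.000",
           "  1.00  0.00"),
    "END"), f)
  st <- read_structure(f)
  expect_equal(st$frame$coords[1, 1], 1.5)
  expect_equal(st$frame$box, c(10, 10, 10))
  expect_equal(st$topology$beads$category, rep("protein", 2))
  expect_equal(st$topology$beads$chain_id, c("A", "A"))
})

test_that("malformed records and degenerate files fail loudly", {
  empty <- tempfile(fileext = ".gro")
  file.create(empty)
  expect_error(read_structure(empty), "empty")
  bad <- write_lines(c("t", "    1",
                       "    1POPC  PO4    1   1.000   xxx   3.000",
                       "  10.0  10.0  10.0"))
  expect_error(read_structure(bad), "line 3")
  expect_error(read_trajectory(empty, toy_topology(2)), "empty")
  expect_error(read_structure(tempfile(fileext = ".xtc")), "not found")
  xtc <- tempfile(fileext = ".xtc")
  file.create(xtc)
  expect_error(read_structure(xtc), "XTC/TRR")
})

test_that("unknown residues are solvent unless strict mode is on", {
  f <- write_lines(c("t", "    1",
                     "    1XYZQ  QQ1    1   1.000   1.000   1.000",
                     "  10.0  10.0  10.0"))
  st <- read_structure(f)
  expect_equal(st$topology$beads$category, "solvent")
  expect_error(read_structure(f, strict = TRUE), "XYZQ")
})

test_that("write/read round trip preserves coordinates and topology", {
  sys <- make_dome_trajectory(dome_spec(
    box = c(12, 12, 16), depth_D = 0, n_frames = 3,
    noise_sigma_xy = 0.05, noise_sigma_z = 0.05, seed = 42,
    tail_beads = 2L))
  f <- tempfile(fileext = ".gro")
  write_gro(sys$trajectory, f)
  top2 <- read_structure(f)$topology
  traj2 <- read_trajectory(f, top2)
  expect_equal(length(traj2$frames), 3)
  expect_equal(frame_times(traj2), frame_times(sys$trajectory))
  # GRO stores 3 decimals, so the round trip is exact to 5e-4 nm
  for (i in 1:3) {
    expect_lt(max(abs(traj2$frames[[i]]$coords -
                        sys$trajectory$frames[[i]]$coords)), 5.01e-4)
  }
  b1 <- sys$trajectory$topology$beads
  b2 <- top2$beads
  expect_equal(b2$category, b1$category)
  expect_equal(b2$species, b1$species)
  expect_equal(b2$is_headgroup, b1$is_headgroup)
  expect_equal(b2$chain_id, b1$chain_id)
  expect_equal(b2$residue_number, b1$residue_number)
})

test_that("a 2-frame multi-GRO without time stamps gets times 0 and 1", {
  block <- c("frame", "    1",
             "    1POPC  PO4    1   1.000   2.000   3.000",
             "  10.0  10.0  10.0")
  f <- write_lines(c(block, block))
  traj <- read_trajectory(f, toy_topology(1))
  expect_equal(frame_times(traj), c(0, 1))
})

test_that("trajectory frames must match the topology bead count", {
  block <- c("frame t= 0", "    2",
             "    1POPC  PO4    1   1.000   2.000   3.000",
             "    2POPC  PO4    2   2.000   2.000   3.000",
             "  10.0  10.0  10.0")
  f <- write_lines(block)
  expect_error(read_trajectory(f, toy_topology(3)), "frame 1")
})

test_that("select_beads filters match a linear-scan oracle", {
  top <- toy_topology(4)
  expect_equal(select_beads(top, category = "lipid",
                            headgroup_only = TRUE), 0:3)

  # 3 chains x 2547 residues, 1 bead each: the pore interval is closed
  chains <- stats::setNames(rep(2547L, 3), c("A", "B", "C"))
  top3 <- toy_topology(0, chains = chains)
  sel <- select_beads(top3, residue_range = c(2105, 2547))
  expect_length(sel, 3 * 443)

  # brute-force filter oracle on a mixed topology
  sys <- make_dome_trajectory(dome_spec(box = c(10, 10, 16),
                                        depth_D = 0, seed = 3))
  b <- sys$trajectory$topology$beads
  for (q in list(list(category = "lipid", headgroup_only = TRUE),
                 list(species = "CHOL"),
                 list(category = "protein", residue_range = c(2, 5)),
                 list(chain = "B"))) {
    got <- do.call(select_beads, c(list(sys$trajectory$topology), q))
    keep <- rep(TRUE, nrow(b))
    if (!is.null(q$category)) keep <- keep & b$category == q$category
    if (!is.null(q$species)) keep <- keep & b$species == q$species
    if (isTRUE(q$headgroup_only)) keep <- keep & b$is_headgroup
    if (!is.null(q$chain)) keep <- keep & b$chain_id == q$chain
    if (!is.null(q$residue_range)) {
      keep <- keep & !is.na(b$residue_number) &
        b$residue_number >= q$residue_range[1] &
        b$residue_number <= q$residue_range[2]
    }
    expect_equal(got, sort(b$bead_index[keep]))
  }
  expect_error(select_beads(top, species = "NOPE"), "empty")
})

test_that("selections are stable under bead-order permutation", {
  sys <- make_dome_trajectory(dome_spec(box = c(8, 8, 16), depth_D = 0,
                                        seed = 5))
  top <- sys$trajectory$topology
  set.seed(1)
  perm <- sample.int(top$n_beads)
  b <- top$beads[perm, ]
  b$bead_index <- 0:(top$n_beads - 1L)
  top_p <- topology(b)
  sel <- select_beads(top, species = "POPC", headgroup_only = TRUE)
  sel_p <- select_beads(top_p, species = "POPC", headgroup_only = TRUE)
  # after mapping permuted indices back, the same beads are selected
  expect_setequal(perm[sel_p + 1L] - 1L, sel)
})
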