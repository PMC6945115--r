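# axial traces, permeation state machine, selectivity, wetting, densities

cyl10 <- pore_cylinder(r_cyl = 5, z_lo = -10, z_hi = 10)

test_that("single monotone traversal counts one event", {
  tr <- make_traces(seq(-20, 20, by = 2), cylinder = cyl10)
  rec <- count_permeations(tr)
  expect_equal(unname(rec$counts[["CL"]]), 1)
  expect_equal(rec$events$direction, 1)
  tr_dn <- make_traces(seq(20, -20, by = -2), cylinder = cyl10)
  expect_equal(count_permeations(tr_dn)$events$direction, -1)
})

test_that("incomplete traversals and re-entries count nothing", {
  # enters from below, returns below
  bounce <- c(seq(-20, 0, by = 2), seq(0, -20, by = -2))
  expect_equal(sum(count_permeations(make_traces(bounce,
                                                 cylinder = cyl10))$counts),
               0)
  # repeated bouncing
  wob <- rep(c(-15, -5, 0, -5, -15), 4)
  expect_equal(sum(count_permeations(make_traces(wob,
                                                 cylinder = cyl10))$counts),
               0)
  # full traversal then bounce then full return: net 1 up + 1 down
  path <- c(seq(-20, 20, by = 4), c(15, 5, 15), seq(20, -20, by = -4))
  rec <- count_permeations(make_traces(path, cylinder = cyl10))
  expect_equal(nrow(rec$events), 2)
  expect_equal(sort(rec$events$direction), c(-1, 1))
})

test_that("leaving the cylinder mid-traversal voids the event", {
  s <- seq(-20, 20, by = 2)
  inside <- s >= -10 & s <= 10
  in_cyl <- rep(TRUE, length(s))
  in_cyl[which(inside)[3]] <- FALSE # one excursion while inside
  rec <- count_permeations(make_traces(s, in_cyl, cylinder = cyl10))
  expect_equal(sum(rec$counts), 0)
  # tolerance of 1 frame forgives it
  rec_tol <- count_permeations(make_traces(s, in_cyl, cylinder = cyl10),
                               tol_frames = 1)
  expect_equal(sum(rec_tol$counts), 1)
})

test_that("lateral masking follows the cylinder radius", {
  m <- build_toy_pentamer()
  cyl <- pore_cylinder(model = m)
  # particle on the axis: in cylinder at all frames
  nfr <- 5
  mk_traj <- function(lateral) {
    atoms <- data.frame(eleno = 1L, name = "CL", resid = "CL", resno = 1L,
                        chain = "X", elem = "CL", stringsAsFactors = FALSE)
    coords <- array(0, c(1, 3, nfr))
    coords[1, 1, ] <- m$axis$origin[1] + lateral
    coords[1, 2, ] <- m$axis$origin[2]
    coords[1, 3, ] <- seq(-20, 20, length.out = nfr)
    pore_trajectory(atoms, coords)
  }
  tr_axis <- axial_traces(mk_traj(0), 1L, m$axis, cyl)
  expect_true(all(tr_axis$in_cyl))
  # 6 A off axis: masked everywhere (r_cyl = 5)
  tr_off <- axial_traces(mk_traj(6), 1L, m$axis, cyl)
  expect_false(any(tr_off$in_cyl))
  expect_equal(tr_off$r_lat[1, ], rep(6, nfr), tolerance = 1e-9)
  expect_error(axial_traces(mk_traj(0), integer(0), m$axis, cyl), "empty")
})

test_that("periodic jumps are unwrapped to the hand-unwrapped path", {
  # particle drifts upward through a 100 A box; emitted wrapped
  true_z <- seq(-45, 45, by = 5)
  lz <- 100
  wrapped <- true_z %% lz # GROMACS convention [0, Lz)
  atoms <- data.frame(eleno = 1L, name = "CL", resid = "CL", resno = 1L,
                      chain = "X", elem = "CL", stringsAsFactors = FALSE)
  coords <- array(0, c(1, 3, length(true_z)))
  coords[1, 3, ] <- wrapped
  traj <- pore_trajectory(atoms, coords, box = c(80, 80, lz))
  tr <- axial_traces(traj, 1L, lab_z_axis(),
                     pore_cylinder(r_cyl = 5, z_lo = -10, z_hi = 10))
  # hand-unwrapped: anchor by minimum image, accumulate min-image deltas
  hand <- wrapped[1] - lz * round(wrapped[1] / lz)
  for (i in 2:length(wrapped)) {
    d <- wrapped[i] - wrapped[i - 1]
    d <- d - lz * round(d / lz)
    hand <- c(hand, hand[i - 1] + d)
  }
  expect_equal(tr$s[1, ], hand, tolerance = 1e-9)
  expect_equal(tr$s[1, ], true_z, tolerance = 1e-9)
  # and no spurious event miscount from the wrap
  expect_equal(sum(count_permeations(tr)$counts), 1)
})

test_that("event balance equals net compartment displacement", {
  # conservation against a brute-force re-scan on random walks
  for (seed in 1:20) {
    set.seed(seed)
    s <- cumsum(c(runif(1, -30, 30), rnorm(400, 0, 4)))
    rec <- count_permeations(make_traces(s, cylinder = cyl10))
    net <- sum(rec$events$direction)
    comp <- function(z) if (z < -10) -1L else if (z > 10) 1L else 0L
    nz <- vapply(s, comp, integer(1))
    nz <- nz[nz != 0L]
    if (length(nz) >= 2) {
      # brute recount: every sign change of the side sequence is an event
      expect_equal(nrow(rec$events), brute_count(s, -10, 10))
      expect_equal(net, (tail(nz, 1) - nz[1]) / 2)
    }
  }
})

test_that("counts are invariant to stride refinement on monotone paths", {
  fine <- seq(-20, 20, length.out = 161)
  for (stride in c(1, 2, 5, 10, 40)) {
    s <- fine[seq(1, length(fine), by = stride)]
    if (length(s) < 2) next
    rec <- count_permeations(make_traces(s, cylinder = cyl10))
    expect_equal(sum(rec$counts), 1)
  }
})

test_that("selectivity ratio handles the degenerate cases", {
  expect_equal(selectivity_ratio(52, 1)$ratio, 52)
  r0 <- selectivity_ratio(49, 0)
  expect_true(is.infinite(r0$ratio))
  expect_equal(r0$flag, "no_cation_events")
  expect_equal(r0$cl, 49)
  und <- selectivity_ratio(0, 0)
  expect_true(is.nan(und$ratio))
  expect_equal(und$flag, "undefined")
  expect_error(selectivity_ratio(-1, 2), "non-negative")
})

test_that("wetting analysis reports occupancy and dewetted stretches", {
  m <- build_toy_pentamer()
  # water-filled pore: 100% wetted
  fx <- build_trajectory(trajectory_spec(traversals = c(CL = 0),
                                         distractors = c(CL = 0),
                                         n_frames = 10, water_fill = 60),
                         m)
  tr <- axial_traces(fx$traj, select_atoms(fx$traj, resid = "SOL"),
                     m$axis, fx$cylinder)
  wet <- wetting_analysis(tr, bin_width = 1)
  expect_equal(wet$fraction_fully_wetted, 1)
  expect_equal(nrow(wet$stretches), 0)
  # water excluded from |s| < 3: dewetted band exactly there
  fx2 <- build_trajectory(trajectory_spec(traversals = c(CL = 0),
                                          distractors = c(CL = 0),
                                          n_frames = 4, water_fill = 120,
                                          water_exclude = c(-3, 3)),
                          m)
  tr2 <- axial_traces(fx2$traj, select_atoms(fx2$traj, resid = "SOL"),
                      m$axis, fx2$cylinder)
  wet2 <- wetting_analysis(tr2, bin_width = 1)
  expect_equal(wet2$fraction_fully_wetted, 0)
  expect_true(all(wet2$stretches$s_lo >= -4 & wet2$stretches$s_hi <= 4))
  expect_true(all(table(wet2$stretches$frame) == 1)) # one band per frame
  # bins outside the band are wetted
  mid <- wet2$bin_edges[-length(wet2$bin_edges)] + 0.5
  outside <- mid < -4 | mid > 4
  expect_false(any(wet2$dewetted[outside, ]))
  expect_error(wetting_analysis(tr2, bin_width = 0), "positive")
})

test_that("empty water selection leaves every bin dewetted", {
  s <- matrix(100, 1, 3) # single particle far outside
  tr <- make_traces(s, cylinder = cyl10)
  wet <- wetting_analysis(tr, bin_width = 2)
  expect_true(all(wet$dewetted))
  expect_equal(wet$fraction_fully_wetted, 0)
})

test_that("density grids integrate to the mean particle count", {
  atoms <- data.frame(eleno = 1:2, name = "CL", resid = "CL", resno = 1:2,
                      chain = "X", elem = "CL", stringsAsFactors = FALSE)
  # one static particle, one voxel of 10 A = 1 nm^3 -> density 1.0
  coords <- array(0, c(2, 3, 3))
  coords[1, , ] <- 5 # center of the single voxel
  coords[2, , ] <- 200 # outside the grid
  traj <- pore_trajectory(atoms, coords)
  g <- density_grid(traj, 1:2, voxel = 10, origin = c(0, 0, 0),
                    n = c(1, 1, 1))
  expect_equal(as.numeric(g$density), 1.0)
  expect_equal(grid_particle_count(g), 1.0)
  # doubling frames with identical coordinates changes nothing
  traj2 <- pore_trajectory(atoms, array(coords[, , c(1, 2, 3, 1, 2, 3)],
                                        c(2, 3, 6)))
  g2 <- density_grid(traj2, 1:2, voxel = 10, origin = c(0, 0, 0),
                     n = c(1, 1, 1))
  expect_equal(g2$density, g$density)
  # empty selection with explicit grid: all zero
  g0 <- density_grid(traj, integer(0), voxel = 5, origin = c(0, 0, 0),
                     n = c(2, 2, 2))
  expect_true(all(g0$density == 0))
  expect_error(density_grid(traj, 1:2, voxel = 0), "positive")
})

test_that("density integration holds for scattered particles", {
  set.seed(11)
  n <- 40
  nfr <- 6
  atoms <- data.frame(eleno = 1:n, name = "OW", resid = "SOL", resno = 1:n,
                      chain = "X", elem = "O", stringsAsFactors = FALSE)
  coords <- array(runif(n * 3 * nfr, 0, 30), c(n, 3, nfr))
  traj <- pore_trajectory(atoms, coords)
  g <- density_grid(traj, 1:n, voxel = 2, origin = c(0, 0, 0),
                    n = c(15, 15, 15))
  expect_equal(grid_particle_count(g), n, tolerance = 1e-9)
  # isosurface utility: voxels above threshold have at least it
  iso <- isosurface_voxels(g, threshold = 0.5)
  if (nrow(iso) > 0) expect_true(all(iso$density >= 0.5))
})

test_that("OpenDX export is well-formed and complete", {
  atoms <- data.frame(eleno = 1L, name = "CL", resid = "CL", resno = 1L,
                      chain = "X", elem = "CL", stringsAsFactors = FALSE)
  coords <- array(2, c(1, 3, 1))
  traj <- pore_trajectory(atoms, coords)
  g <- density_grid(traj, 1L, voxel = 2, origin = c(0, 0, 0), n = c(3, 4, 5))
  dx <- withr::local_tempfile(fileext = ".dx")
  write_opendx(g, dx)
  lines <- readLines(dx)
  expect_true(any(grepl("gridpositions counts 3 4 5", lines)))
  expect_true(any(grepl("items 60 data follows", lines)))
  vals <- suppressWarnings(as.numeric(unlist(strsplit(
    lines[grep("data follows", lines) + seq_len(20)], " "))))
  expect_equal(sum(vals, na.rm = TRUE) * (0.2^3), 1, tolerance = 1e-6)
})
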