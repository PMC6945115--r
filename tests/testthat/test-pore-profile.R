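# HOLE-style radius profiles and hydrophobicity profiles

test_that("ring fixtures match the analytic annulus oracle", {
  # dense ring limit: atoms of vdW 1.5 on a circle of radius 5 -> pore
  # radius 3.5 at ring height
  for (n in c(12, 24)) {
    xyz <- ring_xyz(n, radius = 5)
    p <- pore_radius_profile(xyz, lab_z_axis(), s_grid = 0, vdw = 1.5)
    expect_equal(p$radius, 5 - 1.5, tolerance = 0.1)
  }
  # collapsed pore: ring radius 2.5, vdW 1.5 -> radius ~ 1.0
  xyz <- ring_xyz(24, radius = 2.5)
  p <- pore_radius_profile(xyz, lab_z_axis(), s_grid = 0, vdw = 1.5)
  expect_equal(p$radius, 1.0, tolerance = 0.1)
})

test_that("optimized center search matches the brute-force grid oracle", {
  # stacked off-axis rings make the optimum nontrivial
  xyz <- rbind(ring_xyz(14, 5.2, height = -1.5, phase = 0.2),
               ring_xyz(14, 4.4, height = 0),
               ring_xyz(14, 5.0, height = 1.5, phase = 0.4))
  xyz[, 1] <- xyz[, 1] + 0.7 # shift the pore off the nominal axis
  vdw <- rep(1.6, nrow(xyz))
  for (s in c(-1, 0, 1)) {
    got <- pore_radius_profile(xyz, lab_z_axis(), s_grid = s,
                               vdw = 1.6)$radius
    want <- brute_radius(xyz, vdw, s)
    expect_equal(got, want, tolerance = 0.05)
    expect_gte(got, want - 1e-6) # optimizer at least as good as the grid
  }
})

test_that("slices without atoms in range report the cap", {
  xyz <- ring_xyz(12, 5, height = 0)
  p <- pore_radius_profile(xyz, lab_z_axis(), s_grid = c(-35, 35),
                           vdw = 1.5, cap = 10)
  expect_equal(p$radius, c(10, 10))
  expect_error(pore_radius_profile(xyz[0, , drop = FALSE], lab_z_axis(),
                                   s_grid = 0, vdw = 1.5), "empty")
})

test_that("radius never goes negative on steric overlap", {
  xyz <- ring_xyz(24, 1.0) # vdW 1.5 overlaps the axis entirely
  p <- pore_radius_profile(xyz, lab_z_axis(), s_grid = 0, vdw = 1.5)
  expect_equal(p$radius, 0)
})

test_that("radius profile is rigid-motion invariant", {
  m <- build_toy_pentamer()
  grid <- seq(-4, 4, by = 2)
  p_ref <- model_radius_profile(m, s_grid = grid)
  rt <- random_rigid(7)
  mt <- compute_axis(transform_model(m, rt))
  p_rot <- model_radius_profile(mt, s_grid = grid)
  expect_equal(p_rot$radius, p_ref$radius, tolerance = 1e-4)
})

test_that("shrinking all vdW radii by delta widens the pore by delta", {
  xyz <- rbind(ring_xyz(16, 5, height = -1), ring_xyz(16, 4.6, height = 0),
               ring_xyz(16, 5, height = 1))
  delta <- 0.3
  for (s in c(0, 1)) {
    r1 <- pore_radius_profile(xyz, lab_z_axis(), s_grid = s,
                              vdw = 1.7)$radius
    r2 <- pore_radius_profile(xyz, lab_z_axis(), s_grid = s,
                              vdw = 1.7 - delta)$radius
    expect_equal(r2 - r1, delta, tolerance = 1e-3)
    # against the independent grid oracle
    expect_equal(r2, brute_radius(xyz, rep(1.7 - delta, nrow(xyz)), s),
                 tolerance = 0.05)
  }
})

test_that("hydrophobicity of a Leu-lined pore is constant at Leu's value", {
  m <- build_toy_pentamer(toy_pore_spec(residues = "LEU"))
  grid <- seq(-6, 6, by = 2)
  rp <- model_radius_profile(m, s_grid = grid)
  h <- hydrophobicity_profile(m$atoms, m$axis, rp)
  expect_true(all(abs(h$hydrophobicity - ww_scale()[["LEU"]]) < 1e-9))
})

test_that("scale endpoints map to +1 and -1", {
  sc <- ww_scale()
  expect_equal(sc[["TRP"]], 1) # most hydrophobic
  expect_equal(sc[["GLU"]], -1) # most hydrophilic
  expect_true(all(sc >= -1 & sc <= 1))
  m <- build_toy_pentamer(toy_pore_spec(residues = "TRP"))
  rp <- model_radius_profile(m, s_grid = 0)
  h <- hydrophobicity_profile(m$atoms, m$axis, rp)
  expect_equal(h$hydrophobicity, 1)
})

test_that("alternating Leu/Ser ring averages to the hand-computed mean", {
  # one ring of 10 single-atom residues alternating LEU/SER: all atoms are
  # equidistant from the pore surface and share s = 0, so every Gaussian
  # weight is equal and the profile is the plain arithmetic mean
  xyz <- ring_xyz(10, radius = 5)
  atoms <- data.frame(
    eleno = 1:10, name = "CB",
    resid = rep(c("LEU", "SER"), 5), resno = 1:10, chain = "A",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], elem = "C",
    stringsAsFactors = FALSE
  )
  rp <- pore_radius_profile(xyz, lab_z_axis(), s_grid = 0, vdw = 1.7)
  h <- hydrophobicity_profile(atoms, lab_z_axis(), rp)
  hand <- mean(ww_scale()[c("LEU", "SER")]) # hand-weighted average oracle
  expect_equal(h$hydrophobicity, hand, tolerance = 1e-9)
})

test_that("unknown residues are reported by name", {
  m <- build_toy_pentamer()
  m$atoms$resid[1] <- "XYZ"
  rp <- model_radius_profile(m, s_grid = 0)
  expect_error(hydrophobicity_profile(m$atoms, m$axis, rp), "XYZ")
})

test_that("profile statistics: mean, sd, subsampling", {
  s <- seq(-2, 2, by = 1)
  mk <- function(r) {
    p <- data.frame(s = s, radius = r, cx = 0, cy = 0, cz = s)
    class(p) <- c("pore_profile", "data.frame")
    p
  }
  # identical frames -> sd 0
  st <- profile_statistics(list(mk(rep(3, 5)), mk(rep(3, 5))))
  expect_equal(st$sd, rep(0, 5))
  # two frames r and r + 2 -> mean r + 1, sd sqrt(2)
  st2 <- profile_statistics(list(mk(rep(3, 5)), mk(rep(5, 5))))
  expect_equal(st2$mean, rep(4, 5))
  expect_equal(st2$sd, rep(sqrt(2), 5))
  # 3 of 30 frames requested -> every 10th centre thereabouts; count drops
  profs <- lapply(1:30, function(i) mk(rep(i, 5)))
  st3 <- profile_statistics(profs, n_points = 3)
  expect_equal(attr(st3, "n_frames"), 3)
  expect_equal(st3$mean, rep(mean(c(1, 15.5, 30)), 5), tolerance = 0.5)
  # mismatched grids error
  bad <- mk(rep(3, 5))
  bad$s <- bad$s + 0.1
  expect_error(profile_statistics(list(mk(rep(3, 5)), bad)), "grid")
  expect_error(profile_statistics(list(mk(rep(3, 5)))), "2 frames")
})

test_that("gate geometry classification follows the dehydration heuristic", {
  s <- seq(-20, 10, by = 0.5)
  mkstat <- function(r9) {
    r <- rep(8, length(s))
    r[abs(s) <= 2] <- r9
    r[abs(s + 16) <= 2] <- 5
    st <- data.frame(s = s, mean = r, sd = 0)
    class(st) <- c("profile_statistics", "data.frame")
    st
  }
  hyd_pos <- data.frame(s = s, hydrophobicity = rep(0.6, length(s)))
  hyd_neg <- data.frame(s = s, hydrophobicity = rep(-0.4, length(s)))
  # wide pore: no flag
  wide <- classify_gate_geometry(mkstat(6), hyd_pos)
  expect_false(wide$hydrophobic_gating_risk)
  expect_equal(wide$r_min_9, 6)
  # narrow hydrophobic: flag
  narrow <- classify_gate_geometry(mkstat(2), hyd_pos)
  expect_true(narrow$hydrophobic_gating_risk)
  # narrow hydrophilic: no flag
  hydroph <- classify_gate_geometry(mkstat(2), hyd_neg)
  expect_false(hydroph$hydrophobic_gating_risk)
  # window outside the grid errors
  expect_error(classify_gate_geometry(mkstat(6), hyd_pos,
                                      s_gate_minus2 = -80), "window")
})
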