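# Synthetic fixtures: idealized 5-fold-symmetric pores and scripted
# particle trajectories with known ground truth. No physics — only the
# geometric and statistical structure the analyses need.

#' Specification of an idealized pentameric pore
#'
#' @param ring_radii Named numeric vector, primed position -> C-alpha ring
#'   radius (Angstrom). Radii at intermediate residues are linearly
#'   interpolated.
#' @param rise Helix rise per residue along the axis (Angstrom).
#' @param m2_start Residue number of the -2' position (250 gives the human
#'   alpha-1 GlyR convention 9' = 261).
#' @param residues Named character vector, primed position -> residue name
#'   at that ring; a single unnamed name is used everywhere; unspecified
#'   residues default to `fill`.
#' @param fill Residue name for non-anchor positions.
#' @param wall_atoms Extra carbon atoms per residue spread over the
#'   subunit's angular sector so the wall is sterically tight (0 gives a
#'   sparse 5-atom ring).
#' @param box Box vector (Angstrom).
#' @param seed RNG seed (determinism of any jittered variant).
#' @return List of class `toy_pore_spec`.
#' @export
toy_pore_spec <- function(ring_radii = c("-2" = 6, "2" = 6, "6" = 5.5,
                                         "9" = 5.5, "13" = 6, "16" = 7,
                                         "20" = 8),
                          rise = 1.5, m2_start = 250L,
                          residues = c("-2" = "PRO", "2" = "ALA",
                                       "6" = "THR", "9" = "LEU",
                                       "13" = "VAL", "16" = "SER",
                                       "20" = "ALA"),
                          fill = "ALA", wall_atoms = 4, box = c(80, 80, 100),
                          seed = 42L) {
  if (any(ring_radii <= 0)) {
    stop("ring radii must be positive")
  }
  if (length(residues) == 1 && is.null(names(residues))) {
    residues <- setNames(rep(residues, length(ring_radii)),
                         names(ring_radii))
    fill <- residues[[1]]
  }
  structure(
    list(ring_radii = ring_radii, rise = rise, m2_start = as.integer(m2_start),
         residues = residues, fill = fill, wall_atoms = wall_atoms,
         box = box, seed = as.integer(seed)),
    class = "toy_pore_spec"
  )
}

#' Build an idealized 5-fold-symmetric pentameric pore
#'
#' Five straight "M2 helices" arranged with exact 5-fold symmetry around
#' the lab z axis. Each residue contributes a C-alpha at the (interpolated)
#' ring radius, a side-chain centroid pseudo-atom `CB` pointing into the
#' pore, and `wall_atoms` extra carbons at the ring radius spread over the
#' subunit's 72 degree sector, making the pore wall sterically tight. The
#' 9' ring sits at z = 0; primed position p maps to residue
#' `m2_start + p + 2`.
#'
#' @param spec A `toy_pore_spec`.
#' @return An annotated `channel_model` (primed positions assigned, axis
#'   computed; axis = lab z by construction).
#' @export
build_toy_pentamer <- function(spec = toy_pore_spec()) {
  pp <- as.integer(names(spec$ring_radii))
  ord <- order(pp)
  pp <- pp[ord]
  rr <- as.numeric(spec$ring_radii)[ord]
  p_all <- seq(min(pp), max(pp))
  r_all <- approx(pp, rr, xout = p_all)$y
  res_all <- rep(spec$fill, length(p_all))
  anchor <- match(as.integer(names(spec$residues)), p_all)
  res_all[anchor[!is.na(anchor)]] <- spec$residues[!is.na(anchor)]
  resno_all <- spec$m2_start + p_all + 2L
  resno9 <- spec$m2_start + 9L + 2L
  rows <- list()
  eleno <- 0L
  for (k in 0:4) {
    base_ang <- 2 * pi * k / 5
    for (i in seq_along(p_all)) {
      z <- (resno_all[i] - resno9) * spec$rise
      r <- r_all[i]
      add <- function(name, radius, ang, elem = "C") {
        eleno <<- eleno + 1L
        rows[[length(rows) + 1L]] <<- data.frame(
          eleno = eleno, name = name, resid = res_all[i],
          resno = resno_all[i], chain = LETTERS[k + 1],
          x = radius * cos(ang), y = radius * sin(ang), z = z,
          elem = elem, stringsAsFactors = FALSE
        )
      }
      add("CA", r, base_ang)
      add("CB", max(r - 1.4, 0.5), base_ang)
      if (spec$wall_atoms > 0) {
        # extra wall carbons named as backbone ("C") so they tighten the
        # pore wall without entering side-chain-based metrics
        for (j in seq_len(spec$wall_atoms)) {
          add("C", r, base_ang + 2 * pi / 5 * j / (spec$wall_atoms + 1))
        }
      }
    }
  }
  atoms <- do.call(rbind, rows)
  attr(atoms, "box") <- spec$box
  m <- channel_model(atoms)
  m <- assign_primed_positions(m, spec$m2_start, positions = pp)
  compute_axis(m, method = "ring_centroids")
}

#' Specification of a scripted fixture trajectory
#'
#' @param n_frames Number of frames.
#' @param traversals Named integer vector, species -> number of complete
#'   pore traversals to script (residue names `CL`, `NA`, `SOL`).
#' @param distractors Named integer vector, species -> number of particles
#'   that enter the pore but return without completing a traversal.
#' @param sweep_frames Frames a scripted traversal takes.
#' @param jitter Lateral jitter standard deviation (Angstrom).
#' @param water_fill Number of static water oxygens placed along the pore
#'   (0 = none); they wet every axial bin.
#' @param water_exclude Optional `c(lo, hi)` axial band (Angstrom) kept
#'   free of fill water — a scripted dewetted stretch.
#' @param wrap_z Emit z coordinates wrapped into the periodic box (exercises
#'   unwrapping).
#' @param dt Frame spacing label (ps).
#' @param seed RNG seed; the scripted event log is reproducible from it.
#' @return List of class `trajectory_spec`.
#' @export
trajectory_spec <- function(n_frames = 300, traversals = c(CL = 52, `NA` = 1),
                            distractors = c(CL = 5, `NA` = 5),
                            sweep_frames = 10, jitter = 0.8,
                            water_fill = 0, water_exclude = NULL,
                            wrap_z = FALSE, dt = 1000, seed = 42L) {
  if (any(traversals < 0)) {
    stop("traversal counts must be non-negative")
  }
  structure(
    list(n_frames = as.integer(n_frames), traversals = traversals,
         distractors = distractors, sweep_frames = as.integer(sweep_frames),
         jitter = jitter, water_fill = as.integer(water_fill),
         water_exclude = water_exclude, wrap_z = isTRUE(wrap_z), dt = dt,
         seed = as.integer(seed)),
    class = "trajectory_spec"
  )
}

# species -> (atom name, element) for the fixture roster
.species_atom <- function(sp) {
  switch(sp,
         CL = c("CL", "CL"),
         `NA` = c("NA", "NA"),
         SOL = c("OW", "O"),
         c(sp, "C"))
}

#' Build a scripted particle trajectory with known ground truth
#'
#' Each prescribed traversal is performed by a dedicated particle: it waits
#' in the bulk on one side of the pore, sweeps monotonically through the
#' cylinder (with lateral jitter, kept strictly inside the cylinder
#' radius), and parks on the far side. Direction is drawn at random per
#' traversal. Distractor particles enter the pore and turn back without
#' completing a traversal; fill water is static. The scripted event log is
#' returned as ground truth.
#'
#' @param tspec A `trajectory_spec`.
#' @param model Annotated `channel_model` defining axis and pore bounds
#'   (default: [build_toy_pentamer()]).
#' @param cylinder Optional `pore_cylinder`; defaults to the model's -2'
#'   and 20' ring centroids with a 5 A radius.
#' @return List: `traj` (a `pore_trajectory` of the particles only),
#'   `events` (ground-truth data frame: particle, species, direction,
#'   start_frame, end_frame), `cylinder`, `model`.
#' @export
build_trajectory <- function(tspec = trajectory_spec(),
                             model = build_toy_pentamer(),
                             cylinder = NULL) {
  if (is.null(cylinder)) {
    cylinder <- pore_cylinder(model = model)
  }
  set.seed(tspec$seed)
  nfr <- tspec$n_frames
  z_below <- cylinder$z_lo - 8
  z_above <- cylinder$z_hi + 8
  margin <- 0.5 # keep scripted particles strictly inside r_cyl
  r_max <- cylinder$r_cyl - margin
  particles <- list()
  frames_z <- list() # per particle z(t)
  frames_r <- list() # per particle lateral radius target
  events <- list()
  pid <- 0L
  add_particle <- function(sp, z_t) {
    pid <<- pid + 1L
    at <- .species_atom(sp)
    particles[[pid]] <<- data.frame(
      eleno = pid, name = at[1], resid = sp, resno = pid, chain = "X",
      elem = at[2], stringsAsFactors = FALSE
    )
    frames_z[[pid]] <<- z_t
    frames_r[[pid]] <<- runif(1, 0, max(r_max - tspec$jitter * 2.5, 0.1))
  }
  sweep_len <- max(tspec$sweep_frames, 4L)
  for (sp in names(tspec$traversals)) {
    nt <- tspec$traversals[[sp]]
    if (nt == 0) next
    for (i in seq_len(nt)) {
      dirn <- sample(c(1L, -1L), 1)
      start <- sample.int(max(nfr - sweep_len - 2L, 1L), 1)
      z_t <- rep(if (dirn > 0) z_below else z_above, nfr)
      ramp <- seq(z_below, z_above, length.out = sweep_len)
      if (dirn < 0) ramp <- rev(ramp)
      z_t[start:(start + sweep_len - 1L)] <- ramp
      if (start + sweep_len <= nfr) {
        z_t[(start + sweep_len):nfr] <- if (dirn > 0) z_above else z_below
      }
      add_particle(sp, z_t)
      events[[length(events) + 1L]] <- data.frame(
        particle = pid, species = sp, direction = dirn,
        start_frame = start - 1L, end_frame = start + sweep_len - 2L,
        stringsAsFactors = FALSE
      )
    }
  }
  for (sp in names(tspec$distractors)) {
    nd <- tspec$distractors[[sp]]
    if (nd == 0) next
    for (i in seq_len(nd)) {
      side <- sample(c(1L, -1L), 1)
      start <- sample.int(max(nfr - 2L * sweep_len - 2L, 1L), 1)
      z_home <- if (side < 0) z_below else z_above
      z_mid <- (cylinder$z_lo + cylinder$z_hi) / 2
      z_t <- rep(z_home, nfr)
      half <- seq(z_home, z_mid, length.out = sweep_len)
      path <- c(half, rev(half))
      idx <- seq(start, min(start + 2L * sweep_len - 1L, nfr))
      z_t[idx] <- path[seq_along(idx)]
      add_particle(sp, z_t)
    }
  }
  if (tspec$water_fill > 0) {
    zs <- seq(cylinder$z_lo - 2, cylinder$z_hi + 2,
              length.out = tspec$water_fill)
    if (!is.null(tspec$water_exclude)) {
      zs <- zs[zs < tspec$water_exclude[1] | zs > tspec$water_exclude[2]]
    }
    for (zw in zs) {
      add_particle("SOL", rep(zw, nfr))
    }
  }
  if (pid == 0L) {
    stop("trajectory spec produces no particles")
  }
  atoms <- do.call(rbind, particles)
  coords <- array(NA_real_, c(pid, 3, nfr))
  org <- model$axis$origin
  for (i in seq_len(pid)) {
    ang <- runif(1, 0, 2 * pi)
    r0 <- frames_r[[i]]
    rx <- r0 * cos(ang) + rnorm(nfr, 0, tspec$jitter)
    ry <- r0 * sin(ang) + rnorm(nfr, 0, tspec$jitter)
    rl <- sqrt(rx^2 + ry^2)
    over <- rl > r_max
    if (any(over)) { # clamp back inside the cylinder
      rx[over] <- rx[over] * r_max / rl[over]
      ry[over] <- ry[over] * r_max / rl[over]
    }
    coords[i, 1, ] <- org[1] + rx
    coords[i, 2, ] <- org[2] + ry
    coords[i, 3, ] <- org[3] + frames_z[[i]]
  }
  box <- attr(model$atoms, "box")
  if (is.null(box)) box <- c(80, 80, 100)
  if (tspec$wrap_z) {
    # GROMACS-style wrapping into [0, Lz)
    coords[, 3, ] <- coords[, 3, ] %% box[3]
  }
  ev <- if (length(events) == 0) {
    data.frame(particle = integer(0), species = character(0),
               direction = integer(0), start_frame = integer(0),
               end_frame = integer(0))
  } else {
    do.call(rbind, events)
  }
  list(
    traj = pore_trajectory(atoms, coords, box = box, dt = tspec$dt),
    events = ev,
    cylinder = cylinder,
    model = model
  )
}

#' Write a fixture's ground-truth event log as JSON
#'
#' @param fixture Result of [build_trajectory()].
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(fixture, path) {
  counts <- table(fixture$events$species)
  jsonlite::write_json(
    list(
      counts = as.list(setNames(as.integer(counts), names(counts))),
      events = fixture$events
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
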