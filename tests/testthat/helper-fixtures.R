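# shared helpers for building tiny geometric fixtures in code

# n atoms on a circle of given radius in the z = height plane
ring_xyz <- function(n, radius, height = 0, phase = 0) {
  ang <- phase + 2 * pi * (seq_len(n) - 1) / n
  cbind(radius * cos(ang), radius * sin(ang), height)
}

lab_z_axis <- function() {
  list(origin = c(0, 0, 0), direction = c(0, 0, 1))
}

# brute-force pore radius oracle: exhaustive lattice search in the slice
# plane, independent of the package's optimizer
brute_radius <- function(xyz, vdw, s, lattice_step = 0.1, range = 8,
                         cap = 10) {
  g <- seq(-range, range, by = lattice_step)
  best <- -Inf
  for (a in g) {
    d2xy <- (xyz[, 1] - a)^2
    for (b in g) {
      if (a^2 + b^2 > range^2) next
      d <- sqrt(d2xy + (xyz[, 2] - b)^2 + (xyz[, 3] - s)^2) - vdw
      v <- min(d)
      if (v > best) best <- v
    }
  }
  min(max(best, 0), cap)
}

# random rigid-body transform (rotation + translation), seeded
random_rigid <- function(seed) {
  set.seed(seed)
  th <- runif(3, 0, 2 * pi)
  rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0),
              c(-sin(th[2]), 0, cos(th[2])))
  rz <- rbind(c(cos(th[3]), -sin(th[3]), 0),
              c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
  list(R = rx %*% ry %*% rz, t = runif(3, -20, 20))
}

apply_rigid <- function(xyz, rt) {
  sweep(xyz %*% t(rt$R), 2, -rt$t)
}

# apply a rigid transform to a channel_model's atoms (invalidates nothing:
# caller re-runs axis computation)
transform_model <- function(model, rt) {
  xyz <- apply_rigid(as.matrix(model$atoms[, c("x", "y", "z")]), rt)
  model$atoms$x <- xyz[, 1]
  model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

# minimal hand-built axial_traces object for state-machine tests
make_traces <- function(s, in_cyl = NULL, species = "CL",
                        cylinder = pore_cylinder(r_cyl = 5, z_lo = -10,
                                                 z_hi = 10)) {
  s <- rbind(s)
  if (is.null(in_cyl)) {
    in_cyl <- matrix(TRUE, nrow(s), ncol(s))
  } else {
    in_cyl <- rbind(in_cyl)
  }
  structure(
    list(s = s, s_raw = s, r_lat = matrix(0, nrow(s), ncol(s)),
         in_cyl = in_cyl,
         particles = data.frame(eleno = seq_len(nrow(s))),
         species = rep_len(species, nrow(s)), cylinder = cylinder),
    class = "axial_traces"
  )
}

# independent event recount: brute-force scan over compartment sequences
# (no shared code with count_permeations)
brute_count <- function(s, z_lo, z_hi) {
  comp <- ifelse(s < z_lo, -1L, ifelse(s > z_hi, 1L, 0L))
  nz <- comp[comp != 0L]
  if (length(nz) < 2) return(0L)
  sum(diff(nz) != 0L)
}
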