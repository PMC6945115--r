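# Time-averaged 3D number-density grids (particles/nm^3) and OpenDX export.

#' Time-averaged number-density grid
#'
#' Counts selected particles per voxel, averages the counts over frames and
#' divides by the voxel volume, giving number densities in particles/nm^3
#' (1 nm^3 = 1000 A^3). The grid covers `origin + [0, n*edge)` per
#' dimension; by default it spans the selection's bounding box over all
#' frames, padded to a whole number of voxels.
#'
#' @param traj A `pore_trajectory`.
#' @param selection Integer atom indices.
#' @param voxel Voxel edge length (Angstrom, > 0); cubic voxels.
#' @param origin Optional grid origin (3-vector, Angstrom).
#' @param n Optional voxel counts per dimension (3 integers).
#' @return Object of class `density_grid`: `density` (3D array,
#'   particles/nm^3), `counts` (mean counts per voxel), `origin`, `voxel`,
#'   `n`, `n_frames`.
#' @export
density_grid <- function(traj, selection, voxel = 1, origin = NULL,
                         n = NULL) {
  if (voxel <= 0) {
    stop("voxel edge must be positive")
  }
  nfr <- n_frames(traj)
  if (nfr < 1) {
    stop("trajectory has no frames")
  }
  if (length(selection) == 0 && (is.null(origin) || is.null(n))) {
    stop("empty selection needs an explicit grid (origin and n)")
  }
  if (is.null(origin) || is.null(n)) {
    lo <- c(Inf, Inf, Inf)
    hi <- -lo
    for (f in seq_len(nfr)) {
      xyz <- frame_coords(traj, f - 1)[selection, , drop = FALSE]
      lo <- pmin(lo, apply(xyz, 2, min))
      hi <- pmax(hi, apply(xyz, 2, max))
    }
    if (is.null(origin)) origin <- lo - voxel / 2
    if (is.null(n)) n <- pmax(ceiling((hi - origin) / voxel), 1) + 1
  }
  n <- as.integer(n)
  acc <- array(0, dim = n)
  for (f in seq_len(nfr)) {
    if (length(selection) == 0) break
    xyz <- frame_coords(traj, f - 1)[selection, , drop = FALSE]
    ijk <- floor(sweep(xyz, 2, origin) / voxel) + 1
    keep <- ijk[, 1] >= 1 & ijk[, 1] <= n[1] &
      ijk[, 2] >= 1 & ijk[, 2] <= n[2] &
      ijk[, 3] >= 1 & ijk[, 3] <= n[3]
    ijk <- ijk[keep, , drop = FALSE]
    if (nrow(ijk) > 0) {
      lin <- ijk[, 1] + n[1] * (ijk[, 2] - 1) + n[1] * n[2] * (ijk[, 3] - 1)
      tb <- tabulate(lin, nbins = prod(n))
      acc <- acc + array(tb, dim = n)
    }
  }
  counts <- acc / nfr
  vol_nm3 <- (voxel / 10)^3
  structure(
    list(
      density = counts / vol_nm3, counts = counts,
      origin = origin, voxel = voxel, n = n, n_frames = nfr
    ),
    class = "density_grid"
  )
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("density_grid: %d x %d x %d voxels of %.2f A, max %.3f /nm^3\n",
              x$n[1], x$n[2], x$n[3], x$voxel, max(x$density)))
  invisible(x)
}

#' Total particle content of a density grid
#'
#' Integrates density x voxel volume; equals the mean number of selected
#' particles inside the grid per frame.
#'
#' @param grid A `density_grid`.
#' @return Mean in-grid particle count.
#' @export
grid_particle_count <- function(grid) {
  sum(grid$density) * (grid$voxel / 10)^3
}

#' Voxels at or above an isosurface threshold
#'
#' @param grid A `density_grid`.
#' @param threshold Density threshold (particles/nm^3, e.g. 0.5).
#' @return Data frame of voxel centers (`x`, `y`, `z`, Angstrom) and their
#'   `density`.
#' @export
isosurface_voxels <- function(grid, threshold = 0.5) {
  idx <- which(grid$density >= threshold, arr.ind = TRUE)
  data.frame(
    x = grid$origin[1] + (idx[, 1] - 0.5) * grid$voxel,
    y = grid$origin[2] + (idx[, 2] - 0.5) * grid$voxel,
    z = grid$origin[3] + (idx[, 3] - 0.5) * grid$voxel,
    density = grid$density[idx]
  )
}

#' Write a density grid in OpenDX format
#'
#' Standard OpenDX regular-grid scalar field as consumed by VMD/PyMOL;
#' positions in Angstrom, values in particles/nm^3.
#'
#' @param grid A `density_grid`.
#' @param path Output `.dx` path.
#' @return `path`, invisibly.
#' @export
write_opendx <- function(grid, path) {
  n <- grid$n
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# number density (particles/nm^3) written by porelock",
    sprintf("object 1 class gridpositions counts %d %d %d", n[1], n[2], n[3]),
    sprintf("origin %.6f %.6f %.6f", grid$origin[1], grid$origin[2],
            grid$origin[3]),
    sprintf("delta %.6f 0 0", grid$voxel),
    sprintf("delta 0 %.6f 0", grid$voxel),
    sprintf("delta 0 0 %.6f", grid$voxel),
    sprintf("object 2 class gridconnections counts %d %d %d",
            n[1], n[2], n[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(n))
  ), con)
  # OpenDX expects z fastest
  v <- as.numeric(aperm(grid$density, c(3, 2, 1)))
  pad <- (-length(v)) %% 3
  v <- c(v, rep(NA_real_, pad))
  m <- matrix(v, ncol = 3, byrow = TRUE)
  lines <- apply(m, 1, function(r) {
    paste(sprintf("%.6e", r[!is.na(r)]), collapse = " ")
  })
  writeLines(lines, con)
  writeLines(c('attribute "dep" string "positions"',
               'object "density" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}
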