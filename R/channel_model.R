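#' @importFrom stats approx dist optim rnorm runif sd setNames
#' @importFrom utils head read.table tail write.table
NULL

# primed positions restrained along the pore-lining M2 helix
PRIMED_POSITIONS <- c(-2L, 2L, 6L, 9L, 13L, 16L, 20L)

#' Construct a channel model from an atom table
#'
#' A `channel_model` holds the atom records of a (putatively pentameric)
#' channel structure plus, once assigned, the primed-position map and the
#' channel axis. Coordinates are in Angstrom throughout.
#'
#' @param atoms Data frame with columns `eleno` (atom serial), `name` (atom
#'   name, e.g. `"CA"`), `resid` (residue name), `resno` (residue number),
#'   `chain` (subunit identifier), `x`, `y`, `z` (Angstrom) and optionally
#'   `elem` (element symbol; inferred from `name` when absent).
#' @return Object of class `channel_model`.
#' @export
channel_model <- function(atoms) {
  req <- c("eleno", "name", "resid", "resno", "chain", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0) {
    stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(atoms) == 0) {
    stop("atom table is empty")
  }
  if (is.null(atoms$elem)) {
    atoms$elem <- .infer_element(atoms$name)
  }
  structure(
    list(
      atoms = atoms,
      subunit_order = NULL,
      primed_map = NULL,
      axis = NULL
    ),
    class = "channel_model"
  )
}

#' @export
print.channel_model <- function(x, ...) {
  cat("channel_model:", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$chain)), "chain(s)\n")
  if (!is.null(x$primed_map)) {
    cat("  primed positions:",
        paste(rownames(x$primed_map), collapse = " "), "\n")
    cat("  subunit order:", paste(x$subunit_order, collapse = " "), "\n")
  }
  if (!is.null(x$axis)) {
    cat(sprintf("  axis: origin (%.2f, %.2f, %.2f), direction (%.3f, %.3f, %.3f)\n",
                x$axis$origin[1], x$axis$origin[2], x$axis$origin[3],
                x$axis$direction[1], x$axis$direction[2], x$axis$direction[3]))
  }
  invisible(x)
}

#' Read a channel structure from PDB or GRO
#'
#' PDB files are parsed with \pkg{bio3d}; GRO files with the package's own
#' fixed-width reader (coordinates converted nm -> Angstrom on read). Chains
#' are taken from the PDB chain identifier; GRO files carry no chain field,
#' so contiguous stretches of non-decreasing residue numbers are grouped
#' into subunits labelled `A`, `B`, ...
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"pdb"` or `"gro"`.
#' @return A `channel_model` without primed map or axis.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("structure file not found: ", path)
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "gro") "gro" else "pdb"
  }
  if (format == "gro") {
    return(read_gro(path))
  }
  pdb <- tryCatch(
    bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e))
  )
  a <- pdb$atom
  if (nrow(a) == 0) {
    stop("failed to parse PDB file '", path, "': no atom records")
  }
  chain <- a$chain
  chain[is.na(chain) | chain == ""] <- "A"
  atoms <- data.frame(
    eleno = a$eleno, name = trimws(a$elety), resid = trimws(a$resid),
    resno = a$resno, chain = chain,
    x = a$x, y = a$y, z = a$z,
    stringsAsFactors = FALSE
  )
  el <- trimws(a$elesy)
  atoms$elem <- ifelse(is.na(el) | el == "", .infer_element(atoms$name),
                       toupper(el))
  channel_model(atoms)
}

#' Write a channel structure to PDB or GRO
#'
#' @param model A `channel_model`.
#' @param path Output path.
#' @param format `"auto"` (by extension), `"pdb"` or `"gro"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, format = c("auto", "pdb", "gro")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "gro") "gro" else "pdb"
  }
  a <- model$atoms
  if (format == "gro") {
    write_gro(model, path)
  } else {
    bio3d::write.pdb(
      file = path,
      xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
      resno = a$resno, resid = a$resid, eleno = a$eleno,
      elety = a$name, chain = a$chain
    )
  }
  invisible(path)
}

# five subunit ids, error otherwise
.subunits <- function(model) {
  su <- unique(model$atoms$chain)
  if (length(su) != 5) {
    stop("structure error: expected a pentamer (5 subunits), found ",
         length(su), " chain(s)")
  }
  su
}

#' Map primed pore positions to residue numbers
#'
#' Primed index `p` (one of -2, 2, 6, 9, 13, 16, 20) maps to residue number
#' `m2_start + p + 2` on each subunit, i.e. `m2_start` is the residue number
#' of the -2' position. For the human alpha-1 glycine receptor, where the 9'
#' gate leucine is residue 261, `m2_start = 250`.
#'
#' @param model A `channel_model` with 5 subunits.
#' @param m2_start Residue number of the -2' position: a single number, or a
#'   vector named by subunit for non-identical numbering.
#' @param positions Primed indices to map (default the 7 restrained pore
#'   positions).
#' @return The model with `primed_map` (positions x subunits residue-number
#'   matrix) and `subunit_order` filled in.
#' @export
assign_primed_positions <- function(model, m2_start,
                                    positions = PRIMED_POSITIONS) {
  su <- .subunits(model)
  if (length(m2_start) == 1 && is.null(names(m2_start))) {
    m2_start <- setNames(rep(m2_start, 5), su)
  }
  if (!all(su %in% names(m2_start))) {
    stop("configuration error: m2_start must be a scalar or named for every subunit")
  }
  pm <- matrix(NA_integer_, nrow = length(positions), ncol = length(su),
               dimnames = list(as.character(positions), su))
  a <- model$atoms
  for (s in su) {
    for (p in positions) {
      resno <- m2_start[[s]] + p + 2L
      hit <- which(a$chain == s & a$resno == resno & a$name == "CA")
      if (length(hit) == 0) {
        stop("mapping error: no CA atom for primed position ", p,
             "' (residue ", resno, ") in subunit ", s)
      }
      if (length(hit) > 1) {
        stop("mapping error: primed position ", p, "' resolves to ",
             length(hit), " CA atoms in subunit ", s)
      }
      pm[as.character(p), s] <- resno
    }
  }
  model$primed_map <- pm
  model$subunit_order <- su # provisional; rotational order set with the axis
  model
}

# CA atom rows of one primed ring, one row per subunit in primed_map order
.ring_ca <- function(model, p) {
  a <- model$atoms
  pm <- model$primed_map
  su <- colnames(pm)
  idx <- vapply(su, function(s) {
    which(a$chain == s & a$resno == pm[as.character(p), s] & a$name == "CA")[1]
  }, integer(1))
  a[idx, , drop = FALSE]
}

#' Define the channel axis and axial coordinate system
#'
#' The axis is oriented extracellular-positive (the 20' ring at s > 0) and
#' the origin is placed so that the mean axial coordinate of the five 9'
#' C-alpha atoms is exactly 0. Also fixes the rotational order of the
#' subunits (by angle of the 9' C-alpha atoms about the axis), which defines
#' "non-adjacent" for the restraint generator.
#'
#' @param model A `channel_model` with primed positions assigned.
#' @param method `"ring_centroids"`: best-fit line through the per-ring
#'   centroids of the pore-lining C-alpha atoms (default); `"principal"`:
#'   smallest-moment principal axis of all pore-lining C-alpha atoms.
#' @return The model with `axis` (origin + unit direction) set and
#'   `subunit_order` in rotational order.
#' @export
compute_axis <- function(model, method = c("ring_centroids", "principal")) {
  method <- match.arg(method)
  if (is.null(model$primed_map)) {
    stop("assign_primed_positions() must be called before compute_axis()")
  }
  pos <- as.integer(rownames(model$primed_map))
  rings <- lapply(pos, function(p) {
    as.matrix(.ring_ca(model, p)[, c("x", "y", "z")])
  })
  centroids <- t(vapply(rings, colMeans, numeric(3)))
  pts <- if (method == "ring_centroids") centroids else do.call(rbind, rings)
  ctr <- colMeans(pts)
  dc <- sweep(pts, 2, ctr)
  sv <- svd(dc, nu = 0, nv = 3)
  if (sv$d[1] < 1e-9 || nrow(pts) < 2) {
    stop("axis error: degenerate pore-lining geometry")
  }
  dir <- sv$v[, 1]
  dir <- dir / sqrt(sum(dir^2))
  c9 <- centroids[match(9L, pos), ]
  c20 <- centroids[match(20L, pos), ]
  if (sum((c20 - c9) * dir) < 0) {
    dir <- -dir
  }
  if (abs(sum((c20 - c9) * dir)) < 1e-9) {
    stop("axis error: cannot orient axis (20' and 9' rings coincide axially)")
  }
  # origin: projection of the 9' centroid onto the axis line => mean s of the
  # five 9' CA atoms is exactly 0
  origin <- ctr + sum((c9 - ctr) * dir) * dir
  model$axis <- list(origin = origin, direction = dir)
  # rotational order of subunits: angle of 9' CA about the axis
  ca9 <- .ring_ca(model, 9L)
  u <- .plane_basis(dir)
  d <- sweep(as.matrix(ca9[, c("x", "y", "z")]), 2, origin)
  ang <- atan2(d %*% u$v, d %*% u$u)
  ord <- order(ang)
  # start the cycle at the alphabetically first subunit for determinism
  cyc <- ca9$chain[ord]
  start <- which(cyc == min(cyc))[1]
  model$subunit_order <- cyc[((seq_len(5) + start - 2) %% 5) + 1]
  model
}

# deterministic orthonormal basis of the plane perpendicular to a unit vector
.plane_basis <- function(dir) {
  ref <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * dir) * dir
  u <- u / sqrt(sum(u^2))
  v <- c(
    dir[2] * u[3] - dir[3] * u[2],
    dir[3] * u[1] - dir[1] * u[3],
    dir[1] * u[2] - dir[2] * u[1]
  )
  list(u = u, v = v)
}

#' Axial coordinates of points in a model's axis frame
#'
#' @param model A `channel_model` with its axis computed.
#' @param xyz Optional n x 3 coordinate matrix (Angstrom); defaults to the
#'   model's own atoms.
#' @return Numeric vector of axial coordinates s (Angstrom; 9' ring at 0,
#'   extracellular positive).
#' @export
axial_coords <- function(model, xyz = NULL) {
  if (is.null(model$axis)) {
    stop("model has no axis; call compute_axis() first")
  }
  if (is.null(xyz)) {
    xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  }
  drop(sweep(xyz, 2, model$axis$origin) %*% model$axis$direction)
}

#' Lateral (radial) distances from the channel axis
#'
#' @inheritParams axial_coords
#' @return Numeric vector of distances (Angstrom) from the axis line.
#' @export
lateral_distances <- function(model, xyz = NULL) {
  if (is.null(model$axis)) {
    stop("model has no axis; call compute_axis() first")
  }
  if (is.null(xyz)) {
    xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  }
  d <- sweep(xyz, 2, model$axis$origin)
  s <- drop(d %*% model$axis$direction)
  sqrt(pmax(rowSums(d^2) - s^2, 0))
}

#' Axial position of a primed ring centroid
#'
#' @param model A `channel_model` with axis and primed map.
#' @param p Primed index (e.g. `9` or `-2`).
#' @return Axial coordinate s (Angstrom) of the ring centroid.
#' @export
ring_s <- function(model, p) {
  ca <- .ring_ca(model, p)
  mean(axial_coords(model, as.matrix(ca[, c("x", "y", "z")])))
}

#' Read a channel configuration file
#'
#' YAML file with keys `m2_start` (scalar or per-subunit map), optional
#' `axis_method` (`ring_centroids` or `principal`) and optional `positions`
#' (primed indices).
#'
#' @param path YAML config path.
#' @return Named list of configuration values.
#' @export
read_channel_config <- function(path) {
  if (!file.exists(path)) {
    stop("channel config not found: ", path)
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$m2_start)) {
    stop("channel config must define m2_start")
  }
  if (is.null(cfg$axis_method)) cfg$axis_method <- "ring_centroids"
  if (is.null(cfg$positions)) cfg$positions <- PRIMED_POSITIONS
  cfg$positions <- as.integer(cfg$positions)
  if (is.list(cfg$m2_start)) cfg$m2_start <- unlist(cfg$m2_start)
  cfg
}

#' Build a fully annotated channel model from structure + config
#'
#' Convenience wrapper: read structure, assign primed positions, compute the
#' axis.
#'
#' @param structure_path PDB or GRO file.
#' @param config Path to a channel config YAML, or a list as returned by
#'   [read_channel_config()].
#' @return Annotated `channel_model`.
#' @export
load_channel <- function(structure_path, config) {
  if (is.character(config)) {
    config <- read_channel_config(config)
  }
  m <- read_structure(structure_path)
  m <- assign_primed_positions(m, config$m2_start,
                               positions = config$positions)
  compute_axis(m, method = config$axis_method)
}
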