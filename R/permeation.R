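# Ion/water permeation analysis: axial traces inside the pore cylinder,
# compartment state machine for counting complete traversals, selectivity,
# and wetting/dewetting.

#' Define the pore cylinder
#'
#' The pore region is a cylinder around the channel axis: particles count
#' as "in the pore" when their lateral distance to the axis is below
#' `r_cyl` and their axial coordinate lies in `[z_lo, z_hi]`.
#'
#' @param r_cyl Cylinder radius (Angstrom, default 5, i.e. within 5 A of
#'   the channel axis).
#' @param z_lo,z_hi Axial bounds (Angstrom). When a `model` is given they
#'   default to the -2' and 20' C-alpha ring centroids of that structure.
#' @param model Optional annotated `channel_model` supplying the defaults.
#' @return List of class `pore_cylinder`.
#' @export
pore_cylinder <- function(r_cyl = 5, z_lo = NULL, z_hi = NULL,
                          model = NULL) {
  if (!is.null(model)) {
    if (is.null(z_lo)) z_lo <- ring_s(model, -2L)
    if (is.null(z_hi)) z_hi <- ring_s(model, 20L)
  }
  if (is.null(z_lo) || is.null(z_hi)) {
    stop("z_lo and z_hi must be given (or derived from a model)")
  }
  if (z_lo >= z_hi) {
    stop("pore cylinder needs z_lo < z_hi")
  }
  if (r_cyl <= 0) {
    stop("pore cylinder needs r_cyl > 0")
  }
  structure(list(r_cyl = r_cyl, z_lo = z_lo, z_hi = z_hi),
            class = "pore_cylinder")
}

#' Axial traces of selected particles
#'
#' For every selected particle and frame: the axial coordinate s (Angstrom,
#' unwrapped along the axis when a periodic box is present), the lateral
#' distance to the axis, and whether the particle is inside the cylinder
#' radius. Unwrapping uses the minimum-image displacement between
#' consecutive frames along the axis, so sampling must be fine enough that
#' a particle moves less than half a box per frame.
#'
#' @param traj A `pore_trajectory`.
#' @param selection Integer atom indices (e.g. from [select_atoms()]).
#' @param axis Channel axis (list with `origin`, unit `direction`).
#' @param cylinder A `pore_cylinder`.
#' @return List of class `axial_traces`: matrices `s` (unwrapped),
#'   `s_raw`, `r_lat`, logical `in_cyl` (`n_particles x n_frames`), the
#'   particle table, cylinder, and species labels (residue names).
#' @export
axial_traces <- function(traj, selection, axis, cylinder) {
  if (length(selection) == 0) {
    stop("empty particle selection")
  }
  nfr <- n_frames(traj)
  np <- length(selection)
  dir <- axis$direction / sqrt(sum(axis$direction^2))
  s_raw <- matrix(NA_real_, np, nfr)
  r_lat <- matrix(NA_real_, np, nfr)
  for (f in seq_len(nfr)) {
    xyz <- frame_coords(traj, f - 1)[selection, , drop = FALSE]
    d <- sweep(xyz, 2, axis$origin)
    sf <- drop(d %*% dir)
    s_raw[, f] <- sf
    r_lat[, f] <- sqrt(pmax(rowSums(d^2) - sf^2, 0))
  }
  s <- s_raw
  if (!is.null(traj$box)) {
    # axial box length seen along the axis: the z box edge projected on the
    # axis direction (fixtures and membrane setups have the axis ~ z)
    lz <- abs(sum(c(0, 0, traj$box[3]) * dir))
    if (lz > 1e-6) {
      # anchor the first frame by minimum image about the axis origin, then
      # accumulate minimum-image displacements
      s[, 1] <- s_raw[, 1] - lz * round(s_raw[, 1] / lz)
      if (nfr > 1) {
        for (f in 2:nfr) {
          jump <- s_raw[, f] - s[, f - 1]
          s[, f] <- s_raw[, f] - lz * round(jump / lz)
        }
      }
    }
  }
  structure(
    list(
      s = s, s_raw = s_raw, r_lat = r_lat,
      in_cyl = r_lat <= cylinder$r_cyl,
      particles = traj$atoms[selection, , drop = FALSE],
      species = traj$atoms$resid[selection],
      cylinder = cylinder
    ),
    class = "axial_traces"
  )
}

# state machine for one particle; returns data.frame of events
# comp: -1 below, 0 inside (between z bounds), +1 above
.scan_events <- function(s, in_cyl, z_lo, z_hi, tol_frames = 0) {
  comp <- ifelse(s < z_lo, -1L, ifelse(s > z_hi, 1L, 0L))
  events <- list()
  side <- NA_integer_ # compartment the current approach started from
  entry <- NA_integer_
  viol <- 0L
  voided <- FALSE
  if (comp[1] != 0L) {
    side <- comp[1]
  }
  for (t in seq_along(comp)) {
    ct <- comp[t]
    if (ct == 0L) {
      if (is.na(entry) && !is.na(side)) {
        entry <- t
        viol <- 0L
        voided <- FALSE
      }
      if (!is.na(entry) && !in_cyl[t]) {
        viol <- viol + 1L
        if (viol > tol_frames) {
          voided <- TRUE
        }
      }
    } else {
      if (!is.na(side) && ct != side && !voided) {
        # completed traversal side -> (inside) -> other side; a direct
        # side-to-side jump (entry NA) counts as a traversal too
        events[[length(events) + 1]] <- data.frame(
          entry_frame = (if (is.na(entry)) t else entry) - 1L,
          exit_frame = t - 1L,
          direction = if (ct > side) 1L else -1L
        )
      }
      side <- ct
      entry <- NA_integer_
      viol <- 0L
      voided <- FALSE
    }
  }
  if (length(events) == 0) {
    data.frame(entry_frame = integer(0), exit_frame = integer(0),
               direction = integer(0))
  } else {
    do.call(rbind, events)
  }
}

#' Count permeation events
#'
#' Three-compartment state machine per particle: below (`s < z_lo`),
#' inside (`z_lo <= s <= z_hi`), above (`s > z_hi`). An event is a
#' completed below-inside-above traversal (direction +1) or the reverse
#' (direction -1) with all intervening inside frames within the cylinder
#' radius (up to `tol_frames` excursions tolerated). Re-entries that return
#' to the starting side count nothing. Both directions are pooled in the
#' totals.
#'
#' @param traces An `axial_traces` object.
#' @param tol_frames Number of inside frames allowed outside the cylinder
#'   radius before a traversal is voided (default 0: strict).
#' @return List of class `permeation_record`: `counts` (named per species),
#'   `events` (data frame: particle row, species, entry/exit frame,
#'   direction), `n_frames`.
#' @export
count_permeations <- function(traces, tol_frames = 0) {
  np <- nrow(traces$s)
  if (ncol(traces$s) < 2) {
    stop("traces must cover at least 2 frames")
  }
  ev_all <- list()
  for (i in seq_len(np)) {
    ev <- .scan_events(traces$s[i, ], traces$in_cyl[i, ],
                       traces$cylinder$z_lo, traces$cylinder$z_hi,
                       tol_frames)
    if (nrow(ev) > 0) {
      ev$particle <- i
      ev$species <- traces$species[i]
      ev_all[[length(ev_all) + 1]] <- ev
    }
  }
  events <- if (length(ev_all) == 0) {
    data.frame(entry_frame = integer(0), exit_frame = integer(0),
               direction = integer(0), particle = integer(0),
               species = character(0))
  } else {
    do.call(rbind, ev_all)
  }
  species <- sort(unique(traces$species))
  counts <- vapply(species, function(sp) sum(events$species == sp),
                   integer(1))
  structure(
    list(counts = counts, events = events, n_frames = ncol(traces$s)),
    class = "permeation_record"
  )
}

#' @export
print.permeation_record <- function(x, ...) {
  cat("permeation events over", x$n_frames, "frames:\n")
  for (sp in names(x$counts)) {
    cat(sprintf("  %-6s %d\n", sp, x$counts[[sp]]))
  }
  invisible(x)
}

#' Anion/cation selectivity ratio from event counts
#'
#' @param cl Number of chloride (anion) events, or a `permeation_record`
#'   (then `cl_species`/`na_species` name the species).
#' @param na Number of sodium (cation) events.
#' @param cl_species,na_species Species labels used when `cl` is a record.
#' @return List: `ratio` (`Inf` when `na = 0` with `cl > 0`, `NaN` when
#'   both are 0), `cl`, `na`, `flag` (`"ok"`, `"no_cation_events"` or
#'   `"undefined"`).
#' @export
selectivity_ratio <- function(cl, na = NULL, cl_species = "CL",
                              na_species = "NA") {
  if (inherits(cl, "permeation_record")) {
    rec <- cl
    cl <- if (cl_species %in% names(rec$counts)) rec$counts[[cl_species]] else 0L
    na <- if (na_species %in% names(rec$counts)) rec$counts[[na_species]] else 0L
  }
  if (cl < 0 || na < 0) {
    stop("counts must be non-negative")
  }
  if (cl == 0 && na == 0) {
    return(list(ratio = NaN, cl = cl, na = na, flag = "undefined"))
  }
  if (na == 0) {
    return(list(ratio = Inf, cl = cl, na = na, flag = "no_cation_events"))
  }
  list(ratio = cl / na, cl = cl, na = na, flag = "ok")
}

#' Pore wetting / dewetting analysis
#'
#' Bins the pore axis between the cylinder's z bounds and counts water
#' particles (by their oxygen) inside the cylinder per bin per frame. A bin
#' is dewetted at a frame iff it holds no water; contiguous dewetted bin
#' runs are reported per frame, along with the fraction of frames in which
#' the whole pore is wetted.
#'
#' @param traces An `axial_traces` of the water oxygens.
#' @param bin_width Axial bin width (Angstrom).
#' @return List of class `wetting_report`: `occupancy` (bins x frames
#'   counts), `dewetted` (logical, same shape), `bin_edges`,
#'   `fraction_fully_wetted`, `stretches` (data frame: frame, s_lo, s_hi of
#'   each maximal contiguous dewetted run).
#' @export
wetting_analysis <- function(traces, bin_width = 1) {
  if (bin_width <= 0) {
    stop("bin width must be positive")
  }
  cyl <- traces$cylinder
  edges <- seq(cyl$z_lo, cyl$z_hi, by = bin_width)
  if (tail(edges, 1) < cyl$z_hi) {
    edges <- c(edges, cyl$z_hi)
  }
  nb <- length(edges) - 1
  nfr <- ncol(traces$s)
  occ <- matrix(0L, nb, nfr)
  for (f in seq_len(nfr)) {
    sel <- traces$in_cyl[, f] & traces$s[, f] >= cyl$z_lo &
      traces$s[, f] <= cyl$z_hi
    if (any(sel)) {
      b <- findInterval(traces$s[sel, f], edges, rightmost.closed = TRUE)
      b[b < 1] <- 1
      b[b > nb] <- nb
      tb <- tabulate(b, nbins = nb)
      occ[, f] <- tb
    }
  }
  dew <- occ == 0L
  stretches <- list()
  for (f in seq_len(nfr)) {
    r <- rle(dew[, f])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in which(r$values)) {
      stretches[[length(stretches) + 1]] <- data.frame(
        frame = f - 1L, s_lo = edges[starts[j]], s_hi = edges[ends[j] + 1]
      )
    }
  }
  structure(
    list(
      occupancy = occ, dewetted = dew, bin_edges = edges,
      fraction_fully_wetted = mean(colSums(dew) == 0),
      stretches = if (length(stretches) == 0) {
        data.frame(frame = integer(0), s_lo = numeric(0),
                   s_hi = numeric(0))
      } else {
        do.call(rbind, stretches)
      }
    ),
    class = "wetting_report"
  )
}

#' Write a permeation event table as TSV
#' @param record A `permeation_record`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(record, path) {
  write.table(record$events[, c("particle", "species", "entry_frame",
                                "exit_frame", "direction")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
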