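# HOLE-style pore radius profiles and Wimley-White hydrophobicity profiles
# along the channel axis.
#
# At each axial grid point s the pore radius is the largest probe sphere
# centered in the slice plane: max over in-plane center positions c of
# min over atoms i of (|c - x_i| - vdw_i). The maximization is local, in
# the basin containing the axis point (deterministic 1 A lattice hill
# climb from the axis followed by Nelder-Mead refinement, confined to a
# lateral search box): the probe tracks the pore lumen and cannot leak
# around the outside of the protein wall.

#' Default axial grid
#'
#' @param from,to,by Grid range and step in Angstrom (9' ring at 0).
#' @return Numeric vector of s values.
#' @export
default_s_grid <- function(from = -40, to = 40, by = 0.5) {
  seq(from, to, by = by)
}

# objective: clearance of a probe centered at point c (3-vector)
.clearance <- function(c3, xyz, vdw) {
  d <- sqrt((xyz[, 1] - c3[1])^2 + (xyz[, 2] - c3[2])^2 +
              (xyz[, 3] - c3[3])^2)
  min(d - vdw)
}

#' HOLE-style pore radius profile of one frame
#'
#' @param xyz `n x 3` coordinate matrix (Angstrom) of the atoms bounding the
#'   pore (typically the protein).
#' @param axis List with `origin` and unit `direction` (as in a
#'   `channel_model$axis`).
#' @param s_grid Axial grid (Angstrom); default [default_s_grid()].
#' @param vdw Per-atom van der Waals radii (Angstrom); a single value is
#'   recycled.
#' @param cap Radius cap (Angstrom, default 10): slices whose best probe
#'   exceeds this (open bulk) report `cap`.
#' @param search_range Lateral half-width of the start lattice (Angstrom).
#' @param frame Frame label stored on the result.
#' @return A `pore_profile` data frame: `s`, `radius` (Angstrom, in
#'   `[0, cap]`), plus the probe center coordinates `cx`, `cy`, `cz`.
#' @export
pore_radius_profile <- function(xyz, axis, s_grid = default_s_grid(),
                                vdw, cap = 10, search_range = 8,
                                frame = 0L) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) == 0) {
    stop("empty atom set")
  }
  if (length(vdw) == 1) {
    vdw <- rep(vdw, nrow(xyz))
  }
  stopifnot(length(vdw) == nrow(xyz))
  dir <- axis$direction / sqrt(sum(axis$direction^2))
  basis <- .plane_basis(dir)
  s_atom <- drop(sweep(xyz, 2, axis$origin) %*% dir)
  # 8-neighborhood steps of the lattice hill climb (1 A spacing)
  steps <- as.matrix(expand.grid(da = -1:1, db = -1:1))
  steps <- steps[!(steps[, 1] == 0 & steps[, 2] == 0), ]
  vmax <- max(vdw)
  out <- data.frame(s = s_grid, radius = NA_real_, cx = NA_real_,
                    cy = NA_real_, cz = NA_real_)
  for (gi in seq_along(s_grid)) {
    s <- s_grid[gi]
    p0 <- axis$origin + s * dir
    near <- abs(s_atom - s) < cap + vmax + search_range
    if (!any(near)) {
      out$radius[gi] <- cap
      out[gi, c("cx", "cy", "cz")] <- p0
      next
    }
    sub <- xyz[near, , drop = FALSE]
    svdw <- vdw[near]
    fobj <- function(ab) {
      if (ab[1]^2 + ab[2]^2 > search_range^2) {
        # confine the search laterally; quadratic pull-back keeps the
        # objective continuous for the simplex search
        return(-(ab[1]^2 + ab[2]^2 - search_range^2) - 1e3)
      }
      .clearance(p0 + ab[1] * basis$u + ab[2] * basis$v, sub, svdw)
    }
    # discrete steepest ascent on the 1 A lattice from the axis point:
    # stays in the basin of the lumen, ties resolved toward the axis by
    # strict improvement
    ab <- c(0, 0)
    val <- fobj(ab)
    for (it in seq_len(4 * search_range)) {
      cand <- sweep(steps, 2, -ab)
      cv <- apply(cand, 1, fobj)
      j <- which.max(cv)
      if (cv[j] <= val + 1e-12) break
      ab <- as.numeric(cand[j, ])
      val <- cv[j]
    }
    # Nelder-Mead refinement within the basin
    o <- optim(ab, fobj, control = list(fnscale = -1, reltol = 1e-12,
                                        maxit = 500))
    if (o$value > val) {
      val <- o$value
      ab <- o$par
    }
    opt_ab <- ab
    out$radius[gi] <- min(max(val, 0), cap)
    out[gi, c("cx", "cy", "cz")] <-
      p0 + opt_ab[1] * basis$u + opt_ab[2] * basis$v
  }
  attr(out, "frame") <- frame
  attr(out, "cap") <- cap
  class(out) <- c("pore_profile", "data.frame")
  out
}

#' Pore radius profile of a channel model
#'
#' Convenience wrapper selecting the model's atoms and their Bondi radii.
#'
#' @param model Annotated `channel_model`.
#' @param ... Passed to [pore_radius_profile()].
#' @return A `pore_profile`.
#' @export
model_radius_profile <- function(model, ...) {
  a <- model$atoms
  pore_radius_profile(as.matrix(a[, c("x", "y", "z")]), model$axis,
                      vdw = .vdw_for(a$elem), ...)
}

#' Wimley-White hydrophobicity profile along the pore
#'
#' Every residue is assigned its rescaled Wimley-White value (see
#' [ww_scale()]). A residue is pore-facing at axial position s if any of its
#' heavy atoms lies within `facing_cutoff` of the pore surface there (the
#' sphere of the local pore radius around the local probe center). The
#' profile is the Gaussian(sigma)-weighted average of the facing residues'
#' values, weighted by their axial distance to s.
#'
#' @param atoms Atom table (`resid`, `resno`, `chain`, `name`, `elem`,
#'   `x`, `y`, `z`).
#' @param axis Channel axis (origin + unit direction).
#' @param radius_profile A `pore_profile` for the same frame (supplies the
#'   local pore surface).
#' @param scale Named residue -> value table; default [ww_scale()].
#' @param sigma Gaussian smoothing bandwidth along s (Angstrom).
#' @param facing_cutoff Heavy-atom distance to the pore surface below which
#'   a residue counts as pore-facing (Angstrom).
#' @return A `pore_profile` data frame with `s` and `hydrophobicity`
#'   (NA where no residue faces the pore).
#' @export
hydrophobicity_profile <- function(atoms, axis, radius_profile,
                                   scale = ww_scale(), sigma = 2,
                                   facing_cutoff = 4) {
  heavy <- atoms[atoms$elem != "H", , drop = FALSE]
  unknown <- setdiff(unique(heavy$resid), names(scale))
  if (length(unknown) > 0) {
    stop("residue name(s) not in hydrophobicity scale: ",
         paste(unknown, collapse = ", "))
  }
  xyz <- as.matrix(heavy[, c("x", "y", "z")])
  dir <- axis$direction / sqrt(sum(axis$direction^2))
  s_atom <- drop(sweep(xyz, 2, axis$origin) %*% dir)
  res_key <- paste(heavy$chain, heavy$resno)
  res_val <- scale[heavy$resid]
  sg <- radius_profile$s
  hyd <- rep(NA_real_, length(sg))
  for (gi in seq_along(sg)) {
    ctr <- as.numeric(radius_profile[gi, c("cx", "cy", "cz")])
    r <- radius_profile$radius[gi]
    dsurf <- abs(sqrt((xyz[, 1] - ctr[1])^2 + (xyz[, 2] - ctr[2])^2 +
                        (xyz[, 3] - ctr[3])^2) - r)
    facing <- dsurf <= facing_cutoff
    if (!any(facing)) {
      next
    }
    # one representative per facing residue: its closest-to-surface atom
    f_idx <- which(facing)
    f_idx <- f_idx[order(dsurf[f_idx])]
    f_idx <- f_idx[!duplicated(res_key[f_idx])]
    w <- exp(-(s_atom[f_idx] - sg[gi])^2 / (2 * sigma^2))
    hyd[gi] <- sum(w * res_val[f_idx]) / sum(w)
  }
  out <- data.frame(s = sg, hydrophobicity = hyd)
  class(out) <- c("pore_profile", "data.frame")
  out
}

#' Pointwise statistics over per-frame profiles
#'
#' @param profiles List of `pore_profile`s on a common s grid.
#' @param column Profile column to aggregate (default `"radius"`).
#' @param n_points Subsample to this many equally spaced frames before
#'   aggregating (e.g. 300 points over a 300 ns run); `NULL` uses all.
#' @return A `profile_statistics` data frame: `s`, `mean`, `sd`, with
#'   attribute `n_frames`.
#' @export
profile_statistics <- function(profiles, column = "radius",
                               n_points = NULL) {
  if (length(profiles) < 2) {
    stop("need at least 2 frames for profile statistics")
  }
  s0 <- profiles[[1]]$s
  for (p in profiles) {
    if (!isTRUE(all.equal(p$s, s0))) {
      stop("profiles are not on a common s grid")
    }
  }
  if (!is.null(n_points) && n_points < length(profiles)) {
    idx <- unique(round(seq(1, length(profiles), length.out = n_points)))
    profiles <- profiles[idx]
  }
  m <- vapply(profiles, function(p) p[[column]], numeric(length(s0)))
  out <- data.frame(
    s = s0,
    mean = rowMeans(m),
    sd = apply(m, 1, sd)
  )
  attr(out, "n_frames") <- length(profiles)
  class(out) <- c("profile_statistics", "data.frame")
  out
}

#' Annotate gate geometry of a profile
#'
#' Reports the minimal radius in windows around the 9' hydrophobic gate and
#' the -2' proline gate, and raises a hydrophobic-gating-risk flag when the
#' 9' constriction is narrower than `radius_threshold` (default 4 Angstrom,
#' the lower edge of the ~4-5 A local-dehydration regime for hydrophobic
#' pores) while the local surface is hydrophobic (> 0 on the rescaled
#' Wimley-White scale).
#'
#' @param stats `profile_statistics` (or single-frame profile) with `s` and
#'   `mean` (or `radius`) columns.
#' @param hydrophobicity Optional matching profile with `s` and
#'   `hydrophobicity`; without it, the flag is based on geometry only when
#'   `hydrophobic = TRUE` is asserted.
#' @param s_gate9,s_gate_minus2 Axial centers of the two gates (Angstrom);
#'   9' is at 0 by construction, -2' defaults to -16 (about 11 residues
#'   below at ~1.5 A rise) unless given.
#' @param window Half-width of each gate window (Angstrom).
#' @param radius_threshold Dehydration-risk radius (Angstrom).
#' @param hydrophobic Fallback assertion when no hydrophobicity profile is
#'   supplied.
#' @return List: `r_min_9` and `r_min_minus2` (Angstrom), `hydrophobicity_9`,
#'   `hydrophobic_gating_risk` (logical).
#' @export
classify_gate_geometry <- function(stats, hydrophobicity = NULL,
                                   s_gate9 = 0, s_gate_minus2 = -16,
                                   window = 5, radius_threshold = 4,
                                   hydrophobic = FALSE) {
  r <- if (!is.null(stats$mean)) stats$mean else stats$radius
  win9 <- abs(stats$s - s_gate9) <= window
  winm2 <- abs(stats$s - s_gate_minus2) <= window
  if (!any(win9) || !any(winm2)) {
    stop("gate window lies outside the profile grid")
  }
  r9 <- min(r[win9], na.rm = TRUE)
  rm2 <- min(r[winm2], na.rm = TRUE)
  h9 <- NA_real_
  if (!is.null(hydrophobicity)) {
    hw <- hydrophobicity$hydrophobicity[abs(hydrophobicity$s - s_gate9) <=
                                          window]
    h9 <- if (all(is.na(hw))) NA_real_ else mean(hw, na.rm = TRUE)
  }
  hydro <- if (!is.na(h9)) h9 > 0 else hydrophobic
  list(
    r_min_9 = r9,
    r_min_minus2 = rm2,
    hydrophobicity_9 = h9,
    hydrophobic_gating_risk = (r9 < radius_threshold) && hydro
  )
}

#' Write a profile (or its statistics) as TSV
#' @param profile Data frame (`pore_profile` or `profile_statistics`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
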