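# Conformational signatures: per-residue C-alpha RMSF, 9' hydrophobic
# pocket burial, -2' proline ring pairing/asymmetry, representative frame.

# flatten selected coordinates of a trajectory into bio3d's frame-by-3N
# layout
.xyz_matrix <- function(traj, selection) {
  nfr <- n_frames(traj)
  out <- matrix(NA_real_, nfr, length(selection) * 3)
  for (f in seq_len(nfr)) {
    out[f, ] <- as.numeric(t(frame_coords(traj, f - 1)[selection, ,
                                                       drop = FALSE]))
  }
  out
}

# least-squares superposition of all frames onto a reference frame using
# bio3d's Kabsch fit
.align_frames <- function(xyz, ref_row) {
  idx <- seq_len(ncol(xyz))
  bio3d::fit.xyz(fixed = xyz[ref_row, ], mobile = xyz,
                 fixed.inds = idx, mobile.inds = idx)
}

#' Per-residue C-alpha RMSF
#'
#' Frames are superposed onto the reference frame by least squares over the
#' selection, then `RMSF_i = sqrt(mean_t |x_i(t) - <x_i>|^2)`. Typical
#' values for helical cores are around 0.7 Angstrom; flexible gate regions
#' run higher.
#'
#' @param traj A `pore_trajectory` with at least 2 frames.
#' @param selection C-alpha atom indices (default: all atoms named CA).
#' @param ref_frame 0-based frame used as the alignment reference.
#' @param align Superpose frames before computing fluctuations (default
#'   TRUE; set FALSE for pre-aligned input).
#' @return Data frame: `chain`, `resno`, `rmsf` (Angstrom).
#' @export
rmsf_profile <- function(traj, selection = NULL, ref_frame = 0,
                         align = TRUE) {
  if (is.null(selection)) {
    selection <- select_atoms(traj, name = "CA")
  }
  if (length(selection) == 0) {
    stop("empty C-alpha selection")
  }
  if (n_frames(traj) < 2) {
    stop("RMSF needs at least 2 frames")
  }
  xyz <- .xyz_matrix(traj, selection)
  if (align) {
    xyz <- .align_frames(xyz, ref_frame + 1)
  }
  mean_xyz <- colMeans(xyz)
  dev2 <- sweep(xyz, 2, mean_xyz)^2
  per_atom <- matrix(colMeans(dev2), ncol = 3, byrow = TRUE)
  data.frame(
    chain = traj$atoms$chain[selection],
    resno = traj$atoms$resno[selection],
    rmsf = sqrt(rowSums(per_atom))
  )
}

#' Default 9' hydrophobic pocket definition (GlyR numbering)
#'
#' The pocket that buries the 9' gate leucine of the principal (+) subunit:
#' I257, V260, T264 on the (+) M2 helix; L255, T258, T259, T262 on the (-)
#' M2 helix; L233, I234, L237 on the (-) M1 helix.
#'
#' @param probe_resno Residue number of the 9' probe leucine (261 for human
#'   alpha-1 GlyR).
#' @return List of class `pocket_definition` with `probe_resno` and a data
#'   frame `pocket` (`interface`, `helix`, `resno`).
#' @export
pocket_definition <- function(probe_resno = 261L) {
  structure(
    list(
      probe_resno = probe_resno,
      pocket = data.frame(
        interface = c("+", "+", "+", "-", "-", "-", "-", "-", "-", "-"),
        helix = c("M2", "M2", "M2", "M2", "M2", "M2", "M2",
                  "M1", "M1", "M1"),
        resno = c(257L, 260L, 264L, 255L, 258L, 259L, 262L,
                  233L, 234L, 237L),
        stringsAsFactors = FALSE
      )
    ),
    class = "pocket_definition"
  )
}

#' Burial of a 9' probe residue in its inter-subunit pocket
#'
#' Counts pocket heavy atoms within `cutoff` of any probe side-chain heavy
#' atom. Scores >= `buried_threshold` classify as `"buried"`, 0 as
#' `"vacated"`, anything between as `"partial"`.
#'
#' @param atoms Atom table of one frame (as in a `channel_model`).
#' @param probe_chain Chain id of the principal (+) subunit carrying the
#'   probe.
#' @param minus_chain Chain id of the complementary (-) subunit.
#' @param pocket A `pocket_definition`.
#' @param cutoff Heavy-atom contact cutoff (Angstrom, default 4.5).
#' @param buried_threshold Contact count at or above which the probe counts
#'   as buried (default 10).
#' @return List: `score` (contact count), `class`, `min_distance`
#'   (Angstrom).
#' @export
pocket_burial <- function(atoms, probe_chain, minus_chain,
                          pocket = pocket_definition(), cutoff = 4.5,
                          buried_threshold = 10) {
  if (cutoff < 0) {
    stop("cutoff must be non-negative")
  }
  heavy <- atoms[atoms$elem != "H", , drop = FALSE]
  backbone <- c("N", "CA", "C", "O")
  probe <- heavy[heavy$chain == probe_chain &
                   heavy$resno == pocket$probe_resno &
                   !(heavy$name %in% backbone), , drop = FALSE]
  if (nrow(probe) == 0) {
    stop("missing residue: probe ", pocket$probe_resno, " on chain ",
         probe_chain)
  }
  pk <- pocket$pocket
  pk$chain <- ifelse(pk$interface == "+", probe_chain, minus_chain)
  pock_idx <- rep(FALSE, nrow(heavy))
  for (i in seq_len(nrow(pk))) {
    sel <- heavy$chain == pk$chain[i] & heavy$resno == pk$resno[i]
    if (!any(sel)) {
      stop("missing residue: pocket residue ", pk$resno[i], " on chain ",
           pk$chain[i])
    }
    pock_idx <- pock_idx | sel
  }
  pxyz <- as.matrix(probe[, c("x", "y", "z")])
  kxyz <- as.matrix(heavy[pock_idx, c("x", "y", "z")])
  dmin <- apply(kxyz, 1, function(p) {
    min(sqrt((pxyz[, 1] - p[1])^2 + (pxyz[, 2] - p[2])^2 +
               (pxyz[, 3] - p[3])^2))
  })
  score <- sum(dmin <= cutoff)
  cls <- if (score >= buried_threshold) "buried"
         else if (score == 0) "vacated" else "partial"
  list(score = score, class = cls, min_distance = min(dmin))
}

#' Pairing and asymmetry of the -2' proline ring
#'
#' Builds a contact graph on the side-chain centroids of the five -2'
#' residues (edge iff centroid distance < `cutoff`) and partitions them by
#' greedy minimum-distance matching into pairs and singletons. The
#' arrangement is flagged asymmetric when the coefficient of variation of
#' the centroid-axis distances exceeds `cv_threshold` or any pair formed.
#'
#' @param atoms Atom table of one frame.
#' @param model Annotated `channel_model` (supplies primed map and axis).
#' @param cutoff Pairing contact cutoff on centroid distance (Angstrom,
#'   default 6).
#' @param cv_threshold Coefficient-of-variation threshold on centroid-axis
#'   distances (default 0.1).
#' @return List of class `proline_pairing`: `partition` (list of chain-id
#'   vectors, pairs first), `pairs`, `singletons`, `asymmetric`,
#'   `axis_distances`, `cv`.
#' @export
proline_pairing <- function(atoms, model, cutoff = 6, cv_threshold = 0.1) {
  pm <- model$primed_map
  if (is.null(pm) || !("-2" %in% rownames(pm))) {
    stop("model must map the -2' position")
  }
  su <- colnames(pm)
  if (length(su) != 5) {
    stop("proline pairing needs exactly 5 subunits")
  }
  heavy <- atoms[atoms$elem != "H", , drop = FALSE]
  backbone <- c("N", "CA", "C", "O")
  cent <- t(vapply(su, function(s) {
    res <- heavy[heavy$chain == s & heavy$resno == pm["-2", s], ,
                 drop = FALSE]
    side <- res[!(res$name %in% backbone), , drop = FALSE]
    if (nrow(side) == 0) side <- res # Gly-like: fall back to backbone
    if (nrow(side) == 0) {
      stop("missing -2' residue on chain ", s)
    }
    colMeans(as.matrix(side[, c("x", "y", "z")]))
  }, numeric(3)))
  dmat <- as.matrix(dist(cent))
  # greedy minimum-distance matching under the contact cutoff
  free <- su
  pairs <- list()
  repeat {
    if (length(free) < 2) break
    sub <- dmat[free, free]
    sub[upper.tri(sub, diag = TRUE)] <- Inf
    if (min(sub) >= cutoff) break
    ij <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    pairs[[length(pairs) + 1]] <- sort(c(free[ij[1]], free[ij[2]]))
    free <- setdiff(free, pairs[[length(pairs)]])
  }
  axis_d <- lateral_distances(model, cent)
  cv <- sd(axis_d) / mean(axis_d)
  structure(
    list(
      partition = c(pairs, as.list(free)),
      pairs = pairs,
      singletons = free,
      asymmetric = (cv > cv_threshold) || length(pairs) > 0,
      axis_distances = setNames(axis_d, su),
      cv = cv
    ),
    class = "proline_pairing"
  )
}

#' Representative frame of a trajectory
#'
#' Frames are superposed over the C-alpha selection, the time-average
#' coordinates are formed, and the frame with minimal C-alpha RMSD to that
#' average is returned (earliest frame on ties).
#'
#' @param traj A `pore_trajectory` with at least 2 frames.
#' @param selection C-alpha atom indices (default: atoms named CA).
#' @return List: `frame` (0-based index), `rmsd` (Angstrom to the average),
#'   `rmsd_all` (per frame).
#' @export
representative_frame <- function(traj, selection = NULL) {
  if (is.null(selection)) {
    selection <- select_atoms(traj, name = "CA")
  }
  if (length(selection) == 0) {
    stop("empty C-alpha selection")
  }
  if (n_frames(traj) < 2) {
    stop("representative frame needs at least 2 frames")
  }
  xyz <- .align_frames(.xyz_matrix(traj, selection), 1)
  avg <- colMeans(xyz)
  rmsd <- apply(xyz, 1, function(row) {
    sqrt(mean(rowSums(matrix(row - avg, ncol = 3, byrow = TRUE)^2)))
  })
  best <- which(rmsd <= min(rmsd) + 1e-9)[1] # earliest frame on ties
  list(frame = best - 1L, rmsd = rmsd[best], rmsd_all = rmsd)
}
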