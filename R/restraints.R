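# Flat-bottom cross-pore restraints, ligand tethers and the staged
# equilibration schedule.
#
# Force constants are stored in kJ mol^-1 nm^-2: a half-harmonic
# V = 1/2 k (d - d0)^2 exerts a force proportional to the distance
# difference, |F| = k |d - d0|, so with k = 5000 kJ mol^-1 nm^-2 the force
# 0.1 nm inside the boundary is 500 kJ mol^-1 nm^-1. Distances are kept in
# Angstrom internally and emitted in nm.

#' Build flat-bottom cross-pore restraints
#'
#' For each primed pore-lining position, the C-alpha atoms of the five
#' non-adjacent subunit pairs (i, i+2 in rotational order — the pentagon
#' diagonals) are restrained with a lower-side flat bottom: the potential
#' acts only when the pair comes closer than its distance `d0` in the
#' open-state reference structure. With the 7 standard primed positions this
#' yields 7 x 5 = 35 restraints.
#'
#' @param model `channel_model` the restraints will act on (atom numbers are
#'   taken from it).
#' @param reference `channel_model` supplying the open-state distances;
#'   defaults to `model` itself.
#' @param k Force constant, kJ mol^-1 nm^-2 (default 5000).
#' @return A `restraint_set`: data frame with one row per restraint
#'   (`position`, `chain_i`, `chain_j`, `atom_i`, `atom_j`, `d0` in
#'   Angstrom, `k`, `side`).
#' @export
build_pore_restraints <- function(model, reference = model, k = 5000) {
  for (m in list(model, reference)) {
    if (is.null(m$primed_map) || is.null(m$subunit_order)) {
      stop("configuration error: both models need primed positions and axis")
    }
  }
  if (!identical(rownames(model$primed_map), rownames(reference$primed_map))) {
    stop("configuration error: primed maps of model and reference differ")
  }
  ord <- model$subunit_order
  if (length(ord) != 5) {
    stop("configuration error: pore restraints require a pentamer")
  }
  pos <- as.integer(rownames(model$primed_map))
  rows <- list()
  for (p in pos) {
    ca_m <- .ring_ca(model, p)
    ca_r <- .ring_ca(reference, p)
    for (i in seq_len(5)) {
      ci <- ord[i]
      cj <- ord[(i + 1) %% 5 + 1] # i+2 in cyclic order
      # deterministic tie-break: sorted subunit id
      pair <- sort(c(ci, cj))
      ai <- ca_m[match(pair[1], ca_m$chain), ]
      aj <- ca_m[match(pair[2], ca_m$chain), ]
      ri <- ca_r[match(pair[1], ca_r$chain), ]
      rj <- ca_r[match(pair[2], ca_r$chain), ]
      d0 <- sqrt(sum((c(ri$x, ri$y, ri$z) - c(rj$x, rj$y, rj$z))^2))
      rows[[length(rows) + 1]] <- data.frame(
        position = p, chain_i = pair[1], chain_j = pair[2],
        resno_i = ai$resno, resno_j = aj$resno,
        atom_i = ai$eleno, atom_j = aj$eleno,
        d0 = d0, k = k, side = "lower",
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[, c("position", "chain_i", "chain_j")]), ]
  rownames(out) <- NULL
  if (any(out$d0 <= 0)) {
    stop("configuration error: coincident reference CA atoms (d0 = 0)")
  }
  class(out) <- c("restraint_set", "data.frame")
  attr(out, "provenance") <- list(positions = pos, k = k)
  out
}

#' Evaluate a flat-bottom restraint
#'
#' Lower-side (`side = "lower"`): `V = 1/2 k (d0 - d)^2` for `d < d0`, else
#' 0 — the restraint pushes the pair apart when it comes closer than the
#' reference. Upper-side (`side = "upper"`): harmonic for `d > d0`, used for
#' ligand tethers. Energy is C1-continuous at the boundary.
#'
#' @param d Distance(s), Angstrom.
#' @param d0 Reference (boundary) distance, Angstrom.
#' @param k Force constant, kJ mol^-1 nm^-2.
#' @param side `"lower"` or `"upper"`.
#' @return List with `energy` (kJ mol^-1) and `force` (magnitude,
#'   kJ mol^-1 nm^-1), each the length of `d`.
#' @export
#' @examples
#' evaluate_flat_bottom(d = 9, d0 = 10, k = 5000) # 1 A inside: V = 25
evaluate_flat_bottom <- function(d, d0, k, side = c("lower", "upper")) {
  side <- match.arg(side)
  if (any(d < 0)) {
    stop("distances must be non-negative")
  }
  delta_nm <- (d0 - d) / 10
  active <- if (side == "lower") d < d0 else d > d0
  energy <- ifelse(active, 0.5 * k * delta_nm^2, 0)
  force <- ifelse(active, k * abs(delta_nm), 0)
  list(energy = energy, force = force)
}

#' Staged initial equilibration schedule
#'
#' The seven-stage position-restraint schedule used before the pore-restraint
#' phase: a short NVT stage followed by NPT stages during which the
#' restrained selection is relaxed from all heavy atoms to the backbone and
#' the force constant is stepped down 1024 -> 64.
#'
#' @return Data frame with one row per stage: `stage`, `duration_ps`,
#'   `ensemble`, `restrained_selection`, `force_constant` (printed unit
#'   kJ mol^-1 nm^-1; see Details).
#' @details The stage force constants act in harmonic position restraints
#'   and are therefore dimensionally kJ mol^-1 nm^-2; the printed label
#'   kJ mol^-1 nm^-1 (force per unit displacement) is retained in the column
#'   name used on output.
#' @export
build_equilibration_schedule <- function() {
  heavy <- "protein heavy atoms, ligand heavy atoms, crystal water oxygen"
  backbone <- "protein backbone, ligand Ca atom, crystal water oxygen"
  out <- data.frame(
    stage = 1:7,
    duration_ps = c(100, 1000, 10000, 1000, 1000, 1000, 1000),
    ensemble = c("NVT", rep("NPT", 6)),
    restrained_selection = c(heavy, heavy, rep(backbone, 5)),
    force_constant = c(1000, 1000, 1024, 512, 256, 128, 64),
    stringsAsFactors = FALSE
  )
  class(out) <- c("equilibration_schedule", "data.frame")
  out
}

#' Default glycine-receptor ligand tether specification
#'
#' Anchor residues and threshold distances for tethering the glycine ligand
#' in each orthosteric site: the restraint acts when the ligand C-alpha
#' moves further from the anchor C-alpha than the threshold.
#'
#' @return Data frame with `anchor` (label), `interface` (`+` principal /
#'   `-` complementary), `resid`, `resno`, `threshold` (Angstrom).
#' @export
glyr_tether_spec <- function() {
  data.frame(
    anchor = c("(+)F207", "(-)F63", "(-)S129"),
    interface = c("+", "-", "-"),
    resid = c("PHE", "PHE", "SER"),
    resno = c(207L, 63L, 129L),
    threshold = c(10.60, 10.53, 9.15),
    stringsAsFactors = FALSE
  )
}

#' Build ligand tethers for one binding site
#'
#' Upper-side flat-bottom restraints between the ligand C-alpha and the
#' C-alpha of each anchor residue; zero inside the threshold, harmonic
#' beyond it.
#'
#' @param model Optional `channel_model`; when given, each anchor residue
#'   must resolve to a C-alpha on the stated chain.
#' @param site_spec Data frame as [glyr_tether_spec()]; needs columns
#'   `resno` and `threshold`, plus `chain` when `model` is given.
#' @param ligand_atom Identifier of the ligand C-alpha atom (atom serial or
#'   label; passed through).
#' @param k Force constant, kJ mol^-1 nm^-2.
#' @return Data frame of tethers (`ligand_atom`, `anchor`, `threshold`, `k`,
#'   `side = "upper"`).
#' @export
build_ligand_tethers <- function(model = NULL, site_spec = glyr_tether_spec(),
                                 ligand_atom = "LIG:CA", k = 5000) {
  if (!all(c("resno", "threshold") %in% names(site_spec))) {
    stop("configuration error: site_spec needs resno and threshold columns")
  }
  anchor_atom <- rep(NA_integer_, nrow(site_spec))
  if (!is.null(model)) {
    a <- model$atoms
    for (i in seq_len(nrow(site_spec))) {
      ch <- if (!is.null(site_spec$chain)) site_spec$chain[i] else a$chain[1]
      hit <- which(a$chain == ch & a$resno == site_spec$resno[i] &
                     a$name == "CA")
      if (length(hit) == 0) {
        stop("configuration error: anchor residue ", site_spec$resno[i],
             " (chain ", ch, ") has no CA atom")
      }
      anchor_atom[i] <- a$eleno[hit[1]]
    }
  }
  lbl <- if (!is.null(site_spec$anchor)) site_spec$anchor
         else paste0("res", site_spec$resno)
  data.frame(
    ligand_atom = ligand_atom, anchor = lbl, anchor_atom = anchor_atom,
    resno = site_spec$resno, threshold = site_spec$threshold,
    k = k, side = "upper", stringsAsFactors = FALSE
  )
}

#' Write restraints as a GROMACS topology fragment
#'
#' Emits `[ bonds ]` function-type-10 restraint lines. A lower-side flat
#' bottom at `d0` is encoded as `low = d0`, `up1 = up2 = 99.9 nm` (harmonic
#' below `low`, flat above); an upper-side tether as `low = 0`,
#' `up1 = threshold` with `up2` far beyond. Distances are written in nm at 4
#' decimals.
#'
#' @param set A `restraint_set` or a tether table from
#'   [build_ligand_tethers()].
#' @param path Output `.itp` path.
#' @return `path`, invisibly.
#' @export
write_restraints_itp <- function(set, path) {
  if (is.null(set) || nrow(set) == 0) {
    stop("refusing to write an empty restraint set")
  }
  upper <- !is.null(set$side) && all(set$side == "upper")
  hdr <- c(
    "; flat-bottom restraints written by porelock",
    "; ai  aj  funct  low(nm)  up1(nm)  up2(nm)  k(kJ/mol/nm2)",
    "[ bonds ]"
  )
  if (upper) {
    ai <- ifelse(is.na(set$anchor_atom), 0L, set$anchor_atom)
    lines <- sprintf("%6d %6d  10  %8.4f %8.4f %8.4f %10.1f ; %s",
                     ai, seq_len(nrow(set)), 0,
                     set$threshold / 10, set$threshold / 10 + 89.9,
                     set$k, set$anchor)
  } else {
    lines <- sprintf("%6d %6d  10  %8.4f %8.4f %8.4f %10.1f ; %d' %s-%s",
                     set$atom_i, set$atom_j, set$d0 / 10, 99.9, 99.9,
                     set$k, set$position, set$chain_i, set$chain_j)
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read back a pore restraint topology fragment
#'
#' Inverse of [write_restraints_itp()] for lower-side pore restraint sets.
#'
#' @param path `.itp` path written by this package.
#' @return A `restraint_set` (atom ids, `d0` in Angstrom, `k`, and the
#'   position/chain annotations recovered from the line comments).
#' @export
read_restraints_itp <- function(path) {
  lines <- readLines(path)
  data_lines <- grep("^\\s*\\d+\\s+\\d+\\s+10\\s", lines, value = TRUE)
  if (length(data_lines) == 0) {
    stop("no type-10 restraint lines found in ", path)
  }
  parts <- strsplit(sub("\\s*;\\s*", ";", data_lines), ";")
  num <- lapply(parts, function(p) as.numeric(strsplit(trimws(p[1]),
                                                       "\\s+")[[1]]))
  ann <- vapply(parts, function(p) if (length(p) > 1) p[2] else "",
                character(1))
  annm <- regmatches(ann, regexec("^(-?\\d+)' (\\S+)-(\\S+)$", ann))
  out <- data.frame(
    position = vapply(annm, function(m) {
      if (length(m) == 4) as.integer(m[2]) else NA_integer_
    }, integer(1)),
    chain_i = vapply(annm, function(m) {
      if (length(m) == 4) m[3] else NA_character_
    }, character(1)),
    chain_j = vapply(annm, function(m) {
      if (length(m) == 4) m[4] else NA_character_
    }, character(1)),
    atom_i = vapply(num, function(v) as.integer(v[1]), integer(1)),
    atom_j = vapply(num, function(v) as.integer(v[2]), integer(1)),
    d0 = vapply(num, function(v) v[4] * 10, numeric(1)),
    k = vapply(num, function(v) v[7], numeric(1)),
    side = "lower",
    stringsAsFactors = FALSE
  )
  class(out) <- c("restraint_set", "data.frame")
  out
}

#' Write restraints as TSV
#'
#' @param set A `restraint_set` or tether table.
#' @param path Output `.tsv` path.
#' @return `path`, invisibly.
#' @export
write_restraints_tsv <- function(set, path) {
  if (is.null(set) || nrow(set) == 0) {
    stop("refusing to write an empty restraint set")
  }
  write.table(as.data.frame(set), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read restraints from TSV
#' @param path `.tsv` path written by [write_restraints_tsv()].
#' @return A `restraint_set`.
#' @export
read_restraints_tsv <- function(path) {
  out <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  class(out) <- c("restraint_set", "data.frame")
  out
}

#' Write the equilibration schedule as MDP fragments + index table
#'
#' Per stage, an `.mdp` fragment carrying only the schedule-relevant keys
#' (`define` macro for the stage's position-restraint strength, `nsteps`,
#' `dt`, `pcoupl`) plus a position-restraint include fragment stating the
#' restrained selection and force constant; a `schedule.tsv` table indexes
#' the stages and is what [read_equilibration_schedule()] parses back.
#'
#' @param schedule From [build_equilibration_schedule()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_schedule_files <- function(schedule, dir) {
  if (is.null(schedule) || nrow(schedule) == 0) {
    stop("refusing to write an empty schedule")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(schedule))) {
    st <- schedule[i, ]
    dt <- if (st$ensemble == "NVT") 0.001 else 0.002 # ps
    mdp <- c(
      sprintf("; stage %d: %s ps %s, posres k = %g", st$stage,
              format(st$duration_ps), st$ensemble, st$force_constant),
      sprintf("define                   = -DPOSRES_STAGE%d", st$stage),
      sprintf("dt                       = %.3f", dt),
      sprintf("nsteps                   = %d",
              as.integer(round(st$duration_ps / dt))),
      sprintf("pcoupl                   = %s",
              if (st$ensemble == "NPT") "berendsen" else "no")
    )
    writeLines(mdp, file.path(dir, sprintf("stage_%d.mdp", st$stage)))
    itp <- c(
      sprintf("; stage %d position restraints: %s", st$stage,
              st$restrained_selection),
      sprintf("#ifdef POSRES_STAGE%d", st$stage),
      sprintf("; apply to: %s", st$restrained_selection),
      sprintf("; force constant %g kJ mol^-1 nm^-1 (isotropic)",
              st$force_constant),
      "#endif"
    )
    writeLines(itp, file.path(dir, sprintf("posre_stage_%d.itp", st$stage)))
  }
  write.table(schedule, file.path(dir, "schedule.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read an emitted schedule back
#' @param dir Directory written by [write_schedule_files()].
#' @return An `equilibration_schedule` data frame.
#' @export
read_equilibration_schedule <- function(dir) {
  path <- file.path(dir, "schedule.tsv")
  if (!file.exists(path)) {
    stop("no schedule.tsv under ", dir)
  }
  out <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  class(out) <- c("equilibration_schedule", "data.frame")
  out
}
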