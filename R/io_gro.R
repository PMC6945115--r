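# GROMACS .gro coordinate files. Fixed-width records:
#   resno(5) resname(5) atomname(5) atomno(5) x(8.3) y(8.3) z(8.3) [velocities]
# positions in nm; converted to/from Angstrom at the boundary. No R package
# in the stack reads GRO, so the format is handled here directly.

#' Read a GROMACS .gro coordinate file
#'
#' Coordinates are converted from nm to Angstrom. GRO carries no chain
#' field; subunits are inferred as contiguous stretches of non-decreasing
#' residue numbers and labelled `A`, `B`, ...
#'
#' @param path File path.
#' @return A `channel_model` (box vector, Angstrom, stored as attribute
#'   `box` on the atom table).
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) {
    stop("failed to parse GRO file '", path, "': truncated")
  }
  natoms <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(natoms) || length(lines) < 2 + natoms + 1) {
    stop("failed to parse GRO file '", path,
         "': bad atom count or truncated body")
  }
  body <- lines[3:(2 + natoms)]
  resno <- suppressWarnings(as.integer(substr(body, 1, 5)))
  resid <- trimws(substr(body, 6, 10))
  name <- trimws(substr(body, 11, 15))
  eleno <- suppressWarnings(as.integer(substr(body, 16, 20)))
  x <- suppressWarnings(as.numeric(substr(body, 21, 28))) * 10
  y <- suppressWarnings(as.numeric(substr(body, 29, 36))) * 10
  z <- suppressWarnings(as.numeric(substr(body, 37, 44))) * 10
  if (anyNA(resno) || anyNA(x) || anyNA(y) || anyNA(z)) {
    stop("failed to parse GRO file '", path, "': malformed atom record")
  }
  # new subunit whenever the residue number decreases
  drops <- c(FALSE, diff(resno) < 0)
  chain_idx <- cumsum(drops) + 1
  if (max(chain_idx) > 26) {
    stop("failed to parse GRO file '", path, "': too many inferred chains")
  }
  atoms <- data.frame(
    eleno = eleno, name = name, resid = resid, resno = resno,
    chain = LETTERS[chain_idx], x = x, y = y, z = z,
    stringsAsFactors = FALSE
  )
  box <- suppressWarnings(as.numeric(strsplit(trimws(lines[2 + natoms + 1]),
                                              "\\s+")[[1]])) * 10
  attr(atoms, "box") <- box[1:3]
  model <- channel_model(atoms)
  model
}

#' Write a GROMACS .gro coordinate file
#'
#' Coordinates are converted from Angstrom to nm and written at GRO's
#' native %8.3f precision (0.001 nm quantization).
#'
#' @param model A `channel_model` (or anything with a compatible `$atoms`
#'   table).
#' @param path Output path.
#' @param box Box vector in Angstrom (3 values); defaults to the atom
#'   table's `box` attribute or a bounding box with 10 A margin.
#' @param title Title line.
#' @return `path`, invisibly.
#' @export
write_gro <- function(model, path, box = NULL, title = "written by porelock") {
  a <- model$atoms
  if (is.null(box)) {
    box <- attr(a, "box")
  }
  if (is.null(box)) {
    box <- c(diff(range(a$x)), diff(range(a$y)), diff(range(a$z))) + 20
  }
  lines <- c(
    title,
    sprintf("%5d", nrow(a)),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
            a$resno %% 100000, substr(a$resid, 1, 5), substr(a$name, 1, 5),
            a$eleno %% 100000, a$x / 10, a$y / 10, a$z / 10),
    sprintf("%10.5f%10.5f%10.5f", box[1] / 10, box[2] / 10, box[3] / 10)
  )
  writeLines(lines, path)
  invisible(path)
}
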