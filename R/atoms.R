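#' Atomic configuration
#'
#' The universal currency of the pipeline: a set of atoms with chemical
#' symbols and Cartesian positions (Angstrom), optionally in a periodic
#' (orthorhombic) cell, optionally carrying an energy (eV), forces (eV/A)
#' and a virial tensor (eV), plus free-form provenance in `info`.
#'
#' @param elements character vector of chemical symbols
#' @param positions numeric N x 3 matrix, Angstrom
#' @param cell 3 x 3 cell matrix (rows are lattice vectors), a single cubic
#'   edge length, or `NULL` for an open-boundary cluster
#' @param periodic logical; defaults to `TRUE` when a cell is given
#' @param energy optional total energy, eV
#' @param forces optional N x 3 matrix, eV/A
#' @param virial optional 3 x 3 matrix, eV
#' @param info named list of provenance tags (level label, carve radius,
#'   source frame, ...)
#' @return an object of class `atoms`
#' @export
atoms <- function(elements, positions, cell = NULL, periodic = !is.null(cell),
                  energy = NULL, forces = NULL, virial = NULL, info = list()) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must be an N x 3 matrix")
  n <- nrow(positions)
  if (length(elements) != n) stop("length(elements) must match nrow(positions)")
  if (!all(is.finite(positions))) stop("positions must be finite")
  if (!is.null(cell)) {
    if (length(cell) == 1) cell <- diag(3) * cell
    cell <- as.matrix(cell)
    if (!all(dim(cell) == c(3, 3))) stop("cell must be 3 x 3")
    if (abs(det(cell)) < 1e-10) stop("periodic configuration requires a nonsingular cell")
  } else if (periodic) {
    stop("periodic = TRUE requires a cell")
  }
  if (!is.null(forces)) {
    forces <- as.matrix(forces)
    if (!all(dim(forces) == c(n, 3)))
      stop("forces must have the same shape as positions")
  }
  structure(list(elements = as.character(elements), positions = positions,
                 cell = cell, periodic = isTRUE(periodic), energy = energy,
                 forces = forces, virial = virial, info = info),
            class = "atoms")
}

#' @export
print.atoms <- function(x, ...) {
  cat(sprintf("<atoms: %d atoms (%s)%s%s>\n", length(x$elements),
              paste(names(table(x$elements)), table(x$elements),
                    sep = "", collapse = " "),
              if (x$periodic) sprintf(", cubic cell %.3f A", cell_edge(x)) else ", open",
              if (!is.null(x$energy)) sprintf(", E = %.6f eV", x$energy) else ""))
  invisible(x)
}

#' @export
length.atoms <- function(x) length(x$elements)

# cubic edge of an orthorhombic cell; errors on non-orthorhombic input
#' Cubic cell edge of a periodic configuration
#' @param cfg an [atoms()] object with a cell
#' @return the cell edge in Angstrom
#' @export
cell_edge <- function(cfg) {
  cell <- if (inherits(cfg, "atoms")) cfg$cell else as.matrix(cfg)
  if (is.null(cell)) stop("configuration has no cell")
  .check_orthorhombic(cell)
  d <- diag(cell)
  if (max(abs(d - d[1])) > 1e-9 * d[1])
    stop("cell is orthorhombic but not cubic; cubic cells are required here")
  d[1]
}

.check_orthorhombic <- function(cell) {
  off <- cell; diag(off) <- 0
  if (any(abs(off) > 1e-10))
    stop("unsupported cell: only orthorhombic (diagonal) cells are handled")
  invisible(TRUE)
}

#' Minimum-image convention for orthorhombic cells
#'
#' Maps displacement components into `[-L/2, L/2)` for each cell direction.
#'
#' @param d a displacement vector of length 3 or an N x 3 matrix, Angstrom
#' @param cell a 3 x 3 orthorhombic cell matrix or a single cubic edge
#' @return the displacement(s) folded to the nearest periodic image
#' @export
minimum_image <- function(d, cell) {
  if (length(cell) == 1) cell <- diag(3) * cell
  cell <- as.matrix(cell)
  .check_orthorhombic(cell)
  L <- diag(cell)
  if (is.matrix(d)) {
    Lr <- matrix(L, nrow(d), 3, byrow = TRUE)
    d - Lr * floor(d / Lr + 0.5)
  } else {
    d - L * floor(d / L + 0.5)
  }
}

#' Identify water molecules in a configuration
#'
#' Assigns every H to its nearest O within `oh_cut` (under minimum image for
#' periodic input) and checks that each O acquires exactly two H.  For
#' configurations without hydrogen every atom forms its own single-atom
#' molecule (used e.g. for ideal-gas runs).
#'
#' @param cfg an [atoms()] object containing only O and H (or no H)
#' @param oh_cut O-H bond search cutoff, Angstrom (default 1.2)
#' @return an object of class `molecule_topology`: `mol` (1-based molecule
#'   index per atom), `n_mol`, `o_index` (reference O atom per molecule, the
#'   carving anchor), `h_index` (2-column matrix of H atoms per molecule,
#'   or NULL for monatomic species)
#' @export
identify_molecules <- function(cfg, oh_cut = 1.2) {
  el <- cfg$elements
  if (!all(el %in% c("O", "H")))
    stop("identify_molecules handles O/H (water) systems only")
  n <- length(el)
  io <- which(el == "O"); ih <- which(el == "H")
  if (length(ih) == 0) {
    return(structure(list(mol = seq_len(n), n_mol = n,
                          o_index = seq_len(n), h_index = NULL),
                     class = "molecule_topology"))
  }
  if (length(io) == 0) stop("hydrogens present but no oxygen")
  po <- cfg$positions[io, , drop = FALSE]
  ph <- cfg$positions[ih, , drop = FALSE]
  # all O-H distances at once (minimum image per component when periodic)
  L <- if (cfg$periodic) diag(cfg$cell) else NULL
  d2 <- matrix(0, nrow(po), nrow(ph))
  for (k in 1:3) {
    dk <- outer(po[, k], ph[, k], "-")
    if (!is.null(L)) dk <- dk - L[k] * floor(dk / L[k] + 0.5)
    d2 <- d2 + dk * dk
  }
  assign_o <- max.col(-t(d2))
  rmin <- sqrt(d2[cbind(assign_o, seq_along(ih))])
  if (any(rmin > oh_cut)) {
    k <- which(rmin > oh_cut)[1]
    stop(sprintf("H atom %d has no O within %.2f A", ih[k], oh_cut))
  }
  counts <- tabulate(assign_o, nbins = length(io))
  if (any(counts != 2)) {
    bad <- which(counts != 2)
    stop(sprintf("broken water topology: O atom(s) %s have %s H within %.2f A",
                 paste(io[bad], collapse = ","),
                 paste(counts[bad], collapse = ","), oh_cut))
  }
  mol <- integer(n)
  mol[io] <- seq_along(io)
  mol[ih] <- assign_o
  h_index <- t(vapply(seq_along(io), function(m) ih[assign_o == m],
                      integer(2)))
  structure(list(mol = mol, n_mol = length(io), o_index = io,
                 h_index = h_index),
            class = "molecule_topology")
}

# integer element codes for the compiled layer
.elem_codes <- function(elements) {
  z <- c(H = 1L, O = 8L)[elements]
  if (anyNA(z)) stop("only O and H are supported by the potentials")
  unname(z)
}

#' Trajectory of atomic configurations
#'
#' @param frames list of [atoms()] objects sharing one element ordering
#' @param dt_fs time between stored frames, fs (NA if not a time series)
#' @param ensemble one of "nve", "nvt", "npt" or "unknown"
#' @param series optional per-step scalar data.frame (T, P, E, V, ...)
#' @param meta named list of run metadata (seed, config, ...)
#' @return an object of class `md_trajectory`
#' @export
trajectory <- function(frames, dt_fs = NA_real_, ensemble = "unknown",
                       series = NULL, meta = list()) {
  if (length(frames) == 0) stop("trajectory needs at least one frame")
  el <- frames[[1]]$elements
  for (f in frames)
    if (!identical(f$elements, el))
      stop("all frames must share the same element ordering")
  if (ensemble == "npt")
    for (f in frames)
      if (is.null(f$cell)) stop("NPT trajectory requires a per-frame cell")
  structure(list(frames = frames, dt_fs = dt_fs, ensemble = ensemble,
                 series = series, meta = meta),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("<md_trajectory: %d frames x %d atoms, ensemble %s, dt %.4g fs>\n",
              length(x$frames), length(x$frames[[1]]$elements),
              x$ensemble, x$dt_fs))
  invisible(x)
}

#' @export
length.md_trajectory <- function(x) length(x$frames)
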