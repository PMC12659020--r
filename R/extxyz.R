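# Extended-XYZ I/O (ase dialect): Lattice="..." Properties=species:S:1:pos:R:3
# [:forces:R:3] energy=... pbc="T T T" in the comment line.  Floats are
# written with 10 significant digits in a fixed column order so fixture
# files are byte-for-byte reproducible.

.parse_comment <- function(line) {
  m <- gregexpr('([A-Za-z_][A-Za-z0-9_]*)=("[^"]*"|\\S+)', line)[[1]]
  out <- list()
  if (m[1] == -1) return(out)
  for (k in seq_along(m)) {
    tok <- substr(line, m[k], m[k] + attr(m, "match.length")[k] - 1)
    eq <- regexpr("=", tok)
    key <- substr(tok, 1, eq - 1)
    val <- substr(tok, eq + 1, nchar(tok))
    val <- gsub('^"|"$', "", val)
    out[[key]] <- val
  }
  out
}

.parse_properties <- function(propstr) {
  toks <- strsplit(propstr, ":")[[1]]
  if (length(toks) %% 3 != 0) stop("malformed Properties string: ", propstr)
  data.frame(name = toks[seq(1, length(toks), 3)],
             type = toks[seq(2, length(toks), 3)],
             ncol = as.integer(toks[seq(3, length(toks), 3)]),
             stringsAsFactors = FALSE)
}

#' Read an extended-XYZ file
#'
#' Parses one or more frames in the ase extended-XYZ dialect.  Cell, energy,
#' forces and any extra scalar keys on the comment line (e.g. a
#' `delta_energy` label) are recovered; the periodic flag is set from the
#' presence of a `Lattice` entry.
#'
#' @param path path to an (uncompressed) extended-XYZ file
#' @return an `md_trajectory` whose frames are [atoms()] objects; if the
#'   frames do not share one element ordering (e.g. a cluster dataset of
#'   varying sizes), a `configuration_set` with the same `$frames` field
#' @export
read_extxyz <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  frames <- list()
  i <- 1L; fidx <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    fidx <- fidx + 1L
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n <= 0)
      stop(sprintf("frame %d: invalid atom count header '%s'", fidx, lines[i]))
    if (i + 1L + n > length(lines))
      stop(sprintf("frame %d: truncated (expected %d atom lines)", fidx, n))
    kv <- .parse_comment(lines[i + 1L])
    props <- if (!is.null(kv$Properties)) .parse_properties(kv$Properties)
             else data.frame(name = c("species", "pos"), type = c("S", "R"),
                             ncol = c(1L, 3L), stringsAsFactors = FALSE)
    body <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(body), "\\s+")
    ntok <- sum(props$ncol)
    if (any(vapply(toks, length, 1L) != ntok))
      stop(sprintf("frame %d: atom lines do not match Properties layout", fidx))
    tab <- matrix(unlist(toks), nrow = n, byrow = TRUE)
    col <- 1L; elements <- NULL; positions <- NULL; forces <- NULL
    for (p in seq_len(nrow(props))) {
      idx <- col:(col + props$ncol[p] - 1L)
      blk <- tab[, idx, drop = FALSE]
      if (props$name[p] == "species") elements <- blk[, 1]
      else if (props$name[p] == "pos")
        positions <- matrix(as.numeric(blk), ncol = 3)
      else if (props$name[p] == "forces")
        forces <- matrix(as.numeric(blk), ncol = 3)
      col <- col + props$ncol[p]
    }
    if (is.null(elements) || is.null(positions))
      stop(sprintf("frame %d: missing species/pos columns", fidx))
    cell <- NULL
    if (!is.null(kv$Lattice)) {
      lv <- as.numeric(strsplit(trimws(kv$Lattice), "\\s+")[[1]])
      if (length(lv) != 9) stop(sprintf("frame %d: malformed Lattice", fidx))
      cell <- matrix(lv, nrow = 3, byrow = TRUE)
    }
    energy <- if (!is.null(kv$energy)) as.numeric(kv$energy) else NULL
    info <- list()
    for (key in setdiff(names(kv), c("Lattice", "Properties", "energy", "pbc"))) {
      num <- suppressWarnings(as.numeric(kv[[key]]))
      info[[key]] <- if (!is.na(num)) num else kv[[key]]
    }
    frames[[fidx]] <- atoms(elements, positions, cell = cell,
                            periodic = !is.null(cell), energy = energy,
                            forces = forces, info = info)
    i <- i + 2L + n
  }
  if (fidx == 0L) stop("no frames found in ", path)
  el <- frames[[1]]$elements
  homogeneous <- all(vapply(frames, function(f) identical(f$elements, el), TRUE))
  if (homogeneous) return(trajectory(frames))
  structure(list(frames = frames), class = "configuration_set")
}

#' @export
print.configuration_set <- function(x, ...) {
  cat(sprintf("<configuration_set: %d configurations of varying size>\n",
              length(x$frames)))
  invisible(x)
}

#' @export
length.configuration_set <- function(x) length(x$frames)

.fmt <- function(x) sprintf("%.10g", x)

#' Write an extended-XYZ file
#'
#' Writes a trajectory, a list of [atoms()] or a single configuration in the
#' ase extended-XYZ dialect.  Open-boundary clusters omit the `Lattice`
#' entry; energies, forces and scalar `info` entries are written to the
#' comment line.  Output is bit-stable for fixed input.
#'
#' @param traj an `md_trajectory`, a list of [atoms()], or one [atoms()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_extxyz <- function(traj, path) {
  frames <- if (inherits(traj, "md_trajectory")) traj$frames
            else if (inherits(traj, "atoms")) list(traj)
            else traj
  if (length(frames) == 0) stop("cannot write an empty trajectory")
  el <- frames[[1]]$elements
  con <- file(path, "w"); on.exit(close(con))
  for (f in frames) {
    if (!identical(f$elements, el))
      stop("frames with mismatched element lists cannot share one file")
    n <- length(f$elements)
    parts <- character(0)
    if (f$periodic) {
      parts <- c(parts, sprintf('Lattice="%s"',
                                paste(.fmt(as.vector(t(f$cell))), collapse = " ")))
    }
    hasF <- !is.null(f$forces)
    parts <- c(parts, sprintf("Properties=species:S:1:pos:R:3%s",
                              if (hasF) ":forces:R:3" else ""))
    if (!is.null(f$energy)) parts <- c(parts, sprintf("energy=%s", .fmt(f$energy)))
    for (key in names(f$info)) {
      v <- f$info[[key]]
      if (length(v) == 1 && (is.numeric(v) || is.character(v))) {
        vs <- if (is.numeric(v)) .fmt(v) else v
        if (grepl("\\s", vs)) vs <- sprintf('"%s"', vs)
        parts <- c(parts, sprintf("%s=%s", key, vs))
      }
    }
    parts <- c(parts, sprintf('pbc="%s"',
                              if (f$periodic) "T T T" else "F F F"))
    writeLines(c(as.character(n), paste(parts, collapse = " ")), con)
    for (i in seq_len(n)) {
      ln <- sprintf("%-2s %s %s %s", f$elements[i],
                    .fmt(f$positions[i, 1]), .fmt(f$positions[i, 2]),
                    .fmt(f$positions[i, 3]))
      if (hasF)
        ln <- paste(ln, .fmt(f$forces[i, 1]), .fmt(f$forces[i, 2]),
                    .fmt(f$forces[i, 3]))
      writeLines(ln, con)
    }
  }
  invisible(path)
}
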