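#' Carving specification for cumulative cluster datasets
#'
#' Defines the radii and per-radius draw counts used to carve whole-molecule
#' clusters from periodic snapshots.  The default radii follow the
#' cumulative-dataset construction (2.5, 3.5, 4.5, 5.5 A); the geometric
#' precondition `max(radii) + margin < L/2` must hold for every source
#' frame so that the minimum-image carve is unambiguous and molecules stay
#' whole.
#'
#' @param radii strictly increasing carve radii, A
#' @param counts integer draws per radius (recycled if length 1)
#' @param seed integer seed for the (frame, centre) sampling
#' @param val_fraction validation fraction, stratified by radius
#' @param margin geometric safety margin added to the largest radius when
#'   validating the box size, A
#' @return an object of class `carve_spec`
#' @export
carve_spec <- function(radii = c(2.5, 3.5, 4.5, 5.5),
                       counts = rep(1800L, length(radii)),
                       seed = 1, val_fraction = 0.1, margin = 2.0) {
  if (length(counts) == 1) counts <- rep(counts, length(radii))
  stopifnot(length(counts) == length(radii), all(counts >= 0),
            all(diff(radii) > 0), val_fraction >= 0, val_fraction < 1)
  structure(list(radii = radii, counts = as.integer(counts), seed = seed,
                 val_fraction = val_fraction, margin = margin),
            class = "carve_spec")
}

#' @export
print.carve_spec <- function(x, ...) {
  cat(sprintf("<carve_spec: %s -> %d clusters, seed %d>\n",
              paste(sprintf("%.1fA:%d", x$radii, x$counts), collapse = " "),
              sum(x$counts), x$seed))
  invisible(x)
}

#' Compact-dataset variant of a carving specification
#'
#' Returns the specification with the largest-radius count reduced to
#' `compact_count` (default 100), the others unchanged; with the default
#' full specification of 1800 per radius this yields the 5500-cluster
#' compact dataset.  A `compact_count` above the current count is clamped
#' with a warning.
#'
#' @param spec a [carve_spec()]
#' @param compact_count clusters to keep at the largest radius
#' @return the modified `carve_spec`
#' @export
compact_mode <- function(spec, compact_count = 100L) {
  stopifnot(inherits(spec, "carve_spec"))
  k <- length(spec$counts)
  if (compact_count > spec$counts[k]) {
    warning("compact_count exceeds the full count; clamping")
    compact_count <- spec$counts[k]
  }
  spec$counts[k] <- as.integer(compact_count)
  spec
}

.carve_check_box <- function(L, r_c, margin) {
  if (r_c + margin >= L / 2)
    stop(sprintf("carve radius %.2f A too large for box edge %.3f A (need r + %.1f < L/2)",
                 r_c, L, margin))
}

#' Carve a whole-molecule cluster from a periodic frame
#'
#' Extracts the centre molecule plus every molecule whose O lies within
#' `r_c` (minimum-image O-O distance) of the centre O, unwraps the result
#' to a contiguous open-boundary geometry with the centre O at the origin,
#' and keeps molecules whole (each H placed via the minimum image relative
#' to its own O).  No rotational canonicalisation is applied.
#'
#' @param frame a periodic [atoms()] water configuration
#' @param center_mol 1-based index of the centre molecule
#' @param r_c carve radius, A
#' @param topology optional precomputed [identify_molecules()] result
#' @param margin geometric safety margin (see [carve_spec()])
#' @return an open-boundary [atoms()] cluster; `info` carries the radius,
#'   centre index and molecule count
#' @export
carve_cluster <- function(frame, center_mol, r_c, topology = NULL,
                          margin = 2.0) {
  topo <- .topology_for(frame, topology)
  L <- cell_edge(frame)
  .carve_check_box(L, r_c, margin)
  po <- frame$positions[topo$o_index, , drop = FALSE]
  oc <- po[center_mol, ]
  d <- minimum_image(sweep(po, 2, oc), frame$cell)
  keep <- which(sqrt(rowSums(d^2)) <= r_c)
  keep <- c(center_mol, setdiff(keep, center_mol)) # centre first
  pos <- matrix(0, 3 * length(keep), 3)
  for (k in seq_along(keep)) {
    m <- keep[k]
    o_rel <- minimum_image(po[m, ] - oc, frame$cell)
    hs <- topo$h_index[m, ]
    for (j in 1:2) {
      h_rel <- o_rel + minimum_image(frame$positions[hs[j], ] -
                                       frame$positions[topo$o_index[m], ],
                                     frame$cell)
      pos[3 * k - 3 + 1 + j, ] <- h_rel
    }
    pos[3 * k - 2, ] <- o_rel
  }
  atoms(rep(c("O", "H", "H"), length(keep)), pos,
        info = list(radius = r_c, center = center_mol,
                    n_mol = length(keep)))
}

#' Build a cumulative multi-radius cluster dataset
#'
#' For each radius in `spec`, draws `counts[r]` (frame, centre) pairs
#' uniformly without replacement (independently across radii) using the
#' spec's seed, and carves a cluster at that radius.  The union over radii
#' is cumulative by construction: many small clusters, few large ones.
#' A stratified validation split (fraction `val_fraction` per radius) is
#' assigned at build time.
#'
#' @param frames an `md_trajectory` or list of periodic [atoms()] frames
#' @param spec a [carve_spec()]
#' @return an object of class `cluster_dataset`: `clusters` (list of open
#'   [atoms()]), `manifest` (data.frame with radius, source frame, centre,
#'   molecule count, split), `labels` (NULL until [label_delta()])
#' @export
build_cluster_dataset <- function(frames, spec) {
  stopifnot(inherits(spec, "carve_spec"))
  if (inherits(frames, "md_trajectory")) frames <- frames$frames
  topos <- lapply(frames, identify_molecules)
  n_mol <- topos[[1]]$n_mol
  for (L in vapply(frames, cell_edge, 0))
    .carve_check_box(L, max(spec$radii), spec$margin)
  universe <- nrow(expand.grid(seq_along(frames), seq_len(n_mol)))
  clusters <- list(); rows <- list()
  for (ri in seq_along(spec$radii)) {
    r_c <- spec$radii[ri]; cnt <- spec$counts[ri]
    if (cnt == 0) next
    if (cnt > universe)
      stop(sprintf("insufficient source configurations: need %d (frame, centre) pairs at r = %.1f A, have %d",
                   cnt, r_c, universe))
    pick <- .with_seed(.derive_seed(spec$seed, ri), {
      sample.int(universe, cnt)
    })
    fr_id <- (pick - 1L) %% length(frames) + 1L
    ce_id <- (pick - 1L) %/% length(frames) + 1L
    for (k in seq_len(cnt)) {
      cl <- carve_cluster(frames[[fr_id[k]]], ce_id[k], r_c,
                          topology = topos[[fr_id[k]]], margin = spec$margin)
      cl$info$source_frame <- fr_id[k]
      clusters[[length(clusters) + 1L]] <- cl
      rows[[length(rows) + 1L]] <-
        data.frame(radius = r_c, frame = fr_id[k], center = ce_id[k],
                   n_mol = cl$info$n_mol)
    }
  }
  manifest <- do.call(rbind, rows)
  manifest$split <- "train"
  # stratified validation split: a random val_fraction within each radius
  if (spec$val_fraction > 0) {
    for (r_c in unique(manifest$radius)) {
      idx <- which(manifest$radius == r_c)
      nv <- round(spec$val_fraction * length(idx))
      if (nv > 0) {
        sel <- .with_seed(.derive_seed(spec$seed, 997L, match(r_c, spec$radii)),
                          sample(idx, nv))
        manifest$split[sel] <- "val"
      }
    }
  }
  structure(list(clusters = clusters, manifest = manifest, labels = NULL,
                 spec = spec),
            class = "cluster_dataset")
}

#' @export
print.cluster_dataset <- function(x, ...) {
  tab <- table(x$manifest$radius)
  cat(sprintf("<cluster_dataset: %d clusters (%s)%s>\n", length(x$clusters),
              paste(sprintf("%sA:%s", names(tab), tab), collapse = " "),
              if (is.null(x$labels)) ", unlabelled" else ", labelled"))
  invisible(x)
}

#' @export
length.cluster_dataset <- function(x) length(x$clusters)

#' Cumulative sub-dataset up to a radius
#'
#' Restricts a dataset to clusters carved at radii `<= r_max`.  Because the
#' per-radius draws are seeded independently by radius index, the result is
#' identical to building the dataset with the truncated specification -
#' so one carve-and-label pass serves every cumulative radius set.
#'
#' @param ds a `cluster_dataset`
#' @param r_max largest radius to keep, A
#' @return the restricted `cluster_dataset`
#' @export
subset_dataset <- function(ds, r_max) {
  stopifnot(inherits(ds, "cluster_dataset"))
  keep <- which(ds$manifest$radius <= r_max + 1e-9)
  if (!length(keep)) stop("no clusters at radius <= ", r_max)
  ds$clusters <- ds$clusters[keep]
  ds$manifest <- ds$manifest[keep, , drop = FALSE]
  rownames(ds$manifest) <- NULL
  if (!is.null(ds$labels)) ds$labels <- ds$labels[keep]
  ri <- ds$spec$radii <= r_max + 1e-9
  ds$spec$radii <- ds$spec$radii[ri]
  ds$spec$counts <- ds$spec$counts[ri]
  ds
}

#' Label a cluster dataset with two-level energy differences
#'
#' Sets each cluster's label to the energy difference between the high and
#' low level, `E_HL - E_LL`, evaluated on the open-boundary cluster.
#' Energies only: no force labels are stored, matching an energy-only
#' training protocol.
#'
#' @param ds a [build_cluster_dataset()] result
#' @param theory a [two_level_theory()]
#' @return the dataset with `labels` (eV) filled in
#' @export
label_delta <- function(ds, theory) {
  stopifnot(inherits(ds, "cluster_dataset"))
  labs <- vapply(seq_along(ds$clusters), function(i) {
    cl <- ds$clusters[[i]]
    res <- tryCatch({
      topo <- identify_molecules(cl)
      evaluate_potential(theory, cl, "HL", topo)$energy -
        evaluate_potential(theory, cl, "LL", topo)$energy
    }, error = function(e) {
      stop(sprintf("labelling failed for cluster %d (radius %.1f, frame %s, centre %s): %s",
                   i, ds$manifest$radius[i], ds$manifest$frame[i],
                   ds$manifest$center[i], conditionMessage(e)))
    })
    res
  }, 0)
  if (!all(is.finite(labs))) stop("non-finite labels produced")
  ds$labels <- labs
  ds
}

#' Write a cluster dataset as extended-XYZ plus a CSV manifest
#'
#' @param ds a `cluster_dataset`
#' @param xyz_path output extended-XYZ path (labels in a `delta_energy`
#'   comment field when present)
#' @param manifest_path output CSV manifest path
#' @return `xyz_path`, invisibly
#' @export
write_dataset <- function(ds, xyz_path, manifest_path) {
  frames <- lapply(seq_along(ds$clusters), function(i) {
    cl <- ds$clusters[[i]]
    if (!is.null(ds$labels)) cl$info$delta_energy <- ds$labels[i]
    cl
  })
  # clusters differ in size; write sequentially frame by frame
  con <- file(xyz_path, "w"); close(con)
  for (f in frames) {
    tmp <- tempfile(); write_extxyz(f, tmp)
    cat(readLines(tmp), file = xyz_path, sep = "\n", append = TRUE)
    unlink(tmp)
  }
  write.csv(ds$manifest, manifest_path, row.names = FALSE)
  invisible(xyz_path)
}
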