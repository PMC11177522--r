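#' Centre of gravity of an activation map
#'
#' Mass-weighted mean grid position of the 64 nRMS values:
#' `CoG = sum(AM[i,j] * (i,j)) / sum(AM[i,j])`. The i-coordinate runs
#' lateral to medial, the j-coordinate proximal to distal, both on the
#' 1..8 electrode scale.
#'
#' @param map An [activation_map()] (or an 8 x 8 non-negative matrix).
#' @return List with components `i` and `j`.
#' @export
cog <- function(map) {
  v <- if (inherits(map, "activation_map")) map$values else map
  s <- sum(v)
  if (!is.finite(s) || s <= 0)
    stop("undefined CoG: activation map has no positive mass")
  list(i = sum(row(v) * v) / s, j = sum(col(v) * v) / s)
}

# one geodesic dilation step: 3x3 (8-neighbourhood) or plus-shaped
# (4-neighbourhood) maximum filter, clipped under the mask
.geodesic_dilate <- function(marker, mask, connectivity) {
  nr <- nrow(marker); nc <- ncol(marker)
  out <- marker
  offs <- if (connectivity == 8) .neigh8 else .neigh4
  for (k in seq_len(nrow(offs))) {
    di <- offs[k, "di"]; dj <- offs[k, "dj"]
    src_i <- max(1, 1 - di):min(nr, nr - di)
    src_j <- max(1, 1 - dj):min(nc, nc - dj)
    shifted <- matrix(-Inf, nr, nc)
    shifted[src_i + di, src_j + dj] <- marker[src_i, src_j]
    out <- pmax(out, shifted)
  }
  pmin(out, mask)
}

#' Grayscale reconstruction by dilation
#'
#' Iterates geodesic dilation of `marker` under `mask` to its fixed point.
#' On an 8 x 8 grid this converges in a handful of sweeps.
#'
#' @param marker,mask Numeric matrices of equal size with `marker <= mask`.
#' @param connectivity 4 or 8 (default 8, the usual choice for image
#'   reconstruction).
#' @return The reconstructed matrix.
#' @export
reconstruct_by_dilation <- function(marker, mask, connectivity = 8) {
  stopifnot(all(dim(marker) == dim(mask)), all(marker <= mask + 1e-12))
  repeat {
    nxt <- .geodesic_dilate(marker, mask, connectivity)
    if (identical(nxt, marker)) return(nxt)
    marker <- nxt
  }
}

#' h-dome transform
#'
#' Extracts the "domes" of a grayscale image: local-maximum structures of
#' height at least `h`. Defined as `D_h(AM) = AM - R(AM - h | AM)` where `R`
#' is grayscale reconstruction by dilation of the marker `AM - h` under the
#' mask `AM`. The output is non-negative and bounded above by `h`.
#'
#' @param map An [activation_map()] or numeric matrix.
#' @param h Dome height in the same (absolute) units as the map.
#' @param connectivity Neighbourhood used for reconstruction.
#' @return Matrix of dome heights.
#' @export
hdome <- function(map, h, connectivity = 8) {
  v <- if (inherits(map, "activation_map")) map$values else map
  stopifnot(h > 0)
  v - reconstruct_by_dilation(v - h, v, connectivity)
}

#' Segmentation settings
#'
#' @param h Dome height as a fraction of the map's dynamic range
#'   (`max - min`); dimensionless so that it survives normalisation
#'   differences between subjects. On an 8 x 8 grid `h` must exceed the
#'   one-cell curvature drop of a realistic activation blob, otherwise the
#'   dome degenerates to single electrodes; the default 0.45 yields clusters
#'   of a handful of channels for blobs with SD near 1.2--1.3 electrode
#'   pitches.
#' @param opening_se Side of the square structuring element for the binary
#'   opening (2 by default; 3 annihilates realistic clusters on an 8 x 8
#'   grid).
#' @param connectivity 4 or 8, for component labelling and reconstruction.
#' @param dome_floor Strictly positive threshold at which the dome image is
#'   binarised (guards numerically-zero plateaus).
#' @return A `segmentation_settings` object.
#' @export
segmentation_settings <- function(h = 0.45, opening_se = 2L, connectivity = 4L,
                                  dome_floor = 1e-6) {
  stopifnot(h > 0, h < 1, opening_se %in% 1:3, connectivity %in% c(4L, 8L),
            dome_floor >= 0)
  structure(list(h = h, opening_se = as.integer(opening_se),
                 connectivity = as.integer(connectivity),
                 dome_floor = dome_floor),
            class = "segmentation_settings")
}

# binary opening with a k x k square SE: union of all k x k squares that fit
# entirely inside the foreground
.binary_opening <- function(bin, k) {
  if (k <= 1) return(bin)
  nr <- nrow(bin); nc <- ncol(bin)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr - k + 1)) for (j in seq_len(nc - k + 1)) {
    blk_i <- i:(i + k - 1); blk_j <- j:(j + k - 1)
    if (all(bin[blk_i, blk_j])) out[blk_i, blk_j] <- TRUE
  }
  out
}

# connected-component labelling by flood fill
.label_components <- function(bin, connectivity = 4) {
  nr <- nrow(bin); nc <- ncol(bin)
  lab <- matrix(0L, nr, nc)
  offs <- if (connectivity == 8) .neigh8 else .neigh4
  cur <- 0L
  for (start in which(bin)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0) {
      p <- queue[1]; queue <- queue[-1]
      pi <- (p - 1L) %% nr + 1L; pj <- (p - 1L) %/% nr + 1L
      ni <- pi + offs[, "di"]; nj <- pj + offs[, "dj"]
      ok <- ni >= 1 & ni <= nr & nj >= 1 & nj <= nc
      q <- (nj[ok] - 1L) * nr + ni[ok]
      q <- q[bin[q] & lab[q] == 0L]
      lab[q] <- cur
      queue <- c(queue, q)
    }
  }
  lab
}

#' Segment the relevant channels of an activation map
#'
#' Applies the h-dome transform (with `h` scaled to the map's dynamic
#' range), binarises the dome image, removes small structures with a binary
#' opening, labels connected components, and keeps the cluster with the
#' highest nRMS value — its channels are the "relevant channels" of the map.
#' Ties between clusters with equal peak values go to the larger summed
#' nRMS, then to the smaller row-major index of the cluster peak. If the
#' opening empties the dome image entirely, the unopened binarisation is
#' used with a warning.
#'
#' @param map An [activation_map()] or matrix.
#' @param settings A [segmentation_settings()].
#' @return A `cluster_mask`: list with logical 8 x 8 `mask` and
#'   `n_channels`.
#' @export
segment_relevant_channels <- function(map, settings = segmentation_settings()) {
  v <- if (inherits(map, "activation_map")) map$values else map
  rng <- max(v) - min(v)
  if (!(max(v) > 0) || rng <= 0) return(cluster_mask(matrix(FALSE, nrow(v), ncol(v))))
  h_abs <- settings$h * rng
  if (h_abs <= 0) {
    warning("degenerate segmentation: h = 0, every positive channel is a candidate")
    bin <- v > settings$dome_floor
  } else {
    dome <- hdome(v, h_abs, settings$connectivity)
    bin <- dome > settings$dome_floor
  }
  opened <- .binary_opening(bin, settings$opening_se)
  if (!any(opened)) {
    warning("opening removed all dome structure; falling back to unopened dome")
    opened <- bin
  }
  if (!any(opened)) return(cluster_mask(matrix(FALSE, nrow(v), ncol(v))))
  lab <- .label_components(opened, settings$connectivity)
  ids <- seq_len(max(lab))
  peak_val <- vapply(ids, function(l) max(v[lab == l]), numeric(1))
  sum_val <- vapply(ids, function(l) sum(v[lab == l]), numeric(1))
  peak_idx <- vapply(ids, function(l) {
    cells <- which(lab == l)
    cells[which.max(v[cells])]
  }, numeric(1))
  # order: highest peak, then larger summed nRMS, then smaller row-major
  # index of the cluster peak (row-major = by row i, then column j)
  nr <- nrow(v)
  rowmaj <- (peak_idx - 1) %% nr * ncol(v) + (peak_idx - 1) %/% nr
  best <- ids[order(-peak_val, -sum_val, rowmaj)][1]
  cluster_mask(lab == best)
}

#' @rdname segment_relevant_channels
#' @param mask Logical matrix.
#' @export
cluster_mask <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  structure(list(mask = mask, n_channels = sum(mask)), class = "cluster_mask")
}

#' @export
print.cluster_mask <- function(x, ...) {
  cat(sprintf("<cluster_mask> %d relevant channels\n", x$n_channels))
  invisible(x)
}

#' Overlap degree between two relevant-channel sets
#'
#' `100 * |A intersect B| / max(|A|, |B|)` — the shared channels normalised
#' by the larger of the two clusters. Defined as 0 (with a warning) when
#' both masks are empty.
#'
#' @param a,b `cluster_mask`s (or logical matrices) on the same grid.
#' @return Overlap in percent, in \[0, 100\].
#' @export
overlap_degree <- function(a, b) {
  ma <- if (inherits(a, "cluster_mask")) a$mask else a
  mb <- if (inherits(b, "cluster_mask")) b$mask else b
  stopifnot(all(dim(ma) == dim(mb)))
  na <- sum(ma); nb <- sum(mb)
  if (na == 0 && nb == 0) {
    warning("overlap degree of two empty masks; reporting 0")
    return(0)
  }
  100 * sum(ma & mb) / max(na, nb)
}

#' Within-task overlap degree
#'
#' Mean of the pairwise overlap degrees between the cluster masks of one
#' task family (the three stretch velocities 60/120/180 deg/s, or the three
#' contraction levels 20/50/80 %MVC).
#'
#' @param masks List of `cluster_mask`s.
#' @return Mean pairwise overlap in percent, or `NA` (with a warning) when
#'   fewer than two masks are non-empty.
#' @export
within_task_overlap <- function(masks) {
  stopifnot(length(masks) >= 2)
  nonempty <- sum(vapply(masks, function(m) m$n_channels > 0, logical(1)))
  if (nonempty < 2) {
    warning("fewer than two non-empty masks; within-task overlap undefined")
    return(NA_real_)
  }
  pairs <- utils::combn(length(masks), 2)
  mean(apply(pairs, 2, function(p) overlap_degree(masks[[p[1]]], masks[[p[2]]])))
}

#' Between-tasks overlap degree
#'
#' Overlap degree between the cluster of the averaged passive-stretch map
#' and the cluster of the averaged active-contraction map.
#'
#' @param passive_mask,active_mask `cluster_mask`s from segmenting the two
#'   averaged maps.
#' @return Overlap in percent.
#' @export
between_task_overlap <- function(passive_mask, active_mask) {
  overlap_degree(passive_mask, active_mask)
}
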