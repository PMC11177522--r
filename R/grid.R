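#' Electrode grid geometry
#'
#' Describes the 8 x 8 surface electrode array used to record monopolar
#' HD-sEMG from the biceps brachii. Rows (`i`) run lateral to medial,
#' columns (`j`) proximal to distal, so larger `j` means a more distal
#' position along the muscle fibres.
#'
#' @param n_rows,n_cols Grid dimensions (8 x 8 for this protocol).
#' @param ied_mm Inter-electrode distance in mm (centre to centre).
#' @param electrode_diameter_mm Single electrode diameter in mm.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows = 8L, n_cols = 8L, ied_mm = 12,
                      electrode_diameter_mm = 2) {
  stopifnot(n_rows >= 1, n_cols >= 1, ied_mm > 0)
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         ied_mm = ied_mm, electrode_diameter_mm = electrode_diameter_mm,
         row_axis = "lateral->medial", col_axis = "proximal->distal"),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d, IED %g mm (rows %s, cols %s)\n",
              x$n_rows, x$n_cols, x$ied_mm, x$row_axis, x$col_axis))
  invisible(x)
}

#' Channel index to grid coordinates
#'
#' Channels are numbered 0..63 in row-major order: channel `k` sits at row
#' `i = k %/% 8 + 1` (lateral-medial) and column `j = k %% 8 + 1`
#' (proximal-distal). The mapping is a bijection over the 64 channels; real
#' datasets with a different amplifier ordering declare theirs in the
#' sidecar metadata.
#'
#' @param channel Integer channel index, 0-based, in `0:63`.
#' @param grid A [grid_spec()].
#' @return For `channel_to_grid`, a two-column matrix of (i, j); for
#'   `grid_to_channel`, the 0-based channel index.
#' @export
channel_to_grid <- function(channel, grid = grid_spec()) {
  stopifnot(all(channel >= 0), all(channel < grid$n_rows * grid$n_cols))
  cbind(i = channel %/% grid$n_cols + 1L, j = channel %% grid$n_cols + 1L)
}

#' @rdname channel_to_grid
#' @param i,j 1-based grid coordinates.
#' @export
grid_to_channel <- function(i, j, grid = grid_spec()) {
  stopifnot(all(i >= 1), all(i <= grid$n_rows), all(j >= 1), all(j <= grid$n_cols))
  as.integer((i - 1L) * grid$n_cols + (j - 1L))
}

#' Reshape a 64-channel vector to the 8 x 8 grid (and back)
#'
#' `channels_to_matrix` lays a per-channel vector (channel order 0..63) out as
#' the `[i, j]` grid matrix; `matrix_to_channels` is its inverse.
#'
#' @param x A length-64 vector, or an 8 x 8 matrix.
#' @param grid A [grid_spec()].
#' @export
channels_to_matrix <- function(x, grid = grid_spec()) {
  stopifnot(length(x) == grid$n_rows * grid$n_cols)
  matrix(x, nrow = grid$n_rows, ncol = grid$n_cols, byrow = TRUE)
}

#' @rdname channels_to_matrix
#' @export
matrix_to_channels <- function(x, grid = grid_spec()) {
  stopifnot(is.matrix(x), nrow(x) == grid$n_rows, ncol(x) == grid$n_cols)
  as.vector(t(x))
}

# 4-neighbour (edge-sharing) offsets on the grid
.neigh4 <- cbind(di = c(-1L, 1L, 0L, 0L), dj = c(0L, 0L, -1L, 1L))
# 8-neighbourhood adds the diagonals
.neigh8 <- cbind(di = c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L),
                 dj = c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L))
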