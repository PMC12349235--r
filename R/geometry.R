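#' Sensor-array geometry
#'
#' Describes the 3-D layout of the magnetometer array: 42 recording
#' sensors on a regular 6 x 7 planar grid plus 21 reference sensors on a
#' ring surrounding the grid. Positions are in metres; each sensor has a
#' unit sensing axis (magnetoresistive sensors are uniaxial, so only the
#' field component along the axis is observed).
#'
#' Coordinate convention: right-handed, grid in the x-y plane with its
#' centroid at the origin, sensing normal +z, and the cardiac source in
#' front of the array at negative z.
#'
#' @param recording_positions numeric matrix (42 x 3), metres.
#' @param recording_axes numeric matrix (42 x 3), unit sensing directions.
#' @param reference_positions numeric matrix (21 x 3), metres.
#' @param reference_axes numeric matrix (21 x 3), unit sensing directions.
#' @param grid_shape integer vector `c(rows, cols)`; default `c(6, 7)`.
#' @param pitch grid spacing in metres; default 0.04.
#' @return an object of class `sensor_array_geometry`.
#' @seealso [default_geometry()]
#' @export
sensor_array_geometry <- function(recording_positions, recording_axes,
                                  reference_positions, reference_axes,
                                  grid_shape = c(6L, 7L), pitch = 0.04) {
  g <- structure(
    list(
      recording_positions = as.matrix(recording_positions),
      recording_axes = as.matrix(recording_axes),
      reference_positions = as.matrix(reference_positions),
      reference_axes = as.matrix(reference_axes),
      grid_shape = as.integer(grid_shape),
      pitch = pitch
    ),
    class = "sensor_array_geometry"
  )
  validate_geometry(g)
  g
}

#' @rdname sensor_array_geometry
#' @param g a `sensor_array_geometry` object.
#' @export
validate_geometry <- function(g) {
  n_rec <- prod(g$grid_shape)
  if (nrow(g$recording_positions) != n_rec || nrow(g$recording_axes) != n_rec)
    stopf("expected %d recording sensors (grid %dx%d)", n_rec,
          g$grid_shape[1], g$grid_shape[2])
  for (nm in c("recording_axes", "reference_axes")) {
    nrm <- sqrt(rowSums(g[[nm]]^2))
    if (any(abs(nrm - 1) > 1e-9))
      stopf("%s must have unit norm (max |norm-1| = %.2e)", nm, max(abs(nrm - 1)))
  }
  if (nrow(g$reference_positions) != nrow(g$reference_axes))
    stopf("reference positions/axes row mismatch")
  if (!all(is.finite(unlist(g[1:4])))) stopf("geometry contains non-finite values")
  invisible(g)
}

#' Default STORM-style array geometry
#'
#' Builds the canonical array: 42 recording sensors on a 6 x 7 grid with
#' 4.0 cm pitch in the x-y plane (grid centroid at the origin, sensing
#' axes along +z), and 21 reference sensors evenly spaced on the
#' rectangle `ring_offset` outside the grid perimeter in the same plane.
#' Reference sensing axes cycle through +z, +x, +y (7 per orientation) so
#' the reference set spans three field directions, which adaptive noise
#' cancellation needs in order to observe the full interference subspace.
#'
#' The exact hardware reference layout is not public; this ring is a
#' deterministic, documented stand-in. Channel ordering is row-major over
#' the grid.
#'
#' @param pitch grid spacing in metres (default 0.04).
#' @param ring_offset distance from grid perimeter to reference ring,
#'   metres (default 0.06).
#' @return a [sensor_array_geometry()] object.
#' @examples
#' g <- default_geometry()
#' nrow(g$recording_positions)   # 42
#' nrow(g$reference_positions)   # 21
#' @export
default_geometry <- function(pitch = 0.04, ring_offset = 0.06) {
  rows <- 6L; cols <- 7L
  ix <- expand.grid(col = seq_len(cols), row = seq_len(rows))  # row-major
  x <- (ix$col - (cols + 1) / 2) * pitch
  y <- ((rows + 1) / 2 - ix$row) * pitch
  rec_pos <- cbind(x = x, y = y, z = 0)
  rec_axes <- matrix(rep(c(0, 0, 1), each = 42L), ncol = 3,
                     dimnames = list(NULL, c("x", "y", "z")))

  # reference ring: rectangle ring_offset outside the grid hull
  hx <- (cols - 1) / 2 * pitch + ring_offset
  hy <- (rows - 1) / 2 * pitch + ring_offset
  per <- 2 * (2 * hx + 2 * hy)
  s <- (seq_len(21L) - 1) / 21 * per
  ref_pos <- t(vapply(s, function(si) {
    if (si < 2 * hx) c(-hx + si, hy, 0)
    else if (si < 2 * hx + 2 * hy) c(hx, hy - (si - 2 * hx), 0)
    else if (si < 4 * hx + 2 * hy) c(hx - (si - 2 * hx - 2 * hy), -hy, 0)
    else c(-hx, -hy + (si - 4 * hx - 2 * hy), 0)
  }, numeric(3)))
  colnames(ref_pos) <- c("x", "y", "z")
  ax_cycle <- rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0))
  ref_axes <- ax_cycle[rep_len(1:3, 21L), , drop = FALSE]
  colnames(ref_axes) <- c("x", "y", "z")

  sensor_array_geometry(rec_pos, rec_axes, ref_pos, ref_axes,
                        grid_shape = c(rows, cols), pitch = pitch)
}

#' @export
print.sensor_array_geometry <- function(x, ...) {
  cat(sprintf("<sensor_array_geometry> %d recording (%dx%d grid, pitch %.3f m), %d reference\n",
              nrow(x$recording_positions), x$grid_shape[1], x$grid_shape[2],
              x$pitch, nrow(x$reference_positions)))
  invisible(x)
}

#' Read / write geometry as JSON
#'
#' Standalone JSON serialization of a [sensor_array_geometry()] for use
#' outside the recording container.
#'
#' @param g geometry object.
#' @param path file path.
#' @return `read_geometry_json` returns the geometry; `write_geometry_json`
#'   returns `path` invisibly.
#' @export
write_geometry_json <- function(g, path) {
  validate_geometry(g)
  jsonlite::write_json(
    list(recording_positions = g$recording_positions,
         recording_axes = g$recording_axes,
         reference_positions = g$reference_positions,
         reference_axes = g$reference_axes,
         grid_shape = g$grid_shape, pitch = g$pitch),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_geometry_json
#' @export
read_geometry_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  sensor_array_geometry(j$recording_positions, j$recording_axes,
                        j$reference_positions, j$reference_axes,
                        grid_shape = j$grid_shape, pitch = j$pitch)
}
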