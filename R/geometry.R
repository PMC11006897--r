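#' Stimulus-array geometries
#'
#' A geometry describes the spatial layout of the speaker/LED array used for
#' stimulation: an ordered set of azimuths and elevations (degrees) whose
#' cross product gives the stimulus positions. Azimuth is signed with
#' negative values ipsilateral to the recorded (left) hemisphere and positive
#' values contralateral; elevation 0 is head level.
#'
#' @param azimuths strictly increasing numeric vector of azimuths (degrees),
#'   each in \[-180, 180\].
#' @param elevations strictly increasing numeric vector of elevations
#'   (degrees), each in \[-90, 90\].
#' @return An object of class `array_geometry` with elements `azimuths`,
#'   `elevations` and `positions`, the latter a data.frame with columns
#'   `azimuth` and `elevation` enumerating the full grid row-major with
#'   elevation as the outer (slow) index.
#' @export
array_geometry <- function(azimuths, elevations) {
  stopifnot(length(azimuths) >= 1, length(elevations) >= 1,
            all(azimuths >= -180 & azimuths <= 180),
            all(elevations >= -90 & elevations <= 90))
  if (length(azimuths) > 1 && any(diff(azimuths) <= 0))
    stop("azimuths must be strictly increasing")
  if (length(elevations) > 1 && any(diff(elevations) <= 0))
    stop("elevations must be strictly increasing")
  positions <- expand.grid(azimuth = azimuths, elevation = elevations,
                           KEEP.OUT.ATTRS = FALSE)
  structure(list(azimuths = as.numeric(azimuths),
                 elevations = as.numeric(elevations),
                 positions = positions),
            class = "array_geometry")
}

#' @export
print.array_geometry <- function(x, ...) {
  cat(sprintf("array_geometry: %d azimuths x %d elevations = %d positions\n",
              length(x$azimuths), length(x$elevations), nrow(x$positions)))
  cat(" azimuths:  ", paste(x$azimuths, collapse = " "), "\n")
  cat(" elevations:", paste(x$elevations, collapse = " "), "\n")
  invisible(x)
}

#' Number of positions in a geometry
#' @param geometry an `array_geometry`.
#' @return integer position count.
#' @export
n_positions <- function(geometry) nrow(geometry$positions)

#' Default 39-position speaker/LED array
#'
#' The standard stimulation grid: 13 azimuth columns from -20 deg
#' (ipsilateral) to +100 deg (contralateral) in 10 deg steps, crossed with 3
#' elevation rows at -20, 0 and +20 deg, for 39 positions.
#'
#' @return an `array_geometry` with 39 positions.
#' @export
default_array <- function() {
  array_geometry(azimuths = seq(-20, 100, by = 10),
                 elevations = c(-20, 0, 20))
}

#' Motorized rotating-speaker azimuth array
#'
#' Single-elevation geometry of a loudspeaker on a motorized rotating arm:
#' azimuths -90 to -30 deg in 20 deg steps, then -20 to +100 deg in 10 deg
#' steps (17 positions), all at elevation 0.
#'
#' @param step_plan plan label; only `"published"` is defined.
#' @return an `array_geometry` with a single elevation row.
#' @export
motorized_arm_array <- function(step_plan = "published") {
  if (!identical(step_plan, "published"))
    stop("unknown step plan: ", step_plan)
  array_geometry(azimuths = c(seq(-90, -30, by = 20), seq(-20, 100, by = 10)),
                 elevations = 0)
}

#' Euclidean angular distance between stimulus positions
#'
#' Distance in the (azimuth, elevation) degree plane:
#' sqrt((da)^2 + (de)^2). Vectorized over rows.
#'
#' @param a,b data.frames (or lists) with `azimuth` and `elevation` in
#'   degrees; recycled to a common length.
#' @return numeric vector of distances in degrees.
#' @export
angular_distance <- function(a, b) {
  sqrt((a$azimuth - b$azimuth)^2 + (a$elevation - b$elevation)^2)
}

#' Chance-level decoding error of a geometry
#'
#' Expected angular distance between two positions drawn independently and
#' uniformly from the grid, computed by exact enumeration over all ordered
#' position pairs. This is the error level a decoder guessing uniformly at
#' random attains in expectation.
#'
#' @param geometry an `array_geometry`.
#' @return expected error in degrees.
#' @export
chance_error <- function(geometry) {
  p <- geometry$positions
  daz <- outer(p$azimuth, p$azimuth, "-")
  del <- outer(p$elevation, p$elevation, "-")
  mean(sqrt(daz^2 + del^2))
}

#' Virtual isotropic 40 x 40 deg sub-arrays
#'
#' Because the default grid is anisotropic (10 deg azimuth vs 20 deg
#' elevation steps), azimuth/elevation modulation is compared on virtual
#' isotropic sub-arrays: every subset of three azimuths spaced 20 deg apart
#' and spanning 40 deg (azimuth indices i, i+2, i+4), crossed with the three
#' elevations. The default array yields 9 such 3 x 3 sub-arrays.
#'
#' @param geometry an `array_geometry` with 10 deg-spaced azimuths and at
#'   least 5 azimuth columns.
#' @return list of `array_geometry`, one per sub-array.
#' @export
virtual_isotropic_arrays <- function(geometry) {
  az <- geometry$azimuths
  if (length(az) < 5 || any(abs(diff(az) - 10) > 1e-9))
    stop("geometry incompatible with 40x40 deg virtual-array construction")
  lapply(seq_len(length(az) - 4), function(i) {
    array_geometry(azimuths = az[c(i, i + 2, i + 4)],
                   elevations = geometry$elevations)
  })
}

#' Match positions to row indices of a geometry
#'
#' @param geometry an `array_geometry`.
#' @param azimuth,elevation numeric vectors of coordinates (degrees).
#' @return integer indices into `geometry$positions`; error if any position
#'   is not on the grid.
#' @export
position_index <- function(geometry, azimuth, elevation) {
  key <- paste(geometry$positions$azimuth, geometry$positions$elevation)
  idx <- match(paste(azimuth, elevation), key)
  if (anyNA(idx)) stop("position(s) not on the geometry grid")
  idx
}
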