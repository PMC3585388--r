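## Spherical coordinate system used throughout the package.
##
## Retinal positions live on a unit sphere whose pole is the retinal pole
## (the back of the eye, assumed coincident with the optic axis).  A point
## is described by its colatitude -- the angle in degrees from the pole,
## zero at the pole and increasing towards the retinal rim -- and its
## longitude in (-180, 180].  By convention the nasal pole of the retina is
## at longitude 0, dorsal at 90, temporal at 180 and ventral at -90.
## All angles are stored and exposed in degrees; radians appear only
## transiently inside trigonometric calls.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Construct spherical points
#'
#' Creates a set of points on the standard retinal sphere, described by
#' colatitude (degrees from the retinal pole, in \[0, 180\]) and longitude
#' (degrees, normalised to (-180, 180\]).  At the poles the longitude is
#' canonicalised to 0.
#'
#' @param colatitude Numeric vector of colatitudes in degrees.
#' @param longitude Numeric vector of longitudes in degrees (recycled).
#' @return A `data.frame` with columns `colatitude` and `longitude`.
#' @examples
#' sph_point(90, c(-270, 90))   # longitude normalised to (-180, 180]
#' @export
sph_point <- function(colatitude, longitude) {
  n <- max(length(colatitude), length(longitude))
  colatitude <- rep_len(as.numeric(colatitude), n)
  longitude <- rep_len(as.numeric(longitude), n)
  if (any(!is.finite(colatitude)) || any(!is.finite(longitude)))
    stop("spherical coordinates must be finite")
  if (any(colatitude < -1e-9 | colatitude > 180 + 1e-9))
    stop("colatitude must lie in [0, 180] degrees")
  colatitude <- pmin(pmax(colatitude, 0), 180)
  longitude <- wrap_longitude(longitude)
  at_pole <- colatitude < 1e-12 | colatitude > 180 - 1e-12
  longitude[at_pole] <- 0
  data.frame(colatitude = colatitude, longitude = longitude)
}

## Normalise angles to (-180, 180].
wrap_longitude <- function(lon) {
  lon <- (lon + 180) %% 360 - 180
  lon[lon <= -180] <- 180
  lon
}

#' Convert spherical points to 3D Cartesian coordinates
#'
#' The canonical embedding is the unit sphere with the retinal pole at +z
#' and longitude measured from +x towards +y.
#'
#' @param p Spherical points as returned by [sph_point()].
#' @return An n-by-3 matrix of unit vectors.
#' @export
sph_to_cart <- function(p) {
  phi <- deg2rad(p$colatitude)
  lam <- deg2rad(p$longitude)
  cbind(x = sin(phi) * cos(lam), y = sin(phi) * sin(lam), z = cos(phi))
}

#' Convert 3D Cartesian coordinates to spherical points
#'
#' @param u An n-by-3 matrix; rows need not be normalised.
#' @return Spherical points (see [sph_point()]).
#' @export
cart_to_sph <- function(u) {
  u <- matrix(as.numeric(u), ncol = 3)
  r <- sqrt(rowSums(u^2))
  if (any(r < 1e-12)) stop("zero vector cannot be mapped to the sphere")
  u <- u / r
  colat <- rad2deg(atan2(sqrt(u[, 1]^2 + u[, 2]^2), u[, 3]))
  lon <- rad2deg(atan2(u[, 2], u[, 1]))
  sph_point(colat, lon)
}

#' Great-circle angle between spherical points
#'
#' Central angle between pairs of points, computed with the numerically
#' stable `atan2` form (accurate for both nearly coincident and nearly
#' antipodal points).
#'
#' @param p,q Spherical points ([sph_point()]); rows are paired, shorter
#'   argument recycled.
#' @return Angles in degrees, in \[0, 180\].
#' @export
geodesic_angle <- function(p, q) {
  n <- max(nrow(p), nrow(q))
  up <- sph_to_cart(p)[rep_len(seq_len(nrow(p)), n), , drop = FALSE]
  uq <- sph_to_cart(q)[rep_len(seq_len(nrow(q)), n), , drop = FALSE]
  cross <- cbind(up[, 2] * uq[, 3] - up[, 3] * uq[, 2],
                 up[, 3] * uq[, 1] - up[, 1] * uq[, 3],
                 up[, 1] * uq[, 2] - up[, 2] * uq[, 1])
  unname(rad2deg(atan2(sqrt(rowSums(cross^2)), rowSums(up * uq))))
}

#' Eye measurements
#'
#' Axial measurements of an eye, modelled as a sphere: the distance `a`
#' from the back of the eye to the surface of the cornea (the axial depth,
#' equal to the diameter of the model sphere) and the perpendicular
#' distance `b` from the back of the eye to the rim of the retina.  Both
#' are in micrometres.
#'
#' @param axial_depth Back of eye to cornea surface, micrometres.
#' @param rim_depth Back of eye to retinal rim, micrometres.
#' @return An object of class `eye_measurements`.
#' @export
eye_measurements <- function(axial_depth, rim_depth) {
  if (!is.numeric(axial_depth) || !is.numeric(rim_depth))
    stop("eye measurements must be numeric")
  if (any(axial_depth <= 0) || any(rim_depth <= 0))
    stop("invalid eye measurements: depths must be positive")
  if (any(rim_depth > axial_depth))
    stop("invalid eye measurements: rim_depth must not exceed axial_depth")
  structure(list(axial_depth = axial_depth, rim_depth = rim_depth),
            class = "eye_measurements")
}

#' Rim colatitude from eye measurements
#'
#' Computes the colatitude of the retinal rim (the rim angle phi0) from
#' axial eye measurements.  The eye is modelled as a sphere of diameter
#' equal to the axial depth `a`, with the retinal pole at the back of the
#' eye; a rim at perpendicular distance `b` from the back pole then lies
#' at colatitude `acos(1 - 2 b / a)`.  Because the mouse retina is more
#' than hemispherical, the rim angle typically exceeds 90 degrees.
#'
#' @param eye An [eye_measurements()] object (vectorised over its fields).
#' @return Rim colatitude(s) in degrees, in (0, 180\].
#' @examples
#' rim_colatitude(eye_measurements(3160, 2161))  # adult mouse, about 111.6
#' @export
rim_colatitude <- function(eye) {
  stopifnot(inherits(eye, "eye_measurements"))
  rad2deg(acos(1 - 2 * eye$rim_depth / eye$axial_depth))
}

#' Validate a rim angle
#' @param value Rim colatitude in degrees, strictly between 0 and 180.
#' @return The value, invisibly classed as `rim_angle`.
#' @export
rim_angle <- function(value) {
  value <- as.numeric(value)
  if (length(value) != 1 || !is.finite(value) || value <= 0 || value >= 180)
    stop("rim angle must be a single value strictly between 0 and 180 degrees")
  structure(value, class = "rim_angle")
}

#' Developmental eye measurements of the mouse
#'
#' Mean axial depth and rim depth of mouse eyes at nine developmental
#' stages (postnatal day P0 to adult P64), each averaged over four eyes,
#' together with the published rim colatitude derived from them.  The
#' colatitude column can be recomputed from the first two measurement
#' columns with [rim_colatitude()]; small differences (under 0.1 degrees)
#' arise because the published values averaged eyes before rounding.
#'
#' @return A `data.frame` with columns `age`, `axial_depth_um`,
#'   `rim_depth_um` and `rim_colatitude_deg`.
#' @export
mouse_eye_measurements <- function() {
  data.frame(
    age = c("P0", "P2", "P4", "P6", "P8", "P12", "P16", "P22", "P64"),
    axial_depth_um = c(1632, 2146, 2250, 2450, 2646, 2786, 2808, 2958, 3160),
    rim_depth_um = c(1308, 1780, 1857, 1963, 2088, 2212, 2043, 2117, 2161),
    rim_colatitude_deg = c(127.13, 131.20, 130.58, 127.02, 125.31, 126.03,
                           117.10, 115.57, 111.56),
    stringsAsFactors = FALSE
  )
}

#' Azimuthal equidistant projection centred on the retinal pole
#'
#' Projects spherical points to the plane so that the radial distance of a
#' projected point from the origin equals its colatitude in degrees and the
#' planar azimuth equals its longitude.  This is the standard polar plot of
#' the reconstructed retina.
#'
#' @param p Spherical points.
#' @return An n-by-2 matrix of planar coordinates (degree units).
#' @export
project_azimuthal_equidistant <- function(p) {
  lam <- deg2rad(p$longitude)
  cbind(x = p$colatitude * cos(lam), y = p$colatitude * sin(lam))
}

#' Inverse azimuthal equidistant projection
#' @param xy An n-by-2 matrix of planar coordinates in degree units.
#' @return Spherical points.
#' @export
unproject_azimuthal_equidistant <- function(xy) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  r <- sqrt(rowSums(xy^2))
  lon <- rad2deg(atan2(xy[, 2], xy[, 1]))
  lon[r < 1e-12] <- 0
  sph_point(r, lon)
}

#' Orthographic projection about an arbitrary centre
#'
#' Standard orthographic projection of the sphere onto the tangent plane at
#' `centre`.  Points more than 90 degrees from the centre lie on the hidden
#' hemisphere and are flagged.
#'
#' @param p Spherical points to project.
#' @param centre A single spherical point; the projection centre.
#' @return A `data.frame` with columns `x`, `y` (unit-sphere units, so the
#'   visible hemisphere maps inside the unit disc) and logical `hidden`.
#' @export
project_orthographic <- function(p, centre) {
  u <- sph_to_cart(p)
  C <- drop(sph_to_cart(centre)[1, ])
  basis <- tangent_basis(C)
  data.frame(x = u %*% basis$e1, y = u %*% basis$e2,
             hidden = drop(u %*% C) < -1e-12)
}

## Orthonormal basis of the tangent plane at unit vector C.  e2 points
## towards the +z pole (the "up" direction of the plot); e1 completes a
## right-handed frame (C, e1, e2).  At the poles, e1 is +x.
tangent_basis <- function(C) {
  z <- c(0, 0, 1)
  e2 <- z - sum(z * C) * C
  if (sqrt(sum(e2^2)) < 1e-9) {
    e1 <- c(1, 0, 0)
    e2 <- c(C[2] * e1[3] - C[3] * e1[2],
            C[3] * e1[1] - C[1] * e1[3],
            C[1] * e1[2] - C[2] * e1[1])  # C x e1, fixed frame at the poles
  } else {
    e2 <- e2 / sqrt(sum(e2^2))
    e1 <- c(e2[2] * C[3] - e2[3] * C[2],
            e2[3] * C[1] - e2[1] * C[3],
            e2[1] * C[2] - e2[2] * C[1])  # e2 x C
  }
  list(e1 = e1, e2 = e2)
}

#' Sinusoidal (equal-area) projection
#'
#' Used for whole-visual-field plots.  Interprets points in latitude and
#' longitude: `x = longitude * cos(latitude)`, `y = latitude`.  The
#' Jacobian determinant of the map is `cos(latitude)`, matching the area
#' element of the sphere, so the projection is equal-area by construction.
#'
#' @param latitude,longitude Coordinates in degrees.
#' @return An n-by-2 matrix of planar coordinates in degree units.
#' @export
project_sinusoidal <- function(latitude, longitude) {
  cbind(x = longitude * cos(deg2rad(latitude)), y = latitude)
}
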