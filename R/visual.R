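## Transformation of standard retinal coordinates into head-centred
## visuotopic coordinates.
##
## Visual directions are measured on a notional celestial sphere about
## the animal's head: elevation is the angle above the horizontal, and
## azimuth the angle between the direction's meridian plane and the zero
## meridian plane (the vertical plane through the long axis of the
## head).  Following the convention of plotting the animal as if facing
## the observer, azimuth is positive in the LEFT visual field; the two
## eyes' optic-axis poses are mirror-symmetric about the zero-meridian
## plane.
##
## The optics of the eye are approximated by making the deviation of a
## ray through the posterior nodal point proportional to its angle of
## incidence, with the constant fixed so that rays at 90 degrees to the
## optic axis reach the retinal rim whatever the rim angle: a retinal
## point at colatitude phi therefore lies at visual angle
## 90 * phi / phi0 from the optic axis.  Inversion of the image through
## the nodal point sends nasal retina to the temporal (lateral) visual
## field and dorsal retina to the inferior field.

#' Optic-axis pose
#'
#' Orientation of one eye's optic axis in head-centred visual space.
#' `azimuth` is given as the lateral angle (a magnitude): the axis of
#' the left eye points into the left field (positive head azimuth), that
#' of the right eye into the right field (negative head azimuth).
#'
#' @param azimuth Lateral angle of the axis from the vertical (zero)
#'   meridian, degrees.
#' @param elevation Angle of the axis above the horizontal, degrees.
#' @param eye_side `"left"` or `"right"`.
#' @return An object of class `optic_axis_pose`.
#' @export
optic_axis_pose <- function(azimuth = 64, elevation = 22,
                            eye_side = c("right", "left")) {
  eye_side <- match.arg(eye_side)
  if (abs(elevation) > 90) stop("elevation must be within [-90, 90]")
  structure(list(azimuth = azimuth, elevation = elevation,
                 eye_side = eye_side), class = "optic_axis_pose")
}

## Head-frame unit vector of a visual direction: x forward, y towards
## the animal's left, z up.
visual_to_cart <- function(azimuth, elevation) {
  a <- deg2rad(azimuth); e <- deg2rad(elevation)
  cbind(cos(e) * cos(a), cos(e) * sin(a), sin(e))
}

cart_to_visual <- function(u) {
  u <- u / sqrt(rowSums(u^2))
  data.frame(azimuth = rad2deg(atan2(u[, 2], u[, 1])),
             elevation = rad2deg(asin(pmin(pmax(u[, 3], -1), 1))))
}

## Axis direction and tangent frame for a pose.  e_sup points towards
## the superior field (increasing elevation); e_nasal towards the nasal
## field (the vertical meridian), i.e. towards increasing azimuth for
## the right eye and decreasing azimuth for the left.
pose_frame <- function(pose) {
  az <- if (pose$eye_side == "right") -pose$azimuth else pose$azimuth
  A <- drop(visual_to_cart(az, pose$elevation))
  zen <- c(0, 0, 1)
  e_sup <- zen - sum(zen * A) * A
  ns <- sqrt(sum(e_sup^2))
  if (ns < 1e-9) stop("optic axis at the zenith: frame undefined")
  e_sup <- e_sup / ns
  e_az <- c(zen[2] * A[3] - zen[3] * A[2],
            zen[3] * A[1] - zen[1] * A[3],
            zen[1] * A[2] - zen[2] * A[1])   # zenith x A: increasing azimuth
  e_az <- e_az / sqrt(sum(e_az^2))
  e_nasal <- if (pose$eye_side == "right") e_az else -e_az
  list(A = A, e_sup = e_sup, e_nasal = e_nasal)
}

#' Transform retinal coordinates to head-centred visual coordinates
#'
#' Applies the proportional optics model and the pose rotation: a
#' retinal point at colatitude phi maps to visual angle `90 * phi / phi0`
#' from the posed optic axis; its retinal longitude fixes the direction
#' about the axis with the image inversion through the nodal point
#' (nasal retina to temporal field, dorsal retina to inferior field) and
#' the eye side's chirality.
#'
#' @param p Spherical retinal points.
#' @param phi0 Rim colatitude of the retina, degrees.
#' @param pose An [optic_axis_pose()].
#' @return A `data.frame` with `azimuth` and `elevation` in degrees
#'   (positive azimuth in the left visual field, facing-observer
#'   convention).
#' @export
retina_to_visual <- function(p, phi0, pose) {
  phi0 <- as.numeric(phi0)
  if (any(p$colatitude > phi0 + 1e-9))
    stop("point(s) beyond the retinal rim (colatitude > rim angle)")
  fr <- pose_frame(pose)
  theta <- deg2rad(90 * p$colatitude / phi0)
  lam <- deg2rad(p$longitude)
  ## direction about the axis: nasal retina (lam = 0) -> temporal field,
  ## dorsal retina (lam = 90) -> inferior field
  tdir <- outer(-cos(lam), fr$e_nasal) + outer(-sin(lam), fr$e_sup)
  u <- outer(cos(theta), fr$A) + tdir * sin(theta)
  cart_to_visual(u)
}

#' Transform head-centred visual coordinates to retinal coordinates
#'
#' Exact inverse of [retina_to_visual()] for directions within 90
#' degrees of the posed optic axis.
#'
#' @param v A `data.frame` with `azimuth` and `elevation` in degrees.
#' @param phi0 Rim colatitude, degrees.
#' @param pose An [optic_axis_pose()].
#' @return Spherical retinal points.
#' @export
visual_to_retina <- function(v, phi0, pose) {
  phi0 <- as.numeric(phi0)
  fr <- pose_frame(pose)
  u <- visual_to_cart(v$azimuth, v$elevation)
  ct <- pmin(pmax(drop(u %*% fr$A), -1), 1)
  theta <- acos(ct)
  if (any(theta > pi / 2 + 1e-9))
    stop("direction(s) more than 90 degrees from the optic axis")
  t <- u - outer(ct, fr$A)
  tn <- sqrt(rowSums(t^2))
  lam <- atan2(-(t %*% fr$e_sup), -(t %*% fr$e_nasal))
  lam[tn < 1e-12] <- 0
  sph_point(rad2deg(theta) * phi0 / 90, rad2deg(drop(lam)))
}

#' Overlay two eyes' point sets in the common visual field
#'
#' Transforms labelled retinal point sets of the left and right eyes
#' into the shared head-centred frame under a mirror-symmetric pose
#' pair, for binocular-congruence analysis.  The congruence metric is
#' the mean unsigned angular distance of all points from the vertical
#' meridian plane, and the mean absolute azimuth: for a boundary that
#' should project to the vertical meridian (such as the decussation line
#' between crossed and uncrossed projections), both approach zero when
#' the pose is correct.
#'
#' @param left,right Spherical retinal point sets for the two eyes.
#' @param phi0 Rim colatitude, degrees.
#' @param pose An [optic_axis_pose()]; its mirror image is applied to
#'   the other eye.
#' @return A list with `field` (data.frame: azimuth, elevation, eye) and
#'   `congruence` (list: `mean_meridian_distance_deg`,
#'   `mean_abs_azimuth_deg`, `mean_azimuth_offset_deg` between eyes).
#' @export
binocular_overlay <- function(left, right, phi0, pose) {
  pl <- optic_axis_pose(pose$azimuth, pose$elevation, "left")
  pr <- optic_axis_pose(pose$azimuth, pose$elevation, "right")
  vl <- retina_to_visual(left, phi0, pl)
  vr <- retina_to_visual(right, phi0, pr)
  field <- rbind(data.frame(vl, eye = "left"), data.frame(vr, eye = "right"))
  ## distance to the vertical meridian plane (y = 0 in the head frame)
  u <- visual_to_cart(field$azimuth, field$elevation)
  dmer <- rad2deg(asin(pmin(pmax(abs(u[, 2]), 0), 1)))
  congr <- list(
    mean_meridian_distance_deg = mean(dmer),
    mean_abs_azimuth_deg = mean(abs(field$azimuth)),
    mean_azimuth_offset_deg = mean(vl$azimuth) + mean(vr$azimuth)
  )
  list(field = field, congruence = congr)
}
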