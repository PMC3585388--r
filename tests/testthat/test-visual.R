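test_that("the retinal pole projects to the posed optic axis", {
  pr <- optic_axis_pose(64, 22, "right")
  v <- retina_to_visual(sph_point(0, 0), 111.56, pr)
  expect_equal(v$azimuth, -64, tolerance = 1e-9)   # right field is negative
  expect_equal(v$elevation, 22, tolerance = 1e-9)
  pl <- optic_axis_pose(64, 22, "left")
  vl <- retina_to_visual(sph_point(0, 0), 111.56, pl)
  expect_equal(vl$azimuth, 64, tolerance = 1e-9)
})

test_that("visual angle from the axis is proportional to colatitude", {
  pose <- optic_axis_pose(64, 22, "right")
  phi0 <- 111.56
  axis <- retina_to_visual(sph_point(0, 0), phi0, pose)
  set.seed(2)
  p <- sph_point(runif(40, 0, phi0), runif(40, -180, 180))
  v <- retina_to_visual(p, phi0, pose)
  ua <- sph_to_cart(sph_point(90 - axis$elevation, axis$azimuth))
  uv <- sph_to_cart(sph_point(90 - v$elevation, v$azimuth))
  ang <- acos(pmin(pmax(uv %*% t(ua), -1), 1)) * 180 / pi
  expect_equal(drop(ang), 90 * p$colatitude / phi0, tolerance = 1e-9)
  ## rim points sit exactly 90 degrees from the axis
  rim <- retina_to_visual(sph_point(rep(phi0, 8), seq(-180, 135, by = 45)),
                          phi0, pose)
  urim <- sph_to_cart(sph_point(90 - rim$elevation, rim$azimuth))
  expect_equal(drop(acos(pmin(pmax(urim %*% t(ua), -1), 1))) * 180 / pi,
               rep(90, 8), tolerance = 1e-9)
  ## half the rim colatitude lands 45 degrees out
  h <- retina_to_visual(sph_point(phi0 / 2, 77), phi0, pose)
  uh <- sph_to_cart(sph_point(90 - h$elevation, h$azimuth))
  expect_equal(drop(acos(sum(uh * ua))) * 180 / pi, 45, tolerance = 1e-9)
  ## beyond the rim is an error
  expect_error(retina_to_visual(sph_point(120, 0), phi0, pose), "rim")
})

test_that("retina -> visual -> retina is the identity", {
  for (side in c("left", "right")) {
    pose <- optic_axis_pose(64, 22, side)
    set.seed(6)
    p <- sph_point(runif(60, 0.5, 111), runif(60, -179, 179))
    v <- retina_to_visual(p, 111.56, pose)
    back <- visual_to_retina(v, 111.56, pose)
    expect_equal(back$colatitude, p$colatitude, tolerance = 1e-9)
    expect_equal(back$longitude, p$longitude, tolerance = 1e-9)
  }
  ## the posed axis maps back to the retinal pole
  pose <- optic_axis_pose(64, 22, "right")
  pole <- visual_to_retina(data.frame(azimuth = -64, elevation = 22),
                           111.56, pose)
  expect_equal(pole$colatitude, 0, tolerance = 1e-9)
  ## a point 90 degrees out maps to the rim colatitude
  axis_dir <- sph_point(90 - 22, -64)
  fr <- retinamorph:::pose_frame(pose)
  u90 <- matrix(fr$e_sup, 1)             # orthogonal to the axis
  v90 <- retinamorph:::cart_to_visual(u90)
  r90 <- visual_to_retina(v90, 111.56, pose)
  expect_equal(r90$colatitude, 111.56, tolerance = 1e-9)
  expect_error(visual_to_retina(data.frame(azimuth = 110, elevation = 0),
                                111.56, pose), "90 degrees")
})

test_that("image inversion sends retinal poles to opposite field poles", {
  pose <- optic_axis_pose(64, 22, "right")
  phi0 <- 111.56
  ## dorsal retina (longitude 90) -> inferior field
  d <- retina_to_visual(sph_point(30, 90), phi0, pose)
  axis <- retina_to_visual(sph_point(0, 0), phi0, pose)
  expect_lt(d$elevation, axis$elevation)
  ## ventral retina -> superior field
  v <- retina_to_visual(sph_point(30, -90), phi0, pose)
  expect_gt(v$elevation, axis$elevation)
  ## nasal retina -> temporal (more lateral, i.e. more negative azimuth
  ## for the right eye)
  n <- retina_to_visual(sph_point(30, 0), phi0, pose)
  expect_lt(n$azimuth, axis$azimuth)
  ## temporal retina -> nasal field
  t <- retina_to_visual(sph_point(30, 180), phi0, pose)
  expect_gt(t$azimuth, axis$azimuth)
})

test_that("the two eyes are mirror images of each other", {
  set.seed(13)
  p <- sph_point(runif(40, 0, 110), runif(40, -179, 179))
  vl <- retina_to_visual(p, 111.56, optic_axis_pose(64, 22, "left"))
  vr <- retina_to_visual(p, 111.56, optic_axis_pose(64, 22, "right"))
  expect_equal(vl$azimuth, -vr$azimuth, tolerance = 1e-9)
  expect_equal(vl$elevation, vr$elevation, tolerance = 1e-9)
})

test_that("azimuthal order of points around the axis is preserved", {
  pose <- optic_axis_pose(64, 22, "right")
  lons <- seq(-180, 170, by = 10)
  p <- sph_point(rep(40, length(lons)), lons)
  v <- retina_to_visual(p, 111.56, pose)
  fr <- retinamorph:::pose_frame(pose)
  u <- retinamorph:::visual_to_cart(v$azimuth, v$elevation)
  psi <- atan2(u %*% fr$e_sup, u %*% fr$e_nasal)
  d <- diff(c(psi, psi[1]))
  d <- ifelse(d > pi, d - 2 * pi, ifelse(d < -pi, d + 2 * pi, d))
  expect_true(all(d < 0) || all(d > 0))   # strictly cyclic-monotone
})

test_that("a decussation line projects onto the vertical meridian only
           under its generating pose", {
  phi0 <- 111.56
  pose <- optic_axis_pose(64, 22, "right")
  ## construct the decussation line as the retinal preimage of the
  ## vertical meridian: the locus that should split crossed from
  ## uncrossed projections under the true optic-axis pose
  el <- seq(-25, 85, by = 2.5)
  mer <- data.frame(azimuth = 0, elevation = el)
  keep <- acos(pmin(pmax(
    retinamorph:::visual_to_cart(mer$azimuth, mer$elevation) %*%
      retinamorph:::pose_frame(pose)$A, -1), 1)) * 180 / pi <= 89
  mer <- mer[keep, ]
  dec <- visual_to_retina(mer, phi0, pose)
  ## by mirror symmetry the same retinal locus serves both eyes
  ov_true <- binocular_overlay(dec, dec, phi0, optic_axis_pose(64, 22))
  expect_lt(ov_true$congruence$mean_meridian_distance_deg, 2)
  expect_equal(ov_true$congruence$mean_azimuth_offset_deg, 0,
               tolerance = 1e-9)
  ## the same fixture under the optic-disc pose visibly misaligns
  ov_alt <- binocular_overlay(dec, dec, phi0, optic_axis_pose(60, 35))
  expect_gt(ov_alt$congruence$mean_meridian_distance_deg, 2)
})

test_that("mirrored labels overlay with zero mean azimuthal offset", {
  set.seed(19)
  crescent <- sph_point(runif(50, 64, 110), 225 + runif(50, -60, 60))
  ov <- binocular_overlay(crescent, crescent, 111.56,
                          optic_axis_pose(64, 22))
  expect_equal(ov$congruence$mean_azimuth_offset_deg, 0, tolerance = 1e-9)
  expect_equal(nrow(ov$field), 100)
})
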