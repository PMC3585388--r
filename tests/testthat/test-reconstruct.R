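test_that("elastic energy is zero at natural length and quadratic in strain", {
  rec <- recon_small(0.02, 1)
  u <- rec$u
  sys <- rec$sys
  l <- geodesic_rad(u[sys$edges[, 1], , drop = FALSE],
                    u[sys$edges[, 2], , drop = FALSE])
  ## natural lengths equal to the achieved lengths: energy exactly zero
  sys0 <- sys; sys0$L <- l
  attr(u, "sys") <- sys0
  e0 <- elastic_energy(u, 111.56)
  expect_equal(e0$energy, 0)
  expect_equal(max(abs(e0$gradient)), 0, tolerance = 1e-12)
  ## one edge with natural length l/(1+eps): closed form eps^2 L / 2
  eps <- 0.05
  sys1 <- sys0; sys1$L[1] <- l[1] / (1 + eps)
  attr(u, "sys") <- sys1
  e1 <- elastic_energy(u, 111.56)
  expect_equal(e1$energy, eps^2 * sys1$L[1] / 2, tolerance = 1e-10)
})

test_that("analytic gradient matches finite differences", {
  o <- resample_outline(vcut_disc(n = 40, m = 7), 120)
  m <- suppressMessages(stitch_mesh(triangulate_outline(o, 500)))
  u0 <- initial_projection(m, 100)
  sys <- attr(u0, "sys")
  obj <- retinamorph:::make_objective(sys, 100)
  par <- obj$pack(u0)
  for (w_fold in c(0, 5)) {
    ev <- obj$evaluate(par, w_fold)
    set.seed(4)
    idx <- sample(length(par), 30)
    h <- 1e-6
    for (i in idx) {
      pp <- par; pp[i] <- pp[i] + h
      pm <- par; pm[i] <- pm[i] - h
      fd <- (obj$evaluate(pp, w_fold)$value -
             obj$evaluate(pm, w_fold)$value) / (2 * h)
      expect_equal(ev$grad[i], fd,
                   tolerance = 1e-6 * max(1, abs(fd)))
    }
  }
})

test_that("deformation measure equals the uniform fractional strain", {
  set.seed(3)
  L <- runif(200, 0.5, 2)
  expect_equal(deformation_measure(L, L), 0)
  for (eps in c(-0.2, 0.05, 0.1))
    expect_equal(deformation_measure(L * (1 + eps), L), abs(eps))
  ## invariant under global rescaling of both meshes
  l <- L * (1 + 0.07 * sin(seq_along(L)))
  expect_equal(deformation_measure(l, L),
               deformation_measure(l * 13.7, L * 13.7))
})

test_that("quality flags follow the published thresholds", {
  flag <- retinamorph:::flag_from_EL
  expect_equal(flag(0.05), "ok")
  expect_equal(flag(0.1), "ok")
  expect_equal(flag(0.101), "check-markup")
  expect_equal(flag(0.15), "check-markup")
  expect_equal(flag(0.151), "bad")
  expect_equal(flag(0.2), "bad")
  expect_equal(flag(0.201), "reject")
})

test_that("initial projection pins the rim and keeps cut pairs together", {
  o <- resample_outline(vcut_disc(n = 60, m = 9), 250)
  m <- suppressMessages(stitch_mesh(triangulate_outline(o, 500)))
  u0 <- initial_projection(m, 111.56)
  sys <- attr(u0, "sys")
  sph <- cart_to_sph(u0)
  ## every rim node exactly at the rim colatitude
  expect_equal(sph$colatitude[sys$rim], rep(111.56, length(sys$rim)),
               tolerance = 1e-9)
  expect_true(all(sph$colatitude <= 111.56 + 1e-9))
  ## corresponded cut vertices are one node, so they coincide trivially
  cls <- sys$cls
  expect_true(all(cls[m$correspondences[, 1]] ==
                  cls[m$correspondences[, 2]]))
})

test_that("initial projection of a flattened shallow cap is nearly right", {
  ## for a mildly curved cap the equal-area disc development is close to
  ## isometric, so the area-matched initial placement starts with low
  ## strain before any optimisation
  o <- resample_outline(flat_outline(circle_outline(80, 1000),
                                     nasal_pole_index = 1), 200)
  m <- suppressMessages(stitch_mesh(triangulate_outline(o, 500)))
  u0 <- initial_projection(m, 30)
  sys <- attr(u0, "sys")
  l0 <- geodesic_rad(u0[sys$edges[, 1], , drop = FALSE],
                     u0[sys$edges[, 2], , drop = FALSE])
  expect_lt(deformation_measure(l0, sys$L), 0.05)
})

test_that("optimisation reduces deformation, deterministically", {
  rec <- recon_small(0.02, 1)
  expect_lte(rec$E_L, rec$initial_E_L)
  expect_true(rec$converged)
  ## hard rim constraint after optimisation
  rim_verts <- which(rec$sys$cls %in% rec$sys$rim)
  expect_equal(unique(rec$vertex_sphere$colatitude[rim_verts]), 111.56)
  ## determinism: a second run is bit-identical
  rec2 <- reconstruct_retina(synth_small(0.02, 1)$outline,
                             rim_angle = 111.56)
  expect_identical(rec2$E_L, rec$E_L)
  expect_identical(rec2$u, rec$u)
})

test_that("a finely cut flattening reconstructs with very low deformation", {
  ## with six cuts the flattening of the adult cap is close to
  ## distortion-free, so the reconstruction's residual strain is small
  s <- suppressWarnings(synth_retina(n_cuts = 6, cut_depth = 0.8,
                                     noise = 0, seed = 2,
                                     mesh_triangles = 600))
  rec <- reconstruct_retina(s$outline, rim_angle = 111.56)
  expect_lt(rec$E_L, 0.02)
  expect_equal(rec$folded, 0)
})

test_that("cut-free outlines reconstruct (rim = whole perimeter)", {
  o <- flat_outline(circle_outline(80, 1000), nasal_pole_index = 1)
  rec <- suppressMessages(reconstruct_retina(o, rim_angle = 30))
  expect_s3_class(rec, "retina_reconstruction")
  expect_equal(nrow(rec$mesh$correspondences), 0)
  expect_lt(rec$E_L, 0.05)     # shallow cap: disc is nearly isometric
})

test_that("tissue loss inflates the deformation measure and the flag", {
  s1 <- synth_small(0, 1)
  v <- s1$outline$vertices
  az <- atan2(v[, 2], v[, 1])
  r <- sqrt(rowSums(v^2))
  mangle <- function(depth) {
    r2 <- r * (1 - depth * exp(-((az - 0) / 0.9)^2))
    o <- flat_outline(cbind(r2 * cos(az), r2 * sin(az)),
                      cuts = s1$outline$cuts,
                      nasal_pole_index = s1$outline$nasal_pole_index)
    attr(o, "resampled") <- TRUE
    o
  }
  intact <- recon_small(0, 1)
  lost25 <- reconstruct_retina(mangle(0.6), rim_angle = 111.56)
  lost30 <- reconstruct_retina(mangle(0.85), rim_angle = 111.56)
  expect_lt(intact$E_L, 0.05)
  expect_gt(lost25$E_L, 0.1)            # ~25% of area removed
  expect_true(lost25$flag != "ok")
  expect_gt(lost30$E_L, 0.15)           # ~30% removed: noticeably bad
  expect_true(lost30$flag %in% c("bad", "reject"))
})

test_that("map_to_sphere is exact at vertices and safe at edges", {
  rec <- recon_small(0.02, 1)
  vidx <- c(10, 200, 400)
  mp <- map_to_sphere(rec, rec$mesh$vertices[vidx, ])
  expect_equal(mp$colatitude, rec$vertex_sphere$colatitude[vidx],
               tolerance = 1e-9)
  expect_equal(mp$longitude, rec$vertex_sphere$longitude[vidx],
               tolerance = 1e-9)
  ## a triangle centroid lands within that spherical triangle
  tr <- rec$mesh$triangles[50, ]
  cen <- colMeans(rec$mesh$vertices[tr, ])
  mc <- map_to_sphere(rec, rbind(cen))
  corners <- sph_point(rec$vertex_sphere$colatitude[tr],
                       rec$vertex_sphere$longitude[tr])
  dmax <- max(geodesic_angle(corners[c(1, 2, 3), ],
                             corners[c(2, 3, 1), ]))
  expect_true(all(geodesic_angle(mc, corners) <= dmax + 1e-9))
  ## every mapped point stays inside the rim
  ev <- eval_small(0.02, 1)
  mapped <- map_to_sphere(ev$reconstruction, ev$points$flat)
  expect_true(all(mapped$colatitude <= 111.56 + 1e-6))
  ## far-outside points are unmappable, with indices reported
  far <- rbind(c(1e6, 1e6), cen)
  expect_error(map_to_sphere(rec, far), "unmappable.*1")
  ## slightly outside: snapped with a message
  ring_v <- rec$mesh$vertices[rec$mesh$ring, ]
  out_dir <- ring_v[5, ] / sqrt(sum(ring_v[5, ]^2))
  near <- rbind(ring_v[5, ] + out_dir * 1e-3)
  expect_message(map_to_sphere(rec, near), "snapped")
})

test_that("rim-angle search recovers the generating angle", {
  ## a finely cut, noise-free flattening is nearly isometric, so the
  ## deformation profile has a sharp minimum at the true rim angle (a
  ## coarsely cut equilibrium flattening shortens its rim elastically
  ## and biases the inferred angle low, as real preparations do)
  s <- cached("synth_rim110", function()
    suppressWarnings(synth_retina(rim_angle = 110, n_cuts = 12,
                                  cut_depth = 0.9, noise = 0, seed = 3,
                                  mesh_triangles = 600)))
  inf <- infer_rim_angle(s$outline, centre = 112, half_range = 4)
  expect_equal(nrow(inf$profile), 9)          # 2 * half_range + 1
  expect_lte(abs(inf$rim_angle - 110), 1)     # within a degree of truth
  expect_lte(min(inf$profile$E_L),
             inf$profile$E_L[inf$profile$angle == 112])
})
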