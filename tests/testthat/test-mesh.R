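test_that("triangulation honours the minimum count and equal-size contract", {
  o <- resample_outline(flat_outline(circle_outline(80, r = 1000)), 300)
  m <- triangulate_outline(o, min_triangles = 500)
  expect_gte(nrow(m$triangles), 500)
  ar <- triangle_areas(m$vertices, m$triangles)
  expect_true(all(ar > 0))                     # positively oriented
  ## roughly equal size: empirical bound for the area-constrained mesher
  expect_lte(max(ar) / median(ar), 4)
  ## triangle areas tile the polygon
  expect_equal(sum(ar), polygon_area(o$vertices), tolerance = 1e-6)
  ## no triangle has all three vertices on the outline
  nb <- length(m$ring)
  expect_equal(sum(rowSums(matrix(m$triangles %in% m$ring, ncol = 3)) == 3
                   & triangle_areas(m$vertices, m$triangles) >
                     1e-6 * max(ar)), 0)
})

test_that("triangulation rejects degenerate outlines", {
  line3 <- flat_outline(cbind(c(0, 1, 2), c(0, 1e-13, 0)))
  expect_error(triangulate_outline(line3), "meshing error|degenerate")
  fig8 <- flat_outline(cbind(c(0, 2, 0, 2), c(0, 2, 2, 0)) * 100)
  expect_error(triangulate_outline(fig8), "self-intersecting")
})

test_that("equal-size bound holds across random smooth outlines", {
  set.seed(21)
  for (k in 1:6) {
    th <- seq(0, 2 * pi, length.out = 121)[-121]
    r <- 1000 * (1 + 0.25 * sin(sample(2:5, 1) * th + runif(1, 0, 2 * pi)))
    o <- resample_outline(flat_outline(cbind(r * cos(th), r * sin(th))), 250)
    m <- triangulate_outline(o, min_triangles = 500)
    ar <- triangle_areas(m$vertices, m$triangles)
    expect_gte(nrow(m$triangles), 500)
    expect_lte(max(ar) / median(ar), 4)
  }
})

test_that("resampling preserves marked vertices and total shape", {
  o <- vcut_disc()
  r <- resample_outline(o, 200)
  ## anchors survive at their exact coordinates
  cm0 <- o$cuts[[1]]; cm1 <- r$cuts[[1]]
  expect_equal(r$vertices[cm1$apex, ], o$vertices[cm0$apex, ])
  expect_equal(r$vertices[cm1$forward_a, ], o$vertices[cm0$forward_a, ])
  expect_equal(r$vertices[r$nasal_pole_index, ],
               o$vertices[o$nasal_pole_index, ])
  expect_equal(polygon_area(r$vertices), polygon_area(o$vertices),
               tolerance = 1e-3)
  ## roughly uniform spacing
  v <- r$vertices; n <- nrow(v)
  seg <- sqrt(rowSums((v[c(2:n, 1), ] - v)^2))
  expect_lt(max(seg) / median(seg), 3)
})

test_that("stitching a cut-free outline is a no-op with full-perimeter rim", {
  o <- resample_outline(flat_outline(circle_outline(60, r = 800),
                                     nasal_pole_index = 1), 150)
  m <- stitch_mesh(triangulate_outline(o, min_triangles = 500))
  expect_equal(nrow(m$correspondences), 0)
  expect_equal(sort(m$rim_vertices), sort(m$ring))
  expect_equal(euler_characteristic(m), 1)
})

test_that("symmetric V-cut pairs mirror vertices at equal arc length", {
  o <- resample_outline(vcut_disc(n = 60, m = 9), 250)
  m0 <- triangulate_outline(o, min_triangles = 500)
  v0 <- m0$vertices
  m <- stitch_mesh(m0)
  expect_gt(nrow(m$correspondences), 0)
  ## stitching only inserts vertices, never moves them
  expect_equal(m$vertices[seq_len(nrow(v0)), ], v0)
  ## oracle: the fixture is mirror-symmetric about the x axis, so each
  ## corresponded pair must be a mirror pair (same x, opposite y)
  pa <- m$vertices[m$correspondences[, 1], , drop = FALSE]
  pb <- m$vertices[m$correspondences[, 2], , drop = FALSE]
  expect_equal(pa[, 1], pb[, 1], tolerance = 1e-6)
  expect_equal(pa[, 2], -pb[, 2], tolerance = 1e-6)
  ## oracle: equal normalised arc length along the two flanks, computed
  ## independently from the outline polyline
  cm <- m$cuts[[1]]
  arc <- function(idx) {
    p <- m$vertices[idx, , drop = FALSE]
    c(0, cumsum(sqrt(rowSums(diff(p)^2))))
  }
  fa <- retinamorph:::ring_walk(m$ring, cm$forward_a, cm$apex)
  fb <- rev(retinamorph:::ring_walk(m$ring, cm$apex, cm$forward_b))
  ta <- arc(fa); ta <- ta / max(ta)
  tb <- arc(fb); tb <- tb / max(tb)
  for (k in seq_len(nrow(m$correspondences))) {
    ia <- match(m$correspondences[k, 1], fa)
    ib <- match(m$correspondences[k, 2], fb)
    if (!is.na(ia) && !is.na(ib))
      expect_equal(ta[ia], tb[ib], tolerance = 1e-6)
  }
  ## contraction gives a disc
  expect_equal(euler_characteristic(m), 1)
  ## the rim excludes the flanks but keeps the (merged) mouth
  expect_false(cm$apex %in% m$rim_vertices)
  expect_true(cm$forward_a %in% m$rim_vertices)
})

test_that("stitched synthetic retinae contract to a single-boundary disc", {
  for (noise in c(0, 0.02)) {
    rec <- recon_small(noise, 1)
    m <- rec$mesh
    expect_gte(nrow(m$triangles), 500)
    expect_equal(euler_characteristic(m), 1)
    ## the contracted boundary is one closed ring: every boundary edge
    ## class appears exactly twice in the rim cycle walk
    cls <- m$merged
    tri <- matrix(cls[m$triangles], ncol = 3)
    e <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
    e <- e[e[, 1] != e[, 2], , drop = FALSE]
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    bnd_cls <- names(table(key))[table(key) == 1]
    rim_cls <- unique(cls[m$rim_vertices])
    bnd_verts <- unique(unlist(strsplit(bnd_cls, " ")))
    expect_setequal(as.integer(bnd_verts), rim_cls)
  }
})

test_that("nested tear keeps the outer cut pairing intact", {
  ## outer V-cut with a small tear (a notch of positive width) inside
  ## one flank: flank A of the outer cut runs over vertices 60..68
  o <- vcut_disc(n = 60, m = 9)
  v <- o$vertices
  p1 <- v[63, ]; p2 <- v[64, ]
  dirv <- p2 - p1
  nrm <- c(-dirv[2], dirv[1]); nrm <- nrm / sqrt(sum(nrm^2))
  notch_apex <- (p1 + p2) / 2 + nrm * 60
  v2 <- rbind(v[1:63, ], notch_apex, v[64:nrow(v), ])
  o2 <- flat_outline(v2, cuts = list(cut_markup(60, 69, 1),
                                     cut_markup(63, 64, 65)),
                     nasal_pole_index = 15)
  expect_true(validate_markup(o2)$ok)
  m <- stitch_mesh(triangulate_outline(resample_outline(o2, 250),
                                       min_triangles = 500))
  expect_equal(euler_characteristic(m), 1)
  ## the outer mouth pair is still matched rim-to-rim
  pairs <- m$correspondences
  expect_true(any(pairs[, 1] == m$cuts[[1]]$forward_a &
                  pairs[, 2] == m$cuts[[1]]$forward_b))
  ## tear mouths are identified with each other
  expect_true(any(pairs[, 1] == m$cuts[[2]]$forward_a &
                  pairs[, 2] == m$cuts[[2]]$forward_b))
  ## oracle on the outer flank: the tear interval contributes nothing to
  ## the outer parameterisation, so pairs outside the tear match the
  ## tear-skipping arc-length parameterisation of the two flanks
  stf <- list2env(list(vertices = m$vertices, triangles = m$triangles,
                       ring = m$ring))
  fA <- retinamorph:::flank_params(stf, m$cuts[[1]]$forward_a,
                                   m$cuts[[1]]$apex, TRUE,
                                   list(m$cuts[[2]]))
  fB <- retinamorph:::flank_params(stf, m$cuts[[1]]$forward_b,
                                   m$cuts[[1]]$apex, FALSE, list())
  ## pairs agree in parameter up to the documented vertex-reuse slack
  ## (10% of the local inter-vertex spacing)
  for (k in seq_len(nrow(pairs))) {
    ia <- match(pairs[k, 1], fA$seq)
    ib <- match(pairs[k, 2], fB$seq)
    if (!is.na(ia) && !is.na(ib) && fA$match[ia]) {
      spacing <- max(diff(sort(fB$t))[pmax(1, ib - 1)],
                     retinamorph:::local_spacing(fA$t[!duplicated(fA$t)],
                                                 fA$t[ia]))
      expect_lte(abs(unname(fA$t[ia]) - unname(fB$t[ib])),
                 0.1 * spacing + 1e-9)
    }
  }
})

test_that("zero-length flank raises a stitch error", {
  o <- vcut_disc()
  o$cuts[[1]] <- cut_markup(48, 48, 48)
  m <- triangulate_outline(resample_outline(o, 150), min_triangles = 500)
  expect_error(stitch_mesh(m), "zero length|flank")
})
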