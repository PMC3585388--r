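test_that("Karcher mean handles the degenerate and two-point cases", {
  p1 <- sph_point(37, -12)
  km <- karcher_mean(p1)
  expect_equal(km$mean$colatitude, 37, tolerance = 1e-9)
  expect_equal(km$mean$longitude, -12, tolerance = 1e-9)
  expect_equal(km$sd_deg, 0, tolerance = 1e-7)
  ## two points: the great-circle midpoint (slerp at t = 1/2)
  p2 <- sph_point(c(20, 80), c(10, 60))
  u <- sph_to_cart(p2)
  mid <- cart_to_sph(matrix(colSums(u), 1))    # for two points: normalised sum
  km2 <- karcher_mean(p2)
  expect_equal(km2$mean$colatitude, mid$colatitude, tolerance = 1e-7)
  expect_equal(km2$mean$longitude, mid$longitude, tolerance = 1e-7)
  expect_error(karcher_mean(sph_point(numeric(0), numeric(0))), "non-empty")
})

test_that("Karcher mean matches a brute-force grid minimiser", {
  set.seed(42)
  n <- 50
  p <- sph_point(30 + rnorm(n, sd = 4), 45 + rnorm(n, sd = 5))
  km <- karcher_mean(p)
  ## independent oracle: exhaustive 0.1-degree grid search of the summed
  ## squared geodesic distance around the cluster
  grid <- expand.grid(colat = seq(24, 36, by = 0.1),
                      lon = seq(38, 52, by = 0.1))
  gp <- sph_point(grid$colat, grid$lon)
  gu <- sph_to_cart(gp)
  pu <- sph_to_cart(p)
  ang <- acos(pmin(pmax(tcrossprod(gu, pu), -1), 1))
  best <- which.min(rowSums(ang^2))
  expect_lte(geodesic_angle(km$mean, gp[best, ]), 0.1)
  ## angular SD against the direct definition
  expect_equal(km$sd_deg,
               sqrt(mean(geodesic_angle(p, km$mean)^2)), tolerance = 1e-6)
})

test_that("Karcher mean is rotation-equivariant and order-invariant", {
  set.seed(8)
  p <- sph_point(runif(30, 10, 70), runif(30, -100, 100))
  km <- karcher_mean(p)
  for (k in 1:3) {
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    pr <- cart_to_sph(sph_to_cart(p) %*% t(q))
    kmr <- karcher_mean(pr)
    expected <- cart_to_sph(sph_to_cart(km$mean) %*% t(q))
    expect_lte(geodesic_angle(kmr$mean, expected), 1e-5)
    expect_equal(kmr$sd_deg, km$sd_deg, tolerance = 1e-6)
  }
  perm <- karcher_mean(p[sample(30), ])
  expect_lte(geodesic_angle(perm$mean, km$mean), 1e-6)
})

test_that("vMF kernel density integrates to one and finds tight clusters", {
  ## numeric quadrature of a single kernel centred at the pole
  one <- kde_vmf(sph_point(rep(0, 5), 0), kappa = 50)
  colat <- seq(0.25, 179.75, by = 0.5)
  lon <- seq(-179.5, 180, by = 1)
  g <- expand.grid(colat = colat, lon = lon)
  f <- one$evaluate(sph_point(g$colat, g$lon))
  dA <- sin(g$colat * pi / 180) * (0.5 * pi / 180) * (pi / 180)
  expect_equal(sum(f * dA), 1, tolerance = 0.01)
  ## a single tight cluster: peak within a degree of the centre
  set.seed(5)
  pts <- sph_point(50 + rnorm(40, sd = 1.5), -30 + rnorm(40, sd = 2))
  est <- kde_vmf(pts)
  expect_lte(geodesic_angle(est$peak, sph_point(50, -30)), 1)
  expect_error(kde_vmf(sph_point(c(1, 2), c(3, 4))), "at least 5")
})

test_that("uniform cap samples give a nearly flat density", {
  s <- synth_small(0.02, 1)
  set.seed(9)
  sc <- scatter_truth_points(s, "uniform", n = 400, seed = 9)
  est <- kde_vmf(sc$truth)
  cap_area <- 2 * pi * (1 - cos(111.56 * pi / 180))
  uniform_density <- 1 / cap_area
  peak_f <- est$evaluate(est$peak)
  expect_lt(peak_f, 2 * uniform_density)
})

test_that("exclusion contours exclude the order-statistic count", {
  set.seed(12)
  pts <- sph_point(40 + rnorm(20, sd = 6), 10 + rnorm(20, sd = 6))
  est <- kde_vmf(pts, kappa = 100)
  lev <- exclusion_contours(est, pts, fractions = c(0, 5, 25, 50, 95))
  f <- est$evaluate(pts)
  excluded <- vapply(lev, function(l) sum(f < l), 0)
  expect_equal(unname(excluded), c(0, 1, 5, 10, 19))
  expect_true(all(diff(lev) >= 0))       # levels increase with fraction
  ## f = 0: every point inside
  expect_lte(lev[1], min(f))
})

test_that("mean and mode disagree on a skewed sample", {
  set.seed(31)
  ## dense core plus a one-sided tail
  core <- sph_point(30 + rnorm(60, sd = 2), 45 + rnorm(60, sd = 2.5))
  tail <- sph_point(runif(25, 38, 75), 45 + rnorm(25, sd = 4))
  pts <- rbind(core, tail)
  km <- karcher_mean(pts)
  est <- kde_vmf(pts)
  expect_gt(geodesic_angle(est$peak, km$mean), 2)
  ## the order of the input points changes nothing
  est2 <- kde_vmf(pts[sample(nrow(pts)), ])
  expect_equal(est2$kappa, est$kappa)
  expect_lte(geodesic_angle(est2$peak, est$peak), 0.2)
})

test_that("kernel regression reproduces flat and peaked intensities", {
  set.seed(77)
  centres <- sph_point(runif(60, 5, 100), runif(60, -180, 180))
  ## constant counts give a constant surface
  kr <- kernel_regression(centres, rep(7, 60), kappa = 30)
  q <- sph_point(runif(40, 5, 100), runif(40, -180, 180))
  expect_equal(kr$evaluate(q), rep(7, 40), tolerance = 1e-6)
  ## a single non-zero box puts the peak at that box (evenly spaced
  ## boxes, so the weight denominator is nearly constant)
  i <- 1:120
  z <- 1 - (i - 0.5) / 120 * (1 - cos(100 * pi / 180))
  grid_centres <- cart_to_sph(cbind(
    sqrt(1 - z^2) * cos(pi * (1 + sqrt(5)) * i),
    sqrt(1 - z^2) * sin(pi * (1 + sqrt(5)) * i), z))
  counts1 <- rep(0, 120); counts1[60] <- 5   # an interior box
  kr1 <- kernel_regression(grid_centres, counts1, kappa = 100)
  expect_lte(geodesic_angle(kr1$peak, grid_centres[60, ]), 1)
  expect_error(kernel_regression(centres, rep(0, 60)), "zero")
  expect_error(kernel_regression(centres[1:3, ], rep(1, 3)), "at least 5")
})

test_that("kernel regression recovers a smooth synthetic intensity", {
  ## boxes on a grid over the cap, counts from a smooth field
  set.seed(15)
  n <- 300
  cosphi <- 1 - runif(n) * (1 - cos(111.56 * pi / 180))
  centres <- sph_point(acos(cosphi) * 180 / pi, runif(n, -180, 180))
  field <- function(p) 20 + 15 * cos(p$colatitude * pi / 90) *
    cos(p$longitude * pi / 180)
  counts <- field(centres)
  kr <- kernel_regression(centres, counts)
  probe <- sph_point(runif(100, 10, 100), runif(100, -170, 170))
  pred <- kr$evaluate(probe)
  truth <- field(probe)
  rms <- sqrt(mean((pred - truth)^2)) / mean(abs(truth))
  expect_lt(rms, 0.15)
})
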