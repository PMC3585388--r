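## Synthetic flat-mounts with known spherical ground truth.
##
## The generator emulates the dissection and flattening of a retina: a
## spherical cap of the requested rim colatitude is cut along meridians
## to the requested depth, developed into the plane, and then relaxed as
## a 2D elastic sheet whose spring natural lengths are the true geodesic
## edge lengths on the sphere (optionally perturbed by multiplicative
## noise, emulating tissue distortion).  Because a curved cap cannot be
## flattened isometrically, the elastic equilibrium is the natural model
## of how real tissue distributes the unavoidable strain.  Every flat
## vertex carries its exact spherical origin, so reconstruction accuracy
## can be measured against ground truth at any point.
##
## The development used as the relaxation's starting layout keeps radii
## proportional to colatitude and scales azimuths within each sector so
## that arcs fit their true lengths, which opens a V-shaped gap at each
## cut, as in a real flat-mount.

#' Generate a synthetic flat-mounted retina with known ground truth
#'
#' @param rim_angle Rim colatitude of the true cap, degrees.
#' @param n_cuts Number of meridional relaxing cuts (0 for an uncut cap).
#' @param cut_depth Depth of each cut as a fraction of the rim colatitude
#'   (0 <= cut_depth < 1); the cut apex sits at colatitude
#'   `(1 - cut_depth) * rim_angle`.
#' @param noise Amplitude of multiplicative edge-length noise applied to
#'   the true lengths before relaxation (0 = noise-free flattening).
#' @param seed Integer seed; the generator is deterministic given it.
#' @param flat_radius Approximate flattened radius in micrometres
#'   (default 1600, mimicking an adult mouse flat-mount).
#' @param mesh_triangles Resolution of the generator's internal mesh.
#' @return An object of class `synthetic_retina`: `outline` (a marked-up
#'   [flat_outline()]), `gen` (the generator mesh: relaxed and initial
#'   vertex layouts, triangles, per-vertex spherical truth) and `params`.
#' @export
synth_retina <- function(rim_angle = 111.56, n_cuts = 4, cut_depth = 0.8,
                         noise = 0.02, seed = 1, flat_radius = 1600,
                         mesh_triangles = 800) {
  if (n_cuts < 0 || cut_depth < 0 || cut_depth >= 1 || noise < 0)
    stop("invalid generator parameters")
  phi0 <- deg2rad(rim_angle)
  R <- flat_radius / phi0
  if (cut_depth == 0) n_cuts <- 0
  phia <- (1 - cut_depth) * phi0

  dev <- make_development(phi0, phia, n_cuts, R)
  ring <- build_synth_ring(dev, phi0, phia, n_cuts, R)
  o0 <- flat_outline(ring$pts, cuts = ring$cuts,
                     nasal_pole_index = ring$nasal)
  attr(o0, "resampled") <- TRUE
  mesh <- triangulate_outline(o0, min_triangles = mesh_triangles)
  truth <- dev$invert(mesh$vertices)

  ## spring targets: true geodesic lengths, in micrometres, with noise
  ew <- mesh_edges(mesh$vertices, mesh$triangles)
  ut <- sph_to_cart(truth)
  tgt <- geodesic_rad(ut[ew$edges[, 1], , drop = FALSE],
                      ut[ew$edges[, 2], , drop = FALSE]) * R
  if (noise > 0) {
    set.seed(seed)
    tgt <- tgt * (1 + noise * pmax(pmin(stats::rnorm(length(tgt)), 3), -3))
  }
  stri <- ring$slit_tris
  if (nrow(stri)) {
    neg <- triangle_areas(mesh$vertices, stri) < 0
    stri[neg, ] <- stri[neg, c(1, 3, 2)]
  }
  relaxed <- relax_planar(mesh$vertices, ew$edges, tgt, mesh$triangles, stri)
  relaxed <- procrustes2d(relaxed, mesh$vertices)

  nb <- length(mesh$ring)
  out <- flat_outline(relaxed[seq_len(nb), , drop = FALSE],
                      cuts = mesh$cuts,
                      nasal_pole_index = mesh$nasal_vertex)
  attr(out, "resampled") <- TRUE
  structure(list(
    outline = out,
    gen = list(vertices = relaxed, init_vertices = mesh$vertices,
               triangles = mesh$triangles, truth = truth, n_boundary = nb),
    params = list(rim_angle = rim_angle, n_cuts = n_cuts,
                  cut_depth = cut_depth, noise = noise, seed = seed,
                  flat_radius = flat_radius, sphere_radius = R)
  ), class = "synthetic_retina")
}

#' @export
print.synthetic_retina <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "Synthetic flat-mount: rim angle %.2f deg, %d cut(s) depth %.2f, noise %.3f, seed %d\n",
    p$rim_angle, p$n_cuts, p$cut_depth, p$noise, p$seed))
  cat("  generator mesh:", nrow(x$gen$vertices), "vertices,",
      nrow(x$gen$triangles), "triangles\n")
  invisible(x)
}

## The development maps spherical (colatitude phi, longitude lam, both
## radians) to the plane: radius phi*R; azimuth scaled within each sector
## by g(phi) = (sin phi / phi) * (phia / sin phia) for phi >= phia so
## circumferential arcs keep their true length relative to the apex
## circle, and unscaled below the apexes (where the tissue is uncut).
make_development <- function(phi0, phia, n_cuts, R) {
  gfun <- function(phi) {
    g <- rep(1, length(phi))
    if (n_cuts > 0) {
      above <- phi > phia
      g[above] <- (sin(phi[above]) / phi[above]) * (phia / sin(phia))
    }
    g
  }
  cut_lams <- if (n_cuts > 0)
    deg2rad(-180 + (seq_len(n_cuts) - 0.5) * 360 / n_cuts) else numeric(0)
  centre_of <- function(lam) {
    ## sector centre for each longitude (sectors bounded by cut meridians)
    if (n_cuts == 0) return(rep(0, length(lam)))
    width <- 2 * pi / n_cuts
    k <- floor((lam - cut_lams[1]) / width)
    wrap_pi(cut_lams[1] + (k + 0.5) * width)
  }
  forward <- function(phi, lam) {
    lc <- centre_of(lam)
    alpha <- lc + angdiff(lam, lc) * gfun(phi)
    cbind(phi * R * cos(alpha), phi * R * sin(alpha))
  }
  invert <- function(xy) {
    r <- sqrt(xy[, 1]^2 + xy[, 2]^2)
    alpha <- atan2(xy[, 2], xy[, 1])
    phi <- pmin(r / R, phi0)
    lam <- alpha
    if (n_cuts > 0) {
      above <- phi > phia
      if (any(above)) {
        lc <- centre_of(alpha[above])   # sector centres are fixed points
        g <- gfun(phi[above])
        lam[above] <- lc + angdiff(alpha[above], lc) / g
        ## clamp into the sector
        half <- pi / n_cuts
        lam[above] <- lc + pmin(pmax(angdiff(lam[above], lc), -half), half)
      }
    }
    sph_point(rad2deg(phi), rad2deg(wrap_pi(lam)))
  }
  list(forward = forward, invert = invert, gfun = gfun, cut_lams = cut_lams,
       centre_of = centre_of)
}

wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- pi
  y
}
angdiff <- function(a, b) wrap_pi(a - b)

## Boundary ring of the developed domain: rim arcs of each sector joined
## by the two flanks of each cut (meeting at the apex), walked
## counter-clockwise, with cut mark-up and the nasal vertex at the rim
## point nearest longitude zero.
build_synth_ring <- function(dev, phi0, phia, n_cuts, R) {
  spacing <- phi0 * R / 55   # ring spacing ~ 1/55 of flattened radius
  devpt <- function(phi, lc, lam)   # development with explicit sector centre
    c(phi * R * cos(lc + (lam - lc) * dev$gfun(phi)),
      phi * R * sin(lc + (lam - lc) * dev$gfun(phi)))
  pts <- list()
  add <- function(p) { pts[[length(pts) + 1]] <<- p; length(pts) }
  if (n_cuts == 0) {
    m <- max(24, round(2 * pi * phi0 * R / spacing))
    lam <- seq(-pi, pi, length.out = m + 1)[-(m + 1)]
    for (l in lam) add(devpt(phi0, 0, l))
    return(list(pts = do.call(rbind, pts), cuts = list(),
                nasal = which.min(abs(lam)),
                slit_tris = matrix(integer(0), ncol = 3)))
  }
  cl <- dev$cut_lams                # ascending in (-pi, pi]
  g0 <- dev$gfun(phi0)
  width <- 2 * pi / n_cuts
  kf <- max(4, round((phi0 - phia) * R / spacing))
  phis <- seq(phi0, phia, length.out = kf + 1)
  cuts <- list()
  nasal <- NA_integer_; nasal_best <- Inf
  fa_idx <- integer(n_cuts); apex_idx <- integer(n_cuts)
  fb_idx <- integer(n_cuts)
  desc_idx <- vector("list", n_cuts); asc_idx <- vector("list", n_cuts)
  for (s in seq_len(n_cuts)) {
    lam_a <- cl[s]
    lam_b <- lam_a + width            # next cut meridian (unwrapped)
    lc <- lam_a + width / 2           # this sector's centre
    arc_flat <- width * g0 * phi0 * R
    m <- max(8, round(arc_flat / spacing))
    lam_seq <- seq(lam_a, lam_b, length.out = m + 1)
    for (i in seq_len(m + 1)) {
      idx <- add(devpt(phi0, lc, lam_seq[i]))
      if (i == 1) fb_idx[if (s == 1) n_cuts else s - 1] <- idx
      if (i == m + 1) fa_idx[s] <- idx
      dl <- abs(wrap_pi(lam_seq[i]))
      if (dl < nasal_best) { nasal_best <- dl; nasal <- idx }
    }
    ## descend this sector's side of the meridian lam_b, then the apex
    desc_idx[[s]] <- vapply(2:kf, function(j)
      add(devpt(phis[j], lc, lam_b)), 1L)
    apex_idx[s] <- add(devpt(phia, lc, lam_b))   # g(phia)=1: on the meridian
    ## ascend on the next sector's side (its first rim point comes next)
    asc_idx[[s]] <- rev(vapply(rev(2:kf), function(j)
      add(devpt(phis[j], lc + width, lam_b)), 1L))
  }
  for (s in seq_len(n_cuts))
    cuts[[s]] <- cut_markup(fa_idx[s], apex_idx[s], fb_idx[s])
  ## virtual triangles spanning each open slit: they carry no springs but
  ## enter the relaxation's fold penalty, so the flanks cannot cross
  slit <- list()
  for (s in seq_len(n_cuts)) {
    a <- c(fa_idx[s], desc_idx[[s]], apex_idx[s])   # rim -> apex, this side
    b <- c(fb_idx[s], asc_idx[[s]], apex_idx[s])    # rim -> apex, far side
    for (i in seq_len(length(a) - 1)) {
      if (a[i + 1] != b[i + 1])
        slit[[length(slit) + 1]] <- c(a[i + 1], a[i], b[i + 1])
      slit[[length(slit) + 1]] <- c(b[i + 1], a[i], b[i])
    }
  }
  slit <- if (length(slit)) do.call(rbind, slit) else
    matrix(integer(0), ncol = 3)
  list(pts = do.call(rbind, pts), cuts = cuts, nasal = nasal,
       slit_tris = slit)
}

## Relax a planar mesh so edge lengths approach their targets: L-BFGS-B
## on sum (|e| - t)^2 / (2 t) plus a fold penalty (signed triangle areas
## below a margin), with analytic gradient.  Tissue triangles use margin
## zero (no interpenetration); virtual slit triangles use a small
## positive margin so the flanks of a cut may come close but never into
## exact contact, which keeps the flat outline a simple polygon that
## downstream triangulation can honour.  Deterministic.
relax_planar <- function(v0, edges, targets, triangles, slit_triangles,
                         maxit = 2000) {
  n <- nrow(v0)
  e1 <- edges[, 1]; e2 <- edges[, 2]
  margin <- c(rep(0, nrow(triangles)),
              rep(2e-4 * mean(targets)^2, nrow(slit_triangles)))
  ptri <- rbind(triangles, slit_triangles)
  t1 <- ptri[, 1]; t2 <- ptri[, 2]; t3 <- ptri[, 3]
  scale_pen <- mean(targets)^2   # penalty per unit flipped area ~ O(1) strain
  obj <- function(par, w) {
    x <- matrix(par, ncol = 2)
    d <- x[e1, , drop = FALSE] - x[e2, , drop = FALSE]
    len <- pmax(sqrt(rowSums(d^2)), 1e-12)
    dE <- (len - targets) / targets
    E <- sum((len - targets)^2 / (2 * targets))
    gg <- d * (dE / len)
    G <- matrix(0, n, 2)
    acc <- rowsum(rbind(gg, -gg), c(e1, e2))
    G[as.integer(rownames(acc)), ] <- acc
    if (w > 0) {
      ax <- x[t1, 1]; ay <- x[t1, 2]
      bx <- x[t2, 1]; by <- x[t2, 2]
      cx <- x[t3, 1]; cy <- x[t3, 2]
      a2 <- (bx - ax) * (cy - ay) - (cx - ax) * (by - ay)  # 2 * signed area
      neg <- a2 < margin
      if (any(neg)) {
        wn <- w / scale_pen
        E <- E + wn * sum(margin[neg] - a2[neg])
        s <- rep(0, length(a2)); s[neg] <- -wn
        gA <- cbind(s * (by - cy), s * (cx - bx))
        gB <- cbind(s * (cy - ay), s * (ax - cx))
        gC <- cbind(s * (ay - by), s * (bx - ax))
        accf <- rowsum(rbind(gA, gB, gC), c(t1, t2, t3))
        G[as.integer(rownames(accf)), ] <-
          G[as.integer(rownames(accf)), ] + accf
      }
    }
    list(value = E, grad = as.vector(G))
  }
  par <- as.vector(v0)
  for (w in c(0, 1, 10, 100, 1000, 1e4, 1e5)) {
    fit <- stats::optim(par, fn = function(p) obj(p, w)$value,
                        gr = function(p) obj(p, w)$grad,
                        method = "L-BFGS-B",
                        control = list(maxit = maxit, pgtol = 1e-8,
                                       factr = 1e5))
    par <- fit$par
  }
  matrix(par, ncol = 2)
}

## Rigid (rotation + translation, no scaling, no reflection) alignment
## of x onto y by least squares.
procrustes2d <- function(x, y) {
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  h <- crossprod(xc, yc)
  sv <- svd(h)
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) { sv$v[, 2] <- -sv$v[, 2]; R <- sv$u %*% t(sv$v) }
  sweep(xc %*% R, 2, cy, "+")
}

#' Scatter sample points with known spherical truth on a synthetic retina
#'
#' Samples points on the true spherical cap under a named pattern and
#' pushes them through the generator's known flattening, returning both
#' the flat coordinates (as they would be digitised from the flat-mount)
#' and the true spherical positions.
#'
#' Patterns: `"uniform"` is area-uniform over the whole cap;
#' `"crescent"` is area-uniform over a ventrotemporal crescent
#' (colatitude above `boundary_colat`, longitude within 90 degrees of the
#' ventrotemporal midpoint at 225 degrees), emulating an ipsilaterally
#' projecting region; `"boundary"` places points on the small circle at
#' colatitude `boundary_colat`, emulating a decussation-line boundary.
#'
#' @param s A [synth_retina()] object.
#' @param pattern One of `"uniform"`, `"crescent"`, `"boundary"`.
#' @param n Number of points.
#' @param seed Integer seed.
#' @param boundary_colat Colatitude (degrees) used by the crescent and
#'   boundary patterns.
#' @return A list with `flat` (n-by-2 micrometres) and `truth`
#'   (spherical points).
#' @export
scatter_truth_points <- function(s, pattern = c("uniform", "crescent",
                                                "boundary"),
                                 n = 500, seed = 1, boundary_colat = 64) {
  stopifnot(inherits(s, "synthetic_retina"))
  pattern <- match.arg(pattern)
  set.seed(seed)
  phi0 <- deg2rad(s$params$rim_angle)
  if (pattern == "uniform") {
    cosphi <- 1 - stats::runif(n) * (1 - cos(phi0))
    colat <- rad2deg(acos(cosphi))
    lon <- stats::runif(n, -180, 180)
  } else if (pattern == "crescent") {
    lo <- cos(phi0); hi <- cos(deg2rad(boundary_colat))
    cosphi <- lo + stats::runif(n) * (hi - lo)
    colat <- rad2deg(acos(cosphi))
    lon <- wrap_longitude(225 + stats::runif(n, -90, 90))
  } else {
    colat <- rep(boundary_colat, n)
    lon <- wrap_longitude(seq(0, 360, length.out = n + 1)[-(n + 1)] +
                          stats::runif(1, 0, 360 / n))
  }
  truth <- sph_point(colat, lon)
  flat <- synth_flat_coords(s, truth)
  list(flat = flat, truth = truth)
}

## Push spherical points through the generator's flattening: development
## coordinates, then barycentric transfer from the initial to the relaxed
## layout.  Points exactly on a cut meridian are nudged off it.
synth_flat_coords <- function(s, truth) {
  p <- s$params
  phi0 <- deg2rad(p$rim_angle)
  phia <- (1 - p$cut_depth) * phi0
  dev <- make_development(phi0, phia, p$n_cuts, p$sphere_radius)
  phi <- deg2rad(truth$colatitude)
  lam <- deg2rad(truth$longitude)
  if (p$n_cuts > 0) {
    on_cut <- outer(lam, dev$cut_lams, function(a, b) abs(angdiff(a, b))) |>
      apply(1, min) < 1e-9
    lam[on_cut & phi > phia] <- lam[on_cut & phi > phia] + 1e-8
  }
  w <- dev$forward(phi, lam)
  transfer_barycentric(w, s$gen$init_vertices, s$gen$triangles,
                       s$gen$vertices)
}

## Locate points in a planar mesh and re-express them in a second vertex
## layout with identical topology.
transfer_barycentric <- function(pts, v_from, tri, v_to) {
  ax <- v_from[tri[, 1], 1]; ay <- v_from[tri[, 1], 2]
  bx <- v_from[tri[, 2], 1]; by <- v_from[tri[, 2], 2]
  cx <- v_from[tri[, 3], 1]; cy <- v_from[tri[, 3], 2]
  den <- (by - cy) * (ax - cx) + (cx - bx) * (ay - cy)
  out <- matrix(0, nrow(pts), 2)
  for (k in seq_len(nrow(pts))) {
    w1 <- ((by - cy) * (pts[k, 1] - cx) + (cx - bx) * (pts[k, 2] - cy)) / den
    w2 <- ((cy - ay) * (pts[k, 1] - cx) + (ax - cx) * (pts[k, 2] - cy)) / den
    w3 <- 1 - w1 - w2
    slack <- pmin(w1, w2, w3)
    j <- which.max(slack)
    w <- pmax(c(w1[j], w2[j], w3[j]), 0); w <- w / sum(w)
    out[k, ] <- w[1] * v_to[tri[j, 1], ] + w[2] * v_to[tri[j, 2], ] +
      w[3] * v_to[tri[j, 3], ]
  }
  out
}

#' Reconstruct a synthetic retina and measure point-recovery error
#'
#' Runs the full reconstruction pipeline on the synthetic outline, maps
#' the flat sample points back to the sphere, aligns the recovered
#' longitudes with the truth at the nasal fiducial, and reports the
#' great-circle error of every point against its known truth.
#'
#' @param s A [synth_retina()] object.
#' @param points Output of [scatter_truth_points()]; generated (uniform,
#'   `n_points`, seed from the retina) if omitted.
#' @param n_points Number of uniform sample points when `points` is NULL.
#' @param ... Passed to [reconstruct_retina()].
#' @return A list with `errors` (degrees of arc per point),
#'   `median_error`, `reconstruction` and `points`.
#' @export
evaluate_reconstruction <- function(s, points = NULL, n_points = 500, ...) {
  stopifnot(inherits(s, "synthetic_retina"))
  if (is.null(points))
    points <- scatter_truth_points(s, "uniform", n = n_points,
                                   seed = s$params$seed + 1000L)
  rec <- reconstruct_retina(s$outline, rim_angle = s$params$rim_angle, ...)
  mapped <- map_to_sphere(rec, points$flat)
  ## the reconstruction puts the nasal vertex at longitude 0; the truth
  ## longitude of that vertex fixes the residual rotation about the pole
  nas <- s$outline$nasal_pole_index
  lon_off <- s$gen$truth$longitude[nas]
  aligned <- sph_point(mapped$colatitude, mapped$longitude + lon_off)
  errors <- geodesic_angle(aligned, points$truth)
  list(errors = errors, median_error = stats::median(errors),
       reconstruction = rec, points = points)
}
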