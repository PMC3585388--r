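## Morphing the stitched flat mesh onto a rim-curtailed sphere.
##
## Every mesh edge is treated as a spring whose natural length is the
## length of the corresponding edge in the flat mesh (scaled by the single
## global factor that equates the total flat area with the area of the
## spherical cap inside the rim).  The mesh is first projected onto the
## sphere with all rim vertices on the rim circle, then vertex positions
## are relaxed by quasi-Newton minimisation of the total spring energy
##
##     E = sum_i (l_i - L_i)^2 / (2 L_i)
##
## (stiffness 1/L_i makes the energy extensive and gives the deformation
## measure E_L the character of a mean fractional strain).  Rim vertices
## are constrained to the rim circle (their longitude is the only free
## coordinate); corresponded cut vertices share one position; interior
## vertices are parameterised by unnormalised 3D coordinates, radially
## projected onto the sphere, which avoids coordinate singularities at
## the pole.  A penalty on negatively oriented spherical triangles,
## ramped up over optimisation stages, discourages folds.

## ---- reduced (contracted) system ------------------------------------

## Build the contracted vertex system of a stitched mesh: one node per
## correspondence class, reduced edge list (parallel springs kept,
## self-loops dropped), flat natural lengths scaled to sphere units.
reduced_system <- function(mesh, phi0) {
  stopifnot(isTRUE(mesh$stitched))
  cls <- mesh$merged
  ncls <- max(cls)
  flat_area <- sum(triangle_areas(mesh$vertices, mesh$triangles))
  cap_area <- 2 * pi * (1 - cos(deg2rad(phi0)))
  scale <- sqrt(cap_area / flat_area)
  e1 <- cls[mesh$edges[, 1]]; e2 <- cls[mesh$edges[, 2]]
  keep <- e1 != e2
  ## class representative flat positions (mean over members)
  cx <- rowsum(mesh$vertices, cls)
  cnt <- as.vector(rowsum(rep(1, length(cls)), cls))
  cpos <- cx / cnt
  ## rim classes in ring order (consecutive duplicates collapse)
  rim_cls <- cls[mesh$rim_vertices]
  rim_cls <- rim_cls[c(TRUE, diff(rim_cls) != 0)]
  if (length(rim_cls) > 1 && rim_cls[1] == rim_cls[length(rim_cls)])
    rim_cls <- rim_cls[-length(rim_cls)]
  tri_cls <- matrix(cls[mesh$triangles], ncol = 3)
  good_tri <- tri_cls[, 1] != tri_cls[, 2] & tri_cls[, 2] != tri_cls[, 3] &
    tri_cls[, 3] != tri_cls[, 1]
  list(cls = cls, ncls = ncls, cpos = cpos,
       edges = cbind(e1[keep], e2[keep]),
       L = mesh$edge_lengths[keep] * scale,
       rim = rim_cls,
       interior = setdiff(seq_len(ncls), rim_cls),
       tri = tri_cls[good_tri, , drop = FALSE],
       scale = scale, flat_area = flat_area,
       nasal = if (!is.na(mesh$nasal_vertex)) cls[mesh$nasal_vertex] else NA)
}

## ---- initial projection ---------------------------------------------

#' Initial projection of a stitched mesh onto the curtailed sphere
#'
#' Rim vertices are placed on the rim circle at colatitude `phi0`, with
#' longitudes proportional to cumulative arc length along the rim.
#' Interior vertices are placed by an area-matching rule: a vertex whose
#' radius about the flat area centroid encloses a fraction A of the flat
#' mesh area is given the colatitude whose spherical-cap area is the same
#' fraction of the cap inside the rim; its longitude interpolates the rim
#' assignment by planar azimuth.  Corresponded cut vertices coincide by
#' construction (they are a single contracted node).
#'
#' @param mesh A stitched mesh ([stitch_mesh()]).
#' @param phi0 Rim colatitude in degrees.
#' @return An n-class-by-3 matrix of unit vectors (one row per contracted
#'   vertex class), with attribute `"sys"` holding the contracted system.
#' @export
initial_projection <- function(mesh, phi0) {
  sys <- reduced_system(mesh, phi0)
  if (length(sys$rim) < 3) stop("invalid mesh: rim ring is not closed")
  v <- sys$cpos
  ar <- triangle_areas(mesh$vertices, mesh$triangles)
  cen <- cbind(
    (mesh$vertices[mesh$triangles[, 1], 1] +
     mesh$vertices[mesh$triangles[, 2], 1] +
     mesh$vertices[mesh$triangles[, 3], 1]) / 3,
    (mesh$vertices[mesh$triangles[, 1], 2] +
     mesh$vertices[mesh$triangles[, 2], 2] +
     mesh$vertices[mesh$triangles[, 3], 2]) / 3)
  c0 <- colSums(cen * ar) / sum(ar)
  ## rim longitudes from cumulative arc length, nasal vertex at 0.
  ## Steps are measured between the closest members of consecutive
  ## contracted classes, so a stitched cut mouth (whose two sides merge)
  ## contributes its true, nearly zero arc rather than the chord across
  ## the open V gap of the flat mount.
  members <- split(seq_along(sys$cls), sys$cls)
  nrim <- length(sys$rim)
  step <- vapply(seq_len(nrim), function(i) {
    a <- members[[sys$rim[i]]]
    b <- members[[sys$rim[if (i == nrim) 1 else i + 1]]]
    min(sqrt(outer(mesh$vertices[a, 1], mesh$vertices[b, 1], "-")^2 +
             outer(mesh$vertices[a, 2], mesh$vertices[b, 2], "-")^2))
  }, 0)
  rp <- v[sys$rim, , drop = FALSE]
  cum <- c(0, cumsum(step[-nrim]))
  lon_rim <- 360 * cum / sum(step)
  ## anchor at the nasal class if marked, else at the first rim vertex
  i0 <- if (!is.na(sys$nasal)) match(sys$nasal, sys$rim) else 1L
  if (is.na(i0)) i0 <- 1L
  lon_rim <- wrap_longitude(lon_rim - lon_rim[i0])
  ## interior colatitude: area fraction inside each radius
  rad_t <- sqrt((cen[, 1] - c0[1])^2 + (cen[, 2] - c0[2])^2)
  ord <- order(rad_t)
  cumarea <- cumsum(ar[ord]) / sum(ar)
  rad_v <- sqrt((v[, 1] - c0[1])^2 + (v[, 2] - c0[2])^2)
  frac <- stats::approx(x = c(0, rad_t[ord]), y = c(0, cumarea), xout = rad_v,
                        rule = 2, ties = "ordered")$y
  colat <- rad2deg(acos(1 - frac * (1 - cos(deg2rad(phi0)))))
  ## interior longitude: interpolate the rim's azimuth -> longitude map
  az <- rad2deg(atan2(v[, 2] - c0[2], v[, 1] - c0[1]))
  az_rim <- az[sys$rim]
  lon_of_az <- make_cyclic_interp(az_rim, lon_rim)
  lon <- lon_of_az(az)
  u <- sph_to_cart(sph_point(pmin(colat, phi0), lon))
  ## rim nodes exactly on the rim circle
  u[sys$rim, ] <- sph_to_cart(sph_point(rep(phi0, nrim), lon_rim))
  attr(u, "sys") <- sys
  u
}

## Piecewise-linear cyclic interpolation longitude(azimuth) built from
## rim samples.  Falls back to the identity-like map (longitude = azimuth
## offset) when the rim azimuths are too disordered to invert.
make_cyclic_interp <- function(az, lon) {
  ord <- order(az)
  a <- az[ord]; l <- lon[ord]
  lu <- unwrap_cyclic(l)
  ## require near-monotone longitude along sorted azimuth
  if (mean(diff(lu) > 0) < 0.9) {
    off <- wrap_longitude(stats::median(lon - az))
    return(function(x) wrap_longitude(x + off))
  }
  lu <- cummax(lu)   # enforce monotonicity against small jitters
  a_ext <- c(a - 360, a, a + 360)
  l_ext <- c(lu - 360, lu, lu + 360)
  function(x) wrap_longitude(stats::approx(a_ext, l_ext, xout = x,
                                           ties = "ordered")$y)
}

## Unwrap a cyclic sequence of angles (degrees) to a continuous one.
unwrap_cyclic <- function(x) {
  d <- diff(x)
  d <- ifelse(d < -180, d + 360, ifelse(d > 180, d - 360, d))
  cumsum(c(x[1], d))
}

## ---- energy and gradient --------------------------------------------

## Elastic spring energy, fold penalty and analytic gradient for a
## parameter vector.  Parameters: rim longitudes (radians), then 3 raw
## coordinates per interior node (radially projected onto the sphere).
make_objective <- function(sys, phi0) {
  nr <- length(sys$rim)
  ni <- length(sys$interior)
  sphi <- sin(deg2rad(phi0)); cphi <- cos(deg2rad(phi0))
  e1 <- sys$edges[, 1]; e2 <- sys$edges[, 2]
  L <- sys$L
  tri <- sys$tri
  ## fold-penalty scales: the quadratic hinge activates just below zero
  ## orientation (tiny margin, 0.1% of the mean triangle size) and is
  ## normalised by the mean triangle size so stage weights are
  ## mesh-independent
  mean_det <- 2 * pi * (1 - cos(deg2rad(phi0))) / max(1, nrow(tri))
  fold_margin <- 1e-3 * mean_det

  unpack <- function(par) {
    lam <- par[seq_len(nr)]
    u <- matrix(0, sys$ncls, 3)
    u[sys$rim, ] <- cbind(sphi * cos(lam), sphi * sin(lam), cphi)
    rnorm3 <- 1
    if (ni) {
      x <- matrix(par[nr + seq_len(3 * ni)], ncol = 3)
      rn <- sqrt(rowSums(x^2))
      u[sys$interior, ] <- x / rn
      rnorm3 <- rn
    }
    list(u = u, lam = lam, rn = rnorm3)
  }

  evaluate <- function(par, w_fold) {
    s <- unpack(par)
    u <- s$u
    ua <- u[e1, , drop = FALSE]; ub <- u[e2, , drop = FALSE]
    dot <- rowSums(ua * ub)
    cr <- cbind(ua[, 2] * ub[, 3] - ua[, 3] * ub[, 2],
                ua[, 3] * ub[, 1] - ua[, 1] * ub[, 3],
                ua[, 1] * ub[, 2] - ua[, 2] * ub[, 1])
    sl <- pmax(sqrt(rowSums(cr^2)), 1e-14)
    l <- atan2(sl, dot)
    dE <- (l - L) / L
    E <- sum((l - L)^2 / (2 * L))
    ## gradient of the central angle wrt the two unit endpoints
    ga <- (-(ub - dot * ua) / sl) * dE
    gb <- (-(ua - dot * ub) / sl) * dE
    G <- matrix(0, sys$ncls, 3)
    acc <- rowsum(rbind(ga, gb), c(e1, e2))
    G[as.integer(rownames(acc)), ] <- acc
    ## fold penalty: smooth quadratic hinge on the signed triangle volume
    ## det[u1,u2,u3], active below a small positive margin so a restoring
    ## gradient exists before a triangle actually flips
    if (w_fold > 0 && nrow(tri)) {
      u1 <- u[tri[, 1], , drop = FALSE]
      u2 <- u[tri[, 2], , drop = FALSE]
      u3 <- u[tri[, 3], , drop = FALSE]
      c23 <- cbind(u2[, 2] * u3[, 3] - u2[, 3] * u3[, 2],
                   u2[, 3] * u3[, 1] - u2[, 1] * u3[, 3],
                   u2[, 1] * u3[, 2] - u2[, 2] * u3[, 1])
      d <- rowSums(u1 * c23)
      m <- fold_margin
      wq <- w_fold / mean_det^2     # penalty ~ w_fold for a fully inverted
      neg <- d < m                  # triangle of mean size
      if (any(neg)) {
        E <- E + wq * sum((m - d[neg])^2)
        c31 <- cbind(u3[, 2] * u1[, 3] - u3[, 3] * u1[, 2],
                     u3[, 3] * u1[, 1] - u3[, 1] * u1[, 3],
                     u3[, 1] * u1[, 2] - u3[, 2] * u1[, 1])
        c12 <- cbind(u1[, 2] * u2[, 3] - u1[, 3] * u2[, 2],
                     u1[, 3] * u2[, 1] - u1[, 1] * u2[, 3],
                     u1[, 1] * u2[, 2] - u1[, 2] * u2[, 1])
        w <- rep(0, nrow(tri)); w[neg] <- -2 * wq * (m - d[neg])
        accf <- rowsum(rbind(c23 * w, c31 * w, c12 * w),
                       c(tri[, 1], tri[, 2], tri[, 3]))
        G[as.integer(rownames(accf)), ] <-
          G[as.integer(rownames(accf)), ] + accf
      }
    }
    ## chain rule to parameters
    grad <- numeric(length(par))
    lam <- s$lam
    gr_rim <- G[sys$rim, , drop = FALSE]
    grad[seq_len(nr)] <- sphi * (-sin(lam) * gr_rim[, 1] +
                                  cos(lam) * gr_rim[, 2])
    if (ni) {
      gi <- G[sys$interior, , drop = FALSE]
      ui <- u[sys$interior, , drop = FALSE]
      gi <- (gi - ui * rowSums(gi * ui)) / s$rn
      grad[nr + seq_len(3 * ni)] <- as.vector(gi)
    }
    list(value = E, grad = grad, u = u, l = l)
  }

  pack <- function(u) {
    lam <- atan2(u[sys$rim, 2], u[sys$rim, 1])
    c(lam, as.vector(u[sys$interior, , drop = FALSE]))
  }

  list(evaluate = evaluate, pack = pack, unpack = unpack)
}

#' Elastic energy of a spherical embedding
#'
#' Total spring energy `sum (l - L)^2 / (2 L)` of a stitched mesh whose
#' contracted vertex classes sit at the given spherical positions, with
#' natural lengths taken from the flat mesh (area-scaled to the unit
#' sphere).  Also returns the gradient with respect to the optimisation
#' parameters (rim longitudes, then raw 3D interior coordinates).
#'
#' @param u An n-class-by-3 matrix of unit vectors as produced by
#'   [initial_projection()] (attribute `"sys"` required).
#' @param phi0 Rim colatitude in degrees.
#' @return A list with `energy`, `gradient`, `edge_lengths_sphere`
#'   (radians) and `edge_lengths_flat` (same scale).
#' @export
elastic_energy <- function(u, phi0) {
  sys <- attr(u, "sys")
  if (is.null(sys)) stop("u must carry the contracted system (see initial_projection)")
  obj <- make_objective(sys, phi0)
  r <- obj$evaluate(obj$pack(u), w_fold = 0)
  list(energy = r$value, gradient = r$grad,
       edge_lengths_sphere = r$l, edge_lengths_flat = sys$L)
}

#' Deformation measure of a reconstruction
#'
#' The overall deformation `E_L = sqrt( sum (l_i - L_i)^2 / L_i / (N Lbar) )`
#' over the N mesh edges with flat lengths `L_i` (mean `Lbar`) and
#' reconstructed spherical lengths `l_i`: the square root of the elastic
#' energy in the notional springs, normalised so that a uniform fractional
#' strain of every edge by `eps` gives exactly `|eps|`.  Values above 0.1
#' warrant checking the mark-up; above 0.2 indicate a failure of
#' stitching.
#'
#' @param l Spherical edge lengths.
#' @param L Flat (natural) edge lengths, same units.
#' @return The dimensionless deformation measure.
#' @export
deformation_measure <- function(l, L) {
  sqrt(sum((l - L)^2 / L) / (length(L) * mean(L)))
}

flag_from_EL <- function(E_L) {
  if (E_L > 0.2) "reject" else if (E_L > 0.15) "bad" else
    if (E_L > 0.1) "check-markup" else "ok"
}

## ---- optimisation ----------------------------------------------------

#' Relax a spherical embedding by energy minimisation
#'
#' Limited-memory quasi-Newton (L-BFGS-B) minimisation of the elastic
#' energy, over rim longitudes and interior positions, in stages of
#' increasing fold-penalty weight.  Deterministic given its inputs.
#'
#' @param u Initial embedding from [initial_projection()].
#' @param phi0 Rim colatitude in degrees.
#' @param fold_weights Fold-penalty weight of each optimisation stage.
#' @param maxit Iteration cap per stage.
#' @param pgtol Projected-gradient tolerance passed to the optimiser.
#' @return A list: `u` (relaxed embedding with the `"sys"` attribute),
#'   `energy`, `initial_energy`, `converged`, `iterations`, `folded`
#'   (number of negatively oriented triangles left).
#' @export
optimise_embedding <- function(u, phi0, fold_weights = c(1, 10, 100),
                               maxit = 2000, pgtol = 1e-6) {
  sys <- attr(u, "sys")
  obj <- make_objective(sys, phi0)
  par <- obj$pack(u)
  e0 <- obj$evaluate(par, 0)$value
  iterations <- 0
  converged <- TRUE
  run_stage <- function(par, w) {
    fit <- stats::optim(par, fn = function(p) obj$evaluate(p, w)$value,
                        gr = function(p) obj$evaluate(p, w)$grad,
                        method = "L-BFGS-B",
                        control = list(maxit = maxit, pgtol = pgtol,
                                       factr = 1e4))
    iterations <<- iterations + fit$counts[["function"]]
    if (fit$convergence != 0) converged <<- FALSE
    fit$par
  }
  for (w in fold_weights) par <- run_stage(par, w)
  count_folds <- function(par) {
    un <- obj$evaluate(par, 0)$u
    if (!nrow(sys$tri)) return(0L)
    u1 <- un[sys$tri[, 1], , drop = FALSE]
    u2 <- un[sys$tri[, 2], , drop = FALSE]
    u3 <- un[sys$tri[, 3], , drop = FALSE]
    d <- u1[, 1] * (u2[, 2] * u3[, 3] - u2[, 3] * u3[, 2]) -
         u1[, 2] * (u2[, 1] * u3[, 3] - u2[, 3] * u3[, 1]) +
         u1[, 3] * (u2[, 1] * u3[, 2] - u2[, 2] * u3[, 1])
    sum(d < -1e-12)
  }
  ## stubborn folds: ramp the penalty further (deterministic, only when
  ## needed)
  w_extra <- fold_weights[length(fold_weights)]
  for (k in 1:3) {
    if (count_folds(par) == 0) break
    w_extra <- w_extra * 10
    par <- run_stage(par, w_extra)
  }
  fin <- obj$evaluate(par, 0)
  un <- fin$u
  ## count remaining folds
  folded <- 0L
  if (nrow(sys$tri)) {
    u1 <- un[sys$tri[, 1], , drop = FALSE]
    u2 <- un[sys$tri[, 2], , drop = FALSE]
    u3 <- un[sys$tri[, 3], , drop = FALSE]
    d <- u1[, 1] * (u2[, 2] * u3[, 3] - u2[, 3] * u3[, 2]) -
         u1[, 2] * (u2[, 1] * u3[, 3] - u2[, 3] * u3[, 1]) +
         u1[, 3] * (u2[, 1] * u3[, 2] - u2[, 2] * u3[, 1])
    folded <- sum(d < -1e-12)
  }
  attr(un, "sys") <- sys
  list(u = un, energy = fin$value, initial_energy = e0,
       converged = converged, iterations = iterations, folded = folded,
       edge_lengths_sphere = fin$l)
}

## ---- high-level driver ----------------------------------------------

#' Reconstruct a flat-mounted retina into standard spherical space
#'
#' Runs the full pipeline on a marked-up outline: mark-up validation,
#' perimeter resampling, triangulation into at least `min_triangles`
#' roughly equal triangles, stitching of cuts and tears, initial
#' projection onto the rim-curtailed sphere and elastic relaxation.  The
#' final mesh is rotated about the pole so that the nasal-pole vertex
#' lies at longitude 0.
#'
#' @param outline A [flat_outline()] with mark-up.
#' @param rim_angle Rim colatitude in degrees, or `NULL` to derive it
#'   from `eye`.
#' @param eye Optional [eye_measurements()] used when `rim_angle` is `NULL`.
#' @param min_triangles Minimum triangle count (default 500).
#' @param n_boundary Approximate outline vertex count after resampling.
#' @param fold_weights,maxit,pgtol Optimiser controls, see
#'   [optimise_embedding()].
#' @return An object of class `retina_reconstruction` with elements
#'   `mesh`, `rim_angle`, `u` (unit vectors per contracted class),
#'   `vertex_sphere` (spherical point per flat mesh vertex), `strains`
#'   (per-edge length ratio sphere/flat), `E_L`, `flag`, `converged`,
#'   `iterations`, `folded`, `initial_E_L`.
#' @export
reconstruct_retina <- function(outline, rim_angle = NULL, eye = NULL,
                               min_triangles = 500, n_boundary = 300,
                               fold_weights = c(1, 10, 100), maxit = 2000,
                               pgtol = 1e-6) {
  stopifnot(inherits(outline, "flat_outline"))
  if (is.null(rim_angle)) {
    if (is.null(eye)) stop("supply rim_angle or eye measurements")
    rim_angle <- rim_colatitude(eye)
  }
  phi0 <- as.numeric(rim_angle)
  if (phi0 <= 0 || phi0 >= 180) stop("rim angle must be in (0, 180)")
  val <- validate_markup(outline)
  if (!val$ok)
    stop("mark-up validation failed:\n",
         paste(sprintf("  [%s] %s", val$violations$check,
                       val$violations$detail), collapse = "\n"))
  res <- if (isTRUE(attr(outline, "resampled"))) outline else
    resample_outline(outline, n_target = n_boundary)
  mesh <- stitch_mesh(triangulate_outline(res, min_triangles = min_triangles))
  u0 <- initial_projection(mesh, phi0)
  sys <- attr(u0, "sys")
  fit <- optimise_embedding(u0, phi0, fold_weights = fold_weights,
                            maxit = maxit, pgtol = pgtol)
  u <- fit$u
  ## rotate so the nasal node is at longitude 0
  if (!is.na(sys$nasal)) {
    lam0 <- atan2(u[sys$nasal, 2], u[sys$nasal, 1])
    R <- matrix(c(cos(-lam0), -sin(-lam0), 0,
                  sin(-lam0), cos(-lam0), 0,
                  0, 0, 1), 3, 3, byrow = TRUE)
    u <- u %*% t(R)
    attr(u, "sys") <- sys
  }
  sph <- cart_to_sph(u)
  ## snap rim nodes to the exact rim colatitude (hard constraint)
  sph$colatitude[sys$rim] <- phi0
  l <- geodesic_rad(u[sys$edges[, 1], , drop = FALSE],
                    u[sys$edges[, 2], , drop = FALSE])
  E_L <- deformation_measure(l, sys$L)
  e0 <- elastic_initial_EL(mesh, phi0)
  structure(list(
    outline = res, mesh = mesh, rim_angle = rim_angle(phi0), sys = sys,
    u = u, class_sphere = sph,
    vertex_sphere = sph[sys$cls, , drop = FALSE],
    strains = l / sys$L, E_L = E_L, flag = flag_from_EL(E_L),
    converged = fit$converged, iterations = fit$iterations,
    folded = fit$folded, initial_E_L = e0
  ), class = "retina_reconstruction")
}

geodesic_rad <- function(ua, ub) {
  cr <- cbind(ua[, 2] * ub[, 3] - ua[, 3] * ub[, 2],
              ua[, 3] * ub[, 1] - ua[, 1] * ub[, 3],
              ua[, 1] * ub[, 2] - ua[, 2] * ub[, 1])
  atan2(sqrt(rowSums(cr^2)), rowSums(ua * ub))
}

elastic_initial_EL <- function(mesh, phi0) {
  u0 <- initial_projection(mesh, phi0)
  sys <- attr(u0, "sys")
  l0 <- geodesic_rad(u0[sys$edges[, 1], , drop = FALSE],
                     u0[sys$edges[, 2], , drop = FALSE])
  deformation_measure(l0, sys$L)
}

#' @export
print.retina_reconstruction <- function(x, ...) {
  cat("Retinal reconstruction\n")
  cat(sprintf("  rim angle: %.2f deg; E_L = %.4f (initial %.4f); flag: %s\n",
              as.numeric(x$rim_angle), x$E_L, x$initial_E_L, x$flag))
  cat(sprintf("  %d vertices (%d after stitching), %d triangles, %s\n",
              nrow(x$mesh$vertices), x$sys$ncls, nrow(x$mesh$triangles),
              if (x$converged) "converged" else "NOT converged"))
  if (x$folded > 0) cat("  warning:", x$folded, "folded triangle(s)\n")
  invisible(x)
}

#' Infer the rim angle by grid search
#'
#' Repeats the full reconstruction for rim angles at 1-degree intervals
#' within `centre` plus/minus `half_range` and returns the angle with the
#' lowest deformation measure (ties broken towards the centre).
#'
#' @param outline A marked-up [flat_outline()].
#' @param centre Centre of the search range, degrees.
#' @param half_range Half-width of the search range, degrees.
#' @param ... Passed to [reconstruct_retina()].
#' @return A list with `rim_angle` (best angle, degrees), `profile`
#'   (data.frame of `angle` and `E_L`) and `reconstruction` (the best fit).
#' @export
infer_rim_angle <- function(outline, centre, half_range = 10, ...) {
  angles <- centre + seq(-round(half_range), round(half_range))
  angles <- angles[angles > 0 & angles < 180]
  fits <- lapply(angles, function(a)
    reconstruct_retina(outline, rim_angle = a, ...))
  prof <- data.frame(angle = angles,
                     E_L = vapply(fits, function(f) f$E_L, 0))
  ord <- order(prof$E_L, abs(prof$angle - centre))
  best <- ord[1]
  list(rim_angle = prof$angle[best], profile = prof,
       reconstruction = fits[[best]])
}

#' Map flat points through a reconstruction onto the sphere
#'
#' Locates each point's containing flat triangle, computes its planar
#' barycentric weights, applies them to the triangle's spherical vertex
#' positions in the 3D embedding and renormalises onto the sphere.
#' Points slightly outside the mesh (within `tolerance`) are snapped to
#' the nearest triangle with a message; points farther out raise an
#' error listing their indices.
#'
#' @param r A `retina_reconstruction`.
#' @param pts An n-by-2 matrix of flat coordinates (micrometres).
#' @param tolerance Snap distance in micrometres; defaults to 0.5% of the
#'   outline bounding-box diagonal.
#' @return Spherical points ([sph_point()]) for the mapped data.
#' @export
map_to_sphere <- function(r, pts, tolerance = NULL) {
  stopifnot(inherits(r, "retina_reconstruction"))
  pts <- matrix(as.numeric(as.matrix(pts)), ncol = 2)
  if (!nrow(pts)) return(sph_point(numeric(0), numeric(0)))
  v <- r$mesh$vertices; tri <- r$mesh$triangles
  if (is.null(tolerance))
    tolerance <- 0.005 * sqrt(sum(apply(v, 2, function(z) diff(range(z)))^2))
  ax <- v[tri[, 1], 1]; ay <- v[tri[, 1], 2]
  bx <- v[tri[, 2], 1]; by <- v[tri[, 2], 2]
  cx <- v[tri[, 3], 1]; cy <- v[tri[, 3], 2]
  den <- (by - cy) * (ax - cx) + (cx - bx) * (ay - cy)
  bary_all <- function(px, py) {
    w1 <- ((by - cy) * (px - cx) + (cx - bx) * (py - cy)) / den
    w2 <- ((cy - ay) * (px - cx) + (ax - cx) * (py - cy)) / den
    cbind(w1, w2, 1 - w1 - w2)
  }
  n <- nrow(pts)
  out <- matrix(0, n, 3)
  snapped <- 0L; bad <- integer(0)
  for (k in seq_len(n)) {
    w <- bary_all(pts[k, 1], pts[k, 2])
    slack <- pmin(w[, 1], w[, 2], w[, 3])
    j <- which.max(slack)
    if (slack[j] < -1e-9) {
      ## outside the mesh: snap if within tolerance of the boundary
      d <- dist_to_ring(pts[k, , drop = FALSE],
                        v[r$mesh$ring, , drop = FALSE])
      if (d > tolerance) { bad <- c(bad, k); next }
      snapped <- snapped + 1L
    }
    wk <- pmax(w[j, ], 0); wk <- wk / sum(wk)
    uk <- wk[1] * r$u[r$sys$cls[tri[j, 1]], ] +
          wk[2] * r$u[r$sys$cls[tri[j, 2]], ] +
          wk[3] * r$u[r$sys$cls[tri[j, 3]], ]
    out[k, ] <- uk / sqrt(sum(uk^2))
  }
  if (length(bad))
    stop("unmappable point(s) outside the mesh: indices ",
         paste(utils::head(bad, 10), collapse = ", "))
  if (snapped > 0)
    message("map_to_sphere: snapped ", snapped,
            " point(s) to the nearest triangle")
  cart_to_sph(out)
}
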