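## Intrinsic statistics for point sets on the reconstructed sphere.
##
## Group means are Karcher (intrinsic) means: the point minimising the
## sum of squared geodesic distances, found by iterated tangent-plane
## averaging.  Densities are von Mises-Fisher (vMF) kernel mixtures, the
## spherical analogue of a Gaussian kernel density estimate, with the
## concentration parameter chosen by leave-one-out cross-validated
## likelihood when not supplied.  Distributions are summarised with
## contours that exclude a given fraction of the points: the level for
## fraction f is the f-quantile of the density evaluated at the points
## themselves, so the super-level region excludes about f of them.

#' Karcher mean of spherical points
#'
#' Intrinsic mean on the sphere: iteratively log-maps the points to the
#' tangent plane at the current estimate, averages, and exp-maps back,
#' until the update is below `tol` radians.  Also returns the angular
#' standard deviation, the root mean squared geodesic distance from the
#' mean.
#'
#' @param p Spherical points ([sph_point()]), at least one.
#' @param tol Convergence tolerance in radians.
#' @param maxit Iteration cap; exceeding it raises an error (pathological
#'   spread, e.g. antipodal configurations).
#' @return A list with `mean` (a single spherical point) and `sd_deg`.
#' @export
karcher_mean <- function(p, tol = 1e-8, maxit = 200) {
  u <- sph_to_cart(p)
  n <- nrow(u)
  if (n == 0) stop("karcher_mean needs a non-empty point set")
  m <- colSums(u)
  if (sqrt(sum(m^2)) < 1e-9) m <- u[1, ]   # degenerate start: pick a point
  m <- m / sqrt(sum(m^2))
  for (it in seq_len(maxit)) {
    dots <- pmin(pmax(u %*% m, -1), 1)
    theta <- acos(drop(dots))
    ## log map: tangent vectors of length theta towards each point
    perp <- u - outer(drop(dots), m)
    pn <- sqrt(rowSums(perp^2))
    coef <- ifelse(pn > 1e-14, theta / pn, 0)
    tanm <- colSums(perp * coef) / n
    step <- sqrt(sum(tanm^2))
    if (step < tol) break
    ## exp map
    m <- m * cos(step) + (tanm / step) * sin(step)
    m <- m / sqrt(sum(m^2))
    if (it == maxit) stop("karcher_mean did not converge")
  }
  dots <- pmin(pmax(drop(u %*% m), -1), 1)
  sd_deg <- rad2deg(sqrt(mean(acos(dots)^2)))
  list(mean = cart_to_sph(matrix(m, 1)), sd_deg = sd_deg)
}

## log of the vMF normalising constant c(kappa) = kappa / (4 pi sinh kappa),
## computed on the log scale to stay finite for large kappa.
log_vmf_const <- function(kappa) {
  log(kappa) - log(4 * pi) - kappa - log1p(-exp(-2 * kappa)) + log(2)
}

#' von Mises-Fisher kernel density estimate on the sphere
#'
#' One vMF kernel per datum, normalised over the whole sphere.  With
#' `kappa = "auto"` the concentration is chosen by maximising the
#' leave-one-out cross-validated log likelihood over a log-spaced grid.
#'
#' @param p Spherical points; at least 5 (use [karcher_mean()] for
#'   smaller groups).
#' @param kappa Kernel concentration (dimensionless), or `"auto"`.
#' @param kappa_grid Candidate grid used by `"auto"`.
#' @return An object of class `sphere_density`: `evaluate(q)` returning
#'   density per steradian at spherical points `q`, `kappa`, `peak` (the
#'   highest-density point, located on a refined grid) and the data.
#' @export
kde_vmf <- function(p, kappa = "auto",
                    kappa_grid = 10^seq(0.5, 3.5, length.out = 16)) {
  u <- sph_to_cart(p)
  n <- nrow(u)
  if (n < 5)
    stop("kernel density estimation needs at least 5 points; ",
         "use karcher_mean for small groups")
  if (identical(kappa, "auto")) {
    cv <- vapply(kappa_grid, function(k) loo_loglik(u, k), 0)
    kappa <- kappa_grid[which.max(cv)]
  }
  ## evaluate on the log scale: log c(kappa) + kappa * dot <= log(kappa/4pi),
  ## so exp never overflows even for large concentrations
  d <- structure(list(evaluate = function(q) {
    uq <- if (is.matrix(q)) q else sph_to_cart(q)
    rowMeans(exp(log_vmf_const(kappa) + kappa * tcrossprod(uq, u)))
  }, kappa = kappa, points = p, peak = NULL), class = "sphere_density")
  d$peak <- density_peak(d)
  d
}

## Leave-one-out log likelihood of a vMF mixture with concentration k.
loo_loglik <- function(u, k) {
  n <- nrow(u)
  lc <- log_vmf_const(k)
  K <- exp(lc + k * tcrossprod(u, u))
  fi <- (rowSums(K) - exp(lc + k)) / (n - 1)
  if (any(fi <= 0)) return(-Inf)
  sum(log(fi))
}

## Locate the density peak: coarse spherical Fibonacci grid then local
## refinement around the best node.  The search is restricted to the
## region covered by the data: away from all data the kernel-regression
## ratio extrapolates to the nearest box's count, which is meaningless
## as a peak.
density_peak <- function(d, n_grid = 2000) {
  i <- seq_len(n_grid)
  z <- 1 - (2 * i - 1) / n_grid
  th <- pi * (1 + sqrt(5)) * i
  g <- cbind(sqrt(1 - z^2) * cos(th), sqrt(1 - z^2) * sin(th), z)
  up <- sph_to_cart(d$points)
  near <- acos(pmin(pmax(apply(tcrossprod(g, up), 1, max), -1), 1))
  nn <- vapply(seq_len(nrow(up)), function(k) {
    dots <- tcrossprod(up[k, , drop = FALSE], up[-k, , drop = FALSE])
    acos(min(max(dots), 1))
  }, 0)
  reach <- max(deg2rad(5), 3 * stats::median(nn))
  keep <- near <= reach
  if (!any(keep)) keep <- rep(TRUE, length(near))
  g <- g[keep, , drop = FALSE]
  f <- d$evaluate(g)
  best <- g[which.max(f), ]
  sp <- cart_to_sph(matrix(best, 1))
  fit <- stats::optim(c(sp$colatitude, sp$longitude), function(par) {
    -d$evaluate(sph_point(min(max(par[1], 0), 180), par[2]))
  }, method = "Nelder-Mead", control = list(reltol = 1e-10))
  cand <- sph_point(min(max(fit$par[1], 0), 180), fit$par[2])
  ## keep the refinement only if it stayed within the data's support
  cd <- acos(pmin(pmax(max(tcrossprod(sph_to_cart(cand), up)), -1), 1))
  if (cd <= reach) cand else sp
}

#' Point-exclusion contour levels of a density
#'
#' For each fraction f, the level is an order statistic of the density
#' evaluated at the data points: with k = floor(f * n), the level is the
#' (k+1)-th smallest point density, so that exactly the k lowest-density
#' points fall strictly below the level.  The super-level (contoured)
#' region therefore excludes exactly `floor(f * n)` of the points.
#'
#' @param d A `sphere_density` (from [kde_vmf()] or [kernel_regression()]).
#' @param p The points the density was built from (defaults to `d$points`).
#' @param fractions Exclusion fractions in percent.
#' @return A named numeric vector of density levels, increasing with the
#'   fraction.
#' @export
exclusion_contours <- function(d, p = d$points,
                               fractions = c(5, 25, 50, 75, 95)) {
  f <- sort(d$evaluate(p))
  n <- length(f)
  k <- pmin(floor(fractions / 100 * n), n - 1)
  lev <- f[k + 1]
  names(lev) <- paste0(fractions, "%")
  lev
}

#' Kernel regression of counted sampling boxes on the sphere
#'
#' Nadaraya-Watson estimate with vMF weights of an intensity sampled by
#' counted boxes: `intensity(x) = sum(count_j K(x, x_j)) / sum(K(x, x_j))`.
#' Used when data are cell counts within boxes rather than individual
#' points.  With `kappa = "auto"` the concentration minimises the
#' leave-one-out squared prediction error of the counts.
#'
#' @param centres Spherical points: mapped box centres (at least 5).
#' @param counts Non-negative counts, one per box, not all zero.
#' @param kappa Concentration or `"auto"`.
#' @param kappa_grid Candidate grid used by `"auto"`.
#' @return A `sphere_density`-like object whose `evaluate(q)` returns the
#'   intensity surface (same units as `counts`), with `peak`.
#' @export
kernel_regression <- function(centres, counts, kappa = "auto",
                              kappa_grid = 10^seq(0.5, 3.5, length.out = 16)) {
  u <- sph_to_cart(centres)
  n <- nrow(u)
  if (n < 5) stop("kernel regression needs at least 5 boxes")
  if (length(counts) != n || any(counts < 0))
    stop("counts must be non-negative, one per box")
  if (all(counts == 0)) stop("all box counts are zero")
  if (identical(kappa, "auto")) {
    cv <- vapply(kappa_grid, function(k) {
      K <- exp(k * (tcrossprod(u, u) - 1))
      diag(K) <- 0
      pred <- (K %*% counts) / pmax(rowSums(K), 1e-300)
      sum((pred - counts)^2)
    }, 0)
    kappa <- kappa_grid[which.min(cv)]
  }
  d <- structure(list(evaluate = function(q) {
    uq <- if (is.matrix(q)) q else sph_to_cart(q)
    K <- exp(kappa * (tcrossprod(uq, u) - 1))
    drop(K %*% counts) / pmax(rowSums(K), 1e-300)
  }, kappa = kappa, points = centres, counts = counts, peak = NULL),
  class = "sphere_density")
  d$peak <- density_peak(d)
  d
}

#' @export
print.sphere_density <- function(x, ...) {
  cat("Spherical kernel estimate: kappa =", format(x$kappa, digits = 4),
      "\n  peak at colatitude", sprintf("%.2f", x$peak$colatitude),
      "longitude", sprintf("%.2f", x$peak$longitude), "\n")
  invisible(x)
}
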