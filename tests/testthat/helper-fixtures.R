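## Shared fixtures.  Expensive objects (synthetic retinae and their
## reconstructions) are built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

## internal helpers exercised by the tests
polygon_area <- retinamorph:::polygon_area
triangle_areas <- retinamorph:::triangle_areas
mesh_edges <- retinamorph:::mesh_edges
geodesic_rad <- retinamorph:::geodesic_rad

cached <- function(key, builder) {
  if (!exists(key, .fixture_cache)) assign(key, builder(), .fixture_cache)
  get(key, .fixture_cache)
}

## a circle outline (optionally clockwise) in micrometres
circle_outline <- function(n = 60, r = 1000, clockwise = FALSE) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  if (clockwise) th <- rev(th)
  cbind(r * cos(th), r * sin(th))
}

## a disc with one V-cut, mirror-symmetric about the x axis: rim vertices
## span the circle outside a wedge centred on angle 0; the two flanks
## descend at angles +/- wedge/2 and meet at the apex on the x axis
vcut_disc <- function(n = 48, r = 1000, wedge = pi / 4, depth = 0.7,
                      m = 7) {
  th <- seq(wedge / 2, 2 * pi - wedge / 2, length.out = n)
  rim <- cbind(r * cos(th), r * sin(th))
  radii <- seq(r, r * (1 - depth), length.out = m)
  flankA <- cbind(radii[2:(m - 1)] * cos(2 * pi - wedge / 2),
                  radii[2:(m - 1)] * sin(2 * pi - wedge / 2))
  apex <- c(r * (1 - depth), 0)
  flankB <- cbind(rev(radii[2:(m - 1)]) * cos(wedge / 2),
                  rev(radii[2:(m - 1)]) * sin(wedge / 2))
  ring <- rbind(rim, flankA, apex, flankB)
  flat_outline(ring,
               cuts = list(cut_markup(n, n + m - 1, 1)),
               nasal_pole_index = round(n / 4))
}

synth_small <- function(noise = 0.02, seed = 1)
  cached(sprintf("synth_%g_%d", noise, seed), function()
    suppressWarnings(synth_retina(noise = noise, seed = seed,
                                  mesh_triangles = 600)))

recon_small <- function(noise = 0.02, seed = 1)
  cached(sprintf("recon_%g_%d", noise, seed), function()
    reconstruct_retina(synth_small(noise, seed)$outline, rim_angle = 111.56))

eval_small <- function(noise = 0.02, seed = 1, n_points = 300)
  cached(sprintf("eval_%g_%d_%d", noise, seed, n_points), function()
    evaluate_reconstruction(synth_small(noise, seed), n_points = n_points))
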