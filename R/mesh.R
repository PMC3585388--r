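## Triangulation of the flat outline and stitching of cuts and tears.
##
## The outline is resampled to roughly uniform vertex spacing, filled with
## a hexagonal grid of interior points and triangulated (Delaunay, via the
## 'interp' package), keeping only triangles inside the outline and
## verifying that every boundary segment is an edge of the mesh.  Each
## marked-up cut is then "stitched": the two flanks of the cut are
## parameterised by normalised arc length from rim to apex, and vertices
## at equal parameter on the two flanks are recorded as corresponding
## pairs (a partner is inserted by boundary-edge splitting when no vertex
## at matching parameter exists).  Corresponding vertices are later
## constrained to share a single position on the sphere, which closes the
## cuts.  After contracting all correspondences the mesh boundary is a
## single closed ring: the retinal rim.

#' Resample an outline to roughly uniform vertex spacing
#'
#' Marked-up vertices (cut forwards and apexes, the nasal pole) are kept
#' as anchors; each perimeter arc between consecutive anchors is resampled
#' at the requested spacing.  Mark-up indices are remapped to the new
#' ring.  Attached data are carried over unchanged.
#'
#' @param o A [flat_outline()].
#' @param n_target Approximate number of ring vertices after resampling
#'   (the spacing is perimeter / `n_target`).
#' @return A resampled [flat_outline()].
#' @export
resample_outline <- function(o, n_target = 300) {
  v <- o$vertices
  n <- nrow(v)
  anchors <- sort(unique(stats::na.omit(c(
    1L, o$nasal_pole_index,
    unlist(lapply(o$cuts, function(cm) c(cm$forward_a, cm$apex, cm$forward_b)))
  ))))
  seglen <- sqrt(rowSums((v[c(seq_len(n)[-1], 1), ] - v)^2))
  spacing <- sum(seglen) / n_target
  new_pts <- list(); new_index_of <- integer(n)
  add_pt <- function(p) {
    new_pts[[length(new_pts) + 1]] <<- p
    length(new_pts)
  }
  n_anchor <- length(anchors)
  for (ai in seq_len(n_anchor)) {
    a <- anchors[ai]
    b <- anchors[if (ai == n_anchor) 1 else ai + 1]
    new_index_of[a] <- add_pt(v[a, ])
    ## walk a -> b (a full lap when a is the only anchor)
    path <- a
    i <- a
    repeat {
      i <- if (i == n) 1L else i + 1L
      path <- c(path, i)
      if (i == b) break
    }
    if (length(path) < 2) next
    pv <- v[path, , drop = FALSE]
    d <- c(0, cumsum(sqrt(rowSums(diff(pv)^2))))
    L <- d[length(d)]
    if (L <= 0) next
    k <- max(1, round(L / spacing))
    targets <- L * seq_len(k - 1) / k
    for (t in targets) {
      j <- findInterval(t, d, rightmost.closed = TRUE)
      f <- (t - d[j]) / (d[j + 1] - d[j])
      add_pt(pv[j, ] * (1 - f) + pv[j + 1, ] * f)
    }
  }
  nv <- do.call(rbind, new_pts)
  remap <- function(i) if (is.na(i)) NA_integer_ else new_index_of[i]
  cuts <- lapply(o$cuts, function(cm)
    cut_markup(remap(cm$forward_a), remap(cm$apex), remap(cm$forward_b)))
  out <- flat_outline(nv, cuts = cuts,
                      nasal_pole_index = remap(o$nasal_pole_index),
                      datasets = o$datasets, landmarks = o$landmarks,
                      boxes = o$boxes)
  attr(out, "resampled") <- TRUE
  out
}

## Signed area of triangles given vertex matrix and index triples.
triangle_areas <- function(v, tri) {
  ax <- v[tri[, 1], 1]; ay <- v[tri[, 1], 2]
  bx <- v[tri[, 2], 1]; by <- v[tri[, 2], 2]
  cx <- v[tri[, 3], 1]; cy <- v[tri[, 3], 2]
  ((bx - ax) * (cy - ay) - (cx - ax) * (by - ay)) / 2
}

#' Triangulate a flat-mount outline
#'
#' Builds a mesh of at least `min_triangles` roughly equal-sized triangles
#' respecting the outline as its boundary.  Interior vertices are placed
#' on a hexagonal grid whose spacing is derived from the outline area and
#' the requested triangle count; the point set is Delaunay-triangulated
#' and triangles outside the outline are discarded.  The outline must
#' already be resampled ([resample_outline()]) so that boundary spacing is
#' comparable to the interior spacing.
#'
#' @param o A (resampled) [flat_outline()].
#' @param min_triangles Minimum number of triangles (default 500).
#' @return An (unstitched) `stitched_mesh` object: `vertices` (n-by-2),
#'   `triangles` (t-by-3, counter-clockwise), `ring` (ordered boundary
#'   vertex indices), mark-up carried over as vertex indices.
#' @export
triangulate_outline <- function(o, min_triangles = 500) {
  stopifnot(inherits(o, "flat_outline"))
  ring_v <- o$vertices
  A <- polygon_area(ring_v)
  n <- nrow(ring_v)
  perim <- sum(sqrt(rowSums((ring_v[c(seq_len(n)[-1], 1), ] - ring_v)^2)))
  if (A <= 1e-10 * perim^2 || ring_self_intersects(ring_v))
    stop("meshing error: outline is degenerate or self-intersecting")
  target_area <- A / min_triangles
  s <- sqrt(4 * target_area / sqrt(3))   # equilateral side with that area
  res <- NULL
  for (attempt in 1:6) {
    res <- try(delaunay_in_polygon(ring_v, s), silent = TRUE)
    if (!inherits(res, "try-error") && nrow(res$triangles) >= min_triangles)
      break
    if (attempt == 6) {
      if (inherits(res, "try-error")) stop(attr(res, "condition")$message)
      stop("meshing error: could not reach the requested triangle count")
    }
    s <- s * 0.8                         # too coarse (or failed): refine
  }
  structure(list(
    vertices = res$vertices,
    triangles = res$triangles,
    ring = seq_len(nrow(ring_v)),
    cuts = o$cuts,
    nasal_vertex = o$nasal_pole_index,
    correspondences = matrix(integer(0), ncol = 2),
    stitched = FALSE,
    outline = o
  ), class = "stitched_mesh")
}

## Delaunay triangulation of the ring plus hexagonal interior points with
## spacing s; keeps triangles whose centroid is inside the ring.  The
## first nrow(ring_v) vertices of the result are the ring, in order.
delaunay_in_polygon <- function(ring_v, s) {
  nb <- nrow(ring_v)
  xr <- range(ring_v[, 1]); yr <- range(ring_v[, 2])
  if ((diff(xr) / s) * (diff(yr) / s) > 4e6)
    stop("meshing error: outline too thin for the requested triangle count")
  xs <- seq(xr[1] - s, xr[2] + s, by = s)
  ys <- seq(yr[1] - s, yr[2] + s, by = s * sqrt(3) / 2)
  grid <- do.call(rbind, lapply(seq_along(ys), function(i) {
    off <- if (i %% 2 == 0) s / 2 else 0
    cbind(xs + off, ys[i])
  }))
  ## tiny fixed irrational jitter guards against co-circular degeneracies
  grid <- grid + s * 1e-4 * cbind(sin(seq_len(nrow(grid)) * sqrt(2)),
                                  cos(seq_len(nrow(grid)) * sqrt(3)))
  keep <- points_in_polygon(grid, ring_v)
  grid <- grid[keep, , drop = FALSE]
  if (nrow(grid)) {
    d <- dist_to_ring(grid, ring_v)
    grid <- grid[d > 0.55 * s, , drop = FALSE]
  }
  extra <- matrix(numeric(0), ncol = 2)
  bnd <- cbind(seq_len(nb), c(seq_len(nb)[-1], 1))
  for (round in 1:6) {
    pts <- rbind(ring_v, grid, extra)
    ## the triangulator may jitter via the R RNG on degenerate inputs; pin
    ## the RNG state locally so meshing is deterministic and leaves the
    ## caller's random stream untouched
    tm <- withCallingHandlers(
      with_fixed_rng(interp::tri.mesh(pts[, 1], pts[, 2],
                                      duplicate = "error")),
      warning = function(w) {
        ## the backend warns while retrying near-degenerate inputs with
        ## jitter; the result is validated downstream (boundary
        ## enforcement, area and orientation checks), so the retry
        ## chatter is muffled
        invokeRestart("muffleWarning")
      })
    tri <- interp::triangles(tm)[, 1:3, drop = FALSE]
    ## enforce every outline segment as a mesh edge (the Delaunay
    ## triangulation may miss segments along nearly closed cuts)
    ek <- edge_keys(rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)]))
    miss <- which(!(edge_keys(bnd) %in% ek))
    if (length(miss))
      tri <- enforce_edges(pts, tri, bnd[miss, , drop = FALSE])
    ## keep the triangles inside the outline: flood fill from a deep
    ## interior triangle, with the outline segments as walls (robust even
    ## when a cut slit is nearly closed)
    tri <- flood_inside(pts, tri, bnd, ring_v)
    ## no triangle may have all three vertices on the outline (such
    ## "ears" become degenerate when their vertices are pinned to the rim
    ## circle on the sphere); split them at their centroids
    ears <- which(tri[, 1] <= nb & tri[, 2] <= nb & tri[, 3] <= nb)
    if (!length(ears) || round == 6) break
    ar <- abs(triangle_areas(pts, tri[ears, , drop = FALSE]))
    big <- ears[ar > 1e-6 * max(abs(triangle_areas(pts, tri)))]
    if (!length(big)) break   # only sliver ears remain: leave them
    cen <- cbind(
      (pts[tri[big, 1], 1] + pts[tri[big, 2], 1] + pts[tri[big, 3], 1]) / 3,
      (pts[tri[big, 1], 2] + pts[tri[big, 2], 2] + pts[tri[big, 3], 2]) / 3)
    extra <- rbind(extra, cen)
  }
  ## orient counter-clockwise
  ar <- triangle_areas(pts, tri)
  flip <- ar < 0
  tri[flip, ] <- tri[flip, c(1, 3, 2)]
  if (any(abs(triangle_areas(pts, tri)) < 1e-12 * max(abs(ar))))
    stop("meshing error: degenerate (zero-area) triangle produced")
  ## drop interior vertices used by no kept triangle
  used <- sort(unique(as.vector(tri)))
  if (!all(seq_len(nb) %in% used))
    stop("meshing error: boundary vertex lost during pruning")
  remap <- integer(nrow(pts)); remap[used] <- seq_along(used)
  list(vertices = pts[used, , drop = FALSE],
       triangles = matrix(remap[tri], ncol = 3))
}

## Flood fill across non-boundary edges from the triangle whose centroid
## lies deepest inside the outline; returns the interior triangles.
flood_inside <- function(pts, tri, bnd, ring_v) {
  cen <- cbind((pts[tri[, 1], 1] + pts[tri[, 2], 1] + pts[tri[, 3], 1]) / 3,
               (pts[tri[, 1], 2] + pts[tri[, 2], 2] + pts[tri[, 3], 2]) / 3)
  inside <- points_in_polygon(cen, ring_v)
  depth <- rep(-Inf, nrow(tri))
  depth[inside] <- dist_to_ring(cen[inside, , drop = FALSE], ring_v)
  seed <- which.max(depth)
  wall <- edge_keys(bnd)
  tk <- cbind(edge_keys(tri[, 1:2]), edge_keys(tri[, 2:3]),
              edge_keys(tri[, c(3, 1)]))
  open_edge <- !(as.vector(tk) %in% wall)
  grp <- split(rep(seq_len(nrow(tri)), 3)[open_edge],
               as.vector(tk)[open_edge])
  is_open <- matrix(open_edge, ncol = 3)
  keep <- logical(nrow(tri))
  stack <- seed
  keep[seed] <- TRUE
  while (length(stack)) {
    t <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    for (j in 1:3) {
      if (!is_open[t, j]) next
      for (t2 in grp[[tk[t, j]]])
        if (!keep[t2]) { keep[t2] <- TRUE; stack <- c(stack, t2) }
    }
  }
  tri[keep, , drop = FALSE]
}

edge_keys <- function(e) {
  a <- pmin(e[, 1], e[, 2]); b <- pmax(e[, 1], e[, 2])
  paste(a, b)
}

## Unique undirected edges of a triangle matrix, with flat lengths.
mesh_edges <- function(vertices, triangles) {
  e <- rbind(triangles[, 1:2], triangles[, 2:3], triangles[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- e[!duplicated(paste(e[, 1], e[, 2])), , drop = FALSE]
  len <- sqrt(rowSums((vertices[e[, 1], , drop = FALSE] -
                       vertices[e[, 2], , drop = FALSE])^2))
  list(edges = e, lengths = len)
}

#' @export
print.stitched_mesh <- function(x, ...) {
  cat("Flat-mount mesh:", nrow(x$vertices), "vertices,",
      nrow(x$triangles), "triangles",
      if (isTRUE(x$stitched)) "(stitched)" else "(not stitched)", "\n")
  if (isTRUE(x$stitched))
    cat("  correspondences:", nrow(x$correspondences),
        "; rim vertices:", length(x$rim_vertices), "\n")
  invisible(x)
}

## Walk the ring (cyclically) from vertex a to vertex b inclusive,
## following ring order.  `ring` is the ordered vector of vertex indices.
ring_walk <- function(ring, a, b) {
  ia <- match(a, ring); ib <- match(b, ring)
  if (is.na(ia) || is.na(ib)) stop("vertex not on boundary ring")
  n <- length(ring)
  if (ib >= ia) ring[ia:ib] else ring[c(ia:n, 1:ib)]
}

#' Stitch the marked-up cuts of a triangulated mesh
#'
#' For each cut, both flanks (rim vertex to apex) are parameterised by
#' normalised arc length; for every vertex on one flank a partner at equal
#' parameter is found on the opposite flank, or inserted by splitting the
#' containing boundary edge.  Nested tears are processed after (and
#' excluded from the arc-length parameterisation of) the cuts containing
#' them; the cut mouths (forward vertex pairs) and apexes also correspond.
#' Existing vertices are reused when a required partner falls within 10%
#' of the local inter-vertex spacing.  Stitching only inserts vertices; it
#' never moves them.
#'
#' @param mesh An unstitched mesh from [triangulate_outline()].
#' @return The mesh with `correspondences` (two-column matrix of vertex
#'   index pairs), `merged` (vertex equivalence class per vertex),
#'   `rim_vertices` (ordered rim vertex indices) and `edges` filled in.
#' @export
stitch_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "stitched_mesh"))
  st <- new.env(parent = emptyenv())
  st$vertices <- mesh$vertices
  st$triangles <- mesh$triangles
  st$ring <- mesh$ring
  cuts <- mesh$cuts
  pairs <- list()

  ## order cuts outermost-first (containing intervals before contained)
  if (length(cuts) > 1) {
    ring0 <- st$ring
    ivals <- lapply(cuts, function(cm)
      ring_walk(ring0, cm$forward_a, cm$forward_b))
    depth <- vapply(seq_along(cuts), function(i) {
      sum(vapply(seq_along(cuts), function(j)
        j != i && all(ivals[[i]] %in% ivals[[j]]) &&
          length(ivals[[i]]) < length(ivals[[j]]), TRUE))
    }, 0)
    cuts <- cuts[order(depth)]
  }

  for (cm in cuts) {
    nested <- Filter(function(other) {
      iv_o <- ring_walk(st$ring, other$forward_a, other$forward_b)
      iv_c <- ring_walk(st$ring, cm$forward_a, cm$forward_b)
      all(iv_o %in% iv_c) && length(iv_o) < length(iv_c)
    }, cuts[!vapply(cuts, identical, TRUE, cm)])
    fA <- flank_params(st, cm$forward_a, cm$apex, forwards = TRUE, nested)
    fB <- flank_params(st, cm$forward_b, cm$apex, forwards = FALSE, nested)
    if (fA$length <= 0 || fB$length <= 0)
      stop("stitch error: cut flank of zero length")
    pairs[[length(pairs) + 1]] <- cbind(cm$forward_a, cm$forward_b)
    pairs[[length(pairs) + 1]] <- cbind(cm$apex, cm$apex)
    ## match interior flank vertices at equal normalised arc length
    tA <- fA$t[fA$match]; tB <- fB$t[fB$match]
    for (t in sort(unique(c(tA, tB)))) {
      va <- ensure_flank_vertex(st, cm$forward_a, cm$apex, TRUE, nested, t)
      vb <- ensure_flank_vertex(st, cm$forward_b, cm$apex, FALSE, nested, t)
      pairs[[length(pairs) + 1]] <- cbind(va, vb)
    }
  }

  corr <- if (length(pairs)) do.call(rbind, pairs) else
    matrix(integer(0), ncol = 2)
  corr <- corr[corr[, 1] != corr[, 2], , drop = FALSE]
  mesh$vertices <- st$vertices
  mesh$triangles <- st$triangles
  mesh$ring <- st$ring
  mesh$correspondences <- corr
  mesh$merged <- merge_classes(nrow(st$vertices), corr)
  ## rim = ring vertices not strictly inside any cut interval
  inner <- unique(unlist(lapply(cuts, function(cm) {
    iv <- ring_walk(st$ring, cm$forward_a, cm$forward_b)
    iv[-c(1, length(iv))]
  })))
  rim <- st$ring[!(st$ring %in% inner)]
  mesh$rim_vertices <- rim
  ew <- mesh_edges(st$vertices, st$triangles)
  mesh$edges <- ew$edges
  mesh$edge_lengths <- ew$lengths
  mesh$stitched <- TRUE
  mesh
}

## Arc-length parameterisation of one cut flank, walked rim -> apex.
## Intervals of nested cuts contribute zero effective length (their two
## mouths are identified when the tear itself is stitched), and vertices
## strictly inside them are excluded from matching.  Returns the vertex
## sequence, the effective parameter of each vertex in [0, 1], the
## effective length, and which vertices participate in matching.
flank_params <- function(st, forward, apex, forwards, nested) {
  seqv <- if (forwards) ring_walk(st$ring, forward, apex) else
    rev(ring_walk(st$ring, apex, forward))
  if (length(seqv) < 2)
    return(list(seq = seqv, t = 0, length = 0, match = FALSE))
  pv <- st$vertices[seqv, , drop = FALSE]
  step <- sqrt(rowSums(diff(pv)^2))
  ## collapse steps inside nested cut intervals
  excl <- rep(FALSE, length(seqv))
  for (nc in nested) {
    iv <- ring_walk(st$ring, nc$forward_a, nc$forward_b)
    pos <- match(iv, seqv)
    if (all(!is.na(pos))) {
      step[seq(min(pos), max(pos) - 1)] <- 0
      excl[pos[-c(1, length(pos))]] <- TRUE
    }
  }
  cum <- c(0, cumsum(step))
  L <- cum[length(cum)]
  t <- if (L > 0) cum / L else cum
  match_ok <- !excl
  match_ok[c(1, length(seqv))] <- FALSE    # mouths and apex handled apart
  ## drop duplicated params (vertices at collapsed positions)
  match_ok[duplicated(t)] <- FALSE
  list(seq = seqv, t = t, length = L, match = match_ok)
}

## Find or insert the vertex at effective parameter t on a flank.
## An existing vertex is reused if it is within 10% of the local
## inter-vertex spacing; otherwise the containing boundary edge is split.
ensure_flank_vertex <- function(st, forward, apex, forwards, nested, t) {
  f <- flank_params(st, forward, apex, forwards, nested)
  usable <- !duplicated(f$t)
  dt <- abs(f$t - t)
  j <- which(usable)[which.min(dt[usable])]
  spacing <- local_spacing(f$t[usable], f$t[j])
  if (dt[j] <= max(0.1 * spacing, 1e-9)) return(f$seq[j])
  ## insert: the physical segment containing t is bounded by the last
  ## vertex below t (which may sit at the end of a collapsed-interval
  ## parameter plateau) and the first vertex above it
  k <- max(which(f$t < t))
  k2 <- k + which(f$t[(k + 1):length(f$t)] > t)[1]
  frac <- (t - f$t[k]) / (f$t[k2] - f$t[k])
  va <- f$seq[k]; vb <- f$seq[k2]
  ## degenerate fraction: fall back to the nearer endpoint
  if (frac < 1e-7) return(va)
  if (frac > 1 - 1e-7) return(vb)
  ## the split requires ring-adjacent endpoints; if the segment contains
  ## an intermediate (parameter-duplicated) vertex, reuse the nearest one
  ia <- match(va, st$ring); ib <- match(vb, st$ring)
  gap <- (if (forwards) ib - ia else ia - ib) %% length(st$ring)
  if (gap != 1) return(f$seq[j])
  p <- st$vertices[va, ] * (1 - frac) + st$vertices[vb, ] * frac
  split_boundary_edge(st, va, vb, p, forwards)
}

local_spacing <- function(tsorted, t0) {
  ts <- sort(tsorted)
  i <- which.min(abs(ts - t0))
  cand <- c(if (i > 1) ts[i] - ts[i - 1], if (i < length(ts)) ts[i + 1] - ts[i])
  min(cand)
}

## Split the boundary edge between ring-adjacent vertices va, vb at point
## p: append the new vertex, update the ring, and split the unique
## triangle containing the edge into two.  `forwards` tells whether the
## walk direction va -> vb follows ring order.
split_boundary_edge <- function(st, va, vb, p, forwards) {
  if (!forwards) { tmp <- va; va <- vb; vb <- tmp }   # ring order va -> vb
  st$vertices <- rbind(st$vertices, p)
  vn <- nrow(st$vertices)
  ia <- match(va, st$ring)
  n <- length(st$ring)
  ib <- if (ia == n) 1L else ia + 1L
  if (st$ring[ib] != vb) stop("internal error: vertices not ring-adjacent")
  st$ring <- append(st$ring, vn, after = ia)
  tri <- st$triangles
  hit <- which((tri[, 1] == va & tri[, 2] == vb) |
               (tri[, 2] == va & tri[, 3] == vb) |
               (tri[, 3] == va & tri[, 1] == vb) |
               (tri[, 1] == vb & tri[, 2] == va) |
               (tri[, 2] == vb & tri[, 3] == va) |
               (tri[, 3] == vb & tri[, 1] == va))
  if (length(hit) != 1)
    stop("internal error: boundary edge not in exactly one triangle")
  tr <- tri[hit, ]
  w <- tr[!(tr %in% c(va, vb))]
  ## preserve orientation of the original triangle
  t1 <- tr; t1[t1 == vb] <- vn
  t2 <- tr; t2[t2 == va] <- vn
  st$triangles <- rbind(tri[-hit, , drop = FALSE], t1, t2)
  vn
}

## Union-find contraction of correspondence pairs into equivalence
## classes; returns a class id (1..k, by first member) per vertex.
merge_classes <- function(n, pairs) {
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs)) for (r in seq_len(nrow(pairs))) {
    a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  roots <- vapply(seq_len(n), find, 1L)
  match(roots, sort(unique(roots)))
}

#' Euler characteristic of the stitched mesh after contraction
#'
#' Contracts all correspondence pairs and computes V - E + F (faces not
#' counting the outer region).  A mesh that stitches into a topological
#' disc has Euler characteristic 1.
#'
#' @param mesh A stitched mesh.
#' @return Integer Euler characteristic.
#' @export
euler_characteristic <- function(mesh) {
  stopifnot(isTRUE(mesh$stitched))
  cls <- mesh$merged
  tri <- matrix(cls[mesh$triangles], ncol = 3)
  ## contraction can collapse triangles along a stitched line to edges
  ## or points; only non-degenerate simplices count
  tri <- tri[tri[, 1] != tri[, 2] & tri[, 2] != tri[, 3] &
             tri[, 3] != tri[, 1], , drop = FALSE]
  e <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  e <- e[e[, 1] != e[, 2], , drop = FALSE]
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  length(unique(as.vector(tri))) - nrow(e) + nrow(tri)
}

#' Export a mesh as OFF-format text (debug aid)
#' @param mesh A (possibly unstitched) mesh.
#' @param path Output path.
#' @export
mesh_to_off <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$triangles)), con)
  writeLines(sprintf("%.9g %.9g 0", mesh$vertices[, 1], mesh$vertices[, 2]), con)
  writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1] - 1,
                     mesh$triangles[, 2] - 1, mesh$triangles[, 3] - 1), con)
  invisible(path)
}

## Evaluate expr with a fixed RNG seed, restoring the caller's random
## stream afterwards.
with_fixed_rng <- function(expr, seed = 1742L) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}
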