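## Constraint-edge enforcement for the outline triangulation.
##
## The Delaunay triangulation of the outline-plus-grid point set does not
## always contain every outline segment (in particular along the two
## flanks of a nearly closed cut, which may lie arbitrarily close to each
## other).  Missing segments are enforced with the classical flip-based
## constrained-Delaunay insertion: while the segment is absent, find an
## edge that properly crosses it whose two adjacent triangles form a
## strictly convex quadrilateral, and flip it.  Every step keeps a valid
## triangulation, and for a simple polygon the enforced segments never
## cross each other, so previously enforced segments are never undone.
## Vertices that lie (numerically) on a segment split the constraint,
## which is then enforced recursively on the two halves.

orient2d <- function(ax, ay, bx, by, cx, cy)
  (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)

## Enforce each segment (rows of `segs`) as an edge of the triangulation.
enforce_edges <- function(pts, tri, segs) {
  for (r in seq_len(nrow(segs)))
    tri <- insert_edge(pts, tri, segs[r, 1], segs[r, 2], depth = 0)
  tri
}

has_edge <- function(tri, a, b) {
  any((tri[, 1] == a & tri[, 2] == b) | (tri[, 2] == a & tri[, 3] == b) |
      (tri[, 3] == a & tri[, 1] == b) | (tri[, 1] == b & tri[, 2] == a) |
      (tri[, 2] == b & tri[, 3] == a) | (tri[, 3] == b & tri[, 1] == a))
}

insert_edge <- function(pts, tri, a, b, depth = 0) {
  if (depth > 16) stop("meshing error: constraint enforcement failed")
  if (has_edge(tri, a, b)) return(tri)
  axy <- pts[a, ]; bxy <- pts[b, ]
  scale2 <- sum((bxy - axy)^2)
  tol <- 1e-12 * scale2
  side <- function(i) orient2d(axy[1], axy[2], bxy[1], bxy[2],
                               pts[i, 1], pts[i, 2])
  ## a vertex sitting (numerically) on the open segment splits it
  on_seg <- function(i) {
    if (i == a || i == b) return(FALSE)
    if (abs(side(i)) > tol) return(FALSE)
    t <- sum((pts[i, ] - axy) * (bxy - axy)) / scale2
    t > 1e-9 && t < 1 - 1e-9
  }
  ## does the open segment uv properly cross the open segment ab?
  crosses <- function(u, v) {
    s1 <- side(u); s2 <- side(v)
    if (!((s1 > tol & s2 < -tol) | (s1 < -tol & s2 > tol))) return(FALSE)
    s3 <- orient2d(pts[u, 1], pts[u, 2], pts[v, 1], pts[v, 2],
                   axy[1], axy[2])
    s4 <- orient2d(pts[u, 1], pts[u, 2], pts[v, 1], pts[v, 2],
                   bxy[1], bxy[2])
    s3 * s4 < 0
  }
  for (iter in seq_len(10000)) {
    if (has_edge(tri, a, b)) return(tri)
    ## collect the edges of the triangulation crossing ab
    ed <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
    ed <- cbind(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
    ed <- ed[!duplicated(ed), , drop = FALSE]
    sv <- numeric(max(tri))
    vs <- sort(unique(as.vector(tri)))
    for (i in vs) sv[i] <- side(i)
    if (any(vapply(vs, on_seg, TRUE)))
      stop("meshing error: a vertex lies exactly on an outline segment ",
           "(outline flanks in exact contact?)")
    cross_rows <- which((sv[ed[, 1]] > tol & sv[ed[, 2]] < -tol) |
                        (sv[ed[, 1]] < -tol & sv[ed[, 2]] > tol))
    cross_rows <- cross_rows[vapply(cross_rows, function(r)
      crosses(ed[r, 1], ed[r, 2]), TRUE)]
    if (!length(cross_rows))
      stop("meshing error: constraint segment cannot be recovered")
    flipped <- FALSE
    for (r in cross_rows) {
      u <- ed[r, 1]; v <- ed[r, 2]
      t12 <- which((rowSums(tri == u) > 0) & (rowSums(tri == v) > 0))
      if (length(t12) != 2) next      # hull edge: try another
      p <- setdiff(tri[t12[1], ], c(u, v))
      q <- setdiff(tri[t12[2], ], c(u, v))
      if (length(p) != 1 || length(q) != 1 || p == q) next
      ## flip is valid only if the quad u,p,v,q is strictly convex,
      ## i.e. segment pq properly crosses segment uv
      o1 <- orient2d(pts[p, 1], pts[p, 2], pts[q, 1], pts[q, 2],
                     pts[u, 1], pts[u, 2])
      o2 <- orient2d(pts[p, 1], pts[p, 2], pts[q, 1], pts[q, 2],
                     pts[v, 1], pts[v, 2])
      o3 <- orient2d(pts[u, 1], pts[u, 2], pts[v, 1], pts[v, 2],
                     pts[p, 1], pts[p, 2])
      o4 <- orient2d(pts[u, 1], pts[u, 2], pts[v, 1], pts[v, 2],
                     pts[q, 1], pts[q, 2])
      if (!(o1 * o2 < 0 && o3 * o4 < 0)) next
      tri <- tri[-t12, , drop = FALSE]
      tri <- rbind(tri, c(u, p, q), c(v, q, p))
      flipped <- TRUE
      break
    }
    if (!flipped)
      stop("meshing error: no flippable edge crossing the constraint")
  }
  stop("meshing error: constraint insertion did not terminate")
}
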