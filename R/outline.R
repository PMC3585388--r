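## Flat-mount outlines and their mark-up.
##
## A flat-mount is described by a closed, simple polygon in micrometres
## (the outline), together with mark-up: the locations of the relaxing
## cuts and tears (each a V-shaped incision described by its two rim-side
## "forward" vertices and its apex), the nasal-pole vertex on the
## perimeter, and optional attached data (named point sets, named
## landmark polylines, and counted sampling boxes).
##
## Vertex indices are 1-based indices into the outline ring.  The ring is
## stored counter-clockwise (positive signed area); clockwise input is
## reversed at construction time and all mark-up indices are remapped.
## Inputs using an image origin (y increasing downwards) are flipped at
## read time.

#' Describe one relaxing cut or tear
#'
#' A cut is a V-shaped incision from the retinal rim towards the centre.
#' Walking the outline counter-clockwise from `forward_a` to `forward_b`
#' must pass through `apex`.  The two flanks (`forward_a` to `apex`, and
#' `apex` to `forward_b`) were a single line of tissue before cutting.
#' Tears that occurred during flattening are marked up identically.
#'
#' @param forward_a,apex,forward_b 1-based outline vertex indices.
#' @return An object of class `cut_markup`.
#' @export
cut_markup <- function(forward_a, apex, forward_b) {
  idx <- c(forward_a = forward_a, apex = apex, forward_b = forward_b)
  if (any(idx != round(idx)) || any(idx < 1))
    stop("cut mark-up indices must be positive integers")
  structure(as.list(idx), class = "cut_markup")
}

#' Construct a flat-mount outline
#'
#' @param vertices An n-by-2 matrix of outline vertices in micrometres,
#'   ordered around the perimeter; the ring is closed implicitly (do not
#'   repeat the first vertex).
#' @param cuts A list of [cut_markup()] objects.
#' @param nasal_pole_index 1-based index of the nasal-pole vertex on the
#'   perimeter, or `NA` if not marked.
#' @param datasets Named list of m-by-2 point matrices (micrometres).
#' @param landmarks Named list of m-by-2 polyline matrices.
#' @param boxes `NULL` or a `data.frame` with columns `x`, `y` (box centre,
#'   micrometres), `side` (box side length, micrometres) and `count`.
#' @param scale Micrometres per input unit; applied to all coordinates.
#' @return An object of class `flat_outline`.
#' @export
flat_outline <- function(vertices, cuts = list(), nasal_pole_index = NA,
                         datasets = list(), landmarks = list(), boxes = NULL,
                         scale = 1) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2 || nrow(vertices) < 3)
    stop("degenerate outline: need at least 3 two-column vertices")
  storage.mode(vertices) <- "double"
  if (any(!is.finite(vertices))) stop("outline vertices must be finite")
  vertices <- vertices * scale
  datasets <- lapply(datasets, function(m) {
    m <- matrix(as.numeric(as.matrix(m)), ncol = 2) * scale
    colnames(m) <- c("x", "y"); m
  })
  landmarks <- lapply(landmarks, function(m) {
    m <- matrix(as.numeric(as.matrix(m)), ncol = 2) * scale
    colnames(m) <- c("x", "y"); m
  })
  if (!is.null(boxes)) {
    boxes <- as.data.frame(boxes)
    stopifnot(all(c("x", "y", "side", "count") %in% names(boxes)))
    boxes$x <- boxes$x * scale; boxes$y <- boxes$y * scale
    boxes$side <- boxes$side * scale
  }
  n <- nrow(vertices)
  remap <- seq_len(n)
  if (polygon_area(vertices) < 0) {   # clockwise input: reverse to CCW
    vertices <- vertices[n:1, , drop = FALSE]
    remap <- rev(remap)               # old index i now lives at remap[i]
    remap <- order(remap)
  }
  fix_idx <- function(i) if (is.na(i)) NA_integer_ else remap[i]
  cuts <- lapply(cuts, function(cm) {
    cut_markup(fix_idx(cm$forward_a), fix_idx(cm$apex), fix_idx(cm$forward_b))
  })
  if (!is.na(nasal_pole_index)) {
    if (nasal_pole_index < 1 || nasal_pole_index > n)
      stop("nasal_pole_index out of range")
    nasal_pole_index <- fix_idx(nasal_pole_index)
  }
  structure(list(vertices = vertices, cuts = cuts,
                 nasal_pole_index = as.integer(nasal_pole_index),
                 datasets = datasets, landmarks = landmarks, boxes = boxes),
            class = "flat_outline")
}

#' @export
print.flat_outline <- function(x, ...) {
  cat("Flat-mount outline:", nrow(x$vertices), "vertices,",
      length(x$cuts), "cut(s)\n")
  cat("  area:", format(polygon_area(x$vertices), digits = 6), "um^2;",
      "nasal pole index:", x$nasal_pole_index, "\n")
  if (length(x$datasets))
    cat("  datasets:", paste(sprintf("%s (%d)", names(x$datasets),
                                     vapply(x$datasets, nrow, 1L)),
                             collapse = ", "), "\n")
  if (length(x$landmarks))
    cat("  landmarks:", paste(names(x$landmarks), collapse = ", "), "\n")
  if (!is.null(x$boxes)) cat("  counted boxes:", nrow(x$boxes), "\n")
  invisible(x)
}

## Signed polygon area (shoelace); positive for counter-clockwise rings.
polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  j <- c(seq_len(nrow(v))[-1], 1)
  sum(x * y[j] - x[j] * y) / 2
}

## Even-odd point-in-polygon test, vectorised over points.  Points on the
## boundary may fall either side; callers needing boundary tolerance
## should test distance to the boundary as well.
points_in_polygon <- function(pts, poly) {
  px <- pts[, 1]; py <- pts[, 2]
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

## Minimum distance from each point to the polygon boundary.
dist_to_ring <- function(pts, poly) {
  n <- nrow(poly)
  j <- c(seq_len(n)[-1], 1)
  ax <- poly[, 1]; ay <- poly[, 2]
  bx <- poly[j, 1]; by <- poly[j, 2]
  dx <- bx - ax; dy <- by - ay
  len2 <- dx^2 + dy^2
  out <- numeric(nrow(pts))
  for (k in seq_len(nrow(pts))) {
    t <- ((pts[k, 1] - ax) * dx + (pts[k, 2] - ay) * dy) / pmax(len2, 1e-300)
    t <- pmin(pmax(t, 0), 1)
    out[k] <- sqrt(min((pts[k, 1] - (ax + t * dx))^2 +
                       (pts[k, 2] - (ay + t * dy))^2))
  }
  out
}

## TRUE if the closed ring has a self-intersection between non-adjacent
## segments.
ring_self_intersects <- function(v) {
  n <- nrow(v)
  j <- c(seq_len(n)[-1], 1)
  a <- v; b <- v[j, , drop = FALSE]
  for (i in seq_len(n - 2)) {
    ks <- (i + 2):n
    if (i == 1) ks <- ks[ks != n]   # segment n is adjacent to segment 1
    if (!length(ks)) next
    if (any(segments_cross(a[i, ], b[i, ], a[ks, , drop = FALSE],
                           b[ks, , drop = FALSE])))
      return(TRUE)
  }
  FALSE
}

## Proper crossing test of segment (p1,p2) against rows of (q1,q2).
segments_cross <- function(p1, p2, q1, q2) {
  d1 <- (p2[1] - p1[1]) * (q1[, 2] - p1[2]) - (p2[2] - p1[2]) * (q1[, 1] - p1[1])
  d2 <- (p2[1] - p1[1]) * (q2[, 2] - p1[2]) - (p2[2] - p1[2]) * (q2[, 1] - p1[1])
  d3 <- (q2[, 1] - q1[, 1]) * (p1[2] - q1[, 2]) -
        (q2[, 2] - q1[, 2]) * (p1[1] - q1[, 1])
  d4 <- (q2[, 1] - q1[, 1]) * (p2[2] - q1[, 2]) -
        (q2[, 2] - q1[, 2]) * (p2[1] - q1[, 1])
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

## Perimeter interval of a cut as the CCW index walk forward_a -> forward_b.
cut_interval <- function(cm, n) {
  i <- cm$forward_a
  path <- i
  while (i != cm$forward_b) {
    i <- if (i == n) 1L else i + 1L
    path <- c(path, i)
  }
  path
}

#' Validate flat-mount mark-up
#'
#' Checks the structural invariants of an outline and its mark-up: the
#' ring is simple; the nasal-pole index is a valid perimeter vertex; each
#' cut's apex lies strictly inside its perimeter interval and its flanks
#' have nonzero length; distinct cuts are disjoint or strictly nested (a
#' tear inside a cut flank); and every attached data point and landmark
#' vertex lies inside or on the outline.  Violations are reported, never
#' silently repaired.
#'
#' @param o A [flat_outline()].
#' @return A list with `ok` (logical) and `violations`, a `data.frame`
#'   with columns `check` and `detail`.
#' @export
validate_markup <- function(o) {
  stopifnot(inherits(o, "flat_outline"))
  v <- o$vertices
  n <- nrow(v)
  bad <- list()
  note <- function(check, detail) bad[[length(bad) + 1]] <<- data.frame(
    check = check, detail = detail, stringsAsFactors = FALSE)

  if (ring_self_intersects(v))
    note("simple-ring", "outline ring intersects itself")
  if (!is.na(o$nasal_pole_index) &&
      (o$nasal_pole_index < 1 || o$nasal_pole_index > n))
    note("nasal-pole", sprintf("index %d outside 1..%d", o$nasal_pole_index, n))

  intervals <- list()
  for (ci in seq_along(o$cuts)) {
    cm <- o$cuts[[ci]]
    idx <- c(cm$forward_a, cm$apex, cm$forward_b)
    if (any(idx > n)) {
      note("cut-index", sprintf("cut %d has vertex index beyond %d", ci, n))
      next
    }
    path <- cut_interval(cm, n)
    k <- match(cm$apex, path)
    if (is.na(k) || k == 1 || k == length(path))
      note("cut-apex", sprintf(
        "cut %d: apex %d not strictly inside interval %d..%d",
        ci, cm$apex, cm$forward_a, cm$forward_b))
    intervals[[ci]] <- path
  }
  if (length(intervals) > 1) {
    for (i in seq_along(intervals)) for (j in seq_along(intervals)) {
      if (i >= j) next
      a <- intervals[[i]]; b <- intervals[[j]]
      if (is.null(a) || is.null(b)) next
      common <- intersect(a, b)
      a_in_b <- all(a %in% b) && length(a) < length(b)
      b_in_a <- all(b %in% a) && length(b) < length(a)
      if (length(common) > 0 && !a_in_b && !b_in_a)
        note("cut-overlap", sprintf("cuts %d and %d overlap without nesting",
                                    i, j))
    }
  }

  tol <- 1e-6 * max(diff(range(v[, 1])), diff(range(v[, 2])))
  check_inside <- function(pts, what) {
    if (!nrow(pts)) return()
    inside <- points_in_polygon(pts, v) | dist_to_ring(pts, v) <= tol
    if (!all(inside))
      note("point-outside", sprintf("%s: %d point(s) outside the outline",
                                    what, sum(!inside)))
  }
  for (nm in names(o$datasets)) check_inside(o$datasets[[nm]],
                                             paste("dataset", nm))
  for (nm in names(o$landmarks)) check_inside(o$landmarks[[nm]],
                                              paste("landmark", nm))

  violations <- if (length(bad)) do.call(rbind, bad) else
    data.frame(check = character(), detail = character(),
               stringsAsFactors = FALSE)
  list(ok = nrow(violations) == 0, violations = violations)
}
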