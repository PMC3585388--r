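## Readers and writers.
##
## Two input formats are supported: a plain coordinate-text dialect (the
## native format, suitable for camera-lucida style digitisation) and the
## ImageJ binary .roi format (polygon and freehand ROIs only) for outlines
## traced on bitmap images.
##
## Text dialect (one directive or coordinate pair per line, '#' comments):
##
##   SCALE <um_per_unit>
##   OUTLINE <n>            followed by n lines "x y"
##   NASAL <index>          1-based index into the OUTLINE ring
##   CUT <forward_a> <apex> <forward_b>
##   DATASET <name> <n>     followed by n lines "x y"
##   LANDMARK <name> <n>    followed by n lines "x y"
##   BOXES <name> <side_um> <n>   followed by n lines "x y count"
##
## Coordinates are planar micrometres (after SCALE), y axis up.

parse_fail <- function(path, lineno, msg) {
  stop(sprintf("%s:%d: %s", path, lineno, msg), call. = FALSE)
}

#' Read a flat-mount outline in the coordinate-text dialect
#'
#' @param path Path to a text file in the dialect described above.
#' @return A [flat_outline()].
#' @export
read_outline_text <- function(path) {
  lines <- readLines(path, warn = FALSE)
  strip <- sub("#.*$", "", lines)
  scale <- 1
  vertices <- NULL
  cuts <- list()
  nasal <- NA
  datasets <- list(); landmarks <- list()
  boxes <- NULL
  i <- 1
  n_lines <- length(strip)
  read_pairs <- function(start, n, ncolumns) {
    if (start + n - 1 > n_lines)
      parse_fail(path, n_lines, "unexpected end of file inside a block")
    block <- strip[start:(start + n - 1)]
    vals <- suppressWarnings(lapply(strsplit(trimws(block), "[ \t,]+"),
                                    as.numeric))
    for (k in seq_along(vals))
      if (length(vals[[k]]) != ncolumns || any(is.na(vals[[k]])))
        parse_fail(path, start + k - 1,
                   sprintf("expected %d numeric fields", ncolumns))
    do.call(rbind, vals)
  }
  while (i <= n_lines) {
    line <- trimws(strip[i])
    if (line == "") { i <- i + 1; next }
    tok <- strsplit(line, "[ \t]+")[[1]]
    key <- toupper(tok[1])
    if (key == "SCALE") {
      scale <- suppressWarnings(as.numeric(tok[2]))
      if (is.na(scale) || scale <= 0) parse_fail(path, i, "bad SCALE value")
      i <- i + 1
    } else if (key == "OUTLINE") {
      n <- suppressWarnings(as.integer(tok[2]))
      if (is.na(n) || n < 1) parse_fail(path, i, "bad OUTLINE count")
      vertices <- read_pairs(i + 1, n, 2)
      i <- i + 1 + n
    } else if (key == "NASAL") {
      nasal <- suppressWarnings(as.integer(tok[2]))
      if (is.na(nasal)) parse_fail(path, i, "bad NASAL index")
      i <- i + 1
    } else if (key == "CUT") {
      idx <- suppressWarnings(as.integer(tok[2:4]))
      if (length(idx) != 3 || any(is.na(idx)))
        parse_fail(path, i, "CUT needs three vertex indices")
      cuts[[length(cuts) + 1]] <- cut_markup(idx[1], idx[2], idx[3])
      i <- i + 1
    } else if (key %in% c("DATASET", "LANDMARK")) {
      if (length(tok) < 3) parse_fail(path, i, paste(key, "needs name and count"))
      nm <- tok[2]
      n <- suppressWarnings(as.integer(tok[3]))
      if (is.na(n) || n < 0) parse_fail(path, i, "bad count")
      m <- if (n > 0) read_pairs(i + 1, n, 2) else
        matrix(numeric(0), ncol = 2)
      if (key == "DATASET") datasets[[nm]] <- m else landmarks[[nm]] <- m
      i <- i + 1 + n
    } else if (key == "BOXES") {
      if (length(tok) < 4) parse_fail(path, i, "BOXES needs name, side, count")
      side <- suppressWarnings(as.numeric(tok[3]))
      n <- suppressWarnings(as.integer(tok[4]))
      if (is.na(side) || is.na(n)) parse_fail(path, i, "bad BOXES header")
      m <- if (n > 0) read_pairs(i + 1, n, 3) else matrix(numeric(0), ncol = 3)
      b <- data.frame(x = m[, 1], y = m[, 2], side = side, count = m[, 3])
      boxes <- if (is.null(boxes)) b else rbind(boxes, b)
      i <- i + 1 + n
    } else {
      parse_fail(path, i, sprintf("unknown directive '%s'", tok[1]))
    }
  }
  if (is.null(vertices)) parse_fail(path, n_lines, "no OUTLINE block found")
  flat_outline(vertices, cuts = cuts, nasal_pole_index = nasal,
               datasets = datasets, landmarks = landmarks, boxes = boxes,
               scale = scale)
}

#' Write a flat-mount outline in the coordinate-text dialect
#'
#' @param o A [flat_outline()] (coordinates already in micrometres, so the
#'   file is written with `SCALE 1`).
#' @param path Output path.
#' @export
write_outline_text <- function(o, path) {
  stopifnot(inherits(o, "flat_outline"))
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(m, ...) apply(m, 1, function(r)
    paste(sprintf("%.9g", r), collapse = " "))
  wl <- function(...) writeLines(paste0(...), con)
  wl("# flat-mount outline (coordinate-text dialect)")
  wl("SCALE 1")
  wl("OUTLINE ", nrow(o$vertices))
  writeLines(fmt(o$vertices), con)
  if (!is.na(o$nasal_pole_index)) wl("NASAL ", o$nasal_pole_index)
  for (cm in o$cuts)
    wl("CUT ", cm$forward_a, " ", cm$apex, " ", cm$forward_b)
  for (nm in names(o$datasets)) {
    wl("DATASET ", nm, " ", nrow(o$datasets[[nm]]))
    if (nrow(o$datasets[[nm]])) writeLines(fmt(o$datasets[[nm]]), con)
  }
  for (nm in names(o$landmarks)) {
    wl("LANDMARK ", nm, " ", nrow(o$landmarks[[nm]]))
    if (nrow(o$landmarks[[nm]])) writeLines(fmt(o$landmarks[[nm]]), con)
  }
  if (!is.null(o$boxes) && nrow(o$boxes)) {
    for (side in unique(o$boxes$side)) {
      b <- o$boxes[o$boxes$side == side, ]
      wl("BOXES counts ", sprintf("%.9g", side), " ", nrow(b))
      writeLines(sprintf("%.9g %.9g %.9g", b$x, b$y, b$count), con)
    }
  }
  invisible(path)
}

#' Read an outline from an ImageJ .roi file
#'
#' Reads polygon and freehand ROIs from the ImageJ binary ROI format and
#' returns the traced outline.  Image coordinates have the y axis pointing
#' down; they are flipped to y-up at read time (a message records the
#' flip).  Only the outline geometry is read; cuts and the nasal pole must
#' be marked up separately.
#'
#' @param path Path to a `.roi` file.
#' @param scale Micrometres per pixel.
#' @return A [flat_outline()] with geometry only.
#' @export
read_outline_roi <- function(path, scale = 1) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 64 || rawToChar(raw[1:4]) != "Iout")
    stop("not an ImageJ ROI file (missing 'Iout' magic)")
  be_short <- function(off, n = 1, signed = TRUE)
    readBin(raw[(off + 1):(off + 2 * n)], "integer", n = n, size = 2,
            signed = signed, endian = "big")
  type <- as.integer(raw[7])
  ## ImageJ ROI type codes: 0 polygon, 7 freehand, 8 traced
  if (!type %in% c(0L, 7L, 8L))
    stop(sprintf("unsupported ROI type %d: only polygon/freehand outlines",
                 type))
  top <- be_short(8); left <- be_short(10)
  n <- be_short(16, signed = FALSE)
  if (n < 3) stop("degenerate outline: ROI has fewer than 3 vertices")
  if (length(raw) < 64 + 4 * n) stop("truncated ROI file")
  xs <- be_short(64, n)
  ys <- be_short(64 + 2 * n, n)
  x <- (left + xs) * scale
  y <- -(top + ys) * scale          # flip image y-down to y-up
  message("read_outline_roi: flipped image y axis to y-up")
  flat_outline(cbind(x, y))
}

#' Write a reconstruction to a structured text file
#'
#' The schema is line-oriented: header directives (`RIM_ANGLE`, `E_L`,
#' `FLAG`, `CONVERGED`), then a `VERTICES` block with one line per mesh
#' vertex (`flat_x flat_y colatitude longitude`), then `DATASET` and
#' `LANDMARK` blocks with one mapped point per line.  Files written here
#' are read back losslessly (to the printed precision) by
#' [read_reconstruction()].
#'
#' @param r A reconstruction, see [reconstruct_retina()].
#' @param path Output path.
#' @export
write_reconstruction <- function(r, path) {
  stopifnot(inherits(r, "retina_reconstruction"))
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  num <- function(x) sprintf("%.10g", x)
  wl("# retinamorph reconstruction v1")
  wl("RIM_ANGLE ", num(unclass(r$rim_angle)))
  wl("E_L ", num(r$E_L))
  wl("FLAG ", r$flag)
  wl("CONVERGED ", ifelse(r$converged, "TRUE", "FALSE"))
  sph <- r$vertex_sphere
  flat <- r$mesh$vertices
  wl("VERTICES ", nrow(flat))
  writeLines(sprintf("%.10g %.10g %.10g %.10g", flat[, 1], flat[, 2],
                     sph$colatitude, sph$longitude), con)
  write_mapped <- function(key, flatpts, nm) {
    mp <- map_to_sphere(r, flatpts)
    wl(key, " ", nm, " ", nrow(flatpts))
    if (nrow(flatpts))
      writeLines(sprintf("%.10g %.10g %.10g %.10g", flatpts[, 1],
                         flatpts[, 2], mp$colatitude, mp$longitude), con)
  }
  o <- r$outline
  for (nm in names(o$datasets)) write_mapped("DATASET", o$datasets[[nm]], nm)
  for (nm in names(o$landmarks)) write_mapped("LANDMARK", o$landmarks[[nm]], nm)
  invisible(path)
}

#' Read a reconstruction file written by [write_reconstruction()]
#'
#' @param path Path to a reconstruction text file.
#' @return A list with elements `rim_angle`, `E_L`, `flag`, `converged`,
#'   `vertices` (data.frame: flat_x, flat_y, colatitude, longitude),
#'   `datasets` and `landmarks` (named lists of such data.frames).
#' @export
read_reconstruction <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  out <- list(datasets = list(), landmarks = list())
  i <- 1
  block <- function(start, n) {
    m <- do.call(rbind, lapply(strsplit(trimws(lines[start:(start + n - 1)]),
                                        "[ \t]+"), as.numeric))
    data.frame(flat_x = m[, 1], flat_y = m[, 2], colatitude = m[, 3],
               longitude = m[, 4])
  }
  while (i <= length(lines)) {
    tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    key <- toupper(tok[1])
    if (key == "RIM_ANGLE") { out$rim_angle <- as.numeric(tok[2]); i <- i + 1 }
    else if (key == "E_L") { out$E_L <- as.numeric(tok[2]); i <- i + 1 }
    else if (key == "FLAG") { out$flag <- tok[2]; i <- i + 1 }
    else if (key == "CONVERGED") { out$converged <- as.logical(tok[2]); i <- i + 1 }
    else if (key == "VERTICES") {
      n <- as.integer(tok[2]); out$vertices <- block(i + 1, n); i <- i + 1 + n
    } else if (key %in% c("DATASET", "LANDMARK")) {
      nm <- tok[2]; n <- as.integer(tok[3])
      d <- if (n > 0) block(i + 1, n) else
        data.frame(flat_x = numeric(0), flat_y = numeric(0),
                   colatitude = numeric(0), longitude = numeric(0))
      if (key == "DATASET") out$datasets[[nm]] <- d else
        out$landmarks[[nm]] <- d
      i <- i + 1 + n
    } else stop(sprintf("%s: unknown directive '%s'", path, tok[1]))
  }
  out
}
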