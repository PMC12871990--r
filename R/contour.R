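# Contour data model: an ordered closed polyline (first point NOT repeated),
# stored as a tibble with columns x, y plus `unit` and `id` attributes.

#' Create a cell contour from a data frame of coordinates
#'
#' A contour is an ordered sequence of 2D points tracing a simple closed
#' polygon (the closing segment back to the first point is implicit). A
#' duplicated final point equal to the first is dropped on construction.
#'
#' @param points A data frame (or matrix) with two numeric columns giving the
#'   x and y coordinates of consecutive contour points.
#' @param unit Coordinate unit, `"pixel"` or `"micron"`.
#' @param id Text label for the cell.
#' @param check If `TRUE` (default), verify the polygon is simple
#'   (no self-intersection) and has no repeated consecutive points.
#'
#' @return A `cellph_contour`: a tibble with columns `x` and `y` and
#'   attributes `unit` and `id`.
#' @export
#' @examples
#' sq <- as_contour(data.frame(x = c(0, 2, 2, 0), y = c(0, 0, 1, 1)))
#' contour_unit(sq)
as_contour <- function(points, unit = c("pixel", "micron"), id = "cell",
                       check = TRUE) {
  unit <- match.arg(unit)
  pts <- as.data.frame(points)
  if (ncol(pts) < 2L) abort("contour needs two coordinate columns")
  pts <- pts[, 1:2]
  names(pts) <- c("x", "y")
  if (!is.numeric(pts$x) || !is.numeric(pts$y)) {
    abort("contour coordinates must be numeric")
  }
  # drop an explicit closure point repeating the first row
  n <- nrow(pts)
  if (n >= 2L && pts$x[n] == pts$x[1L] && pts$y[n] == pts$y[1L]) {
    pts <- pts[-n, , drop = FALSE]
  }
  if (nrow(pts) < 3L) {
    abort("malformed contour: fewer than 3 distinct points",
          class = "cellph_malformed_input")
  }
  if (check) {
    dup <- which(diff(pts$x) == 0 & diff(pts$y) == 0)
    if (length(dup) > 0L) {
      abort(sprintf("repeated consecutive point at row %d", dup[1L] + 1L),
            class = "cellph_malformed_input")
    }
    if (!is_simple_polygon(pts$x, pts$y)) {
      abort("contour is self-intersecting", class = "cellph_geometry_error")
    }
  }
  out <- as_tibble(pts)
  attr(out, "unit") <- unit
  attr(out, "id") <- as.character(id)
  class(out) <- c("cellph_contour", class(out))
  out
}

#' @rdname as_contour
#' @param x A `cellph_contour`.
#' @export
contour_unit <- function(x) attr(x, "unit")

#' @rdname as_contour
#' @export
contour_id <- function(x) attr(x, "id")

#' Read a contour from a two-column CSV file
#'
#' The file must contain two numeric columns (x, y), one row per contour
#' point in traversal order, with an optional header. A final row repeating
#' the first is treated as an explicit closure and dropped. The file stem is
#' used as the cell id unless `id` is given.
#'
#' @param path Path to the CSV file.
#' @param unit Coordinate unit of the file, `"pixel"` (default) or `"micron"`.
#' @param id Cell id; defaults to the file name without extension.
#' @return A [as_contour()] object.
#' @export
read_contour <- function(path, unit = c("pixel", "micron"), id = NULL) {
  unit <- match.arg(unit)
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                         strip.white = TRUE)
  if (ncol(raw) < 2L) abort(sprintf("%s: need two columns", path))
  # optional header: first row non-numeric
  first <- suppressWarnings(as.numeric(unlist(raw[1L, 1:2])))
  if (anyNA(first)) raw <- raw[-1L, , drop = FALSE]
  xy <- data.frame(
    x = suppressWarnings(as.numeric(raw[[1L]])),
    y = suppressWarnings(as.numeric(raw[[2L]]))
  )
  bad <- which(is.na(xy$x) | is.na(xy$y))
  if (length(bad) > 0L) {
    abort(sprintf("%s: non-numeric coordinate at data row %d", path, bad[1L]),
          class = "cellph_parse_error")
  }
  if (nrow(xy) < 3L) {
    abort(sprintf("%s: fewer than 3 points", path),
          class = "cellph_malformed_input")
  }
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  as_contour(xy, unit = unit, id = id)
}

#' Write a contour to CSV
#'
#' @param contour A `cellph_contour`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_contour <- function(contour, path) {
  readr::write_csv(tibble(x = contour$x, y = contour$y), path)
  invisible(path)
}

#' Convert a pixel-space contour to microns
#'
#' Microscopy coordinates recorded in pixels are translated to physical
#' units by the spatial calibration of the imaging system: a length of n
#' pixels corresponds to d = n * s microns, where s is the scale factor in
#' microns per pixel.
#'
#' @param contour A `cellph_contour` in pixel units.
#' @param microns_per_pixel Positive scale factor s (microns per pixel).
#' @return The contour with every coordinate multiplied by
#'   `microns_per_pixel` and unit set to `"micron"`.
#' @export
to_microns <- function(contour, microns_per_pixel) {
  stopifnot(is.numeric(microns_per_pixel), length(microns_per_pixel) == 1L)
  if (microns_per_pixel <= 0) abort("microns_per_pixel must be > 0")
  if (contour_unit(contour) == "micron") {
    abort("contour is already in microns", class = "cellph_unit_error")
  }
  out <- contour
  out$x <- contour$x * microns_per_pixel
  out$y <- contour$y * microns_per_pixel
  attr(out, "unit") <- "micron"
  out
}

# Segment-pair intersection test for polygon simplicity. O(n^2) over the
# closed polyline; adjacent segments share an endpoint and are skipped.
is_simple_polygon <- function(x, y) {
  n <- length(x)
  x2 <- c(x[-1L], x[1L])
  y2 <- c(y[-1L], y[1L])
  for (i in seq_len(n - 2L)) {
    # segments strictly after i, excluding neighbours of i
    jmax <- if (i == 1L) n - 1L else n
    js <- seq.int(i + 2L, jmax)
    if (length(js) == 0L) next
    if (any(segments_intersect(x[i], y[i], x2[i], y2[i],
                               x[js], y[js], x2[js], y2[js]))) {
      return(FALSE)
    }
  }
  TRUE
}

# Vectorised proper/improper intersection between segment (ax,ay)-(bx,by)
# and segments (cx,cy)-(dx,dy). Touching at shared endpoints counts.
segments_intersect <- function(ax, ay, bx, by, cx, cy, dx, dy) {
  d1 <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  d2 <- (bx - ax) * (dy - ay) - (by - ay) * (dx - ax)
  d3 <- (dx - cx) * (ay - cy) - (dy - cy) * (ax - cx)
  d4 <- (dx - cx) * (by - cy) - (dy - cy) * (bx - cx)
  proper <- (sign(d1) * sign(d2) < 0) & (sign(d3) * sign(d4) < 0)
  on_seg <- function(px, py, qx, qy, rx, ry) {
    # r collinear with p-q and within its bounding box
    col <- (qx - px) * (ry - py) - (qy - py) * (rx - px) == 0
    col & rx >= pmin(px, qx) & rx <= pmax(px, qx) &
      ry >= pmin(py, qy) & ry <= pmax(py, qy)
  }
  touch <- (d1 == 0 & on_seg(ax, ay, bx, by, cx, cy)) |
    (d2 == 0 & on_seg(ax, ay, bx, by, dx, dy)) |
    (d3 == 0 & on_seg(cx, cy, dx, dy, ax, ay)) |
    (d4 == 0 & on_seg(cx, cy, dx, dy, bx, by))
  proper | touch
}

#' Build the cyclic graph representation of a contour
#'
#' The contour becomes a graph whose vertices are the contour points in
#' order, with edges between consecutive vertices and a closing edge from
#' the last vertex back to the first. Every vertex has degree 2, so the
#' graph is connected and contains exactly one cycle.
#'
#' @param contour A `cellph_contour`.
#' @return A `cellph_graph`: list with elements `vertices` (tibble `x`, `y`),
#'   `unit` and `id`.
#' @export
build_graph <- function(contour) {
  stopifnot(inherits(contour, "cellph_contour"))
  if (!is_simple_polygon(contour$x, contour$y)) {
    abort("contour is self-intersecting", class = "cellph_geometry_error")
  }
  structure(
    list(vertices = tibble(x = contour$x, y = contour$y),
         unit = contour_unit(contour), id = contour_id(contour)),
    class = "cellph_graph"
  )
}

#' Collapse axis-aligned vertex runs of a contour graph
#'
#' Pixelated contours traced from binary masks contain long runs of
#' consecutive vertices sharing the same x coordinate (vertical runs) or the
#' same y coordinate (horizontal runs). Each maximal such run of edges is
#' replaced by the single edge joining its two endpoint vertices and the
#' interior vertices are removed. Only axis-aligned runs are collapsed;
#' general collinearity is left untouched. The cleaned graph is still a
#' single cycle of degree-2 vertices in the original order.
#'
#' @param graph A `cellph_graph`.
#' @return The cleaned `cellph_graph`.
#' @export
clean_graph <- function(graph) {
  stopifnot(inherits(graph, "cellph_graph"))
  x <- graph$vertices$x
  y <- graph$vertices$y
  n <- length(x)
  keep <- rep(TRUE, n)
  idx <- function(i) ((i - 1L) %% n) + 1L  # cyclic indexing
  for (i in seq_len(n)) {
    ip <- idx(i - 1L)
    im <- idx(i + 1L)
    # interior of a run: both incident edges share the same x, or the same y
    if ((x[ip] == x[i] && x[i] == x[im]) ||
        (y[ip] == y[i] && y[i] == y[im])) {
      keep[i] <- FALSE
    }
  }
  if (sum(keep) < 3L) {
    abort("cleaning leaves fewer than 3 vertices (degenerate contour)",
          class = "cellph_degeneracy_error")
  }
  out <- graph
  out$vertices <- graph$vertices[keep, , drop = FALSE]
  out
}

#' Test whether a point lies strictly inside a contour
#'
#' Even-odd (ray casting) point-in-polygon test. Points on the boundary are
#' reported as not inside, so an accepted point is always usable as the base
#' of a radial distance function.
#'
#' @param contour A `cellph_contour` (or any data frame with `x`, `y`).
#' @param point Numeric vector `c(x, y)`.
#' @return `TRUE` if strictly interior, else `FALSE`.
#' @export
contains_point <- function(contour, point) {
  stopifnot(length(point) == 2L, is.numeric(point))
  point_in_polygon(contour$x, contour$y, point[1L], point[2L])
}

# scalar even-odd test with an explicit boundary check
point_in_polygon <- function(px, py, qx, qy) {
  n <- length(px)
  x2 <- c(px[-1L], px[1L])
  y2 <- c(py[-1L], py[1L])
  # boundary: on any closed segment -> outside by convention
  cross <- (x2 - px) * (qy - py) - (y2 - py) * (qx - px)
  on <- cross == 0 & qx >= pmin(px, x2) & qx <= pmax(px, x2) &
    qy >= pmin(py, y2) & qy <= pmax(py, y2)
  if (any(on)) return(FALSE)
  # even-odd rule with half-open vertical intervals
  crossings <- ((py > qy) != (y2 > qy)) &
    (qx < (x2 - px) * (qy - py) / (y2 - py) + px)
  sum(crossings) %% 2L == 1L
}

# vectorised even-odd test over many query points (used by rasterisation);
# boundary handling is irrelevant at pixel-centre resolution
points_in_polygon <- function(px, py, qx, qy) {
  n <- length(px)
  x2 <- c(px[-1L], px[1L])
  y2 <- c(py[-1L], py[1L])
  inside <- logical(length(qx))
  for (i in seq_len(n)) {
    active <- (py[i] > qy) != (y2[i] > qy)
    if (any(active)) {
      xin <- (x2[i] - px[i]) * (qy[active] - py[i]) / (y2[i] - py[i]) + px[i]
      flip <- qx[active] < xin
      inside[active] <- xor(inside[active], flip)
    }
  }
  inside
}

#' Read nucleus centres for a population
#'
#' Expects a CSV with columns `id`, `x`, `y`.
#'
#' @param path Path to the centres CSV.
#' @return A named list of numeric `c(x, y)` vectors, one per cell id.
#' @export
read_centers <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "x", "y")
  if (!all(need %in% names(tab))) {
    abort("centres file must have columns id, x, y")
  }
  setNames(lapply(seq_len(nrow(tab)), function(i) c(tab$x[i], tab$y[i])),
           as.character(tab$id))
}

#' @export
print.cellph_contour <- function(x, ...) {
  cat(sprintf("<cellph_contour> id=%s, %d points, unit=%s\n",
              contour_id(x), nrow(x), contour_unit(x)))
  NextMethod()
}

#' @export
print.cellph_graph <- function(x, ...) {
  cat(sprintf("<cellph_graph> id=%s, %d vertices (single cycle, degree 2)\n",
              x$id, nrow(x$vertices)))
  invisible(x)
}
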