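# Dimension-0 persistence of the radial sub-level filtration on a contour
# graph, with the essential connected component paired to the birth of the
# essential 1-cycle (which enters with the last edge, at the global vertex
# maximum).

#' Radial distance function on a contour graph
#'
#' Assigns to each vertex its Euclidean distance to the nucleus centre.
#' Edges take the maximum of their two endpoint values, so the sub-level set
#' at threshold a contains a vertex v iff f(v) <= a and an edge iff both of
#' its endpoints do.
#'
#' @param graph A `cellph_graph`.
#' @param center Numeric `c(x, y)`, strictly inside the contour, in the same
#'   unit as the graph.
#' @return A numeric vector of vertex values, aligned with `graph$vertices`.
#' @export
radial_function <- function(graph, center) {
  stopifnot(inherits(graph, "cellph_graph"), length(center) == 2L)
  v <- graph$vertices
  if (!point_in_polygon(v$x, v$y, center[1L], center[2L])) {
    abort("nucleus centre is not strictly inside the contour",
          class = "cellph_geometry_error")
  }
  sqrt((v$x - center[1L])^2 + (v$y - center[2L])^2)
}

#' Construct a persistence diagram object
#'
#' @param births,deaths Numeric vectors of equal length with
#'   `births <= deaths`.
#' @param id Cell label.
#' @return A `cellph_diagram`: a tibble with columns `birth` and `death`,
#'   sorted lexicographically, with attribute `id`.
#' @export
new_diagram <- function(births, deaths, id = "cell") {
  stopifnot(length(births) == length(deaths))
  if (any(deaths < births)) abort("diagram point with death < birth")
  ord <- order(births, deaths)
  out <- tibble(birth = as.numeric(births[ord]),
                death = as.numeric(deaths[ord]))
  attr(out, "id") <- as.character(id)
  class(out) <- c("cellph_diagram", class(out))
  out
}

#' @rdname new_diagram
#' @param x A `cellph_diagram`.
#' @export
diagram_id <- function(x) attr(x, "id")

#' Dimension-0 sub-level persistence diagram with essential pairing
#'
#' Computes the persistence of connected components of the sub-level sets
#' G_a = f^-1((-inf, a]) of a cyclic graph, where a vertex enters at its
#' function value and an edge at the maximum of its endpoint values. When
#' two components merge, the elder rule lets the component whose canonical
#' representative has the lower function value survive; the younger dies,
#' recording the point (birth, merge value). Zero-persistence pairs created
#' by non-generic ties are discarded. The essential component (born at
#' min f, never dying) is paired with the birth of the essential 1-cycle:
#' the cycle closes when the last vertex enters, at max f, giving the finite
#' point (min f, max f).
#'
#' Tie handling for non-generic functions: at each filtration value all
#' vertices enter before any edge, both in index order; when two merging
#' components have canonical representatives with equal value, the one
#' containing the lower vertex index survives.
#'
#' @param graph A `cellph_graph` with n vertices (cyclic adjacency
#'   v_i ~ v_(i+1), v_(n+1) = v_1).
#' @param values Numeric vertex function aligned with the graph vertices.
#' @return A [new_diagram()] with one point per surviving component; exactly
#'   one point has `birth == min(values)` and `death == max(values)`.
#' @export
sublevel_diagram0 <- function(graph, values) {
  stopifnot(inherits(graph, "cellph_graph"))
  n <- nrow(graph$vertices)
  if (length(values) != n) {
    abort("vertex function length does not match vertex count",
          class = "cellph_contract_error")
  }
  cyclic_sublevel_pd(values, id = graph$id)
}

# Core union-find computation on a cycle 1..n with vertex values f.
# Exposed internally so fixtures with prescribed values can bypass geometry.
cyclic_sublevel_pd <- function(f, id = "cell") {
  n <- length(f)
  stopifnot(n >= 1L)
  if (n == 1L) return(new_diagram(f, f, id = id))

  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  # birth value and canonical (lowest-value, then lowest-index) vertex of
  # each component root
  birth <- rep(NA_real_, n)
  canon <- seq_len(n)
  alive <- rep(FALSE, n)

  # edge i joins vertex i and vertex i %% n + 1; entry value = max endpoint
  enext <- c(seq_len(n)[-1L], 1L)
  evals <- pmax(f, f[enext])

  births <- numeric(0)
  deaths <- numeric(0)

  levels <- sort(unique(f))
  for (a in levels) {
    # vertices first, in index order
    for (v in which(f == a)) {
      alive[v] <- TRUE
      birth[v] <- a
      canon[v] <- v
    }
    # then edges whose entry value equals a, in index order
    for (e in which(evals == a)) {
      u <- e
      w <- enext[e]
      if (!alive[u] || !alive[w]) next  # cannot happen: max endpoint = a
      ru <- find(u)
      rw <- find(w)
      if (ru == rw) next  # closing the essential cycle: no 0-dim event
      cu <- canon[ru]
      cw <- canon[rw]
      # elder rule: survivor has lower canonical value, ties -> lower index
      if (f[cu] < f[cw] || (f[cu] == f[cw] && cu < cw)) {
        old <- ru; young <- rw
      } else {
        old <- rw; young <- ru
      }
      if (birth[young] < a) {  # drop zero-persistence pairs
        births <- c(births, birth[young])
        deaths <- c(deaths, a)
      }
      parent[young] <- old
    }
  }
  # essential pairing: component born at min f dies with the 1-cycle birth,
  # i.e. when the last vertex (global max) enters
  births <- c(births, min(f))
  deaths <- c(deaths, max(f))
  new_diagram(births, deaths, id = id)
}

#' Persistence diagram of a cell from its contour and nucleus centre
#'
#' Convenience composition: [build_graph()] then [clean_graph()] then
#' [radial_function()] then [sublevel_diagram0()].
#'
#' @param contour A `cellph_contour`.
#' @param center Numeric `c(x, y)` strictly inside the contour.
#' @param clean Collapse axis-aligned vertex runs first (default `TRUE`).
#' @return A `cellph_diagram`.
#' @export
diagram_for_cell <- function(contour, center, clean = TRUE) {
  g <- build_graph(contour)
  if (clean) g <- clean_graph(g)
  f <- radial_function(g, center)
  sublevel_diagram0(g, f)
}

#' Write a persistence diagram to JSON
#'
#' Serialises as `{"id": ..., "points": [[birth, death], ...]}` with points
#' in lexicographic order.
#'
#' @param diagram A `cellph_diagram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_diagram <- function(diagram, path) {
  obj <- list(id = diagram_id(diagram),
              points = unname(as.matrix(diagram[, c("birth", "death")])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a persistence diagram from JSON
#'
#' @param path Path to a JSON file written by [write_diagram()].
#' @return A `cellph_diagram`.
#' @export
read_diagram <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pts <- obj$points
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2L, byrow = TRUE)
  new_diagram(pts[, 1L], pts[, 2L], id = obj$id)
}

#' @export
print.cellph_diagram <- function(x, ...) {
  cat(sprintf("<cellph_diagram> id=%s, %d points\n", diagram_id(x), nrow(x)))
  NextMethod()
}
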