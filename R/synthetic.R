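# Synthetic cell populations: star-shaped lobed contours with controllable
# lobe count, size, elongation and boundary noise, plus pixelation to a
# binary grid with axis-aligned boundary tracing, emulating the
# area-outline contours exported from binarised fluorescence images.

#' The worked-example cyclic filtration
#'
#' A 14-vertex cyclic graph whose radial distance values to the origin are
#' (1, 4, 3, 5, 3, 5, 3, 5, 4, 5, 4, 5, 4, 5): one global minimum at value
#' 1, three local minima at 3, three at 4, and alternating maxima. Its
#' essential-paired dimension-0 diagram is
#' `{(1,5), (3,4), (3,5) x2, (4,5) x3}`. The geometry is realised as a star
#' polygon whose vertex radii equal these values at equally spaced angles,
#' with the nucleus centre at the origin.
#'
#' @return List with `contour` (a `cellph_contour`), `center` (`c(0, 0)`),
#'   `values` (the 14 radial values), and `graph` (the `cellph_graph`).
#' @export
worked_example_graph <- function() {
  vals <- c(1, 4, 3, 5, 3, 5, 3, 5, 4, 5, 4, 5, 4, 5)
  n <- length(vals)
  theta <- 2 * pi * (seq_len(n) - 1L) / n
  ct <- as_contour(data.frame(x = vals * cos(theta), y = vals * sin(theta)),
                   unit = "micron", id = "worked-example")
  list(contour = ct, center = c(0, 0), values = vals,
       graph = build_graph(ct))
}

#' Generate a lobed star-shaped contour with an interior centre
#'
#' The radius function is `r(theta) = mid + amp * cos(lobes * theta)` with
#' `mid = (r_in + r_out)/2` and `amp = (r_out - r_in)/2`, sampled at
#' `n_points` equally spaced angles; the shape is then stretched by
#' `elongation` along x, and independent Gaussian noise (sd `noise_sd`,
#' applied radially so the contour stays star-shaped and hence simple) is
#' added to the radius. `noise_sd` must stay below `r_in / 4` so the
#' contour cannot fold through the origin. The nucleus centre is the
#' origin.
#'
#' @param lobes Number of lobes (>= 0; 0 gives an ellipse/circle).
#' @param r_in,r_out Inner and outer radius, `r_out > r_in > 0`.
#' @param n_points Number of contour points (default 128).
#' @param elongation Stretch factor along x (default 1).
#' @param noise_sd Radial Gaussian noise sd (default 0).
#' @param seed Optional integer seed for the noise.
#' @param id Cell id.
#' @param unit Unit tag for the coordinates (default `"micron"`).
#' @return List with `contour` (a `cellph_contour`) and `center`
#'   (`c(0, 0)`).
#' @export
lobed_contour <- function(lobes, r_in, r_out, n_points = 128L,
                          elongation = 1, noise_sd = 0, seed = NULL,
                          id = "cell", unit = "micron") {
  if (lobes < 0 || r_in <= 0 || r_out <= r_in || elongation <= 0 ||
      noise_sd < 0) {
    abort("invalid lobed-contour parameters",
          class = "cellph_parameter_error")
  }
  if (noise_sd >= r_in / 4) {
    abort("noise_sd must be below r_in / 4 to guarantee simplicity",
          class = "cellph_parameter_error")
  }
  if (!is.null(seed)) set.seed(seed)
  theta <- 2 * pi * (seq_len(n_points) - 1L) / n_points
  mid <- (r_in + r_out) / 2
  amp <- (r_out - r_in) / 2
  r <- mid + amp * cos(lobes * theta)
  if (noise_sd > 0) r <- r + rnorm(n_points, sd = noise_sd)
  r <- pmax(r, r_in / 2)  # belt and braces: keep radius positive
  ct <- as_contour(data.frame(x = elongation * r * cos(theta),
                              y = r * sin(theta)),
                   unit = unit, id = id, check = FALSE)
  list(contour = ct, center = c(0, 0))
}

#' Pixelate a contour onto a binary grid and trace its area outline
#'
#' Rasterises the polygon onto a square grid of the given pixel size
#' (even-odd rule on pixel centres), then walks the boundary of the filled
#' region along pixel edges, keeping the region to the left, starting at
#' the topmost-then-leftmost boundary corner. The result is a closed
#' contour through pixel corners consisting solely of axis-aligned unit
#' steps, which is what [clean_graph()] is designed to collapse.
#'
#' @param contour A `cellph_contour`.
#' @param pixel_size Edge length of a pixel in contour units.
#' @return A `cellph_contour` through pixel corners (same unit).
#' @export
pixelate_contour <- function(contour, pixel_size) {
  stopifnot(pixel_size > 0)
  x0 <- min(contour$x) - 2 * pixel_size
  y0 <- min(contour$y) - 2 * pixel_size
  nx <- ceiling((max(contour$x) - x0) / pixel_size) + 2L
  ny <- ceiling((max(contour$y) - y0) / pixel_size) + 2L
  cx <- x0 + (seq_len(nx) - 0.5) * pixel_size
  cy <- y0 + (seq_len(ny) - 0.5) * pixel_size
  grid <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  inside <- points_in_polygon(contour$x, contour$y,
                              cx[grid$ix], cy[grid$iy])
  if (!any(inside)) {
    abort("contour thinner than one pixel", class = "cellph_degeneracy_error")
  }
  mask <- matrix(FALSE, nx, ny)
  mask[cbind(grid$ix, grid$iy)] <- inside

  # directed boundary edges between pixel corners, region kept on the left;
  # corner (i, j) sits at x0 + (i-1)*pixel_size, y0 + (j-1)*pixel_size
  filled <- which(mask, arr.ind = TRUE)
  edges <- list()
  at <- function(i, j) i >= 1L && i <= nx && j >= 1L && j <= ny && mask[i, j]
  k <- 0L
  for (r in seq_len(nrow(filled))) {
    i <- filled[r, 1L]; j <- filled[r, 2L]
    if (!at(i, j - 1L)) { k <- k + 1L; edges[[k]] <- c(i, j, i + 1L, j) }
    if (!at(i + 1L, j)) { k <- k + 1L; edges[[k]] <- c(i + 1L, j, i + 1L, j + 1L) }
    if (!at(i, j + 1L)) { k <- k + 1L; edges[[k]] <- c(i + 1L, j + 1L, i, j + 1L) }
    if (!at(i - 1L, j)) { k <- k + 1L; edges[[k]] <- c(i, j + 1L, i, j) }
  }
  em <- do.call(rbind, edges)
  key <- function(i, j) (j - 1L) * (nx + 2L) + i
  from_key <- key(em[, 1L], em[, 2L])
  # successor lookup: at most two outgoing edges per corner (degree-4
  # corners from diagonally touching pixels); walk loops greedily
  used <- rep(FALSE, nrow(em))
  by_from <- split(seq_len(nrow(em)), from_key)
  loops <- list()
  while (any(!used)) {
    start <- which(!used)[1L]
    path <- integer(0)
    e <- start
    repeat {
      used[e] <- TRUE
      path <- c(path, e)
      nxt_key <- key(em[e, 3L], em[e, 4L])
      cand <- by_from[[as.character(nxt_key)]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0L) break
      e <- cand[1L]
    }
    loops[[length(loops) + 1L]] <- path
  }
  # outer boundary: the loop enclosing the largest area
  loop_area <- vapply(loops, function(p) {
    xs <- x0 + (em[p, 1L] - 1L) * pixel_size
    ys <- y0 + (em[p, 2L] - 1L) * pixel_size
    abs(signed_area(xs, ys))
  }, numeric(1))
  p <- loops[[which.max(loop_area)]]
  xs <- x0 + (em[p, 1L] - 1L) * pixel_size
  ys <- y0 + (em[p, 2L] - 1L) * pixel_size
  # deterministic start: topmost, then leftmost corner
  startidx <- which(ys == max(ys))
  startidx <- startidx[which.min(xs[startidx])]
  ordidx <- c(startidx:length(p), seq_len(startidx - 1L))
  as_contour(data.frame(x = xs[ordidx], y = ys[ordidx]),
             unit = contour_unit(contour), id = contour_id(contour),
             check = FALSE)
}

#' Specify a synthetic cell population
#'
#' Ranges are sampled uniformly per cell. Defaults describe a mildly noisy
#' population of medium-size lobed cells.
#'
#' @param n_cells Number of cells.
#' @param lobes Integer range `c(min, max)` of lobe counts.
#' @param r_in,r_out Ranges for the inner and outer radius (microns).
#' @param elongation Range of x-stretch factors.
#' @param boundary_noise_sd Radial noise sd (microns).
#' @param n_points Contour resolution per cell.
#' @param pixelate Rasterise each contour (default `FALSE`).
#' @param pixel_size Pixel edge for rasterisation (microns).
#' @param prefix Id prefix for the cells.
#' @return A `cellph_popspec` list.
#' @export
population_spec <- function(n_cells = 20L, lobes = c(3L, 5L),
                            r_in = c(8, 12), r_out = c(20, 30),
                            elongation = c(1, 1.4),
                            boundary_noise_sd = 0.5, n_points = 128L,
                            pixelate = FALSE, pixel_size = 0.5,
                            prefix = "cell") {
  stopifnot(n_cells >= 1L, min(r_in) > 0, min(r_out) > max(r_in))
  structure(
    list(n_cells = as.integer(n_cells), lobes = lobes, r_in = r_in,
         r_out = r_out, elongation = elongation,
         boundary_noise_sd = boundary_noise_sd,
         n_points = as.integer(n_points), pixelate = pixelate,
         pixel_size = pixel_size, prefix = prefix),
    class = "cellph_popspec"
  )
}

#' Generate a population of synthetic cells from a specification
#'
#' @param spec A [population_spec()].
#' @param seed Integer seed; the population is bit-reproducible given the
#'   same spec and seed.
#' @return List with `contours` (named list), `centers` (named list of
#'   `c(x, y)`).
#' @export
generate_population <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cellph_popspec"))
  set.seed(as.integer(seed))
  contours <- list()
  centers <- list()
  for (i in seq_len(spec$n_cells)) {
    id <- sprintf("%s-%03d", spec$prefix, i)
    lob <- if (length(spec$lobes) > 1L) {
      sample(seq.int(spec$lobes[1L], spec$lobes[2L]), 1L)
    } else spec$lobes
    rin <- runif(1L, min(spec$r_in), max(spec$r_in))
    rout <- runif(1L, min(spec$r_out), max(spec$r_out))
    elo <- runif(1L, min(spec$elongation), max(spec$elongation))
    cell <- lobed_contour(lob, rin, rout, n_points = spec$n_points,
                          elongation = elo,
                          noise_sd = min(spec$boundary_noise_sd,
                                         rin / 4 * 0.99),
                          id = id)
    ct <- cell$contour
    if (isTRUE(spec$pixelate)) ct <- pixelate_contour(ct, spec$pixel_size)
    contours[[id]] <- ct
    centers[[id]] <- cell$center
  }
  list(contours = contours, centers = centers)
}

#' Generate two labelled populations for clustering and ROC tests
#'
#' @param specA,specB [population_spec()] objects with distinct prefixes.
#' @param seed Integer seed (specB uses `seed + 1`).
#' @return List with `contours`, `centers` (named lists over both
#'   populations) and `labels` (named character vector of group names
#'   `"A"`/`"B"`).
#' @export
two_population <- function(specA, specB, seed = 1L) {
  if (specA$prefix == specB$prefix) {
    abort("population prefixes must differ so ids are disjoint")
  }
  a <- generate_population(specA, seed = seed)
  b <- generate_population(specB, seed = as.integer(seed) + 1L)
  contours <- c(a$contours, b$contours)
  centers <- c(a$centers, b$centers)
  labels <- setNames(c(rep("A", specA$n_cells), rep("B", specB$n_cells)),
                     names(contours))
  list(contours = contours, centers = centers, labels = labels)
}

#' Write a synthetic population to disk
#'
#' One `<id>.csv` contour per cell, a `centers.csv` (`id`, `x`, `y`) and,
#' when labels are given, a `labels.csv` (`id`, `group`).
#'
#' @param pop Output of [generate_population()] or [two_population()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_population <- function(pop, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(pop$contours)) {
    write_contour(pop$contours[[id]], file.path(dir, paste0(id, ".csv")))
  }
  ctr <- dplyr::bind_rows(lapply(names(pop$centers), function(id) {
    tibble(id = id, x = pop$centers[[id]][1L], y = pop$centers[[id]][2L])
  }))
  readr::write_csv(ctr, file.path(dir, "centers.csv"))
  if (!is.null(pop$labels)) {
    readr::write_csv(tibble(id = names(pop$labels),
                            group = unname(pop$labels)),
                     file.path(dir, "labels.csv"))
  }
  invisible(dir)
}
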