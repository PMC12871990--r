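# Shared geometric fixtures for the test suite.

regular_polygon <- function(n, r = 1, center = c(0, 0), id = "poly",
                            unit = "micron", phase = 0) {
  theta <- phase + 2 * pi * (seq_len(n) - 1L) / n
  as_contour(data.frame(x = center[1L] + r * cos(theta),
                        y = center[2L] + r * sin(theta)),
             unit = unit, id = id)
}

# apply a rigid motion (rotation by phi then translation) to a contour
rigid_motion <- function(contour, phi = 0, shift = c(0, 0)) {
  x <- cos(phi) * contour$x - sin(phi) * contour$y + shift[1L]
  y <- sin(phi) * contour$x + cos(phi) * contour$y + shift[2L]
  as_contour(data.frame(x = x, y = y), unit = contour_unit(contour),
             id = contour_id(contour), check = FALSE)
}

rigid_motion_point <- function(p, phi = 0, shift = c(0, 0)) {
  c(cos(phi) * p[1L] - sin(phi) * p[2L] + shift[1L],
    sin(phi) * p[1L] + cos(phi) * p[2L] + shift[2L])
}

# star polygon with prescribed vertex radii at equally spaced angles
star_from_radii <- function(radii, id = "star") {
  n <- length(radii)
  theta <- 2 * pi * (seq_len(n) - 1L) / n
  as_contour(data.frame(x = radii * cos(theta), y = radii * sin(theta)),
             unit = "micron", id = id)
}

random_diagram <- function(n_max = 5L, scale = 10) {
  n <- sample(0:n_max, 1L)
  b <- runif(n, 0, scale)
  d <- b + runif(n, 0, scale)
  new_diagram(b, d)
}

random_distance_matrix <- function(n, labels = NULL) {
  v <- matrix(runif(n * n), n, n)
  m <- (v + t(v)) / 2
  diag(m) <- 0
  if (is.null(labels)) labels <- sprintf("o%02d", seq_len(n))
  dimnames(m) <- list(labels, labels)
  m
}
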