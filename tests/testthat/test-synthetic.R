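# Synthetic populations: lobed contours, pixelation, and reproducibility.

test_that("the worked-example geometry realises its prescribed radii", {
  we <- worked_example_graph()
  expect_equal(sqrt(we$contour$x^2 + we$contour$y^2), we$values)
  expect_equal(nrow(we$graph$vertices), 14L)
})

test_that("lobe count controls the number of radial minima", {
  for (k in 1:5) {
    cell <- lobed_contour(k, 2, 6, n_points = max(64L, 32L * k))
    d <- diagram_for_cell(cell$contour, cell$center)
    expect_equal(nrow(d), k)
  }
  # lobes 0 is a circle: every point collapses onto (r_out, r_out)
  # (floating-point noise may split the constant value into
  # near-zero-persistence points)
  circle <- lobed_contour(0, 2, 6, n_points = 64L)
  dc <- diagram_for_cell(circle$contour, circle$center)
  expect_lt(max(abs(dc$birth - 6), abs(dc$death - 6)), 1e-9)
})

test_that("elongation stretches the aspect ratio quadratically", {
  circle <- lobed_contour(0, 4, 12, n_points = 200L)$contour   # r = 8
  expect_equal(aspect_ratio(circle), 1, tolerance = 1e-3)
  stretched <- lobed_contour(0, 4, 12, n_points = 200L,
                             elongation = 2)$contour
  expect_equal(aspect_ratio(stretched), 4, tolerance = 0.02)
})

test_that("parameter validation rejects impossible shapes", {
  expect_error(lobed_contour(-1, 1, 2), class = "cellph_parameter_error")
  expect_error(lobed_contour(3, 2, 1), class = "cellph_parameter_error")
  expect_error(lobed_contour(3, 2, 5, noise_sd = 1),
               class = "cellph_parameter_error")  # noise >= r_in / 4
})

test_that("generated contours are simple with an interior nucleus", {
  set.seed(121)
  for (trial in 1:200) {
    spec <- population_spec(
      n_cells = 1L,
      lobes = sort(sample(0:6, 2, replace = TRUE)),
      r_in = sort(runif(2, 3, 10)),
      r_out = 10 + sort(runif(2, 1, 15)),
      elongation = sort(runif(2, 1, 2)),
      boundary_noise_sd = runif(1, 0, 0.7),
      n_points = 64L)
    pop <- generate_population(spec, seed = trial)
    ct <- pop$contours[[1L]]
    expect_true(cellph:::is_simple_polygon(ct$x, ct$y))
    expect_true(contains_point(ct, pop$centers[[1L]]))
  }
})

test_that("a pixelated rectangle cleans back to its four corners", {
  rect <- as_contour(data.frame(x = c(0.01, 5.01, 5.01, 0.01),
                                y = c(0.01, 0.01, 3.01, 3.01)))
  px <- pixelate_contour(rect, 1)
  # raw trace: only axis-aligned unit steps
  dx <- diff(c(px$x, px$x[1]))
  dy <- diff(c(px$y, px$y[1]))
  expect_true(all(abs(abs(dx) + abs(dy) - 1) < 1e-9))  # unit L1 steps
  expect_true(all(pmin(abs(dx), abs(dy)) < 1e-9))      # one axis at a time
  cg <- clean_graph(build_graph(px))
  expect_equal(nrow(cg$vertices), 4L)
})

test_that("pixelation resolution governs the diagram perturbation", {
  cell <- lobed_contour(3, 4, 10, n_points = 128L)
  d0 <- diagram_for_cell(cell$contour, cell$center, clean = FALSE)
  w_at <- function(psize) {
    px <- pixelate_contour(cell$contour, psize)
    dpx <- diagram_for_cell(px, cell$center)   # cleaned
    wasserstein(d0, dpx)
  }
  w_coarse <- w_at(0.5)
  w_fine <- w_at(0.25)
  # every matched point moves by at most twice the pixel size
  expect_lt(sqrt(max(w_coarse$plan$cost)), 2 * 0.5)
  expect_lt(sqrt(max(w_fine$plan$cost)), 2 * 0.25)
  # and the aggregate distance shrinks with the pixels
  expect_lt(w_fine$distance, w_coarse$distance)
})

test_that("populations are bit-reproducible given spec and seed", {
  spec <- population_spec(n_cells = 5L, n_points = 48L)
  p1 <- generate_population(spec, seed = 77)
  p2 <- generate_population(spec, seed = 77)
  expect_identical(lapply(p1$contours, as.data.frame),
                   lapply(p2$contours, as.data.frame))
  p3 <- generate_population(spec, seed = 78)
  expect_false(identical(as.data.frame(p1$contours[[1]]),
                         as.data.frame(p3$contours[[1]])))
})

test_that("two-population output is labelled and disjointly named", {
  specA <- population_spec(n_cells = 3L, prefix = "A", n_points = 48L)
  specB <- population_spec(n_cells = 4L, prefix = "B", n_points = 48L)
  pop <- two_population(specA, specB, seed = 2)
  expect_equal(length(pop$contours), 7L)
  expect_equal(unname(table(pop$labels)[c("A", "B")]), c(3L, 4L),
               ignore_attr = TRUE)
  expect_equal(names(pop$labels), names(pop$contours))
  expect_error(two_population(specA, specA), regexp = "prefix")
})

test_that("well-separated populations are recovered by the PH distance", {
  specA <- population_spec(n_cells = 8L, lobes = c(4L, 6L), r_in = c(8, 12),
                           r_out = c(24, 32), n_points = 64L, prefix = "A")
  specB <- population_spec(n_cells = 8L, lobes = c(0L, 2L), r_in = c(5, 7),
                           r_out = c(9, 12), n_points = 64L, prefix = "B")
  pop <- two_population(specA, specB, seed = 3)
  m <- shape_distance_matrix(pop$contours, metric = "ph",
                             centers = pop$centers)
  expect_gte(roc_analysis(m, pop$labels)$auc, 0.95)
})

test_that("identical specifications are indistinguishable", {
  spec <- function(prefix) {
    population_spec(n_cells = 8L, lobes = c(3L, 4L), r_in = c(7, 9),
                    r_out = c(18, 22), n_points = 64L, prefix = prefix)
  }
  pop <- two_population(spec("A"), spec("B"), seed = 4)
  m <- shape_distance_matrix(pop$contours, metric = "ph",
                             centers = pop$centers)
  auc <- roc_analysis(m, pop$labels)$auc
  expect_lt(abs(auc - 0.5), 0.2)
})

test_that("written populations are readable by the I/O layer", {
  dir <- file.path(tempdir(), "popio")
  pop <- two_population(
    population_spec(n_cells = 2L, prefix = "A", n_points = 32L),
    population_spec(n_cells = 2L, prefix = "B", n_points = 32L),
    seed = 6)
  write_population(pop, dir)
  ct <- read_contour(file.path(dir, "A-001.csv"))
  expect_equal(nrow(ct), nrow(pop$contours[["A-001"]]))
  ctrs <- read_centers(file.path(dir, "centers.csv"))
  expect_equal(ctrs[["B-002"]], pop$centers[["B-002"]])
})
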