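# Baseline shape distances: aspect ratio, Fourier descriptors, elastic
# (square-root velocity) distance, and the common distance-matrix driver.

smooth_star <- function(n = 128L, lobes = 3, mid = 2, amp = 0.5,
                        warp = NULL, id = "star") {
  t <- (seq_len(n) - 1L) / n
  if (!is.null(warp)) t <- warp(t)
  theta <- 2 * pi * t
  r <- mid + amp * cos(lobes * theta)
  as_contour(data.frame(x = r * cos(theta), y = r * sin(theta)),
             unit = "micron", id = id, check = FALSE)
}

test_that("a regular polygon is isotropic and an ellipse has ratio a^2/b^2", {
  expect_equal(aspect_ratio(regular_polygon(64, r = 10)), 1,
               tolerance = 1e-6)
  t <- 2 * pi * (0:199) / 200
  ell <- as_contour(data.frame(x = 2 * cos(t), y = sin(t)))
  expect_equal(aspect_ratio(ell), 4, tolerance = 1e-3)
  expect_equal(aspect_ratio(ell, sqrt = TRUE), 2, tolerance = 1e-3)
})

test_that("aspect ratio is invariant to rigid motion and at least 1", {
  set.seed(91)
  for (trial in 1:10) {
    ct <- lobed_contour(sample(0:4, 1), 2, 5, n_points = 64L,
                        elongation = runif(1, 1, 2))$contour
    a0 <- aspect_ratio(ct)
    expect_gte(a0, 1)
    a1 <- aspect_ratio(rigid_motion(ct, runif(1, 0, 2 * pi),
                                    runif(2, -9, 9)))
    expect_equal(a1, a0, tolerance = 1e-9)
  }
})

test_that("collinear points give a degeneracy error, not a huge ratio", {
  flat <- as_contour(data.frame(x = c(0, 1, 2), y = c(0, 0, 0)),
                     check = FALSE)
  expect_error(aspect_ratio(flat), class = "cellph_geometry_error")
})

test_that("aspect distance is a log-ratio: zero iff equal, scale-free", {
  expect_equal(aspect_distance(3, 3), 0)
  expect_equal(aspect_distance(2, 4), aspect_distance(4, 8))
  expect_equal(aspect_distance(1, exp(1)), 1)
  expect_equal(aspect_distance(2, 5), aspect_distance(5, 2))
})

test_that("Fourier descriptors of a circle put all energy in E_1", {
  f <- fourier_descriptor(regular_polygon(256, r = 10), M = 5)
  expect_equal(as.numeric(f[1]), 10, tolerance = 1e-2)
  expect_lt(max(as.numeric(f[-1])), 1e-6)
})

test_that("centring makes the zeroth Fourier coefficient vanish", {
  ct <- smooth_star(id = "s")
  rc <- cellph:::ensure_ccw(cellph:::resample_contour(ct, 256L))
  z <- complex(real = rc$x, imaginary = rc$y)
  z <- z - mean(z)
  F0 <- stats::fft(z)[1L] / length(z)
  expect_lt(Mod(F0), 1e-12)
})

test_that("Fourier descriptors are invariant to rotation, translation and
           starting point", {
  ct <- smooth_star(lobes = 4, id = "s")
  f0 <- fourier_descriptor(ct)
  rot <- fourier_descriptor(rigid_motion(ct, 0.9, c(13, -4)))
  expect_equal(as.numeric(rot), as.numeric(f0), tolerance = 1e-8)
  shifted <- as_contour(rbind(ct[33:nrow(ct), ], ct[1:32, ]),
                        unit = "micron", id = "s", check = FALSE)
  fs <- fourier_descriptor(shifted)
  expect_equal(as.numeric(fs), as.numeric(f0), tolerance = 1e-6)
})

test_that("Fourier descriptors keep physical scale", {
  small <- fourier_descriptor(regular_polygon(128, r = 10))
  big <- fourier_descriptor(regular_polygon(128, r = 20))
  expect_equal(fourier_distance(small, big), 10, tolerance = 1e-2)
})

test_that("descriptors of unequal harmonic count cannot be compared", {
  f1 <- fourier_descriptor(smooth_star(), M = 5)
  f2 <- fourier_descriptor(smooth_star(), M = 8)
  expect_error(fourier_distance(f1, f2), class = "cellph_parameter_error")
})

test_that("the elastic distance vanishes on the same shape", {
  ct <- smooth_star(lobes = 3)
  expect_lt(elastic_distance(ct, ct), 1e-8)
})

test_that("the elastic distance is invariant to rigid motion and
           reparameterisation", {
  ct <- smooth_star(lobes = 3)
  moved <- rigid_motion(ct, 1.1, c(7, 3))
  expect_lt(elastic_distance(ct, moved), 1e-5)
  # same curve sampled non-uniformly (a genuine reparameterisation)
  warped <- smooth_star(lobes = 3,
                        warp = function(t) t + 0.12 * sin(2 * pi * t) /
                          (2 * pi))
  expect_lt(elastic_distance(ct, warped), 5e-2)
})

test_that("the elastic distance is symmetric and separates unlike shapes", {
  a <- smooth_star(lobes = 3)
  b <- smooth_star(lobes = 5, amp = 0.8)
  dab <- elastic_distance(a, b)
  expect_equal(dab, elastic_distance(b, a), tolerance = 1e-12)
  expect_gt(dab, 10 * elastic_distance(a, a) + 0.05)
})

test_that("all four metrics build valid matrices and are rigid-invariant", {
  set.seed(92)
  cells <- lapply(1:4, function(i) {
    lobed_contour(i, 2 + i / 2, 6 + i, n_points = 48L,
                  id = sprintf("c%d", i))
  })
  contours <- lapply(cells, `[[`, "contour")
  names(contours) <- vapply(contours, contour_id, character(1))
  centers <- lapply(cells, `[[`, "center")
  names(centers) <- names(contours)
  phi <- 0.7; shift <- c(11, -6)
  moved <- lapply(contours, rigid_motion, phi = phi, shift = shift)
  moved_centers <- lapply(centers, rigid_motion_point, phi = phi,
                          shift = shift)
  for (metric in c("ph", "aspect", "fourier", "elastic")) {
    m0 <- shape_distance_matrix(contours, metric = metric,
                                centers = centers, n_grid = 32L)
    m1 <- shape_distance_matrix(moved, metric = metric,
                                centers = moved_centers, n_grid = 32L)
    expect_equal(m0, t(m0), tolerance = 1e-9)
    expect_true(all(diag(m0) == 0))
    tol <- if (metric == "elastic") 2e-2 else 1e-6
    expect_equal(m1, m0, tolerance = tol)
  }
})

test_that("the PH metric demands nucleus centres", {
  contours <- list(a = regular_polygon(12, id = "a"),
                   b = regular_polygon(16, r = 2, id = "b"))
  expect_error(shape_distance_matrix(contours, metric = "ph"))
})
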