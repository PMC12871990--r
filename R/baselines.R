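# Three baseline contour distances used alongside the persistence-based
# distance: log aspect ratio, elliptic Fourier descriptor magnitudes, and a
# simplified square-root-velocity elastic distance.

signed_area <- function(x, y) {
  x2 <- c(x[-1L], x[1L])
  y2 <- c(y[-1L], y[1L])
  sum(x * y2 - x2 * y) / 2
}

# normalise traversal to counterclockwise (positive signed area)
ensure_ccw <- function(contour) {
  if (signed_area(contour$x, contour$y) >= 0) return(contour)
  as_contour(data.frame(x = rev(contour$x), y = rev(contour$y)),
             unit = contour_unit(contour), id = contour_id(contour),
             check = FALSE)
}

#' Resample a closed contour to n points equally spaced in arc length
#'
#' @param contour A `cellph_contour`.
#' @param n Number of output points (the closing point is implicit).
#' @return A `cellph_contour` with `n` points.
#' @export
resample_contour <- function(contour, n = 256L) {
  x <- c(contour$x, contour$x[1L])
  y <- c(contour$y, contour$y[1L])
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  if (any(seg == 0)) {
    abort("zero-length segment in contour", class = "cellph_geometry_error")
  }
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  target <- (seq_len(n) - 1L) * L / n
  xi <- stats::approx(s, x, xout = target)$y
  yi <- stats::approx(s, y, xout = target)$y
  as_contour(data.frame(x = xi, y = yi), unit = contour_unit(contour),
             id = contour_id(contour), check = FALSE)
}

#' Rotation- and translation-invariant aspect ratio of a contour
#'
#' Centres the contour points at their mean and eigen-decomposes the 2x2
#' covariance matrix; with eigenvalues lambda1 >= lambda2 (the variances
#' along the principal axes), the aspect ratio is lambda1/lambda2 >= 1.
#' A value of 1 corresponds to an isotropic shape; larger values indicate
#' increasing elongation. With `sqrt = TRUE` the square root of the variance
#' ratio (the ratio of principal standard deviations) is returned instead;
#' the two conventions differ by a factor 2 in log space, so rank-based
#' analyses are unaffected.
#'
#' @param contour A `cellph_contour`.
#' @param sqrt Use the standard-deviation ratio instead of the variance
#'   ratio. Default `FALSE`.
#' @return Aspect ratio, a scalar >= 1.
#' @export
aspect_ratio <- function(contour, sqrt = FALSE) {
  xc <- contour$x - mean(contour$x)
  yc <- contour$y - mean(contour$y)
  cv <- stats::cov(cbind(xc, yc))
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (ev[2L] <= .Machine$double.eps * max(1, ev[1L])) {
    abort("degenerate contour: all points collinear",
          class = "cellph_geometry_error")
  }
  a <- ev[1L] / ev[2L]
  if (sqrt) a <- base::sqrt(a)
  a
}

#' Log-ratio distance between two aspect ratios
#'
#' `|log A1 - log A2|`: the aspect ratio is multiplicative (a change from
#' 2 to 4 is the same deformation as 4 to 8), so differences are taken in
#' log space. Zero iff the two contours have identical elongation.
#'
#' @param a1,a2 Aspect ratios (>= 1).
#' @return Non-negative scalar.
#' @export
aspect_distance <- function(a1, a2) {
  abs(log(a1) - log(a2))
}

#' Fourier descriptor magnitudes of a closed contour
#'
#' The contour is resampled to `n_resample` points equally spaced in arc
#' length and traversed counterclockwise, encoded as the complex sequence
#' z_n = x_n + i y_n, centred so that the zeroth DFT coefficient vanishes
#' (translation invariance), phase-normalised by the argument of the first
#' coefficient (starting-point invariance), and summarised by the
#' magnitudes E_k = |F_k|, k = 1..M (rotation invariance). No scale
#' normalisation is applied: physical size is informative for cells.
#'
#' @param contour A `cellph_contour`.
#' @param M Number of harmonics retained (default 10).
#' @param n_resample Resampling resolution (default 256; must exceed 2*M).
#' @return A `cellph_fourier`: numeric vector `E_1..E_M` with attribute
#'   `id`.
#' @export
fourier_descriptor <- function(contour, M = 10L, n_resample = 256L) {
  stopifnot(M >= 1L)
  if (n_resample <= 2L * M) abort("n_resample must exceed 2*M")
  rc <- ensure_ccw(resample_contour(contour, n_resample))
  z <- complex(real = rc$x, imaginary = rc$y)
  z <- z - mean(z)                      # F_0 = 0 after centring
  Fk <- stats::fft(z) / length(z)       # F_k = (1/N) sum z_n e^{-2pi i kn/N}
  F1 <- Fk[2L]
  if (Mod(F1) == 0) {
    abort("first Fourier coefficient vanishes; phase undefined",
          class = "cellph_degeneracy_error")
  }
  theta1 <- Arg(F1)
  k <- seq_len(M)
  Ft <- Fk[k + 1L] * exp(-1i * k * theta1)  # F~_1 real positive
  out <- Mod(Ft)
  attr(out, "id") <- contour_id(contour)
  class(out) <- "cellph_fourier"
  out
}

#' Euclidean distance between Fourier descriptor vectors
#'
#' The square root of the summed squared differences of the magnitude
#' descriptors, so the measure is a metric on descriptor vectors.
#'
#' @param f1,f2 Descriptors from [fourier_descriptor()] with equal `M`.
#' @return Non-negative scalar.
#' @export
fourier_distance <- function(f1, f2) {
  if (length(f1) != length(f2)) {
    abort("descriptors have different numbers of harmonics",
          class = "cellph_parameter_error")
  }
  sqrt(sum((as.numeric(f1) - as.numeric(f2))^2))
}

# square-root velocity samples of a centred closed contour resampled to n
# points: q_i = c'(t_i) / sqrt(||c'(t_i)||), derivative by forward
# differences over the closed polyline.
srv_samples <- function(contour, n) {
  rc <- ensure_ccw(resample_contour(contour, n))
  x <- rc$x - mean(rc$x)
  y <- rc$y - mean(rc$y)
  dx <- (c(x[-1L], x[1L]) - x) * n      # d/dt with dt = 1/n
  dy <- (c(y[-1L], y[1L]) - y) * n
  nrm <- sqrt(dx^2 + dy^2)
  if (any(nrm == 0)) {
    abort("zero-length segment after resampling",
          class = "cellph_geometry_error")
  }
  cbind(dx, dy) / sqrt(nrm)
}

# optimal rotation (2x2, det +1) minimising ||q1 - q2 R||_F, applied to q2
procrustes_rotate <- function(q1, q2) {
  A <- crossprod(q2, q1)
  sv <- svd(A)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, d)) %*% t(sv$v)
  q2 %*% R
}

l2_cost <- function(q1, q2) {
  sum((q1 - q2)^2) / nrow(q1)
}

# apply a grid warping gamma (values in [0,1]) to SRV samples q (n x 2)
warp_srv <- function(q, gamma) {
  n <- nrow(q)
  grid <- seq(0, 1, length.out = n)
  gx <- stats::approx(grid, q[, 1L], xout = pmin(pmax(gamma, 0), 1))$y
  gy <- stats::approx(grid, q[, 2L], xout = pmin(pmax(gamma, 0), 1))$y
  dg <- c(diff(gamma), gamma[n] - gamma[n - 1L]) / (grid[2L] - grid[1L])
  dg[dg < 0] <- 0
  cbind(gx, gy) * sqrt(dg)
}

# one-directional elastic alignment cost between SRV sample sets
elastic_align_cost <- function(q1, q2, max_iter = 20L, tol = 1e-6) {
  q2r <- procrustes_rotate(q1, q2)
  best <- l2_cost(q1, q2r)
  for (it in seq_len(max_iter)) {
    dp <- srvf_dp_align(q1, q2r)
    q2w <- warp_srv(q2r, dp$gamma)
    q2w <- procrustes_rotate(q1, q2w)
    cur <- l2_cost(q1, q2w)
    if (cur > best - tol * max(best, 1e-12)) {
      best <- min(best, cur)
      break
    }
    best <- cur
    q2r <- q2w
  }
  best
}

#' Simplified elastic (square-root velocity) distance between two contours
#'
#' Both contours are resampled to a uniform grid, centred at their
#' centroids, and converted to square-root velocity (SRV) samples, under
#' which the elastic metric on curves becomes the L2 metric. The distance
#' minimises the L2 norm over rotations (closed-form Procrustes), cyclic
#' shifts of the starting point (coarse search over the grid with local
#' refinement), and grid reparameterisations (dynamic programming with the
#' sqrt(gamma') weighting), iterating rotation and warping to convergence.
#' Because grid-based warping is not exactly symmetric, the result is
#' symmetrised by averaging both directions. This is a discretised
#' approximation of the elastic shape distance on the quotient space of
#' curves modulo rotation, translation and reparameterisation.
#'
#' @param c1,c2 `cellph_contour` objects.
#' @param n_grid Resampling grid size (default 64).
#' @param shift_stride Coarse stride of the starting-point search
#'   (default `max(1, n_grid %/% 16)`).
#' @return Non-negative scalar distance.
#' @export
elastic_distance <- function(c1, c2, n_grid = 64L,
                             shift_stride = max(1L, n_grid %/% 16L)) {
  stopifnot(n_grid >= 8L)
  d12 <- elastic_one_way(c1, c2, n_grid, shift_stride)
  d21 <- elastic_one_way(c2, c1, n_grid, shift_stride)
  (d12 + d21) / 2
}

elastic_one_way <- function(c1, c2, n_grid, shift_stride) {
  q1 <- srv_samples(c1, n_grid)
  q2 <- srv_samples(c2, n_grid)
  shift_cost <- function(s) {
    q2s <- if (s == 0L) q2 else q2[c((s + 1L):n_grid, 1L:s), , drop = FALSE]
    elastic_align_cost(q1, q2s)
  }
  coarse <- seq(0L, n_grid - 1L, by = shift_stride)
  costs <- vapply(coarse, shift_cost, numeric(1))
  s0 <- coarse[which.min(costs)]
  refine <- setdiff(unique((s0 + seq(-shift_stride + 1L, shift_stride - 1L)) %% n_grid),
                    coarse)
  best <- min(costs)
  if (length(refine) > 0L) {
    best <- min(best, vapply(refine, shift_cost, numeric(1)))
  }
  sqrt(best)
}

#' Distance matrix between contours under a chosen metric
#'
#' Computes all pairwise distances for a population of cells using one of
#' the four contour metrics. The persistence (`"ph"`) metric additionally
#' needs the nucleus centres.
#'
#' @param contours Named list of `cellph_contour` objects.
#' @param metric One of `"ph"`, `"aspect"`, `"fourier"`, `"elastic"`.
#' @param centers Named list of `c(x, y)` nucleus centres (required for
#'   `"ph"`), names matching the contour ids.
#' @param p Wasserstein order for `"ph"` (default 2).
#' @param M Harmonic count for `"fourier"` (default 10).
#' @param n_resample Fourier resampling resolution (default 256).
#' @param n_grid Elastic grid size (default 64).
#' @param aspect_sqrt Use the standard-deviation convention for the aspect
#'   ratio (default `FALSE`).
#' @param clean Clean contour graphs before the PH filtration (default
#'   `TRUE`).
#' @return Symmetric distance matrix with cell ids as dimnames.
#' @export
shape_distance_matrix <- function(contours,
                                  metric = c("ph", "aspect", "fourier",
                                             "elastic"),
                                  centers = NULL, p = 2, M = 10L,
                                  n_resample = 256L, n_grid = 64L,
                                  aspect_sqrt = FALSE, clean = TRUE) {
  metric <- match.arg(metric)
  ids <- names(contours)
  if (is.null(ids)) ids <- vapply(contours, contour_id, character(1))
  n <- length(contours)
  if (n < 2L) abort("need at least 2 contours")
  if (anyDuplicated(ids)) abort("duplicate cell ids",
                                class = "cellph_input_error")
  if (metric == "ph") {
    if (is.null(centers)) abort("metric 'ph' needs nucleus centres")
    diagrams <- lapply(seq_len(n), function(i) {
      diagram_for_cell(contours[[i]], centers[[ids[i]]], clean = clean)
    })
    names(diagrams) <- ids
    return(ph_distance_matrix(diagrams, p = p))
  }
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  if (metric == "aspect") {
    a <- vapply(contours, aspect_ratio, numeric(1), sqrt = aspect_sqrt)
    m <- abs(outer(log(a), log(a), "-"))
    dimnames(m) <- list(ids, ids)
  } else if (metric == "fourier") {
    fd <- lapply(contours, fourier_descriptor, M = M,
                 n_resample = n_resample)
    E <- do.call(rbind, lapply(fd, as.numeric))
    m <- as.matrix(dist(E))
    dimnames(m) <- list(ids, ids)
  } else {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        d <- elastic_distance(contours[[i]], contours[[j]], n_grid = n_grid)
        m[i, j] <- d
        m[j, i] <- d
      }
    }
  }
  m
}
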