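# Classical MDS of a distance matrix, ROC evaluation of pairwise distances
# against group labels, and the nucleus-position sensitivity experiment.

#' Classical multidimensional scaling of a distance matrix
#'
#' Squares the distances, double-centres with J = I - (1/n) 11', and
#' eigen-decomposes B = -(1/2) J D2 J. Coordinates come from the top p
#' positive eigenvalues, X_p = V_p Lambda_p^(1/2). The explained-variance
#' fractions divide each retained eigenvalue by the sum of the positive
#' eigenvalues only: non-Euclidean inputs (such as Wasserstein matrices)
#' produce negative eigenvalues that would otherwise make the fractions
#' uninterpretable.
#'
#' @param m Symmetric distance matrix.
#' @param p Number of embedding dimensions requested.
#' @return A `cellph_mds`: list with `coordinates` (tibble `id`,
#'   `dim1`..`dimp`), `explained` (fractions per retained dimension),
#'   `eigenvalues` (all n), and `warning` (message when fewer than p
#'   positive eigenvalues exist, else `NULL`).
#' @export
cmds <- function(m, p = 2L) {
  check_distance_matrix(m)
  n <- nrow(m)
  if (p > n) abort("p must not exceed the number of objects",
                   class = "cellph_parameter_error")
  ids <- rownames(m)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  D2 <- m^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% D2 %*% J
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- which(eg$values > .Machine$double.eps * max(1, abs(eg$values[1L])))
  warn <- NULL
  keep <- seq_len(min(p, length(pos)))
  if (length(pos) < p) {
    warn <- sprintf("only %d positive eigenvalues; returning %d dimensions",
                    length(pos), length(pos))
  }
  lam <- eg$values[pos[keep]]
  X <- eg$vectors[, pos[keep], drop = FALSE] %*% diag(sqrt(lam),
                                                      length(lam))
  coords <- as_tibble(X, .name_repair = ~ paste0("dim", seq_along(.x)))
  coords <- dplyr::bind_cols(tibble(id = ids), coords)
  structure(
    list(coordinates = coords,
         explained = lam / sum(eg$values[pos]),
         eigenvalues = eg$values,
         warning = warn),
    class = "cellph_mds"
  )
}

#' ROC analysis of a distance matrix against group labels
#'
#' Every unordered pair of objects is labelled positive when both belong to
#' the same group and negative otherwise. Sweeping a threshold over the
#' sorted distinct distances, all pairs with distance less than or equal to
#' the threshold are called positive; the true-positive rate is plotted
#' against the false-positive rate and scored by the trapezoid area under
#' the curve (AUC) together with the partial area up to a false-positive
#' rate of 0.1 (pAUC10, unnormalised, so its maximum is 0.1). An AUC of 1
#' means all same-group pairs have smaller distances than any cross-group
#' pair; 0.5 means the distance carries no group information.
#'
#' @param m Distance matrix with dimnames.
#' @param labels Named character vector (or factor) of group labels, names
#'   matching the matrix dimnames; or an unnamed vector aligned with them.
#' @return A `cellph_roc`: list with `curve` (tibble `threshold`, `fpr`,
#'   `tpr`), `auc`, `pauc10`, `n_pos`, `n_neg`.
#' @export
roc_analysis <- function(m, labels) {
  check_distance_matrix(m)
  n <- nrow(m)
  ids <- rownames(m)
  if (!is.null(names(labels))) {
    lab <- as.character(labels[ids])
  } else {
    stopifnot(length(labels) == n)
    lab <- as.character(labels)
  }
  if (anyNA(lab)) abort("labels missing for some ids")
  if (length(unique(lab)) < 2L) {
    abort("ROC needs at least two groups (no negative pairs otherwise)",
          class = "cellph_domain_error")
  }
  iu <- which(upper.tri(m))
  d <- m[iu]
  same <- outer(lab, lab, "==")[iu]
  np <- sum(same)
  nn <- sum(!same)
  if (np == 0L) abort("no positive pairs", class = "cellph_domain_error")
  th <- sort(unique(d))
  # counts of positives/negatives at or below each threshold
  ord <- order(d)
  ds <- d[ord]
  ss <- same[ord]
  cp <- cumsum(ss)
  cn <- cumsum(!ss)
  last <- findInterval(th, ds)           # index of last pair <= threshold
  tpr <- c(0, cp[last] / np, 1)
  fpr <- c(0, cn[last] / nn, 1)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  pauc10 <- partial_auc(fpr, tpr, 0.1)
  structure(
    list(curve = tibble(threshold = c(-Inf, th, Inf), fpr = fpr, tpr = tpr),
         auc = auc, pauc10 = pauc10, n_pos = np, n_neg = nn),
    class = "cellph_roc"
  )
}

# trapezoid area under (fpr, tpr) restricted to fpr <= cut, with linear
# interpolation at the cut
partial_auc <- function(fpr, tpr, cut) {
  if (max(fpr) <= cut) {
    return(sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2))
  }
  t_at <- stats::approx(fpr, tpr, xout = cut, ties = "ordered")$y
  keep <- fpr < cut
  f <- c(fpr[keep], cut)
  t <- c(tpr[keep], t_at)
  sum(diff(f) * (head(t, -1) + tail(t, -1)) / 2)
}

#' Nucleus-position sensitivity of the PH distance
#'
#' For each noise level s, every nucleus centre is independently perturbed
#' by shifts drawn uniformly from \[-s, s\] in x and in y (redrawn until the
#' perturbed centre falls strictly inside the cell contour), all
#' persistence diagrams and the PH distance matrix are recomputed, and two
#' quantities are recorded: the relative Frobenius change
#' `delta(s) = ||D(s) - D(0)||_F / ||D(0)||_F` and the ROC AUC of the
#' perturbed matrix for each provided labelling. The experiment is repeated
#' `repeats` times per level and summarised by mean and standard deviation.
#'
#' Randomness is controlled by a single seed; each (level, repeat, cell)
#' triple draws from its own derived stream, so results do not depend on
#' iteration order.
#'
#' @param contours Named list of `cellph_contour` objects.
#' @param centers Named list of `c(x, y)` centres.
#' @param s_levels Numeric vector of noise levels (same unit as the
#'   contours); level 0 is the unperturbed reference and is always
#'   included.
#' @param repeats Repetitions per level (default 20).
#' @param seed Integer seed.
#' @param labelings Named list of label vectors (each as in
#'   [roc_analysis()]); one AUC curve is reported per labelling.
#' @param p Wasserstein order (default 2).
#' @param max_draws Rejection-sampling cap per cell (default 10000).
#' @return A `cellph_sensitivity`: list with `delta` (tibble `s`,
#'   `delta_mean`, `delta_sd`) and `auc` (tibble `level`, `s`, `auc_mean`,
#'   `auc_sd`), plus `auc0` (unperturbed AUC per labelling).
#' @export
nucleus_sensitivity <- function(contours, centers, s_levels,
                                repeats = 20L, seed = 1L,
                                labelings = list(), p = 2,
                                max_draws = 10000L) {
  stopifnot(repeats >= 1L)
  s_levels <- sort(unique(c(0, s_levels)))
  ids <- names(contours)
  graphs <- lapply(contours, function(cc) clean_graph(build_graph(cc)))

  diagrams_for <- function(ctrs) {
    ds <- lapply(seq_along(graphs), function(i) {
      g <- graphs[[i]]
      sublevel_diagram0(g, radial_function(g, ctrs[[ids[i]]]))
    })
    names(ds) <- ids
    ds
  }
  D0 <- ph_distance_matrix(diagrams_for(centers), p = p)
  f0 <- norm(D0, "F")
  auc0 <- vapply(labelings, function(lb) roc_analysis(D0, lb)$auc,
                 numeric(1))

  jitter_center <- function(contour, ctr, s, stream_seed) {
    if (s == 0) return(ctr)
    set.seed(stream_seed)
    for (draw in seq_len(max_draws)) {
      cand <- ctr + runif(2L, -s, s)
      if (contains_point(contour, cand)) return(cand)
    }
    abort(sprintf("rejection sampling exceeded %d draws for cell %s",
                  max_draws, contour_id(contour)),
          class = "cellph_geometry_error")
  }

  delta_rows <- list()
  auc_rows <- list()
  for (si in seq_along(s_levels)) {
    s <- s_levels[si]
    deltas <- numeric(repeats)
    aucs <- matrix(NA_real_, repeats, length(labelings))
    for (r in seq_len(repeats)) {
      ctrs <- centers
      if (s > 0) {
        for (ci in seq_along(ids)) {
          stream <- (as.integer(seed) + 97L * si + 1009L * r +
                       30011L * ci) %% .Machine$integer.max
          ctrs[[ids[ci]]] <- jitter_center(contours[[ci]],
                                           centers[[ids[ci]]], s, stream)
        }
      }
      Ds <- ph_distance_matrix(diagrams_for(ctrs), p = p)
      deltas[r] <- norm(Ds - D0, "F") / f0
      if (length(labelings) > 0L) {
        aucs[r, ] <- vapply(labelings, function(lb) {
          roc_analysis(Ds, lb)$auc
        }, numeric(1))
      }
    }
    delta_rows[[si]] <- tibble(s = s, delta_mean = mean(deltas),
                               delta_sd = sd_or_zero(deltas))
    if (length(labelings) > 0L) {
      auc_rows[[si]] <- tibble(
        level = names(labelings), s = s,
        auc_mean = colMeans(aucs),
        auc_sd = apply(aucs, 2L, sd_or_zero)
      )
    }
  }
  structure(
    list(delta = dplyr::bind_rows(delta_rows),
         auc = if (length(auc_rows)) dplyr::bind_rows(auc_rows) else
           tibble(level = character(0), s = numeric(0),
                  auc_mean = numeric(0), auc_sd = numeric(0)),
         auc0 = auc0),
    class = "cellph_sensitivity"
  )
}

sd_or_zero <- function(x) if (length(x) < 2L) 0 else stats::sd(x)

#' Flag outlier cells in a distance matrix
#'
#' A cell is flagged when its mean distance to all other cells exceeds the
#' population mean of those row means by more than `n_sd` standard
#' deviations. This operationalises spotting the bright row/column of a
#' distance heat map.
#'
#' @param m Distance matrix with dimnames.
#' @param n_sd Threshold in standard deviations (default 3).
#' @return Tibble with columns `id`, `mean_distance`, `outlier`.
#' @export
flag_outliers <- function(m, n_sd = 3) {
  check_distance_matrix(m)
  rm_ <- rowSums(m) / (nrow(m) - 1L)
  thr <- mean(rm_) + n_sd * stats::sd(rm_)
  tibble(id = rownames(m), mean_distance = rm_, outlier = rm_ > thr)
}
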