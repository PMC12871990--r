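# p-Wasserstein distance between persistence diagrams. Each diagram is
# augmented with one diagonal "ghost" per point of the other diagram; a real
# point may be transported to the diagonal at the cost of reaching its own
# orthogonal projection ((b+d)/2, (b+d)/2), ghosts pair with ghosts for
# free, and the balanced assignment is solved exactly.

# Exact linear sum assignment (square cost matrix) by shortest augmenting
# paths with dual potentials; O(n^3) with a vectorised inner scan.
# Returns the column assigned to each row.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  if (n == 0L) return(integer(0))
  u <- numeric(n + 1L)      # row potentials, index i+1 (row 0 virtual)
  v <- numeric(n + 1L)      # column potentials, index j+1 (col 0 virtual)
  p <- integer(n + 1L)      # p[j+1]: row matched to column j (0 = none)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n)
    way <- integer(n)
    used <- rep(FALSE, n)
    repeat {
      if (j0 > 0L) used[j0] <- TRUE
      i0 <- p[j0 + 1L]
      free <- which(!used)
      cur <- cost[i0, free] - u[i0 + 1L] - v[free + 1L]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd]] <- j0
      }
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      # update potentials along the alternating tree
      tree_cols <- which(used)
      u[p[c(0L, tree_cols) + 1L] + 1L] <- u[p[c(0L, tree_cols) + 1L] + 1L] + delta
      v[c(0L, tree_cols) + 1L] <- v[c(0L, tree_cols) + 1L] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    # augment: flip matches back along the path
    repeat {
      j1 <- way[j0]
      p[j0 + 1L] <- if (j1 == 0L) i else p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  out <- integer(n)
  for (j in seq_len(n)) out[p[j + 1L]] <- j
  out
}

# cost of sending a diagram point to the diagonal, to the p-th power
diag_cost <- function(birth, death, p) {
  ((death - birth) / sqrt(2))^p
}

#' p-Wasserstein distance between two persistence diagrams
#'
#' Augments each diagram with as many diagonal ghost points as the other has
#' real points; the cost of matching two real points is the p-th power of
#' their Euclidean distance in the (birth, death) plane, a real point pays
#' its distance to the diagonal (to the p-th power) to match a ghost, and
#' ghost-ghost matches are free. The optimal balanced assignment is solved
#' exactly and the p-th root of its total cost returned. With this
#' convention W_p is a true metric on diagrams.
#'
#' @param d1,d2 `cellph_diagram` objects (or tibbles with `birth`, `death`).
#' @param p Order of the distance, a real number >= 1. Default 2
#'   (the 2-Wasserstein distance used for the PH cell distance).
#' @return A list with elements `distance` (numeric scalar) and `plan`
#'   (tibble with columns `from`, `to`, `cost`; index 0 denotes the
#'   diagonal).
#' @export
wasserstein <- function(d1, d2, p = 2) {
  if (!is.numeric(p) || length(p) != 1L || p < 1) {
    abort("p must be a single number >= 1", class = "cellph_parameter_error")
  }
  b1 <- d1$birth; h1 <- d1$death
  b2 <- d2$birth; h2 <- d2$death
  n1 <- length(b1); n2 <- length(b2)
  if (n1 == 0L && n2 == 0L) {
    return(list(distance = 0,
                plan = tibble(from = integer(0), to = integer(0),
                              cost = numeric(0))))
  }
  N <- n1 + n2
  cost <- matrix(0, N, N)
  if (n1 > 0L && n2 > 0L) {
    dx <- outer(b1, b2, "-")
    dy <- outer(h1, h2, "-")
    cost[seq_len(n1), seq_len(n2)] <- (sqrt(dx^2 + dy^2))^p
  }
  if (n1 > 0L) {
    # real D1 point -> any D2 ghost: its own diagonal cost
    cost[seq_len(n1), n2 + seq_len(n1)] <- matrix(diag_cost(b1, h1, p),
                                                  n1, n1)
  }
  if (n2 > 0L) {
    cost[n1 + seq_len(n2), seq_len(n2)] <- matrix(diag_cost(b2, h2, p),
                                                  n2, n2, byrow = TRUE)
  }
  assign <- solve_assignment(cost)
  total <- sum(cost[cbind(seq_len(N), assign)])
  from <- ifelse(seq_len(N) <= n1, seq_len(N), 0L)   # 0 = diagonal ghost
  to <- ifelse(assign <= n2, assign, 0L)
  keep <- from > 0L | to > 0L
  plan <- tibble(from = from[keep], to = to[keep],
                 cost = cost[cbind(seq_len(N), assign)][keep])
  list(distance = total^(1 / p), plan = plan)
}

#' All-pairs Wasserstein distance matrix for a set of diagrams
#'
#' @param diagrams A list of `cellph_diagram` objects with unique ids
#'   (taken from [diagram_id()], or from the list names if set).
#' @param p Wasserstein order, default 2.
#' @return A symmetric numeric matrix with zero diagonal, dimnames set to
#'   the cell ids.
#' @export
ph_distance_matrix <- function(diagrams, p = 2) {
  n <- length(diagrams)
  if (n < 2L) abort("need at least 2 diagrams")
  ids <- names(diagrams)
  if (is.null(ids)) ids <- vapply(diagrams, diagram_id, character(1))
  if (anyDuplicated(ids)) {
    abort("duplicate diagram ids", class = "cellph_input_error")
  }
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d <- wasserstein(diagrams[[i]], diagrams[[j]], p = p)$distance
      m[i, j] <- d
      m[j, i] <- d
    }
  }
  m
}

# validate a distance matrix (symmetric, non-negative, zero diagonal)
check_distance_matrix <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    abort("distance matrix must be square", class = "cellph_input_error")
  }
  if (any(m < 0)) {
    abort("distance matrix has negative entries",
          class = "cellph_input_error")
  }
  if (max(abs(m - t(m))) > tol * max(1, max(abs(m)))) {
    abort("distance matrix is not symmetric", class = "cellph_input_error")
  }
  invisible(m)
}

#' Write / read a labelled distance matrix as CSV
#'
#' The CSV has the ids as both header row and first column.
#'
#' @param m Square matrix with dimnames.
#' @param path File path.
#' @return `path` (write) or the matrix (read).
#' @export
write_distance_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- ids
  storage.mode(m) <- "double"
  check_distance_matrix(m)
}
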