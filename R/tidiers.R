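# broom-style tidiers for the package's result objects.

#' Tidy a persistence diagram into a tibble of points
#'
#' @param x A `cellph_diagram`.
#' @param ... Unused.
#' @return Tibble with columns `id`, `birth`, `death`, `persistence`.
#' @method tidy cellph_diagram
#' @export
tidy.cellph_diagram <- function(x, ...) {
  tibble(id = diagram_id(x), birth = x$birth, death = x$death,
         persistence = x$death - x$birth)
}

#' Tidy a distance matrix into long pair form
#'
#' @param x Square distance matrix with dimnames.
#' @param ... Unused.
#' @return Tibble with columns `from`, `to`, `distance` (unordered pairs,
#'   upper triangle).
#' @export
tidy_distance_matrix <- function(x, ...) {
  iu <- which(upper.tri(x), arr.ind = TRUE)
  tibble(from = rownames(x)[iu[, 1L]], to = colnames(x)[iu[, 2L]],
         distance = x[iu])
}

#' @rdname roc_analysis
#' @param x A `cellph_roc`.
#' @param ... Unused.
#' @method tidy cellph_roc
#' @export
tidy.cellph_roc <- function(x, ...) x$curve

#' @rdname roc_analysis
#' @method glance cellph_roc
#' @export
glance.cellph_roc <- function(x, ...) {
  tibble(auc = x$auc, pauc10 = x$pauc10, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @rdname cmds
#' @param x A `cellph_mds`.
#' @param ... Unused.
#' @method tidy cellph_mds
#' @export
tidy.cellph_mds <- function(x, ...) x$coordinates

#' @rdname cmds
#' @method glance cellph_mds
#' @export
glance.cellph_mds <- function(x, ...) {
  tibble(dims = length(x$explained),
         explained_total = sum(x$explained),
         explained_dim1 = x$explained[1L],
         explained_dim2 = if (length(x$explained) >= 2L) x$explained[2L]
         else NA_real_)
}

#' @rdname nucleus_sensitivity
#' @param x A `cellph_sensitivity`.
#' @param ... Unused.
#' @method tidy cellph_sensitivity
#' @export
tidy.cellph_sensitivity <- function(x, ...) {
  if (nrow(x$auc) == 0L) return(x$delta)
  dplyr::left_join(x$auc, x$delta, by = "s")
}
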