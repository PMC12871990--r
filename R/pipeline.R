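# End-to-end orchestration: contours -> diagrams -> distance matrix ->
# clustering / MDS / ROC, with all artefacts written to an output
# directory.

#' Assemble a pipeline run configuration
#'
#' @param input_dir Directory of per-cell contour CSVs (`<id>.csv`).
#' @param centers_path CSV of nucleus centres (`id`, `x`, `y`); required
#'   for the `"ph"` metric.
#' @param labels_path Optional CSV of group labels (`id`, `group`) enabling
#'   the ROC summary.
#' @param metric Distance metric (see [shape_distance_matrix()]).
#' @param p,M,n_resample,n_grid,aspect_sqrt Metric parameters.
#' @param microns_per_pixel Scale factor applied to pixel-unit inputs
#'   (default 1 = no conversion).
#' @param linkages Linkages to cluster with.
#' @param k Number of clusters cut from the average-linkage tree.
#' @param seed Integer seed recorded with the run.
#' @param out_dir Output directory.
#' @return A `cellph_config` list.
#' @export
run_config <- function(input_dir, centers_path = NULL, labels_path = NULL,
                       metric = "ph", p = 2, M = 10L, n_resample = 256L,
                       n_grid = 64L, aspect_sqrt = FALSE,
                       microns_per_pixel = 1,
                       linkages = c("average", "single", "complete",
                                    "ward"),
                       k = 4L, seed = 1L, out_dir = "cellph-out") {
  structure(
    list(input_dir = input_dir, centers_path = centers_path,
         labels_path = labels_path, metric = metric, p = p, M = M,
         n_resample = n_resample, n_grid = n_grid,
         aspect_sqrt = aspect_sqrt,
         microns_per_pixel = microns_per_pixel, linkages = linkages,
         k = as.integer(k), seed = as.integer(seed), out_dir = out_dir),
    class = "cellph_config"
  )
}

#' Run the full contour-analysis pipeline
#'
#' Reads contours (and centres / labels when given), converts pixel units
#' to microns if requested, computes per-cell persistence diagrams (for the
#' PH metric), the all-pairs distance matrix, dendrograms for every
#' requested linkage (Newick and merge-table CSV), the cluster assignment
#' and purity table from the average-linkage cut, the cMDS embedding, an
#' outlier report, and (when labels are available) the ROC summary. All
#' artefacts are written under `config$out_dir`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`distance`,
#'   `trees`, `clusters`, `purity`, `mds`, `roc`, `outliers`, `log`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "cellph_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  files <- sort(list.files(config$input_dir, pattern = "\\.csv$",
                           full.names = TRUE))
  files <- files[!grepl("centers\\.csv$|labels\\.csv$", files)]
  if (length(files) < 2L) abort("need at least 2 contour files")
  contours <- lapply(files, read_contour, unit = "pixel")
  names(contours) <- vapply(contours, contour_id, character(1))

  centers <- NULL
  if (!is.null(config$centers_path)) {
    centers <- read_centers(config$centers_path)
  }
  if (config$microns_per_pixel != 1) {
    contours <- lapply(contours, to_microns, config$microns_per_pixel)
    if (!is.null(centers)) {
      centers <- lapply(centers, function(p) p * config$microns_per_pixel)
    }
  } else {
    # unit bookkeeping only; coordinates unchanged
    contours <- lapply(contours, function(cc) {
      attr(cc, "unit") <- "micron"
      cc
    })
  }

  if (config$metric == "ph") {
    if (is.null(centers)) abort("metric 'ph' needs a centres file")
    diag_dir <- file.path(out, "diagrams")
    dir.create(diag_dir, showWarnings = FALSE)
    diagrams <- lapply(names(contours), function(id) {
      d <- diagram_for_cell(contours[[id]], centers[[id]])
      write_diagram(d, file.path(diag_dir, paste0(id, ".json")))
      d
    })
    names(diagrams) <- names(contours)
    m <- ph_distance_matrix(diagrams, p = config$p)
  } else {
    m <- shape_distance_matrix(contours, metric = config$metric,
                               centers = centers, p = config$p,
                               M = config$M,
                               n_resample = config$n_resample,
                               n_grid = config$n_grid,
                               aspect_sqrt = config$aspect_sqrt)
  }
  write_distance_matrix(m, file.path(out, "distance_matrix.csv"))

  trees <- lapply(config$linkages, function(l) hca(m, l))
  names(trees) <- config$linkages
  for (l in config$linkages) {
    writeLines(dendrogram_newick(trees[[l]]),
               file.path(out, sprintf("dendrogram_%s.nwk", l)))
    readr::write_csv(trees[[l]]$merges,
                     file.path(out, sprintf("merges_%s.csv", l)))
  }

  clusters <- NULL
  ptab <- NULL
  if ("average" %in% config$linkages && config$k <= nrow(m)) {
    clusters <- cut_clusters(trees[["average"]], config$k)
    readr::write_csv(clusters, file.path(out, "clusters.csv"))
    ptab <- purity_table(m, k = config$k, ref_linkage = "average",
                         linkages = config$linkages)
    readr::write_csv(ptab, file.path(out, "purity.csv"))
  }

  emb <- cmds(m, p = 2L)
  readr::write_csv(emb$coordinates, file.path(out, "mds.csv"))

  outliers <- flag_outliers(m)
  readr::write_csv(outliers, file.path(out, "outliers.csv"))

  roc <- NULL
  if (!is.null(config$labels_path)) {
    lt <- utils::read.csv(config$labels_path, stringsAsFactors = FALSE)
    labels <- setNames(as.character(lt$group), as.character(lt$id))
    roc <- roc_analysis(m, labels)
    readr::write_csv(roc$curve, file.path(out, "roc_curve.csv"))
    jsonlite::write_json(list(auc = roc$auc, pauc10 = roc$pauc10),
                         file.path(out, "roc_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  log <- list(
    package_version = as.character(utils::packageVersion("cellph")),
    n_cells = length(contours), metric = config$metric,
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")])
  )
  jsonlite::write_json(log, file.path(out, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(distance = m, trees = trees, clusters = clusters,
                 purity = ptab, mds = emb, roc = roc, outliers = outliers,
                 log = log))
}
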