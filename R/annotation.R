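# Cluster extraction and probabilistic-atlas labeling of thresholded
# component maps.

neighbor_offsets <- function(connectivity) {
  stopifnot(connectivity %in% c(6, 18, 26))
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  keep <- switch(as.character(connectivity),
                 "6" = rowSums(abs(off)) == 1,
                 "18" = rowSums(abs(off)) <= 2,
                 "26" = rep(TRUE, nrow(off)))
  off[keep, , drop = FALSE]
}

#' Extract connected clusters of supra-threshold voxels
#'
#' Partitions a set of voxels into maximal connected components under 6-,
#' 18-, or 26-neighborhood adjacency (26, the most inclusive convention,
#' counts corner-adjacent voxels as adjacent and is the default).
#'
#' @param mask Logical vector over the voxel set (or integer indices of the
#'   supra-threshold voxels).
#' @param coordinates Voxels x 3 integer coordinate matrix for the full
#'   voxel set.
#' @param connectivity One of 6, 18, 26.
#' @return List of integer vectors, each holding the voxel indices (into
#'   `coordinates`) of one cluster, ordered by decreasing size (ties by
#'   smallest member index).
#' @export
extract_clusters <- function(mask, coordinates, connectivity = 26) {
  coordinates <- as.matrix(coordinates)
  idx <- if (is.logical(mask)) which(mask) else as.integer(mask)
  if (length(idx) == 0) return(list())
  coords <- coordinates[idx, , drop = FALSE]
  off <- neighbor_offsets(connectivity)

  # Hash voxel coordinates to scalar keys for O(1) neighbor lookup.
  base <- max(coordinates) + 3L
  key <- function(xyz) xyz[, 1] + base * xyz[, 2] + base^2 * xyz[, 3]
  keys <- key(coords)
  pos <- seq_along(idx)
  names(pos) <- as.character(keys)

  edges <- NULL
  for (r in seq_len(nrow(off))) {
    nb_keys <- key(sweep(coords, 2, off[r, ], "+"))
    hit <- pos[as.character(nb_keys)]
    found <- !is.na(hit)
    if (any(found)) {
      edges <- rbind(edges, cbind(pos[found], unname(hit[found])))
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges)) {
    edges <- edges[edges[, 1] < edges[, 2], , drop = FALSE]
    g <- igraph::add_edges(g, t(edges))
  }
  comp <- igraph::components(g)$membership
  clusters <- split(idx, comp)
  sizes <- lengths(clusters)
  firsts <- vapply(clusters, min, numeric(1))
  clusters <- clusters[order(-sizes, firsts)]
  names(clusters) <- NULL
  lapply(clusters, sort)
}

#' Label clusters against a probabilistic atlas
#'
#' Assigns each voxel of the analysis set to its maximum-probability atlas
#' region provided that probability is at least `prob_floor` (default 25%;
#' ties broken by the lower region index); voxels below the floor stay
#' unlabeled. For every cluster and region, the voxel count is reported when
#' it exceeds `min_voxels` (default 10), together with the percentage of the
#' region's total labeled voxels that the cluster covers and the
#' peak-absolute-loading voxel.
#'
#' @param clusters List of voxel-index vectors as returned by
#'   [extract_clusters()].
#' @param atlas A `wmn_atlas` whose `voxel_coordinates` match the analysis
#'   voxel set (or a regions x voxels probability matrix).
#' @param loadings Numeric vector of voxel loadings over the full voxel set.
#' @param coordinates Voxels x 3 coordinate matrix of the analysis voxel
#'   set.
#' @param min_voxels Report regions with more than this many cluster voxels.
#' @param prob_floor Minimum assignment probability (default 0.25).
#' @param region_names Optional region names when `atlas` is a bare matrix.
#' @param sign Optional sign label ("positive"/"negative") carried into the
#'   output.
#' @return A list of class `cluster_annotation` with data.frames `clusters`
#'   (id, sign, size, peak voxel and loading) and `regions` (cluster id,
#'   region, voxel count, percent of the region's labeled voxels, peak
#'   voxel), plus the per-voxel `assignment` vector (`NA` = unlabeled).
#' @export
label_clusters <- function(clusters, atlas, loadings, coordinates,
                           min_voxels = 10, prob_floor = 0.25,
                           region_names = NULL, sign = NA_character_) {
  P <- if (inherits(atlas, "wmn_atlas")) atlas$probability_maps else
    as.matrix(atlas)
  if (is.null(region_names)) {
    region_names <- if (inherits(atlas, "wmn_atlas")) atlas$region_names else
      sprintf("region_%02d", seq_len(nrow(P)))
  }
  n <- ncol(P)
  if (length(loadings) != n || nrow(coordinates) != n) {
    stop("atlas, loadings, and coordinates are not aligned", call. = FALSE)
  }
  best <- max.col(t(P), ties.method = "first")
  best_p <- P[cbind(best, seq_len(n))]
  assignment <- ifelse(best_p >= prob_floor, best, NA_integer_)
  region_totals <- tabulate(assignment[!is.na(assignment)], nrow(P))

  cl_rows <- list()
  rg_rows <- list()
  for (ci in seq_along(clusters)) {
    vox <- clusters[[ci]]
    peak <- vox[which.max(abs(loadings[vox]))]
    cl_rows[[ci]] <- data.frame(
      cluster = ci, sign = sign, size = length(vox),
      peak_x = coordinates[peak, 1], peak_y = coordinates[peak, 2],
      peak_z = coordinates[peak, 3], peak_loading = loadings[peak])
    lab <- assignment[vox]
    counts <- tabulate(lab[!is.na(lab)], nrow(P))
    for (r in which(counts > min_voxels)) {
      rvox <- vox[!is.na(lab) & lab == r]
      rpeak <- rvox[which.max(abs(loadings[rvox]))]
      rg_rows[[length(rg_rows) + 1]] <- data.frame(
        cluster = ci, sign = sign, region = region_names[r],
        count = counts[r],
        percent = 100 * counts[r] / region_totals[r],
        peak_x = coordinates[rpeak, 1], peak_y = coordinates[rpeak, 2],
        peak_z = coordinates[rpeak, 3], peak_loading = loadings[rpeak])
    }
  }
  structure(list(
    clusters = if (length(cl_rows)) do.call(rbind, cl_rows) else
      data.frame(),
    regions = if (length(rg_rows)) do.call(rbind, rg_rows) else
      data.frame(),
    assignment = assignment),
    class = "cluster_annotation")
}

#' Annotate all thresholded components against an atlas
#'
#' Convenience wrapper: for each component of a decomposition, extracts
#' positive and negative supra-threshold clusters separately (per the pooled
#' threshold) and labels them against the atlas.
#'
#' @param decomp A `wmn_ica` decomposition.
#' @param thresholded A `wmn_threshold` from [pooled_threshold()].
#' @param atlas A `wmn_atlas`.
#' @param coordinates Voxels x 3 coordinate matrix of the analysis voxel
#'   set.
#' @param connectivity Cluster adjacency (default 26).
#' @param ... Passed to [label_clusters()].
#' @return A data.frame stacking the per-region annotation rows of all
#'   components and signs, with a `component` column.
#' @export
annotate_components <- function(decomp, thresholded, atlas, coordinates,
                                connectivity = 26, ...) {
  rows <- list()
  for (j in seq_len(decomp$k)) {
    for (sgn in c("positive", "negative")) {
      mask <- thresholded[[sgn]][j, ]
      if (!any(mask)) next
      cl <- extract_clusters(mask, coordinates, connectivity)
      ann <- label_clusters(cl, atlas, decomp$S[j, ], coordinates,
                            sign = sgn, ...)
      if (nrow(ann$regions) > 0) {
        ann$regions$component <- j
        rows[[length(rows) + 1]] <- ann$regions
      }
    }
  }
  if (length(rows) == 0) return(data.frame())
  out <- do.call(rbind, rows)
  out[, c("component", setdiff(names(out), "component"))]
}

#' Threshold-sweep overlap between two components
#'
#' For each threshold t, classifies every analysis voxel by whether its
#' loading exceeds t on component a and/or component b and reports the four
#' resulting fractions (both, only a, only b, neither), which sum to 1.
#'
#' @param S A `wmn_ica` decomposition or k x voxels loading matrix.
#' @param component_a,component_b Distinct component indices.
#' @param thresholds Numeric vector of loading thresholds.
#' @return Data.frame with columns `threshold`, `both`, `only_a`, `only_b`,
#'   `neither`.
#' @export
overlap_analysis <- function(S, component_a, component_b,
                             thresholds = seq(0, 5, by = 0.25)) {
  S_mat <- if (inherits(S, "wmn_ica")) S$S else as.matrix(S)
  if (component_a == component_b) {
    stop("components must be distinct", call. = FALSE)
  }
  za <- S_mat[component_a, ]
  zb <- S_mat[component_b, ]
  n <- length(za)
  out <- lapply(thresholds, function(t) {
    a <- za > t
    b <- zb > t
    data.frame(threshold = t,
               both = sum(a & b) / n,
               only_a = sum(a & !b) / n,
               only_b = sum(!a & b) / n,
               neither = sum(!a & !b) / n)
  })
  do.call(rbind, out)
}

#' Fraction of a mask contained in a reference mask
#'
#' @param map_mask Logical vector (the mask whose containment is measured).
#' @param reference_mask Logical vector over the same voxel set.
#' @return `|map & reference| / |map|`.
#' @export
mask_fraction <- function(map_mask, reference_mask) {
  stopifnot(length(map_mask) == length(reference_mask))
  if (!any(map_mask)) {
    stop("undefined fraction: map mask is empty", call. = FALSE)
  }
  sum(map_mask & reference_mask) / sum(map_mask)
}
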