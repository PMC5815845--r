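# NIfTI and TSV interfaces. Contrast stacks are stored as 4-D NIfTI with
# subject as the fourth axis; atlases as 4-D NIfTI with region as the fourth
# axis; tables as tab-separated text with a header row.

vector_to_volume <- function(values, coordinates, grid_dims, fill = 0) {
  vol <- array(fill, dim = grid_dims)
  vol[as.matrix(coordinates)] <- values
  vol
}

#' Write a synthetic dataset to disk in standard formats
#'
#' Writes the contrast maps as a 4-D NIfTI stack plus a 3-D brain-mask
#' NIfTI, the atlas as a 4-D NIfTI, behavior and FA tables as TSV, and the
#' ground truth as JSON plus a 4-D NIfTI of the planted sources.
#'
#' @param dataset A `wmn_dataset` from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "wmn_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dims <- dataset$config$grid_dims
  cm <- dataset$contrast
  m <- nrow(cm$values)

  contrast_arr <- array(0, dim = c(dims, m))
  for (i in seq_len(m)) {
    contrast_arr[, , , i] <- vector_to_volume(cm$values[i, ],
                                              cm$coordinates, dims,
                                              fill = NA)
  }
  mask_arr <- vector_to_volume(rep(1, nrow(cm$coordinates)),
                               cm$coordinates, dims)
  atlas <- dataset$atlas
  atlas_arr <- array(0, dim = c(dims, nrow(atlas$probability_maps)))
  for (r in seq_len(nrow(atlas$probability_maps))) {
    atlas_arr[, , , r] <- vector_to_volume(atlas$probability_maps[r, ],
                                           atlas$voxel_coordinates, dims)
  }
  k <- nrow(dataset$truth$true_sources)
  src_arr <- array(0, dim = c(dims, k))
  for (j in seq_len(k)) {
    src_arr[, , , j] <- vector_to_volume(dataset$truth$true_sources[j, ],
                                         cm$coordinates, dims)
  }

  paths <- c(contrast = file.path(dir, "contrast_maps.nii.gz"),
             mask = file.path(dir, "brain_mask.nii.gz"),
             atlas = file.path(dir, "atlas.nii.gz"),
             sources = file.path(dir, "true_sources.nii.gz"),
             behavior = file.path(dir, "behavior.tsv"),
             fa = file.path(dir, "fa.tsv"),
             truth = file.path(dir, "ground_truth.json"))
  RNifti::writeNifti(RNifti::asNifti(contrast_arr), paths["contrast"])
  RNifti::writeNifti(RNifti::asNifti(mask_arr), paths["mask"])
  RNifti::writeNifti(RNifti::asNifti(atlas_arr), paths["atlas"])
  RNifti::writeNifti(RNifti::asNifti(src_arr), paths["sources"])
  utils::write.table(dataset$behavior, paths["behavior"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(dataset$fa, paths["fa"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  truth <- dataset$truth
  jsonlite::write_json(
    list(true_scores = truth$true_scores,
         batch_assignments = lapply(truth$batch_assignments, as.integer),
         planted_effects = truth$planted_effects,
         seed = truth$seed),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a 4-D contrast stack and mask into a contrast matrix
#'
#' @param contrast_path Path to a 4-D NIfTI (x, y, z, subject).
#' @param mask_path Path to a 3-D brain-mask NIfTI (nonzero = in brain).
#' @return A [contrast_matrix()] over the in-mask voxels; `NA` intensities
#'   become missing entries.
#' @export
read_contrast_nifti <- function(contrast_path, mask_path) {
  stack <- RNifti::readNifti(contrast_path)
  mask <- RNifti::readNifti(mask_path)
  dims <- dim(mask)
  stopifnot(length(dims) == 3, identical(dim(stack)[1:3], dims))
  coords <- which(array(mask != 0, dims), arr.ind = TRUE)
  coords <- coords[order(coords[, 3], coords[, 2], coords[, 1]), ,
                   drop = FALSE]
  m <- dim(stack)[4]
  flat <- matrix(stack, prod(dims), m)
  lin <- coords[, 1] + dims[1] * (coords[, 2] - 1) +
    dims[1] * dims[2] * (coords[, 3] - 1)
  vals <- t(flat[lin, , drop = FALSE])
  colnames(coords) <- c("x", "y", "z")
  contrast_matrix(vals, coords, grid_dims = dims)
}

#' Write per-component voxel-loading volumes as 4-D NIfTI
#'
#' @param decomp A `wmn_ica` decomposition.
#' @param coordinates Voxels x 3 coordinates of the analysis voxel set.
#' @param grid_dims Integer 3-vector of the full grid.
#' @param path Output NIfTI path.
#' @return Invisibly, `path`.
#' @export
write_loadings_nifti <- function(decomp, coordinates, grid_dims, path) {
  arr <- array(0, dim = c(grid_dims, decomp$k))
  for (j in seq_len(decomp$k)) {
    arr[, , , j] <- vector_to_volume(decomp$S[j, ], coordinates, grid_dims)
  }
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

#' Write subject scores as TSV
#'
#' @param decomp A `wmn_ica` decomposition (or score matrix).
#' @param path Output TSV path.
#' @param subject_ids Optional subject identifiers.
#' @return Invisibly, `path`.
#' @export
write_scores_tsv <- function(decomp, path, subject_ids = NULL) {
  A <- if (inherits(decomp, "wmn_ica")) decomp$A else as.matrix(decomp)
  df <- as.data.frame(A)
  names(df) <- sprintf("ic%d", seq_len(ncol(A)))
  df <- cbind(subject = subject_ids %||% sprintf("sub%04d", seq_len(nrow(A))),
              df)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
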