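# Independent oracles and small fixture builders used across test files.

# Step-up BH oracle: reject the k tests with the smallest p values, where k
# is the largest i with p_(i) <= i * alpha / n.
bh_oracle_reject <- function(p, alpha) {
  n <- length(p)
  o <- order(p)
  k <- max(c(0L, which(p[o] <= seq_len(n) / n * alpha)))
  reject <- logical(n)
  if (k > 0) reject[o[seq_len(k)]] <- TRUE
  reject
}

# Iterative flood-fill connected components on a voxel set, independent of
# the package's graph-based implementation.
flood_fill_clusters <- function(mask, coordinates, connectivity) {
  idx <- which(mask)
  if (length(idx) == 0) return(list())
  coords <- coordinates[idx, , drop = FALSE]
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  off <- switch(as.character(connectivity),
                "6" = off[rowSums(abs(off)) == 1, , drop = FALSE],
                "18" = off[rowSums(abs(off)) <= 2, , drop = FALSE],
                "26" = off)
  key <- do.call(paste, c(as.data.frame(coords), sep = ","))
  lookup <- seq_along(idx)
  names(lookup) <- key
  visited <- logical(length(idx))
  clusters <- list()
  for (start in seq_along(idx)) {
    if (visited[start]) next
    stack <- start
    members <- integer(0)
    visited[start] <- TRUE
    while (length(stack) > 0) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      members <- c(members, cur)
      nb <- sweep(off, 2, coords[cur, ], "+")
      nb_key <- do.call(paste, c(as.data.frame(nb), sep = ","))
      hits <- lookup[nb_key]
      hits <- hits[!is.na(hits)]
      new <- hits[!visited[hits]]
      visited[new] <- TRUE
      stack <- c(stack, new)
    }
    clusters[[length(clusters) + 1]] <- sort(idx[members])
  }
  sizes <- lengths(clusters)
  firsts <- vapply(clusters, min, numeric(1))
  clusters[order(-sizes, firsts)]
}

# Canonical form of a cluster partition for comparison.
partition_signature <- function(clusters) {
  lapply(clusters[order(vapply(clusters, min, numeric(1)))], sort)
}

# A small noiseless dataset used by several ICA tests.
tiny_noiseless_dataset <- function(k = 3, m = 50, seed = 7) {
  cfg <- synth_config(n_subjects = m, grid_dims = c(12, 12, 8),
                      n_components_true = k, noise_sd = 0,
                      batch_offset_sd = 0, seed = seed,
                      behavioral_effects = list(), fa_effect = NULL,
                      n_atlas_regions = 5)
  generate_dataset(cfg)
}
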