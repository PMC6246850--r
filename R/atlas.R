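# Labeled atlas volumes and high-resolution subdivision.
#
# Atlas volumes are 3-D integer arrays whose voxel values are parcellation
# indices (0 = background).  They are exchanged on disk as a plain-text
# voxel table (one row per labeled voxel) rather than NIfTI: no NIfTI
# reader ships with the supported R stack, and the subdivision algorithm
# only needs voxel coordinates and labels.

#' Read / write a labeled atlas volume
#'
#' Plain-text format: a first comment line `# dims: nx ny nz`, then a
#' tab-separated table with columns `x`, `y`, `z`, `label` listing every
#' labeled voxel (1-based coordinates).
#'
#' @param path file path.
#' @return `read_atlas_volume()` returns a 3-D integer array.
#' @export
read_atlas_volume <- function(path) {
  first <- readLines(path, n = 1)
  dims <- as.integer(strsplit(sub("^#\\s*dims:\\s*", "", first), "\\s+")[[1]])
  if (length(dims) != 3 || anyNA(dims)) stop("malformed dims header in ", path, call. = FALSE)
  df <- utils::read.delim(path, skip = 1, stringsAsFactors = FALSE)
  vol <- array(0L, dim = dims)
  vol[cbind(df$x, df$y, df$z)] <- as.integer(df$label)
  vol
}

#' @param volume a 3-D integer array of region labels.
#' @rdname read_atlas_volume
#' @export
write_atlas_volume <- function(volume, path) {
  stopifnot(is.array(volume), length(dim(volume)) == 3)
  idx <- which(volume != 0L, arr.ind = TRUE)
  df <- data.frame(x = idx[, 1], y = idx[, 2], z = idx[, 3],
                   label = volume[idx])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# dims:", paste(dim(volume), collapse = " ")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Subdivide a parcellation into a high-resolution template
#'
#' Splits every region of a labeled atlas volume into spatially compact
#' subregions so that the total subregion count reaches `n_target`
#' (e.g. 1024 from the default 92).  Seeds are distributed across
#' regions with probability proportional to regional voxel volume, under
#' two constraints: every region receives at least one seed, and the two
#' hemispheres receive exactly `n_target/2` seeds each.  Seed counts are
#' drawn for the left hemisphere and mirrored onto each region's
#' homologous right partner, which enforces the hemisphere balance
#' exactly and keeps subregions pairable.  Within a region the voxels are
#' partitioned into its seed-count clusters by k-means (Lloyd's
#' algorithm, k-means++ initialization, 100 iterations) on voxel
#' coordinates, so every subregion stays inside its parent region.
#'
#' @param volume 3-D integer array of parcellation indices (0 background).
#' @param parc the `parcellation` matching the labels in `volume`.
#' @param n_target total number of subregions; must be even and at least
#'   the current region count.
#' @param seed RNG seed; the subdivision is a pure function of
#'   `(volume, parc, n_target, seed)`.
#' @return A list with `volume` (relabeled array, labels `1..n_target`)
#'   and `parcellation` (new `parcellation` with `parent_index` and
#'   `parent_abbreviation` columns).
#' @export
subdivide_parcellation <- function(volume, parc, n_target, seed = 1L) {
  stopifnot(inherits(parc, "parcellation"))
  n_orig <- nrow(parc)
  if (n_target %% 2L != 0L) {
    stop("n_target must be even (seeds are split equally between hemispheres)",
         call. = FALSE)
  }
  if (n_target < n_orig) {
    stop("n_target (", n_target, ") must be at least the region count (",
         n_orig, ")", call. = FALSE)
  }
  counts <- vapply(seq_len(n_orig), function(r) sum(volume == r), integer(1))
  if (any(counts == 0)) {
    stop("empty region(s) in atlas volume: ",
         paste(parc$abbreviation[counts == 0], collapse = ", "), call. = FALSE)
  }
  set.seed(seed)

  pairs <- pair_table(parc)
  left_idx <- vapply(pairs$pair_id, function(p) pair_indices(parc, p)[1], integer(1))
  right_idx <- vapply(pairs$pair_id, function(p) pair_indices(parc, p)[2], integer(1))
  n_half <- n_target %/% 2L
  left_counts <- allocate_seeds(counts[left_idx], n_half)

  nx <- dim(volume)[1]
  new_vol <- array(0L, dim = dim(volume))
  rows <- list()
  next_pair <- 1L
  next_index <- 1L
  for (k in seq_len(nrow(pairs))) {
    n_sub <- left_counts[k]
    for (side in c("L", "R")) {
      region <- if (side == "L") left_idx[k] else right_idx[k]
      vox <- which(volume == region, arr.ind = TRUE)
      # Mirror the x axis for the right member so that cluster c of the
      # left region and cluster c of the right region occupy homologous
      # positions in a mirror-symmetric atlas.
      ord_x <- if (side == "L") vox[, 1] else nx + 1 - vox[, 1]
      cl <- cluster_region(vox, n_sub, order_x = ord_x)
      for (c_id in seq_len(n_sub)) {
        sub_vox <- vox[cl == c_id, , drop = FALSE]
        lab <- next_index + 2L * (c_id - 1L) + (side == "R")
        new_vol[sub_vox] <- as.integer(lab)
      }
      base <- parc$pair_abbreviation[region]
      rows[[length(rows) + 1L]] <- data.frame(
        index = next_index + 2L * (seq_len(n_sub) - 1L) + (side == "R"),
        abbreviation = paste0(base, "_", seq_len(n_sub), ".", side),
        description = paste0(parc$description[region], ", subregion ",
                             seq_len(n_sub)),
        lobe = parc$lobe[region],
        hemisphere = side,
        pair_id = next_pair + seq_len(n_sub) - 1L,
        pair_abbreviation = paste0(base, "_", seq_len(n_sub)),
        parent_index = region,
        parent_abbreviation = parc$abbreviation[region],
        stringsAsFactors = FALSE)
    }
    next_index <- next_index + 2L * n_sub
    next_pair <- next_pair + n_sub
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$index), ]
  rownames(df) <- NULL
  list(volume = new_vol, parcellation = parcellation(df))
}

# Distribute n seeds over regions with probability proportional to
# volume, then enforce the >=1-seed floor by stealing from the largest
# allocation.
allocate_seeds <- function(volumes, n) {
  if (n < length(volumes)) {
    stop("cannot place ", n, " seeds into ", length(volumes),
         " regions with the one-seed floor", call. = FALSE)
  }
  alloc <- as.integer(stats::rmultinom(1, n, prob = volumes))
  while (any(alloc == 0L)) {
    donor <- which.max(alloc)
    recipient <- which(alloc == 0L)[1]
    alloc[donor] <- alloc[donor] - 1L
    alloc[recipient] <- 1L
  }
  alloc
}

# k-means partition of one region's voxels; k = 1 short-circuits to the
# identity.  Clusters are renumbered by centroid position (mirrored x
# first) so numbering is stable given the RNG state.
cluster_region <- function(vox, k, order_x) {
  if (k == 1L) return(rep(1L, nrow(vox)))
  if (k >= nrow(vox)) {
    stop("region has fewer voxels (", nrow(vox), ") than requested seeds (",
         k, ")", call. = FALSE)
  }
  coords <- cbind(order_x, vox[, 2], vox[, 3])
  centers <- kmeanspp_init(coords, k)
  km <- suppressWarnings(
    stats::kmeans(coords, centers = centers, algorithm = "Lloyd",
                  iter.max = 100)
  )
  cent <- km$centers
  ord <- order(cent[, 1], cent[, 2], cent[, 3])
  match(km$cluster, ord)
}

# k-means++ seeding: first center uniform, subsequent centers drawn with
# probability proportional to squared distance to the nearest chosen one.
kmeanspp_init <- function(coords, k) {
  n <- nrow(coords)
  centers <- matrix(NA_real_, k, ncol(coords))
  centers[1, ] <- coords[sample.int(n, 1), ]
  d2 <- rowSums((coords - matrix(centers[1, ], n, ncol(coords), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 == 0)) {
      pick <- sample.int(n, 1)
    } else {
      pick <- sample.int(n, 1, prob = d2)
    }
    centers[j, ] <- coords[pick, ]
    d2 <- pmin(d2, rowSums((coords - matrix(centers[j, ], n, ncol(coords),
                                            byrow = TRUE))^2))
  }
  # stats::kmeans requires distinct centers; break exact ties by a small
  # deterministic jitter (well below the voxel grid spacing)
  dup <- duplicated(centers)
  if (any(dup)) {
    centers[dup, ] <- centers[dup, , drop = FALSE] +
      stats::runif(sum(dup) * ncol(coords), -0.25, 0.25)
  }
  centers
}
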