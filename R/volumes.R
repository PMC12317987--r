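#' Voxel volume on a regular grid
#'
#' Holds per-voxel values (source power, noise power, or their ratio) on a
#' regular grid with equal edge length, plus an optional logical region
#' mask (atlas-like restriction of which voxels participate in
#' thresholding).
#'
#' @param values 3-D numeric array (nx x ny x nz).
#' @param spacing grid edge length in mm (default 5).
#' @param mask optional logical array of the same dimensions.
#' @return An object of class `source_volume`.
#' @export
source_volume <- function(values, spacing = 5, mask = NULL) {
  if (!is.array(values) || length(dim(values)) != 3)
    stop_ncreann("'values' must be a 3-D array")
  if (any(dim(values) <= 0)) stop_ncreann("grid dimensions must be positive")
  if (!is.numeric(spacing) || spacing <= 0)
    stop_ncreann("'spacing' must be a positive edge length in mm")
  if (anyNA(values) || any(!is.finite(values)))
    stop_ncreann("volume contains missing or non-finite values")
  if (!is.null(mask) && !identical(dim(mask), dim(values)))
    stop_ncreann("mask dimensions must match the volume")
  structure(list(values = values, dims = dim(values), spacing = spacing,
                 mask = mask),
            class = "source_volume")
}

#' @export
print.source_volume <- function(x, ...) {
  cat(sprintf("<source_volume> %d x %d x %d voxels @ %g mm, range [%.3g, %.3g]\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Neural activity index
#'
#' Divides the source power estimate by the local noise power estimate per
#' voxel, normalizing away the depth-dependent noise amplification of the
#' spatial filter.
#'
#' @param power,noise matching [source_volume()]s; all noise values must be
#'   strictly positive.
#' @return A [source_volume()] of voxelwise power/noise ratios.
#' @export
compute_nai <- function(power, noise) {
  stopifnot(inherits(power, "source_volume"), inherits(noise, "source_volume"))
  if (!identical(power$dims, noise$dims) || power$spacing != noise$spacing)
    stop_ncreann("power and noise volumes must share the same grid")
  if (any(noise$values <= 0))
    stop_ncreann("noise volume has non-positive voxels; cannot form the ratio")
  source_volume(power$values / noise$values, spacing = power$spacing,
                mask = power$mask)
}

#' Top-percentile voxel threshold
#'
#' Finds the voxels whose value reaches the top `percent` of the (masked)
#' value distribution. The threshold is the `(100 - percent)` linear-
#' interpolation percentile; ties at the threshold are all included, which
#' makes the rule deterministic.
#'
#' @param volume a [source_volume()].
#' @param percent percentage of the distribution to keep (default 1).
#' @param mask optional logical array overriding the volume's own mask.
#' @return Data frame of suprathreshold voxels with grid indices `i, j, k`,
#'   millimetre coordinates `x_mm, y_mm, z_mm` (voxel centers,
#'   `(index - 1) * spacing`), and `value`; the threshold is attached as
#'   attribute `"threshold"`.
#' @export
top_percent_threshold <- function(volume, percent = 1, mask = NULL) {
  stopifnot(inherits(volume, "source_volume"))
  mask <- mask %||% volume$mask %||% array(TRUE, volume$dims)
  if (!any(mask)) stop_ncreann("mask selects no voxels")
  vals <- volume$values[mask]
  if (length(unique(vals)) == 1)
    warning("all masked voxels share one value; returning all of them",
            call. = FALSE)
  thr <- if (percent >= 100) min(vals)
         else as.numeric(quantile(vals, 1 - percent / 100, type = 7))
  sel <- mask & volume$values >= thr
  idx <- which(sel, arr.ind = TRUE)
  colnames(idx) <- c("i", "j", "k")
  out <- data.frame(idx,
                    x_mm = (idx[, 1] - 1) * volume$spacing,
                    y_mm = (idx[, 2] - 1) * volume$spacing,
                    z_mm = (idx[, 3] - 1) * volume$spacing,
                    value = volume$values[sel])
  out <- out[order(out$i, out$j, out$k), ]
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  out
}

#' Density-based clustering of suprathreshold voxels
#'
#' Groups adjacent voxels by Euclidean distance on their center
#' coordinates: two voxels are neighbors when they lie within `eps` of each
#' other, clusters are the connected groups of mutually reachable voxels,
#' and any group smaller than `min_pts` voxels is labeled noise. With the
#' default `eps = 1.5 * spacing`, face neighbors (distance 1 x spacing) and
#' edge neighbors (sqrt(2) x spacing) connect while corner neighbors
#' (sqrt(3) x spacing) do not. Voxels are scanned in input order, so
#' cluster labels are deterministic (label 1 is the first-found cluster).
#'
#' @param voxels data frame with `x_mm`, `y_mm`, `z_mm` columns (as
#'   returned by [top_percent_threshold()]); extra columns are carried
#'   through.
#' @param spacing grid edge length in mm, used for the default `eps`.
#' @param eps neighborhood radius in mm (default `1.5 * spacing`).
#' @param min_pts minimum voxels per cluster (default 5); smaller groups
#'   become noise.
#' @return An object of class `voxel_clusters`: the input data frame with a
#'   `cluster` column (0 = noise), plus `n_clusters`, `sizes` and the
#'   parameters used.
#' @export
dbscan_clusters <- function(voxels, spacing = 5, eps = 1.5 * spacing,
                            min_pts = 5) {
  voxels <- as.data.frame(voxels)
  n <- nrow(voxels)
  if (n == 0) {
    return(structure(list(voxels = cbind(voxels, cluster = integer(0)),
                          n_clusters = 0L, sizes = integer(0),
                          eps = eps, min_pts = min_pts),
                     class = "voxel_clusters"))
  }
  xyz <- as.matrix(voxels[, c("x_mm", "y_mm", "z_mm")])
  d2 <- as.matrix(stats::dist(xyz))^2
  nb <- lapply(seq_len(n), function(i) which(d2[i, ] <= eps^2))  # incl. self
  comp <- integer(n)               # connected component of the eps graph
  nc <- 0L
  for (i in seq_len(n)) {          # fixed scan order -> deterministic labels
    if (comp[i] != 0L) next
    nc <- nc + 1L
    frontier <- i
    while (length(frontier)) {
      q <- frontier[[1]]
      frontier <- frontier[-1]
      if (comp[q] == 0L) {
        comp[q] <- nc
        frontier <- c(frontier, nb[[q]][comp[nb[[q]]] == 0L])
      }
    }
  }
  sizes_all <- tabulate(comp, nc)
  keep <- which(sizes_all >= min_pts)
  relabel <- integer(nc)
  relabel[keep] <- seq_along(keep)  # preserves first-found order
  cluster <- ifelse(comp > 0 & relabel[comp] > 0, relabel[comp], 0L)
  voxels$cluster <- as.integer(cluster)
  structure(list(voxels = voxels, n_clusters = length(keep),
                 sizes = sizes_all[keep], eps = eps, min_pts = min_pts),
            class = "voxel_clusters")
}

#' @export
print.voxel_clusters <- function(x, ...) {
  cat(sprintf("<voxel_clusters> %d clusters from %d voxels (eps = %g mm, minPts = %d)\n",
              x$n_clusters, nrow(x$voxels), x$eps, x$min_pts))
  if (x$n_clusters > 0)
    cat("  sizes:", paste(x$sizes, collapse = ", "),
        " noise:", sum(x$voxels$cluster == 0), "\n")
  invisible(x)
}

#' Threshold a volume and extract its activity clusters
#'
#' Convenience wrapper: [top_percent_threshold()] followed by
#' [dbscan_clusters()].
#'
#' @inheritParams top_percent_threshold
#' @inheritParams dbscan_clusters
#' @return A `voxel_clusters` object.
#' @export
extract_clusters <- function(volume, percent = 1, mask = NULL,
                             eps = 1.5 * volume$spacing, min_pts = 5) {
  vox <- top_percent_threshold(volume, percent = percent, mask = mask)
  dbscan_clusters(vox, spacing = volume$spacing, eps = eps,
                  min_pts = min_pts)
}
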