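#' Principal signal curvatures of a 3D intensity volume
#'
#' Gaussian-smooths the volume at scale `smoothing_sigma` (voxels) and
#' returns the eigenvalues of the negated Hessian at every voxel, sorted
#' descending, so the centre of a bright blob yields three positive
#' curvatures. A one-voxel border is set to zero.
#'
#' @param vol 3D numeric array (intensity).
#' @param smoothing_sigma Gaussian scale in voxels (`>= 0.5`); choose it
#'   near the expected nucleus radius (default 2).
#' @return A list of class `signal_curvatures` with 3D arrays `k1 >= k2 >=
#'   k3`.
#' @export
signal_curvatures <- function(vol, smoothing_sigma = 2) {
  stopifnot(is.array(vol), length(dim(vol)) == 3L, smoothing_sigma >= 0.5)
  if (any(dim(vol) < 8L)) stop("volume must be at least 8 voxels per axis")
  sm <- .gauss_smooth3(vol, dim(vol), smoothing_sigma)
  r <- .hessian_curvatures(sm, dim(vol), 1L)
  structure(list(k1 = r$k1, k2 = r$k2, k3 = r$k3), class = "signal_curvatures")
}

#' Blob score from principal signal curvatures
#'
#' `ks = (k1+ k2+ k3+)^(1/3)` with `ki+ = max(ki, 0)`: the geometric mean of
#' the positive parts, zero wherever any curvature is non-positive, so only
#' voxels that curve downward in all three directions (blob centres) score.
#'
#' @param k A `signal_curvatures` object, or a list with arrays `k1`, `k2`,
#'   `k3`.
#' @return 3D array of scores.
#' @export
blob_score <- function(k) {
  (pmax(k$k1, 0) * pmax(k$k2, 0) * pmax(k$k3, 0))^(1 / 3)
}

# ks field computed without materializing k1..k3 (used on large volumes)
blob_score_volume <- function(vol, smoothing_sigma = 2) {
  sm <- .gauss_smooth3(vol, dim(vol), smoothing_sigma)
  .hessian_curvatures(sm, dim(vol), 0L)$ks
}

#' Reference blob-score threshold calibration
#'
#' Renders one isolated Gaussian blob of amplitude `peak` and width
#' `blob_sigma` in a quiet volume, runs the curvature pipeline at
#' `smoothing_sigma`, and returns half its peak score. Detection thresholds
#' have no universal scale (they depend on intensity units, nucleus size
#' and smoothing), so the default threshold is anchored to this reference.
#'
#' @param peak Blob peak intensity in the units of the data.
#' @param blob_sigma Expected nucleus Gaussian radius (voxels).
#' @param smoothing_sigma Smoothing scale passed to the detector.
#' @param fraction Fraction of the reference peak score used as threshold.
#' @return Scalar threshold for [detect_cells()].
#' @export
calibrate_k_threshold <- function(peak = 1, blob_sigma = 2,
                                  smoothing_sigma = 2, fraction = 0.5) {
  n <- as.integer(max(16, ceiling(8 * (blob_sigma + smoothing_sigma))))
  vol <- array(0, c(n, n, n))
  ctr <- matrix((n + 1) / 2, 1, 3)
  vol <- .add_blobs(vol, dim(vol), ctr, blob_sigma, peak)
  ks <- blob_score_volume(vol, smoothing_sigma)
  fraction * max(ks)
}

#' Detect nuclei as blob-score components
#'
#' Thresholds the blob score at `k_threshold`, labels 26-connected
#' components, and reports one centroid per component (plain voxel mean,
#' 1-based continuous voxel coordinates).
#'
#' @inheritParams signal_curvatures
#' @param k_threshold Positive score threshold; see
#'   [calibrate_k_threshold()].
#' @param min_voxels Discard components smaller than this (default 2;
#'   suppresses single-voxel noise hits).
#' @return A tibble of class `cell_centroids` with columns `x`, `y`, `z`
#'   (voxel coordinates) and `size` (component voxel count).
#' @export
detect_cells <- function(vol, smoothing_sigma = 2, k_threshold,
                         min_voxels = 2L) {
  stopifnot(is.array(vol), length(dim(vol)) == 3L, k_threshold > 0)
  ks <- blob_score_volume(vol, smoothing_sigma)
  lab <- .label_centroids(ks > k_threshold, dim(vol))
  keep <- lab$sizes >= min_voxels
  out <- tibble::tibble(x = lab$centroids[keep, 1],
                        y = lab$centroids[keep, 2],
                        z = lab$centroids[keep, 3],
                        size = lab$sizes[keep])
  class(out) <- c("cell_centroids", class(out))
  out
}

#' Clipped-box density estimation within one tissue layer
#'
#' At each sampling point, counts detected cells inside an axis-aligned box
#' of `box_edge` voxels intersected with the layer (and the volume bounds)
#' and divides by the clipped volume. Sampling points default to a regular
#' lattice inside the layer with spacing `box_edge / 2`.
#'
#' @param cells A `cell_centroids` tibble from [detect_cells()].
#' @param labels 3D integer/numeric array of layer ids.
#' @param layer Layer id whose density is estimated.
#' @param box_edge Box edge length in voxels (default 80).
#' @param sampling_points Optional `n x 3` matrix of voxel coordinates; must
#'   lie in the layer.
#' @return A tibble of class `density_estimate` with the sampling points,
#'   per-point `density` (cells per voxel^3), `count` and `clipped_volume`;
#'   the `layer` id is kept as an attribute.
#' @details The layer clip is evaluated per voxel column of the label
#'   array, so arbitrarily shaped (not just slab) layers are supported.
#'   Sampling points whose clipped volume is zero are skipped with a
#'   warning.
#' @export
layer_density <- function(cells, labels, layer, box_edge = 80,
                          sampling_points = NULL) {
  stopifnot(is.array(labels), length(dim(labels)) == 3L, box_edge > 0)
  dims <- dim(labels)
  if (is.null(sampling_points)) {
    sp <- box_edge / 2
    gr <- lapply(dims, function(n) seq(sp / 2, n, by = sp))
    sampling_points <- as.matrix(expand.grid(gr[[1]], gr[[2]], gr[[3]]))
    colnames(sampling_points) <- NULL
    # keep lattice points inside the layer
    vi <- pmin(pmax(round(sampling_points), 1),
               matrix(dims, nrow(sampling_points), 3, byrow = TRUE))
    inlayer <- labels[vi] == layer
    sampling_points <- sampling_points[inlayer, , drop = FALSE]
  }
  np <- nrow(sampling_points)
  if (np == 0) stop("no sampling points inside layer ", layer)
  half <- box_edge / 2
  lo <- pmax(sweep(sampling_points, 2, half), 0.5)
  hi <- sweep(sampling_points, 2, half, "+")
  hi <- pmin(hi, matrix(dims + 0.5, np, 3, byrow = TRUE))

  pts <- as.matrix(cells[, c("x", "y", "z")])
  inlab <- rep(FALSE, nrow(pts))
  if (nrow(pts)) {
    vi <- pmin(pmax(round(pts), 1), matrix(dims, nrow(pts), 3, byrow = TRUE))
    inlab <- labels[vi] == layer
  }
  counts <- .count_in_boxes(pts[inlab, , drop = FALSE], lo, hi)

  # clipped volume: voxels of the layer inside each box, via a 3D
  # summed-area table over the layer indicator
  ilo <- matrix(as.integer(ceiling(lo - 0.5 + 1e-9)), np, 3)
  ihi <- matrix(as.integer(floor(hi - 0.5)), np, 3)
  storage.mode(labels) <- "integer"
  vol <- .box_label_volumes(labels, dim(labels), as.integer(layer), ilo, ihi)
  ok <- vol > 0
  if (any(!ok)) warning(sum(!ok), " sampling point(s) with zero clipped volume skipped")
  out <- tibble::tibble(x = sampling_points[ok, 1], y = sampling_points[ok, 2],
                        z = sampling_points[ok, 3], count = counts[ok],
                        clipped_volume = vol[ok],
                        density = counts[ok] / vol[ok])
  attr(out, "layer") <- layer
  attr(out, "box_edge") <- box_edge
  class(out) <- c("density_estimate", class(out))
  out
}

#' Percent density contrast between two layers
#'
#' `100 (mean(epi) - mean(derm)) / mean(derm)`: the percent excess of the
#' epidermal over the dermal cell density.
#'
#' @param epi,derm `density_estimate` tibbles from [layer_density()].
#' @return Scalar percent contrast.
#' @export
density_contrast <- function(epi, derm) {
  stopifnot(nrow(epi) > 0, nrow(derm) > 0)
  me <- mean(epi$density); md <- mean(derm$density)
  if (md == 0) stop("dermal density is zero; contrast undefined")
  100 * (me - md) / md
}
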