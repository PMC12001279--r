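#' Specification of a synthetic EdU-labelled two-layer volume
#'
#' Emulates a light-sheet volume of proliferating (EdU+) nuclei in a flat
#' two-layer tissue: an epidermis band on top of dermis along the z axis.
#' Nuclei are Poisson-placed Gaussian blobs; each layer has its own
#' density; Gaussian background noise is added.
#'
#' @param grid_shape Integer length-3 voxel dimensions.
#' @param epidermis_band_thickness Thickness of the epidermis band in
#'   voxels (the band occupies the top `z` slices).
#' @param dermal_density Expected nuclei per voxel^3 in the dermis.
#' @param epidermal_to_dermal_ratio Ratio of epidermal to dermal density;
#'   the default 1.23 reproduces the 23% higher epidermal proliferation
#'   measured in untreated E13 chicken toepads.
#' @param blob_sigma Gaussian radius of a nucleus in voxels (`>= 1`).
#' @param peak_intensity Blob amplitude.
#' @param background_sd Standard deviation of the additive Gaussian noise.
#' @param seed Integer seed; the generator is fully reproducible.
#' @return An object of class `edu_volume_spec`.
#' @export
edu_volume_spec <- function(grid_shape = c(200L, 200L, 200L),
                            epidermis_band_thickness = 100L,
                            dermal_density = 5e-5,
                            epidermal_to_dermal_ratio = 1.23,
                            blob_sigma = 2, peak_intensity = 1,
                            background_sd = 0.1, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8L),
            dermal_density >= 0, epidermal_to_dermal_ratio >= 0,
            blob_sigma >= 1, background_sd >= 0,
            epidermis_band_thickness >= 1,
            epidermis_band_thickness < grid_shape[3])
  if (any(grid_shape < 4 * blob_sigma))
    stop("each grid dimension must be at least 4 * blob_sigma")
  structure(list(grid_shape = grid_shape,
                 epidermis_band_thickness = as.integer(epidermis_band_thickness),
                 dermal_density = dermal_density,
                 epidermal_to_dermal_ratio = epidermal_to_dermal_ratio,
                 blob_sigma = blob_sigma, peak_intensity = peak_intensity,
                 background_sd = background_sd, seed = as.integer(seed)),
            class = "edu_volume_spec")
}

#' Generate a synthetic EdU volume with ground truth
#'
#' Draws Poisson counts for each layer at the specified densities, places
#' nucleus centres uniformly inside the layer, renders them as isotropic
#' Gaussian blobs, and adds Gaussian background noise. The epidermis band
#' is the top `epidermis_band_thickness` z-slices (label 1); the rest is
#' dermis (label 2).
#'
#' @param spec An [edu_volume_spec()].
#' @return A list with `intensity` (3D array), `labels` (3D integer array,
#'   1 = epidermis, 2 = dermis), and `centroids` (tibble `x, y, z, layer`
#'   of true nucleus centres, 1-based voxel coordinates).
#' @export
make_edu_volume <- function(spec) {
  stopifnot(inherits(spec, "edu_volume_spec"))
  d <- spec$grid_shape
  zsplit <- d[3] - spec$epidermis_band_thickness  # dermis: z <= zsplit
  old <- .Random.seed_safe()
  set.seed(spec$seed)
  on.exit(.Random.seed_restore(old))

  vol_epi <- as.numeric(d[1]) * d[2] * spec$epidermis_band_thickness
  vol_derm <- as.numeric(d[1]) * d[2] * zsplit
  rho_d <- spec$dermal_density
  rho_e <- rho_d * spec$epidermal_to_dermal_ratio
  n_e <- stats::rpois(1, rho_e * vol_epi)
  n_d <- stats::rpois(1, rho_d * vol_derm)

  draw <- function(n, zlo, zhi) {
    cbind(stats::runif(n, 0.5, d[1] + 0.5),
          stats::runif(n, 0.5, d[2] + 0.5),
          stats::runif(n, zlo, zhi))
  }
  ce <- draw(n_e, zsplit + 0.5, d[3] + 0.5)
  cd <- draw(n_d, 0.5, zsplit + 0.5)
  centers <- rbind(ce, cd)

  intensity <- stats::rnorm(prod(d), 0, spec$background_sd)
  dim(intensity) <- d
  if (nrow(centers) > 0)
    intensity <- .add_blobs_inplace(intensity, d, centers, spec$blob_sigma,
                                    spec$peak_intensity)
  labels <- rep(c(2L, 1L), c(as.double(d[1]) * d[2] * zsplit,
                             as.double(d[1]) * d[2] * spec$epidermis_band_thickness))
  dim(labels) <- d

  centroids <- tibble::tibble(
    x = centers[, 1], y = centers[, 2], z = centers[, 3],
    layer = rep(c(1L, 2L), c(n_e, n_d)))
  list(intensity = intensity, labels = labels, centroids = centroids)
}
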