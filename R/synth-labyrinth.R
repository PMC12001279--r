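#' Specification of a synthetic labyrinthine target network
#'
#' Band-pass-filtered seeded noise thresholded at a quantile and
#' skeletonized: a labyrinth of valleys with cycles and dead ends, used as
#' a stand-in target pattern for calibration tests.
#'
#' @param domain_size Square domain side length.
#' @param characteristic_wavelength Dominant wavelength of the pattern
#'   (`< domain_size`).
#' @param threshold_quantile Fraction of the field kept as "valley"
#'   (in (0, 1), default 0.35).
#' @param seed Integer seed.
#' @return An object of class `labyrinth_spec`.
#' @export
labyrinth_spec <- function(domain_size = 1, characteristic_wavelength = 0.15,
                           threshold_quantile = 0.35, seed = 1L) {
  stopifnot(domain_size > 0, characteristic_wavelength > 0,
            characteristic_wavelength < domain_size,
            threshold_quantile > 0, threshold_quantile < 1)
  structure(list(domain_size = domain_size,
                 characteristic_wavelength = characteristic_wavelength,
                 threshold_quantile = threshold_quantile,
                 seed = as.integer(seed)),
            class = "labyrinth_spec")
}

#' Generate a labyrinthine fold network
#'
#' White noise on a raster is band-passed with a difference of Gaussians
#' whose power peaks at the characteristic wavelength; the lowest
#' `threshold_quantile` of the field is skeletonized and traced into a
#' [fold_network()] with `toepad_length = domain_size`.
#'
#' @param spec A [labyrinth_spec()].
#' @param spur_fraction Spur pruning fraction (default 0.02).
#' @return A simplified, classified [fold_network()]. If the threshold is
#'   so extreme that no pattern survives, an empty network is returned
#'   with a warning.
#' @export
make_labyrinth_network <- function(spec, spur_fraction = 0.02) {
  stopifnot(inherits(spec, "labyrinth_spec"))
  px <- spec$characteristic_wavelength / 10
  n <- as.integer(ceiling(spec$domain_size / px))
  old <- .Random.seed_safe()
  set.seed(spec$seed)
  on.exit(.Random.seed_restore(old))

  noise <- array(stats::rnorm(n * n), c(n, n, 1L))
  # DoG band-pass: power peak at wavelength ~ 5.72 sigma1 (sigma2 = 1.6 sigma1)
  s1 <- (spec$characteristic_wavelength / px) / 5.72
  f <- .gauss_smooth3(noise, dim(noise), s1) -
       .gauss_smooth3(noise, dim(noise), 1.6 * s1)
  f <- f[, , 1]
  thr <- stats::quantile(f, spec$threshold_quantile, names = FALSE)
  img <- f < thr
  if (!any(img)) {
    warning("threshold too extreme: empty labyrinth network")
    return(classify_network_edges(fold_network(matrix(0, 0, 2), list(),
                                               spec$domain_size)))
  }
  skel <- .thin_raster(img)
  raw <- trace_skeleton(skel, px, 0, 0, spec$domain_size)
  net <- simplify_network(raw, spur_fraction)
  if (!length(net$edges))
    warning("threshold too extreme: empty labyrinth network")
  net
}
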