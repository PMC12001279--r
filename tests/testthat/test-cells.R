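test_that("signal curvatures are zero on constant volumes and isotropic at blob centres", {
  vol <- array(0.7, c(24, 24, 24))
  k <- signal_curvatures(vol, 2)
  expect_equal(max(abs(k$k1)), 0)
  expect_true(all(k$k1 >= k$k2 & k$k2 >= k$k3))

  # single Gaussian blob: at the centre k1 = k2 = k3 > 0
  s <- 2.5
  vol <- array(0, c(32, 32, 32))
  vol <- morphofold:::.add_blobs(vol, dim(vol), matrix(16, 1, 3), s, 1)
  k <- signal_curvatures(vol, 2)
  ctr <- which(k$k1 == max(k$k1), arr.ind = TRUE)[1, ]
  ks3 <- c(k$k1[ctr[1], ctr[2], ctr[3]], k$k2[ctr[1], ctr[2], ctr[3]],
           k$k3[ctr[1], ctr[2], ctr[3]])
  expect_true(all(ks3 > 0))
  expect_lt(diff(range(ks3)) / mean(ks3), 0.05)
  # the smoothed blob has sd^2 = s^2 + sigma^2; peak curvature = A' / (s^2+sigma^2)
  s2 <- s^2 + 2^2
  amp <- (s^2 / s2)^(3 / 2)            # amplitude after extra smoothing
  expect_equal(mean(ks3), amp / s2, tolerance = 0.05)
})

test_that("a bright sheet has one large curvature and two near zero", {
  vol <- array(0, c(24, 24, 24))
  z <- rep(1:24, each = 24 * 24)
  vol[] <- exp(-(z - 12.5)^2 / (2 * 2^2))
  k <- signal_curvatures(vol, 1.5)
  mid <- k$k1[12, 12, 12:13]
  expect_true(all(mid > 0))
  expect_lt(max(abs(k$k2[12, 12, 12:13])) / max(mid), 0.05)
})

test_that("blob score is the geometric mean of positive parts", {
  k <- list(k1 = array(8, c(2, 2, 2)), k2 = array(1, c(2, 2, 2)),
            k3 = array(1, c(2, 2, 2)))
  expect_equal(blob_score(k), array(2, c(2, 2, 2)))
  k$k3[] <- -0.1
  expect_equal(max(blob_score(k)), 0)
  k2 <- list(k1 = array(1, c(2, 2, 2)), k2 = array(1, c(2, 2, 2)),
             k3 = array(1, c(2, 2, 2)))
  expect_equal(blob_score(k2), array(1, c(2, 2, 2)))
})

test_that("blob score scales linearly with intensity", {
  set.seed(3)
  vol <- array(rnorm(20^3, 1, 0.2), c(20, 20, 20))
  ks1 <- morphofold:::blob_score_volume(vol, 1.5)
  ks3 <- morphofold:::blob_score_volume(3 * vol, 1.5)
  expect_equal(ks3, 3 * ks1, tolerance = 1e-10)
})

test_that("detection finds isolated blobs and nothing in noise", {
  thr <- calibrate_k_threshold(peak = 1, blob_sigma = 2, smoothing_sigma = 2)
  vol <- array(0, c(40, 40, 40))
  truthc <- matrix(c(14.2, 20.7, 18.9), 1, 3)
  vol <- morphofold:::.add_blobs(vol, dim(vol), truthc, 2, 1)
  set.seed(5)
  vol <- vol + array(rnorm(length(vol), 0, 0.1), dim(vol))
  cells <- detect_cells(vol, 2, thr)
  expect_identical(nrow(cells), 1L)
  expect_lt(sqrt(sum((as.numeric(cells[1, 1:3]) - truthc)^2)), 1)

  # two blobs >= 6 sd apart resolve into two centroids
  two <- matrix(c(12, 12, 12, 12 + 13, 12, 12), 2, 3, byrow = TRUE)
  vol2 <- morphofold:::.add_blobs(array(0, c(40, 40, 40)), c(40L, 40L, 40L),
                                  two, 2, 1)
  cells2 <- detect_cells(vol2, 2, thr)
  expect_identical(nrow(cells2), 2L)

  # pure noise at a conservative threshold: nothing
  set.seed(6)
  noise <- array(rnorm(40^3, 0, 0.1), c(40, 40, 40))
  expect_identical(nrow(detect_cells(noise, 2, thr)), 0L)
})

test_that("detection F1 >= 0.95 at 6-sigma separation and SNR >= 5 over seeds", {
  thr <- calibrate_k_threshold(peak = 1, blob_sigma = 2, smoothing_sigma = 2)
  f1s <- vapply(1:5, function(sd) {
    v <- make_edu_volume(edu_volume_spec(
      grid_shape = c(96L, 96L, 96L), epidermis_band_thickness = 48L,
      dermal_density = 2e-5, epidermal_to_dermal_ratio = 1,
      blob_sigma = 2, peak_intensity = 1, background_sd = 0.2, seed = sd))
    cells <- detect_cells(v$intensity, 2, thr)
    truthc <- as.matrix(v$centroids[, c("x", "y", "z")])
    if (nrow(truthc) == 0) return(1)
    found <- as.matrix(cells[, c("x", "y", "z")])
    # greedy matching within 3 voxels
    used <- rep(FALSE, nrow(found))
    tp <- 0
    for (i in seq_len(nrow(truthc))) {
      if (!nrow(found)) break
      dd <- sqrt(colSums((t(found) - truthc[i, ])^2))
      j <- which.min(ifelse(used, Inf, dd))
      if (is.finite(dd[j]) && dd[j] < 3 && !used[j]) { used[j] <- TRUE; tp <- tp + 1 }
    }
    prec <- tp / max(nrow(found), 1)
    rec <- tp / nrow(truthc)
    2 * prec * rec / max(prec + rec, 1e-9)
  }, 0)
  expect_gte(mean(f1s), 0.95)
})

test_that("clipped-box density estimation is unbiased on Poisson fields", {
  # estimator property: use true centroids directly (no detection)
  dims <- c(120L, 120L, 120L)
  labels <- array(2L, dims); labels[, , 61:120] <- 1L
  rho <- 2e-4
  rel_bias <- vapply(1:20, function(sd) {
    set.seed(sd)
    n <- rpois(1, rho * prod(dims))
    pts <- tibble::tibble(x = runif(n, 0.5, dims[1] + 0.5),
                          y = runif(n, 0.5, dims[2] + 0.5),
                          z = runif(n, 0.5, dims[3] + 0.5), size = 1L)
    d1 <- layer_density(pts, labels, 1L, box_edge = 80)
    d2 <- layer_density(pts, labels, 2L, box_edge = 80)
    (mean(c(d1$density, d2$density)) - rho) / rho
  }, 0)
  expect_lt(abs(mean(rel_bias)), 0.02)

  # homogeneous field: mean density inside 95% CI of rho
  set.seed(77)
  n <- rpois(1, rho * prod(dims))
  pts <- tibble::tibble(x = runif(n, 0.5, dims[1] + 0.5),
                        y = runif(n, 0.5, dims[2] + 0.5),
                        z = runif(n, 0.5, dims[3] + 0.5), size = 1L)
  est <- layer_density(pts, labels, 2L, box_edge = 80)
  se <- sqrt(n) / prod(dims)    # Poisson CI on the total count
  expect_lt(abs(mean(est$density) - rho), 2.5 * se)
})

test_that("density at a flat layer boundary is unbiased (count and volume halve)", {
  dims <- c(100L, 100L, 100L)
  labels <- array(2L, dims); labels[, , 51:100] <- 1L
  set.seed(8)
  rho <- 5e-4
  n <- rpois(1, rho * prod(dims))
  pts <- tibble::tibble(x = runif(n, 0.5, dims[1] + 0.5),
                        y = runif(n, 0.5, dims[2] + 0.5),
                        z = runif(n, 0.5, dims[3] + 0.5), size = 1L)
  # sampling point exactly on the boundary plane: clipped volume is half a box
  bpt <- matrix(c(50, 50, 50.5), 1, 3)
  est <- layer_density(pts, labels, 1L, box_edge = 40, sampling_points = bpt)
  expect_equal(est$clipped_volume, 40 * 40 * 20)
  expect_lt(abs(est$density - rho) / rho, 0.5)   # single box, Poisson noise
})

test_that("density contrast formula and errors", {
  d1 <- tibble::tibble(density = c(1, 1.2, 1.1) * 1e-4)
  d2 <- tibble::tibble(density = c(1, 1.2, 1.1) * 1e-4)
  expect_equal(density_contrast(d1, d2), 0)
  d3 <- tibble::tibble(density = d2$density * 1.23)
  expect_equal(density_contrast(d3, d2), 23, tolerance = 1e-10)
  d4 <- tibble::tibble(density = d2$density * 0.5)
  expect_equal(density_contrast(d4, d2), -50, tolerance = 1e-10)
  expect_error(density_contrast(d1, tibble::tibble(density = 0)), "zero")
})

test_that("edu volume generator: Poisson counts, ratio, determinism, empty case", {
  sp <- edu_volume_spec(grid_shape = c(64L, 64L, 64L),
                        epidermis_band_thickness = 32L,
                        dermal_density = 1e-4, epidermal_to_dermal_ratio = 2,
                        seed = 3)
  v1 <- make_edu_volume(sp)
  v2 <- make_edu_volume(sp)
  expect_identical(v1, v2)
  # counts within 4 sqrt(rho V) of rho V
  Vd <- 64 * 64 * 32
  nd <- sum(v1$centroids$layer == 2L)
  expect_lt(abs(nd - 1e-4 * Vd), 4 * sqrt(1e-4 * Vd) + 1)
  # ratio over 10 seeds
  ratios <- vapply(1:10, function(sd) {
    v <- make_edu_volume(edu_volume_spec(
      grid_shape = c(64L, 64L, 64L), epidermis_band_thickness = 32L,
      dermal_density = 2e-4, epidermal_to_dermal_ratio = 2, seed = sd))
    sum(v$centroids$layer == 1L) / sum(v$centroids$layer == 2L)
  }, 0)
  expect_equal(mean(ratios), 2, tolerance = 0.1)
  # zero densities: flat noise, no centroids
  v0 <- make_edu_volume(edu_volume_spec(grid_shape = c(16L, 16L, 16L),
                                        epidermis_band_thickness = 8L,
                                        dermal_density = 0,
                                        epidermal_to_dermal_ratio = 0, seed = 1))
  expect_identical(nrow(v0$centroids), 0L)
  expect_lt(max(abs(v0$intensity)), 1)   # noise only
})

test_that("per-layer counts are Poisson-consistent (dispersion test)", {
  counts <- vapply(1:20, function(sd) {
    v <- make_edu_volume(edu_volume_spec(
      grid_shape = c(48L, 48L, 48L), epidermis_band_thickness = 24L,
      dermal_density = 3e-4, epidermal_to_dermal_ratio = 1.5, seed = sd))
    sum(v$centroids$layer == 2L)
  }, 0)
  # index of dispersion ~ chi2(n-1)/(n-1) under Poisson
  disp <- var(counts) / mean(counts) * (length(counts) - 1)
  lim <- qchisq(c(0.005, 0.995), df = length(counts) - 1)
  expect_gt(disp, lim[1])
  expect_lt(disp, lim[2])
})
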