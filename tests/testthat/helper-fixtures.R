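# Shared fixtures, computed once per test session. The wrinkling slab and
# the treated-dome runs are the expensive ones; several test files reuse
# them.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (is.null(.fx[[name]])) .fx[[name]] <- fn()
  .fx[[name]]
}

# structured-grid plane surface z = f(x, y) on [0,1]^2
grid_surface <- function(n = 41, f = function(x, y) rep(0, length(x))) {
  xs <- seq(0, 1, length.out = n)
  g <- expand.grid(x = xs, y = xs)
  id <- function(i, j) i + n * (j - 1)
  tris <- matrix(0L, 0, 3)
  for (j in seq_len(n - 1)) {
    i <- seq_len(n - 1)
    tris <- rbind(tris,
                  cbind(id(i, j), id(i + 1, j), id(i, j + 1)),
                  cbind(id(i + 1, j), id(i + 1, j + 1), id(i, j + 1)))
  }
  surface_mesh(cbind(g$x, g$y, f(g$x, g$y)), tris)
}

# stiff-film bilayer slab driven past wrinkling onset (shared by the
# mechanics tests and the acceptance suite)
wrinkle_run <- function() fixture("wrinkle", function() {
  lam_cl <- 2 * pi * 0.05 * (30 / 3)^(1 / 3)
  mesh <- make_bilayer_slab(
    bilayer_slab_spec(5 * lam_cl, 0.05, 0.05, 0.4, 0.025), clamp_sides = "x")
  mat <- list(epidermis = elastic_constants(30, 0.3),
              dermis = elastic_constants(1, 0.3))
  g <- list(epidermis = growth_law(0, 0.12), dermis = growth_law(0, 0))
  cfg <- solver_config(time_step = 0.3, force_tolerance = 1e-5,
                       max_steps = 100000, damping_coefficient = 0.2,
                       growth_ramp_end = 1200)
  state <- relax_to_steady_state(mesh, mat, g, cfg, seed = 1)
  list(mesh = mesh, state = state, lam_classical = lam_cl)
})

# surface height profile (mean over y) and its dominant wavelength
wrinkle_wavelength <- function(mesh, state) {
  idx <- which(abs(mesh$nodes[, 3]) < 1e-9)
  h <- tapply(state$positions[idx, 3], mesh$nodes[idx, 1], mean)
  xs <- as.numeric(names(h)); o <- order(xs)
  h <- as.numeric(h)[o]; xs <- xs[o]
  hc <- h - mean(h)
  P <- (Mod(stats::fft(hc))[2:floor(length(hc) / 2)])^2
  kmax <- min(length(P), 15)
  kbar <- sum(seq_len(kmax) * P[seq_len(kmax)]) / sum(P[seq_len(kmax)])
  diff(range(xs)) / kbar
}

# coarse treated-parameter dome, one relaxation per seed
dome_mesh <- function() fixture("dome_mesh", function()
  make_toepad_dome(toepad_dome_spec(0.9, 0.55, 0.1, 0.25, 0.1)))

dome_config <- function() solver_config(
  time_step = 0, force_tolerance = 2e-5, max_steps = 30000,
  damping_coefficient = 0.3, growth_ramp_end = 250,
  contact_stiffness = 2, contact_range = 0.05)

treated_params <- list(E_epi = 3, nu_epi = 0.35, nu_derm = 0.15,
                       lambda_T_epi = 1.55, lambda_T_derm = 1.2)

dome_run <- function(seed, params = treated_params) {
  fixture(paste0("dome_run_", seed, "_", paste(unlist(params), collapse = "_")),
          function() {
    mat <- list(epidermis = elastic_constants(params$E_epi, params$nu_epi),
                dermis = elastic_constants(1, params$nu_derm))
    g <- list(epidermis = growth_law(0, params$lambda_T_epi),
              dermis = growth_law(0, params$lambda_T_derm))
    relax_to_steady_state(dome_mesh(), mat, g, dome_config(), seed = seed)
  })
}

dome_metrics <- function(seed, params = treated_params) {
  fold_pipeline(dome_run(seed, params)$surface, quantile = 0.55,
                spur_fraction = 0.02, pixel_size = 0.035)$metrics
}

# random elastic deformation gradients with positive determinant
random_Fe <- function(n, spread = 0.35, seed = 1) {
  set.seed(seed)
  out <- vector("list", n)
  i <- 1
  while (i <= n) {
    Fe <- diag(3) + matrix(stats::rnorm(9, 0, spread), 3)
    if (det(Fe) > 0.15) { out[[i]] <- Fe; i <- i + 1 }
  }
  out
}

# central finite differences of the strain energy: sigma = (1/J) dPsi/dFe Fe^T
fd_cauchy <- function(Fe, mu, K, h = 1e-6) {
  P <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    Fp <- Fe; Fp[i, j] <- Fp[i, j] + h
    Fm <- Fe; Fm[i, j] <- Fm[i, j] - h
    P[i, j] <- (strain_energy(Fp, mu, K) - strain_energy(Fm, mu, K)) / (2 * h)
  }
  (P %*% t(Fe)) / det(Fe)
}

# EdU recovery experiment shared by the cells tests and acceptance
edu_contrast_run <- function(seeds = 1:5) {
  fixture(paste0("edu_contrast_", paste(seeds, collapse = "-")), function() {
    thr <- calibrate_k_threshold(peak = 1, blob_sigma = 2,
                                 smoothing_sigma = 2)
    contrasts <- vapply(seeds, function(s) {
      v <- make_edu_volume(edu_volume_spec(
        grid_shape = c(576L, 576L, 256L), epidermis_band_thickness = 128L,
        dermal_density = 5e-5, epidermal_to_dermal_ratio = 1.23,
        blob_sigma = 2, peak_intensity = 1, background_sd = 0.1, seed = s))
      cells <- detect_cells(v$intensity, smoothing_sigma = 2,
                            k_threshold = thr)
      epi <- layer_density(cells, v$labels, 1L, box_edge = 80)
      derm <- layer_density(cells, v$labels, 2L, box_edge = 80)
      density_contrast(epi, derm)
    }, 0)
    contrasts
  })
}
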