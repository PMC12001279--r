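test_that("principal curvature matches analytic surfaces", {
  s <- icosphere(3, 1)
  cv <- min_principal_curvature(s)
  expect_true(all(abs(cv$kappa_min - 1) < 0.05))

  plane <- grid_surface(31)
  cvp <- min_principal_curvature(plane)
  expect_lt(max(abs(cvp$kappa_min)), 1e-8)

  A <- 0.02; k <- 2 * pi * 2
  sine <- grid_surface(51, function(x, y) A * sin(k * x))
  cvs <- min_principal_curvature(sine)
  troughs <- abs(sin(k * sine$vertices[, 1]) + 1) < 0.02 & !cvs$boundary
  expect_equal(mean(cvs$kappa_min[troughs]), -A * k^2, tolerance = 0.05)
})

test_that("curvature estimation rejects non-manifold surfaces", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1))
  tr <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5))   # edge 1-2 in 3 triangles
  expect_error(min_principal_curvature(surface_mesh(v, tr)), "non-manifold")
})

test_that("fold mask selects concave vertices below the quantile", {
  plane <- grid_surface(31)
  cvp <- min_principal_curvature(plane)
  expect_false(any(extract_fold_mask(cvp, 0.3)))   # nothing below zero

  A <- 0.02; k <- 2 * pi * 2
  sine <- grid_surface(51, function(x, y) A * sin(k * x))
  cvs <- min_principal_curvature(sine)
  m <- extract_fold_mask(cvs, 0.3)
  expect_lte(mean(m), 0.3 + 1e-9)
  # mask bands centred on the troughs
  ph <- sin(k * sine$vertices[, 1])
  expect_gt(mean(ph[m] < -0.5), 0.95)
})

test_that("skeletonization recovers a straight band and an annulus", {
  # straight valley along y = 0.5
  sine1 <- grid_surface(61, function(x, y) -0.05 * cos(2 * pi * (y - 0.5)))
  cv <- min_principal_curvature(sine1)
  mask <- extract_fold_mask(cv, 0.12)
  net <- skeletonize_fold_mask(sine1, mask, "z")
  net <- simplify_network(net, 0.05)
  lens <- vapply(net$edges, function(e) e$length, 0)
  e <- net$edges[[which.max(lens)]]
  # interior of the traced midline follows the trough (endpoints snap to
  # junction-cluster centroids and may sit a few cells off)
  mid <- e$path[4:(nrow(e$path) - 3), 2]
  expect_lt(max(abs(mid - 0.5)), 0.03)
  expect_equal(e$length, 1, tolerance = 0.12)

  # annular Gaussian valley centred on radius r0
  r0 <- 0.3
  dome <- grid_surface(81, function(x, y) {
    r <- sqrt((x - 0.5)^2 + (y - 0.5)^2)
    -0.03 * exp(-((r - r0) / 0.08)^2)
  })
  cv2 <- min_principal_curvature(dome)
  mask2 <- extract_fold_mask(cv2, 0.2)
  net2 <- simplify_network(skeletonize_fold_mask(dome, mask2, "z"), 0.05)
  expect_gte(length(net2$cycles), 1L)
  # skeleton follows the mid-radius of the masked band
  rmask <- sqrt((dome$vertices[mask2, 1] - 0.5)^2 +
                (dome$vertices[mask2, 2] - 0.5)^2)
  per <- sum(vapply(net2$cycles[[1]], function(i) net2$edges[[i]]$length, 0))
  expect_equal(per, 2 * pi * mean(rmask), tolerance = 0.05)

  # empty mask: empty network
  net0 <- skeletonize_fold_mask(sine1, rep(FALSE, nrow(sine1$vertices)), "z")
  expect_identical(length(net0$edges), 0L)
})

test_that("simplification merges chains, prunes spurs, and is idempotent", {
  # chain of 100 degree-2 nodes
  n <- 101
  nodes <- cbind(seq(0, 1, length.out = n), 0)
  edges <- lapply(seq_len(n - 1), function(i)
    list(from = i, to = i + 1, path = nodes[c(i, i + 1), , drop = FALSE],
         length = 1 / (n - 1)))
  net <- fold_network(nodes, edges, 1)
  s1 <- simplify_network(net, 0.02)
  expect_identical(length(s1$edges), 1L)
  expect_equal(s1$edges[[1]]$length, 1, tolerance = 1e-9)

  # square cycle with one short spur: spur pruned, cycle intact
  nd <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(1.05, 0))
  mke <- function(f, t) list(from = f, to = t,
                             path = nd[c(f, t), , drop = FALSE],
                             length = sqrt(sum((nd[f, ] - nd[t, ])^2)))
  net2 <- fold_network(nd, list(mke(1, 2), mke(2, 3), mke(3, 4), mke(4, 1),
                                mke(2, 5)), 4)
  s2 <- simplify_network(net2, 0.02)
  expect_identical(length(s2$cycles), 1L)
  expect_identical(length(s2$incomplete), 0L)
  expect_equal(network_length(s2), 4, tolerance = 1e-9)

  # idempotence
  s3 <- simplify_network(s2, 0.02)
  expect_equal(compute_metrics(s3), compute_metrics(s2))
  expect_identical(length(s3$edges), length(s2$edges))
})

test_that("metrics match their definitions exactly", {
  empty <- fold_network(matrix(0, 0, 2), list(), 5)
  expect_equal(as.numeric(compute_metrics(empty)), c(0, 0))

  s <- 0.7; L <- 3
  nd <- rbind(c(0, 0), c(s, 0), c(s, s), c(0, s))
  mke <- function(f, t) list(from = f, to = t,
                             path = nd[c(f, t), , drop = FALSE], length = s)
  sq <- fold_network(nd, list(mke(1, 2), mke(2, 3), mke(3, 4), mke(4, 1)), L)
  expect_equal(as.numeric(compute_metrics(sq)), c(4 * s / L, 0))

  p <- 1.3
  nd2 <- rbind(c(0, 0), c(p, 0))
  path <- fold_network(nd2, list(list(from = 1, to = 2, path = nd2,
                                      length = p)), L)
  expect_equal(as.numeric(compute_metrics(path)), c(0, p / L))
})

test_that("a shared edge contributes to both adjacent domains", {
  # two unit squares sharing one edge
  nd <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(2, 0), c(2, 1))
  mke <- function(f, t) list(from = f, to = t,
                             path = nd[c(f, t), , drop = FALSE],
                             length = sqrt(sum((nd[f, ] - nd[t, ])^2)))
  net <- fold_network(nd, list(mke(1, 2), mke(2, 3), mke(3, 4), mke(4, 1),
                               mke(2, 5), mke(5, 6), mke(6, 3)), 1)
  net <- classify_network_edges(net)
  expect_identical(length(net$cycles), 2L)
  mv <- compute_metrics(net)
  expect_equal(as.numeric(mv), c(8, 0))   # 4 + 4, shared edge counted twice
})

test_that("metrics are invariant to rigid motion and to uniform scaling", {
  lab <- make_labyrinth_network(labyrinth_spec(1, 0.18, 0.5, seed = 4))
  m0 <- compute_metrics(lab)
  th <- 0.6; R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  moved <- lab
  moved$nodes <- lab$nodes %*% t(R) + 2
  moved$edges <- lapply(lab$edges, function(e) {
    e$path <- e$path %*% t(R) + 2; e
  })
  expect_equal(compute_metrics(classify_network_edges(moved)), m0,
               tolerance = 1e-9)
  scaled <- lab
  scaled$nodes <- lab$nodes * 3
  scaled$toepad_length <- lab$toepad_length * 3
  scaled$edges <- lapply(lab$edges, function(e) {
    e$path <- e$path * 3; e$length <- e$length * 3; e
  })
  expect_equal(compute_metrics(classify_network_edges(scaled)), m0,
               tolerance = 1e-9)
})

test_that("normalizer centres the fitting set and distances behave metrically", {
  set.seed(10)
  samples <- lapply(1:6, function(i) c(runif(1, 0, 2), runif(1, 0, 3)))
  nm <- fit_normalizer(samples)
  normed <- vapply(samples, function(v) normalize_metrics(v, nm), c(0, 0))
  expect_equal(rowMeans(normed), c(c1 = 0, c2 = 0), tolerance = 1e-12)
  expect_equal(apply(normed, 1, sd), c(1, 1), tolerance = 1e-12,
               ignore_attr = TRUE)
  # identity normalizer
  id <- structure(list(mean = c(0, 0), sd = c(1, 1)),
                  class = "metric_normalizer")
  expect_equal(as.numeric(normalize_metrics(c(0.3, 0.8), id)), c(0.3, 0.8))
  expect_equal(as.numeric(normalize_metrics(nm$mean, nm)), c(0, 0))
  expect_error(fit_normalizer(samples[1]), "at least 2")
  expect_error(fit_normalizer(list(c(1, 1), c(1, 2))), "zero inter-sample")

  a <- c(1, 2); b <- c(0.5, 1); cc <- c(2, 0.2)
  expect_equal(network_distance(a, a, nm), 0)
  expect_equal(network_distance(a, b, nm), network_distance(b, a, nm))
  for (i in 1:20) {
    x <- runif(2, 0, 3); y <- runif(2, 0, 3); z <- runif(2, 0, 3)
    expect_lte(network_distance(x, z, nm),
               network_distance(x, y, nm) + network_distance(y, z, nm) + 1e-12)
  }
})

test_that("layer thickness matches analytic gaps", {
  out <- icosphere(3, 1)
  inn <- icosphere(3, 0.9)
  th <- layer_thickness(out, inn)
  expect_equal(mean(th), 0.1, tolerance = 0.02)
  expect_true(all(abs(th - 0.1) < 0.02 * 1))
  expect_equal(max(layer_thickness(out, out)), 0)
  p1 <- grid_surface(21)
  p2 <- grid_surface(21, function(x, y) rep(-0.37, length(x)))
  expect_equal(layer_thickness(p1, p2), rep(0.37, nrow(p1$vertices)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("labyrinth generator is seeded and wavelength controls total length", {
  sp <- labyrinth_spec(1, 0.15, 0.4, seed = 9)
  l1 <- make_labyrinth_network(sp)
  l2 <- make_labyrinth_network(sp)
  expect_identical(l1, l2)
  mv <- compute_metrics(l1)
  expect_true(all(mv >= 0))
  # halving the wavelength increases total network length (5 seeds)
  longer <- vapply(1:5, function(sd) {
    a <- network_length(make_labyrinth_network(labyrinth_spec(1, 0.2, 0.4, seed = sd)))
    b <- network_length(make_labyrinth_network(labyrinth_spec(1, 0.1, 0.4, seed = sd)))
    b > a
  }, TRUE)
  expect_true(all(longer))
  # extreme threshold: empty network with a warning, not an error
  expect_warning(
    e0 <- make_labyrinth_network(labyrinth_spec(1, 0.2, 1e-6, seed = 1)),
    "empty")
  expect_identical(length(e0$edges), 0L)
})

test_that("fold pipeline: wrinkled slab has c1 + c2 > 0, unbuckled slab gives (0,0)", {
  w <- wrinkle_run()
  mv <- fold_pipeline(w$state$surface, quantile = 0.3)$metrics
  expect_gt(sum(mv), 0)

  # unbuckled slab: quantile masking alone would select numerical
  # curvature noise (folds have |kappa| ~ 1/h; residual ripples are orders
  # of magnitude flatter), so a floor of 1/(10 h) accompanies the quantile
  mesh <- make_bilayer_slab(bilayer_slab_spec(1.5, 0.05, 0.05, 0.3, 0.025))
  mat <- list(epidermis = elastic_constants(30, 0.3),
              dermis = elastic_constants(1, 0.3))
  g0 <- list(epidermis = growth_law(0, 0), dermis = growth_law(0, 0))
  s0 <- relax_to_steady_state(mesh, mat, g0,
                              solver_config(force_tolerance = 1e-7),
                              seed = 1)
  mv0 <- fold_pipeline(s0$surface, quantile = 0.3,
                       min_curvature = 1 / (10 * 0.05))$metrics
  expect_equal(as.numeric(mv0), c(0, 0))

  # growth below the wrinkling onset: still smooth, still empty
  g1 <- list(epidermis = growth_law(0, 0.01), dermis = growth_law(0, 0))
  s1 <- relax_to_steady_state(mesh, mat, g1,
                              solver_config(time_step = 0.3,
                                            force_tolerance = 1e-5,
                                            max_steps = 60000,
                                            damping_coefficient = 0.2),
                              seed = 1)
  mv1 <- fold_pipeline(s1$surface, quantile = 0.3,
                       min_curvature = 1 / (10 * 0.05))$metrics
  expect_equal(as.numeric(mv1), c(0, 0))
})
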