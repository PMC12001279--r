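test_that("assembled forces are the negative energy gradient", {
  set.seed(42)
  m <- make_bilayer_slab(bilayer_slab_spec(0.3, 0.3, 0.1, 0.2, 0.1))
  mat <- list(epidermis = elastic_constants(5, 0.3),
              dermis = elastic_constants(1, 0.2))
  g <- list(epidermis = growth_law(0.05, 0.1), dermis = growth_law(0, 0.02))
  x <- m$nodes + matrix(rnorm(length(m$nodes), 0, 0.005), ncol = 3)
  r <- assemble_internal_forces(m, x, mat, g, t = 2)
  en <- function(x) assemble_internal_forces(m, x, mat, g, t = 2)$energy
  h <- 1e-6
  for (i in sample(nrow(x), 5)) for (j in 1:3) {
    xp <- x; xp[i, j] <- xp[i, j] + h
    xm <- x; xm[i, j] <- xm[i, j] - h
    fd <- -(en(xp) - en(xm)) / (2 * h)
    expect_equal(r$forces[i, j], fd, tolerance = 1e-5)
  }
})

test_that("free bodies feel zero net force and torque; stress-free states no force", {
  m <- make_bilayer_slab(bilayer_slab_spec(0.3, 0.3, 0.1, 0.2, 0.1))
  mat <- list(epidermis = elastic_constants(2, 0.25),
              dermis = elastic_constants(1, 0.25))
  g <- list(epidermis = growth_law(0, 0.3), dermis = growth_law(0, 0.1))
  set.seed(7)
  x <- m$nodes + matrix(rnorm(length(m$nodes), 0, 0.01), ncol = 3)
  r <- assemble_internal_forces(m, x, mat, g, t = 3)
  scale <- max(abs(r$forces))
  expect_lt(max(abs(colSums(r$forces))) / scale, 1e-8)
  torque <- colSums(cbind(
    x[, 2] * r$forces[, 3] - x[, 3] * r$forces[, 2],
    x[, 3] * r$forces[, 1] - x[, 1] * r$forces[, 3],
    x[, 1] * r$forces[, 2] - x[, 2] * r$forces[, 1]))
  expect_lt(max(abs(torque)) / scale, 1e-8)

  # stress-free reference: zero forces; rigid rotation: still zero
  g0 <- list(epidermis = growth_law(0, 0), dermis = growth_law(0, 0))
  r0 <- assemble_internal_forces(m, m$nodes, mat, g0, t = 5)
  expect_lt(max(abs(r0$forces)), 1e-10)
  th <- 0.4
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rR <- assemble_internal_forces(m, m$nodes %*% t(R), mat, g0, t = 5)
  expect_lt(max(abs(rR$forces)), 1e-8)
})

test_that("single-tet forces match the hand-assembled traction integral", {
  # unit right tet, homogeneous stretch along x
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  tets <- matrix(1:4, 1)
  mesh <- layered_tet_mesh(nodes, tets, "dermis", integer(0),
                           matrix(c(0, 0, 1), 1), matrix(c(1, 3, 2), 1), TRUE)
  mat <- list(epidermis = elastic_constants(1, 0.2),
              dermis = elastic_constants(1, 0.2))
  g <- list(epidermis = growth_law(0, 0), dermis = growth_law(0, 0))
  a <- 1.3
  x <- nodes %*% diag(c(a, 1, 1))
  r <- assemble_internal_forces(mesh, x, mat, g)
  # hand assembly: f_a = -V0 P grad(N_a); F = diag(a,1,1), P = J sigma F^-T
  Fdef <- diag(c(a, 1, 1))
  sig <- cauchy_stress(Fdef, mat$dermis$mu, mat$dermis$K)
  P <- det(Fdef) * sig %*% t(solve(Fdef))
  V0 <- 1 / 6
  grads <- rbind(c(-1, -1, -1), diag(3))   # shape gradients of the unit tet
  expect_equal(r$forces, -V0 * grads %*% t(P), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("contact forces are zero when separated and antisymmetric in contact", {
  # two parallel triangle patches
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
             c(0, 0, 1), c(1, 0, 1), c(0, 1, 1))
  tris <- rbind(c(1, 2, 3), c(4, 6, 5))
  cfg <- solver_config(contact_stiffness = 10, contact_range = 0.2)
  f_far <- contact_forces(v, tris, cfg)
  expect_equal(max(abs(f_far)), 0)
  v2 <- v; v2[4:6, 3] <- 0.1            # inside contact range
  f <- contact_forces(v2, tris, cfg)
  expect_gt(max(abs(f)), 0)
  expect_lt(max(abs(colSums(f))), 1e-12)            # action = reaction
  expect_true(all(f[4:6, 3] >= 0) && all(f[1:3, 3] <= 0))  # repulsive along z
})

test_that("zero growth is a fixed point of the relaxation", {
  m <- make_bilayer_slab(bilayer_slab_spec(0.4, 0.4, 0.1, 0.3, 0.1))
  mat <- list(epidermis = elastic_constants(1, 0.2),
              dermis = elastic_constants(1, 0.2))
  g0 <- list(epidermis = growth_law(0, 0), dermis = growth_law(0, 0))
  s <- relax_to_steady_state(m, mat, g0,
                             solver_config(force_tolerance = 1e-8), seed = 1)
  expect_lt(max(abs(s$positions - m$nodes)), 1e-8)
})

test_that("uniform free growth rescales a free body stress-free", {
  m <- make_bilayer_slab(bilayer_slab_spec(0.4, 0.4, 0.1, 0.3, 0.1))
  m$fixed_nodes <- integer(0)
  mat <- list(epidermis = elastic_constants(1, 0.2),
              dermis = elastic_constants(1, 0.2))
  lam <- 0.3
  g <- list(epidermis = growth_law(lam, lam), dermis = growth_law(lam, lam))
  s <- relax_to_steady_state(
    m, mat, g, solver_config(force_tolerance = 1e-6, max_steps = 200000,
                             damping_coefficient = 0.3), seed = 1)
  sfac <- 1 + lam * (1 - exp(-s$t))
  ext <- apply(s$positions, 2, function(z) diff(range(z)))
  expect_equal(ext, c(0.4, 0.4, 0.4) * sfac, tolerance = 0.01)
  expect_lt(max(abs(s$sigma)), 1e-3 * mat$dermis$E)
})

test_that("energy decreases monotonically once growth is frozen", {
  w <- wrinkle_run()
  lg <- w$state$log
  post <- lg[lg$time > 30, ]   # growth is saturated well before this
  expect_true(all(diff(post$energy) <= 1e-6 * abs(post$energy[1])))
})

test_that("wrinkling wavelength matches the film-on-substrate closed form", {
  w <- wrinkle_run()
  lam <- wrinkle_wavelength(w$mesh, w$state)
  expect_lt(abs(lam / w$lam_classical - 1), 0.2)
})

test_that("deep folding completes without surface self-intersection", {
  s <- dome_run(1)
  surf <- s$surface
  expect_identical(morphofold:::.self_intersections(surf$vertices,
                                                    surf$triangles), 0L)
})

test_that("non-convergence raises an error carrying the residual history", {
  m <- make_bilayer_slab(bilayer_slab_spec(0.4, 0.4, 0.1, 0.2, 0.1))
  mat <- list(epidermis = elastic_constants(2, 0.3),
              dermis = elastic_constants(1, 0.3))
  g <- list(epidermis = growth_law(0, 0.5), dermis = growth_law(0, 0.2))
  err <- tryCatch(
    relax_to_steady_state(m, mat, g,
                          solver_config(force_tolerance = 1e-14,
                                        max_steps = 200), seed = 1),
    error = function(e) e)
  expect_s3_class(err, "morphofold_no_convergence")
  expect_true(length(err$residual_history) > 0)
})
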