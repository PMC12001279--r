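test_that("moduli follow the isotropic conversion formulas", {
  m <- compute_moduli(1, 0.15)
  expect_equal(m$mu, 0.4347826, tolerance = 1e-6)
  expect_equal(m$K, 0.4761905, tolerance = 1e-6)
  m2 <- compute_moduli(3, 0.35)       # treated epidermis values
  expect_equal(m2$mu, 1.111111, tolerance = 1e-6)
  expect_equal(m2$K, 3.333333, tolerance = 1e-6)
  expect_error(compute_moduli(1, 0.4999999999), "incompressible")
  expect_error(compute_moduli(-1, 0.3), "positive")
  expect_warning(compute_moduli(1, 0.46), "0.45")
})

test_that("growth tensor saturates with the right eigenstructure", {
  g <- growth_law(lambda_N = 0.3, lambda_T = 1.2, beta = 1)
  expect_equal(growth_tensor(g, c(0, 0, 1), 0), diag(3))
  # saturated control-dermis tangential growth: tangential eigenvalue 2.2
  gd <- growth_law(lambda_N = 0, lambda_T = 1.2, beta = 1)
  Fg <- growth_tensor(gd, c(0, 0, 1), 20)
  expect_equal(Fg, diag(c(2.2, 2.2, 1)), tolerance = 1e-8)
  # determinant identity det Fg = (1 + lN s)(1 + lT s)^2
  for (t in c(0.3, 1, 4)) {
    s <- 1 - exp(-t)
    N <- c(1, 2, -1) / sqrt(6)
    Fg <- growth_tensor(g, N, t)
    expect_equal(det(Fg), (1 + 0.3 * s) * (1 + 1.2 * s)^2, tolerance = 1e-12)
    # symmetric positive definite
    expect_equal(Fg, t(Fg))
    expect_true(all(eigen(Fg, symmetric = TRUE, only.values = TRUE)$values > 0))
  }
  expect_error(growth_tensor(g, c(0, 0, 2), 1), "unit")
})

test_that("elastic decomposition round-trips", {
  set.seed(4)
  for (i in 1:10) {
    F <- diag(3) + matrix(rnorm(9, 0, 0.3), 3)
    A <- matrix(rnorm(9), 3)
    Fg <- crossprod(A) + diag(3) * 0.5    # SPD
    Fe <- elastic_part(F, Fg)
    expect_lt(max(abs(Fe %*% Fg - F)), 1e-12)
  }
  F1 <- diag(3) + matrix(0.1, 3, 3)
  expect_equal(elastic_part(F1, F1), diag(3), tolerance = 1e-12)
  expect_equal(elastic_part(F1, diag(3)), F1)
  expect_error(elastic_part(F1, matrix(0, 3, 3)), "singular")
})

test_that("strain energy matches closed forms and vanishes on rotations", {
  mu <- 0.7; K <- 1.3
  expect_equal(strain_energy(diag(3), mu, K), 0)
  a <- 1.4   # isochoric stretch: only the deviatoric term survives
  expect_equal(strain_energy(diag(c(a, 1 / a, 1)), mu, K),
               mu / 2 * (a^2 + a^-2 - 2), tolerance = 1e-12)
  # pure dilation: only the volumetric term survives
  expect_equal(strain_energy(diag(3) * a, mu, K),
               K * (a^3 - 3 * log(a) - 1), tolerance = 1e-12)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(strain_energy(R, mu, K), 0, tolerance = 1e-14)
  expect_gt(strain_energy(diag(c(1.2, 1, 1)), mu, K), 0)
  expect_error(strain_energy(diag(c(-1, 1, 1)), mu, K), "inverted")
})

test_that("Cauchy stress matches closed forms and the energy derivative", {
  mu <- 0.43; K <- 0.91
  expect_equal(cauchy_stress(diag(3), mu, K), matrix(0, 3, 3))
  a <- 1.25  # dilation: deviatoric part vanishes
  expect_equal(cauchy_stress(diag(3) * a, mu, K),
               K * (1 - a^-3) * diag(3), tolerance = 1e-12)
  for (Fe in random_Fe(20, seed = 11)) {
    sig <- cauchy_stress(Fe, mu, K)
    expect_equal(sig, t(sig), tolerance = 1e-12)
    fd <- fd_cauchy(Fe, mu, K)
    expect_lt(max(abs(sig - fd)) / max(abs(sig)), 1e-5)
  }
})

test_that("Cauchy stress is objective under rotations", {
  mu <- 1.1; K <- 2.3
  set.seed(9)
  for (i in 1:10) {
    Fe <- diag(3) + matrix(rnorm(9, 0, 0.2), 3)
    if (det(Fe) <= 0.2) next
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2)); th <- runif(1, 0, pi)
    Kx <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
    R <- diag(3) + sin(th) * Kx + (1 - cos(th)) * Kx %*% Kx
    lhs <- cauchy_stress(R %*% Fe, mu, K)
    rhs <- R %*% cauchy_stress(Fe, mu, K) %*% t(R)
    expect_lt(max(abs(lhs - rhs)), 1e-10)
  }
})
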