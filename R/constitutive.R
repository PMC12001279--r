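#' Shear and bulk moduli from Young's modulus and Poisson's ratio
#'
#' Converts the engineering constants of an isotropic material to the
#' shear modulus `mu = E / (2 (1 + nu))` and bulk modulus
#' `K = E / (3 (1 - 2 nu))` used by the neo-Hookean energy.
#'
#' @param E Young's modulus (any consistent stress unit; the simulator works
#'   in relative units with the dermis at `E = 1`).
#' @param nu Poisson's ratio, in `(-1, 0.5)`. Values at or above `0.5`
#'   (incompressible limit) are rejected; values above `0.45` trigger a
#'   warning because linear tetrahedra lock near incompressibility.
#' @return A list with elements `mu` and `K`.
#' @examples
#' compute_moduli(1, 0.15)
#' @export
compute_moduli <- function(E, nu) {
  stopifnot(is.numeric(E), is.numeric(nu), length(E) == 1L, length(nu) == 1L)
  if (!is.finite(E) || E <= 0) stop("Young's modulus must be positive")
  if (!is.finite(nu) || nu <= -1) stop("Poisson's ratio must exceed -1")
  if (nu >= 0.5 - 1e-9) {
    stop("Poisson's ratio at the incompressible limit (nu >= 0.5); ",
         "the bulk modulus is singular there")
  }
  if (nu > 0.45) {
    warning("nu > 0.45: near-incompressible materials are unsupported ",
            "(P1 tetrahedra lock); results will be unreliable")
  }
  list(mu = E / (2 * (1 + nu)), K = E / (3 * (1 - 2 * nu)))
}

#' Saturating anisotropic growth law
#'
#' Bundles the parameters of the saturating growth deformation gradient
#' `Fg(t) = I + lambda_N (1 - exp(-beta t)) N (x) N +
#'            lambda_T (1 - exp(-beta t)) (I - N (x) N)`,
#' where `N` is the layer normal in the reference configuration,
#' `lambda_N` and `lambda_T` the final relative growth along and
#' perpendicular to `N`, and `beta` the saturation rate.
#'
#' @param lambda_N Final relative normal growth (dimensionless, `>= 0`).
#' @param lambda_T Final relative tangential growth (dimensionless, `>= 0`).
#' @param beta Growth rate (1/time, `> 0`).
#' @return An object of class `growth_law`.
#' @examples
#' growth_law(lambda_T = 1.2)            # control dermis, tangential only
#' @export
growth_law <- function(lambda_N = 0, lambda_T = 0, beta = 1) {
  stopifnot(is.numeric(lambda_N), is.numeric(lambda_T), is.numeric(beta))
  if (lambda_N < 0 || lambda_T < 0) stop("growth factors must be >= 0")
  if (beta <= 0) stop("growth rate beta must be > 0")
  structure(list(lambda_N = lambda_N, lambda_T = lambda_T, beta = beta),
            class = "growth_law")
}

#' @export
print.growth_law <- function(x, ...) {
  cat(sprintf("<growth_law> lambda_N = %g, lambda_T = %g, beta = %g\n",
              x$lambda_N, x$lambda_T, x$beta))
  invisible(x)
}

#' Growth deformation gradient at time t
#'
#' Evaluates the saturating growth tensor of a [growth_law()] for a unit
#' reference normal `N`. The result is symmetric positive definite with
#' eigenvalue `1 + lambda_N s` along `N` and the double eigenvalue
#' `1 + lambda_T s` in the tangent plane, where `s = 1 - exp(-beta t)`.
#'
#' @param g A [growth_law()].
#' @param N Unit reference normal (numeric length 3).
#' @param t Time (`>= 0`).
#' @return A 3x3 matrix.
#' @export
growth_tensor <- function(g, N, t) {
  stopifnot(inherits(g, "growth_law"), length(N) == 3L, t >= 0)
  n2 <- sum(N * N)
  if (abs(n2 - 1) > 1e-8) stop("N must be a unit vector")
  s <- 1 - exp(-g$beta * t)
  NN <- tcrossprod(N)
  diag(3) + g$lambda_N * s * NN + g$lambda_T * s * (diag(3) - NN)
}

#' Elastic part of the deformation gradient
#'
#' Multiplicative decomposition `F = Fe Fg`: returns `Fe = F Fg^{-1}`.
#'
#' @param F Total deformation gradient (3x3).
#' @param Fg Growth deformation gradient (3x3, `det Fg > 0`).
#' @return The elastic deformation gradient `Fe` (3x3).
#' @export
elastic_part <- function(F, Fg) {
  stopifnot(is.matrix(F), is.matrix(Fg), all(dim(F) == c(3, 3)),
            all(dim(Fg) == c(3, 3)))
  dg <- det(Fg)
  if (!is.finite(dg) || dg <= 1e-12) stop("Fg is singular or inverted (det <= 0)")
  F %*% solve(Fg)
}

#' Neo-Hookean strain energy density
#'
#' `Psi = mu/2 (tr(Fe Fe^T) J^{-2/3} - 3) + K (J - log J - 1)` with
#' `J = det Fe`. Non-negative, zero exactly when `Fe` is a rotation.
#'
#' @param Fe Elastic deformation gradient (3x3) with `det Fe > 0`.
#' @param mu Shear modulus.
#' @param K Bulk modulus.
#' @return Energy density (scalar, per unit grown volume).
#' @export
strain_energy <- function(Fe, mu, K) {
  J <- det(Fe)
  if (!is.finite(J) || J <= 0) stop("inverted element: det Fe <= 0")
  b <- tcrossprod(Fe)        # Fe Fe^T
  mu / 2 * (sum(diag(b)) * J^(-2 / 3) - 3) + K * (J - log(J) - 1)
}

#' Cauchy stress of the neo-Hookean model
#'
#' `sigma = mu J^{-5/3} dev(Fe Fe^T) + K (1 - 1/J) I`, the closed form of
#' `sigma = (1/J) (dPsi/dFe) Fe^T` for the energy of [strain_energy()].
#'
#' @inheritParams strain_energy
#' @return Symmetric 3x3 stress tensor.
#' @export
cauchy_stress <- function(Fe, mu, K) {
  J <- det(Fe)
  if (!is.finite(J) || J <= 0) stop("inverted element: det Fe <= 0")
  b <- tcrossprod(Fe)
  devb <- b - sum(diag(b)) / 3 * diag(3)
  mu * J^(-5 / 3) * devb + K * (1 - 1 / J) * diag(3)
}

#' Elastic material constants for one tissue layer
#'
#' @inheritParams compute_moduli
#' @return An object of class `elastic_constants` with fields `E`, `nu`,
#'   `mu`, `K`.
#' @examples
#' elastic_constants(3, 0.35)   # stiffened epidermis, dermis units
#' @export
elastic_constants <- function(E, nu) {
  m <- compute_moduli(E, nu)
  structure(list(E = E, nu = nu, mu = m$mu, K = m$K),
            class = "elastic_constants")
}

#' @export
print.elastic_constants <- function(x, ...) {
  cat(sprintf("<elastic_constants> E = %g, nu = %g (mu = %.5g, K = %.5g)\n",
              x$E, x$nu, x$mu, x$K))
  invisible(x)
}
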