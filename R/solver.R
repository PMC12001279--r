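#' Solver configuration for steady-state relaxation
#'
#' Controls the damped explicit dynamics used to relax the grown tissue to
#' mechanical equilibrium. Nodal masses are lumped to unity (fictitious at
#' steady state), so times are in simulation units.
#'
#' @param time_step Integration step; `0` (default) auto-sets it from a
#'   stiffness-based stability estimate.
#' @param damping_coefficient Viscous damping rate (1/time).
#' @param contact_stiffness Penalty spring stiffness (stress/length); `0`
#'   disables contact.
#' @param contact_range Distance below which surface primitives repel.
#' @param force_tolerance Convergence threshold on the maximum nodal
#'   residual force.
#' @param max_steps Step budget before the solver gives up.
#' @param growth_ramp_end Minimum value of `beta * t` before convergence is
#'   tested; at the default 5 the growth law has reached more than 99.3% of
#'   saturation.
#' @param log_every Record (time, residual, energy) every this many steps.
#' @param contact_every Rebuild contact candidate pairs every this many
#'   steps.
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(time_step = 0, damping_coefficient = 0.1,
                          contact_stiffness = 0, contact_range = 0,
                          force_tolerance = 1e-4, max_steps = 200000L,
                          growth_ramp_end = 5, log_every = 50L,
                          contact_every = 10L) {
  if (growth_ramp_end < 5)
    stop("growth_ramp_end must be >= 5 (>= 99.3% of growth saturation)")
  stopifnot(damping_coefficient > 0, force_tolerance > 0, max_steps > 0,
            time_step >= 0, contact_stiffness >= 0, contact_range >= 0)
  structure(list(time_step = time_step,
                 damping_coefficient = damping_coefficient,
                 contact_stiffness = contact_stiffness,
                 contact_range = contact_range,
                 force_tolerance = force_tolerance,
                 max_steps = as.integer(max_steps),
                 growth_ramp_end = growth_ramp_end,
                 log_every = as.integer(log_every),
                 contact_every = as.integer(contact_every)),
            class = "solver_config")
}

# expand per-layer material/growth tables to per-element vectors
layer_fields <- function(mesh, materials, growth) {
  stopifnot(all(c("epidermis", "dermis") %in% names(materials)),
            all(c("epidermis", "dermis") %in% names(growth)))
  for (l in c("epidermis", "dermis")) {
    if (!inherits(materials[[l]], "elastic_constants"))
      stop("materials$", l, " must be an elastic_constants object")
    if (!inherits(growth[[l]], "growth_law"))
      stop("growth$", l, " must be a growth_law object")
  }
  iepi <- mesh$layer == "epidermis"
  pick <- function(field, from) {
    ifelse(iepi, from$epidermis[[field]], from$dermis[[field]])
  }
  betas <- c(growth$epidermis$beta, growth$dermis$beta)
  if (length(unique(betas)) > 1L)
    stop("all layers must share the growth rate beta (one simulation clock)")
  list(mu = pick("mu", materials), K = pick("K", materials),
       lamN = pick("lambda_N", growth), lamT = pick("lambda_T", growth),
       beta = betas[1])
}

#' Assemble internal (elastic) nodal forces
#'
#' Linear-tetrahedron, single-quadrature-point forces from the morphoelastic
#' neo-Hookean stress at the supplied nodal positions and growth saturation.
#' On a fully free body the net force and net torque vanish to round-off.
#'
#' @param mesh A [layered_tet_mesh()].
#' @param positions `n x 3` current nodal positions.
#' @param materials Named list with `elastic_constants` for `epidermis` and
#'   `dermis`.
#' @param growth Named list with [growth_law()]s for `epidermis` and
#'   `dermis`.
#' @param t Growth time at which `Fg(t)` is evaluated (default fully
#'   saturated).
#' @return List with `forces` (`n x 3`) and total elastic `energy`.
#' @export
assemble_internal_forces <- function(mesh, positions, materials, growth,
                                     t = Inf) {
  lf <- layer_fields(mesh, materials, growth)
  s <- 1 - exp(-lf$beta * t)
  if (!is.finite(t)) s <- 1
  .fem_forces(mesh$nodes, mesh$tets, lf$mu, lf$K, lf$lamN, lf$lamT,
              mesh$normals, as.matrix(positions), s)
}

#' Penalty contact forces between non-neighbouring surface primitives
#'
#' Node-triangle penalty with a linear spring inside `contact_range`:
#' zero when separated, equal-and-opposite when active. Triangles within
#' the topological 1-ring of a node are excluded.
#'
#' @param positions `n x 3` nodal positions.
#' @param surface_tris `k x 3` surface triangle index matrix.
#' @param config A [solver_config()] providing `contact_range` and
#'   `contact_stiffness`.
#' @return `n x 3` matrix of contact forces.
#' @export
contact_forces <- function(positions, surface_tris, config) {
  stopifnot(inherits(config, "solver_config"))
  .fem_contact(as.matrix(positions), as.matrix(surface_tris),
               config$contact_range, config$contact_stiffness)
}

#' Relax a grown layered mesh to mechanical steady state
#'
#' Damped explicit dynamics: the growth tensor saturates along the
#' simulation clock (`s(t) = 1 - exp(-beta t)`), and the solver integrates
#' Newton's second law with viscous damping and penalty contact until the
#' growth ramp is essentially complete (`beta t >= growth_ramp_end`) and the
#' maximum nodal residual force falls below `force_tolerance`. A tiny seeded
#' perturbation of the initial positions (1e-4 of the mean edge length)
#' breaks the symmetry of perfect geometries so buckling can select a
#' pattern.
#'
#' @inheritParams assemble_internal_forces
#' @param config A [solver_config()].
#' @param seed Integer seed for the symmetry-breaking perturbation.
#' @return An object of class `sim_state`: nodal `positions`, `velocities`,
#'   time `t`, per-element `F`, `Fg`, `Fe` and `sigma` (rows are flattened
#'   3x3, row-major), `J`, `psi`, a convergence `log` tibble
#'   (time, residual, energy), and the deformed outer `surface`.
#' @export
relax_to_steady_state <- function(mesh, materials, growth, config, seed = 1L) {
  stopifnot(inherits(mesh, "layered_tet_mesh"), inherits(config, "solver_config"))
  lf <- layer_fields(mesh, materials, growth)
  nu_max <- max(materials$epidermis$nu, materials$dermis$nu)
  if (nu_max > 0.45)
    warning("nu > 0.45 is unsupported (element locking); expect artefacts")

  edge <- mean(sqrt(rowSums((mesh$nodes[mesh$tets[, 2], , drop = FALSE] -
                             mesh$nodes[mesh$tets[, 1], , drop = FALSE])^2)))
  any_growth <- max(lf$lamN, lf$lamT) > 0
  if (any_growth) {
    # symmetry breaking is only needed when growth can drive buckling
    old <- .Random.seed_safe()
    set.seed(as.integer(seed))
    x0 <- mesh$nodes + matrix(stats::runif(3 * nrow(mesh$nodes), -1, 1),
                              ncol = 3) * (1e-4 * edge)
    .Random.seed_restore(old)
    x0[mesh$fixed_nodes, ] <- mesh$nodes[mesh$fixed_nodes, , drop = FALSE]
  } else {
    x0 <- mesh$nodes
  }

  cfg <- unclass(config)
  cfg$beta <- lf$beta
  res <- .fem_relax(mesh$nodes, mesh$tets, lf$mu, lf$K, lf$lamN, lf$lamT,
                    mesh$normals, mesh$fixed_nodes, x0, mesh$surface_tris,
                    cfg)
  if (!res$converged) {
    cond <- structure(
      class = c("morphofold_no_convergence", "error", "condition"),
      list(message = sprintf(
             "relaxation did not converge in %d steps (residual %.3g > %.3g)",
             res$steps, res$residual, config$force_tolerance),
           call = sys.call(),
           residual_history = res$log_residual))
    stop(cond)
  }
  structure(list(
    positions = res$x, velocities = res$v, t = res$t, time_step = res$dt,
    steps = res$steps, F = res$F, Fg = res$Fg, Fe = res$Fe,
    sigma = res$sigma, J = res$J, psi = res$psi,
    log = tibble::tibble(time = res$log_t, residual = res$log_residual,
                         energy = res$log_energy),
    surface = deformed_surface(mesh, res$x, which = "outer"),
    mesh = mesh, seed = as.integer(seed)),
    class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf(
    "<sim_state> %d nodes, t = %.3g (%d steps), max |residual| = %.3g, energy = %.5g\n",
    nrow(x$positions), x$t, x$steps, utils::tail(x$log$residual, 1),
    utils::tail(x$log$energy, 1)))
  invisible(x)
}

# save/restore .Random.seed so seeded internals do not disturb the caller's RNG
.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible()
}
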