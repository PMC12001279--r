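#' Parameter space for layer calibration
#'
#' The free parameters of the skin model and their bounds. The dermis
#' Young's modulus is the unit of stress (`E_dermis = 1` always). The
#' control stage optimizes five parameters
#' (`E_epi, nu_epi, nu_derm, lambda_T_epi, lambda_T_derm`); the treated
#' stage optimizes the three epidermis parameters while dermis values are
#' carried over unchanged.
#'
#' @param stage `"control"` (5 parameters) or `"treated"` (3 parameters).
#' @param fixed Named list of fixed parameter values (for the treated
#'   stage: `nu_derm` and `lambda_T_derm`).
#' @param E_bounds,nu_bounds,lambda_bounds Bounds; the Poisson cap at 0.45
#'   keeps linear tetrahedra away from the locking regime.
#' @return An object of class `param_space` with `lower`, `upper`, `fixed`.
#' @export
param_space <- function(stage = c("control", "treated"), fixed = list(),
                        E_bounds = c(0.5, 10), nu_bounds = c(0.05, 0.45),
                        lambda_bounds = c(0.5, 3)) {
  stage <- match.arg(stage)
  if (nu_bounds[2] > 0.45) stop("nu upper bound capped at 0.45 (element locking)")
  free <- if (stage == "control") {
    c("E_epi", "nu_epi", "nu_derm", "lambda_T_epi", "lambda_T_derm")
  } else {
    c("E_epi", "nu_epi", "lambda_T_epi")
  }
  if (stage == "treated" &&
      !all(c("nu_derm", "lambda_T_derm") %in% names(fixed)))
    stop("treated stage requires fixed nu_derm and lambda_T_derm ",
         "(carried over from the control fit)")
  if (length(intersect(names(fixed), free)))
    stop("fixed and free parameter sets overlap")
  lo <- c(E_epi = E_bounds[1], nu_epi = nu_bounds[1], nu_derm = nu_bounds[1],
          lambda_T_epi = lambda_bounds[1], lambda_T_derm = lambda_bounds[1])
  hi <- c(E_epi = E_bounds[2], nu_epi = nu_bounds[2], nu_derm = nu_bounds[2],
          lambda_T_epi = lambda_bounds[2], lambda_T_derm = lambda_bounds[2])
  structure(list(stage = stage, free = free,
                 lower = lo[free], upper = hi[free], fixed = fixed),
            class = "param_space")
}

#' @export
print.param_space <- function(x, ...) {
  cat(sprintf("<param_space> stage %s: %s\n", x$stage,
              paste(sprintf("%s in [%g, %g]", x$free, x$lower, x$upper),
                    collapse = ", ")))
  if (length(x$fixed))
    cat("  fixed:", paste(names(x$fixed), unlist(x$fixed), sep = " = ",
                          collapse = ", "), "\n")
  invisible(x)
}

# complete a free-parameter vector with the fixed values
full_params <- function(space, p) {
  out <- as.list(p)
  names(out) <- space$free
  c(out, space$fixed)
}

#' Simulation-based objective: distance of a candidate's fold pattern to a
#' target
#'
#' Runs the mechanical model with the candidate layer parameters, extracts
#' the fold network of the relaxed surface, and returns the normalized
#' metric distance to the target. Deterministic given `seed`. A failed
#' simulation (element inversion, non-convergence) returns `NA`;
#' [bayes_optimize()] converts this into a penalty so calibration never
#' crashes.
#'
#' @param params Named list/vector with `E_epi`, `nu_epi`, `nu_derm`,
#'   `lambda_T_epi`, `lambda_T_derm` (`E_derm = 1`).
#' @param mesh A [layered_tet_mesh()].
#' @param target Raw metric vector of the target network.
#' @param norm A `metric_normalizer` shared by candidate and target.
#' @param config A [solver_config()].
#' @param seed Seed for the symmetry-breaking perturbation.
#' @param quantile,spur_fraction,projection_axis,pixel_size Fold-pipeline
#'   settings (see [fold_pipeline()]).
#' @return Scalar objective (`>= 0`), or `NA` on simulation failure.
#' @export
simulate_and_score <- function(params, mesh, target, norm, config, seed = 1L,
                               quantile = 0.45, spur_fraction = 0.02,
                               projection_axis = "z", pixel_size = NULL) {
  params <- as.list(params)
  need <- c("E_epi", "nu_epi", "nu_derm", "lambda_T_epi", "lambda_T_derm")
  if (!all(need %in% names(params)))
    stop("params must include: ", paste(need, collapse = ", "))
  mv <- tryCatch({
    mat <- list(epidermis = elastic_constants(params$E_epi, params$nu_epi),
                dermis = elastic_constants(1, params$nu_derm))
    g <- list(epidermis = growth_law(0, params$lambda_T_epi),
              dermis = growth_law(0, params$lambda_T_derm))
    s <- relax_to_steady_state(mesh, mat, g, config, seed = seed)
    fold_pipeline(s$surface, quantile = quantile,
                  spur_fraction = spur_fraction,
                  projection_axis = projection_axis,
                  pixel_size = pixel_size)$metrics
  }, error = function(e) NULL)
  if (is.null(mv)) return(NA_real_)
  network_distance(mv, target, norm)
}

#' Stopping rule for Bayesian optimization
#'
#' @param patience Stop after this many evaluations without improvement
#'   (default 500, the production-scale rule; tests use far less).
#' @param max_iterations Hard evaluation budget.
#' @return An object of class `stopping_rule`.
#' @export
stopping_rule <- function(patience = 500L, max_iterations = 3000L) {
  stopifnot(patience >= 1, max_iterations >= patience)
  structure(list(patience = as.integer(patience),
                 max_iterations = as.integer(max_iterations)),
            class = "stopping_rule")
}

#' Seeded Bayesian (surrogate/expected-improvement) minimization
#'
#' Latin-hypercube initial design, Gaussian-process surrogate (Matern 5/2)
#' and expected-improvement acquisition maximized over a seeded candidate
#' sweep with local refinement. Failed evaluations (`NA`) receive a penalty
#' of 10x the worst successful objective so the surrogate learns to avoid
#' that region. Fully reproducible under `seed`.
#'
#' @param space A [param_space()].
#' @param objective Function taking a named free-parameter vector, returning
#'   a scalar (or `NA` on failure).
#' @param stop A [stopping_rule()].
#' @param seed Integer seed.
#' @param n_init Number of initial Latin-hypercube evaluations (default
#'   `max(5, 3 d)`).
#' @param polish Number of evaluations reserved for a final coordinate
#'   pattern search around the incumbent (default 0). Useful when the
#'   response surface has a narrow basin that the smooth surrogate
#'   underrates.
#' @return An object of class `opt_result`: `best_params`, `best_objective`,
#'   `history` tibble (parameters, objective, penalized flag, iteration),
#'   `stopped_because`, `seed`.
#' @export
bayes_optimize <- function(space, objective, stop = stopping_rule(100L, 300L),
                           seed = 1L, n_init = NULL, polish = 0L) {
  stopifnot(inherits(space, "param_space"), inherits(stop, "stopping_rule"))
  d <- length(space$free)
  if (is.null(n_init)) n_init <- max(5L, 3L * d)
  n_init <- min(n_init, stop$max_iterations)
  lo <- space$lower; hi <- space$upper

  old <- .Random.seed_safe()
  set.seed(as.integer(seed))
  on.exit(.Random.seed_restore(old))

  U <- lhs::randomLHS(n_init, d)              # unit-cube design
  X <- matrix(NA_real_, 0, d); raw <- numeric(0)
  evaluate <- function(u) {
    p <- lo + u * (hi - lo)
    names(p) <- space$free
    objective(p)
  }
  for (i in seq_len(n_init)) {
    X <- rbind(X, U[i, ]); raw <- c(raw, evaluate(U[i, ]))
  }
  penalize <- function(raw) {
    ok <- is.finite(raw)
    if (!any(ok)) stop("all objective evaluations failed")
    worst <- max(raw[ok])
    y <- raw
    y[!ok] <- 10 * max(worst, 1e-8)
    y
  }
  best_hist <- function(y) cummin(y)

  while (nrow(X) < stop$max_iterations) {
    y <- penalize(raw)
    bi <- which.min(y)
    since <- nrow(X) - which.min(best_hist(y))  # evals since last improvement
    if (since >= stop$patience) break
    fit <- tryCatch(gp_fit(X, y), error = function(e) NULL)
    if (is.null(fit)) {
      u <- stats::runif(d)
    } else {
      ncand <- 1024L
      cand <- matrix(stats::runif(ncand * d), ncand, d)
      # densify around the incumbent
      local <- matrix(stats::rnorm(256L * d, 0, 0.05), 256L, d) +
        matrix(X[bi, ], 256L, d, byrow = TRUE)
      cand <- rbind(cand, pmin(pmax(local, 0), 1))
      pr <- gp_predict(fit, cand)
      ei <- expected_improvement(pr$mean, pr$sd, min(y))
      u0 <- cand[which.max(ei), ]
      negei <- function(u) {
        u <- pmin(pmax(u, 0), 1)
        p <- gp_predict(fit, matrix(u, 1))
        -expected_improvement(p$mean, p$sd, min(y))
      }
      u <- tryCatch(
        stats::optim(u0, negei, method = "L-BFGS-B", lower = rep(0, d),
                     upper = rep(1, d),
                     control = list(maxit = 30))$par,
        error = function(e) u0)
    }
    X <- rbind(X, u); raw <- c(raw, evaluate(u))
  }

  if (polish > 0) {
    # coordinate pattern search with step halving around the incumbent
    step <- 0.08
    budget <- as.integer(polish)
    while (budget > 0 && step > 0.004) {
      y <- penalize(raw)
      bi <- which.min(y)
      improved <- FALSE
      for (j in seq_len(d)) {
        for (sgn in c(-1, 1)) {
          if (budget <= 0) break
          u <- X[bi, ]
          u[j] <- min(max(u[j] + sgn * step, 0), 1)
          X <- rbind(X, u); raw <- c(raw, evaluate(u)); budget <- budget - 1L
          y <- penalize(raw)
          if (which.min(y) == nrow(X)) { improved <- TRUE; bi <- nrow(X) }
        }
      }
      if (!improved) step <- step / 2
    }
  }

  y <- penalize(raw)
  bi <- which.min(y)
  P <- sweep(sweep(X, 2, hi - lo, "*"), 2, lo, "+")
  colnames(P) <- space$free
  hist <- tibble::tibble(iteration = seq_len(nrow(X)))
  for (j in seq_len(d)) hist[[space$free[j]]] <- P[, j]
  hist$objective <- y
  hist$failed <- !is.finite(raw)
  bp <- as.list(P[bi, ]); names(bp) <- space$free
  structure(list(best_params = bp, best_objective = y[bi],
                 history = hist,
                 stopped_because = if (nrow(X) >= stop$max_iterations)
                   "max_iterations" else "patience",
                 space = space, seed = as.integer(seed)),
            class = "opt_result")
}

#' @export
print.opt_result <- function(x, ...) {
  cat(sprintf("<opt_result> best objective %.5g after %d evaluations (%s)\n",
              x$best_objective, nrow(x$history), x$stopped_because))
  cat("  best:", paste(names(x$best_params),
                       signif(unlist(x$best_params), 4),
                       sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Two-stage calibration protocol
#'
#' Stage 1 fits the five-parameter control space to the control target;
#' stage 2 fits the three epidermis parameters to the treated target while
#' the dermis parameters are kept at the stage-1 optimum.
#'
#' @param control_target,treated_target Raw metric vectors.
#' @param mesh A [layered_tet_mesh()].
#' @param norm A shared `metric_normalizer`.
#' @param config A [solver_config()].
#' @param stop A [stopping_rule()] (applied per stage).
#' @param seed Integer seed.
#' @param simulate_fn Objective factory, by default wrapping
#'   [simulate_and_score()]; it receives `(params, target)` and returns the
#'   objective value. Overridable to calibrate against surrogate objectives
#'   in tests.
#' @param ... Passed to [simulate_and_score()].
#' @return List with `control` and `treated` [bayes_optimize()] results.
#' @export
staged_fit <- function(control_target, treated_target, mesh, norm, config,
                       stop = stopping_rule(100L, 300L), seed = 1L,
                       simulate_fn = NULL, ...) {
  if (is.null(simulate_fn)) {
    simulate_fn <- function(params, target)
      simulate_and_score(params, mesh, target, norm, config,
                         seed = seed, ...)
  }
  s1 <- param_space("control")
  r1 <- bayes_optimize(s1, function(p)
    simulate_fn(full_params(s1, p), control_target), stop, seed = seed)
  carried <- r1$best_params[c("nu_derm", "lambda_T_derm")]
  s2 <- param_space("treated", fixed = carried)
  r2 <- bayes_optimize(s2, function(p)
    simulate_fn(full_params(s2, p), treated_target), stop,
    seed = seed + 1L)
  list(control = r1, treated = r2)
}
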