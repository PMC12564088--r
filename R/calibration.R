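#' Optimizer settings for model calibration
#'
#' @param lower,upper box bounds on `(D_t0, D_v0, k_t, k_v)`: diffusivities
#'   in `[1e-6, 1]` mm^2/day, rates in `[1e-3, 5]` /day by default, keeping
#'   the Levenberg-Marquardt search in a physical, numerically stable
#'   region.
#' @param ftol relative reduction in the sum of squares below which the fit
#'   is declared converged.
#' @param ptol relative parameter-step tolerance.
#' @param maxiter maximum number of Levenberg-Marquardt iterations.
#' @param epsfcn forward-difference Jacobian step control (the effective
#'   relative step is about `sqrt(epsfcn)`, i.e. 1e-3 per parameter).
#' @param weights per-species residual weights `c(tumor, vasc)`; the default
#'   weights both species equally per voxel, so the combined objective is
#'   dominated by the larger-magnitude tumor residuals.
#' @param init initial-guess policy: `"perturb"` draws a seeded uniform
#'   factor in `[1 - perturb_frac, 1 + perturb_frac]` around `truth` per
#'   parameter (experiment mode, truth known); `"fixed"` uses
#'   `init_values`.
#' @param truth `model_parameters` holding the generating values (for
#'   `init = "perturb"`).
#' @param perturb_frac half-width of the uniform perturbation.
#' @param init_values 4-vector `(D_t0, D_v0, k_t, k_v)` for `init = "fixed"`;
#'   defaults to a literature mid-range guess.
#' @param dt,mechanics_interval forward-model settings used inside the
#'   objective.
#' @return A list of settings for [calibrate_growth()].
#' @export
calibration_config <- function(lower = c(1e-6, 1e-6, 1e-3, 1e-3),
                               upper = c(1, 1, 5, 5),
                               ftol = 1e-6, ptol = 1e-8, maxiter = 50,
                               epsfcn = 1e-6,
                               weights = c(tumor = 1, vasc = 1),
                               init = c("perturb", "fixed"),
                               truth = NULL, perturb_frac = 0.5,
                               init_values = c(0.02, 0.02, 0.5, 0.5),
                               dt = 0.01, mechanics_interval = 1) {
  list(lower = lower, upper = upper, ftol = ftol, ptol = ptol,
       maxiter = maxiter, epsfcn = epsfcn, weights = weights,
       init = match.arg(init), truth = truth, perturb_frac = perturb_frac,
       init_values = init_values, dt = dt,
       mechanics_interval = mechanics_interval)
}

# forward-simulate a candidate parameter vector from the observed day-1
# fields and return snapshots at the observed days
forward_for_calibration <- function(par4, observed, fixed, domain, dt,
                                    mechanics_interval,
                                    suppression_trajectory = NULL) {
  params <- fixed
  params$D_t0 <- par4[1]; params$D_v0 <- par4[2]
  params$k_t <- par4[3]; params$k_v <- par4[4]
  horizon <- max(observed$days)
  tc <- simulate_growth(list(N_t = observed$N_t[[1]], N_v = observed$N_v[[1]]),
                        params, domain, days = horizon, dt = dt,
                        mechanics_interval = mechanics_interval,
                        suppression_trajectory = suppression_trajectory)
  out <- select_timepoints(tc, observed$days)
  out$suppression <- tc$suppression
  out
}

# concatenated weighted voxelwise residuals of a forward run against the
# observations, days after day 1
residuals_from_sim <- function(sim, observed, weights) {
  res <- vector("list", 2L * (length(observed$days) - 1L))
  k <- 0L
  for (i in seq_along(observed$days)[-1]) {
    res[[k <- k + 1L]] <- weights[1] *
      as.vector(sim$N_t[[i]]$values - observed$N_t[[i]]$values)
    res[[k <- k + 1L]] <- weights[2] *
      as.vector(sim$N_v[[i]]$values - observed$N_v[[i]]$values)
  }
  unlist(res, use.names = FALSE)
}

#' Calibration residuals for a candidate parameter vector
#'
#' Forward-simulates from the observed day-1 fields with the candidate
#' `(D_t0, D_v0, k_t, k_v)` and returns the concatenated voxelwise
#' differences (model - observed) for both species at every observed day
#' after day 1, each species scaled by its residual weight. A forward-model
#' failure (e.g. a stability violation at an extreme candidate) yields a
#' large constant penalty residual so the optimizer retreats.
#'
#' @param par4 numeric 4-vector `(D_t0, D_v0, k_t, k_v)`.
#' @param observed `time_course` of the (degraded) observations; day 1 is
#'   the initial condition, later days are fit targets.
#' @param fixed `model_parameters` supplying the non-calibrated constants.
#' @param domain [build_tissue_domain()] domain.
#' @param weights per-species weights `c(tumor, vasc)`.
#' @param dt,mechanics_interval forward-model settings.
#' @param suppression_trajectory optional cached stress-suppression
#'   trajectory (see [simulate_growth()]).
#' @return Numeric residual vector of length
#'   `(#days - 1) * 2 * #voxels`.
#' @export
growth_residuals <- function(par4, observed, fixed, domain,
                             weights = c(tumor = 1, vasc = 1),
                             dt = 0.01, mechanics_interval = 1,
                             suppression_trajectory = NULL) {
  if (length(observed$days) < 2L)
    stop("observed time course must contain day 1 plus at least one later day")
  nvox <- prod(domain$grid$shape)
  m <- (length(observed$days) - 1L) * 2L * nvox
  sim <- tryCatch(
    forward_for_calibration(par4, observed, fixed, domain, dt,
                            mechanics_interval, suppression_trajectory),
    error = function(e) e)
  if (inherits(sim, "error")) {
    warning("forward model failed during calibration (",
            conditionMessage(sim), "); returning penalty residual")
    return(rep(1e3, m))
  }
  residuals_from_sim(sim, observed, weights)
}

#' Calibrate the four global model parameters
#'
#' Levenberg-Marquardt least squares (damped Gauss-Newton with a
#' forward-difference Jacobian over the four parameters) on the
#' [growth_residuals()] objective. The observed (degraded) day-1 fields are
#' the initial condition; the calibrator never sees clean data.
#' Deterministic for fixed inputs and seed.
#'
#' @param observed `time_course` of the degraded observations.
#' @param domain [build_tissue_domain()] domain.
#' @param fixed `model_parameters` supplying the non-calibrated constants.
#' @param config [calibration_config()] settings.
#' @param seed integer; fixes the initial-guess perturbation.
#' @return An object of class `calibration_result`: `estimated`
#'   (`model_parameters`), `initial_guess`, `objective_trace` (residual
#'   sum-of-squares at accepted iterations), `converged`, `n_iterations`,
#'   `message`.
#' @export
calibrate_growth <- function(observed, domain, fixed = model_parameters(),
                             config = calibration_config(), seed = 1L) {
  guess <- switch(config$init,
    perturb = {
      if (is.null(config$truth))
        stop("init = 'perturb' needs config$truth")
      tr <- with(config$truth, c(D_t0, D_v0, k_t, k_v))
      fac <- with_seed(seed, stats::runif(4, 1 - config$perturb_frac,
                                          1 + config$perturb_frac))
      tr * fac
    },
    fixed = config$init_values)
  guess <- pmin(pmax(guess, config$lower), config$upper)

  # Stress-trajectory reuse. The day-1 stress state is shared by every
  # candidate (the initial field is fixed and the suppression factor does
  # not involve the diffusivities), so it is computed once. For candidates
  # within 0.5 percent of the last fully solved one -- the forward-
  # difference Jacobian columns, whose relative step is ~1e-3 -- the whole
  # suppression trajectory is reused: the stress perturbation it ignores is
  # second order in the parameter step. Residuals at full Levenberg-
  # Marquardt steps always re-solve the mechanics.
  mcache <- new.env(parent = emptyenv())
  mcache$par <- NULL
  mcache$traj <- NULL
  nvox <- prod(domain$grid$shape)
  mres <- (length(observed$days) - 1L) * 2L * nvox

  wrap <- function(p) {
    near <- !is.null(mcache$par) &&
      max(abs(p / mcache$par - 1)) < 5e-3
    traj <- if (near) mcache$traj
            else if (!is.null(mcache$traj)) mcache$traj[1]
            else NULL
    sim <- tryCatch(
      forward_for_calibration(p, observed, fixed, domain, config$dt,
                              config$mechanics_interval, traj),
      error = function(e) e)
    if (inherits(sim, "error")) {
      warning("forward model failed during calibration (",
              conditionMessage(sim), "); returning penalty residual")
      return(rep(1e3, mres))
    }
    if (!near) {
      mcache$par <- p
      mcache$traj <- sim$suppression
    }
    residuals_from_sim(sim, observed, config$weights)
  }

  as_params <- function(p) {
    out <- fixed
    out$D_t0 <- p[1]; out$D_v0 <- p[2]; out$k_t <- p[3]; out$k_v <- p[4]
    out
  }

  if (config$maxiter == 0) {
    r0 <- wrap(guess)
    return(structure(list(estimated = as_params(guess),
                          initial_guess = as_params(guess),
                          objective_trace = sum(r0^2),
                          converged = FALSE, n_iterations = 0L,
                          message = "maxiter = 0: initial guess returned"),
                     class = "calibration_result"))
  }

  fit <- minpack.lm::nls.lm(par = guess, lower = config$lower,
                            upper = config$upper, fn = wrap,
                            control = minpack.lm::nls.lm.control(
                              ftol = config$ftol, ptol = config$ptol,
                              maxiter = config$maxiter,
                              epsfcn = config$epsfcn))

  structure(list(estimated = as_params(fit$par),
                 initial_guess = as_params(guess),
                 objective_trace = fit$rsstrace,
                 converged = fit$info %in% 1:4,
                 n_iterations = fit$niter,
                 message = fit$message),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> converged=%s after %d iterations\n",
              x$converged, x$n_iterations))
  print(x$estimated)
  invisible(x)
}

#' Predict forward with calibrated parameters
#'
#' Forward simulation from the (degraded) day-1 state with the estimated
#' parameters, recording every integer day through the horizon.
#'
#' @param result a `calibration_result` (or `model_parameters`).
#' @param initial list with day-1 `N_t` and `N_v` fields.
#' @param domain [build_tissue_domain()] domain.
#' @param horizon last day to simulate (>= the last calibration day).
#' @param dt,mechanics_interval forward-model settings.
#' @return A `time_course` with snapshots at days 1..horizon.
#' @export
predict_growth <- function(result, initial, domain, horizon = 10,
                           dt = 0.01, mechanics_interval = 1) {
  params <- if (inherits(result, "calibration_result")) result$estimated
            else result
  simulate_growth(initial, params, domain, days = horizon, dt = dt,
                  mechanics_interval = mechanics_interval)
}
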