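#' Vasculature-dependent carrying capacity
#'
#' The total carrying capacity rises linearly from `theta_min` at zero
#' vasculature to `theta_max` at the vasculature threshold and saturates
#' there; it is continuous at the threshold.
#'
#' @param N_v vasculature fractions (array, vector or `scalar_field`).
#' @param theta_min,theta_max capacity bounds.
#' @param N_v_thresh vasculature fraction supporting the maximum capacity.
#' @return Carrying capacities with the shape of the input.
#' @export
carrying_capacity <- function(N_v, theta_min = 0.1, theta_max = 0.9716,
                              N_v_thresh = 0.022) {
  v <- if (inherits(N_v, "scalar_field")) N_v$values else N_v
  th <- ifelse(v < N_v_thresh,
               theta_min + v * (theta_max - theta_min) / N_v_thresh,
               theta_max)
  if (inherits(N_v, "scalar_field"))
    scalar_field(array(th, dim = dim(v)), N_v$grid, "capacity", check = FALSE)
  else th
}

#' Normalized distance to the tumor periphery
#'
#' Voxels above `threshold` form the tumor mask. Within the mask, depth is
#' the exact Euclidean distance (mm, anisotropic spacing respected) to the
#' nearest mask-boundary voxel; `d = 1 - depth / max(depth)`, so boundary
#' voxels have d = 1 and the deepest voxel d = 0. Outside the mask d = 1.
#' An empty mask yields d = 1 everywhere (no tumor, hence no regression
#' zone).
#'
#' @param N_t tumor-fraction `scalar_field`.
#' @param threshold absolute tumor fraction defining the mask.
#' @return A `"distance"` `scalar_field` with values in `[0, 1]`.
#' @export
distance_to_periphery <- function(N_t, threshold) {
  g <- N_t$grid
  mask <- N_t$values > threshold
  d <- periphery_distance_cpp(as.vector(mask), g$shape, g$spacing)
  scalar_field(array(d, dim = g$shape), g, "distance", check = FALSE)
}

# explicit-Euler diffusion stability audit
check_stability <- function(D_max, spacing, dt, what) {
  lim <- 2 * D_max * sum(1 / spacing^2)
  if (dt * lim > 1)
    stop(sprintf(
      "time step dt=%g violates the explicit stability bound for %s (max D = %g mm^2/day; need dt <= %g)",
      dt, what, D_max, 1 / lim))
  invisible(TRUE)
}

# refresh the stress-modulated diffusivity fields from the current N_t;
# `supp` is the stress suppression factor exp(-gamma sigma_vm / 1000),
# which depends on N_t, lambda_f and gamma but not on the diffusivities
mechanics_update <- function(nt_arr, domain, params) {
  g <- domain$grid
  if (params$lambda_f == 0) {
    supp <- array(1, g$shape)
  } else {
    st <- solve_equilibrium(scalar_field(nt_arr, g, "tumor_fraction",
                                         check = FALSE),
                            domain, params$lambda_f)
    supp <- exp(-params$gamma_stress * st$von_mises$values / 1000)
  }
  list(D_t = params$D_t0 * supp, D_v = params$D_v0 * supp, supp = supp)
}

#' Advance the coupled tumor/vasculature system
#'
#' One (or several) explicit forward-Euler steps of the coupled
#' reaction-diffusion system: self-diffusion of each species damped by the
#' other species' share of the carrying capacity, cross-diffusion driven by
#' the other species' gradient, logistic tumor proliferation, and
#' distance-gated angiogenesis (at the tumor periphery, d = 1) and vessel
#' regression (in the core, d = 0). Fluxes are divergence-form with
#' face-averaged diffusivities and vanish across the brain-mask boundary;
#' after each step both species are clipped to `[0, theta_tot]`. The
#' carrying capacity and periphery distance are refreshed every step (the
#' distance cadence is configurable); the diffusivity fields are held fixed
#' for the duration of the call.
#'
#' @param N_t,N_v species `scalar_field`s.
#' @param D_t,D_v diffusivity `scalar_field`s (typically from
#'   [stress_modulated_diffusion()], or constant).
#' @param params [model_parameters()].
#' @param domain [build_tissue_domain()] domain.
#' @param dt time step, days; must satisfy the explicit stability bound.
#' @param nsteps number of steps to take.
#' @param mask_threshold_frac tumor-mask threshold for the periphery
#'   distance, as a fraction of `theta_max`.
#' @param d_update_every steps between periphery-distance refreshes.
#' @return A list with updated `N_t`, `N_v` fields plus the last periphery
#'   distance `d` and capacity `theta_tot` fields.
#' @export
growth_step <- function(N_t, N_v, D_t, D_v, params, domain, dt,
                        nsteps = 1L, mask_threshold_frac = 0.05,
                        d_update_every = 1L) {
  if (dt <= 0) stop("dt must be > 0")
  g <- domain$grid
  check_stability(max(D_t$values), g$spacing, dt, "tumor diffusion (D_t)")
  check_stability(max(D_v$values), g$spacing, dt, "vasculature diffusion (D_v)")
  res <- rd_advance_cpp(as.vector(N_t$values), as.vector(N_v$values),
                        as.vector(D_t$values), as.vector(D_v$values),
                        as.vector(domain$brain_mask), g$shape, g$spacing,
                        params$theta_min, params$theta_max, params$N_v_thresh,
                        params$k_t, params$k_v, params$k_dv,
                        mask_threshold_frac * params$theta_max,
                        dt, as.integer(nsteps), as.integer(d_update_every))
  list(N_t = scalar_field(array(res$N_t, g$shape), g, "tumor_fraction",
                          check = FALSE),
       N_v = scalar_field(array(res$N_v, g$shape), g, "vasculature_fraction",
                          check = FALSE),
       d = scalar_field(array(res$d, g$shape), g, "distance", check = FALSE),
       theta_tot = scalar_field(array(res$theta_tot, g$shape), g, "capacity",
                                check = FALSE))
}

#' Simulate a multi-day growth time course
#'
#' Advances the model from the day-1 initial condition and records a
#' snapshot of both species at every integer day. The mechanical equilibrium
#' is re-solved (and the stress-modulated diffusivity fields refreshed)
#' every `mechanics_interval` days, starting at day 1; the carrying capacity
#' and periphery distance are refreshed every step. The forward model is
#' fully deterministic.
#'
#' @param initial list with day-1 `N_t` and `N_v` `scalar_field`s.
#' @param params [model_parameters()].
#' @param domain [build_tissue_domain()] domain.
#' @param days horizon; snapshots at days 1..days (day 1 is the initial
#'   condition).
#' @param dt time step in days; must divide one day evenly.
#' @param mechanics_interval days between equilibrium solves.
#' @param mask_threshold_frac,d_update_every see [growth_step()].
#' @param suppression_trajectory optional list of precomputed
#'   stress-suppression fields `exp(-gamma sigma_vm / 1000)`, one per
#'   mechanics event (the day-1 solve, then one per scheduled re-solve);
#'   events beyond the list length are solved fresh. The suppression
#'   depends on the tumor field, `lambda_f` and `gamma_stress` but not on
#'   the diffusivities, so the day-1 entry can always be shared between
#'   candidate parameter sets that start from one observed state, and a
#'   full trajectory can be reused across infinitesimally perturbed
#'   candidates (finite-difference Jacobian columns).
#' @return An object of class `time_course`: `days`, lists `N_t` and `N_v`
#'   of per-day fields, `parameters`, `grid` and the solver settings.
#' @export
simulate_growth <- function(initial, params, domain, days = 10, dt = 0.01,
                            mechanics_interval = 1,
                            mask_threshold_frac = 0.05,
                            d_update_every = 1L,
                            suppression_trajectory = NULL) {
  if (days < 1) stop("days must be >= 1")
  spd <- round(1 / dt)
  if (abs(spd * dt - 1) > 1e-9)
    stop("dt must divide one day evenly")
  g <- domain$grid

  nt <- initial$N_t$values
  nv <- initial$N_v$values
  snaps_t <- vector("list", days)
  snaps_v <- vector("list", days)
  snaps_t[[1]] <- initial$N_t
  snaps_v[[1]] <- initial$N_v

  supp_traj <- list()
  event <- 0L
  next_mech <- function(nt_now) {
    event <<- event + 1L
    if (event <= length(suppression_trajectory)) {
      s <- suppression_trajectory[[event]]
      supp_traj[[event]] <<- s
      list(D_t = params$D_t0 * s, D_v = params$D_v0 * s, supp = s)
    } else {
      m <- mechanics_update(nt_now, domain, params)
      supp_traj[[event]] <<- m$supp
      m
    }
  }

  mech <- next_mech(nt)
  check_stability(max(mech$D_t), g$spacing, dt, "tumor diffusion (D_t)")
  check_stability(max(mech$D_v), g$spacing, dt, "vasculature diffusion (D_v)")
  mask_thr <- mask_threshold_frac * params$theta_max

  if (days > 1) {
    for (day in 2:days) {
      elapsed <- day - 2          # days completed before this block
      if (elapsed > 0 && mechanics_interval > 0 &&
          elapsed %% mechanics_interval == 0)
        mech <- next_mech(nt)
      res <- rd_advance_cpp(as.vector(nt), as.vector(nv),
                            as.vector(mech$D_t), as.vector(mech$D_v),
                            as.vector(domain$brain_mask), g$shape, g$spacing,
                            params$theta_min, params$theta_max,
                            params$N_v_thresh,
                            params$k_t, params$k_v, params$k_dv,
                            mask_thr, dt, spd, as.integer(d_update_every))
      nt <- array(res$N_t, g$shape)
      nv <- array(res$N_v, g$shape)
      snaps_t[[day]] <- scalar_field(nt, g, "tumor_fraction", check = FALSE)
      snaps_v[[day]] <- scalar_field(nv, g, "vasculature_fraction",
                                     check = FALSE)
    }
  }

  structure(list(days = seq_len(days), N_t = snaps_t, N_v = snaps_v,
                 parameters = params, grid = g,
                 suppression = supp_traj,
                 settings = list(dt = dt,
                                 mechanics_interval = mechanics_interval,
                                 mask_threshold_frac = mask_threshold_frac,
                                 d_update_every = d_update_every)),
            class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf("<time_course> days %s\n",
              paste(range(x$days), collapse = "-")))
  print(x$grid)
  invisible(x)
}

#' Total species mass of a field (fraction x mm^3)
#' @param field a `scalar_field`.
#' @return Sum of values times voxel volume.
#' @export
field_mass <- function(field) sum(field$values) * voxel_volume(field$grid)

#' Persist / load a time course
#'
#' One NIfTI volume per day and species plus a JSON manifest holding the
#' parameters, grid geometry and solver settings.
#'
#' @param tc a `time_course`.
#' @param dir output directory (created if needed).
#' @return `write_timecourse` returns `dir` invisibly; `read_timecourse`
#'   returns the `time_course`.
#' @export
write_timecourse <- function(tc, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(tc$days)) {
    write_field(tc$N_t[[i]], file.path(dir, sprintf("day%02d_Nt.nii.gz",
                                                    tc$days[i])))
    write_field(tc$N_v[[i]], file.path(dir, sprintf("day%02d_Nv.nii.gz",
                                                    tc$days[i])))
  }
  manifest <- list(days = tc$days, parameters = unclass(tc$parameters),
                   grid = unclass(tc$grid), settings = tc$settings)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_timecourse
#' @export
read_timecourse <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  g <- grid3d(man$grid$shape, man$grid$spacing, man$grid$origin)
  days <- man$days
  nt <- lapply(days, function(d)
    read_field(file.path(dir, sprintf("day%02d_Nt.nii.gz", d)),
               "tumor_fraction", g$origin))
  nv <- lapply(days, function(d)
    read_field(file.path(dir, sprintf("day%02d_Nv.nii.gz", d)),
               "vasculature_fraction", g$origin))
  params <- do.call(model_parameters, man$parameters)
  structure(list(days = days, N_t = nt, N_v = nv, parameters = params,
                 grid = g, settings = man$settings),
            class = "time_course")
}
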