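#' Dice similarity coefficient between binarized fields
#'
#' Fields are binarized at `threshold`; Dice = 2|A n B| / (|A| + |B|).
#' When both masks are empty the agreement is trivially perfect and 1 is
#' returned.
#'
#' @param predicted,truth `scalar_field`s on a common grid.
#' @param threshold absolute binarization threshold.
#' @param mask optional logical array restricting the evaluation (e.g. the
#'   brain mask).
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_coefficient <- function(predicted, truth, threshold, mask = NULL) {
  if (!grids_identical(predicted$grid, truth$grid))
    stop("predicted and truth fields are on different grids")
  A <- predicted$values > threshold
  B <- truth$values > threshold
  if (!is.null(mask)) { A <- A & mask; B <- B & mask }
  na <- sum(A); nb <- sum(B)
  if (na + nb == 0L) return(1)
  2 * sum(A & B) / (na + nb)
}

#' Lin's concordance correlation coefficient
#'
#' Voxelwise agreement between prediction and truth over the detection set:
#' voxels where either field exceeds `detection_threshold` (optionally
#' within a mask). Uses population moments:
#' `CCC = 2 cov(p, t) / (var(p) + var(t) + (mean(p) - mean(t))^2)`.
#' A degenerate evaluation set (fewer than two voxels, or both fields
#' constant) raises an error rather than silently returning a value.
#'
#' @param predicted,truth `scalar_field`s on a common grid.
#' @param detection_threshold absolute threshold defining the evaluation
#'   set (union of supra-threshold voxels of the two fields).
#' @param mask optional logical array restricting the evaluation.
#' @return CCC in `[-1, 1]`.
#' @export
lins_ccc <- function(predicted, truth, detection_threshold, mask = NULL) {
  if (!grids_identical(predicted$grid, truth$grid))
    stop("predicted and truth fields are on different grids")
  sel <- (predicted$values > detection_threshold) |
    (truth$values > detection_threshold)
  if (!is.null(mask)) sel <- sel & mask
  if (sum(sel) < 2L)
    stop("undefined CCC: fewer than two voxels in the evaluation set")
  p <- predicted$values[sel]; t <- truth$values[sel]
  mp <- mean(p); mt <- mean(t)
  vp <- mean((p - mp)^2); vt <- mean((t - mt)^2)
  if (vp + vt == 0)
    stop("undefined CCC: both fields are constant on the evaluation set")
  cv <- mean((p - mp) * (t - mt))
  2 * cv / (vp + vt + (mp - mt)^2)
}

#' Percent error of an estimate
#'
#' `100 |estimated - true| / |true|`; scale-invariant and symmetric in the
#' relative sense.
#'
#' @param true_value reference value (nonzero).
#' @param estimated estimate.
#' @return Percent error (>= 0).
#' @export
percent_error <- function(true_value, estimated) {
  if (any(true_value == 0)) stop("percent error undefined for a true value of 0")
  100 * abs(estimated - true_value) / abs(true_value)
}

#' Spatial scale of the in silico study
#'
#' Defines the field of view and the spatial-resolution ladder. The base
#' grid carries the 0.063 mm^3 voxel volume; the other resolutions scale
#' every voxel spacing by a common per-axis factor (0.5 for 0.008 mm^3,
#' 2 for 0.50 mm^3). The default 3.5 x 3.5 x 6 mm field of view puts the
#' finest grid at 28 x 28 x 12 voxels, a desk-scale analogue of a
#' whole-brain acquisition.
#'
#' @param fov field of view, mm per axis.
#' @param base_spacing voxel spacing of the base (0.063 mm^3) grid, mm.
#' @return A list with the scale settings.
#' @export
study_scale <- function(fov = c(3.5, 3.5, 6), base_spacing = c(0.25, 0.25, 1)) {
  shape <- fov / base_spacing
  if (any(abs(shape - round(shape)) > 1e-9))
    stop("fov must be an integer number of base voxels per axis")
  list(fov = fov, base_spacing = base_spacing)
}

#' Grid of the spatial-resolution ladder for a voxel volume
#'
#' @param scale a [study_scale()].
#' @param voxel_volume target voxel volume (mm^3); must correspond to a
#'   power-of-two per-axis factor relative to the base spacing.
#' @return An [grid3d()] grid covering the field of view.
#' @export
resolution_grid <- function(scale, voxel_volume) {
  f <- (voxel_volume / prod(scale$base_spacing))^(1 / 3)
  f2 <- 2^round(log2(f))
  if (abs(f / f2 - 1) > 0.12)
    stop(sprintf("voxel volume %g mm^3 is not on the resolution ladder",
                 voxel_volume))
  spacing <- scale$base_spacing * f2
  shape <- scale$fov / spacing
  if (any(abs(shape - round(shape)) > 1e-9))
    stop("field of view is not divisible by the target spacing")
  grid3d(round(shape), spacing)
}

#' Run the SNR x SR x TR experiment grid
#'
#' For every tumor specification, condition and noise replicate: build the
#' SR-specific domain and noiseless ground truth, degrade it (noise +
#' timepoint subset), calibrate the four global parameters from the
#' degraded days, predict to the horizon, and score the prediction against
#' the same-SR noiseless ground truth at the evaluation days. Rows that
#' fail at any stage are recorded with a failure code and the grid
#' continues. Fully reproducible from the master seed via a counter-based
#' per-row seed fan-out.
#'
#' @param cohort list of `virtual_tumor_spec`s (see
#'   [build_virtual_cohort()]).
#' @param conditions data frame from [experiment_conditions()] (or a
#'   subset).
#' @param replicates named vector `c(central = ..., variant = ...)` of noise
#'   replicates per tumor, or a single count for all tumors.
#' @param seed master seed.
#' @param scale [study_scale()] of the simulation.
#' @param domain_cfg,lesion_cfg domain / lesion settings.
#' @param horizon prediction horizon (days).
#' @param eval_days days at which predictions are scored.
#' @param dt,mechanics_interval forward-model settings.
#' @param threshold_frac binarization / detection threshold for Dice, CCC
#'   and the periphery distance, as a fraction of `theta_max`.
#' @param progress print one line per tumor x condition.
#' @return A data frame with one row per (tumor, condition, replicate):
#'   estimated parameters, percent errors, Dice and CCC at the evaluation
#'   days, convergence info and status.
#' @export
run_experiment_grid <- function(cohort,
                                conditions = experiment_conditions(),
                                replicates = c(central = 50, variant = 5),
                                seed = 1L,
                                scale = study_scale(),
                                domain_cfg = domain_config(),
                                lesion_cfg = lesion_config(),
                                horizon = 10, eval_days = c(6, 10),
                                dt = 0.01, mechanics_interval = 1,
                                threshold_frac = 0.05,
                                progress = FALSE) {
  if (length(replicates) == 1L && is.null(names(replicates)))
    replicates <- c(central = replicates, variant = replicates)
  vols <- unique(conditions$voxel_volume)

  # SR-specific domains are shared by every tumor (and their cached
  # elasticity factorizations with them)
  domains <- lapply(vols, function(v)
    build_tissue_domain(resolution_grid(scale, v), domain_cfg,
                        seed = derive_seed(seed, 0)))
  names(domains) <- as.character(vols)

  # The initial condition is synthesized once at the finest resolution of
  # the ladder and resampled to each SR, mirroring an acquisition at the
  # best spatial resolution that is then down-sampled: with cell-centered
  # grids the lesion peak would otherwise be sampled very differently by
  # each lattice.
  fine_dom <- build_tissue_domain(resolution_grid(scale, 0.008), domain_cfg,
                                  seed = derive_seed(seed, 0))
  ic_fine <- synthesize_initial_conditions(fine_dom, lesion_cfg,
                                           seed = derive_seed(seed, 1))
  ic_for <- function(domain) {
    vol <- voxel_volume(domain$grid)
    nt <- resample_field(ic_fine$N_t, target_voxel_volume = vol)
    nv <- resample_field(ic_fine$N_v, target_voxel_volume = vol)
    nt$values[!domain$brain_mask] <- 0
    nv$values[!domain$brain_mask] <- 0
    list(N_t = nt, N_v = nv)
  }

  rows <- list()
  counter <- 0L
  for (spec in cohort) {
    truth <- spec$parameters
    thr <- threshold_frac * truth$theta_max
    n_rep <- unname(if (spec$tumor_id == "central") replicates["central"]
                    else replicates["variant"])
    for (v in vols) {
      domain <- domains[[as.character(v)]]
      ic <- ic_for(domain)
      gt <- simulate_growth(ic, truth, domain, days = horizon, dt = dt,
                            mechanics_interval = mechanics_interval,
                            mask_threshold_frac = threshold_frac)
      conds_v <- conditions[conditions$voxel_volume == v, , drop = FALSE]
      for (ci in seq_len(nrow(conds_v))) {
        cond <- conds_v[ci, , drop = FALSE]
        if (progress)
          message(sprintf("tumor %s | %s", spec$tumor_id, cond$condition_id))
        for (rep_i in seq_len(n_rep)) {
          counter <- counter + 1L
          rseed <- derive_seed(seed, counter)
          row <- data.frame(tumor_id = spec$tumor_id,
                            condition_id = cond$condition_id,
                            snr = cond$snr, voxel_volume = cond$voxel_volume,
                            tr = cond$tr, replicate = rep_i, seed = rseed,
                            stringsAsFactors = FALSE)
          out <- tryCatch({
            degraded <- degrade_timecourse(gt, cond, rseed,
                                           theta_max = truth$theta_max)
            cfg <- calibration_config(truth = truth, dt = dt,
                                      mechanics_interval = mechanics_interval)
            fit <- calibrate_growth(degraded, domain, fixed = truth,
                                    config = cfg, seed = rseed)
            pred <- predict_growth(fit,
                                   list(N_t = degraded$N_t[[1]],
                                        N_v = degraded$N_v[[1]]),
                                   domain, horizon = horizon, dt = dt,
                                   mechanics_interval = mechanics_interval)
            est <- fit$estimated
            met <- list(D_t0_hat = est$D_t0, D_v0_hat = est$D_v0,
                        k_t_hat = est$k_t, k_v_hat = est$k_v,
                        pe_Dt = percent_error(truth$D_t0, est$D_t0),
                        pe_Dv = percent_error(truth$D_v0, est$D_v0),
                        pe_kt = percent_error(truth$k_t, est$k_t),
                        pe_kv = percent_error(truth$k_v, est$k_v),
                        converged = fit$converged,
                        n_iterations = fit$n_iterations)
            for (d in eval_days) {
              i <- match(d, gt$days)
              met[[paste0("dice_day", d)]] <- dice_coefficient(
                pred$N_t[[i]], gt$N_t[[i]], thr, domain$brain_mask)
              met[[paste0("ccc_tumor_day", d)]] <- tryCatch(
                lins_ccc(pred$N_t[[i]], gt$N_t[[i]], thr, domain$brain_mask),
                error = function(e) NA_real_)
              met[[paste0("ccc_vasc_day", d)]] <- tryCatch(
                lins_ccc(pred$N_v[[i]], gt$N_v[[i]], thr, domain$brain_mask),
                error = function(e) NA_real_)
            }
            met$status <- "ok"
            met
          }, error = function(e) list(status = paste0("failed: ",
                                                      conditionMessage(e))))
          for (nm in names(out)) row[[nm]] <- out[[nm]]
          rows[[counter]] <- row
        }
      }
    }
  }
  nms <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (nm in setdiff(nms, names(r))) r[[nm]] <- NA
    r[nms]
  })
  do.call(rbind, rows)
}

#' Summarize experiment-grid metrics as median and interquartile range
#'
#' Per (tumor, condition, metric): the median and the 25/75 percent
#' quartiles (linear interpolation between order statistics, R quantile
#' type 7).
#'
#' @param tbl data frame from [run_experiment_grid()].
#' @param metrics metric columns to summarize; defaults to all percent
#'   errors, Dice and CCC columns present.
#' @return A long data frame with columns `tumor_id`, `condition_id`,
#'   `snr`, `voxel_volume`, `tr`, `metric`, `n`, `median`, `q25`, `q75`.
#' @export
summarize_metrics <- function(tbl, metrics = NULL) {
  if (is.null(metrics))
    metrics <- grep("^(pe_|dice_|ccc_)", names(tbl), value = TRUE)
  ok <- tbl[tbl$status == "ok", , drop = FALSE]
  if (!nrow(ok)) stop("no successful rows to summarize")
  keys <- unique(ok[, c("tumor_id", "condition_id", "snr", "voxel_volume",
                        "tr")])
  out <- list()
  k <- 0L
  for (i in seq_len(nrow(keys))) {
    sel <- ok$tumor_id == keys$tumor_id[i] &
      ok$condition_id == keys$condition_id[i]
    for (m in metrics) {
      vals <- ok[[m]][sel]
      vals <- vals[!is.na(vals)]
      if (!length(vals)) {
        warning(sprintf("no valid values for %s in %s/%s; cell omitted",
                        m, keys$tumor_id[i], keys$condition_id[i]))
        next
      }
      k <- k + 1L
      out[[k]] <- data.frame(keys[i, , drop = FALSE], metric = m,
                             n = length(vals),
                             median = stats::median(vals),
                             q25 = unname(stats::quantile(vals, 0.25,
                                                          type = 7)),
                             q75 = unname(stats::quantile(vals, 0.75,
                                                          type = 7)),
                             stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  do.call(rbind, out)
}
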