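#' The in silico image-quality experiment grid
#'
#' Enumerates the full factorial grid of acquisition conditions: six
#' signal-to-noise ratios (5, 10, 20, 40, 80, 160), three spatial
#' resolutions (voxel volumes 0.008, 0.063, 0.50 mm^3) and three temporal
#' resolutions (calibration days 1+5, 1+3+5, or 1-5), 54 cells in all.
#'
#' @return A data frame with one row per condition: `condition_id`, `snr`,
#'   `voxel_volume` (mm^3), `tr` (label) and `tr_days` (list column of
#'   calibration days).
#' @export
experiment_conditions <- function() {
  snr <- c(5, 10, 20, 40, 80, 160)
  vol <- c(0.008, 0.063, 0.50)
  trs <- list(`2` = c(1, 5), `3` = c(1, 3, 5), `5` = c(1, 2, 3, 4, 5))
  grid <- expand.grid(snr = snr, voxel_volume = vol, tr = names(trs),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$tr_days <- trs[grid$tr]
  grid$condition_id <- sprintf("snr%g_sr%g_tr%s", grid$snr,
                               grid$voxel_volume, grid$tr)
  grid[, c("condition_id", "snr", "voxel_volume", "tr", "tr_days")]
}

#' Degrade the signal-to-noise ratio of a field
#'
#' Multiplies each voxel by an independent Normal(1, 1/SNR) draw and clips
#' the result to the physical volume-fraction range. Deterministic for a
#' fixed seed; zeros are preserved exactly (the noise is multiplicative).
#'
#' @param field a `scalar_field`.
#' @param snr signal-to-noise ratio (> 0; `Inf` is a no-op).
#' @param seed integer RNG seed.
#' @param clip lower/upper clipping bounds; the default keeps volume
#'   fractions in `[0, 0.9716]`.
#' @return The degraded `scalar_field`.
#' @export
add_noise <- function(field, snr, seed, clip = c(0, 0.9716)) {
  if (!is.numeric(snr) || length(snr) != 1L || is.na(snr) || snr <= 0)
    stop("snr must be a single positive number")
  v <- field$values
  if (is.finite(snr)) {
    mult <- with_seed(seed, stats::rnorm(length(v), mean = 1, sd = 1 / snr))
    v <- v * array(mult, dim = dim(v))
  }
  v <- pmin(pmax(v, clip[1]), clip[2])
  scalar_field(array(v, dim = dim(field$values)), field$grid, field$role,
               check = FALSE)
}

#' Restrict a time course to selected calibration days
#'
#' @param tc a `time_course`.
#' @param tr_days integer vector of days to keep (all must be present).
#' @return The `time_course` containing only the requested days.
#' @export
select_timepoints <- function(tc, tr_days) {
  miss <- setdiff(tr_days, tc$days)
  if (length(miss))
    stop("requested day(s) not present in the time course: ",
         paste(miss, collapse = ", "))
  keep <- match(tr_days, tc$days)
  out <- tc
  out$days <- tc$days[keep]
  out$N_t <- tc$N_t[keep]
  out$N_v <- tc$N_v[keep]
  out
}

#' Produce in silico experimental data for one condition
#'
#' Applies the degradation protocol to a ground-truth time course already at
#' the condition's spatial resolution: independent multiplicative noise per
#' retained day and species (seeds fanned out deterministically from
#' `replicate_seed`), then restriction to the condition's calibration days.
#'
#' @param tc ground-truth `time_course` at the condition's spatial
#'   resolution.
#' @param condition one row of [experiment_conditions()] (or a list with
#'   `snr` and `tr_days`).
#' @param replicate_seed integer seed identifying the noise replicate.
#' @param theta_max upper clipping bound for the noisy fractions.
#' @return The degraded `time_course` restricted to the calibration days.
#' @export
degrade_timecourse <- function(tc, condition, replicate_seed,
                               theta_max = 0.9716) {
  tr_days <- if (is.list(condition$tr_days)) condition$tr_days[[1]] else
    condition$tr_days
  sub <- select_timepoints(tc, tr_days)
  snr <- condition$snr
  for (i in seq_along(sub$days)) {
    day <- sub$days[i]
    sub$N_t[[i]] <- add_noise(sub$N_t[[i]], snr,
                              derive_seed(replicate_seed, 2 * day),
                              clip = c(0, theta_max))
    sub$N_v[[i]] <- add_noise(sub$N_v[[i]], snr,
                              derive_seed(replicate_seed, 2 * day + 1),
                              clip = c(0, theta_max))
  }
  sub
}
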