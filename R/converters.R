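#' Convert an ADC map to tumor cellularity
#'
#' Maps the apparent diffusion coefficient to a tumor volume fraction by
#' linear rescaling between the ADC of free water at body temperature and
#' the minimum ADC within the field of view:
#' `N_t = theta_max * (ADC_w - ADC) / (ADC_w - ADC_min)`, clipped to
#' `[0, theta_max]`. `ADC_min` is always taken as the minimum of the supplied
#' field.
#'
#' @param adc a `scalar_field` of ADC values (mm^2/s), all > 0.
#' @param theta_max maximum tumor carrying capacity.
#' @param adc_w ADC of free water at 37 C, mm^2/s.
#' @return A `scalar_field` of tumor volume fractions.
#' @export
adc_to_cellularity <- function(adc, theta_max = 0.9716, adc_w = 3e-3) {
  v <- adc$values
  if (min(v) <= 0) stop("adc values must be > 0")
  adc_min <- min(v)
  if (abs(adc_w - adc_min) < .Machine$double.eps * adc_w)
    stop("degenerate ADC field: ADC_min equals ADC_w, the cellularity map is undefined")
  nt <- theta_max * (adc_w - v) / (adc_w - adc_min)
  nt <- pmin(pmax(nt, 0), theta_max)
  scalar_field(array(nt, dim = dim(v)), adc$grid, "tumor_fraction",
               check = FALSE)
}

#' Convert a DCE concentration time course to a vascularity map
#'
#' The blood volume fraction is the ratio of the time integrals of the voxel
#' contrast-agent concentration and of the arterial input function (AIF)
#' over the first `window_s` seconds after injection, so a voxel whose
#' time course equals the AIF has blood volume fraction 1. Integrals are
#' trapezoidal on the common time base.
#'
#' @param concentration 4-D numeric array (x, y, z, time) of concentrations.
#' @param aif numeric vector, AIF concentration at the same time points;
#'   must be strictly positive over the window.
#' @param times numeric vector of sample times, seconds post-injection.
#' @param grid the `rd_grid` of the spatial axes.
#' @param window_s integration window, seconds.
#' @return A `scalar_field` of vasculature volume fractions.
#' @export
dce_to_vascularity <- function(concentration, aif, times, grid,
                               window_s = 60) {
  dims <- dim(concentration)
  if (length(dims) != 4L) stop("concentration must be a 4-D (x,y,z,t) array")
  if (length(aif) != dims[4] || length(times) != dims[4])
    stop("mismatched time bases: concentration, aif and times must share one time axis")
  sel <- times <= window_s
  if (sum(sel) < 2L) stop("need at least two samples inside the window")
  if (any(aif[sel] <= 0)) stop("AIF must be strictly positive over the window")

  tw <- times[sel]
  trap_w <- diff(tw)
  w <- c(trap_w / 2, 0) + c(0, trap_w / 2)  # trapezoid weights
  aif_int <- sum(aif[sel] * w)
  if (aif_int <= 0) stop("nonpositive AIF integral")

  cmat <- matrix(concentration, nrow = prod(dims[1:3]), ncol = dims[4])
  cint <- as.vector(cmat[, sel, drop = FALSE] %*% w)
  nv <- array(cint / aif_int, dim = dims[1:3])
  scalar_field(nv, grid, "vasculature_fraction", check = FALSE)
}

#' Synthetic ADC / DCE emulators
#'
#' Inverse maps used to exercise the MRI converters on synthetic data:
#' `synthesize_adc` inverts the cellularity relation for a chosen in-field
#' minimum ADC; `synthesize_dce` builds a separable concentration time
#' course `C(x, t) = N_v(x) * AIF(t)`, the exact forward model of the
#' ratio-of-integrals vascularity estimate.
#'
#' @param N_t,N_v `scalar_field`s of tumor / vasculature fractions.
#' @param theta_max maximum carrying capacity used in the forward relation.
#' @param adc_w free-water ADC, mm^2/s.
#' @param adc_min ADC assigned to a voxel at `theta_max`, mm^2/s.
#' @param aif AIF samples (positive) at `times`.
#' @param times sample times, seconds.
#' @return `synthesize_adc`: an `"adc"` `scalar_field`; `synthesize_dce`: a
#'   4-D (x, y, z, t) concentration array.
#' @export
synthesize_adc <- function(N_t, theta_max = 0.9716, adc_w = 3e-3,
                           adc_min = 0.6e-3) {
  v <- adc_w - N_t$values / theta_max * (adc_w - adc_min)
  scalar_field(array(v, dim = dim(N_t$values)), N_t$grid, "adc",
               check = FALSE)
}

#' @rdname synthesize_adc
#' @export
synthesize_dce <- function(N_v, aif, times) {
  if (length(aif) != length(times)) stop("aif and times must align")
  dims <- c(dim(N_v$values), length(times))
  array(outer(as.vector(N_v$values), aif), dim = dims)
}

#' A population-shaped arterial input function
#'
#' A gamma-variate bolus shape `(t/tp)^a * exp(a (1 - t/tp))` peaking at
#' `tp` seconds, offset by a small recirculation plateau so the AIF stays
#' strictly positive over the first minute.
#'
#' @param times sample times, seconds post-injection.
#' @param peak_time bolus peak time, seconds.
#' @param sharpness gamma-variate shape parameter.
#' @param plateau late recirculation level relative to the peak.
#' @return Numeric vector of AIF concentrations (arbitrary units).
#' @export
default_aif <- function(times, peak_time = 12, sharpness = 3,
                        plateau = 0.1) {
  tt <- pmax(times, 0)
  g <- (tt / peak_time)^sharpness * exp(sharpness * (1 - tt / peak_time))
  g + plateau * (1 - exp(-tt / peak_time))
}
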