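#' Model parameters for the coupled tumor/vasculature model
#'
#' The four calibrated global rates/coefficients plus the fixed model
#' constants. Defaults are the central-tumor values: tumor and vasculature
#' diffusion 0.0263 and 0.0100 mm^2/day, tumor and vasculature proliferation
#' 0.45 and 0.25 /day; vessel death rate 0.125 /day; carrying-capacity
#' bounds 0.1 and 0.9716 with a vasculature threshold of 0.022; stress
#' sensitivity 0.25 per kPa of von Mises stress. The force-coupling constant
#' `lambda_f` (Pa per unit tumor-fraction gradient, scaled by length) is not
#' a literature constant; its default makes peak lesion stress comparable to
#' the tissue shear moduli (hundreds of Pa).
#'
#' @param D_t0 tumor diffusion coefficient, mm^2/day.
#' @param D_v0 vasculature diffusion coefficient, mm^2/day.
#' @param k_t tumor proliferation rate, 1/day.
#' @param k_v vasculature proliferation rate, 1/day.
#' @param k_dv vasculature death (regression) rate, 1/day.
#' @param theta_min,theta_max minimum/maximum voxel carrying capacity.
#' @param N_v_thresh vasculature fraction supporting the maximum capacity.
#' @param gamma_stress diffusion-stress sensitivity, 1/kPa.
#' @param lambda_f tumor-gradient force coupling constant, Pa.
#' @return An object of class `model_parameters`.
#' @export
model_parameters <- function(D_t0 = 0.0263, D_v0 = 0.0100,
                             k_t = 0.45, k_v = 0.25, k_dv = 0.125,
                             theta_min = 0.1, theta_max = 0.9716,
                             N_v_thresh = 0.022,
                             gamma_stress = 0.25, lambda_f = 15000) {
  p <- list(D_t0 = D_t0, D_v0 = D_v0, k_t = k_t, k_v = k_v, k_dv = k_dv,
            theta_min = theta_min, theta_max = theta_max,
            N_v_thresh = N_v_thresh, gamma_stress = gamma_stress,
            lambda_f = lambda_f)
  rates <- unlist(p[c("D_t0", "D_v0", "k_t", "k_v", "k_dv",
                      "gamma_stress", "lambda_f")])
  if (any(!is.finite(unlist(p))))
    stop("all model parameters must be finite")
  if (any(rates < 0)) stop("rates and coefficients must be >= 0")
  if (!(p$theta_min < p$theta_max))
    stop("theta_min must be smaller than theta_max")
  if (p$N_v_thresh <= 0 || p$N_v_thresh >= 1)
    stop("N_v_thresh must lie in (0, 1)")
  structure(p, class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat(sprintf(paste0("<model_parameters> D_t0=%g D_v0=%g mm^2/day; ",
                     "k_t=%g k_v=%g k_dv=%g /day\n  theta=[%g, %g], ",
                     "N_v_thresh=%g, gamma=%g /kPa, lambda_f=%g Pa\n"),
              x$D_t0, x$D_v0, x$k_t, x$k_v, x$k_dv, x$theta_min, x$theta_max,
              x$N_v_thresh, x$gamma_stress, x$lambda_f))
  invisible(x)
}

#' Geometry settings for the synthetic brain domain
#'
#' The synthetic domain is an ellipsoidal brain (gray matter) with an
#' ellipsoidal white-matter core whose boundary can be modulated by a
#' seeded low-order angular wobble, giving mild anatomical irregularity
#' while remaining deterministic for a fixed seed.
#'
#' @param brain_semiaxes ellipsoid semi-axes of the brain, mm.
#' @param center brain center, mm; `NULL` places it at the domain center.
#' @param white_fraction linear scale of the white-matter core relative to
#'   the brain semi-axes; 0 disables white matter (all-gray domain).
#' @param wobble relative amplitude of the seeded white-matter boundary
#'   modulation.
#' @param G_white,G_gray shear moduli, Pa.
#' @param poisson_ratio Poisson's ratio of brain tissue.
#' @return A plain list of settings.
#' @export
domain_config <- function(brain_semiaxes = c(1.4, 1.4, 1.7), center = NULL,
                          white_fraction = 0.55, wobble = 0.05,
                          G_white = 800, G_gray = 466,
                          poisson_ratio = 0.45) {
  list(brain_semiaxes = brain_semiaxes, center = center,
       white_fraction = white_fraction, wobble = wobble,
       G_white = G_white, G_gray = G_gray, poisson_ratio = poisson_ratio)
}

#' Build a synthetic two-tissue brain domain
#'
#' Discretizes the parametric brain geometry of [domain_config()] on a voxel
#' grid: a brain mask, white/gray tissue labels inside it, and the voxelwise
#' shear-modulus map (800 Pa in white matter, 466 Pa in gray matter). The
#' mask must leave at least a one-voxel margin at every domain face.
#'
#' @param grid an [grid3d()] grid.
#' @param config settings from [domain_config()].
#' @param seed integer; fixes the white-matter boundary wobble.
#' @return An object of class `tissue_domain` with elements `grid`,
#'   `brain_mask` (logical array), `tissue` (character array: `"white"`,
#'   `"gray"` or `"outside"`), `shear_modulus` (Pa, gray-matter value kept
#'   outside the mask where it is inert), `poisson_ratio`, `config`, `seed`.
#' @export
build_tissue_domain <- function(grid, config = domain_config(), seed = 1L) {
  ctr <- config$center %||% (grid$origin + grid$shape * grid$spacing / 2)
  ax <- config$brain_semiaxes
  xs <- voxel_centers(grid, 1); ys <- voxel_centers(grid, 2)
  zs <- voxel_centers(grid, 3)
  dx <- (xs - ctr[1]) / ax[1]
  dy <- (ys - ctr[2]) / ax[2]
  dz <- (zs - ctr[3]) / ax[3]
  r2 <- outer(outer(dx^2, dy^2, `+`), dz^2, `+`)
  brain <- r2 < 1

  if (!any(brain))
    stop("domain construction failed: grid too small to contain the brain")
  # margin check: no mask voxel on any boundary face of the array
  n <- grid$shape
  if (any(brain[c(1, n[1]), , ]) || any(brain[, c(1, n[2]), ]) ||
      any(brain[, , c(1, n[3])]))
    stop("domain construction failed: brain mask touches the domain boundary (need >= 1 voxel margin)")

  tissue <- array("outside", dim = n)
  tissue[brain] <- "gray"

  wf <- config$white_fraction
  if (wf > 0) {
    # white core: scaled ellipsoid with a seeded angular modulation of its
    # boundary radius
    ph <- with_seed(seed, stats::runif(2, 0, 2 * pi))
    X <- outer(outer(dx, rep(1, n[2]), `*`), rep(1, n[3]), `*`)
    Y <- outer(outer(rep(1, n[1]), dy, `*`), rep(1, n[3]), `*`)
    Z <- outer(outer(rep(1, n[1]), rep(1, n[2]), `*`), dz, `*`)
    rr <- sqrt(r2)
    theta <- atan2(Y, X)
    phi <- ifelse(rr > 0, acos(pmin(pmax(Z / pmax(rr, 1e-12), -1), 1)), 0)
    mod <- 1 + config$wobble * sin(3 * theta + ph[1]) * cos(2 * phi + ph[2])
    white <- brain & (rr < wf * mod)
    tissue[white] <- "white"
    if (!any(white) || !any(tissue == "gray"))
      stop("domain construction failed: grid too small to resolve both tissue classes")
  }

  Gmap <- array(config$G_gray, dim = n)
  Gmap[tissue == "white"] <- config$G_white

  structure(list(grid = grid, brain_mask = brain, tissue = tissue,
                 shear_modulus = Gmap, poisson_ratio = config$poisson_ratio,
                 config = config, seed = as.integer(seed),
                 cache = new.env(parent = emptyenv())),
            class = "tissue_domain")
}

#' @export
print.tissue_domain <- function(x, ...) {
  cat(sprintf("<tissue_domain> %d brain voxels (%d white, %d gray), nu=%g\n",
              sum(x$brain_mask), sum(x$tissue == "white"),
              sum(x$tissue == "gray"), x$poisson_ratio))
  print(x$grid)
  invisible(x)
}

#' Settings for the synthetic seed lesion
#'
#' The initial tumor is a smooth compact lesion: a raised-cosine
#' (cosine-squared) radial profile `peak * cos^2(pi * r / (2 * R))` inside
#' radius R, centered in the brain. The vasculature field is a physiological
#' background blood-volume fraction throughout the brain plus a co-localized
#' raised-cosine bump over a radius `vasc_radius_factor * R`.
#'
#' @param radius lesion radius R, mm.
#' @param peak_tumor peak tumor volume fraction at the lesion center
#'   (default: the maximum carrying capacity 0.9716).
#' @param vasc_background brain-wide baseline vasculature fraction.
#' @param peak_vasc amplitude of the lesion-co-localized vasculature bump.
#' @param vasc_radius_factor vasculature bump radius relative to `radius`.
#' @param center_jitter mm of seeded uniform jitter of the lesion center.
#' @return A plain list of settings.
#' @export
lesion_config <- function(radius = 0.6, peak_tumor = 0.9716,
                          vasc_background = 0.02, peak_vasc = 0.03,
                          vasc_radius_factor = 1.5, center_jitter = 0) {
  list(radius = radius, peak_tumor = peak_tumor,
       vasc_background = vasc_background, peak_vasc = peak_vasc,
       vasc_radius_factor = vasc_radius_factor, center_jitter = center_jitter)
}

#' Synthesize tumor and vasculature initial conditions
#'
#' @param domain a [build_tissue_domain()] domain.
#' @param tumor_config settings from [lesion_config()].
#' @param seed integer; fixes the (optional) lesion-center jitter.
#' @return A list with `scalar_field`s `N_t` and `N_v`, both zero outside the
#'   brain mask and bounded by the peak fractions.
#' @export
synthesize_initial_conditions <- function(domain,
                                          tumor_config = lesion_config(),
                                          seed = 1L) {
  g <- domain$grid
  cfg <- tumor_config
  if (cfg$radius < 0) stop("lesion radius must be >= 0")
  if (cfg$radius > min(domain$config$brain_semiaxes))
    stop("lesion configuration error: radius exceeds the brain extent")
  ctr <- domain$config$center %||% (g$origin + g$shape * g$spacing / 2)
  if (cfg$center_jitter > 0)
    ctr <- ctr + with_seed(seed, stats::runif(3, -1, 1)) * cfg$center_jitter

  xs <- voxel_centers(g, 1); ys <- voxel_centers(g, 2)
  zs <- voxel_centers(g, 3)
  r <- sqrt(outer(outer((xs - ctr[1])^2, (ys - ctr[2])^2, `+`),
                  (zs - ctr[3])^2, `+`))

  raised_cos <- function(r, R, peak) {
    p <- array(0, dim = dim(r))
    if (R > 0) {
      inside <- r <= R
      p[inside] <- peak * cos(pi * r[inside] / (2 * R))^2
    }
    p
  }

  nt <- raised_cos(r, cfg$radius, cfg$peak_tumor)
  nv <- array(cfg$vasc_background, dim = g$shape) +
    raised_cos(r, cfg$vasc_radius_factor * cfg$radius, cfg$peak_vasc)
  nt[!domain$brain_mask] <- 0
  nv[!domain$brain_mask] <- 0

  list(N_t = scalar_field(nt, g, "tumor_fraction", check = FALSE),
       N_v = scalar_field(nv, g, "vasculature_fraction", check = FALSE),
       center = ctr, config = cfg, seed = as.integer(seed))
}

#' Analytic mass of the raised-cosine lesion profile
#'
#' Closed-form integral of `peak * cos^2(pi r / (2 R))` over the ball of
#' radius R: `2 pi peak R^3 (1/3 - 2/pi^2)`. Used to validate the discretized
#' initial condition.
#'
#' @param radius lesion radius R, mm.
#' @param peak peak fraction at the center.
#' @return Lesion mass in fraction x mm^3.
#' @export
lesion_mass_closed_form <- function(radius, peak) {
  2 * pi * peak * radius^3 * (1 / 3 - 2 / pi^2)
}

#' Build the 13-tumor virtual cohort
#'
#' The cohort is the central tumor plus 12 variants obtained by jointly
#' offsetting the proliferation pair (k_t, k_v) and the diffusion pair
#' (D_t0, D_v0) by +/-25, 50 or 75 percent. IDs follow a
#' quadrant-digit + magnitude-digit convention: quadrant 1 =
#' (+proliferation, +diffusion), 2 = (+, -), 3 = (-, +), 4 = (-, -);
#' magnitude digit 1/2/3 = 25/50/75 percent, so e.g. tumor "23" has
#' proliferation +75 percent and diffusion -75 percent.
#'
#' @param central `model_parameters` of the central tumor.
#' @return A list of 13 `virtual_tumor_spec` objects, each with `tumor_id`,
#'   `parameters` and the signed percent `offsets` applied to the
#'   proliferation and diffusion pairs.
#' @export
build_virtual_cohort <- function(central = model_parameters()) {
  quad_sign <- list(`1` = c(prolif = 1, diff = 1),
                    `2` = c(prolif = 1, diff = -1),
                    `3` = c(prolif = -1, diff = 1),
                    `4` = c(prolif = -1, diff = -1))
  mags <- c(`1` = 25, `2` = 50, `3` = 75)

  make_spec <- function(id, prolif_pct, diff_pct) {
    prolif_pct <- unname(prolif_pct)
    diff_pct <- unname(diff_pct)
    p <- central
    p$k_t <- central$k_t * (1 + prolif_pct / 100)
    p$k_v <- central$k_v * (1 + prolif_pct / 100)
    p$D_t0 <- central$D_t0 * (1 + diff_pct / 100)
    p$D_v0 <- central$D_v0 * (1 + diff_pct / 100)
    structure(list(tumor_id = id, parameters = p,
                   offsets = c(prolif = prolif_pct, diff = diff_pct)),
              class = "virtual_tumor_spec")
  }

  cohort <- list(make_spec("central", 0, 0))
  for (q in names(quad_sign))
    for (m in names(mags)) {
      s <- quad_sign[[q]]
      cohort <- c(cohort, list(make_spec(paste0(q, m),
                                         s["prolif"] * mags[m],
                                         s["diff"] * mags[m])))
    }
  names(cohort) <- vapply(cohort, `[[`, "", "tumor_id")
  cohort
}
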