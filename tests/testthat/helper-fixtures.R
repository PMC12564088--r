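# shared fixtures: small domains and fields built in code at test time

# a tiny isotropic brain that fits a 9^3 grid with margin
tiny_domain <- function(shape = c(9, 9, 9), spacing = 0.25,
                        semiaxes = c(0.8, 0.8, 0.8), white_fraction = 0.5,
                        wobble = 0, seed = 1L) {
  g <- grid3d(shape, rep(spacing, 3))
  cfg <- domain_config(brain_semiaxes = semiaxes,
                       white_fraction = white_fraction, wobble = wobble)
  build_tissue_domain(g, cfg, seed = seed)
}

# a rectangular all-brain "slab" domain (no geometry, for analytic limits)
slab_domain <- function(shape, spacing = c(0.2, 0.2, 0.2)) {
  g <- grid3d(shape, spacing)
  structure(list(grid = g,
                 brain_mask = array(TRUE, dim = g$shape),
                 tissue = array("gray", dim = g$shape),
                 shear_modulus = array(466, dim = g$shape),
                 poisson_ratio = 0.45,
                 config = list(), seed = 1L,
                 cache = new.env(parent = emptyenv())),
            class = "tissue_domain")
}

field_on <- function(domain, values, role = "tumor_fraction") {
  scalar_field(array(values, dim = domain$grid$shape), domain$grid, role,
               check = FALSE)
}

rel_l2 <- function(a, b) sqrt(sum((a - b)^2) / sum(b^2))

# base-resolution study domain + initial conditions, shared across files;
# the lesion is synthesized at the finest resolution and resampled down,
# as in the experiment pipeline
base_study <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      sc <- study_scale()
      dom <- build_tissue_domain(resolution_grid(sc, 0.063), seed = 1L)
      fine_dom <- build_tissue_domain(resolution_grid(sc, 0.008), seed = 1L)
      icf <- synthesize_initial_conditions(fine_dom, seed = 1L)
      nt <- resample_field(icf$N_t, target_voxel_volume = 0.063)
      nv <- resample_field(icf$N_v, target_voxel_volume = 0.063)
      nt$values[!dom$brain_mask] <- 0
      nv$values[!dom$brain_mask] <- 0
      memo <<- list(scale = sc, domain = dom, ic = list(N_t = nt, N_v = nv))
    }
    memo
  }
})
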