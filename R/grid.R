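#' Regular 3-D voxel grid
#'
#' Defines the geometry shared by all volumetric fields: number of voxels per
#' axis, voxel spacing in mm, and the position (mm) of the corner of the
#' domain. Voxel centers sit at `origin + (i - 1/2) * spacing` with 1-based
#' voxel indices and axis order (x, y, z).
#'
#' @param shape integer vector of length 3, voxels per axis (all >= 1).
#' @param spacing numeric vector of length 3, mm per voxel per axis (all > 0).
#' @param origin numeric vector of length 3, mm position of the domain corner.
#' @return An object of class `rd_grid`.
#' @export
grid3d <- function(shape, spacing, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("grid shape must be three integers >= 1")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("grid spacing must be three positive lengths (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("grid origin must be three finite lengths (mm)")
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "rd_grid")
}

#' @export
print.rd_grid <- function(x, ...) {
  cat(sprintf("<rd_grid> %d x %d x %d voxels, spacing (%g, %g, %g) mm, voxel volume %g mm^3\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3], voxel_volume(x)))
  invisible(x)
}

#' Voxel volume of a grid (mm^3)
#' @param grid an `rd_grid`.
#' @return Product of the three voxel spacings.
#' @export
voxel_volume <- function(grid) prod(grid$spacing)

#' Voxel-center coordinates along one axis
#' @param grid an `rd_grid`.
#' @param axis 1, 2 or 3.
#' @return Numeric vector of center coordinates (mm).
#' @export
voxel_centers <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 0.5) * grid$spacing[axis]
}

grids_identical <- function(a, b) {
  identical(a$shape, b$shape) &&
    isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-10)) &&
    isTRUE(all.equal(a$origin, b$origin, tolerance = 1e-10))
}

field_roles <- c("tumor_fraction", "vasculature_fraction", "adc",
                 "concentration", "stress", "distance", "capacity",
                 "displacement", "generic")

#' 3-D scalar field on a voxel grid
#'
#' A voxel array tagged with its grid geometry and a role describing the
#' physical quantity it carries (tumor or vasculature volume fraction, ADC,
#' contrast-agent concentration, stress, normalized distance, carrying
#' capacity, ...). Role-specific range invariants are checked on
#' construction.
#'
#' @param values numeric array whose dimensions match `grid$shape`.
#' @param grid an `rd_grid`.
#' @param role one of `"tumor_fraction"`, `"vasculature_fraction"`, `"adc"`,
#'   `"concentration"`, `"stress"`, `"distance"`, `"capacity"`,
#'   `"displacement"`, `"generic"`.
#' @param check validate role-specific ranges (default TRUE).
#' @return An object of class `scalar_field` with elements `values`, `grid`,
#'   `role`.
#' @export
scalar_field <- function(values, grid, role = "generic", check = TRUE) {
  role <- match.arg(role, field_roles)
  values <- as.array(values)
  if (!identical(as.integer(dim(values)), grid$shape))
    stop("field dimensions do not match grid shape")
  storage.mode(values) <- "double"
  if (check) {
    if (anyNA(values)) stop("field contains NA values")
    if (role %in% c("tumor_fraction", "vasculature_fraction") &&
        (min(values) < -1e-12 || max(values) > 1 + 1e-12))
      stop(sprintf("%s values must lie in [0, 1]", role))
    if (role == "adc" && min(values) < 0)
      stop("adc values must be >= 0")
    if (role == "distance" &&
        (min(values) < -1e-12 || max(values) > 1 + 1e-12))
      stop("distance values must lie in [0, 1]")
  }
  structure(list(values = values, grid = grid, role = role),
            class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  cat(sprintf("<scalar_field role=%s> range [%g, %g]\n", x$role,
              min(x$values), max(x$values)))
  print(x$grid)
  invisible(x)
}

#' @export
as.array.scalar_field <- function(x, ...) x$values

#' Read / write a scalar field in NIfTI-1 format
#'
#' Voxel spacing is carried in the NIfTI header (`pixdim`); the role is not
#' representable in NIfTI-1 and must be resupplied on read.
#'
#' @param field a `scalar_field`.
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `write_field` returns `path` invisibly; `read_field` returns a
#'   `scalar_field`.
#' @export
write_field <- function(field, path) {
  img <- RNifti::asNifti(field$values)
  RNifti::pixdim(img) <- field$grid$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_field
#' @param role role tag to attach to the field read from disk.
#' @param origin domain corner (mm); NIfTI-1 srow handling is deliberately
#'   not interpreted, the default places the corner at the coordinate origin.
#' @export
read_field <- function(path, role = "generic", origin = c(0, 0, 0)) {
  img <- RNifti::readNifti(path)
  vals <- as.array(img)
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  g <- grid3d(dim(vals)[1:3], spacing, origin)
  scalar_field(array(as.numeric(vals), dim = g$shape), g, role, check = FALSE)
}

#' Resample a field to a different spatial resolution
#'
#' Trilinear interpolation at the target voxel centers, with all three voxel
#' spacings scaled by the same linear factor (so a voxel-volume change of 8x
#' is a per-axis factor of 2). The physical extent of the domain is
#' preserved; values are interpolated between voxel centers with clamping at
#' the border, so constants are reproduced exactly and no overshoot is
#' introduced in volume-fraction fields.
#'
#' @param field a `scalar_field`.
#' @param factor linear per-axis scale factor (> 1 coarsens). The target
#'   shape `shape / factor` must be a whole number of voxels per axis.
#' @param target_voxel_volume alternative to `factor`: the target voxel
#'   volume in mm^3 (converted to the cube root ratio).
#' @return The resampled `scalar_field`.
#' @export
resample_field <- function(field, factor = NULL, target_voxel_volume = NULL) {
  g <- field$grid
  if (is.null(factor)) {
    if (is.null(target_voxel_volume))
      stop("supply either factor or target_voxel_volume")
    factor <- (target_voxel_volume / voxel_volume(g))^(1 / 3)
    # printed voxel volumes (0.008, 0.063, 0.50 mm^3) are rounded values of
    # the power-of-two ladder; snap to it
    f2 <- 2^round(log2(factor))
    if (abs(factor / f2 - 1) > 0.12)
      stop(sprintf("voxel volume %g mm^3 is not on the resolution ladder",
                   target_voxel_volume))
    factor <- f2
  }
  if (abs(factor - 1) < 1e-9) return(field)
  new_shape <- g$shape / factor
  if (any(abs(new_shape - round(new_shape)) > 1e-6))
    stop(sprintf("target resolution not grid-compatible: shape %s / factor %g is not integral",
                 paste(g$shape, collapse = "x"), factor))
  new_shape <- as.integer(round(new_shape))
  new_g <- grid3d(new_shape, g$spacing * factor, g$origin)
  vals <- interp_trilinear(field$values, g, new_g)
  scalar_field(vals, new_g, field$role, check = FALSE)
}

# trilinear interpolation of `values` (on grid gs) at the voxel centers of gt,
# clamped at the border
interp_trilinear <- function(values, gs, gt) {
  # fractional (0-based) source indices of target centers, per axis
  fr <- lapply(1:3, function(a) {
    x <- voxel_centers(gt, a)
    f <- (x - gs$origin[a]) / gs$spacing[a] - 0.5
    pmin(pmax(f, 0), gs$shape[a] - 1)
  })
  lo <- lapply(seq_along(fr), function(a) {
    l <- floor(fr[[a]])
    pmin(l, gs$shape[a] - 1)
  })
  w <- lapply(seq_along(fr), function(a) fr[[a]] - lo[[a]])
  hi <- lapply(seq_along(fr), function(a) pmin(lo[[a]] + 1, gs$shape[a] - 1))

  nxt <- gt$shape
  ix <- rep(seq_len(nxt[1]), times = nxt[2] * nxt[3])
  iy <- rep(rep(seq_len(nxt[2]), each = nxt[1]), times = nxt[3])
  iz <- rep(seq_len(nxt[3]), each = nxt[1] * nxt[2])

  out <- numeric(prod(nxt))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    gx <- if (cx == 0) lo[[1]] else hi[[1]]
    gy <- if (cy == 0) lo[[2]] else hi[[2]]
    gz <- if (cz == 0) lo[[3]] else hi[[3]]
    wx <- if (cx == 0) 1 - w[[1]] else w[[1]]
    wy <- if (cy == 0) 1 - w[[2]] else w[[2]]
    wz <- if (cz == 0) 1 - w[[3]] else w[[3]]
    wt <- wx[ix] * wy[iy] * wz[iz]
    out <- out + wt * values[cbind(gx[ix] + 1L, gy[iy] + 1L, gz[iz] + 1L)]
  }
  array(out, dim = nxt)
}
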