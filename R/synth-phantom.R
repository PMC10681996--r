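#' Voxel grid specification
#'
#' @param shape integer voxel counts per axis.
#' @param spacing mm per voxel per axis; anisotropy allowed.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(shape, spacing = c(1, 1, 1)) {
  stopifnot(length(shape) == 3L, all(shape >= 1),
            length(spacing) == 3L, all(spacing > 0))
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing)),
            class = "grid_spec")
}

#' PET acquisition specification for phantom simulation
#'
#' The phantom model is deliberately simple: a two-valued uptake map
#' (tumor plateau over homogeneous background), convolved with an isotropic
#' Gaussian point-spread function, then additive Gaussian noise. Poisson-like
#' count statistics are intentionally not modeled; the additive model is
#' sufficient for exercising threshold-based delineation.
#'
#' @param tumor_suv plateau uptake inside the lesion (SUV).
#' @param background_suv surrounding-tissue uptake (SUV); must be below
#'   `tumor_suv`.
#' @param psf_fwhm_mm full width at half maximum of the Gaussian blur, mm.
#' @param noise_sd additive Gaussian noise standard deviation (SUV).
#' @param seed integer RNG seed; the phantom is a pure function of the spec
#'   and this seed.
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(tumor_suv = 10, background_suv = 1,
                             psf_fwhm_mm = 0, noise_sd = 0, seed = 1L) {
  stopifnot(tumor_suv > background_suv, background_suv >= 0,
            psf_fwhm_mm >= 0, noise_sd >= 0)
  structure(list(tumor_suv = tumor_suv, background_suv = background_suv,
                 psf_fwhm_mm = psf_fwhm_mm, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "acquisition_spec")
}

# evaluate code with a locally set RNG seed, restoring global state after
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a PET-like digital phantom with ground-truth mask
#'
#' Voxels whose centers fall inside the analytic shape carry the tumor
#' plateau uptake, all others the background uptake; the map is then blurred
#' by the Gaussian PSF and Gaussian noise is added, in that order. The
#' ground-truth mask is the pre-blur analytic occupancy (voxel-center-inside
#' rule), which matches the voxel-count volume convention used by the
#' feature metrics.
#'
#' The shape is placed at the grid center plus the shape's `center` offset.
#' The grid must contain the shape with at least a 3-voxel background margin
#' on every axis.
#'
#' @param shape a [shape_spec()].
#' @param grid a [grid_spec()].
#' @param acq an [acquisition_spec()].
#' @return A list with `volume` (a [pet_volume()]) and `truth` (a
#'   [tumor_mask()]).
#' @export
make_phantom <- function(shape, grid, acq) {
  stopifnot(inherits(shape, "shape_spec"), inherits(grid, "grid_spec"),
            inherits(acq, "acquisition_spec"))
  nv <- grid$shape
  sp <- grid$spacing
  grid_center <- (nv - 1) / 2 * sp
  center <- grid_center + shape$center

  ext <- shape_extent(shape)
  margin <- 3 * sp
  for (ax in 1:3) {
    lo <- center[ax] - ext[ax]
    hi <- center[ax] + ext[ax]
    if (lo < margin[ax] - 1e-9 || hi > (nv[ax] - 1) * sp[ax] - margin[ax] + 1e-9) {
      stop(sprintf(
        "shape exceeds grid bounds (with 3-voxel margin) along axis %d", ax
      ))
    }
  }

  cx <- (seq_len(nv[1]) - 1) * sp[1]
  cy <- (seq_len(nv[2]) - 1) * sp[2]
  cz <- (seq_len(nv[3]) - 1) * sp[3]
  xyz <- as.matrix(expand.grid(x = cx, y = cy, z = cz))
  spec_centered <- shape
  spec_centered$center <- center
  inside <- array(shape_contains(spec_centered, xyz), dim = nv)

  vol <- array(acq$background_suv, dim = nv)
  vol[inside] <- acq$tumor_suv

  if (acq$psf_fwhm_mm > 0) {
    sigma_vox <- acq$psf_fwhm_mm / (2 * sqrt(2 * log(2))) / sp
    vol <- cpp_gauss_blur(vol, nv, sigma_vox)
  }
  if (acq$noise_sd > 0) {
    vol <- vol + with_local_seed(acq$seed,
                                 array(rnorm(prod(nv), 0, acq$noise_sd), nv))
  }

  list(volume = pet_volume(vol, spacing = sp),
       truth = tumor_mask(inside, spacing = sp, provenance = "automatic"))
}
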