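#' Delineation parameters for adaptive-threshold segmentation
#'
#' The delineation scheme is an iterative background-corrected relative
#' threshold: the threshold is placed at a fixed fraction `f` of the
#' lesion's peak uptake above the local background, the background being
#' estimated in a shell around the current region. Background-corrected
#' thresholds around 40% of SUVmax are the established family of PET
#' delineation methods for FDG lesions; every constant here is exposed.
#'
#' @param threshold_fraction fraction `f` in (0,1) of the background-
#'   corrected peak used as threshold (default 0.41).
#' @param init_fraction fraction of the global/seed SUVmax used for the
#'   initial region (default 0.5).
#' @param shell_inner_mm,shell_outer_mm distances (mm) from the region
#'   bounding the background shell; `0 < inner < outer`.
#' @param max_iterations iteration cap (default 20).
#' @param convergence relative volume-change tolerance declaring
#'   convergence (default 0.01).
#' @return An object of class `delineation_params`.
#' @export
delineation_params <- function(threshold_fraction = 0.41,
                               init_fraction = 0.5,
                               shell_inner_mm = 2, shell_outer_mm = 4,
                               max_iterations = 20, convergence = 0.01) {
  stopifnot(threshold_fraction > 0, threshold_fraction < 1,
            init_fraction > 0, init_fraction < 1,
            shell_outer_mm > shell_inner_mm, shell_inner_mm > 0,
            max_iterations >= 1, convergence > 0)
  structure(list(threshold_fraction = threshold_fraction,
                 init_fraction = init_fraction,
                 shell_inner_mm = shell_inner_mm,
                 shell_outer_mm = shell_outer_mm,
                 max_iterations = as.integer(max_iterations),
                 convergence = convergence),
            class = "delineation_params")
}

# connected component (6-neighborhood) of vol > threshold containing seed
component_above <- function(vol, threshold, seed_idx) {
  fg <- vol$data > threshold
  seed0 <- (seed_idx[1] - 1L) +
    dim(vol$data)[1] * ((seed_idx[2] - 1L) +
                          dim(vol$data)[2] * (seed_idx[3] - 1L))
  cpp_flood6(fg, dim(vol$data), as.integer(seed0))
}

#' Estimate the local background around a region
#'
#' Mean SUV over the shell of voxels whose Euclidean distance to the
#' region lies in `[shell_inner_mm, shell_outer_mm]`. Distances are taken
#' from the region in physical mm, honoring anisotropic voxel spacing.
#'
#' @param vol a [pet_volume()].
#' @param region a [tumor_mask()] (or logical array) on the same grid.
#' @param shell_inner_mm,shell_outer_mm shell bounds in mm.
#' @return Background SUV (scalar).
#' @export
estimate_background <- function(vol, region, shell_inner_mm = 2,
                                shell_outer_mm = 4) {
  reg <- if (inherits(region, "tumor_mask")) region$data else region
  stopifnot(identical(dim(reg), dim(vol$data)))
  d2 <- cpp_edt_sq(reg, dim(vol$data), vol$spacing)
  shell <- d2 >= shell_inner_mm^2 & d2 <= shell_outer_mm^2 & !reg
  if (!any(shell)) {
    stop(sprintf(
      "empty background shell [%g, %g] mm; increase shell_outer_mm",
      shell_inner_mm, shell_outer_mm
    ))
  }
  mean(vol$data[shell])
}

#' Delineate the metabolically active tumor by adaptive thresholding
#'
#' Iterative scheme: (1) the initial region is the connected component
#' containing the seed above `init_fraction * SUVmax(seed)`; then
#' repeatedly (2) estimate the local background `B` in a shell around the
#' current region, (3) set the threshold `T = B + f * (SUVmax_region - B)`
#' with `SUVmax_region` re-evaluated inside the current region, (4) regrow
#' the component containing the seed above `T`; stop when the relative
#' volume change drops below the convergence tolerance or the iteration cap
#' is hit. If the region alternates between two states the smaller one is
#' returned and the mask is flagged oscillating.
#'
#' On a two-valued (tumor/background) image the scheme converges in at
#' most two iterations and returns exactly the high-valued component
#' containing the seed.
#'
#' @param vol a [pet_volume()].
#' @param seed_point voxel index `c(i, j, k)` inside the lesion, or
#'   `"auto"` to use the global SUV maximum.
#' @param params a [delineation_params()].
#' @return A [tumor_mask()] with attributes `threshold` (final SUV
#'   threshold), `background`, `iterations`, `converged` and `oscillating`.
#' @export
delineate <- function(vol, seed_point = "auto",
                      params = delineation_params()) {
  stopifnot(inherits(vol, "pet_volume"), inherits(params, "delineation_params"))
  if (identical(seed_point, "auto")) {
    seed_point <- arrayInd(which.max(vol$data), dim(vol$data))[1, ]
  }
  seed_point <- as.integer(seed_point)
  stopifnot(length(seed_point) == 3L, all(seed_point >= 1),
            all(seed_point <= dim(vol$data)))

  suv_seed <- vol$data[seed_point[1], seed_point[2], seed_point[3]]
  t0 <- params$init_fraction * suv_seed
  region <- component_above(vol, t0, seed_point)
  if (!any(region)) {
    stop(sprintf("empty initial region at threshold %.4g", t0))
  }

  threshold <- t0
  background <- NA_real_
  converged <- FALSE
  oscillating <- FALSE
  prev_vol <- sum(region)
  history <- list(region)
  iterations <- 0L

  for (it in seq_len(params$max_iterations)) {
    iterations <- it
    background <- estimate_background(vol, region, params$shell_inner_mm,
                                      params$shell_outer_mm)
    suv_max_region <- max(vol$data[region])
    if (suv_max_region <= background) {
      stop(sprintf(
        "seed region maximum (%.4g) does not exceed background (%.4g)",
        suv_max_region, background
      ))
    }
    threshold <- background +
      params$threshold_fraction * (suv_max_region - background)
    new_region <- component_above(vol, threshold, seed_point)
    if (!any(new_region)) {
      stop(sprintf("empty region at threshold %.4g", threshold))
    }
    new_vol <- sum(new_region)
    rel_change <- abs(new_vol - prev_vol) / prev_vol
    # two-state oscillation: new region identical to the one before last
    if (length(history) >= 2 &&
        identical(new_region, history[[length(history) - 1]])) {
      oscillating <- TRUE
      if (sum(history[[length(history)]]) < new_vol) {
        new_region <- history[[length(history)]]
      }
      warning("delineation oscillates between two regions; returning the smaller")
      region <- new_region
      break
    }
    region <- new_region
    history <- c(history, list(new_region))
    if (rel_change < params$convergence) {
      converged <- TRUE
      break
    }
    prev_vol <- new_vol
  }
  if (!converged && !oscillating) {
    warning(sprintf("delineation did not converge in %d iterations",
                    params$max_iterations))
  }

  mask <- tumor_mask(region, spacing = vol$spacing, provenance = "automatic")
  attr(mask, "threshold") <- threshold
  attr(mask, "background") <- background
  attr(mask, "iterations") <- iterations
  attr(mask, "converged") <- converged
  attr(mask, "oscillating") <- oscillating
  mask
}

#' Substitute an externally supplied mask for the automatic delineation
#'
#' Replaces the role of manual correction: an external mask (e.g. drawn in
#' another tool and exported as NIfTI) is validated against the volume grid
#' and used with provenance `"override"`. If the mask has several connected
#' components only the largest is kept, with a warning.
#'
#' @param vol a [pet_volume()].
#' @param mask a [tumor_mask()], a logical/0-1 array, or a NIfTI file path.
#' @return A [tumor_mask()] with provenance `"override"`.
#' @export
apply_override <- function(vol, mask) {
  if (is.character(mask)) mask <- read_mask_nifti(mask)
  if (!inherits(mask, "tumor_mask")) {
    mask <- tumor_mask(mask, spacing = vol$spacing, provenance = "override")
  }
  check_congruent(vol, mask)
  lab <- cpp_label6(mask$data, dim(mask$data))
  k <- max(lab)
  dat <- mask$data
  if (k > 1) {
    sizes <- tabulate(lab[lab > 0], nbins = k)
    keep <- which.max(sizes)
    warning(sprintf(
      "override mask has %d components (sizes %s); keeping the largest",
      k, paste(sizes, collapse = ", ")
    ))
    dat <- array(lab == keep, dim(mask$data))
  }
  tumor_mask(dat, spacing = vol$spacing, provenance = "override")
}
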