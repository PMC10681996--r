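#' PET volume container
#'
#' A 3-D scalar field in SUV units with physical voxel spacing. This is the
#' imaging substrate every delineation and feature routine works on. SUV
#' (standardized uptake value) is the tracer concentration normalized to
#' injected dose and body weight, so values are unitless but comparable
#' across patients.
#'
#' @param data 3-D numeric array of SUV values.
#' @param spacing numeric length-3, mm per voxel along each array axis.
#' @param origin numeric length-3, mm position of the first voxel center
#'   (used only to populate the NIfTI affine on export).
#' @return An object of class `pet_volume`.
#' @export
pet_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- unclass(data)
  if (length(dim(data)) != 3L) stop("`data` must be a 3-D array")
  attributes(data) <- list(dim = dim(data))  # drop stray file metadata
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("`spacing` must be 3 positive values (mm per voxel)")
  }
  if (!all(is.finite(data))) stop("volume contains non-finite values")
  structure(
    list(data = data, spacing = as.numeric(spacing),
         origin = as.numeric(origin)),
    class = "pet_volume"
  )
}

#' Binary tumor mask tied to a PET volume grid
#'
#' @param data 3-D logical (or 0/1) array congruent with the parent volume.
#' @param spacing mm per voxel, same convention as [pet_volume()].
#' @param provenance `"automatic"` for masks produced by [delineate()],
#'   `"override"` for externally supplied masks.
#' @return An object of class `tumor_mask`.
#' @export
tumor_mask <- function(data, spacing = c(1, 1, 1),
                       provenance = c("automatic", "override")) {
  provenance <- match.arg(provenance)
  data <- unclass(data)
  if (length(dim(data)) != 3L) stop("mask must be a 3-D array")
  attributes(data) <- list(dim = dim(data))
  storage.mode(data) <- "logical"
  if (!any(data)) stop("mask is empty")
  structure(
    list(data = data, spacing = as.numeric(spacing), provenance = provenance),
    class = "tumor_mask"
  )
}

#' @export
print.pet_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<pet_volume> %d x %d x %d voxels, spacing %s mm, SUV range [%.3g, %.3g]\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 3), collapse = " x "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.tumor_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<tumor_mask> %d x %d x %d voxels, %d foreground, provenance=%s\n",
              d[1], d[2], d[3], sum(x$data), x$provenance))
  invisible(x)
}

#' @export
dim.pet_volume <- function(x) dim(x$data)

#' @export
dim.tumor_mask <- function(x) dim(x$data)

check_congruent <- function(vol, mask) {
  if (!identical(dim(vol$data), dim(mask$data))) {
    stop(sprintf(
      "volume grid %s and mask grid %s differ",
      paste(dim(vol$data), collapse = "x"),
      paste(dim(mask$data), collapse = "x")
    ))
  }
  if (max(abs(vol$spacing - mask$spacing)) > 1e-6) {
    stop(sprintf(
      "volume spacing (%s) and mask spacing (%s) differ",
      paste(signif(vol$spacing, 6), collapse = ", "),
      paste(signif(mask$spacing, 6), collapse = ", ")
    ))
  }
  invisible(TRUE)
}

#' Read and write PET volumes and masks as NIfTI
#'
#' Voxel spacing is carried in the NIfTI affine / pixdim fields. Masks are
#' written as 0/1 integer volumes on the same grid.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param x a `pet_volume` or `tumor_mask`.
#' @return `read_pet_nifti()` returns a `pet_volume`; `read_mask_nifti()` a
#'   `tumor_mask`; the writers return `path` invisibly.
#' @export
read_pet_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  pet_volume(as.array(img), spacing = RNifti::pixdim(img)[1:3])
}

#' @rdname read_pet_nifti
#' @param provenance provenance tag for the mask being read.
#' @export
read_mask_nifti <- function(path, provenance = "override") {
  img <- RNifti::readNifti(path)
  tumor_mask(as.array(img) > 0.5, spacing = RNifti::pixdim(img)[1:3],
             provenance = provenance)
}

#' @rdname read_pet_nifti
#' @export
write_pet_nifti <- function(x, path) {
  stopifnot(inherits(x, "pet_volume") || inherits(x, "tumor_mask"))
  dat <- if (inherits(x, "tumor_mask")) array(as.integer(x$data), dim(x$data)) else x$data
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
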