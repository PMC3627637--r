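#' Attenuation volume
#'
#' A 3D grid of CT attenuation values in Hounsfield units (HU) together with
#' the physical voxel spacing. Air is approximately -1000 HU, water 0 HU.
#' Values outside the usual CT range (-1024 to 3071 HU) are kept as stored
#' but trigger a warning, since they usually indicate a calibration or
#' format problem rather than tissue.
#'
#' @param grid numeric 3D array of HU values; all values must be finite.
#' @param spacing numeric vector of length 3, voxel edge lengths in mm;
#'   all strictly positive.
#' @return An object of class \code{attenuation_volume} with elements
#'   \code{grid} and \code{spacing}.
#' @examples
#' vol <- attenuation_volume(array(-900, dim = c(4, 4, 4)), c(0.7, 0.7, 0.5))
#' dim(vol$grid)
#' @export
attenuation_volume <- function(grid, spacing = c(1, 1, 1)) {
  if (!is.array(grid) || length(dim(grid)) != 3L)
    stop("grid must be a 3D array", call. = FALSE)
  if (any(dim(grid) < 1L))
    stop("grid must have three positive dimensions", call. = FALSE)
  if (!is.numeric(grid))
    stop("grid must be numeric (HU values)", call. = FALSE)
  if (!all(is.finite(grid)))
    stop("grid contains non-finite HU values", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive voxel edge lengths (mm)",
         call. = FALSE)
  if (any(grid < -1024 | grid > 3071))
    warning("HU values outside [-1024, 3071]: possible calibration/format issue",
            call. = FALSE)
  structure(list(grid = grid, spacing = spacing),
            class = "attenuation_volume")
}

#' Lung segmentation mask
#'
#' A binary mask identifying the lung voxels of a companion
#' \code{\link{attenuation_volume}}. Any nonzero input value is treated as
#' lung, so masks read from integer-valued NIfTI label maps work directly.
#'
#' @param mask logical or numeric 3D array; nonzero/TRUE marks lung.
#' @return An object of class \code{lung_segmentation} with element
#'   \code{mask} (logical array).
#' @export
lung_segmentation <- function(mask) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("mask must be a 3D array", call. = FALSE)
  if (is.numeric(mask)) {
    if (any(!is.finite(mask)))
      stop("mask contains non-finite values", call. = FALSE)
    mask <- mask != 0
  }
  if (!is.logical(mask))
    stop("mask must be logical or numeric", call. = FALSE)
  if (anyNA(mask))
    stop("mask contains missing values", call. = FALSE)
  structure(list(mask = mask), class = "lung_segmentation")
}

#' Paired inspiratory-expiratory scan
#'
#' Bundles one subject's inspiratory and expiratory attenuation volumes with
#' their lung masks and the subject's smoking status (needed for the
#' emphysema severity cut-points, which are shifted by 1 percentage point in
#' current smokers to compensate for smoking-related increases in lung
#' density). The two phases are acquired separately, so their grids may
#' differ in shape; each mask must match its own volume.
#'
#' @param insp_volume,exp_volume \code{\link{attenuation_volume}} objects for
#'   the full-inspiration and end-tidal-expiration acquisitions.
#' @param insp_mask,exp_mask \code{\link{lung_segmentation}} objects aligned
#'   to the corresponding volume.
#' @param smoking_status \code{"current"} or \code{"former"}.
#' @return An object of class \code{scan_pair}.
#' @export
scan_pair <- function(insp_volume, insp_mask, exp_volume, exp_mask,
                      smoking_status = c("former", "current")) {
  smoking_status <- match.arg(smoking_status)
  stopifnot(inherits(insp_volume, "attenuation_volume"),
            inherits(exp_volume, "attenuation_volume"),
            inherits(insp_mask, "lung_segmentation"),
            inherits(exp_mask, "lung_segmentation"))
  check_alignment(insp_volume, insp_mask, "inspiratory")
  check_alignment(exp_volume, exp_mask, "expiratory")
  structure(list(insp_volume = insp_volume, insp_mask = insp_mask,
                 exp_volume = exp_volume, exp_mask = exp_mask,
                 smoking_status = smoking_status),
            class = "scan_pair")
}

check_alignment <- function(volume, mask, phase = "") {
  if (!identical(dim(volume$grid), dim(mask$mask)))
    stop(sprintf("alignment error: %s mask shape (%s) does not match volume shape (%s)",
                 phase,
                 paste(dim(mask$mask), collapse = "x"),
                 paste(dim(volume$grid), collapse = "x")),
         call. = FALSE)
  invisible(TRUE)
}

masked_hu <- function(volume, mask, require_nonempty = TRUE) {
  check_alignment(volume, mask)
  hu <- volume$grid[mask$mask]
  if (require_nonempty && length(hu) == 0L)
    stop("empty segmentation: no lung voxels in mask", call. = FALSE)
  hu
}

#' @export
print.attenuation_volume <- function(x, ...) {
  cat(sprintf("<attenuation_volume> %s voxels, spacing %s mm, HU range [%.1f, %.1f]\n",
              paste(dim(x$grid), collapse = "x"),
              paste(format(x$spacing), collapse = " x "),
              min(x$grid), max(x$grid)))
  invisible(x)
}

#' @export
print.scan_pair <- function(x, ...) {
  cat(sprintf("<scan_pair> insp %s (%d lung voxels), exp %s (%d lung voxels), %s smoker\n",
              paste(dim(x$insp_volume$grid), collapse = "x"),
              sum(x$insp_mask$mask),
              paste(dim(x$exp_volume$grid), collapse = "x"),
              sum(x$exp_mask$mask),
              x$smoking_status))
  invisible(x)
}
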