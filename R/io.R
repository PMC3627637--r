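## NIfTI and tabular I/O. Volumes and masks travel as NIfTI-1 (.nii/.nii.gz)
## with HU already in physical units: RNifti applies any scl_slope/scl_inter
## stored in the header when the data are read, so thresholds operate on
## calibrated HU. Masks treat any nonzero voxel as lung.

read_nifti_array <- function(path, what = "volume") {
  if (!file.exists(path))
    stop(sprintf("missing file (%s): %s", what, path), call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- array(arr, dim = dim(arr)[1:3])
  if (length(dim(arr)) != 3L)
    stop(sprintf("%s is not a 3D image: %s", what, path), call. = FALSE)
  attr(arr, "pixdim") <- RNifti::pixdim(img)[1:3]
  arr
}

#' Read one subject's paired scans from NIfTI files
#'
#' Loads the four images (inspiratory/expiratory volume and mask), applies
#' the NIfTI scale slope/intercept (done by the reader), validates
#' alignment and finiteness, and returns a \code{\link{scan_pair}}.
#'
#' @param insp_volume,insp_mask,exp_volume,exp_mask file paths.
#' @param smoking_status \code{"current"} or \code{"former"}.
#' @param subject_id optional label used in error messages.
#' @return A \code{\link{scan_pair}}.
#' @export
read_scan_pair <- function(insp_volume, insp_mask, exp_volume, exp_mask,
                           smoking_status = "former", subject_id = NULL) {
  label <- if (is.null(subject_id)) "" else paste0(" [subject ", subject_id, "]")
  ctx <- function(phase, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("%s phase%s: %s", phase, label, conditionMessage(e)),
           call. = FALSE))
  }
  iv <- ctx("inspiratory", {
    arr <- read_nifti_array(insp_volume, "volume")
    attenuation_volume(unclass_array(arr), attr(arr, "pixdim"))
  })
  im <- ctx("inspiratory", lung_segmentation(unclass_array(
    read_nifti_array(insp_mask, "mask"))))
  ev <- ctx("expiratory", {
    arr <- read_nifti_array(exp_volume, "volume")
    attenuation_volume(unclass_array(arr), attr(arr, "pixdim"))
  })
  em <- ctx("expiratory", lung_segmentation(unclass_array(
    read_nifti_array(exp_mask, "mask"))))
  ctx("pair", scan_pair(iv, im, ev, em, smoking_status))
}

unclass_array <- function(arr) {
  array(as.numeric(arr), dim = dim(arr))
}

#' Write one scan pair as four NIfTI files
#'
#' Writes volume and mask for both phases under \code{dir}, named
#' \code{<prefix>_{insp,exp}{,_mask}.nii.gz}, carrying the voxel spacing in
#' the header. Voxel values round-trip exactly (volumes as float32 may lose
#' sub-HU precision; use \code{datatype = "double"} for bit-exact storage).
#'
#' @param pair a \code{\link{scan_pair}}.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix, e.g. the subject id.
#' @param datatype NIfTI storage type for the volumes (default
#'   \code{"double"} so phantom HU round-trip voxel-exactly).
#' @return Named character vector of the four paths, invisibly usable as a
#'   manifest row.
#' @export
write_scan_pair <- function(pair, dir, prefix, datatype = "double") {
  stopifnot(inherits(pair, "scan_pair"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(insp_volume = file.path(dir, paste0(prefix, "_insp.nii.gz")),
             insp_mask = file.path(dir, paste0(prefix, "_insp_mask.nii.gz")),
             exp_volume = file.path(dir, paste0(prefix, "_exp.nii.gz")),
             exp_mask = file.path(dir, paste0(prefix, "_exp_mask.nii.gz")))
  wr <- function(arr, spacing, path, dt) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- spacing
    RNifti::writeNifti(img, path, datatype = dt)
  }
  wr(pair$insp_volume$grid, pair$insp_volume$spacing, paths["insp_volume"], datatype)
  wr(array(as.integer(pair$insp_mask$mask), dim = dim(pair$insp_mask$mask)),
     pair$insp_volume$spacing, paths["insp_mask"], "uint8")
  wr(pair$exp_volume$grid, pair$exp_volume$spacing, paths["exp_volume"], datatype)
  wr(array(as.integer(pair$exp_mask$mask), dim = dim(pair$exp_mask$mask)),
     pair$exp_volume$spacing, paths["exp_mask"], "uint8")
  invisible(paths)
}

#' Read a subject manifest
#'
#' The manifest is a CSV with one row per subject and columns
#' \code{subject_id}, \code{insp_volume}, \code{insp_mask},
#' \code{exp_volume}, \code{exp_mask}, \code{smoking_status}. Relative paths
#' are resolved against the manifest's directory.
#'
#' @param path manifest CSV path.
#' @return Data frame with resolved paths.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path))
    stop("manifest not found: ", path, call. = FALSE)
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "insp_volume", "insp_mask", "exp_volume",
                "exp_mask", "smoking_status")
  missing_cols <- setdiff(required, names(man))
  if (length(missing_cols))
    stop("manifest lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  base <- dirname(normalizePath(path))
  for (col in c("insp_volume", "insp_mask", "exp_volume", "exp_mask")) {
    rel <- !grepl("^(/|[A-Za-z]:)", man[[col]])
    man[[col]][rel] <- file.path(base, man[[col]][rel])
  }
  man
}

#' Write per-subject metrics as CSV
#'
#' One row per subject with columns \code{subject_id}, \code{insp_950},
#' \code{exp_856}, \code{ei_mla}, \code{rvc_856_950}, \code{tlc_l},
#' \code{frc_l}, \code{frc_tlc}, \code{emphysema_class} (plus
#' \code{residual} once fitted).
#'
#' @param metrics data frame of metric rows.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_metrics_csv <- function(metrics, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}

#' Write a phantom pair plus its ground truth to disk
#'
#' NIfTI images for the four grids and a JSON sidecar holding the spec,
#' realized compartment counts and closed-form expected metrics.
#'
#' @param phantom result of \code{\link{generate_phantom_pair}}.
#' @param dir output directory.
#' @param prefix file name prefix.
#' @return Named vector of written paths, invisibly.
#' @export
write_phantom_pair <- function(phantom, dir, prefix = "phantom") {
  paths <- write_scan_pair(phantom$pair, dir, prefix)
  truth_path <- file.path(dir, paste0(prefix, "_truth.json"))
  tr <- phantom$truth
  jsonlite::write_json(
    list(spec = tr$spec[setdiff(names(tr$spec), "f")],
         n_insp = tr$n_insp, n_exp = tr$n_exp,
         counts_insp = as.list(tr$counts_insp),
         counts_exp = as.list(tr$counts_exp),
         expected = tr$expected, se = tr$se),
    truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, truth = truth_path))
}
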