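## Voxel-level densitometry. All thresholded measures use strict
## inequalities, so the emphysema set (HU < -950), the trapping band
## (-950 <= HU < -856) and the denser lung (HU >= -856) partition the
## segmented lung exactly.

#' Percent of lung voxels below an attenuation threshold (density mask)
#'
#' The classic density-mask index: the percentage of segmented lung voxels
#' with attenuation strictly below a threshold. At -950 HU on inspiratory
#' scans this is the CT emphysema index (Insp-950); at -856 HU on expiratory
#' scans it is the whole-lung gas-trapping index (Exp-856).
#'
#' @param volume an \code{\link{attenuation_volume}}.
#' @param mask a \code{\link{lung_segmentation}} aligned to \code{volume}.
#' @param threshold attenuation cutoff in HU; voxels with HU strictly below
#'   it are counted.
#' @return Percentage in [0, 100].
#' @examples
#' vol <- attenuation_volume(array(c(-1000, -960, -900, -800), c(4, 1, 1)))
#' msk <- lung_segmentation(array(TRUE, c(4, 1, 1)))
#' percent_voxels_below(vol, msk, -950)  # 50
#' @export
percent_voxels_below <- function(volume, mask, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, is.finite(threshold))
  hu <- masked_hu(volume, mask)
  100 * sum(hu < threshold) / length(hu)
}

#' Mean lung attenuation
#'
#' Arithmetic mean HU over the segmented lung (the mean of the density
#' histogram). Expiration densifies normal lung, so expiratory MLA is less
#' negative than inspiratory MLA in healthy subjects.
#'
#' @inheritParams percent_voxels_below
#' @return Mean attenuation in HU.
#' @export
mean_lung_attenuation <- function(volume, mask) {
  mean(masked_hu(volume, mask))
}

#' Expiratory-to-inspiratory ratio of mean lung attenuation (E/I MLA)
#'
#' Gas trapping keeps expiratory lung lucent, pushing expiratory MLA toward
#' the inspiratory value and hence this ratio toward 1; in lungs that empty
#' normally the ratio is clearly below 1 (cohort means around 0.87). Both
#' MLAs are negative for air-containing lung, so the ratio is positive.
#'
#' @param pair a \code{\link{scan_pair}}.
#' @return Dimensionless ratio, typically in (0, 1].
#' @export
ei_mla <- function(pair) {
  stopifnot(inherits(pair, "scan_pair"))
  mla_i <- mean_lung_attenuation(pair$insp_volume, pair$insp_mask)
  mla_e <- mean_lung_attenuation(pair$exp_volume, pair$exp_mask)
  if (abs(mla_i) <= 1)
    stop("degenerate attenuation: inspiratory MLA within 1 HU of zero, ratio unstable",
         call. = FALSE)
  mla_e / mla_i
}

#' Relative lung volume of the -856 to -950 HU band
#'
#' The fraction of non-emphysematous lung (HU >= -950) occupying the
#' gas-trapping attenuation band (-950 <= HU < -856) on a single scan.
#'
#' @inheritParams percent_voxels_below
#' @return Ratio in [0, 1].
#' @export
relative_lung_volume <- function(volume, mask) {
  hu <- masked_hu(volume, mask)
  denom <- sum(hu >= -950)
  if (denom == 0L)
    stop("no non-emphysematous lung: every voxel below -950 HU, relative volume undefined",
         call. = FALSE)
  sum(hu >= -950 & hu < -856) / denom
}

#' Relative volume change of the -856 to -950 HU band (RVC 856-950)
#'
#' Expiratory minus inspiratory relative lung volume
#' (\code{\link{relative_lung_volume}}). Normal lung leaves the band on
#' expiration as it densifies, giving negative values; trapped lung stays in
#' the band, pulling the change toward zero.
#'
#' @param pair a \code{\link{scan_pair}}.
#' @return Difference in [-1, 1]; typically negative.
#' @export
rvc_856_950 <- function(pair) {
  stopifnot(inherits(pair, "scan_pair"))
  rv_e <- tryCatch(relative_lung_volume(pair$exp_volume, pair$exp_mask),
                   error = function(e) stop("expiratory scan: ", conditionMessage(e),
                                            call. = FALSE))
  rv_i <- tryCatch(relative_lung_volume(pair$insp_volume, pair$insp_mask),
                   error = function(e) stop("inspiratory scan: ", conditionMessage(e),
                                            call. = FALSE))
  rv_e - rv_i
}

#' Segmented lung volume in liters
#'
#' Voxel count times the physical voxel volume. Applied to the inspiratory
#' scan this is the CT-derived total lung capacity (TLC); on the expiratory
#' scan it is the functional residual capacity (FRC).
#'
#' @inheritParams percent_voxels_below
#' @return Volume in liters. An empty mask returns 0 with a warning.
#' @export
lung_volume_liters <- function(volume, mask) {
  check_alignment(volume, mask)
  n <- sum(mask$mask)
  if (n == 0L)
    warning("empty segmentation: lung volume is 0 L", call. = FALSE)
  n * prod(volume$spacing) * 1e-6
}

#' Classify emphysema severity from the CT emphysema index
#'
#' Cut-points on Insp-950 are shifted down by one percentage point in
#' current smokers because smoking-related lung density inflation depresses
#' the emphysema index. Former smokers: absent below 5%, severe above 15%;
#' current smokers: absent below 4%, severe above 14%. Values exactly on a
#' cut-point fall in the intermediate class (both bounds are strict).
#'
#' @param insp_950 percent of inspiratory lung below -950 HU, in [0, 100].
#'   Vectorised.
#' @param smoking_status \code{"current"} or \code{"former"}; recycled
#'   against \code{insp_950}.
#' @return Factor with levels \code{absent}, \code{intermediate},
#'   \code{severe}.
#' @examples
#' classify_emphysema_severity(c(3.9, 16), c("current", "former"))
#' @export
classify_emphysema_severity <- function(insp_950, smoking_status) {
  insp_950 <- as.numeric(insp_950)
  if (any(!is.finite(insp_950)) || any(insp_950 < 0) || any(insp_950 > 100))
    stop("insp_950 must lie in [0, 100]", call. = FALSE)
  smoking_status <- as.character(smoking_status)
  if (!all(smoking_status %in% c("current", "former")))
    stop("smoking_status must be 'current' or 'former'", call. = FALSE)
  n <- max(length(insp_950), length(smoking_status))
  insp_950 <- rep_len(insp_950, n)
  smoking_status <- rep_len(smoking_status, n)
  lo <- ifelse(smoking_status == "current", 4, 5)
  hi <- ifelse(smoking_status == "current", 14, 15)
  cls <- ifelse(insp_950 < lo, "absent",
                ifelse(insp_950 > hi, "severe", "intermediate"))
  factor(cls, levels = c("absent", "intermediate", "severe"))
}

#' Compute all densitometry metrics for one scan pair
#'
#' Runs the full per-subject panel: the emphysema index Insp-950, the four
#' single- and paired-scan gas-trapping measures that can be computed
#' without the cohort (Exp-856, E/I MLA, RVC 856-950), CT lung volumes (TLC
#' from the inspiratory mask, FRC from the expiratory mask, their ratio),
#' and the emphysema severity class. The cohort-level residual measure is
#' added later by \code{\link{fit_gas_trapping_residuals}}.
#'
#' @param pair a \code{\link{scan_pair}}.
#' @param emph_threshold HU cutoff for the inspiratory emphysema index
#'   (default -950).
#' @param trap_threshold HU cutoff for the expiratory gas-trapping index
#'   (default -856); must exceed \code{emph_threshold}.
#' @return Object of class \code{density_metrics}: a list with elements
#'   \code{insp_950}, \code{exp_856}, \code{ei_mla}, \code{rvc_856_950},
#'   \code{tlc_l}, \code{frc_l}, \code{frc_tlc}, \code{emphysema_class}.
#' @export
compute_scan_pair_metrics <- function(pair, emph_threshold = -950,
                                      trap_threshold = -856) {
  stopifnot(inherits(pair, "scan_pair"))
  if (emph_threshold >= trap_threshold)
    stop("emph_threshold must be below trap_threshold (default -950 < -856)",
         call. = FALSE)
  wrap <- function(metric, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("%s: %s", metric, conditionMessage(e)), call. = FALSE))
  }
  insp_950 <- wrap("insp_950",
                   percent_voxels_below(pair$insp_volume, pair$insp_mask,
                                        emph_threshold))
  exp_856 <- wrap("exp_856",
                  percent_voxels_below(pair$exp_volume, pair$exp_mask,
                                       trap_threshold))
  eimla <- wrap("ei_mla", ei_mla(pair))
  rvc <- wrap("rvc_856_950", rvc_856_950(pair))
  tlc <- wrap("tlc_l", lung_volume_liters(pair$insp_volume, pair$insp_mask))
  frc <- wrap("frc_l", lung_volume_liters(pair$exp_volume, pair$exp_mask))
  if (tlc <= 0)
    stop("frc_tlc: TLC is zero, ratio undefined", call. = FALSE)
  structure(list(insp_950 = insp_950,
                 exp_856 = exp_856,
                 ei_mla = eimla,
                 rvc_856_950 = rvc,
                 tlc_l = tlc,
                 frc_l = frc,
                 frc_tlc = frc / tlc,
                 emphysema_class = as.character(
                   classify_emphysema_severity(insp_950, pair$smoking_status))),
            class = "density_metrics")
}

#' @export
print.density_metrics <- function(x, ...) {
  cat(sprintf(paste0("<density_metrics> Insp-950 %.2f%%  Exp-856 %.2f%%  ",
                     "E/I MLA %.4f  RVC %.4f\n  TLC %.3f L  FRC %.3f L  ",
                     "FRC/TLC %.3f  emphysema: %s\n"),
              x$insp_950, x$exp_856, x$ei_mla, x$rvc_856_950,
              x$tlc_l, x$frc_l, x$frc_tlc, x$emphysema_class))
  invisible(x)
}

#' @export
as.data.frame.density_metrics <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(insp_950 = x$insp_950, exp_856 = x$exp_856, ei_mla = x$ei_mla,
             rvc_856_950 = x$rvc_856_950, tlc_l = x$tlc_l, frc_l = x$frc_l,
             frc_tlc = x$frc_tlc, emphysema_class = x$emphysema_class,
             stringsAsFactors = FALSE, row.names = row.names)
}
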