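## Synthetic paired-scan phantoms. Lung voxels belong to one of three
## compartments: emphysema (lucent on both phases), air-trapped lung (stays
## lucent on expiration) and normal lung (densifies markedly on expiration).
## Inspiratory HU are truncated-normal draws per compartment; expiration
## retains a random subset of voxels (lung shrinks) and adds a
## per-compartment HU shift. Everything has a closed-form expectation, so
## the phantoms double as oracles for the densitometry code.

## Truncated normal on [a, b]: standard Mills-ratio closed forms.
tn_z <- function(mu, sd, a, b) stats::pnorm(b, mu, sd) - stats::pnorm(a, mu, sd)

tn_cdf <- function(q, mu, sd, a, b) {
  z <- tn_z(mu, sd, a, b)
  p <- (stats::pnorm(pmin(pmax(q, a), b), mu, sd) - stats::pnorm(a, mu, sd)) / z
  pmin(pmax(p, 0), 1)
}

tn_mean <- function(mu, sd, a, b) {
  al <- (a - mu) / sd; be <- (b - mu) / sd
  z <- stats::pnorm(be) - stats::pnorm(al)
  mu + sd * (stats::dnorm(al) - stats::dnorm(be)) / z
}

tn_var <- function(mu, sd, a, b) {
  al <- (a - mu) / sd; be <- (b - mu) / sd
  z <- stats::pnorm(be) - stats::pnorm(al)
  d <- (stats::dnorm(al) - stats::dnorm(be)) / z
  sd^2 * (1 + (al * stats::dnorm(al) - be * stats::dnorm(be)) / z - d^2)
}

tn_sample <- function(n, mu, sd, a, b) {
  pa <- stats::pnorm(a, mu, sd); pb <- stats::pnorm(b, mu, sd)
  stats::qnorm(pa + stats::runif(n) * (pb - pa), mu, sd)
}

## Run expr with a private RNG stream; the caller's .Random.seed is restored.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Phantom specification
#'
#' Parameters of a synthetic paired-scan phantom. The defaults place the
#' emphysema compartment almost entirely below -950 HU on both phases
#' (destroyed lung stays lucent), keep the trapped compartment inside the
#' -950 to -856 HU band on expiration (it fails to empty), and move normal
#' lung across -856 HU on expiration (it densifies by about +150 HU) — the
#' mechanism by which expiratory lucency alone conflates emphysema with
#' small-airway disease.
#'
#' @param shape integer 3-vector, grid dimensions.
#' @param spacing numeric 3-vector, voxel edge lengths in mm.
#' @param f_emph,f_trap fractions of lung voxels in the emphysema and
#'   air-trapping compartments (the remainder is normal lung);
#'   \code{f_emph + f_trap <= 1}.
#' @param insp_mean,insp_sd length-3 numeric (emphysema, trapped, normal):
#'   inspiratory compartment HU means and SDs.
#' @param exp_shift length-3 numeric: HU added to each compartment at
#'   expiration.
#' @param exp_volume_scale fraction of inspiratory lung voxels retained at
#'   expiration, in (0, 1].
#' @param hu_range truncation bounds for the inspiratory HU draws.
#' @param seed integer seed; the same spec is bit-reproducible.
#' @return Object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(shape = c(48L, 48L, 48L),
                         spacing = c(0.7, 0.7, 0.7),
                         f_emph = 0.25,
                         f_trap = 0.25,
                         insp_mean = c(emphysema = -990, trapped = -880, normal = -870),
                         insp_sd = c(emphysema = 15, trapped = 20, normal = 25),
                         exp_shift = c(emphysema = 5, trapped = 10, normal = 150),
                         exp_volume_scale = 0.65,
                         hu_range = c(-1024, 100),
                         seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 4L))
    stop("shape must be three integers >= 4", call. = FALSE)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three positive lengths", call. = FALSE)
  if (f_emph < 0 || f_trap < 0 || f_emph + f_trap > 1 + 1e-12)
    stop("compartment fractions must be in [0, 1] with f_emph + f_trap <= 1",
         call. = FALSE)
  stopifnot(length(insp_mean) == 3L, length(insp_sd) == 3L,
            length(exp_shift) == 3L, all(insp_sd > 0))
  if (exp_volume_scale <= 0 || exp_volume_scale > 1)
    stop("exp_volume_scale must be in (0, 1]", call. = FALSE)
  if (hu_range[1] >= hu_range[2])
    stop("hu_range must be increasing", call. = FALSE)
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 f_emph = f_emph, f_trap = f_trap,
                 f = c(emphysema = f_emph, trapped = f_trap,
                       normal = 1 - f_emph - f_trap),
                 insp_mean = unname(insp_mean), insp_sd = unname(insp_sd),
                 exp_shift = unname(exp_shift),
                 exp_volume_scale = exp_volume_scale,
                 hu_range = as.numeric(hu_range),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

## Filled ellipsoid with semi-axes 0.45 * dim, centred in the grid.
ellipsoid_mask <- function(shape) {
  cx <- (shape + 1) / 2
  ax <- 0.45 * shape
  dx <- (seq_len(shape[1]) - cx[1]) / ax[1]
  dy <- (seq_len(shape[2]) - cx[2]) / ax[2]
  dz <- (seq_len(shape[3]) - cx[3]) / ax[3]
  r2 <- outer(outer(dx^2, dy^2, `+`), dz^2, `+`)
  array(r2 <= 1, dim = shape)
}

#' Generate a synthetic paired inspiratory-expiratory phantom
#'
#' Builds an ellipsoidal lung inside the grid, assigns each lung voxel
#' independently to a compartment, draws inspiratory HU from the
#' compartment's truncated normal, and derives the expiratory scan by
#' retaining a random fraction of the lung voxels (volume loss) and shifting
#' the retained voxels' HU by the compartment shift. Background voxels are
#' set to soft-tissue attenuation (50 HU). Identical specs (including seed)
#' give bit-identical output.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return List with \code{pair} (a \code{\link{scan_pair}}) and
#'   \code{truth} (a \code{phantom_truth}: realized compartment counts per
#'   phase, the expected metrics from
#'   \code{\link{expected_phantom_metrics}}, and their Monte-Carlo standard
#'   errors from \code{\link{phantom_metric_se}} at the realized voxel
#'   counts).
#' @export
generate_phantom_pair <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    mask <- ellipsoid_mask(spec$shape)
    idx <- which(mask)
    n_lung <- length(idx)
    comp <- sample.int(3L, n_lung, replace = TRUE, prob = spec$f)
    hu <- numeric(n_lung)
    for (c in 1:3) {
      sel <- comp == c
      if (any(sel))
        hu[sel] <- tn_sample(sum(sel), spec$insp_mean[c], spec$insp_sd[c],
                             spec$hu_range[1], spec$hu_range[2])
    }
    insp_grid <- array(50, dim = spec$shape)
    insp_grid[idx] <- hu

    n_exp <- max(1L, round(spec$exp_volume_scale * n_lung))
    keep <- sort(sample.int(n_lung, n_exp))
    exp_grid <- array(50, dim = spec$shape)
    exp_mask_arr <- array(FALSE, dim = spec$shape)
    exp_mask_arr[idx[keep]] <- TRUE
    exp_grid[idx[keep]] <- hu[keep] + spec$exp_shift[comp[keep]]

    pair <- scan_pair(
      insp_volume = attenuation_volume(insp_grid, spec$spacing),
      insp_mask = lung_segmentation(mask),
      exp_volume = attenuation_volume(exp_grid, spec$spacing),
      exp_mask = lung_segmentation(exp_mask_arr),
      smoking_status = "former")

    counts_insp <- tabulate(comp, nbins = 3L)
    counts_exp <- tabulate(comp[keep], nbins = 3L)
    names(counts_insp) <- names(counts_exp) <- c("emphysema", "trapped", "normal")
    truth <- structure(
      list(spec = spec,
           n_insp = n_lung, n_exp = n_exp,
           counts_insp = counts_insp, counts_exp = counts_exp,
           expected = expected_phantom_metrics(spec),
           se = phantom_metric_se(spec, n_insp = n_lung, n_exp = n_exp)),
      class = "phantom_truth")
    list(pair = pair, truth = truth)
  })
}

## Per-compartment probabilities used by the closed-form expectations.
phantom_probs <- function(spec) {
  a <- spec$hu_range[1]; b <- spec$hu_range[2]
  m <- spec$insp_mean; s <- spec$insp_sd; sh <- spec$exp_shift
  list(
    p950_insp = tn_cdf(-950, m, s, a, b),
    band_insp = tn_cdf(-856, m, s, a, b) - tn_cdf(-950, m, s, a, b),
    above950_insp = 1 - tn_cdf(-950, m, s, a, b),
    # expiratory HU = inspiratory HU + shift, so P(X + s < t) = F(t - s)
    p856_exp = tn_cdf(-856 - sh, m, s, a, b),
    band_exp = tn_cdf(-856 - sh, m, s, a, b) - tn_cdf(-950 - sh, m, s, a, b),
    above950_exp = 1 - tn_cdf(-950 - sh, m, s, a, b),
    mean_insp = tn_mean(m, s, a, b),
    mean_exp = tn_mean(m, s, a, b) + sh,
    var_comp = tn_var(m, s, a, b))
}

#' Closed-form expected metrics for a phantom specification
#'
#' Expectations of the densitometry metrics under the phantom's generative
#' model, from truncated-normal tail probabilities: each thresholded percent
#' is 100 times the compartment-weighted tail mass, the mean lung
#' attenuations are compartment-weighted truncated-normal means, the E/I MLA
#' expectation is the ratio of those means, and the relative-volume terms
#' are ratios of band to non-emphysema probability per phase. These are the
#' oracle values the measured phantom metrics converge to as the voxel count
#' grows.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return List with \code{insp_950}, \code{exp_856}, \code{ei_mla},
#'   \code{rvc_856_950}, \code{mla_insp}, \code{mla_exp},
#'   \code{relvol_insp}, \code{relvol_exp}.
#' @export
expected_phantom_metrics <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  f <- spec$f
  pr <- phantom_probs(spec)
  mla_i <- sum(f * pr$mean_insp)
  mla_e <- sum(f * pr$mean_exp)
  q1_i <- sum(f * pr$band_insp); q2_i <- sum(f * pr$above950_insp)
  q1_e <- sum(f * pr$band_exp); q2_e <- sum(f * pr$above950_exp)
  list(insp_950 = 100 * sum(f * pr$p950_insp),
       exp_856 = 100 * sum(f * pr$p856_exp),
       ei_mla = mla_e / mla_i,
       rvc_856_950 = q1_e / q2_e - q1_i / q2_i,
       mla_insp = mla_i, mla_exp = mla_e,
       relvol_insp = q1_i / q2_i, relvol_exp = q1_e / q2_e)
}

#' Monte-Carlo standard errors of the measured phantom metrics
#'
#' Standard errors of the metrics measured on one realized phantom around
#' their closed-form expectations. Thresholded percents are binomial
#' (voxels are i.i.d. given the spec). The E/I MLA and relative-volume
#' ratios use the delta method; the inspiratory-expiratory covariance
#' induced by voxel thinning is positive and is deliberately ignored, which
#' overstates the SE of the ratio and of the RVC difference — the resulting
#' 3-SE acceptance band is conservative.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @param n_insp,n_exp realized lung voxel counts per phase.
#' @return List with \code{insp_950}, \code{exp_856}, \code{ei_mla},
#'   \code{rvc_856_950}.
#' @export
phantom_metric_se <- function(spec, n_insp, n_exp) {
  stopifnot(inherits(spec, "phantom_spec"), n_insp >= 1, n_exp >= 1)
  f <- spec$f
  pr <- phantom_probs(spec)

  p_i <- sum(f * pr$p950_insp)
  p_e <- sum(f * pr$p856_exp)
  se_insp950 <- 100 * sqrt(p_i * (1 - p_i) / n_insp)
  se_exp856 <- 100 * sqrt(p_e * (1 - p_e) / n_exp)

  # mixture variances (law of total variance over the compartment label)
  mla_i <- sum(f * pr$mean_insp)
  mla_e <- sum(f * pr$mean_exp)
  v_i <- sum(f * (pr$var_comp + pr$mean_insp^2)) - mla_i^2
  v_e <- sum(f * (pr$var_comp + pr$mean_exp^2)) - mla_e^2
  se_eimla <- sqrt(v_e / (n_exp * mla_i^2) + mla_e^2 * v_i / (n_insp * mla_i^4))

  relvol_var <- function(q1, q2, n) {
    # X = band count, Y = non-emphysema count, X subset of Y:
    # Cov(X, Y) = n q1 (1 - q2); delta method on X/Y
    r <- q1 / q2
    (q1 * (1 - q1) - 2 * r * q1 * (1 - q2) + r^2 * q2 * (1 - q2)) / (n * q2^2)
  }
  q1_i <- sum(f * pr$band_insp); q2_i <- sum(f * pr$above950_insp)
  q1_e <- sum(f * pr$band_exp); q2_e <- sum(f * pr$above950_exp)
  se_rvc <- sqrt(relvol_var(q1_i, q2_i, n_insp) + relvol_var(q1_e, q2_e, n_exp))

  list(insp_950 = se_insp950, exp_856 = se_exp856,
       ei_mla = se_eimla, rvc_856_950 = se_rvc)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %s grid, f_emph %.2f, f_trap %.2f, exp scale %.2f, seed %d\n",
              paste(x$shape, collapse = "x"), x$f_emph, x$f_trap,
              x$exp_volume_scale, x$seed))
  invisible(x)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %d insp / %d exp lung voxels\n", x$n_insp, x$n_exp))
  cat(sprintf("  expected: Insp-950 %.2f%%, Exp-856 %.2f%%, E/I MLA %.4f, RVC %.4f\n",
              x$expected$insp_950, x$expected$exp_856, x$expected$ei_mla,
              x$expected$rvc_856_950))
  invisible(x)
}
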