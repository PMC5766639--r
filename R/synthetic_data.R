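# Synthetic phantoms and cohorts with the statistical structure the
# analysis assumes, so every stage is testable without any download.

#' Tissue class specification for phantoms
#'
#' A named tissue class carrying its IVIM and/or Tofts ground truth and
#' its spatial extent (inclusive index ranges) on the phantom grid.
#'
#' @param name class label.
#' @param ivim an [ivim_params] (required for DWI phantoms).
#' @param tofts a [tofts_params] (required for DCE phantoms).
#' @param extent list with integer vectors `x`, `y`, `z` of occupied
#'   voxel indices (1-based).
#' @return An object of class `tissue_class`.
#' @export
tissue_class <- function(name, ivim = NULL, tofts = NULL, extent) {
  if (!all(c("x", "y", "z") %in% names(extent)))
    stop("extent must name x, y and z index vectors")
  structure(list(name = name, ivim = ivim, tofts = tofts, extent = extent),
            class = "tissue_class")
}

class_voxels <- function(cl, dims) {
  ex <- cl$extent
  if (any(ex$x < 1) || any(ex$x > dims[1]) ||
      any(ex$y < 1) || any(ex$y > dims[2]) ||
      any(ex$z < 1) || any(ex$z > dims[3]))
    stop(sprintf("class '%s' extent exceeds the phantom grid", cl$name))
  g <- expand.grid(x = ex$x, y = ex$y, z = ex$z)
  (g$z - 1) * dims[1] * dims[2] + (g$y - 1) * dims[1] + g$x
}

check_disjoint <- function(classes, dims) {
  vox <- lapply(classes, class_voxels, dims = dims)
  all_v <- unlist(vox)
  if (anyDuplicated(all_v))
    stop("tissue classes overlap")
  vox
}

#' Mean of a Rician distribution
#'
#' `E[sqrt((nu + e1)^2 + e2^2)]` with independent Gaussian channels of
#' scale `sigma`: `sigma * sqrt(pi/2) * L_{1/2}(-nu^2 / (2 sigma^2))`,
#' evaluated through exponentially-scaled Bessel functions so it stays
#' finite at high SNR. Used as the moment oracle for phantom noise tests.
#'
#' @param nu noiseless magnitude.
#' @param sigma per-channel Gaussian noise scale.
#' @return The expected magnitude.
#' @export
rician_mean <- function(nu, sigma) {
  t <- nu^2 / (2 * sigma^2)
  # L_{1/2}(-t) = exp(-t/2) * ((1 + t) I0(t/2) + t I1(t/2));
  # besselI(..., expon.scaled) supplies the exp(t/2) factor implicitly.
  lag <- (1 + t) * besselI(t / 2, 0, expon.scaled = TRUE) +
    t * besselI(t / 2, 1, expon.scaled = TRUE)
  sigma * sqrt(pi / 2) * lag
}

#' Generate a multi-b-value DWI phantom
#'
#' Voxel signals follow [ivim_signal()] for each tissue class, corrupted
#' by Rician noise of scale `S0 / snr` (Gaussian noise added to the two
#' quadrature channels, then magnitude). `snr = Inf` disables noise.
#' Deterministic for a fixed seed.
#'
#' @param classes list of [tissue_class] objects with non-overlapping,
#'   in-grid extents and `ivim` set.
#' @param scheme a [bvalue_scheme] (default: the 10-b-value scheme).
#' @param snr signal-to-noise ratio `S0 / sigma` at b = 0 (> 0; may be
#'   `Inf`).
#' @param seed optional RNG seed.
#' @param dims length-3 phantom grid size (default: tight bounding box).
#' @param S0 baseline signal, arbitrary units.
#' @param voxel_size voxel dimensions, mm.
#' @return List: `volume` (4D array), `scheme`, `mask` (3D logical, union
#'   of classes), `truth` (maps `f`, `D`, `D_star`, `SPF` — the noiseless
#'   three-point SPF), `class_map` (integer array), `S0`, `snr`.
#' @export
make_dwi_phantom <- function(classes, scheme = default_bvalue_scheme(),
                             snr = Inf, seed = NULL, dims = NULL,
                             S0 = 100, voxel_size = c(1, 1, 1)) {
  if (!is.finite(snr) && !is.infinite(snr)) stop("snr must be positive")
  if (snr <= 0) stop("snr must be positive")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dims))
    dims <- c(max(unlist(lapply(classes, function(cl) max(cl$extent$x)))),
              max(unlist(lapply(classes, function(cl) max(cl$extent$y)))),
              max(unlist(lapply(classes, function(cl) max(cl$extent$z)))))
  vox <- check_disjoint(classes, dims)
  nb <- length(scheme$b_values)
  volume <- array(0, c(dims, nb))
  mask <- array(FALSE, dims)
  class_map <- array(0L, dims)
  truth <- list(f = array(NA_real_, dims), D = array(NA_real_, dims),
                D_star = array(NA_real_, dims), SPF = array(NA_real_, dims))
  nvox <- prod(dims)
  for (ci in seq_along(classes)) {
    cl <- classes[[ci]]
    if (is.null(cl$ivim)) stop(sprintf("class '%s' has no IVIM params", cl$name))
    sig <- ivim_signal(cl$ivim, scheme$b_values, S0 = S0)
    spf_true <- tryCatch(
      compute_spf(dwi_series(scheme, sig))$SPF, error = function(e) NA_real_)
    for (k in seq_len(nb))
      volume[vox[[ci]] + (k - 1L) * nvox] <- sig[k]
    mask[vox[[ci]]] <- TRUE
    class_map[vox[[ci]]] <- ci
    truth$f[vox[[ci]]] <- cl$ivim$f
    truth$D[vox[[ci]]] <- cl$ivim$D
    truth$D_star[vox[[ci]]] <- cl$ivim$D_star
    truth$SPF[vox[[ci]]] <- spf_true
  }
  if (is.finite(snr)) {
    sigma <- S0 / snr
    n_total <- length(volume)
    e1 <- stats::rnorm(n_total, sd = sigma)
    e2 <- stats::rnorm(n_total, sd = sigma)
    volume <- sqrt((volume + e1)^2 + e2^2)
  }
  truth_maps <- lapply(stats::setNames(names(truth), names(truth)),
                       function(nm) parametric_map(
                         truth[[nm]], mask = mask, voxel_size = voxel_size,
                         parameter_name = nm,
                         meta = list(source = "phantom ground truth")))
  list(volume = volume, scheme = scheme, mask = mask, truth = truth_maps,
       class_map = class_map, S0 = S0, snr = snr,
       voxel_size = voxel_size)
}

#' Generate a DCE concentration phantom
#'
#' Voxel curves follow [tofts_concentration()] for each class plus
#' additive Gaussian noise in concentration units.
#'
#' @param classes list of [tissue_class] objects with `tofts` set.
#' @param aif an [aif].
#' @param times sample times, min (default: the AIF grid); must lie
#'   within the AIF span.
#' @param noise_sd Gaussian noise standard deviation, mM (0 = noiseless).
#' @param seed optional RNG seed.
#' @param dims grid size (default: tight bounding box).
#' @param voxel_size voxel dimensions, mm.
#' @return List: `volume` (4D concentration array), `times`, `aif`,
#'   `mask`, `truth` (maps `Ktrans`, `ve`, `vp`), `class_map`.
#' @export
make_dce_phantom <- function(classes, aif, times = aif$times,
                             noise_sd = 0, seed = NULL, dims = NULL,
                             voxel_size = c(1, 1, 1)) {
  if (min(times) < min(aif$times) - 1e-9 ||
      max(times) > max(aif$times) + 1e-9)
    stop("times must lie within the AIF span")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dims))
    dims <- c(max(unlist(lapply(classes, function(cl) max(cl$extent$x)))),
              max(unlist(lapply(classes, function(cl) max(cl$extent$y)))),
              max(unlist(lapply(classes, function(cl) max(cl$extent$z)))))
  vox <- check_disjoint(classes, dims)
  nt <- length(times)
  volume <- array(0, c(dims, nt))
  mask <- array(FALSE, dims)
  class_map <- array(0L, dims)
  truth <- list(Ktrans = array(NA_real_, dims), ve = array(NA_real_, dims),
                vp = array(NA_real_, dims))
  nvox <- prod(dims)
  for (ci in seq_along(classes)) {
    cl <- classes[[ci]]
    if (is.null(cl$tofts)) stop(sprintf("class '%s' has no Tofts params", cl$name))
    ct <- tofts_concentration(cl$tofts, aif, times)
    for (k in seq_len(nt))
      volume[vox[[ci]] + (k - 1L) * nvox] <- ct[k]
    mask[vox[[ci]]] <- TRUE
    class_map[vox[[ci]]] <- ci
    truth$Ktrans[vox[[ci]]] <- cl$tofts$Ktrans
    truth$ve[vox[[ci]]] <- cl$tofts$v_e
    truth$vp[vox[[ci]]] <- cl$tofts$v_p
  }
  if (noise_sd > 0)
    volume <- volume + stats::rnorm(length(volume), sd = noise_sd)
  truth_maps <- lapply(stats::setNames(names(truth), names(truth)),
                       function(nm) parametric_map(
                         truth[[nm]], mask = mask, voxel_size = voxel_size,
                         parameter_name = nm,
                         meta = list(source = "phantom ground truth")))
  list(volume = volume, times = times, aif = aif, mask = mask,
       truth = truth_maps, class_map = class_map, voxel_size = voxel_size)
}

#' Calibrate a log-normal distribution from a median and IQR
#'
#' For a positive, right-skewed parameter summarized by its median and
#' interquartile range, the log-normal with `mu = log(median)` and
#' `sigma = log(q3 / q1) / (2 * 0.67449)` reproduces the median and the
#' quartile ratio `q3 / q1` exactly in closed form (0.67449 is the upper
#' quartile of the standard normal, `qnorm(0.75)`). The individual
#' quartile endpoints are reproduced exactly only when the printed IQR is
#' geometrically symmetric about the median (`q1 * q3 = median^2`); a
#' two-parameter family cannot match three independent quantiles.
#'
#' @param median,q1,q3 positive summary statistics with `q1 < median < q3`.
#' @return List with `mu` and `sigma` (log-scale parameters).
#' @export
lognormal_from_median_iqr <- function(median, q1, q3) {
  if (any(c(median, q1, q3) <= 0))
    stop("median and quartiles must be positive")
  if (!(q1 < median && median < q3))
    stop("require q1 < median < q3")
  list(mu = log(median), sigma = log(q3 / q1) / (2 * stats::qnorm(0.75)))
}

#' Reference glioma cohort calibration
#'
#' Per-parameter, per-group (low/high grade) medians and IQRs used to
#' calibrate the synthetic cohort generator, shipped as a human-readable
#' CSV in `inst/extdata/`. Units follow clinical reporting convention:
#' `SPF` and `f` in %, `ADC_0_1000`, `D`, `D_star` in 1e-3 mm^2/s,
#' `Ktrans` in 1/min, `v_e` and `v_p` as fractions.
#'
#' @return Data frame: `parameter`, `group`, `median`, `q1`, `q3`, `units`.
#' @export
cohort_reference_specs <- function() {
  path <- system.file("extdata", "glioma_cohort_calibration.csv",
                      package = "spfmri", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Generate a calibrated two-group cohort table
#'
#' Per-group log-normal draws for each parameter, calibrated by
#' [lognormal_from_median_iqr()] from the supplied spec table. Parameters
#' are drawn independently by default; an optional Gaussian copula couples
#' them at a specified Spearman rank correlation (converted to the latent
#' Pearson correlation by `2 * sin(pi * rho / 6)`).
#'
#' @param specs data frame like [cohort_reference_specs()]: columns
#'   `parameter`, `group` (`"low"`/`"high"`), `median`, `q1`, `q3`. Every
#'   parameter must have a row for both groups.
#' @param n_low,n_high group sizes (defaults 19 and 31).
#' @param seed optional RNG seed.
#' @param rank_correlation optional square Spearman correlation matrix
#'   with dimnames naming the parameters.
#' @return Data frame with `subject_id`, `grade` and one column per
#'   parameter.
#' @export
make_cohort <- function(specs = cohort_reference_specs(), n_low = 19,
                        n_high = 31, seed = NULL, rank_correlation = NULL) {
  if (!is.null(seed)) set.seed(seed)
  params <- unique(specs$parameter)
  for (p in params) for (g in c("low", "high"))
    if (sum(specs$parameter == p & specs$group == g) != 1L)
      stop(sprintf("missing spec for parameter '%s', group '%s'", p, g))
  n <- c(low = n_low, high = n_high)
  draw_group <- function(g) {
    m <- n[[g]]
    if (!is.null(rank_correlation)) {
      rc <- rank_correlation[params, params, drop = FALSE]
      pearson <- 2 * sin(pi * rc / 6)
      diag(pearson) <- 1
      L <- chol(pearson)
      z <- matrix(stats::rnorm(m * length(params)), m) %*% L
      u <- stats::pnorm(z)
    } else {
      u <- matrix(stats::runif(m * length(params)), m)
    }
    out <- as.data.frame(lapply(seq_along(params), function(j) {
      row <- specs[specs$parameter == params[j] & specs$group == g, ]
      ln <- lognormal_from_median_iqr(row$median, row$q1, row$q3)
      stats::qlnorm(u[, j], meanlog = ln$mu, sdlog = ln$sigma)
    }))
    names(out) <- params
    out$grade <- g
    out
  }
  tab <- rbind(draw_group("low"), draw_group("high"))
  tab <- cbind(subject_id = sprintf("S%03d", seq_len(nrow(tab))), tab)
  tab[, c("subject_id", "grade", params)]
}

#' Mean ROC AUC of a parameter over calibrated synthetic cohorts
#'
#' Repeatedly draws two-group cohorts from the per-group log-normal
#' distributions calibrated by [lognormal_from_median_iqr()] and averages
#' the rank-based AUC (direction auto-oriented so AUC >= 0.5) over the
#' replicates. This is the Monte-Carlo estimate of the population
#' discriminability implied by the printed group medians/IQRs.
#'
#' @param parameter parameter name present in `specs`.
#' @param specs calibration table (default [cohort_reference_specs()]).
#' @param n_low,n_high group sizes per replicate (defaults 19 and 31).
#' @param n_rep number of replicates (default 2000).
#' @param seed optional RNG seed.
#' @return List: `mean_auc`, `sd_auc`, `n_rep`.
#' @export
simulate_parameter_auc <- function(parameter,
                                   specs = cohort_reference_specs(),
                                   n_low = 19, n_high = 31, n_rep = 2000,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lo <- specs[specs$parameter == parameter & specs$group == "low", ]
  hi <- specs[specs$parameter == parameter & specs$group == "high", ]
  if (nrow(lo) != 1L || nrow(hi) != 1L)
    stop(sprintf("missing spec for parameter '%s'", parameter))
  ln_lo <- lognormal_from_median_iqr(lo$median, lo$q1, lo$q3)
  ln_hi <- lognormal_from_median_iqr(hi$median, hi$q1, hi$q3)
  labels <- c(rep("low", n_low), rep("high", n_high))
  aucs <- vapply(seq_len(n_rep), function(i) {
    v <- c(stats::rlnorm(n_low, ln_lo$mu, ln_lo$sigma),
           stats::rlnorm(n_high, ln_hi$mu, ln_hi$sigma))
    roc_analysis(v, labels)$auc
  }, numeric(1))
  list(mean_auc = mean(aucs), sd_auc = stats::sd(aucs), n_rep = n_rep)
}
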