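# Estimation of SPF components, conventional ADC and IVIM parameters from
# multi-b-value DWI signals, per voxel and over whole volumes.

#' A single-voxel DWI signal series
#'
#' Signals measured on a [bvalue_scheme]. Signals must be positive for
#' fitting; voxels with non-positive signal are masked upstream.
#'
#' @param scheme a [bvalue_scheme].
#' @param signals numeric vector, one signal per b-value.
#' @return An object of class `dwi_series`.
#' @export
dwi_series <- function(scheme, signals) {
  if (!inherits(scheme, "bvalue_scheme")) scheme <- bvalue_scheme(scheme)
  signals <- as.numeric(signals)
  if (length(signals) != length(scheme$b_values))
    stop(sprintf("signal length (%d) does not match scheme length (%d)",
                 length(signals), length(scheme$b_values)))
  if (any(!is.finite(signals)))
    stop("signals must be finite")
  structure(list(scheme = scheme, signals = signals), class = "dwi_series")
}

#' Two-point apparent diffusion coefficient
#'
#' `ADC = log(S_low / S_high) / (b_high - b_low)`. May legitimately be
#' negative for noisy inputs (when `S_high > S_low`); the value is returned
#' as-is and downstream code carries a flag rather than clipping.
#'
#' @param S_low,S_high positive signal intensities at `b_low` and `b_high`.
#' @param b_low,b_high b-values with `b_high > b_low >= 0`, s/mm^2.
#' @return ADC in mm^2/s (vectorized).
#' @export
two_point_adc <- function(S_low, S_high, b_low, b_high) {
  if (any(S_low <= 0) || any(S_high <= 0))
    stop("signals must be positive")
  if (any(b_low < 0) || any(b_high <= b_low))
    stop("require b_high > b_low >= 0")
  log(S_low / S_high) / (b_high - b_low)
}

#' Simplified perfusion fraction from three b-values
#'
#' Computes the four two-point-ADC quantities from a DWI series:
#' `ADC_0_200` from the (0, b_cut) pair, `ADC_200_1000` from the
#' (b_cut, b_max) pair, their difference `ADC_perf`, and
#' `SPF = ADC_perf / ADC_0_200`. The default (`method = "three_point"`)
#' uses exactly the three named b-values; `method = "range_regression"`
#' instead fits log-linear regressions over all b-values within
#' `[0, b_cut]` and `[b_cut, b_max]` (non-default alternative reading).
#' The identities `ADC_perf = ADC_0_200 - ADC_200_1000` and
#' `SPF * ADC_0_200 = ADC_perf` hold exactly as stored.
#'
#' @param series a [dwi_series].
#' @param b_cut perfusion/diffusion cutoff b-value, s/mm^2 (default 200).
#' @param b_max top b-value, s/mm^2 (default 1000).
#' @param method `"three_point"` (default) or `"range_regression"`.
#' @return An object of class `spf_components` with fields `ADC_0_200`,
#'   `ADC_200_1000`, `ADC_perf`, `SPF`, plus `valid` (FALSE when
#'   `ADC_0_200 <= 0`, in which case `SPF` is `NA`) and `negative_perf`
#'   (noise flag; the negative value is retained, not clipped).
#' @export
compute_spf <- function(series, b_cut = 200, b_max = 1000,
                        method = c("three_point", "range_regression")) {
  method <- match.arg(method)
  b <- series$scheme$b_values
  s <- series$signals
  if (any(s <= 0)) stop("signals must be positive; mask this voxel")
  idx_of <- function(target) {
    i <- which(abs(b - target) < 1e-9)
    if (length(i) != 1L)
      stop(sprintf("scheme is missing required b-value %g s/mm^2", target))
    i
  }
  if (method == "three_point") {
    i0 <- idx_of(0); ic <- idx_of(b_cut); im <- idx_of(b_max)
    adc_low <- two_point_adc(s[i0], s[ic], 0, b_cut)
    adc_high <- two_point_adc(s[ic], s[im], b_cut, b_max)
  } else {
    lo <- b <= b_cut + 1e-9
    hi <- b >= b_cut - 1e-9 & b <= b_max + 1e-9
    if (sum(lo) < 2L || sum(hi) < 2L)
      stop("range_regression needs at least two b-values in each range")
    adc_low <- -unname(stats::coef(stats::lm(log(s[lo]) ~ b[lo]))[2])
    adc_high <- -unname(stats::coef(stats::lm(log(s[hi]) ~ b[hi]))[2])
  }
  adc_perf <- adc_low - adc_high
  valid <- adc_low > 0
  structure(list(
    ADC_0_200 = adc_low,
    ADC_200_1000 = adc_high,
    ADC_perf = adc_perf,
    SPF = if (valid) adc_perf / adc_low else NA_real_,
    valid = valid,
    negative_perf = adc_perf < 0,
    b_cut = b_cut, b_max = b_max, method = method
  ), class = "spf_components")
}

#' @export
print.spf_components <- function(x, ...) {
  cat(sprintf(
    "SPF components (b_cut = %g, b_max = %g, %s):\n", x$b_cut, x$b_max,
    x$method))
  cat(sprintf("  ADC_0_%g    = %.4g x10^-3 mm^2/s\n", x$b_cut,
              1e3 * x$ADC_0_200))
  cat(sprintf("  ADC_%g_%g = %.4g x10^-3 mm^2/s\n", x$b_cut, x$b_max,
              1e3 * x$ADC_200_1000))
  cat(sprintf("  ADC_perf   = %.4g x10^-3 mm^2/s\n", 1e3 * x$ADC_perf))
  cat(sprintf("  SPF        = %.2f%%\n", 100 * x$SPF))
  invisible(x)
}

#' Conventional clinical ADC (b = 0 and 1000)
#'
#' [two_point_adc()] applied to the (0, 1000) pair — the routine clinical
#' ADC, which is perfusion-inflated above the tissue diffusion coefficient
#' whenever `f > 0`.
#'
#' @param series a [dwi_series] whose scheme contains 0 and `b_high`.
#' @param b_high top b-value, default 1000 s/mm^2.
#' @return ADC in mm^2/s.
#' @export
conventional_adc <- function(series, b_high = 1000) {
  b <- series$scheme$b_values
  s <- series$signals
  i0 <- which(abs(b) < 1e-9)
  ih <- which(abs(b - b_high) < 1e-9)
  if (length(i0) != 1L) stop("scheme is missing required b-value 0 s/mm^2")
  if (length(ih) != 1L)
    stop(sprintf("scheme is missing required b-value %g s/mm^2", b_high))
  two_point_adc(s[i0], s[ih], 0, b_high)
}

# Residual sum of squares of the IVIM model against a measured series.
ivim_sse <- function(f, D, D_star, S0, b, s) {
  m <- S0 * (f * exp(-b * D_star) + (1 - f) * exp(-b * D))
  sum((m - s)^2)
}

#' Segmented (optionally refined) IVIM biexponential fit
#'
#' Three-stage segmented estimate: (1) `D` and the high-b intercept by
#' unweighted least squares on log-signal for `b >= b_cut`; (2)
#' `f = 1 - intercept / S(0)`; (3) `D_star` by bounded one-dimensional
#' least squares on the full curve with `f`, `D`, `S0` fixed. With
#' `refine = TRUE` (the default) a full bounded nonlinear least-squares
#' refinement over `(f, D, D_star, S0)` is run from the segmented
#' solution; the segmented pass alone is available via `refine = FALSE`.
#' Parameter bounds: `0 <= f <= 0.7`, `1e-5 <= D <= 4e-3`,
#' `D < D_star <= 0.5` mm^2/s.
#'
#' @param series a [dwi_series] with at least 3 b-values below `b_cut` and
#'   3 at or above it, including b = 0; all signals positive.
#' @param b_cut segmentation cutoff, s/mm^2.
#' @param refine run full nonlinear refinement (default TRUE).
#' @return An object of class `ivim_fit`: `f`, `D`, `D_star`, `S0`,
#'   `residual` (residual norm), `converged`, and `flags` (character
#'   vector, e.g. `"no_perfusion"`, `"D_at_bound"`).
#' @export
fit_ivim <- function(series, b_cut = 200, refine = TRUE) {
  b <- series$scheme$b_values
  s <- series$signals
  if (any(s <= 0)) stop("signals must be positive; mask this voxel")
  hi <- b >= b_cut
  if (sum(hi) < 3L || sum(!hi) < 3L)
    stop("need at least 3 b-values on each side of b_cut")
  i0 <- which(abs(b) < 1e-9)
  if (length(i0) != 1L) stop("scheme must contain b = 0")
  bounds <- list(f = c(0, 0.7), D = c(1e-5, 4e-3), D_star_max = 0.5)
  flags <- character(0)

  # (1) log-linear high-b fit
  co <- stats::coef(stats::lm(log(s[hi]) ~ b[hi]))
  D <- min(max(-unname(co[2]), bounds$D[1]), bounds$D[2])
  if (D <= bounds$D[1] || D >= bounds$D[2]) flags <- c(flags, "D_at_bound")
  intercept <- exp(unname(co[1]))

  # (2) perfusion fraction from the intercept deficit
  S0 <- s[i0]
  f <- min(max(1 - intercept / S0, 0), bounds$f[2])

  # (3) 1-D bounded search for D*
  if (f > 1e-6) {
    lo <- max(D * 1.0001, 1e-4)
    opt <- stats::optimize(function(ds) ivim_sse(f, D, ds, S0, b, s),
                           interval = c(lo, bounds$D_star_max))
    D_star <- opt$minimum
  } else {
    f <- 0
    D_star <- min(10 * D, bounds$D_star_max)  # placeholder, flagged
    flags <- c(flags, "no_perfusion")
  }

  converged <- TRUE
  if (refine) {
    # parameterize delta = D* - D so the box keeps D* > D
    obj <- function(th) ivim_sse(th[1], th[2], th[2] + th[3], th[4], b, s)
    fit <- stats::nlminb(
      start = c(f, D, max(D_star - D, 1e-5), S0), objective = obj,
      lower = c(0, bounds$D[1], 1e-6, 1e-12),
      upper = c(bounds$f[2], bounds$D[2], bounds$D_star_max, Inf),
      control = list(iter.max = 500, eval.max = 1000))
    if (fit$convergence != 0 && fit$objective > ivim_sse(f, D, D_star, S0, b, s)) {
      flags <- c(flags, "refine_not_converged")
      converged <- FALSE
    } else {
      f <- fit$par[1]; D <- fit$par[2]
      D_star <- fit$par[2] + fit$par[3]; S0 <- fit$par[4]
      if (f <= 1e-6 && !("no_perfusion" %in% flags))
        flags <- c(flags, "no_perfusion")
    }
  }
  structure(list(f = f, D = D, D_star = D_star, S0 = S0,
                 residual = sqrt(ivim_sse(f, D, D_star, S0, b, s)),
                 converged = converged, flags = flags, b_cut = b_cut,
                 refined = refine),
            class = "ivim_fit")
}

#' @export
print.ivim_fit <- function(x, ...) {
  cat(sprintf(
    "IVIM fit (%s): f = %.4g, D = %.4g, D* = %.4g mm^2/s, S0 = %.4g\n",
    if (x$refined) "segmented + refined" else "segmented",
    x$f, x$D, x$D_star, x$S0))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

# Exhaustive grid-search least-squares IVIM oracle. S0 is profiled out
# analytically (the model is linear in S0). Used only in tests as the
# independent reference for the fitter; chunked over f to bound memory.
ivim_grid_oracle <- function(series, n_grid = 200,
                             f_range = c(0, 0.7), D_range = c(1e-5, 4e-3),
                             D_star_max = 0.5) {
  b <- series$scheme$b_values
  s <- series$signals
  fs <- seq(f_range[1], f_range[2], length.out = n_grid)
  Ds <- seq(D_range[1], D_range[2], length.out = n_grid)
  DSs <- seq(D_range[1], D_star_max, length.out = n_grid)
  ED <- exp(-outer(b, Ds))       # nb x nD
  EDS <- exp(-outer(b, DSs))     # nb x nDS
  best <- list(sse = Inf)
  ss <- sum(s^2)
  for (fi in seq_along(fs)) {
    f <- fs[fi]
    # model shape m = f*EDS + (1-f)*ED for every (D, D*) pair;
    # sse(S0) minimized at S0 = <s,m>/<m,m>; min sse = ss - <s,m>^2/<m,m>.
    # Cross terms built without materializing nb x nD x nDS.
    A <- (1 - f) * ED               # nb x nD
    B <- f * EDS                    # nb x nDS
    sA <- as.numeric(t(A) %*% s)    # nD
    sB <- as.numeric(t(B) %*% s)    # nDS
    AA <- colSums(A * A)            # nD
    BB <- colSums(B * B)            # nDS
    AB <- t(A) %*% B                # nD x nDS
    num <- outer(sA, sB, "+")^2
    den <- outer(AA, BB, "+") + 2 * AB
    sse <- ss - num / den
    i <- arrayInd(which.min(sse), dim(sse))
    if (sse[i] < best$sse) {
      best <- list(sse = sse[i[1], i[2]], f = f, D = Ds[i[1]],
                   D_star = DSs[i[2]],
                   steps = c(f = diff(f_range) / (n_grid - 1),
                             D = diff(D_range) / (n_grid - 1),
                             D_star = (D_star_max - D_range[1]) / (n_grid - 1)))
    }
  }
  best
}

#' Parametric map container
#'
#' A scalar value per voxel on a 3D grid with a validity mask and voxel
#' size. Values must be finite wherever the mask is TRUE; masked voxels
#' are stored as `NA` and serialized as NaN.
#'
#' @param values 3D numeric array.
#' @param mask logical array matching `values`.
#' @param voxel_size length-3 voxel dimensions, mm.
#' @param parameter_name label (e.g. `"SPF"`).
#' @param meta named list of provenance (method, b_cut, scheme, ...).
#' @return An object of class `parametric_map`.
#' @export
parametric_map <- function(values, mask = NULL, voxel_size = c(1, 1, 1),
                           parameter_name = "value", meta = list()) {
  values <- as.array(values)
  if (length(dim(values)) == 2L) dim(values) <- c(dim(values), 1L)
  if (length(dim(values)) != 3L) stop("values must form a 3D grid")
  if (is.null(mask)) mask <- is.finite(values)
  mask <- as.array(mask)
  if (length(dim(mask)) == 2L) dim(mask) <- c(dim(mask), 1L)
  if (!identical(as.integer(dim(mask)), as.integer(dim(values))))
    stop("mask dimensions must match values")
  mask <- array(as.logical(mask), dim(values))
  if (any(!is.finite(values[mask])))
    stop("values must be finite wherever mask is TRUE")
  values[!mask] <- NA_real_
  structure(list(values = values, mask = mask,
                 voxel_size = as.numeric(voxel_size),
                 parameter_name = parameter_name, meta = meta),
            class = "parametric_map")
}

#' @export
print.parametric_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("parametric map '%s': %dx%dx%d, %d valid voxels\n",
              x$parameter_name, d[1], d[2], d[3], sum(x$mask)))
  invisible(x)
}

#' Voxelwise DWI fitting over a 4D volume
#'
#' Applies [compute_spf()], [fit_ivim()] or [conventional_adc()] to every
#' in-mask voxel of a 4D `(x, y, z, b)` volume. Voxels with any
#' non-positive signal, or failed fits, are masked out rather than floored.
#'
#' @param volume 4D numeric array `(x, y, z, b)`.
#' @param scheme a [bvalue_scheme]; its length must equal `dim(volume)[4]`.
#' @param mask optional 3D logical array of voxels to fit (default: all).
#' @param method `"spf"`, `"ivim"` or `"adc"`.
#' @param b_cut,b_max cutoff and top b-values, s/mm^2.
#' @param voxel_size voxel dimensions, mm.
#' @param ... passed to the per-voxel fitter (e.g. `refine` for ivim,
#'   `method` is consumed here).
#' @return A named list of [parametric_map] objects: `SPF`, `ADC_0_200`,
#'   `ADC_200_1000`, `ADC_perf` for spf; `f`, `D`, `D_star` for ivim;
#'   `ADC_0_1000` for adc. Map `meta` records method, b_cut and scheme.
#' @export
fit_volume <- function(volume, scheme, mask = NULL,
                       method = c("spf", "ivim", "adc"),
                       b_cut = 200, b_max = 1000, voxel_size = c(1, 1, 1),
                       ...) {
  method <- match.arg(method)
  if (!inherits(scheme, "bvalue_scheme")) scheme <- bvalue_scheme(scheme)
  d <- dim(volume)
  if (length(d) != 4L)
    stop("volume must be 4D (x, y, z, b)")
  if (d[4] != length(scheme$b_values))
    stop(sprintf("4th dimension (%d) does not match scheme length (%d)",
                 d[4], length(scheme$b_values)))
  sp <- d[1:3]
  if (is.null(mask)) mask <- array(TRUE, sp)
  mask <- array(as.logical(mask), dim = dim(as.array(mask)))
  if (length(dim(mask)) == 2L) dim(mask) <- c(dim(mask), 1L)
  if (!identical(dim(mask), as.integer(sp)) &&
      !identical(dim(mask), sp))
    stop("mask dimensions do not match the spatial grid")

  names_for <- switch(method,
    spf = c("SPF", "ADC_0_200", "ADC_200_1000", "ADC_perf"),
    ivim = c("f", "D", "D_star"),
    adc = "ADC_0_1000")
  vals <- lapply(names_for, function(nm) array(NA_real_, sp))
  names(vals) <- names_for
  ok <- array(FALSE, sp)

  idx <- which(mask)
  nvox <- prod(sp)
  for (v in idx) {
    sig <- volume[v + (seq_len(d[4]) - 1L) * nvox]
    if (any(!is.finite(sig)) || any(sig <= 0)) next
    ser <- dwi_series(scheme, sig)
    res <- tryCatch(switch(method,
      spf = {
        cs <- compute_spf(ser, b_cut = b_cut, b_max = b_max)
        if (!cs$valid) NULL else
          c(SPF = cs$SPF, ADC_0_200 = cs$ADC_0_200,
            ADC_200_1000 = cs$ADC_200_1000, ADC_perf = cs$ADC_perf)
      },
      ivim = {
        ft <- fit_ivim(ser, b_cut = b_cut, ...)
        if (!ft$converged) NULL else
          c(f = ft$f, D = ft$D, D_star = ft$D_star)
      },
      adc = c(ADC_0_1000 = conventional_adc(ser, b_high = b_max))
    ), error = function(e) NULL)
    if (is.null(res)) next
    for (nm in names_for) vals[[nm]][v] <- res[[nm]]
    ok[v] <- TRUE
  }
  meta <- list(method = method, b_cut = b_cut, b_max = b_max,
               scheme = scheme$b_values)
  lapply(stats::setNames(names_for, names_for), function(nm)
    parametric_map(vals[[nm]], mask = ok & is.finite(vals[[nm]]),
                   voxel_size = voxel_size, parameter_name = nm,
                   meta = meta))
}
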