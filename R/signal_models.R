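# Closed-form forward models for DWI and DCE signals. These are the ground
# truth every fitter and simulator in the package is tested against.

#' Diffusion b-value scheme
#'
#' An ordered set of diffusion weightings (s/mm^2) defining a DWI
#' acquisition. Values must be non-negative, strictly increasing, and at
#' least two.
#'
#' @param b_values numeric vector of b-values, s/mm^2.
#' @return An object of class `bvalue_scheme`.
#' @seealso [default_bvalue_scheme()]
#' @export
bvalue_scheme <- function(b_values) {
  b <- as.numeric(b_values)
  if (length(b) < 2L)
    stop("a b-value scheme needs at least two b-values")
  if (any(!is.finite(b)) || any(b < 0))
    stop("b-values must be finite and non-negative")
  if (any(diff(b) <= 0))
    stop("b-values must be strictly increasing")
  structure(list(b_values = b), class = "bvalue_scheme")
}

#' Default 10-b-value acquisition scheme
#'
#' The multi-b-value scheme used throughout: 0, 20, 50, 80, 150, 200, 300,
#' 500, 800, 1000 s/mm^2. Five b-values lie at or below the 200 s/mm^2
#' perfusion/diffusion cutoff and five at or above it.
#'
#' @return A `bvalue_scheme`.
#' @export
default_bvalue_scheme <- function() {
  bvalue_scheme(c(0, 20, 50, 80, 150, 200, 300, 500, 800, 1000))
}

#' @export
print.bvalue_scheme <- function(x, ...) {
  cat("b-value scheme (s/mm^2):", paste(x$b_values, collapse = ", "), "\n")
  invisible(x)
}

#' IVIM perfusion-diffusion parameters
#'
#' The biexponential intravoxel incoherent motion triple: perfusion
#' fraction `f` (dimensionless), tissue diffusion coefficient `D` (mm^2/s)
#' and pseudodiffusion coefficient `D_star` (mm^2/s). Invariants: `0 <= f <
#' 1`, `D > 0`, `D_star > D`.
#'
#' @param f perfusion fraction in `[0, 1)`.
#' @param D diffusion coefficient, mm^2/s.
#' @param D_star pseudodiffusion coefficient, mm^2/s; must exceed `D`.
#' @return An object of class `ivim_params`.
#' @export
ivim_params <- function(f, D, D_star) {
  if (!is.finite(f) || f < 0 || f >= 1)
    stop("invalid IVIM parameters: f must satisfy 0 <= f < 1")
  if (!is.finite(D) || D <= 0)
    stop("invalid IVIM parameters: D must be positive")
  if (!is.finite(D_star) || D_star <= D)
    stop("invalid IVIM parameters: D_star must exceed D")
  structure(list(f = f, D = D, D_star = D_star), class = "ivim_params")
}

#' @export
print.ivim_params <- function(x, ...) {
  cat(sprintf("IVIM parameters: f = %.4g, D = %.4g mm^2/s, D* = %.4g mm^2/s\n",
              x$f, x$D, x$D_star))
  invisible(x)
}

#' Extended Tofts pharmacokinetic parameters
#'
#' `Ktrans` (volume transfer constant, 1/min), `v_e` (extravascular
#' extracellular volume fraction) and `v_p` (plasma volume fraction).
#' Invariants: `Ktrans >= 0`, `0 <= v_e <= 1`, `0 <= v_p <= 1`,
#' `v_e + v_p <= 1`.
#'
#' @param Ktrans volume transfer constant, 1/min.
#' @param v_e extravascular extracellular volume fraction.
#' @param v_p plasma volume fraction.
#' @return An object of class `tofts_params`.
#' @export
tofts_params <- function(Ktrans, v_e, v_p) {
  if (!is.finite(Ktrans) || Ktrans < 0)
    stop("invalid Tofts parameters: Ktrans must be non-negative")
  if (!is.finite(v_e) || v_e < 0 || v_e > 1)
    stop("invalid Tofts parameters: v_e must lie in [0, 1]")
  if (!is.finite(v_p) || v_p < 0 || v_p > 1)
    stop("invalid Tofts parameters: v_p must lie in [0, 1]")
  if (v_e + v_p > 1 + 1e-12)
    stop("invalid Tofts parameters: v_e + v_p must not exceed 1")
  structure(list(Ktrans = Ktrans, v_e = v_e, v_p = v_p),
            class = "tofts_params")
}

#' @export
print.tofts_params <- function(x, ...) {
  cat(sprintf("Tofts parameters: Ktrans = %.4g /min, v_e = %.4g, v_p = %.4g\n",
              x$Ktrans, x$v_e, x$v_p))
  invisible(x)
}

#' Arterial input function
#'
#' A supplied arterial plasma concentration curve: `times` in minutes
#' (strictly increasing, starting at 0) and `Cp` in mM (non-negative, zero
#' before bolus arrival). AIF extraction from images is out of scope; use
#' [population_aif()] or [read_aif()].
#'
#' @param times sample times, min.
#' @param Cp arterial plasma concentration at each time, mM.
#' @return An object of class `aif`.
#' @export
aif <- function(times, Cp) {
  times <- as.numeric(times); Cp <- as.numeric(Cp)
  if (length(times) != length(Cp))
    stop("times and Cp must have the same length")
  if (length(times) < 2L || any(!is.finite(times)) || any(!is.finite(Cp)))
    stop("AIF needs at least two finite samples")
  if (times[1] != 0 || any(diff(times) <= 0))
    stop("AIF times must be strictly increasing and start at 0")
  if (any(Cp < 0))
    stop("AIF concentrations must be non-negative")
  if (Cp[1] != 0)
    warning("AIF does not start at Cp = 0 (expected pre-bolus baseline)")
  structure(list(times = times, Cp = Cp), class = "aif")
}

#' Population arterial input function
#'
#' A documented biexponential bolus: `Cp(t) = 0` for `t < onset` and
#' `Cp(t) = A * (exp(-wash_out * u) - exp(-wash_in * u))` with
#' `u = t - onset` otherwise. `A` is chosen so the curve peaks at `peak`
#' mM. Defaults give a sharp first pass (peak ~33 s post-onset at 5 mM)
#' with a slow washout, sampled every 5 s over 4 min — matching a typical
#' ~4 min DCE acquisition.
#'
#' @param times sample times in minutes; default 4 min at 5 s resolution.
#' @param peak peak plasma concentration, mM.
#' @param wash_in fast (wash-in) rate constant, 1/min.
#' @param wash_out slow (washout) rate constant, 1/min.
#' @param onset bolus arrival time, min.
#' @return An [aif] sampled on `times`.
#' @export
population_aif <- function(times = seq(0, 4, by = 5 / 60), peak = 5,
                           wash_in = 6, wash_out = 0.25, onset = 0.1) {
  if (peak <= 0 || wash_in <= wash_out || wash_out <= 0)
    stop("population AIF requires peak > 0 and wash_in > wash_out > 0")
  shape <- function(u) exp(-wash_out * u) - exp(-wash_in * u)
  u_peak <- log(wash_in / wash_out) / (wash_in - wash_out)
  A <- peak / shape(u_peak)
  u <- pmax(times - onset, 0)
  aif(times, A * shape(u))
}

#' IVIM biexponential signal
#'
#' Forward model `S_b = S0 * (f * exp(-b * D_star) + (1 - f) * exp(-b * D))`.
#' Strictly positive and non-increasing in `b`.
#'
#' @param params an [ivim_params] object.
#' @param b b-value(s), s/mm^2 (vectorized).
#' @param S0 signal at b = 0 (arbitrary units, positive).
#' @return Signal value(s), same length as `b`.
#' @export
ivim_signal <- function(params, b, S0 = 1) {
  if (!inherits(params, "ivim_params"))
    params <- ivim_params(params$f, params$D, params$D_star)
  if (any(!is.finite(b)) || any(b < 0)) stop("b must be non-negative")
  if (!is.finite(S0) || S0 <= 0) stop("S0 must be positive")
  S0 * (params$f * exp(-b * params$D_star) +
          (1 - params$f) * exp(-b * params$D))
}

#' Monoexponential DWI signal
#'
#' `S_b = S0 * exp(-b * ADC)` — the two-point model specialized to
#' `S_low = S0` at `b_low = 0`.
#'
#' @param ADC apparent diffusion coefficient, mm^2/s (non-negative).
#' @param b b-value(s), s/mm^2.
#' @param S0 signal at b = 0.
#' @return Signal value(s).
#' @export
monoexp_signal <- function(ADC, b, S0 = 1) {
  if (any(!is.finite(b)) || any(b < 0)) stop("b must be non-negative")
  if (!is.finite(S0) || S0 <= 0) stop("S0 must be positive")
  if (any(!is.finite(ADC)) || any(ADC < 0)) stop("ADC must be non-negative")
  S0 * exp(-b * ADC)
}

#' SPF in the infinite-pseudodiffusion limit
#'
#' Closed-form value of the simplified perfusion fraction when the
#' perfusion compartment has fully decayed by the cutoff b-value:
#' `SPF = -log(1 - f) / (-log(1 - f) + b_cut * D)`. Used as an analytic
#' oracle for [compute_spf()].
#'
#' @param f IVIM perfusion fraction in `[0, 1)`.
#' @param D diffusion coefficient, mm^2/s.
#' @param b_cut cutoff b-value, s/mm^2.
#' @return SPF fraction.
#' @export
spf_infinite_dstar_limit <- function(f, D, b_cut = 200) {
  if (any(!is.finite(f)) || any(f < 0) || any(f >= 1))
    stop("f must satisfy 0 <= f < 1 (f = 1 hits the log singularity)")
  if (any(D <= 0)) stop("D must be positive")
  if (any(b_cut <= 0)) stop("b_cut must be positive")
  a <- -log(1 - f)
  a / (a + b_cut * D)
}

# Exact convolution of a piecewise-linear input with exp(-k t).
# Recursive update: I(t_i) = I(t_{i-1}) e^{-k h} + closed-form integral of
# the linear segment against the exponential kernel. Exact (to machine
# precision) for inputs that are linear between samples; in particular
# exact for a constant AIF.
exp_conv_linear <- function(times, cp, k) {
  n <- length(times)
  out <- numeric(n)
  if (k <= 0) stop("exp_conv_linear requires k > 0")
  for (i in 2:n) {
    h <- times[i] - times[i - 1]
    kh <- k * h
    if (kh < 1e-8) {            # trapezoid limit, avoids 0/0
      E <- 1 - kh
      w0 <- w1 <- h / 2
    } else {
      E <- exp(-kh)
      a <- (1 - E) / k                 # integral of kernel
      b <- (1 - (1 - E) / kh) / k      # integral of (tau/h) * kernel
      w0 <- a - b
      w1 <- b
    }
    out[i] <- out[i - 1] * E + cp[i - 1] * w0 + cp[i] * w1
  }
  out
}

# Tissue concentration on the AIF's own time grid (optionally resampled to
# a uniform step). Returns a numeric vector aligned with the grid times.
tofts_on_grid <- function(params, aif_obj, resample_dt = NULL) {
  times <- aif_obj$times
  cp <- aif_obj$Cp
  if (!is.null(resample_dt)) {
    tt <- seq(times[1], times[length(times)], by = resample_dt)
    cp <- stats::approx(times, cp, xout = tt)$y
    times <- tt
  }
  ct <- params$v_p * cp
  if (params$Ktrans > 0) {
    if (params$v_e <= 0)
      stop("Ktrans > 0 requires v_e > 0")
    kep <- params$Ktrans / params$v_e
    ct <- ct + params$Ktrans * exp_conv_linear(times, cp, kep)
  }
  list(times = times, Ct = ct)
}

#' Extended Tofts tissue concentration
#'
#' `C_t(t) = v_p * C_p(t) + Ktrans * int_0^t C_p(tau) *
#' exp(-Ktrans (t - tau) / v_e) dtau`, evaluated by exact convolution of
#' the piecewise-linear AIF with the exponential kernel (exact for a
#' constant input; error for smooth inputs is governed by the AIF's
#' linear-interpolation error).
#'
#' @param params a [tofts_params] object.
#' @param aif an [aif] object.
#' @param t evaluation time(s), min; must lie within the AIF time span.
#' @param resample_dt optional uniform resampling step for the quadrature
#'   grid, min (default: the AIF's native grid).
#' @return Tissue concentration(s), mM.
#' @export
tofts_concentration <- function(params, aif, t, resample_dt = NULL) {
  if (!inherits(params, "tofts_params"))
    params <- tofts_params(params$Ktrans, params$v_e, params$v_p)
  span <- range(aif$times)
  if (any(t < span[1] - 1e-12) || any(t > span[2] + 1e-12))
    stop(sprintf("t outside AIF time span [%g, %g] min", span[1], span[2]))
  g <- tofts_on_grid(params, aif, resample_dt)
  stats::approx(g$times, g$Ct, xout = t, rule = 2)$y
}

#' Extended Tofts concentration curve on the AIF grid
#'
#' Convenience wrapper returning a [concentration_curve] sampled at the
#' AIF's time points.
#'
#' @inheritParams tofts_concentration
#' @return A [concentration_curve].
#' @export
tofts_curve <- function(params, aif, resample_dt = NULL) {
  if (!inherits(params, "tofts_params"))
    params <- tofts_params(params$Ktrans, params$v_e, params$v_p)
  g <- tofts_on_grid(params, aif, resample_dt)
  if (!is.null(resample_dt)) {
    ct <- stats::approx(g$times, g$Ct, xout = aif$times, rule = 2)$y
  } else ct <- g$Ct
  concentration_curve(aif$times, ct)
}
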