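#' Monoexponential (ADC) signal model
#'
#' Relative diffusion-weighted signal `S(b)/S0 = exp(-b * adc)`. All model
#' functions in this package work on the normalised signal, so the b = 0
#' intensity is exactly 1.
#'
#' @param b Diffusion weighting(s) in s/mm^2, all >= 0. Vectorised.
#' @param adc Apparent diffusion coefficient in mm^2/s (>= 0; 0 gives the
#'   no-decay limit).
#' @return Relative signal in (0, 1], same length as `b`.
#' @export
#' @examples
#' mono_signal(1000, 2.33e-3)  # ~ exp(-2.33)
mono_signal <- function(b, adc) {
  .check_b(b)
  if (length(adc) != 1L || !is.finite(adc) || adc < 0) {
    stop("`adc` must be a single nonnegative number (mm^2/s)")
  }
  exp(-b * adc)
}

#' Biexponential (IVIM) signal model
#'
#' Relative signal
#' `S(b)/S0 = f * exp(-b * d_fast) + (1 - f) * exp(-b * d_slow)`,
#' the intravoxel incoherent motion decomposition into a perfusion-driven
#' fast pseudo-diffusion compartment (weight `f`) and a slow tissue-water
#' compartment.
#'
#' @param b Diffusion weighting(s) in s/mm^2, all >= 0.
#' @param f Perfusion fraction in `[0, 1]`.
#' @param d_slow True (tissue) diffusion coefficient, mm^2/s, > 0.
#' @param d_fast Pseudo-diffusion coefficient, mm^2/s, > `d_slow`.
#' @return Relative signal in (0, 1].
#' @export
#' @examples
#' biexp_signal(200, f = 0.19, d_slow = 1.65e-3, d_fast = 15.6e-3)
biexp_signal <- function(b, f, d_slow, d_fast) {
  .check_b(b)
  if (length(f) != 1L || !is.finite(f) || f < 0 || f > 1) {
    stop("`f` must be a single number in [0, 1]")
  }
  if (!is.finite(d_slow) || d_slow <= 0) stop("`d_slow` must be > 0 (mm^2/s)")
  if (!is.finite(d_fast) || d_fast <= d_slow) {
    stop("`d_fast` must exceed `d_slow`")
  }
  f * exp(-b * d_fast) + (1 - f) * exp(-b * d_slow)
}

#' Stretched-exponential signal model
#'
#' Relative signal `S(b)/S0 = exp(-(b * ddc)^alpha)`. `ddc` is the
#' distributed diffusion coefficient (mean intravoxel diffusion rate) and
#' `alpha` in (0, 1] the heterogeneity index; `alpha = 1` recovers the
#' monoexponential model with `adc = ddc`, smaller values indicate a broader
#' intravoxel distribution of diffusion rates.
#'
#' @param b Diffusion weighting(s) in s/mm^2, all >= 0.
#' @param ddc Distributed diffusion coefficient, mm^2/s, > 0.
#' @param alpha Heterogeneity index in (0, 1].
#' @return Relative signal in (0, 1].
#' @export
#' @examples
#' stretched_signal(800, ddc = 3.12e-3, alpha = 0.64)
stretched_signal <- function(b, ddc, alpha) {
  .check_b(b)
  if (!is.finite(ddc) || ddc <= 0) stop("`ddc` must be > 0 (mm^2/s)")
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0 || alpha > 1) {
    stop("`alpha` must be in (0, 1]")
  }
  exp(-(b * ddc)^alpha)
}

.check_b <- function(b) {
  if (any(!is.finite(b)) || any(b < 0)) {
    stop("b-values must be finite and nonnegative (s/mm^2)")
  }
  invisible(b)
}
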