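#' Fitting configuration
#'
#' Controls the estimation strategy for all three signal models.
#'
#' `segmented_then_refine` (default) initialises the IVIM fit from a
#' segmented analysis: a log-linear fit restricted to b >= `b_split` gives
#' the slow diffusion coefficient and, through its intercept, the perfusion
#' fraction; the pseudo-diffusion coefficient is then profiled by 1-D
#' minimisation before a full Levenberg-Marquardt refinement of all three
#' parameters. `free` skips the segmented stage and starts from generic
#' renal-tissue values. Both strategies finish with the same deterministic
#' 3 x 3 multistart grid around the initial estimate; the lowest residual
#' sum of squares wins, ties broken by first occurrence, so fitting involves
#' no randomness.
#'
#' @param strategy `"segmented_then_refine"` or `"free"`.
#' @param b_split b-value threshold (s/mm^2) separating the
#'   perfusion-dominated low-b points from the diffusion-dominated high-b
#'   points.
#' @param bounds Named list of parameter bounds in mm^2/s (fractions for `f`
#'   and `alpha`). The non-overlapping `d_slow`/`d_fast` boxes enforce
#'   `d_fast > d_slow` by construction.
#' @param max_iterations Levenberg-Marquardt iteration cap.
#' @param tol Relative cost/step convergence tolerance.
#' @param weighting `"none"` (default, unweighted least squares) or `"nex"`
#'   (weights proportional to the excitation count of each b-value).
#' @param normalize Divide each curve by its b = 0 value before fitting.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(strategy = c("segmented_then_refine", "free"),
                       b_split = 200,
                       bounds = list(
                         adc    = c(0, 10e-3),
                         d_slow = c(0.1e-3, 3.0e-3),
                         d_fast = c(3.0e-3, 100e-3),
                         f      = c(0, 1),
                         ddc    = c(0.1e-3, 5.0e-3),
                         alpha  = c(0.01, 1)
                       ),
                       max_iterations = 500,
                       tol = 1e-10,
                       weighting = c("none", "nex"),
                       normalize = TRUE) {
  strategy <- match.arg(strategy)
  weighting <- match.arg(weighting)
  for (nm in c("adc", "d_slow", "d_fast", "f", "ddc", "alpha")) {
    bb <- bounds[[nm]]
    if (is.null(bb) || length(bb) != 2L || bb[1L] >= bb[2L]) {
      stop(sprintf("`bounds$%s` must be c(lower, upper) with lower < upper", nm))
    }
  }
  if (bounds$d_fast[1L] < bounds$d_slow[2L]) {
    stop("`d_fast` lower bound must be >= `d_slow` upper bound")
  }
  structure(list(strategy = strategy, b_split = b_split, bounds = bounds,
                 max_iterations = max_iterations, tol = tol,
                 weighting = weighting, normalize = normalize),
            class = "fit_config")
}

.fit_result <- function(model, params, rss, converged, n_points_used,
                        flags = character(0), rss_init = NA_real_) {
  structure(list(model = model, params = params, rss = rss,
                 converged = converged, n_points_used = n_points_used,
                 flags = flags, rss_init = rss_init),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result:", x$model, "> ",
      paste(names(x$params), signif(unlist(x$params), 4),
            sep = "=", collapse = ", "),
      sprintf(" | rss=%.3g, converged=%s", x$rss, x$converged),
      if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]"),
      "\n", sep = "")
  invisible(x)
}

.curve_data <- function(curve, cfg) {
  if (!inherits(curve, "signal_curve")) stop("`curve` must be a signal_curve")
  y <- curve$signal
  if (cfg$normalize) y <- y / y[1L]
  list(b = curve$scheme$b_values, y = y,
       w = if (cfg$weighting == "nex") curve$scheme$nex
           else rep(1, length(y)))
}

#' Fit the monoexponential model
#'
#' Ordinary least squares on the log-linear form `log S = log S0 - b * adc`
#' over all b-values; points with non-positive signal are excluded with a
#' warning. A non-decaying curve is clamped to `adc = 0` and flagged
#' `degenerate`.
#'
#' @param curve A [signal_curve()].
#' @param cfg A [fit_config()].
#' @return A `fit_result` with `params$adc` (mm^2/s) and `params$s0`.
#' @export
#' @examples
#' sch <- renal_bscheme()
#' cv <- signal_curve(sch, mono_signal(sch$b_values, 2.33e-3))
#' fit_mono(cv)$params$adc
fit_mono <- function(curve, cfg = fit_config()) {
  d <- .curve_data(curve, cfg)
  usable <- d$y > 0
  if (any(!usable)) {
    warning(sprintf("%d non-positive signal value(s) excluded from log-linear fit",
                    sum(!usable)))
  }
  b <- d$b[usable]; y <- d$y[usable]; w <- d$w[usable]
  if (length(unique(b)) < 2L) {
    stop("monoexponential fit needs >= 2 distinct b-values with positive signal")
  }
  co <- stats::coef(stats::lm(log(y) ~ b, weights = w))
  adc <- max(-unname(co[2L]), 0)
  s0 <- exp(unname(co[1L]))
  rss <- sum(w * (s0 * exp(-b * adc) - y)^2)
  flags <- if (adc < 1e-8) "degenerate" else character(0)
  .fit_result("mono", list(adc = adc, s0 = s0), rss, TRUE, length(b), flags)
}

.lm_refine <- function(par, lower, upper, resid_fn, cfg) {
  ctl <- minpack.lm::nls.lm.control(maxiter = cfg$max_iterations,
                                    ftol = cfg$tol, ptol = cfg$tol)
  fit <- minpack.lm::nls.lm(par = par, lower = lower, upper = upper,
                            fn = resid_fn, control = ctl)
  list(par = fit$par, rss = sum(fit$fvec^2), info = fit$info)
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Fit the biexponential (IVIM) model
#'
#' Levenberg-Marquardt estimation of `(f, d_slow, d_fast)` within bounds,
#' initialised per the configured strategy (see [fit_config()]). Internally
#' the diffusion coefficients are scaled to 1e-3 mm^2/s so that all three
#' parameters are O(1) for the optimiser. A fit ending with `f` or `d_fast`
#' pinned at a bound is flagged `weakly_identified` (typical for an
#' effectively monoexponential curve).
#'
#' @inheritParams fit_mono
#' @return A `fit_result` with `params$f`, `params$d_slow`, `params$d_fast`
#'   (mm^2/s); `rss_init` records the residual sum of squares of the
#'   segmented initial estimate.
#' @export
#' @examples
#' sch <- renal_bscheme()
#' cv <- signal_curve(sch, biexp_signal(sch$b_values, 0.19, 1.65e-3, 15.6e-3))
#' fit_biexp(cv)$params
fit_biexp <- function(curve, cfg = fit_config()) {
  d <- .curve_data(curve, cfg)
  b <- d$b; y <- d$y; w <- d$w
  if (length(unique(b)) < 4L ||
      !any(b < cfg$b_split) || sum(b >= cfg$b_split) < 2L) {
    stop("biexponential fit needs >= 4 distinct b-values spanning `b_split`")
  }
  lo <- c(cfg$bounds$f[1L], cfg$bounds$d_slow[1L] * 1e3,
          cfg$bounds$d_fast[1L] * 1e3)
  hi <- c(cfg$bounds$f[2L], cfg$bounds$d_slow[2L] * 1e3,
          cfg$bounds$d_fast[2L] * 1e3)
  model <- function(th) {
    th[1L] * exp(-b * th[3L] * 1e-3) + (1 - th[1L]) * exp(-b * th[2L] * 1e-3)
  }
  resid_fn <- function(th) sqrt(w) * (model(th) - y)
  rss_of <- function(th) sum(w * (model(th) - y)^2)

  if (cfg$strategy == "segmented_then_refine") {
    sel <- b >= cfg$b_split & y > 0
    co <- stats::coef(stats::lm(log(y[sel]) ~ b[sel], weights = w[sel]))
    ds0 <- .clamp(-unname(co[2L]) * 1e3, lo[2L], hi[2L])
    amp <- .clamp(exp(unname(co[1L])), 1e-6, 1)
    f0 <- .clamp(1 - amp, 0.01, 0.8)
    prof <- stats::optimize(function(df_ms) rss_of(c(f0, ds0, df_ms)),
                            interval = c(lo[3L], hi[3L]))
    df0 <- prof$minimum
  } else {
    f0 <- 0.25; ds0 <- 1.5; df0 <- 15
  }
  init <- c(f0, ds0, df0)
  rss_init <- rss_of(init)

  starts <- expand.grid(ff = c(1, 0.5, 1.5), dff = c(1, 0.5, 2),
                        KEEP.OUT.ATTRS = FALSE)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    par <- c(.clamp(f0 * starts$ff[i], lo[1L], hi[1L]),
             ds0,
             .clamp(df0 * starts$dff[i], lo[3L], hi[3L]))
    res <- .lm_refine(par, lo, hi, resid_fn, cfg)
    if (is.null(best) || res$rss < best$rss) best <- res
  }

  th <- best$par
  flags <- character(0)
  eps <- 1e-3
  if (th[1L] <= lo[1L] + eps || th[1L] >= hi[1L] - eps ||
      th[3L] <= lo[3L] + eps * (hi[3L] - lo[3L]) ||
      th[3L] >= hi[3L] - eps * (hi[3L] - lo[3L])) {
    flags <- c(flags, "weakly_identified")
  }
  .fit_result("biexp",
              list(f = th[1L], d_slow = th[2L] * 1e-3, d_fast = th[3L] * 1e-3),
              best$rss, best$info %in% 1:4, length(b), flags, rss_init)
}

#' Fit the stretched-exponential model
#'
#' Levenberg-Marquardt estimation of `(ddc, alpha)` within bounds,
#' initialised from the monoexponential ADC with the same deterministic
#' 3 x 3 multistart grid as the IVIM fit.
#'
#' @inheritParams fit_mono
#' @return A `fit_result` with `params$ddc` (mm^2/s) and `params$alpha`.
#' @export
#' @examples
#' sch <- renal_bscheme()
#' cv <- signal_curve(sch, stretched_signal(sch$b_values, 2.28e-3, 0.55))
#' fit_stretched(cv)$params
fit_stretched <- function(curve, cfg = fit_config()) {
  d <- .curve_data(curve, cfg)
  b <- d$b; y <- d$y; w <- d$w
  if (length(unique(b)) < 3L || b[1L] != 0) {
    stop("stretched-exponential fit needs >= 3 distinct b-values including b = 0")
  }
  lo <- c(cfg$bounds$ddc[1L] * 1e3, cfg$bounds$alpha[1L])
  hi <- c(cfg$bounds$ddc[2L] * 1e3, cfg$bounds$alpha[2L])
  model <- function(th) exp(-(b * th[1L] * 1e-3)^th[2L])
  resid_fn <- function(th) sqrt(w) * (model(th) - y)
  rss_of <- function(th) sum(w * (model(th) - y)^2)

  ddc0 <- .clamp(suppressWarnings(fit_mono(curve, cfg))$params$adc * 1e3,
                 lo[1L], hi[1L])
  init <- c(ddc0, 0.8)
  rss_init <- rss_of(init)

  starts <- expand.grid(dd = c(1, 0.7, 1.3), a0 = c(0.8, 0.55, 0.95),
                        KEEP.OUT.ATTRS = FALSE)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    par <- c(.clamp(ddc0 * starts$dd[i], lo[1L], hi[1L]), starts$a0[i])
    res <- .lm_refine(par, lo, hi, resid_fn, cfg)
    if (is.null(best) || res$rss < best$rss) best <- res
  }

  th <- best$par
  flags <- character(0)
  if (th[1L] <= lo[1L] * 1.001 || th[1L] >= hi[1L] * 0.999 ||
      th[2L] <= lo[2L] + 1e-3) {
    flags <- c(flags, "weakly_identified")
  }
  .fit_result("stretched", list(ddc = th[1L] * 1e-3, alpha = th[2L]),
              best$rss, best$info %in% 1:4, length(b), flags, rss_init)
}

#' Fit all three signal models to one curve
#'
#' Runs [fit_mono()], [fit_biexp()] and [fit_stretched()] on the same curve.
#' Errors in one model are captured and reported as a failed `fit_result`
#' rather than aborting the other fits. Deterministic given the
#' configuration.
#'
#' @inheritParams fit_mono
#' @return Named list with elements `mono`, `biexp`, `stretched`.
#' @export
fit_all_models <- function(curve, cfg = fit_config()) {
  one <- function(fun, model, pars) {
    tryCatch(fun(curve, cfg), error = function(e) {
      .fit_result(model, pars, NA_real_, FALSE, 0L,
                  flags = paste0("error: ", conditionMessage(e)))
    })
  }
  list(
    mono = one(fit_mono, "mono", list(adc = NA_real_, s0 = NA_real_)),
    biexp = one(fit_biexp, "biexp",
                list(f = NA_real_, d_slow = NA_real_, d_fast = NA_real_)),
    stretched = one(fit_stretched, "stretched",
                    list(ddc = NA_real_, alpha = NA_real_))
  )
}
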