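# Group-level anchors for the synthetic cohort. Diffusion entries are
# (median, q25, q75) in 1e-3 mm^2/s; `f` is (mean, sd) as a fraction;
# eGFR is (median, q25, q75) in mL/min/1.73 m^2; age is (mean, sd) years.
.anchors <- list(
  params = list(
    control = list(adc = c(2.33, 2.25, 2.40), d_slow = c(1.80, 1.70, 1.93),
                   d_fast = c(31.40, 30.00, 32.25), f = c(0.34, 0.04),
                   ddc = c(3.30, 3.20, 3.35), alpha = c(0.75, 0.72, 0.79)),
    high_egfr = list(adc = c(2.40, 2.31, 2.51), d_slow = c(1.73, 1.70, 1.80),
                     d_fast = c(26.75, 25.00, 28.75), f = c(0.28, 0.02),
                     ddc = c(3.23, 3.01, 3.38), alpha = c(0.63, 0.61, 0.66)),
    low_egfr = list(adc = c(2.03, 1.80, 2.18), d_slow = c(1.63, 1.50, 1.72),
                    d_fast = c(14.50, 10.58, 16.69), f = c(0.17, 0.06),
                    ddc = c(2.24, 2.13, 2.41), alpha = c(0.54, 0.51, 0.56))
  ),
  egfr = list(control = c(122.39, 98.45, 128.84),
              high_egfr = c(116.63, 101.63, 150.55),
              low_egfr = c(62.51, 53.03, 78.66)),
  age = list(control = c(26.95, 10.29), high_egfr = c(28.85, 11.33),
             low_egfr = c(35.29, 13.19)),
  male_frac = c(control = 7 / 19, high_egfr = 17 / 33, low_egfr = 20 / 28),
  # Binomial success probabilities for the pathology components at median
  # latent severity, chosen so the component medians match the observed
  # group medians (glomerular /12, tubulointerstitial /9, vasculopathy /6).
  pathology = list(
    high_egfr = c(glomerular = 0.20, tubulointerstitial = 0.25,
                  vasculopathy = 0.08),
    low_egfr = c(glomerular = 5 / 12, tubulointerstitial = 5 / 9,
                 vasculopathy = 1 / 3)
  ),
  pathology_denom = c(glomerular = 12L, tubulointerstitial = 9L,
                      vasculopathy = 6L)
)

.param_names <- function() c("adc", "d_slow", "d_fast", "f", "ddc", "alpha")

#' Synthetic cohort configuration
#'
#' Defaults reproduce the study conditions: 19 healthy controls, 33 CKD
#' patients with preserved eGFR (>= 90 mL/min/1.73 m^2) and 28 with reduced
#' eGFR; cortical parameter distributions anchored group-wise to the
#' published medians/IQRs; 6-9 cortical ROIs of 35-50 mm^2 per subject; and
#' two readers whose measurements differ by independent per-ROI placement
#' jitter.
#'
#' @param n_control,n_high,n_low Group sizes (all >= 1).
#' @param snr Signal-to-noise ratio at b = 0 for the ROI-averaged curves
#'   (> 0, may be `Inf`). The default 80 reflects that each curve is the mean
#'   of a multi-voxel cortical ROI, not a single voxel.
#' @param rois_per_subject Integer range (min, max) of ROIs per subject.
#' @param roi_area Range of ROI areas in mm^2 (recorded, not used in the
#'   signal model).
#' @param roi_scatter Log-scale SD of the biological ROI-to-ROI parameter
#'   scatter around each subject's cortical value.
#' @param reader_noise Log-scale SD of the per-ROI, per-reader measurement
#'   jitter (placement/partial-volume variability). 0 makes both readers
#'   identical.
#' @param severity_coupling Rank-correlation strength (0-1) between the
#'   latent per-subject severity and the diffusion parameters / eGFR within
#'   each group.
#' @param severity_score_slope Logistic slope linking latent severity to the
#'   pathology-score component probabilities.
#' @param scheme The [bvalue_scheme()] used for ROI signal curves.
#' @param seed Integer seed; mandatory for any stochastic call.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_control = 19L, n_high = 33L, n_low = 28L,
                          snr = 80, rois_per_subject = c(6L, 9L),
                          roi_area = c(35, 50), roi_scatter = 0.04,
                          reader_noise = 0.12, severity_coupling = 0.5,
                          severity_score_slope = 0.5,
                          scheme = renal_bscheme(), seed = NULL) {
  cfg <- structure(list(
    n_control = as.integer(n_control), n_high = as.integer(n_high),
    n_low = as.integer(n_low), snr = snr,
    rois_per_subject = as.integer(rois_per_subject), roi_area = roi_area,
    roi_scatter = roi_scatter, reader_noise = reader_noise,
    severity_coupling = severity_coupling,
    severity_score_slope = severity_score_slope,
    scheme = scheme, seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "cohort_config")
  .validate_cohort_config(cfg, need_seed = FALSE)
  cfg
}

.validate_cohort_config <- function(cfg, need_seed = TRUE) {
  bad <- character(0)
  if (any(c(cfg$n_control, cfg$n_high, cfg$n_low) < 1L)) {
    bad <- c(bad, "group sizes must be >= 1")
  }
  if (!is.numeric(cfg$snr) || is.na(cfg$snr) || cfg$snr <= 0) {
    bad <- c(bad, "snr must be > 0")
  }
  if (length(cfg$rois_per_subject) != 2L ||
      cfg$rois_per_subject[1L] > cfg$rois_per_subject[2L] ||
      cfg$rois_per_subject[1L] < 1L) {
    bad <- c(bad, "rois_per_subject must be a valid (min, max) range")
  }
  if (cfg$roi_scatter < 0 || cfg$reader_noise < 0) {
    bad <- c(bad, "roi_scatter and reader_noise must be >= 0")
  }
  if (cfg$severity_coupling < 0 || cfg$severity_coupling > 1) {
    bad <- c(bad, "severity_coupling must be in [0, 1]")
  }
  if (!inherits(cfg$scheme, "bvalue_scheme")) {
    bad <- c(bad, "scheme must be a bvalue_scheme")
  }
  if (need_seed && is.null(cfg$seed)) bad <- c(bad, "seed is required")
  if (length(bad)) {
    stop("invalid cohort configuration: ", paste(bad, collapse = "; "))
  }
  invisible(cfg)
}

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Stratified (Latin-hypercube style) uniforms: one draw per probability
# stratum, in random subject order. Keeps small-group sample quantiles
# faithful to the target marginal.
.u_strat <- function(n) (sample.int(n) - stats::runif(n)) / n

# Quantile functions matched to the published summaries.
.q_lognorm <- function(u, med, q1, q3) {
  stats::qlnorm(u, log(med), log(q3 / q1) / (2 * stats::qnorm(0.75)))
}

.q_truncnorm <- function(u, mean, sd, lo, hi) {
  pl <- stats::pnorm(lo, mean, sd)
  ph <- stats::pnorm(hi, mean, sd)
  stats::qnorm(pl + u * (ph - pl), mean, sd)
}

.q_param <- function(u, name, group) {
  a <- .anchors$params[[group]][[name]]
  if (name == "f") {
    .q_truncnorm(u, a[1L], a[2L], 0, 1)
  } else if (name == "alpha") {
    pmin(.q_lognorm(u, a[1L], a[2L], a[3L]), 0.999)
  } else {
    .q_lognorm(u, a[1L], a[2L], a[3L]) * 1e-3
  }
}

# Rank-couple stratified marginal draws to the latent severity: subjects
# with higher (lambda-blended) severity rank receive the smaller parameter
# values, preserving the marginal exactly (Iman-Conover style).
.couple_desc <- function(values, severity, lambda) {
  n <- length(values)
  w <- -lambda * severity + sqrt(1 - lambda^2) * stats::rnorm(n)
  sort(values)[rank(w, ties.method = "first")]
}

#' Draw per-subject cortical parameters for one study group
#'
#' Samples the six cortical diffusion parameters from the group-anchored
#' marginals (log-normal matched to median/IQR; truncated normal for the
#' perfusion fraction, which is summarised as mean +/- SD) using stratified
#' quantiles, and rank-couples them to the latent severity so that sicker
#' subjects have lower diffusion parameters.
#'
#' @param group `"control"`, `"high_egfr"` or `"low_egfr"`.
#' @param n Number of subjects.
#' @param cfg A [cohort_config()].
#' @param severity Optional numeric latent severity (length `n`); drawn
#'   standard normal if omitted.
#' @param seed Optional seed applied locally.
#' @return Data frame with columns `adc`, `d_slow`, `d_fast`, `f`, `ddc`,
#'   `alpha` (diffusion coefficients in mm^2/s) and attribute `severity`.
#' @export
draw_group_params <- function(group, n, cfg = cohort_config(),
                              severity = NULL, seed = NULL) {
  group <- match.arg(group, group_levels())
  .with_seed(seed, {
    if (is.null(severity)) severity <- stats::rnorm(n)
    stopifnot(length(severity) == n)
    out <- lapply(.param_names(), function(p) {
      v <- .q_param(.u_strat(n), p, group)
      .couple_desc(v, severity, cfg$severity_coupling)
    })
    names(out) <- .param_names()
    out <- as.data.frame(out)
    attr(out, "severity") <- severity
    out
  })
}

#' Simulate a noisy multi-b signal curve
#'
#' Evaluates the chosen forward model and adds Rician magnitude noise:
#' `S_noisy = sqrt((S + sigma_b * e1)^2 + (sigma_b * e2)^2)` with
#' `sigma_b = 1 / (snr * sqrt(nex_b))`, i.e. the per-b noise level is reduced
#' by the square root of the number of averaged excitations. With
#' `snr = Inf` the forward model is returned exactly.
#'
#' @param params Named list/row with the fields the model needs (`f`,
#'   `d_slow`, `d_fast` for `"biexp"`; `adc` for `"mono"`; `ddc`, `alpha` for
#'   `"stretched"`), diffusion coefficients in mm^2/s.
#' @param scheme A [bvalue_scheme()].
#' @param snr Signal-to-noise ratio at b = 0 (> 0 or `Inf`).
#' @param model Forward model name.
#' @param seed Optional seed applied locally.
#' @return A [signal_curve()] (not renormalised, so the noise at b = 0 is
#'   preserved).
#' @export
make_signal <- function(params, scheme = renal_bscheme(), snr = Inf,
                        model = c("biexp", "mono", "stretched"),
                        seed = NULL) {
  model <- match.arg(model)
  if (!is.numeric(snr) || is.na(snr) || snr <= 0) stop("`snr` must be > 0")
  b <- scheme$b_values
  s <- switch(model,
    mono = mono_signal(b, params$adc),
    biexp = biexp_signal(b, params$f, params$d_slow, params$d_fast),
    stretched = stretched_signal(b, params$ddc, params$alpha)
  )
  if (is.finite(snr)) {
    s <- .with_seed(seed, {
      sigma <- 1 / (snr * sqrt(scheme$nex))
      e1 <- stats::rnorm(length(b))
      e2 <- stats::rnorm(length(b))
      sqrt((s + sigma * e1)^2 + (sigma * e2)^2)
    })
  }
  signal_curve(scheme, s, normalize = FALSE)
}

#' Simulate semi-quantitative pathology scores
#'
#' Each component score is binomial over its range with a logistic link to
#' the latent severity, so scores increase with severity and the reduced-eGFR
#' group stochastically dominates the preserved-eGFR group component-wise.
#' Controls are not biopsied and calling this for them is an error.
#'
#' @param severity Latent severity values (standard-normal scale).
#' @param group `"high_egfr"` or `"low_egfr"`.
#' @param cfg A [cohort_config()] (supplies the severity-score slope).
#' @param seed Optional seed applied locally.
#' @return A [pathology_score()] data frame, one row per severity value.
#' @export
make_pathology <- function(severity, group, cfg = cohort_config(),
                           seed = NULL) {
  group <- match.arg(group, c("high_egfr", "low_egfr"))
  .with_seed(seed, {
    n <- length(severity)
    p0 <- .anchors$pathology[[group]]
    dn <- .anchors$pathology_denom
    comp <- lapply(names(dn), function(k) {
      p <- stats::plogis(stats::qlogis(p0[[k]]) +
                           cfg$severity_score_slope * severity)
      stats::rbinom(n, dn[[k]], p)
    })
    pathology_score(comp[[1L]], comp[[2L]], comp[[3L]])
  })
}

#' Simulate the two-reader ROI measurement protocol
#'
#' Each reader measures every ROI of a subject on the parameter maps; the
#' measurement equals the ROI's true parameter value times an independent
#' per-ROI, per-reader log-normal jitter (placement variability), and the
#' reader's reported value is the mean across that reader's ROIs. With
#' `reader_noise = 0` both readers agree exactly.
#'
#' @param roi_params Data frame of per-ROI true parameters for one subject
#'   (columns `adc` ... `alpha`).
#' @param cfg A [cohort_config()].
#' @param seed Optional seed applied locally.
#' @return Data frame with two rows (`reader` 1 and 2) and one column per
#'   parameter.
#' @export
simulate_readers <- function(roi_params, cfg = cohort_config(), seed = NULL) {
  stopifnot(is.data.frame(roi_params), nrow(roi_params) >= 1L)
  pn <- .param_names()
  .with_seed(seed, {
    m <- as.matrix(roi_params[, pn])
    one <- function() {
      jit <- exp(cfg$reader_noise *
                   matrix(stats::rnorm(length(m)), nrow(m), ncol(m)))
      colMeans(m * jit)
    }
    out <- rbind(one(), one())
    data.frame(reader = 1:2, as.data.frame(out))
  })
}

.draw_egfr <- function(group, n, severity, lambda) {
  a <- .anchors$egfr[[group]]
  med <- a[1L]; q1 <- a[2L]; q3 <- a[3L]
  sdlog <- log(q3 / q1) / (2 * stats::qnorm(0.75))
  # truncation consistent with the grouping rule
  rng <- switch(group,
    control = c(90, Inf), high_egfr = c(90, Inf), low_egfr = c(15, 90))
  pl <- stats::plnorm(rng[1L], log(med), sdlog)
  ph <- stats::plnorm(rng[2L], log(med), sdlog)
  u <- pl + .u_strat(n) * (ph - pl)
  v <- stats::qlnorm(u, log(med), sdlog)
  .couple_desc(v, severity, lambda)
}

#' Generate a complete synthetic study cohort
#'
#' Produces subjects (demographics, serum creatinine consistent with the
#' assigned eGFR through the MDRD formula, true cortical parameters), per-ROI
#' noisy signal curves, pathology scores for the patients, and two simulated
#' reader measurement tables. Fully determined by `cfg$seed`.
#'
#' @param cfg A [cohort_config()] with a non-`NULL` seed.
#' @return A list of class `ivim_cohort` with data frames `subjects`,
#'   `pathology`, `readers`, `roi_params`, `signals` and the `config`.
#'   Diffusion coefficients are stored in mm^2/s.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(seed = 1))
#' table(coh$subjects$group)
generate_cohort <- function(cfg = cohort_config(seed = 1L)) {
  .validate_cohort_config(cfg, need_seed = TRUE)
  set.seed(cfg$seed)
  sizes <- c(control = cfg$n_control, high_egfr = cfg$n_high,
             low_egfr = cfg$n_low)
  lam <- cfg$severity_coupling
  b_cols <- paste0("b", cfg$scheme$b_values)

  subjects <- list(); pathology <- list(); readers <- list()
  roi_params <- list(); signals <- list()
  sid0 <- 0L
  for (g in names(sizes)) {
    n <- sizes[[g]]
    sev <- stats::rnorm(n)
    pars <- draw_group_params(g, n, cfg, severity = sev)
    egfr <- .draw_egfr(g, n, sev, lam)
    aa <- .anchors$age[[g]]
    age <- round(.q_truncnorm(.u_strat(n), aa[1L], aa[2L], 18, 70))
    n_male <- round(.anchors$male_frac[[g]] * n)
    sex <- sample(rep(c("male", "female"), c(n_male, n - n_male)))
    k <- ifelse(sex == "female", 0.742, 1)
    scr_mgdl <- (egfr / (186 * age^-0.203 * k))^(-1 / 1.154)
    scr <- scr_mgdl * 88.4
    ids <- sprintf("S%03d", sid0 + seq_len(n))
    sid0 <- sid0 + n

    n_roi <- sample(seq(cfg$rois_per_subject[1L], cfg$rois_per_subject[2L]),
                    n, replace = TRUE)
    if (g != "control") {
      pathology[[g]] <- cbind(subject_id = ids,
                              make_pathology(sev, g, cfg))
    }
    for (i in seq_len(n)) {
      nr <- n_roi[i]
      scat <- exp(cfg$roi_scatter *
                    matrix(stats::rnorm(nr * 6L), nr, 6L))
      rp <- as.data.frame(
        matrix(rep(unlist(pars[i, ]), each = nr), nr, 6L) * scat)
      names(rp) <- .param_names()
      rp$alpha <- pmin(rp$alpha, 0.999)
      area <- stats::runif(nr, cfg$roi_area[1L], cfg$roi_area[2L])
      sig <- t(vapply(seq_len(nr), function(r) {
        make_signal(as.list(rp[r, ]), cfg$scheme, cfg$snr, "biexp")$signal
      }, numeric(length(b_cols))))
      colnames(sig) <- b_cols
      roi_params[[ids[i]]] <- cbind(
        data.frame(subject_id = ids[i], roi_id = seq_len(nr),
                   roi_area_mm2 = area), rp)
      signals[[ids[i]]] <- cbind(
        data.frame(subject_id = ids[i], roi_id = seq_len(nr)),
        as.data.frame(sig))
      rd <- simulate_readers(rp, cfg)
      readers[[ids[i]]] <- cbind(data.frame(subject_id = ids[i]), rd)
    }
    subjects[[g]] <- cbind(
      data.frame(subject_id = ids, group = g, age = age, sex = sex,
                 scr_umol = scr, egfr = egfr, severity = sev,
                 n_roi = n_roi),
      pars)
  }

  subjects <- do.call(rbind, c(subjects, make.row.names = FALSE))
  subjects$group <- factor(subjects$group, levels = group_levels())
  # internal consistency with the clinical rules
  stopifnot(all(abs(egfr_mdrd(subjects$scr_umol, subjects$age,
                              subjects$sex) - subjects$egfr) < 1e-8))
  stopifnot(identical(
    as.character(assign_group(subjects$egfr,
                              subjects$group != "control")),
    as.character(subjects$group)))

  structure(list(
    subjects = subjects,
    pathology = do.call(rbind, c(unname(pathology), make.row.names = FALSE)),
    readers = do.call(rbind, c(unname(readers), make.row.names = FALSE)),
    roi_params = do.call(rbind, c(unname(roi_params), make.row.names = FALSE)),
    signals = do.call(rbind, c(unname(signals), make.row.names = FALSE)),
    config = cfg
  ), class = "ivim_cohort")
}

#' @export
print.ivim_cohort <- function(x, ...) {
  cat("<ivim_cohort> ", nrow(x$subjects), " subjects (",
      paste(table(x$subjects$group), collapse = "/"), "), ",
      nrow(x$signals), " ROI curves, seed ", x$config$seed, "\n", sep = "")
  invisible(x)
}
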