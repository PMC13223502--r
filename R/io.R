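# On-disk convention: diffusion coefficients are written in 1e-3 mm^2/s
# (the reporting unit); f and alpha are fractions. read_* converts back to
# the internal mm^2/s representation.

.to_disk_units <- function(df) {
  for (p in .param_names()) {
    if (p %in% names(df)) df[[p]] <- df[[p]] * .display_scale(p)
  }
  df
}

.from_disk_units <- function(df) {
  for (p in .param_names()) {
    if (p %in% names(df)) df[[p]] <- df[[p]] / .display_scale(p)
  }
  df
}

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Write / read cohort tables
#'
#' `write_cohort()` writes `subjects.csv`, `signals.csv`, `pathology.csv`,
#' `readers.csv`, `roi_params.csv` and a `config.json` echo into `dir`;
#' `read_cohort()` reconstructs the `ivim_cohort`. Writing the same cohort
#' twice produces byte-identical files. Diffusion coefficients are stored in
#' 1e-3 mm^2/s on disk.
#'
#' @param cohort An `ivim_cohort`.
#' @param dir Output directory (created if needed).
#' @return `write_cohort()` the directory, invisibly; `read_cohort()` an
#'   `ivim_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ivim_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .write_csv(.to_disk_units(cohort$subjects), file.path(dir, "subjects.csv"))
  .write_csv(cohort$signals, file.path(dir, "signals.csv"))
  .write_csv(cohort$pathology, file.path(dir, "pathology.csv"))
  .write_csv(.to_disk_units(cohort$readers), file.path(dir, "readers.csv"))
  .write_csv(.to_disk_units(cohort$roi_params),
             file.path(dir, "roi_params.csv"))
  cfg <- cohort$config
  cfg_out <- c(unclass(cfg)[setdiff(names(cfg), "scheme")],
               list(b_values = cfg$scheme$b_values, nex = cfg$scheme$nex,
                    units = "diffusion coefficients in 1e-3 mm^2/s on disk"))
  jsonlite::write_json(cfg_out, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  cfgj <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  cfg <- cohort_config(
    n_control = cfgj$n_control, n_high = cfgj$n_high, n_low = cfgj$n_low,
    snr = if (is.character(cfgj$snr)) Inf else cfgj$snr,
    rois_per_subject = cfgj$rois_per_subject, roi_area = cfgj$roi_area,
    roi_scatter = cfgj$roi_scatter, reader_noise = cfgj$reader_noise,
    severity_coupling = cfgj$severity_coupling,
    severity_score_slope = cfgj$severity_score_slope,
    scheme = bvalue_scheme(cfgj$b_values, cfgj$nex), seed = cfgj$seed)
  rd <- function(f) utils::read.csv(file.path(dir, f))
  subjects <- .from_disk_units(rd("subjects.csv"))
  subjects$group <- factor(subjects$group, levels = group_levels())
  structure(list(
    subjects = subjects,
    pathology = rd("pathology.csv"),
    readers = .from_disk_units(rd("readers.csv")),
    roi_params = .from_disk_units(rd("roi_params.csv")),
    signals = rd("signals.csv"),
    config = cfg
  ), class = "ivim_cohort")
}

#' Read a signals table and validate its schema
#'
#' Expected columns: `subject_id`, `roi_id`, then one column per b-value
#' named `b0`, `b10`, ... in strictly ascending order starting at `b0`.
#' If the b-values equal the 13-point renal protocol, its NEX pattern is
#' attached; otherwise NEX defaults to 1.
#'
#' @param x Path to a CSV file, or a data frame already in that shape.
#' @return List with `data` (the table) and `scheme` (a [bvalue_scheme()]).
#' @export
read_signals <- function(x) {
  df <- if (is.character(x)) {
    if (!file.exists(x)) stop("signals file not found: ", x)
    utils::read.csv(x)
  } else as.data.frame(x)
  if (nrow(df) == 0L) stop("signals table is empty")
  need <- c("subject_id", "roi_id")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("signals schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  bcols <- grep("^b[0-9]+$", names(df), value = TRUE)
  if (length(bcols) < 2L) stop("signals schema error: no b-value columns")
  bvals <- as.numeric(sub("^b", "", bcols))
  if (is.unsorted(bvals, strictly = TRUE) || bvals[1L] != 0) {
    stop("signals schema error: b-value columns must be b0, ... ascending ",
         "(offending columns: ", paste(bcols, collapse = ", "), ")")
  }
  ref <- renal_bscheme()
  scheme <- if (identical(bvals, ref$b_values)) ref else bvalue_scheme(bvals)
  list(data = df[, c(need, bcols)], scheme = scheme)
}

.log_line <- function(stage, ...) {
  message(sprintf("[renivim:%s] %s", stage, sprintf(...)))
}

.config_hash <- function(cfg) {
  txt <- paste(deparse(unclass(cfg)), collapse = "")
  sum(utf8ToInt(txt) * (seq_len(nchar(txt)) %% 97 + 1)) %% 1e9
}

#' Pipeline stage: generate a cohort to disk
#'
#' @param out Output directory.
#' @param seed Integer seed (required).
#' @param config A [cohort_config()]; its seed is overridden by `seed`.
#' @return The output directory, invisibly.
#' @export
cmd_generate <- function(out, seed, config = cohort_config()) {
  if (missing(seed) || is.null(seed)) stop("`seed` is required for generate")
  config$seed <- as.integer(seed)
  .validate_cohort_config(config)
  cohort <- generate_cohort(config)
  write_cohort(cohort, out)
  .log_line("generate", "seed=%d config_hash=%d subjects=%d roi_curves=%d",
            config$seed, .config_hash(config), nrow(cohort$subjects),
            nrow(cohort$signals))
  invisible(out)
}

#' Pipeline stage: fit all models to every curve of a signals table
#'
#' One output row per ROI curve with the six fitted parameters (diffusion
#' coefficients in 1e-3 mm^2/s in the CSV), residual sums of squares and
#' convergence flags. Deterministic given the configuration.
#'
#' @param signals Path to a signals CSV or an equivalent data frame.
#' @param out Optional path for the fitted-parameters CSV.
#' @param cfg A [fit_config()].
#' @return Data frame of fitted parameters (internal mm^2/s units),
#'   invisibly if `out` is given.
#' @export
cmd_fit <- function(signals, out = NULL, cfg = fit_config()) {
  sg <- read_signals(signals)
  df <- sg$data
  bcols <- paste0("b", sg$scheme$b_values)
  rows <- lapply(seq_len(nrow(df)), function(i) {
    curve <- signal_curve(sg$scheme, as.numeric(df[i, bcols]),
                          normalize = FALSE)
    ft <- fit_all_models(curve, cfg)
    data.frame(
      subject_id = df$subject_id[i], roi_id = df$roi_id[i],
      adc = ft$mono$params$adc,
      d_slow = ft$biexp$params$d_slow, d_fast = ft$biexp$params$d_fast,
      f = ft$biexp$params$f,
      ddc = ft$stretched$params$ddc, alpha = ft$stretched$params$alpha,
      rss_mono = ft$mono$rss, rss_biexp = ft$biexp$rss,
      rss_stretched = ft$stretched$rss,
      converged_mono = ft$mono$converged,
      converged_biexp = ft$biexp$converged,
      converged_stretched = ft$stretched$converged,
      flags_biexp = paste(ft$biexp$flags, collapse = ";"),
      flags_stretched = paste(ft$stretched$flags, collapse = ";")
    )
  })
  fitted <- do.call(rbind, rows)
  .log_line("fit", "curves=%d converged_biexp=%d/%d", nrow(fitted),
            sum(fitted$converged_biexp), nrow(fitted))
  if (!is.null(out)) {
    .write_csv(.to_disk_units(fitted), out)
    return(invisible(fitted))
  }
  fitted
}

#' Pipeline stage: run the statistical analysis and write the report
#'
#' Builds the [build_study_report()] tables from the cohort (single-reader
#' measurements; both readers for the ICC table) and writes them as CSVs
#' plus a JSON results bundle. If a fitted-parameters table is supplied, its
#' subject ids are checked against the cohort and a fit-quality table
#' (fitted vs generated biexponential parameters, per-subject ROI means) is
#' added.
#'
#' @param cohort_dir Directory written by [cmd_generate()], or an
#'   `ivim_cohort`.
#' @param fitted Optional fitted-parameters data frame or CSV path from
#'   [cmd_fit()].
#' @param out Output directory for the report files.
#' @param reader Reader whose measurements feed the analyses.
#' @return The `study_report`, invisibly.
#' @export
cmd_analyze <- function(cohort_dir, fitted = NULL, out, reader = 1L) {
  cohort <- if (inherits(cohort_dir, "ivim_cohort")) cohort_dir
            else read_cohort(cohort_dir)
  rep_ <- build_study_report(cohort, reader = reader)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  .write_csv(rep_$demographics, file.path(out, "table1_demographics.csv"))
  .write_csv(rep_$params_by_group, file.path(out, "table2_params_by_group.csv"))
  .write_csv(rep_$pathology_by_group,
             file.path(out, "table3_pathology_by_group.csv"))
  .write_csv(rep_$correlations, file.path(out, "table4_correlations.csv"))
  .write_csv(rep_$roc, file.path(out, "table5_roc.csv"))
  .write_csv(rep_$roc_points, file.path(out, "roc_points.csv"))
  .write_csv(rep_$icc, file.path(out, "icc.csv"))

  results <- list(sex_p = rep_$sex_p, meta = rep_$meta)
  if (!is.null(fitted)) {
    if (is.character(fitted)) {
      fitted <- .from_disk_units(utils::read.csv(fitted))
    }
    orphans <- setdiff(fitted$subject_id, cohort$subjects$subject_id)
    if (length(orphans)) {
      stop("fitted table contains unknown subject ids: ",
           paste(orphans, collapse = ", "))
    }
    agg <- stats::aggregate(fitted[, c("f", "d_slow", "d_fast")],
                            list(subject_id = fitted$subject_id), mean)
    mrg <- merge(agg, cohort$subjects[, c("subject_id", "f", "d_slow",
                                          "d_fast")],
                 by = "subject_id", suffixes = c("_fitted", "_true"))
    fq <- data.frame(
      parameter = c("f", "d_slow", "d_fast"),
      median_abs_rel_err = vapply(c("f", "d_slow", "d_fast"), function(p) {
        stats::median(abs(mrg[[paste0(p, "_fitted")]] /
                            mrg[[paste0(p, "_true")]] - 1))
      }, numeric(1)),
      convergence_rate = mean(fitted$converged_biexp)
    )
    .write_csv(fq, file.path(out, "fit_quality.csv"))
    results$fit_quality <- fq
  }
  jsonlite::write_json(results, file.path(out, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .log_line("analyze", "report written to %s", out)
  invisible(rep_)
}

#' One-shot reproducible pipeline run
#'
#' Runs generate -> fit -> analyze with the default study configuration into
#' `out` and writes `summary.txt` with the run's qualitative pattern checks:
#' whether the group medians of the five bi/stretched-exponential parameters
#' decrease from controls through preserved- to reduced-eGFR patients,
#' whether the perfusion-sensitive parameters correlate positively with eGFR
#' and negatively with pathology scores, and whether the control-vs-CKD AUC
#' of alpha, f and the pseudo-diffusion coefficient each exceed those of DDC
#' and the slow diffusion coefficient. Byte-identical outputs for a given
#' seed.
#'
#' @param seed Integer seed.
#' @param out Output directory.
#' @return List with the pattern checks, invisibly.
#' @export
cmd_reproduce <- function(seed, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  cdir <- file.path(out, "cohort")
  cmd_generate(cdir, seed = seed)
  fitted <- cmd_fit(file.path(cdir, "signals.csv"),
                    out = file.path(out, "fitted.csv"))
  rep_ <- cmd_analyze(cdir, fitted = fitted, out = file.path(out, "report"))

  cohort <- read_cohort(cdir)
  subj <- cohort$subjects
  med <- function(p) tapply(subj[[p]], subj$group, stats::median)
  decreasing <- vapply(c("d_slow", "d_fast", "f", "ddc", "alpha"),
                       function(p) all(diff(med(p)) < 0), logical(1))
  cors <- rep_$correlations
  sign_ok <- vapply(c("d_fast", "f", "alpha"), function(p) {
    e <- cors$rho[cors$variable == p & cors$target == "egfr"]
    s <- cors$rho[cors$variable == p & cors$target != "egfr"]
    e > 0 && all(s < 0)
  }, logical(1))
  roc <- rep_$roc[rep_$roc$contrast == "control_vs_ckd", ]
  auc <- function(p) roc$auc[roc$marker == p]
  auc_ordered <- all(c(auc("alpha"), auc("f"), auc("d_fast")) >
                       max(auc("ddc"), auc("d_slow")))

  lines <- c(
    sprintf("seed: %d", as.integer(seed)),
    sprintf("group medians decreasing (control > high eGFR > low eGFR): %s",
            paste(sprintf("%s=%s", names(decreasing), decreasing),
                  collapse = " ")),
    sprintf("correlation signs (+eGFR, -scores) for d_fast/f/alpha: %s",
            paste(sprintf("%s=%s", names(sign_ok), sign_ok),
                  collapse = " ")),
    sprintf("AUC ordering alpha,f,d_fast > ddc,d_slow (control vs CKD): %s",
            auc_ordered)
  )
  writeLines(lines, file.path(out, "summary.txt"))
  .log_line("reproduce", "done: %s", out)
  invisible(list(decreasing = decreasing, correlation_signs = sign_ok,
                 auc_ordered = auc_ordered))
}
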