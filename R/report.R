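# Display helpers: diffusion coefficients are reported in 1e-3 mm^2/s to
# match the field's table convention; f and alpha stay as fractions.
.display_scale <- function(param) {
  if (param %in% c("f", "alpha")) 1 else 1e3
}

.summarise <- function(x, normal) {
  if (normal) {
    sprintf("%.2f ± %.2f", mean(x), stats::sd(x))
  } else {
    q <- stats::quantile(x, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
    sprintf("%.2f (%.2f, %.2f)", q[1L], q[2L], q[3L])
  }
}

# One variable compared across the three groups: Shapiro screen per group
# decides between one-way ANOVA (+ pairwise t, Bonferroni) and
# Kruskal-Wallis (+ Dunn, Bonferroni). Pairwise columns follow the table
# convention: p1 = control vs high, p2 = control vs low, p3 = high vs low.
.compare_groups <- function(values, groups, name, scale = 1) {
  groups <- droplevels(as.factor(groups))
  v <- values * scale
  normal <- all(vapply(levels(groups), function(g) {
    normality_screen(v[groups == g])$class == "normal"
  }, logical(1)))
  if (normal) {
    fit <- stats::aov(v ~ groups)
    omni <- summary(fit)[[1L]][["Pr(>F)"]][1L]
    pt <- stats::pairwise.t.test(v, groups, p.adjust.method = "bonferroni",
                                 pool.sd = TRUE)$p.value
    lev <- levels(groups)
    pw <- c(pt[lev[2L], lev[1L]], pt[lev[3L], lev[1L]], pt[lev[3L], lev[2L]])
    branch <- "anova"
  } else {
    kw <- kruskal_wallis_posthoc(v, groups)
    omni <- kw$p
    pw <- kw$pairwise$p_adj
    branch <- "kruskal_wallis"
  }
  sm <- vapply(levels(groups), function(g) .summarise(v[groups == g], normal),
               character(1))
  data.frame(variable = name, branch = branch,
             control = sm[1L], high_egfr = sm[2L], low_egfr = sm[3L],
             p_omnibus = omni, p1_control_high = pw[1L],
             p2_control_low = pw[2L], p3_high_low = pw[3L])
}

#' Build the full study analysis report
#'
#' Runs the complete statistical pipeline on a synthetic (or equivalently
#' structured) cohort and returns result tables mirroring the study layout:
#' demographics, cortical parameters by group, pathology scores by group,
#' Spearman correlations of parameters with eGFR and pathology scores, ROC
#' diagnostic performance (control vs all CKD and control vs preserved-eGFR
#' CKD), and the two-reader ICC table. Group comparisons, correlations and
#' ROC analyses use a single reader's measurements (`reader`); the ICC table
#' uses both.
#'
#' @param cohort An `ivim_cohort` from [generate_cohort()] (or
#'   [read_cohort()]).
#' @param reader Which reader's measurements feed the analyses (1 or 2).
#' @param conf Confidence level for intervals.
#' @return A list of class `study_report` with data frames `demographics`,
#'   `params_by_group`, `pathology_by_group`, `correlations`, `roc`, `icc`,
#'   and `meta` (family sizes and settings). Diffusion coefficients appear
#'   in 1e-3 mm^2/s.
#' @export
build_study_report <- function(cohort, reader = 1L, conf = 0.95) {
  stopifnot(inherits(cohort, "ivim_cohort"))
  subj <- cohort$subjects
  meas <- cohort$readers[cohort$readers$reader == reader, ]
  meas <- meas[match(subj$subject_id, meas$subject_id), ]
  stopifnot(!anyNA(meas$subject_id))
  pn <- .param_names()
  grp <- subj$group

  ## demographics (age, sex, creatinine, eGFR)
  demo <- rbind(
    .compare_groups(subj$age, grp, "age_years"),
    .compare_groups(subj$scr_umol, grp, "creatinine_umol_L"),
    .compare_groups(subj$egfr, grp, "egfr_ml_min_1.73m2")
  )
  sex_tab <- table(subj$sex, grp)
  sex_p <- chi_square_counts(sex_tab)$p

  ## parameters by group
  params_tab <- do.call(rbind, lapply(pn, function(p) {
    .compare_groups(meas[[p]], grp, p, .display_scale(p))
  }))

  ## pathology scores: high vs low eGFR (Mann-Whitney)
  pat <- merge(cohort$pathology, subj[, c("subject_id", "group")],
               by = "subject_id")
  path_tab <- do.call(rbind, lapply(
    c("glomerular", "tubulointerstitial", "vasculopathy", "total"),
    function(sc) {
      hi <- pat[[sc]][pat$group == "high_egfr"]
      lo <- pat[[sc]][pat$group == "low_egfr"]
      mw <- mann_whitney(hi, lo)
      data.frame(score = sc,
                 high_egfr = .summarise(hi, FALSE),
                 low_egfr = .summarise(lo, FALSE),
                 U = mw$U, p = mw$p)
    }))

  ## correlations: params vs eGFR (all subjects) and vs scores (patients)
  pdat <- meas[, pn]
  for (p in pn) pdat[[p]] <- pdat[[p]] * .display_scale(p)
  cor_egfr <- spearman_bonferroni(pdat, subj$egfr)
  cor_egfr$target <- "egfr"
  is_pat <- grp != "control"
  pat_ord <- cohort$pathology[
    match(subj$subject_id[is_pat], cohort$pathology$subject_id), ]
  cor_scores <- do.call(rbind, lapply(
    c("glomerular", "tubulointerstitial", "vasculopathy", "total"),
    function(sc) {
      out <- spearman_bonferroni(pdat[is_pat, ], pat_ord[[sc]])
      out$target <- sc
      out
    }))
  correlations <- rbind(cor_egfr, cor_scores)
  correlations <- correlations[, c("variable", "target", "rho", "p_raw",
                                   "p_adj", "m", "n")]

  ## ROC: control vs CKD, and control vs high-eGFR CKD
  roc_rows <- list(); roc_curves <- list()
  for (contrast in c("control_vs_ckd", "control_vs_high")) {
    keep <- if (contrast == "control_vs_ckd") rep(TRUE, nrow(subj)) else
      grp %in% c("control", "high_egfr")
    cases <- grp[keep] != "control"
    for (p in pn) {
      rr <- roc_analysis(pdat[[p]][keep], cases, direction = "auto",
                         conf = conf, adjust_m = length(pn))
      roc_rows[[paste(contrast, p)]] <- data.frame(
        contrast = contrast, marker = p, auc = rr$auc,
        ci_low = rr$ci[1L], ci_high = rr$ci[2L], youden = rr$youden,
        rule = rr$rule, threshold = rr$threshold,
        sensitivity = rr$sensitivity, specificity = rr$specificity,
        p_adj = rr$p_adj)
      cv <- rr$curve
      cv$contrast <- contrast; cv$marker <- p
      roc_curves[[paste(contrast, p)]] <- cv
    }
  }

  ## two-reader ICC per parameter
  icc_tab <- do.call(rbind, lapply(pn, function(p) {
    wide <- cbind(
      cohort$readers[[p]][cohort$readers$reader == 1L],
      cohort$readers[[p]][cohort$readers$reader == 2L])
    ic <- icc_two_reader(wide, conf)
    data.frame(parameter = p, icc = ic$icc,
               ci_low = ic$ci[1L], ci_high = ic$ci[2L])
  }))

  structure(list(
    demographics = demo,
    sex_counts = as.data.frame.matrix(sex_tab),
    sex_p = sex_p,
    params_by_group = params_tab,
    pathology_by_group = path_tab,
    correlations = correlations,
    roc = do.call(rbind, c(unname(roc_rows), make.row.names = FALSE)),
    roc_points = do.call(rbind, c(unname(roc_curves),
                                  make.row.names = FALSE)),
    icc = icc_tab,
    meta = list(reader = reader, conf = conf,
                bonferroni_family_correlations = length(pn),
                bonferroni_family_roc = length(pn))
  ), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat("Parameters by group (1e-3 mm^2/s; f, alpha as fractions):\n")
  print(x$params_by_group, row.names = FALSE, digits = 3)
  cat("\nROC (control vs CKD):\n")
  print(x$roc[x$roc$contrast == "control_vs_ckd",
              c("marker", "auc", "youden", "threshold", "p_adj")],
        row.names = FALSE, digits = 3)
  invisible(x)
}
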