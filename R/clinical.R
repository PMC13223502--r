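#' MDRD estimated glomerular filtration rate
#'
#' ID-MS-traceable MDRD equation
#' `eGFR = 186 * SCr^-1.154 * age^-0.203 * (0.742 if female)` with serum
#' creatinine entered in mg/dL. Laboratory creatinine is supplied here in
#' umol/L (the reporting convention of Chinese laboratories) and converted
#' internally by dividing by 88.4; only with this conversion does the formula
#' return values on the expected mL/min/1.73 m^2 scale for physiologic
#' creatinine levels.
#'
#' @param scr Serum creatinine in umol/L, > 0. Vectorised.
#' @param age Age in years, > 0. Vectorised (recycled against `scr`).
#' @param sex `"male"` or `"female"` (vectorised).
#' @return eGFR in mL/min/1.73 m^2.
#' @export
#' @examples
#' egfr_mdrd(88.4, 50, "male")   # 186 * 50^-0.203
#' egfr_mdrd(88.4, 50, "female") # 0.742 x the male value
egfr_mdrd <- function(scr, age, sex) {
  if (any(!is.finite(scr)) || any(scr <= 0)) stop("`scr` must be > 0 (umol/L)")
  if (any(!is.finite(age)) || any(age <= 0)) stop("`age` must be > 0 (years)")
  sex <- match.arg(as.character(sex), c("male", "female"), several.ok = TRUE)
  scr_mgdl <- scr / 88.4
  k <- ifelse(sex == "female", 0.742, 1)
  186 * scr_mgdl^-1.154 * age^-0.203 * k
}

#' Assign the eGFR-based study group
#'
#' CKD patients are split at eGFR 90 mL/min/1.73 m^2: `>= 90` is the
#' preserved ("high eGFR") group, `< 90` the reduced ("low eGFR") group.
#' Healthy non-patients are labelled `control` regardless of their eGFR.
#'
#' @param egfr eGFR in mL/min/1.73 m^2, >= 0. Vectorised.
#' @param is_patient Logical; `TRUE` for CKD patients.
#' @return Factor with levels `control`, `high_egfr`, `low_egfr`.
#' @export
#' @examples
#' assign_group(c(90, 62.51, 150), c(TRUE, TRUE, FALSE))
assign_group <- function(egfr, is_patient) {
  if (any(!is.finite(egfr)) || any(egfr < 0)) stop("`egfr` must be >= 0")
  is_patient <- as.logical(is_patient)
  if (any(is.na(is_patient))) stop("`is_patient` must be TRUE/FALSE")
  out <- ifelse(!is_patient, "control",
                ifelse(egfr >= 90, "high_egfr", "low_egfr"))
  factor(out, levels = group_levels())
}

#' @rdname assign_group
#' @export
group_levels <- function() c("control", "high_egfr", "low_egfr")

#' Semi-quantitative renal pathology score
#'
#' Katafuchi-style component scores: glomerular 0-12, tubulointerstitial 0-9,
#' vasculopathy 0-6; the total (0-27) is their sum. Only the component ranges
#' and the summation are modelled, not the sub-item rubric.
#'
#' @param glomerular,tubulointerstitial,vasculopathy Integer component scores
#'   (vectorised).
#' @return `pathology_score()` returns a data frame with the three components
#'   and `total`; `total_pathology()` returns just the total.
#' @export
#' @examples
#' total_pathology(2, 6, 2)  # 10
pathology_score <- function(glomerular, tubulointerstitial, vasculopathy) {
  .check_score(glomerular, 12, "glomerular")
  .check_score(tubulointerstitial, 9, "tubulointerstitial")
  .check_score(vasculopathy, 6, "vasculopathy")
  data.frame(
    glomerular = as.integer(glomerular),
    tubulointerstitial = as.integer(tubulointerstitial),
    vasculopathy = as.integer(vasculopathy),
    total = as.integer(glomerular + tubulointerstitial + vasculopathy)
  )
}

#' @rdname pathology_score
#' @export
total_pathology <- function(glomerular, tubulointerstitial, vasculopathy) {
  pathology_score(glomerular, tubulointerstitial, vasculopathy)$total
}

.check_score <- function(x, max, name) {
  if (any(!is.finite(x)) || any(x != round(x)) || any(x < 0) || any(x > max)) {
    stop(sprintf("`%s` scores must be integers in 0-%d", name, max))
  }
  invisible(x)
}
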