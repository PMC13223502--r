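test_that("group parameter draws match their anchored marginals at large n", {
  cfg <- cohort_config()
  ctl <- draw_group_params("control", 1e5, cfg, seed = 11)
  expect_lt(abs(median(ctl$f) - 0.34), 0.01)
  low <- draw_group_params("low_egfr", 1e5, cfg, seed = 12)
  expect_lt(abs(median(low$ddc) - 2.24e-3), 0.05e-3)
  expect_lt(abs(median(low$d_fast) - 14.5e-3), 0.3e-3)
  # distributional ordering control > high > low for the five parameters
  high <- draw_group_params("high_egfr", 1e5, cfg, seed = 13)
  for (p in c("d_slow", "d_fast", "f", "ddc", "alpha")) {
    expect_gt(median(ctl[[p]]), median(high[[p]]))
    expect_gt(median(high[[p]]), median(low[[p]]))
  }
  # seeded reproducibility
  expect_identical(draw_group_params("control", 50, cfg, seed = 5),
                   draw_group_params("control", 50, cfg, seed = 5))
  expect_error(draw_group_params("nephron", 10, cfg), "arg")
})

test_that("simulated signals obey the Rician noise model", {
  sch <- renal_bscheme()
  tp <- fig3_params$biexp
  # infinite SNR returns the forward model exactly
  cv <- make_signal(tp, sch, snr = Inf, model = "biexp")
  expect_identical(cv$signal,
                   biexp_signal(sch$b_values, tp$f, tp$d_slow, tp$d_fast))
  # noisy signals are nonnegative and reproducible under a fixed seed
  cv1 <- make_signal(tp, sch, snr = 20, model = "biexp", seed = 3)
  cv2 <- make_signal(tp, sch, snr = 20, model = "biexp", seed = 3)
  expect_identical(cv1$signal, cv2$signal)
  expect_true(all(cv1$signal >= 0))
  # sample mean at b = 0 matches the closed-form Rician mean within 1%
  # (sigma at b = 0 is reduced by sqrt(nex) = sqrt(2))
  set.seed(99)
  sigma <- 1 / (20 * sqrt(2))
  b0 <- replicate(1e4, make_signal(tp, sch, snr = 20,
                                   model = "biexp")$signal[1])
  expect_lt(abs(mean(b0) / rician_mean(1, sigma) - 1), 0.01)
  expect_error(make_signal(tp, sch, snr = 0), "> 0")
})

test_that("pathology scores track Table-style group medians and severity", {
  cfg <- cohort_config()
  set.seed(21)
  sev <- rnorm(2e4)
  hi <- make_pathology(sev, "high_egfr", cfg)
  lo <- make_pathology(sev, "low_egfr", cfg)
  expect_equal(median(hi$glomerular), 2)
  expect_lte(abs(median(lo$total) - 11), 1)
  # reduced-eGFR group stochastically dominates in every component
  for (k in c("glomerular", "tubulointerstitial", "vasculopathy")) {
    expect_gt(mean(lo[[k]]), mean(hi[[k]]))
    expect_true(all(lo[[k]] >= 0))
  }
  expect_true(all(hi$glomerular <= 12 & hi$tubulointerstitial <= 9 &
                    hi$vasculopathy <= 6))
  expect_identical(hi$total,
                   hi$glomerular + hi$tubulointerstitial + hi$vasculopathy)
  # scores increase with latent severity
  expect_gt(cor(sev, lo$total, method = "spearman"), 0.2)
  expect_error(make_pathology(0, "control", cfg), "arg")
})

test_that("reader simulation averages ROIs and collapses at zero noise", {
  cfg0 <- cohort_config(reader_noise = 0)
  rp <- draw_group_params("control", 7, cohort_config(), seed = 4)
  rd0 <- simulate_readers(rp, cfg0, seed = 9)
  expect_equal(unlist(rd0[1, -1]), unlist(rd0[2, -1]), tolerance = 1e-12)
  expect_equal(rd0$f[1], mean(rp$f), tolerance = 1e-12)
  rd1 <- simulate_readers(rp, cohort_config(), seed = 9)
  expect_false(isTRUE(all.equal(rd1$f[1], rd1$f[2])))
  expect_identical(rd1, simulate_readers(rp, cohort_config(), seed = 9))
})

test_that("generated cohorts are internally consistent and seed-deterministic", {
  cfg <- cohort_config(seed = 123)
  coh <- generate_cohort(cfg)
  subj <- coh$subjects
  expect_identical(as.integer(table(subj$group)), c(19L, 33L, 28L))
  # eGFR consistent with drawn creatinine/age/sex through the MDRD formula
  expect_equal(egfr_mdrd(subj$scr_umol, subj$age, subj$sex), subj$egfr,
               tolerance = 1e-10)
  # grouping rule holds by construction
  expect_identical(
    as.character(assign_group(subj$egfr, subj$group != "control")),
    as.character(subj$group))
  expect_true(all(subj$egfr[subj$group == "high_egfr"] >= 90))
  expect_true(all(subj$egfr[subj$group == "low_egfr"] < 90))
  # controls carry no pathology record; all patients do
  expect_false(any(coh$pathology$subject_id %in%
                     subj$subject_id[subj$group == "control"]))
  expect_setequal(coh$pathology$subject_id,
                  subj$subject_id[subj$group != "control"])
  # ROI counts within the configured range
  expect_true(all(subj$n_roi >= 6 & subj$n_roi <= 9))
  expect_identical(nrow(coh$signals), sum(subj$n_roi))
  # end-to-end determinism from one integer seed
  expect_identical(coh, generate_cohort(cfg))
  expect_error(generate_cohort(cohort_config(n_control = 0, seed = 1)),
               "group sizes")
})

test_that("latent severity induces the expected correlation regime", {
  # default cohort scaled x10 to pin down the coefficients
  cfg <- cohort_config(n_control = 190, n_high = 330, n_low = 280,
                       seed = 2024)
  coh <- generate_cohort(cfg)
  subj <- coh$subjects
  pat <- merge(coh$pathology, subj, by = "subject_id")
  r_egfr <- cor(subj$d_fast, subj$egfr, method = "spearman")
  r_tub <- cor(pat$d_fast, pat$tubulointerstitial, method = "spearman")
  expect_gt(r_egfr, 0.4)
  expect_lt(r_egfr, 0.8)
  expect_lt(r_tub, -0.4)
  expect_gt(r_tub, -0.8)
})
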