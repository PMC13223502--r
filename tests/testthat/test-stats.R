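test_that("normality screen separates normal from grossly non-normal data", {
  set.seed(1)
  expect_identical(normality_screen(rnorm(5000))$class, "normal")
  expect_identical(normality_screen(rlnorm(5000, sdlog = 1))$class,
                   "non_normal")
  expect_warning(res <- normality_screen(rep(1, 10)), "constant")
  expect_identical(res$class, "non_normal")
  expect_error(normality_screen(c(1, 2)), "n >= 3")
})

test_that("Mann-Whitney U matches hand computation and enumeration", {
  # complete separation: no x beats any y
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_identical(unname(mw$U), 0)
  # identical samples: U = n^2/2 by tie midranks, p in the null regime
  mw2 <- mann_whitney(1:6, 1:6)
  expect_identical(unname(mw2$U), 18)
  expect_gt(mw2$p, 0.9)
  # exact two-sided p verified by full enumeration of group assignments:
  # choose(3,1) placements of y among ranks {1,2,3}; U <= 0 in 1 of 3
  mw3 <- mann_whitney(c(1, 2), 3)
  expect_identical(unname(mw3$U), 0)
  cmb <- utils::combn(3, 1)
  p_enum <- 2 * mean(sapply(seq_len(ncol(cmb)), function(j) {
    ranks <- 1:3
    uy <- sum(ranks[cmb[, j]]) - 1 * 2 / 2        # U of the singleton side
    ux <- 2 * 1 - uy
    ux <= mw3$U
  }))
  expect_equal(mw3$p, min(1, p_enum), tolerance = 1e-12)
  expect_error(mann_whitney(numeric(0), 1), "nonempty")
})

test_that("Kruskal-Wallis H and Dunn comparisons match the rank formulas", {
  vals <- c(1, 2, 3, 4, 5, 6)
  grp <- rep(c("a", "b", "c"), each = 2)
  kw <- kruskal_wallis_posthoc(vals, grp)
  # direct rank-sum formula (no ties): H = 12/(N(N+1)) sum n_i Rbar_i^2 - 3(N+1)
  H_hand <- 12 / (6 * 7) * sum(2 * c(1.5, 3.5, 5.5)^2) - 3 * 7
  expect_equal(unname(kw$H), H_hand, tolerance = 1e-12)
  # Dunn z for groups a vs c by hand: sigma2 = N(N+1)/12
  z_hand <- (1.5 - 5.5) / sqrt(6 * 7 / 12 * (1 / 2 + 1 / 2))
  expect_equal(kw$pairwise$z[kw$pairwise$group1 == "a" &
                               kw$pairwise$group2 == "c"],
               z_hand, tolerance = 1e-12)
  expect_equal(kw$pairwise$p_adj,
               pmin(1, 3 * kw$pairwise$p_raw), tolerance = 1e-15)
  # identical distributions: omnibus null, all adjusted p capped at 1
  set.seed(2)
  vals2 <- rnorm(300)
  grp2 <- rep(c("a", "b", "c"), each = 100)
  kw2 <- kruskal_wallis_posthoc(vals2, grp2)
  expect_gt(kw2$p, 0.05)
  expect_true(all(kw2$pairwise$p_adj <= 1))
  expect_error(kruskal_wallis_posthoc(1:4, rep(c("a", "b"), 2)),
               "3 groups")
})

test_that("Spearman correlation matches the hand-rank oracle with Bonferroni", {
  r <- spearman_bonferroni(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(r$rho, 0.8, tolerance = 1e-12)  # 1 - 6*2/(4*15)
  expect_equal(spearman_bonferroni(1:10, (1:10)^3)$rho, 1, tolerance = 1e-12)
  expect_equal(spearman_bonferroni(1:10, -(1:10)^3)$rho, -1, tolerance = 1e-12)
  # Bonferroni is monotone and capped
  r6 <- spearman_bonferroni(c(1, 2, 3, 4), c(1, 3, 2, 4), m = 6)
  expect_equal(r6$p_adj, min(1, 6 * r6$p_raw), tolerance = 1e-15)
  df <- data.frame(a = 1:8, b = c(2, 1, 4, 3, 6, 5, 8, 7))
  rr <- spearman_bonferroni(df, 1:8)
  expect_identical(rr$m, c(2L, 2L))
  expect_identical(rr$variable, c("a", "b"))
  expect_error(spearman_bonferroni(1:3, 1:4), "equal length")
})

test_that("two-reader ICC behaves at its anchor points", {
  set.seed(3)
  x <- rnorm(50, 10)
  expect_equal(icc_two_reader(cbind(x, x))$icc, 1, tolerance = 1e-12)
  # independent readers: ICC near 0
  null_icc <- icc_two_reader(cbind(rnorm(200), rnorm(200)))
  expect_lt(abs(null_icc$icc), 0.1)
  expect_lte(null_icc$ci[1], null_icc$icc)
  expect_gte(null_icc$ci[2], null_icc$icc)
  # correlated readers: high ICC with a sensible CI
  truth <- rnorm(100, 5)
  m <- cbind(truth + rnorm(100, sd = 0.1), truth + rnorm(100, sd = 0.1))
  ic <- icc_two_reader(m)
  expect_gt(ic$icc, 0.95)
  expect_true(ic$ci[1] <= ic$icc && ic$icc <= ic$ci[2])
  expect_error(icc_two_reader(cbind(1:10, c(1:9, NA))), "missing")
  expect_error(icc_two_reader(cbind(1:3, 1:3)), ">= 5")
})

test_that("ROC analysis matches the Mann-Whitney identity and Youden rules", {
  # perfect separation
  r <- roc_analysis(c(1, 2, 3, 10, 11, 12), c(rep(TRUE, 3), rep(FALSE, 3)),
                    direction = "lower")
  expect_identical(r$auc, 1)
  expect_identical(r$youden, 1)
  expect_identical(r$rule, "<=")
  # null: labels independent of marker
  set.seed(4)
  r0 <- roc_analysis(rnorm(2000), rep(c(TRUE, FALSE), 1000),
                     direction = "lower")
  expect_lt(abs(r0$auc - 0.5), 0.05)
  # AUC = U / (n1 n2) on random small instances, including ties
  set.seed(5)
  for (i in 1:100) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    vals <- if (i %% 2) rnorm(n1 + n2) else sample(1:4, n1 + n2, TRUE)
    lab <- c(rep(FALSE, n1), rep(TRUE, n2))
    r <- roc_analysis(vals, lab, direction = "lower")
    U <- unname(suppressWarnings(
      stats::wilcox.test(vals[!lab], vals[lab])$statistic))
    expect_equal(r$auc, U / (n1 * n2), tolerance = 1e-12)
    # reported Youden equals sensitivity + specificity - 1 exactly
    expect_equal(r$youden, r$sensitivity + r$specificity - 1,
                 tolerance = 1e-12)
  }
  expect_error(roc_analysis(1:5, rep(TRUE, 5)), "both classes")
})

test_that("chi-square on counts matches hand computation", {
  expect_equal(chi_square_counts(matrix(c(10, 0, 0, 10), 2))$statistic, 20,
               tolerance = 1e-12)
  # perfectly proportional table (row 2 = 2 x row 1) gives statistic 0
  prop <- matrix(c(4, 6, 10, 8, 12, 20), nrow = 2, byrow = TRUE)
  expect_lt(chi_square_counts(prop)$statistic, 1e-10)
  # observed gender composition: no significant difference regime
  gender <- matrix(c(7, 17, 20, 12, 16, 8), nrow = 2, byrow = TRUE)
  expect_gt(chi_square_counts(gender)$p, 0.05)
  expect_error(chi_square_counts(matrix(c(0, 0, 1, 2), 2)), "marginal")
  expect_error(chi_square_counts(matrix(c(1.5, 1, 1, 1), 2)), "integer")
})

test_that("rank-based tests are invariant under strictly monotone transforms", {
  set.seed(6)
  x <- rnorm(25); y <- rnorm(20, 0.5)
  tr <- function(v) exp(v)  # strictly increasing
  expect_equal(mann_whitney(x, y)$p, mann_whitney(tr(x), tr(y))$p,
               tolerance = 1e-12)
  g <- rep(c("a", "b", "c"), c(15, 15, 15))
  v <- rnorm(45)
  expect_equal(kruskal_wallis_posthoc(v, g)$H,
               kruskal_wallis_posthoc(tr(v), g)$H, tolerance = 1e-12)
  y2 <- x + rnorm(25)
  expect_equal(spearman_bonferroni(x, y2)$rho,
               spearman_bonferroni(tr(x), y2)$rho, tolerance = 1e-12)
  lab <- rep(c(TRUE, FALSE), length.out = 45)
  expect_equal(roc_analysis(v, lab, direction = "lower")$auc,
               roc_analysis(tr(v), lab, direction = "lower")$auc,
               tolerance = 1e-12)
})

test_that("study report reproduces the expected analysis structure", {
  coh <- generate_cohort(cohort_config(seed = 8))
  rep_ <- build_study_report(coh)
  expect_named(rep_, c("demographics", "sex_counts", "sex_p",
                       "params_by_group", "pathology_by_group",
                       "correlations", "roc", "roc_points", "icc", "meta"))
  expect_identical(nrow(rep_$params_by_group), 6L)
  expect_identical(nrow(rep_$roc), 12L)
  expect_true(all(rep_$correlations$p_adj >= rep_$correlations$p_raw - 1e-15))
  expect_true(all(rep_$correlations$p_adj <= 1))
  expect_identical(unique(rep_$correlations$m), 6L)
  # creatinine pattern: control vs high null, the low-group contrasts strong
  cr <- rep_$demographics[rep_$demographics$variable == "creatinine_umol_L", ]
  expect_gt(cr$p1_control_high, 0.05)
  expect_lt(cr$p2_control_low, 0.001)
  expect_lt(cr$p3_high_low, 0.001)
  # pathology scores higher in the reduced-eGFR group
  expect_true(all(rep_$pathology_by_group$p < 0.05))
  # permuting group labels destroys the omnibus signal on average
  subj <- coh$subjects
  meas <- coh$readers[coh$readers$reader == 1, ]
  meas <- meas[match(subj$subject_id, meas$subject_id), ]
  set.seed(9)
  pvals <- replicate(20, {
    kruskal_wallis_posthoc(meas$d_fast, sample(subj$group))$p
  })
  expect_gt(mean(pvals), 0.05)
})

test_that("spearman correlation test helper handles mismatched rank pattern", {
  # hand-rank oracle: rho = 1 - 6*sum(d^2)/(n(n^2-1))
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  y <- c(2, 7, 1, 8, 2, 8, 1, 8)
  d <- rank(x) - rank(y)
  rho_hand <- 1 - 6 * sum(d^2) / (8 * (64 - 1))
  # with ties the average-rank (Pearson-on-ranks) form is the oracle
  rho_ties <- cor(rank(x), rank(y))
  expect_equal(spearman_bonferroni(x, y)$rho, rho_ties, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(rho_hand, rho_ties)))  # ties matter here
})
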