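test_that("Bonferroni correction multiplies and caps", {
  expect_equal(bonferroni(0.01, 5), 0.05)
  expect_equal(bonferroni(0.4, 5), 1.0)
  p <- c(0.001, 0.02, 0.3)
  expect_equal(bonferroni(p, 6), pmin(1, p * 6))
  # agrees with p.adjust when the family is the vector itself
  expect_equal(bonferroni(p, length(p)), stats::p.adjust(p, "bonferroni"))
})

test_that("ANCOVA partial F matches the brute-force nested-RSS oracle", {
  # closed-form toy data: 3 groups x 4 subjects, integer values with
  # non-zero residuals
  y <- c(1, 2, 4, 4, 3, 5, 5, 6, 6, 7, 9, 9)
  g <- rep(c("A", "B", "C"), each = 4)
  covs <- data.frame(age = c(1, 2, 3, 4, 1, 2, 3, 4, 1, 2, 3, 4))
  fit <- ancova_tract(y, g, covs)
  oracle <- partial_f_oracle(y, g, covs)
  expect_equal(fit$F, oracle$F, tolerance = 1e-12)
  expect_equal(fit$p, oracle$p, tolerance = 1e-12)
  # and against car's type-III ANOVA
  d <- data.frame(y = y, g = factor(g), age = covs$age)
  lm_fit <- stats::lm(y ~ g + age, data = d)
  car_tab <- car::Anova(lm_fit, type = 3)
  expect_equal(fit$F, car_tab["g", "F value"], tolerance = 1e-10)
  # random instances
  set.seed(51)
  for (r in 1:10) {
    n <- 40
    gg <- sample(c("HC", "RRMS", "SPMS"), n, replace = TRUE,
                 prob = c(0.4, 0.4, 0.2))
    cc <- data.frame(age = stats::rnorm(n), sex = stats::rbinom(n, 1, 0.5))
    yy <- stats::rnorm(n) + 0.3 * cc$age
    f1 <- ancova_tract(yy, gg, cc)
    o1 <- partial_f_oracle(yy, gg, cc)
    expect_equal(f1$F, o1$F, tolerance = 1e-9)
  }
})

test_that("identical groups give a group F of exactly 0", {
  # every group repeats the same (y, age) pattern, so the group indicators
  # explain nothing beyond the covariate (yet residuals are non-zero)
  y <- rep(c(1, 2, 2, 4), times = 3)
  g <- rep(c("A", "B", "C"), each = 4)
  covs <- data.frame(age = rep(c(1, 2, 3, 4), times = 3))
  fit <- suppressWarnings(ancova_tract(y, g, covs))
  expect_equal(fit$F, 0, tolerance = 1e-12)
})

test_that("adjusted means and pairwise contrasts agree with emmeans", {
  set.seed(52)
  n <- 60
  g <- sample(c("HC", "RRMS", "SPMS"), n, replace = TRUE)
  covs <- data.frame(age = stats::rnorm(n, 48, 10), sex = stats::rbinom(n, 1, 0.5))
  y <- stats::rnorm(n) - 0.5 * (g == "SPMS") + 0.02 * covs$age
  fit <- ancova_tract(y, g, covs)
  d <- data.frame(.y = y, .g = factor(g), age = covs$age, sex = covs$sex)
  # proportional weights so emmeans also adjusts at the observed covariate mean
  em <- emmeans::emmeans(stats::lm(.y ~ .g + age + sex, data = d), ".g",
                         weights = "proportional")
  em_df <- as.data.frame(em)
  expect_equal(fit$adjusted_means$mean, em_df$emmean, tolerance = 1e-8)
  expect_equal(fit$adjusted_means$se, em_df$SE, tolerance = 1e-8)
  pr <- as.data.frame(emmeans::contrast(em, "pairwise", adjust = "bonferroni"))
  expect_equal(sort(abs(fit$posthoc$difference)), sort(abs(pr$estimate)),
               tolerance = 1e-8)
  expect_equal(sort(fit$posthoc$p_bonferroni), sort(pr$p.value),
               tolerance = 1e-8)
})

test_that("post-hoc pairwise table enumerates all pairs and caps p at 1", {
  set.seed(53)
  n <- 48
  g <- rep(c("HC", "RRMS", "SPMS", "PPMS"), each = 12)
  y <- stats::rnorm(n)
  fit <- ancova_tract(y, g, data.frame(age = stats::rnorm(n)))
  expect_equal(nrow(fit$posthoc), 6)
  expect_equal(fit$family_size, 6)
  expect_true(all(fit$posthoc$p_bonferroni <= 1))
  expect_equal(fit$posthoc$p_bonferroni,
               pmin(1, fit$posthoc$p_raw * 6))
})

test_that("pairwise differences match subset refits on noise-free data", {
  # noiseless additive structure: group effects + covariate effect
  g <- rep(c("A", "B", "C"), each = 6)
  age <- rep(1:6, times = 3)
  eff <- c(A = 0, B = -1, C = -3)
  # residual wiggle repeated identically in each group keeps the adjusted
  # group differences exact while avoiding a degenerate zero-residual fit
  y <- eff[g] + 0.5 * age + rep(c(0.1, -0.2, 0.15, -0.05, 0.3, -0.3), 3)
  fit <- ancova_tract(y, g, data.frame(age = age))
  ph <- fit$posthoc
  for (i in seq_len(nrow(ph))) {
    expect_equal(ph$difference[i],
                 unname(eff[ph$group1[i]] - eff[ph$group2[i]]),
                 tolerance = 1e-10)
  }
})

test_that("confounded designs raise a rank error", {
  g <- rep(c("A", "B"), each = 5)
  x <- as.numeric(g == "A")   # covariate identical to the group indicator
  expect_error(ancova_tract(stats::rnorm(10), g, data.frame(x = x)),
               "confounded|rank")
})

test_that("mixed model reduces to OLS when the random-intercept variance is zero", {
  set.seed(61)
  n <- 60
  d <- data.frame(subject = rep(seq_len(n), each = 2),
                  group = rep(rep(c("HC", "SPMS"), each = n / 2), each = 2),
                  time_years = rep(c(0, 5), n))
  # no subject-level heterogeneity at all
  d$value <- 0.5 - 0.004 * d$time_years * (d$group == "SPMS") +
    stats::rnorm(2 * n, 0, 0.01)
  fit <- lmm_longitudinal(d)
  ols <- stats::lm(value ~ group * time_years, data = d)
  co <- stats::coef(ols)
  fe <- stats::setNames(fit$fixed$estimate, fit$fixed$term)
  expect_equal(unname(fe["(Intercept)"]), unname(co["(Intercept)"]),
               tolerance = 1e-4)
  expect_equal(unname(fe[".t"]), unname(co["time_years"]), tolerance = 1e-4)
  expect_equal(unname(fe[".gSPMS:.t"]), unname(co["groupSPMS:time_years"]),
               tolerance = 1e-4)
})

test_that("mixed-model estimates are invariant to subject relabeling", {
  set.seed(62)
  n <- 40
  d <- data.frame(subject = rep(seq_len(n), each = 2),
                  group = rep(rep(c("HC", "RRMS"), each = n / 2), each = 2),
                  time_years = rep(c(0, 4.8), n))
  d$value <- 0.5 + rep(stats::rnorm(n, 0, 0.03), each = 2) +
    stats::rnorm(2 * n, 0, 0.01)
  f1 <- lmm_longitudinal(d)
  d2 <- d
  d2$subject <- paste0("S", sample(900 + seq_len(n)))[match(d$subject, seq_len(n))]
  f2 <- lmm_longitudinal(d2)
  expect_equal(f1$fixed$estimate, f2$fixed$estimate, tolerance = 1e-8)
  expect_equal(f1$varcomp, f2$varcomp, tolerance = 1e-8)
})

test_that("per-phenotype slopes recover simulated decline", {
  set.seed(63)
  n_per <- 60
  subj <- seq_len(2 * n_per)
  d <- data.frame(subject = rep(subj, each = 2),
                  group = rep(rep(c("HC", "SPMS"), each = n_per), each = 2),
                  time_years = rep(c(0, 5), 2 * n_per))
  slope <- ifelse(d$group == "SPMS", -0.004, 0)
  d$value <- 0.5 + slope * d$time_years +
    rep(stats::rnorm(2 * n_per, 0, 0.03), each = 2) +
    stats::rnorm(4 * n_per, 0, 0.005)
  fit <- lmm_longitudinal(d)
  sl <- fit$slopes
  expect_equal(sl$slope[sl$group == "SPMS"], -0.004, tolerance = 0.3)
  expect_lt(sl$p[sl$group == "SPMS"], 0.001)
  expect_gt(sl$p[sl$group == "HC"], 0.001)
  expect_true(all(fit$varcomp >= 0))
})

test_that("cross-sectional data are refused by the longitudinal model", {
  d <- data.frame(subject = 1:20, group = rep(c("HC", "RRMS"), 10),
                  time_years = 0, value = stats::rnorm(20))
  expect_error(lmm_longitudinal(d), "cross-sectional")
})

test_that("lesion masking leaves tracts without lesioned voxels untouched", {
  w <- stats::setNames(rep(1e-9, 20), tract_names())
  w[c("CST_L", "CST_R")] <- 1   # lesions land (almost) only in the CSTs
  coh <- generate_cohort(small_config(
    seed = 13, lesion = list(tract_weights = w,
                             expected_voxels = c(RRMS = 3, SPMS = 5, PPMS = 4))))
  tt_raw <- tract_metric_table(coh, mask_lesions = FALSE)
  tt_mask <- tract_metric_table(coh, mask_lesions = TRUE)
  # tracts none of whose voxels intersect any lesion (crossing voxels can
  # carry a lesion into a second tract, so intersect at voxel level)
  fx <- coh$template$fixels
  vox_of <- paste(fx$i, fx$j, fx$k)
  les_vox <- unique(unlist(lapply(coh$lesions, function(m)
    paste(m[, 1], m[, 2], m[, 3]))))
  touched <- unique(fx$tract[vox_of %in% les_vox])
  clean <- setdiff(tract_names(), touched)
  expect_gt(length(clean), 0)
  expect_identical(tt_raw[tt_raw$tract %in% clean, ],
                   tt_mask[tt_mask$tract %in% clean, ])
  # and masked rows differ where lesions fall
  expect_false(identical(tt_raw, tt_mask))
})

test_that("tract-level group analysis reports family-corrected p-values", {
  coh <- generate_cohort(small_config(seed = 14))
  tt <- tract_metric_table(coh)
  res <- tract_group_analysis(tt, coh$subjects, metric = "mean_fdc")
  expect_equal(nrow(res), 20)
  expect_equal(unique(res$family_size), 20)
  expect_equal(res$p_bonferroni, pmin(1, res$p * 20))
  expect_true(all(c("mean_HC", "effect_pct_SPMS") %in% names(res)))
  # treatment covariate variants run
  res_b <- tract_group_analysis(tt[tt$tract %in% c("ATR_L", "SLF_R"), ],
                                coh$subjects, treatment = "binary")
  expect_equal(nrow(res_b), 2)
})
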