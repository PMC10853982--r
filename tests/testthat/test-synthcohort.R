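test_that("generated template satisfies its structural invariants", {
  cfg <- small_config(seed = 1)
  tpl <- generate_template(cfg)
  expect_silent(validate_template(tpl))
  expect_setequal(unique(tpl$fixels$tract), tract_names())
  # determinism
  tpl2 <- generate_template(cfg)
  expect_identical(tpl, tpl2)
  # crossing regions: voxels shared by >= 2 bundle paths hold 2-3 fixels,
  # each keeping its own tract label
  vox <- paste(tpl$fixels$i, tpl$fixels$j, tpl$fixels$k)
  counts <- table(vox)
  crossing <- names(counts)[counts >= 2]
  expect_gt(length(crossing), 0)
  expect_true(all(counts[crossing] %in% 2:3))
  expect_true(any(counts == 3))
  for (v in crossing) {
    labs <- tpl$fixels$tract[vox == v]
    expect_equal(anyDuplicated(labs), 0)
  }
})

test_that("too-small grids are rejected as configuration errors", {
  expect_error(
    generate_template(simulation_config(template = list(grid_dim = c(6L, 6L, 6L)))),
    "too small")
})

test_that("cohort generation is deterministic and conserves group sizes", {
  cfg <- small_config(seed = 7)
  coh <- generate_cohort(cfg)
  coh2 <- generate_cohort(cfg)
  expect_identical(coh, coh2)
  b <- coh$subjects[coh$subjects$timepoint == 1, ]
  expect_equal(sum(b$group != "HC"),
               sum(cfg$group_sizes[c("RRMS", "SPMS", "PPMS")]))
  expect_equal(as.vector(table(b$group)[names(cfg$group_sizes)]),
               unname(cfg$group_sizes))
  # every follow-up record has a matching baseline record
  f <- coh$subjects[coh$subjects$timepoint == 2, ]
  expect_true(all(f$subject %in% b$subject))
})

test_that("degenerate noise yields exact HC tract means at both timepoints", {
  eff <- list(fd = matrix(0, 20, 3, dimnames = list(tract_names(),
                                                    c("RRMS", "SPMS", "PPMS"))))
  eff$fc <- eff$fd
  slp <- list(fd = matrix(0, 20, 4, dimnames = list(tract_names(),
                                                    c("HC", "RRMS", "SPMS", "PPMS"))))
  slp$fc <- slp$fd
  cfg <- small_config(seed = 2, tract_effects = eff, slope_effects = slp,
                      noise = c(between_sd = 0, within_sd = 0, fixel_sd = 0))
  coh <- generate_cohort(cfg)
  for (tp in 1:2) {
    fd <- coh$ground_truth$tract_fd[[tp]]
    expect_equal(unname(fd),
                 matrix(0.5, nrow(fd), ncol(fd)), tolerance = 1e-12)
  }
})

test_that("configured FD deficits are recovered exactly without noise", {
  # lesion-free so the diffuse deficit is the only FD mechanism in play
  cfg <- small_config(seed = 5,
                      noise = c(between_sd = 0, within_sd = 0, fixel_sd = 0),
                      lesion = list(expected_voxels = c(RRMS = 0, SPMS = 0,
                                                        PPMS = 0)))
  coh <- generate_cohort(cfg)
  tt <- tract_metric_table(coh)
  tt1 <- tt[tt$timepoint == 1, ]
  grp <- coh$subjects$group[match(tt1$subject, coh$subjects$subject)]
  for (g in c("RRMS", "SPMS")) {
    for (tr in c("ATR_L", "SLF_R")) {
      m_hc <- mean(tt1$mean_fd[grp == "HC" & tt1$tract == tr])
      m_g <- mean(tt1$mean_fd[grp == g & tt1$tract == tr])
      expect_equal(1 - m_g / m_hc, cfg$tract_effects$fd[tr, g],
                   tolerance = 1e-6)
    }
  }
})

test_that("default deficits order groups HC > RRMS ~ PPMS > SPMS in most tracts", {
  coh <- generate_cohort(small_config(seed = 11))
  fd <- coh$ground_truth$tract_fd[[1]]
  grp <- coh$subjects$group[match(rownames(fd), coh$subjects$subject)]
  ok <- 0
  for (tr in colnames(fd)) {
    m <- tapply(fd[, tr], grp, mean)
    if (m["HC"] > max(m["RRMS"], m["PPMS"]) &&
        min(m["RRMS"], m["PPMS"]) > m["SPMS"]) ok <- ok + 1
  }
  expect_gte(ok, 18)
})

test_that("cognition is an exact affine function of tract FDC when noise-free", {
  cfg <- small_config(
    seed = 3,
    cognition = list(domain_sd = 0, age_coef = 0, sex_coef = 0, edu_coef = 0))
  coh <- generate_cohort(cfg)
  z <- coh$ground_truth$tract_fdc_z[[1]]
  cg1 <- coh$cognition[coh$cognition$timepoint == 1, ]
  idx <- match(cg1$subject, rownames(z))
  L <- cfg$cognition$loading
  for (d in seq_len(nrow(L))) {
    pred <- drop(z[idx, ] %*% L[d, ]) + cfg$cognition$intercept
    expect_equal(unname(cg1[[cognitive_domains()[d]]]), unname(pred),
                 tolerance = 1e-10)
  }
})

test_that("intended FC field is realized exactly by the generated warps", {
  coh <- generate_cohort(small_config(seed = 4))
  rec <- coh$fixel_data[[3]]
  dirs <- as.matrix(coh$template$fixels[, c("dx", "dy", "dz")])
  expect_equal(compute_fc(rec$jacobian, dirs), rec$fc, tolerance = 1e-10)
})

test_that("invalid configurations are rejected with validation errors", {
  expect_error(simulation_config(group_sizes = c(HC = -1, RRMS = 1, SPMS = 1, PPMS = 1)),
               "non-negative")
  expect_error(simulation_config(noise = c(between_sd = -0.1, within_sd = 0, fixel_sd = 0)),
               "noise")
  expect_error(simulation_config(nonsense_key = 1), "nonsense_key")
  bad <- small_config()
  bad$tract_effects$fd[1, 1] <- 1.2
  expect_error(generate_cohort(bad), "deficits")
})

test_that("lesions target patients and respect tract preference weights", {
  w <- stats::setNames(rep(1e-6, 20), tract_names())
  w["CST_L"] <- 1
  # expected counts kept below the preferred tract's voxel count so the
  # preference is not exhausted by without-replacement sampling
  cfg <- small_config(seed = 9,
                      lesion = list(tract_weights = w,
                                    expected_voxels = c(RRMS = 4, SPMS = 6,
                                                        PPMS = 5)))
  coh <- generate_cohort(cfg)
  hc <- coh$subjects$subject[coh$subjects$group == "HC"]
  expect_false(any(names(coh$lesions) %in% hc))
  tpl <- coh$template
  cst_vox <- paste(tpl$fixels$i, tpl$fixels$j, tpl$fixels$k)[tpl$fixels$tract == "CST_L"]
  les_vox <- unlist(lapply(coh$lesions, function(m) paste(m[, 1], m[, 2], m[, 3])))
  expect_gt(mean(les_vox %in% cst_vox), 0.9)
})
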