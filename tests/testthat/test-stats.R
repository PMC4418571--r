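test_that("near-constant time courses segment as one long plateau", {
  set.seed(1)
  tc <- null_cohort_tcs(n_sub = 6, sd = 0.05)
  seg <- segment_phases(tc)
  expect_true(all(seg$transitions$label == "plateau"))
  expect_equal(nrow(seg$transitions), 14)
})

test_that("a piecewise-linear response is segmented at its true breakpoints", {
  # up over 4 transitions, flat 6, down 4; high SNR across 9 subjects
  shape <- c(0, 1, 2, 3, 4, 4, 4, 4, 4, 4, 4, 3, 2, 1, 0)
  set.seed(2)
  tc <- tidyr::expand_grid(subject = paste0("S", 1:9), frame = 1:15) |>
    dplyr::mutate(time_s = (frame - 1) * 2,
                  psc = shape[frame] + rnorm(dplyr::n(), 0, 0.05))
  seg <- segment_phases(tc)
  ph <- seg$phases
  expect_equal(ph$start_s[ph$phase == "rise"], 0)
  expect_equal(ph$end_s[ph$phase == "rise"], 8)
  expect_equal(ph$start_s[ph$phase == "plateau"], 8)
  expect_equal(ph$end_s[ph$phase == "plateau"], 20)
  expect_equal(ph$start_s[ph$phase == "decay"], 20)
  expect_equal(ph$end_s[ph$phase == "decay"], 28)
})

test_that("segmentation requires at least three subjects", {
  tc <- null_cohort_tcs(n_sub = 2)
  expect_error(segment_phases(tc), "at least 3 subjects")
})

test_that("segmentation and contrast ignore subject-specific offsets", {
  gt <- make_tonotopic_sheet(small_sheet(), seed = 1)
  design <- make_block_design()
  tcs <- purrr::map_dfr(1:5, function(s)
    simulate_subject_tcs(gt, design, hrf_model(), seed = 700 + s * 3))
  offsets <- setNames(seq(-2, 2, length.out = 5), unique(tcs$subject))
  shifted <- dplyr::mutate(tcs, psc = psc + offsets[subject])
  s1 <- segment_phases(tcs)
  s2 <- segment_phases(shifted)
  expect_equal(s2$transitions$p_value, s1$transitions$p_value)
  c1 <- contrast_conditions(tcs, s1)
  c2 <- contrast_conditions(shifted, s2)
  expect_equal(tidy(c2)$p_value, tidy(c1)$p_value)
})

test_that("identical conditions give no repetition effect", {
  set.seed(3)
  base <- tidyr::expand_grid(subject = paste0("S", 1:8), frame = 1:15) |>
    dplyr::mutate(psc = rnorm(dplyr::n()))
  tc <- dplyr::bind_rows(dplyr::mutate(base, condition = "REP"),
                         dplyr::mutate(base, condition = "CTRL")) |>
    dplyr::mutate(time_s = (frame - 1) * 2)
  ctr <- contrast_conditions(tc)
  expect_true(all(!tidy(ctr)$significant))
  expect_false(glance(ctr)$repetition_effect[1])
})

test_that("unpaired subjects are rejected by the contrast", {
  tc <- null_cohort_tcs(n_sub = 4)
  broken <- tc[!(tc$subject == "S1" & tc$condition == "REP"), ]
  expect_error(contrast_conditions(broken), "not paired")
})

test_that("the suppression effect is detected in almost every replicate", {
  # power of the repetition-effect verdict for a 0.7-factor region, full
  # generator path, 9 subjects x 2 runs per replicate
  gt <- make_tonotopic_sheet(small_sheet(), seed = 1)
  design <- make_block_design()
  prof <- suppression_profile(factors = c(A1 = 0.7), lead_s = 2)
  verdicts <- sapply(1:30, function(k) {
    coh <- sample_subject_hrfs(9, seed = 4000 + k)
    tcs <- purrr::map_dfr(1:9, function(s)
      simulate_subject_tcs(gt, design, coh$hrf[[s]],
                           seed = 4000 + k * 131 + s * 7,
                           amplitude = coh$amplitude[s], profile = prof,
                           n_runs = 2))
    v <- glance(contrast_conditions(tcs, segment_phases(tcs)))
    v$repetition_effect[v$roi == "A1"]
  })
  expect_gte(mean(verdicts), 0.9)
})

test_that("the verdict false-positive rate stays near the nominal level", {
  # null profile: REP and CTRL expectations identical; the two-consecutive-
  # frame rule keeps the verdict rate low
  gt <- make_tonotopic_sheet(small_sheet(), seed = 1)
  design <- make_block_design()
  null_prof <- suppression_profile(factors = c(A1 = 1), lead_s = 0)
  verdicts <- sapply(1:60, function(k) {
    coh <- sample_subject_hrfs(9, seed = 6000 + k)
    tcs <- purrr::map_dfr(1:9, function(s)
      simulate_subject_tcs(gt, design, coh$hrf[[s]],
                           seed = 6000 + k * 173 + s * 11,
                           amplitude = coh$amplitude[s],
                           profile = null_prof, n_runs = 2))
    v <- glance(contrast_conditions(tcs, segment_phases(tcs)))
    v$repetition_effect[v$roi == "A1"]
  })
  expect_gte(mean(verdicts), 0)
  expect_lte(mean(verdicts), 0.15)
})

test_that("identical cells give zero F throughout the 2x2 ANOVA", {
  df <- tidyr::expand_grid(subject = paste0("S", 1:6),
                           hemisphere = c("LH", "RH"),
                           condition = c("REP", "CTRL"), frame = 1:3) |>
    dplyr::mutate(psc = as.numeric(factor(subject)))   # subject offsets only
  an <- anova_2x2_timepoint(df)
  expect_true(all(an$by_frame$statistic == 0))
  expect_true(all(an$by_frame$p_value == 1))
})

test_that("a pure condition offset loads only on the condition effect", {
  set.seed(4)
  df <- tidyr::expand_grid(subject = paste0("S", 1:9),
                           hemisphere = c("LH", "RH"),
                           condition = c("REP", "CTRL"), frame = 1) |>
    dplyr::mutate(psc = rnorm(dplyr::n(), 0, 0.2) +
                    ifelse(condition == "REP", -1, 0))
  an <- tidy(anova_2x2_timepoint(df))
  expect_lt(an$p_value[an$effect == "condition"], 0.001)
  expect_gt(an$p_value[an$effect == "hemisphere"], 0.05)
  expect_gt(an$p_value[an$effect == "interaction"], 0.05)
})

test_that("the ANOVA decomposition matches the aov oracle to 6 decimals", {
  set.seed(5)
  for (rep in 1:5) {
    df <- tidyr::expand_grid(subject = paste0("S", 1:7),
                             hemisphere = c("LH", "RH"),
                             condition = c("REP", "CTRL"), frame = 1) |>
      dplyr::mutate(psc = rnorm(dplyr::n()))
    an <- tidy(anova_2x2_timepoint(df))
    oracle <- aov_2x2_oracle(df)
    for (eff in c("hemisphere", "condition", "interaction")) {
      expect_equal(an$statistic[an$effect == eff],
                   unname(oracle[[eff]]["f"]), tolerance = 1e-6)
      expect_equal(an$p_value[an$effect == eff],
                   unname(oracle[[eff]]["p"]), tolerance = 1e-6)
    }
  }
})

test_that("with hemisphere collapsed the condition F equals the paired t squared", {
  set.seed(6)
  base <- tidyr::expand_grid(subject = paste0("S", 1:9),
                             condition = c("REP", "CTRL"), frame = 1) |>
    dplyr::mutate(psc = rnorm(dplyr::n()) +
                    ifelse(condition == "REP", -0.4, 0))
  # duplicate identically into both hemispheres so hemisphere is inert
  df <- dplyr::bind_rows(dplyr::mutate(base, hemisphere = "LH"),
                         dplyr::mutate(base, hemisphere = "RH"))
  an <- tidy(anova_2x2_timepoint(df))
  w <- tidyr::pivot_wider(base, names_from = condition, values_from = psc)
  tt <- t.test(w$REP, w$CTRL, paired = TRUE)
  expect_equal(an$statistic[an$effect == "condition"],
               unname(tt$statistic)^2, tolerance = 1e-4)
})

test_that("the ANOVA rejects incomplete cells", {
  df <- tidyr::expand_grid(subject = paste0("S", 1:4),
                           hemisphere = c("LH", "RH"),
                           condition = c("REP", "CTRL"), frame = 1) |>
    dplyr::mutate(psc = rnorm(dplyr::n()))
  expect_error(anova_2x2_timepoint(df[-1, ]), "every subject")
})

test_that("extrema locate the right frames and amplitude is shift-invariant", {
  inc <- tidyr::expand_grid(subject = paste0("S", 1:4),
                            condition = c("REP", "CTRL"), frame = 1:15) |>
    dplyr::mutate(psc = frame / 15)
  ex <- extrema_stats(inc)
  expect_true(all(ex$per_subject$maximum == 1))
  expect_true(all(ex$per_subject$minimum == 1 / 15))
  shifted <- dplyr::mutate(inc, psc = psc + 5)
  ex2 <- extrema_stats(shifted)
  expect_equal(ex2$per_subject$amplitude, ex$per_subject$amplitude)
})

test_that("a constant REP deficit shows in maxima but not amplitude", {
  set.seed(7)
  base <- tidyr::expand_grid(subject = paste0("S", 1:12), frame = 1:15) |>
    dplyr::mutate(shape = sin((frame - 1) / 14 * pi))
  tc <- dplyr::bind_rows(
    dplyr::mutate(base, condition = "CTRL",
                  psc = shape + rnorm(dplyr::n(), 0, 0.02)),
    dplyr::mutate(base, condition = "REP",
                  psc = shape - 0.5 + rnorm(dplyr::n(), 0, 0.02)))
  tst <- tidy(extrema_stats(tc))
  expect_lt(tst$p_value[tst$measure == "maximum"], 0.001)
  expect_lt(tst$p_value[tst$measure == "minimum"], 0.001)
  expect_gt(tst$p_value[tst$measure == "amplitude"], 0.05)
})

test_that("plateau ratios recover the suppression factor without bias", {
  # factors 1.0 / 0.9 / 0.8 / 0.7; monotone and unbiased within 0.03
  gt <- make_tonotopic_sheet(small_sheet(), seed = 1)
  design <- make_block_design()
  factors <- c(1, 0.9, 0.8, 0.7)
  means <- sapply(factors, function(f) {
    prof <- suppression_profile(factors = c(A1 = f), lead_s = 2)
    mean(sapply(1:25, function(k) {
      coh <- sample_subject_hrfs(9, seed = 8000 + k)
      tcs <- purrr::map_dfr(1:9, function(s)
        simulate_subject_tcs(gt, design, coh$hrf[[s]],
                             seed = 8000 + round(f * 1000) + k * 97 + s,
                             amplitude = coh$amplitude[s], profile = prof))
      plateau_ratio(tcs, roi = "A1")
    }))
  })
  expect_true(all(diff(means) < 0))            # monotone in the factor
  expect_true(all(abs(means - factors) < 0.03))
})

test_that("per-frame type-I error of the contrast is calibrated", {
  # 200 null cohorts: per-frame paired rejection rate within [0.03, 0.07]
  set.seed(8)
  rates <- replicate(200, {
    tc <- null_cohort_tcs(n_sub = 9)
    bf <- tidy(contrast_conditions(tc))
    mean(bf$p_value[bf$frame > 1] < 0.05)
  })
  expect_gte(mean(rates), 0.03)
  expect_lte(mean(rates), 0.07)
})

test_that("the GLM t map separates responsive from silent voxels", {
  gt <- make_tonotopic_sheet(small_sheet(), seed = 1)
  design <- make_block_design(n_blocks_per_condition = 4)
  run <- simulate_repetition_run(gt, design, noise_sd = 0.01,
                                 global_sd = 0, seed = 2)
  g <- glm_sound_vs_rest(run, design)
  expect_gt(min(abs(g$t[gt$label != 0])), 50)
  expect_lt(mean(abs(g$t[gt$label == 0])), 2)
})

test_that("per-voxel GLM t equals the lm oracle to 6 decimals", {
  gt <- make_tonotopic_sheet(small_sheet(), seed = 1)
  design <- make_block_design(n_blocks_per_condition = 2)
  run <- simulate_repetition_run(gt, design, seed = 3)
  g <- glm_sound_vs_rest(run, design)
  flat <- matrix(run$data, prod(dim(run$data)[1:3]), dim(run$data)[4])
  for (v in c(1, which(gt$label == 1)[1], which(gt$label == 5)[1])) {
    fit <- summary(lm(flat[v, ] ~ g$regressor))
    expect_equal(g$t[v], fit$coefficients[2, 3], tolerance = 1e-6)
    expect_equal(g$p[v], fit$coefficients[2, 4], tolerance = 1e-6)
  }
})

test_that("an all-rest design is rejected as degenerate", {
  gt <- make_tonotopic_sheet(small_sheet(), seed = 1)
  design <- make_block_design(n_blocks_per_condition = 1)
  run <- simulate_repetition_run(gt, design, seed = 1)
  empty <- design
  empty$blocks$stim_s <- 0
  expect_error(glm_sound_vs_rest(run, empty), "degenerate")
})

test_that("Bonferroni thresholding controls the family-wise error", {
  # null volumes of 10,000 voxels; FWE at 0.05 across 40 replicates
  design <- make_block_design(n_blocks_per_condition = 2)
  fwe <- sapply(1:40, function(k) {
    set.seed(900 + k)
    run <- volume_series(array(rnorm(100 * 100 * 60), c(100, 100, 1, 60)),
                         tr = 2)
    g <- glm_sound_vs_rest(run, design)
    any(g$significant)
  })
  expect_lte(mean(fwe), 0.05 + 2.5 * sqrt(0.05 * 0.95 / 40))
})
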