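test_that("class posteriors are probabilities that sum to one", {
  m <- make_overlap_model()
  withr::with_seed(2, {
    h <- rpois(nrow(m$P), as.vector(m$P %*% c(2000, 1000)))
  })
  fit <- lpm_fit_tumor(m, h)
  post <- posterior_maps(m, fit)
  sup <- dplyr::filter(post, supported)
  expect_true(all(sup$p_treatment >= 0 & sup$p_treatment <= 1))
  expect_equal(sup$p_treatment + sup$p_control, rep(1, nrow(sup)))
  # histogram-weighted posterior mass reproduces QT at the fixed point
  qt_from_post <- sum(fit$observed[post$supported] *
                        sup$p_treatment)
  expect_equal(qt_from_post, sum(fit$weights[m$classes == "treatment"]),
               tolerance = 1e-3)
})

test_that("bins owned by one class have posterior one for it", {
  m <- make_disjoint_model()
  fit <- lpm_fit_tumor(m, round(1000 * (0.6 * m$P[, 1] + 0.4 * m$P[, 2])))
  post <- posterior_maps(m, fit)
  expect_true(all(post$p_treatment[13:20] == 1))
  expect_true(all(post$p_control[1:8] == 1))
  expect_true(all(!post$supported[9:12]))
})

test_that("zero treatment weight gives QT = 0, Z = 0 and no responder call", {
  m <- make_disjoint_model()
  fit <- lpm_fit_tumor(m, round(800 * m$P[, 1]))
  row <- lpmadc:::assess_fit(fit)
  expect_equal(row$q_treatment, 0)
  expect_equal(row$z, 0)
  expect_equal(row$p_value, 0.5)
  expect_false(row$responder)
})

test_that("decomposition conserves the fitted expectation exactly", {
  m <- make_overlap_model()
  withr::with_seed(3, {
    h <- rpois(nrow(m$P), as.vector(m$P %*% c(1500, 700)))
  })
  tbl <- counts_as_hist(h, m$grid)
  dec <- lpm_decompose(tbl, m)
  expect_equal(dec$affected + dec$unaffected, dec$expected)
  fit <- lpm_fit_tumor(m, tbl)
  expect_equal(sum(dec$affected), sum(fit$weights[m$classes == "treatment"]),
               tolerance = 1e-6)
  expect_equal(sum(dec$unaffected), sum(fit$weights[m$classes == "control"]),
               tolerance = 1e-6)
  # exactly zero treatment weight means an identically zero affected part
  fit0 <- lpm_fit_tumor(m, round(900 * m$P[, 1]))
  fit0$weights[m$classes == "treatment"] <- 0
  dec0 <- lpmadc:::decompose_fit(m, fit0)
  expect_true(all(dec0$affected == 0))
  # and a pure-control histogram attracts almost no treatment mass
  dec1 <- lpm_decompose(counts_as_hist(round(900 * m$P[, 1]), m$grid), m)
  expect_lt(sum(dec1$affected), 0.005 * sum(dec1$unaffected))
})

test_that("summary parameters match their definitions", {
  g <- bin_grid(n_bins = 10, adc_min = 0, adc_max = 1e-3, visits = "V1")
  cells <- grid_cells(g)
  one <- dplyr::mutate(cells, count = ifelse(bin == 4, 50, 0))
  sp <- summary_params(one, voxel_vol = 0.25)
  expect_equal(sp$mean_adc, cells$bin_mid[4])
  expect_equal(sp$p95_adc, cells$bin_mid[4])
  expect_equal(sp$volume, 50 * 0.25)

  # 1000 voxels at the Calu6 geometry occupy 250 mm^3
  many <- dplyr::mutate(cells, count = rep(100, 10))
  expect_equal(summary_params(many, voxel_vol = voxel_volume(0.5, 0.5, 1))$volume,
               250)

  expect_error(summary_params(dplyr::mutate(cells, count = 0)), "zero total")
})

test_that("the binned 95th percentile tracks a sorted-sample oracle", {
  g <- bin_grid(n_bins = 25, adc_min = 0, adc_max = 2.5e-3, visits = "V1")
  cells <- grid_cells(g)
  width <- diff(g$edges[1:2])
  withr::with_seed(6, {
    for (i in 1:10) {
      w <- rpois(25, lambda = rexp(25, 1 / 40))
      if (sum(w) == 0) w[3] <- 10
      tbl <- dplyr::mutate(cells, count = w)
      p95 <- summary_params(tbl)$p95_adc
      sample_expanded <- rep(cells$bin_mid, w)
      oracle <- quantile(sample_expanded, 0.95, type = 1)
      expect_lt(abs(p95 - oracle), width)
    }
  })
})

test_that("the Welch comparator matches the textbook formula", {
  x <- c(1.2, 1.5, 1.1, 1.9); y <- c(2.1, 2.6, 2.2)
  p <- cohort_t_test(x, y)
  # closed-form Welch oracle
  t <- (mean(y) - mean(x)) / sqrt(var(x) / 4 + var(y) / 3)
  df <- (var(x) / 4 + var(y) / 3)^2 /
    ((var(x) / 4)^2 / 3 + (var(y) / 3)^2 / 2)
  expect_equal(p, 2 * pt(-abs(t), df), tolerance = 1e-12)

  expect_equal(cohort_t_test(c(1, 2, 3), c(1, 2, 3)), 1)
  withr::with_seed(1, {
    p_sep <- cohort_t_test(rnorm(4, 0, 1e-4), 1 + rnorm(4, 0, 1e-4))
  })
  expect_lt(p_sep, 1e-6)
  expect_error(cohort_t_test(c(1, 1), c(2, 2)), "zero variance")
  expect_error(cohort_t_test(1, c(2, 3)), "at least 2")
})

test_that("a tumor's QT does not depend on its cohort companions", {
  study <- small_study(seed = 9)
  trt <- dplyr::filter(study$histograms, cohort == "treated")
  m <- study$truth_model$model
  alone <- lpm_assess(dplyr::filter(trt, tumor_id == "T01"), m)
  together <- lpm_assess(trt, m)
  expect_equal(alone$q_treatment,
               together$q_treatment[together$tumor_id == "T01"])
})

test_that("conservation holds: QT + QC equals the fitted voxel count", {
  study <- small_study(seed = 9)
  m <- study$truth_model$model
  asr <- lpm_assess(study$histograms, m)
  expect_equal(asr$q_treatment + asr$q_control, asr$total - asr$excess,
               tolerance = 1e-4)
})
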