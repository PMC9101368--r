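test_that("single-component EM reduces to the pooled-histogram closed form", {
  g <- bin_grid(n_bins = 15, adc_max = 2e-3, visits = "V1")
  withr::with_seed(2, {
    H <- matrix(rpois(15 * 4, lambda = rep(c(40, 10, 80), length.out = 15)),
                nrow = 15, ncol = 4)
  })
  fit <- em_fit(H, k_free = 1, restarts = 2, seed = 1)
  pooled <- rowSums(H) / sum(H)
  expect_equal(as.vector(fit$P), pooled, tolerance = 1e-8)
  expect_equal(as.vector(fit$Q), colSums(H), tolerance = 1e-8)
})

test_that("disjoint-support components are recovered from noise-free data", {
  # the cohort includes pure tumors of each class, which pins the mixture
  # decomposition (without them only the block totals are identified)
  m <- make_disjoint_model()
  Q_true <- rbind(c(1000, 0, 600, 300), c(0, 800, 200, 700))
  H <- m$P %*% Q_true  # expectation-valued histograms
  fit <- em_fit(H, k_free = 2, restarts = 4, seed = 3)
  # fitted expectations reproduce the data, so per-block masses are exact
  # (closed-form partition oracle: each block's weight is its block total)
  M <- fit$P %*% fit$Q
  expect_lt(max(abs(colSums(M[1:8, ]) - colSums(H[1:8, ]))), 1e-3)
  expect_lt(max(abs(colSums(M[13:20, ]) - colSums(H[13:20, ]))), 1e-3)
  # components align with the true blocks and weights are recovered
  ord <- order(apply(fit$P, 2, function(p) sum(p[1:8])), decreasing = TRUE)
  expect_equal(unname(fit$Q[ord, ]), unname(Q_true), tolerance = 5e-3)
})

test_that("EM log-likelihood is monotone non-decreasing on every dataset", {
  datasets <- withr::with_seed(8, list(
    matrix(rpois(40 * 6, 25), 40, 6),
    matrix(rpois(100 * 3, c(rep(5, 50), rep(60, 50))), 100, 3),
    matrix(rpois(30 * 10, 3), 30, 10)
  ))
  for (H in datasets) {
    for (k in c(1, 2, 3)) {
      fit <- em_fit(H, k_free = k, restarts = 3, seed = 5)
      ll <- fit$ll_history
      expect_true(all(diff(ll) >= -1e-6 * (abs(ll[-length(ll)]) + 1)))
      # direct likelihood re-evaluation matches the reported optimum
      expect_equal(lpmadc:::extended_poisson_ll(H, fit$P %*% fit$Q),
                   fit$loglik, tolerance = 1e-10)
      # fixed point: weights sum to the observed totals
      expect_equal(colSums(fit$Q), colSums(H), tolerance = 1e-6)
      # every component PMF sums to one
      expect_equal(unname(colSums(fit$P)), rep(1, k), tolerance = 1e-9)
    }
  }
})

test_that("weights-only fits match a brute-force grid search", {
  m <- make_overlap_model()
  withr::with_seed(13, {
    h <- rpois(nrow(m$P), as.vector(m$P %*% c(1500, 900)))
  })
  wf <- lpmadc:::fit_weights(m$P, h)
  # grid oracle over both weights
  grid_q <- seq(0, 3000, by = 5)
  ll <- outer(grid_q, grid_q, Vectorize(function(q1, q2) {
    lpmadc:::extended_poisson_ll(h, as.vector(m$P %*% c(q1, q2)))
  }))
  best <- arrayInd(which.max(ll), dim(ll))
  expect_lt(abs(unname(wf$weights[1]) - grid_q[best[1]]), 10)
  expect_lt(abs(unname(wf$weights[2]) - grid_q[best[2]]), 10)
})

test_that("fitting a pure-component expectation recovers its weight", {
  m <- make_disjoint_model()
  # the absent component has no information: singular-covariance warning
  fit <- suppressWarnings(lpm_fit_tumor(m, 1000 * m$P[, 1]))
  expect_equal(unname(fit$weights[1]), 1000, tolerance = 1e-3)
  expect_equal(unname(fit$weights[2]), 0, tolerance = 1e-3)
  expect_equal(sum(fit$weights), fit$total, tolerance = 1e-6)
})

test_that("chi-square per d.f. behaves at its extremes", {
  g <- bin_grid(n_bins = 20, adc_max = 2e-3, visits = "V1")
  e <- rep(20, 20)
  expect_equal(chi2_per_df(e, e, n_params = 2, grid = g)$value, 0)
  expect_error(chi2_per_df(e, e, n_params = 20, grid = g),
               "degrees of freedom")

  # a model missing a populated habitat is visibly misspecified
  m <- make_disjoint_model()
  withr::with_seed(4, {
    h <- rpois(20, as.vector(m$P %*% c(1200, 600)))
  })
  wf <- lpmadc:::fit_weights(m$P[, 1, drop = FALSE], h)
  bad <- chi2_per_df(h, wf$expected, n_params = 1, grid = m$grid)
  expect_gt(bad$value, 3)
})

test_that("low-count bins are pooled to the expected floor", {
  g <- bin_grid(n_bins = 12, adc_max = 1e-3, visits = "V1")
  e <- rep(1.2, 12)  # all bins below the floor of 5
  o <- rep(1, 12)
  res <- chi2_per_df(o, e, n_params = 1, grid = g, floor = 5)
  expect_true(all(res$groups$expected >= 5 |
                    seq_len(res$n_groups) == res$n_groups))
  expect_equal(sum(res$groups$observed), sum(o))
  expect_equal(sum(res$groups$expected), sum(e))
})

test_that("leave-one-out selection finds the generating model order", {
  # 1-component truth
  g <- bin_grid(n_bins = 30, adc_max = 3e-3, visits = "V1")
  p <- dgamma(bin_mids(g), shape = 25, scale = 4e-5); p <- p / sum(p)
  withr::with_seed(17, {
    H <- vapply(1:8, function(j) rpois(30, p * runif(1, 800, 1500)),
                numeric(30))
  })
  tbl <- purrr::map_dfr(1:8, function(j)
    counts_as_hist(H[, j], g, sprintf("C%02d", j), "control"))
  sel <- lpm_select_k(tbl, k_range = 1:3, settings = quick_settings(),
                      seed = 2)
  expect_equal(sel$selected_k, 1)
  expect_true(sel$sufficient)

  # LOO fits are no better than training fits on average
  fit1 <- em_fit(H, k_free = 1, restarts = 2, seed = 2)
  train_fits <- vapply(seq_len(ncol(H)), function(j) {
    lpmadc:::loo_score(fit1$P, H[, j], g, quick_settings())
  }, numeric(1))
  expect_gte(mean(sel$curves$loo_fit[sel$curves$k == 1]), mean(train_fits))
})

test_that("a three-habitat truth selects three or four components", {
  g <- bin_grid(n_bins = 60, adc_max = 3e-3, visits = "V1")
  gs <- function(mu, s) {
    d <- dgamma(bin_mids(g), shape = (mu / s)^2, scale = s^2 / mu)
    d / sum(d)
  }
  P <- cbind(gs(0.5e-3, 0.07e-3), gs(1.3e-3, 0.10e-3), gs(2.4e-3, 0.12e-3))
  withr::with_seed(23, {
    tbl <- purrr::map_dfr(1:12, function(j) {
      q <- 4000 * as.vector(lpmadc:::rdirichlet(1, c(2, 2, 2)))
      counts_as_hist(rpois(60, as.vector(P %*% q)), g,
                     sprintf("C%02d", j), "control")
    })
  })
  sel <- lpm_select_k(tbl, k_range = 1:5, settings = quick_settings(),
                      seed = 31)
  expect_true(sel$selected_k %in% c(3, 4))
})

test_that("control training is bit-reproducible", {
  study <- small_study(seed = 6)
  ctrl <- dplyr::filter(study$histograms, cohort == "control")
  st <- quick_settings()
  m1 <- lpm_train_control(ctrl, k = 3, settings = st, seed = 11)
  m2 <- lpm_train_control(ctrl, k = 3, settings = st, seed = 11)
  expect_identical(m1$P, m2$P)
  expect_equal(unname(colSums(m1$P)), rep(1, ncol(m1$P)), tolerance = 1e-9)
  expect_true(all(m1$classes == "control"))
})

test_that("a matched control-only study passes the sufficiency checks", {
  study <- sample_study(make_truth_model(truth_config()), seed = 6)
  ctrl <- dplyr::filter(study$histograms, cohort == "control")
  m <- lpm_train_control(ctrl, k = 3, settings = quick_settings(),
                         seed = 11)
  # Poisson-consistent residuals (Bland-Altman) on a matched model family
  expect_true(isTRUE(m$meta$sufficiency$bland_altman$pass))
  expect_lt(m$meta$sufficiency$fit_value, 1.2)
})

test_that("treatment extension freezes control components bit-for-bit", {
  study <- small_study(seed = 6)
  ctrl <- dplyr::filter(study$histograms, cohort == "control")
  trt <- dplyr::filter(study$histograms, cohort == "treated")
  st <- quick_settings()
  cm <- lpm_train_control(ctrl, k = 3, settings = st, seed = 11)
  fm <- lpm_add_treatment(cm, trt, k = 1, settings = st, seed = 12)
  kc <- ncol(cm$P)
  expect_identical(fm$P[, seq_len(kc)], cm$P)
  expect_equal(fm$classes, c(rep("control", kc), "treatment"))

  # grid mismatch is refused
  other <- dplyr::mutate(trt, bin_low = bin_low * 2, bin_high = bin_high * 2)
  expect_error(lpm_add_treatment(cm, other, k = 1, settings = st, seed = 1),
               "different grid")
})

test_that("a treated cohort with pure control behaviour yields QT near zero", {
  cfg <- truth_config(n_control = 8, n_treated = 5, voxels_per_tumor = 1000,
                      responder_fraction = 0)
  study <- sample_study(make_truth_model(cfg), seed = 19)
  ctrl <- dplyr::filter(study$histograms, cohort == "control")
  trt <- dplyr::filter(study$histograms, cohort == "treated")
  st <- quick_settings()
  cm <- lpm_train_control(ctrl, k = 3, settings = st, seed = 21)
  # the LOO selection finds that no treatment component is needed
  fm <- lpm_add_treatment(cm, trt, k_range = 0:1, settings = st, seed = 22)
  expect_equal(sum(fm$classes == "treatment"), 0)
  asr <- suppressWarnings(lpm_assess(trt, fm, settings = st))
  expect_true(all(asr$z < 3))
  expect_lt(mean(asr$q_treatment / asr$total), 0.05)
})

test_that("an injected treatment habitat is recovered within two sigma", {
  study <- small_study(seed = 6)
  ctrl <- dplyr::filter(study$histograms, cohort == "control")
  trt <- dplyr::filter(study$histograms, cohort == "treated")
  st <- quick_settings()
  cm <- lpm_train_control(ctrl, k = 3, settings = st, seed = 11)
  fm <- lpm_add_treatment(cm, trt, k = 1, settings = st, seed = 12)
  asr <- lpm_assess(trt, fm, settings = st)
  rec <- recovery_report(asr, dplyr::filter(study$truth, cohort == "treated"))
  expect_gte(rec$summary$coverage, 3 / 5)
  expect_lt(rec$summary$median_rel_error, 0.15)
  expect_equal(rec$summary$tp, 5)
})

test_that("near-duplicate components are merged after fitting", {
  P <- cbind(c(0.5, 0.3, 0.2), c(0.5, 0.3, 0.2) + c(1e-5, -1e-5, 0),
             c(0, 0.1, 0.9))
  P <- sweep(P, 2, colSums(P), "/")
  Q <- matrix(c(100, 200, 50), 3, 2)
  merged <- lpmadc:::merge_degenerate(P, Q, rep(TRUE, 3))
  expect_equal(ncol(merged$P), 2)
  expect_equal(colSums(merged$Q), colSums(Q))
})

test_that("degenerate or invalid training inputs are rejected", {
  H <- matrix(rpois(20, 10), 10, 2)
  expect_error(em_fit(H[, 0], k_free = 1), "no histograms")
  expect_error(em_fit(H, k_free = 50), "occupied bins")
  expect_error(em_fit(H, k_free = 1, restarts = 0), "restarts")
})
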