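test_that("noiseless mono-exponential decay is recovered exactly", {
  b <- c(150, 500, 1000)
  f <- fit_adc_voxel(b, 1000 * exp(-b * 1e-3))
  expect_equal(f$adc, 1e-3, tolerance = 1e-9)
  expect_equal(f$s0, 1000, tolerance = 1e-6)
  expect_false(f$clipped)

  # flat decay has zero diffusivity
  expect_equal(fit_adc_voxel(b, c(500, 500, 500))$adc, 0)

  # exact recovery holds for any D >= 0, S0 > 0
  withr::with_seed(7, {
    for (i in 1:20) {
      d0 <- runif(1, 0, 3e-3); s0 <- runif(1, 10, 5000)
      f <- fit_adc_voxel(b, s0 * exp(-b * d0))
      expect_equal(f$adc, d0, tolerance = 1e-9)
    }
  })
})

test_that("a rising signal is clipped to zero ADC and flagged", {
  f <- fit_adc_voxel(c(150, 500, 1000), c(100, 110, 130))
  expect_equal(f$adc, 0)
  expect_true(f$clipped)
})

test_that("invalid voxel signals are rejected", {
  expect_error(fit_adc_voxel(c(500, 500), c(100, 90)), "distinct b")
  expect_error(fit_adc_voxel(c(150, 500), c(100, -3)), "positive")
  expect_error(fit_adc_voxel(c(-10, 500), c(100, 90)), "non-negative")
})

test_that("noisy ADC fits agree with a brute-force log-residual search", {
  # oracle: 1-D grid search over D minimising the squared log-residual
  # (profiling out log S0 at its closed-form optimum)
  oracle <- function(b, s) {
    dd <- seq(0, 2e-3, by = 1e-7)
    sse <- vapply(dd, function(d) {
      r <- log(s) + b * d
      sum((r - mean(r))^2)
    }, numeric(1))
    dd[which.min(sse)]
  }
  b <- c(150, 500, 1000)
  withr::with_seed(42, {
    for (i in 1:5) {
      s <- 1200 * exp(-b * 0.8e-3) * exp(rnorm(3, sd = 0.01))
      # oracle is exact to half its grid step
      expect_lt(abs(fit_adc_voxel(b, s)$adc - oracle(b, s)), 1e-7)
    }
  })
})

test_that("the data-frame ADC interface fits within id groups", {
  b <- c(150, 500, 1000)
  tbl <- tidyr::expand_grid(voxel = c("a", "b"), b = b) |>
    dplyr::mutate(signal = ifelse(voxel == "a",
                                  900 * exp(-b * 0.5e-3),
                                  400 * exp(-b * 1.5e-3)))
  out <- fit_adc(tbl)
  expect_equal(nrow(out), 2)
  expect_equal(out$adc[out$voxel == "a"], 0.5e-3, tolerance = 1e-9)
  expect_equal(out$adc[out$voxel == "b"], 1.5e-3, tolerance = 1e-9)
})

test_that("binning respects half-open bins and conserves every value", {
  g <- bin_grid(n_bins = 10, adc_min = 0, adc_max = 1e-3, visits = "V1")
  # values exactly at lower edges land in their own bin
  h <- build_histogram(g$edges[1:10], g, "V1")
  expect_equal(h$count, rep(1, 10))
  expect_equal(attr(h, "overflow"), 0)

  # 100 values inside one bin
  h <- build_histogram(runif(100, 3.0e-4, 3.9e-4), g, "V1")
  expect_equal(h$count[4], 100)
  expect_equal(sum(h$count), 100)

  # conservation against an independent sort-and-count oracle
  withr::with_seed(11, {
    x <- runif(500, -2e-4, 1.3e-3)  # includes out-of-range values
    h <- build_histogram(x, g, "V1")
    oracle <- vapply(seq_len(10), function(i) {
      if (i < 10) sum(x >= g$edges[i] & x < g$edges[i + 1])
      else sum(x >= g$edges[10] & x <= g$edges[11])
    }, numeric(1))
    expect_equal(h$count, oracle)
    expect_equal(sum(h$count) + attr(h, "overflow"), length(x))
  })
})

test_that("an empty voxel list yields a zero histogram with a warning", {
  g <- bin_grid(n_bins = 5, adc_max = 1e-3, visits = "V1")
  expect_warning(h <- build_histogram(numeric(0), g, "V1"), "zero histogram")
  expect_equal(sum(h$count), 0)
})

test_that("visit assembly conserves counts and honours ordering", {
  g <- bin_grid(n_bins = 6, adc_max = 1e-3, visits = c("V1", "V2", "V3"))
  withr::with_seed(3, {
    counts <- rpois(lpmadc:::n_cells(g), 30)
  })
  tbl <- counts_as_hist(counts, g)

  one <- assemble_tumor_histogram(tbl, "V1")
  expect_equal(one$count, tbl$count[tbl$visit == "V1"])

  two <- assemble_tumor_histogram(tbl, c("V1", "V3"))
  expect_equal(sum(two$count),
               sum(tbl$count[tbl$visit %in% c("V1", "V3")]))

  # permuted subsets carry the same multiset of counts, laid out differently
  ab <- assemble_tumor_histogram(tbl, c("V1", "V2"))
  ba <- assemble_tumor_histogram(tbl, c("V2", "V1"))
  expect_equal(sort(ab$count), sort(ba$count))
  expect_equal(ab$count,
               c(ba$count[ba$visit == "V1"], ba$count[ba$visit == "V2"]))
  expect_false(identical(ab$count, ba$count) &&
                 !all(ab$count[ab$visit == "V1"] ==
                        ab$count[ab$visit == "V2"]))

  expect_error(assemble_tumor_histogram(tbl, c("V1", "V9")), "V9")
})

test_that("voxel volumes match the acquisition geometries", {
  expect_equal(voxel_volume(0.5, 0.5, 1.0), 0.25)
  expect_equal(voxel_volume(0.4, 0.4, 1.2), 0.192)
  expect_equal(voxel_volume(1, 1, 1), 1)
  expect_error(voxel_volume(0, 0.4, 1), "positive")
})

test_that("raw ADC tables produce complete per-tumor histograms", {
  g <- bin_grid(n_bins = 8, adc_max = 2e-3, visits = c("V1", "V2"))
  withr::with_seed(5, {
    raw <- tidyr::expand_grid(tumor_id = c("A", "B"),
                              visit = c("V1", "V2")) |>
      dplyr::mutate(vals = purrr::map(dplyr::row_number(),
                                      ~runif(50, 0, 2e-3))) |>
      tidyr::unnest("vals") |>
      dplyr::rename(adc_value = "vals")
  })
  out <- adc_to_histograms(raw, g)
  expect_equal(nrow(out), 2 * lpmadc:::n_cells(g))
  expect_equal(sum(out$count) + attr(out, "overflow"), nrow(raw))
})

test_that("masked NIfTI volumes round-trip into ADC values", {
  skip_if_not_installed("RNifti")
  dir <- withr::local_tempdir()
  withr::with_seed(9, {
    adc <- array(runif(4 * 4 * 2, 0, 3e-3), dim = c(4, 4, 2))
    mask <- array(0L, dim = c(4, 4, 2)); mask[2:3, 2:3, 1] <- 1L
  })
  ap <- file.path(dir, "adc.nii.gz"); mp <- file.path(dir, "mask.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(adc), ap)
  RNifti::writeNifti(RNifti::asNifti(mask), mp)
  vals <- read_adc_nifti(ap, mp)
  expect_equal(sort(vals), sort(as.numeric(adc[mask != 0])),
               tolerance = 1e-6)
})
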