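# shared fixtures, built in code

# convergence controls for tests (study conditions live in truth_config())
quick_settings <- function(restarts = 4L, max_iter = 500L, tol = 1e-7) {
  lpm_settings(restarts = restarts, max_iter = max_iter, tol = tol)
}

# two components with exactly disjoint support on a 20-bin single-visit grid
make_disjoint_model <- function() {
  g <- bin_grid(n_bins = 20, adc_min = 0, adc_max = 2e-3, visits = "V1")
  pc <- rep(0, 20); pc[1:8] <- 1 / 8
  pt <- rep(0, 20); pt[13:20] <- 1 / 8
  lpmadc:::new_lpm_model(cbind(pc, pt), c("control", "treatment"), g)
}

# strongly overlapping control/treatment pair (high-ambiguity regime)
make_overlap_model <- function() {
  g <- bin_grid(n_bins = 60, adc_min = 0, adc_max = 3e-3, visits = "V1")
  gshape <- function(mu, s) {
    d <- dgamma(bin_mids(g), shape = (mu / s)^2, scale = s^2 / mu)
    d / sum(d)
  }
  lpmadc:::new_lpm_model(cbind(gshape(1.0e-3, 0.30e-3),
                               gshape(1.4e-3, 0.30e-3)),
                         c("control", "treatment"), g)
}

# well-separated two-habitat model used for error-propagation checks
make_separated_model <- function() {
  g <- bin_grid(n_bins = 100, adc_min = 0, adc_max = 3e-3, visits = "V1")
  gshape <- function(mu, s) {
    d <- dgamma(bin_mids(g), shape = (mu / s)^2, scale = s^2 / mu)
    d / sum(d)
  }
  lpmadc:::new_lpm_model(cbind(gshape(0.8e-3, 0.15e-3),
                               gshape(2.2e-3, 0.15e-3)),
                         c("control", "treatment"), g)
}

# two-visit variant of the separated model: the treatment habitat appears
# only at the second visit (used where visit-to-visit changes matter)
make_separated_model_2v <- function() {
  g <- bin_grid(n_bins = 50, adc_min = 0, adc_max = 3e-3,
                visits = c("V1", "V2"))
  gshape <- function(mu, s) {
    d <- dgamma(bin_mids(g), shape = (mu / s)^2, scale = s^2 / mu)
    d / sum(d)
  }
  pc <- as.vector(outer(gshape(0.8e-3, 0.15e-3), c(0.5, 0.5)))
  pt <- as.vector(outer(gshape(2.2e-3, 0.15e-3), c(0, 1)))
  lpmadc:::new_lpm_model(cbind(pc, pt), c("control", "treatment"), g)
}

# histogram tibble for one tumor from a counts vector on a model's grid
counts_as_hist <- function(counts, grid, tumor_id = "T1", cohort = "treated") {
  lpmadc:::hist_tibble(counts, grid, tumor_id, cohort)
}

# small synthetic study for pipeline unit tests (fewer tumors/voxels than
# the default study conditions, which the acceptance tests use)
small_study <- function(seed = 1) {
  cfg <- truth_config(n_control = 8, n_treated = 5, voxels_per_tumor = 1000)
  truth <- make_truth_model(cfg)
  c(sample_study(truth, seed = seed), list(truth_model = truth))
}
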