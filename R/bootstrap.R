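#' Bootstrap standard error of the treatment-attributed count
#'
#' Nonparametric check on the propagated (Fisher-information) standard
#' error of QT: bin counts are resampled and the weights refitted, and the
#' standard deviation of the resampled QT estimates is returned. The
#' resampled total follows a Poisson law (voxels drawn with replacement
#' from the empirical bin distribution with a Poisson-distributed total,
#' equivalent to independent Poisson draws per bin), matching the extended
#' Poisson likelihood under which the total count is itself informative.
#'
#' @param model An `lpm_model`.
#' @param fit A `tumor_fit` against `model`.
#' @param n_boot Number of resamples (default 200).
#' @param seed Integer seed.
#' @param settings [lpm_settings()].
#' @return A list with `sd_qt` (bootstrap SD), `qt` (resampled estimates)
#'   and `sigma_fisher` (the propagated SE, for comparison).
#' @export
bootstrap_sigma <- function(model, fit, n_boot = 200, seed = 1L,
                            settings = lpm_settings()) {
  stopifnot(inherits(fit, "tumor_fit"))
  tr <- model$classes == "treatment"
  h <- fit$observed
  qt <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      hb <- rpois(length(h), h)
      wf <- fit_weights(model$P, hb, max_iter = settings$max_iter,
                        tol = settings$tol)
      sum(wf$weights[tr])
    }, numeric(1))
  })
  u <- as.numeric(tr)
  list(sd_qt = sd(qt), qt = qt,
       sigma_fisher = sqrt(max(drop(t(u) %*% fit$covariance %*% u), 0)))
}
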