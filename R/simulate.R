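#' Monte Carlo cohort simulation settings
#'
#' @param n_cohort Total cohort size N.
#' @param n_responders Number of responding tumors n (0 \eqn{\le} n
#'   \eqn{\le} N).
#' @param cohorts_per_setting Replicate cohorts per setting (default 10).
#' @param thresholds p-value detection thresholds, each in (0, 1).
#' @param deviation_fraction Maximum relative weight perturbation when
#'   interpolating between base tumors (\eqn{\le} 0.5).
#' @param seed Integer seed.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_cohort, n_responders,
                            cohorts_per_setting = 10,
                            thresholds = c(0.05, 0.01, 0.001),
                            deviation_fraction = 0.5, seed = 1L) {
  if (n_responders < 0 || n_responders > n_cohort) {
    abort("n_responders must satisfy 0 <= n <= N")
  }
  if (any(thresholds <= 0 | thresholds >= 1)) {
    abort("thresholds must lie in (0, 1)")
  }
  if (deviation_fraction < 0 || deviation_fraction > 0.5) {
    abort("deviation_fraction must lie in [0, 0.5]")
  }
  structure(list(n_cohort = as.integer(n_cohort),
                 n_responders = as.integer(n_responders),
                 cohorts_per_setting = as.integer(cohorts_per_setting),
                 thresholds = sort(thresholds, decreasing = TRUE),
                 deviation_fraction = deviation_fraction,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

fits_to_weights <- function(fits, model) {
  if (inherits(fits, "tumor_fit")) fits <- list(fits)
  if (is.matrix(fits)) {
    stopifnot(nrow(fits) == ncol(model$P))
    return(fits)
  }
  W <- vapply(fits, function(f) {
    stopifnot(inherits(f, "tumor_fit"),
              length(f$weights) == ncol(model$P))
    unname(f$weights)
  }, numeric(ncol(model$P)))
  W
}

# one synthetic weight vector from a pair of base weight vectors:
# uniform interpolation between the pair, then a uniform relative
# perturbation of at most `deviation`, clipped at zero
interp_weights <- function(w_a, w_b, deviation) {
  u <- runif(length(w_a))
  w <- w_a + u * (w_b - w_a)
  pmax(w * runif(length(w), 1 - deviation, 1 + deviation), 0)
}

synth_counts <- function(P, w) {
  lam <- as.vector(P %*% w)
  rpois(length(lam), lam)
}

#' Synthesize one histogram from a pair of fitted tumors
#'
#' Mixing weights are drawn uniformly between the pair's fitted weights,
#' perturbed by at most `deviation` of their value, and used to form
#' expected counts from the model PMFs; each bin is then sampled with a
#' Poisson random number generator. Randomness comes from the current RNG
#' state (seed at the caller).
#'
#' @param model An `lpm_model`.
#' @param fit_a,fit_b `tumor_fit` objects (or weight vectors) on `model`.
#' @param deviation Maximum relative weight perturbation (\eqn{\le} 0.5).
#' @param tumor_id,cohort Identifiers for the output tibble.
#' @return A histogram tibble with attributes `weights` (the realised
#'   mixing weights) and `qt_true` (their treatment-class sum).
#' @export
synthesize_histogram <- function(model, fit_a, fit_b, deviation = 0.5,
                                 tumor_id = "sim", cohort = "sim") {
  get_w <- function(f) {
    if (inherits(f, "tumor_fit")) {
      if (length(f$weights) != ncol(model$P)) {
        abort("fit was made against a different model")
      }
      unname(f$weights)
    } else {
      stopifnot(length(f) == ncol(model$P))
      as.numeric(f)
    }
  }
  w <- interp_weights(get_w(fit_a), get_w(fit_b), deviation)
  counts <- synth_counts(model$P, w)
  out <- hist_tibble(counts, model$grid, tumor_id, cohort)
  attr(out, "weights") <- w
  attr(out, "qt_true") <- sum(w[model$classes == "treatment"])
  out
}

#' Build labelled simulated cohorts
#'
#' For each replicate, three cohorts are generated from randomly selected
#' base-tumor pairs: a reference control cohort and a null test cohort
#' (control-derived tumors only), and a treatment cohort with exactly
#' `n_responders` responder-derived and `N - n_responders` control-derived
#' tumors. Truth labels are retained per tumor.
#'
#' @param spec A [simulation_spec()].
#' @param model The `lpm_model` the base fits were made against.
#' @param control_fits,responder_fits Lists of `tumor_fit`s (or weight
#'   matrices, components x tumors) for the base pools.
#' @return A tibble with one row per simulated tumor: `replicate`, `role`
#'   (`reference` / `null` / `treatment`), `tumor`, `is_responder`,
#'   `qt_true` and the `counts` list-column.
#' @export
build_sim_cohorts <- function(spec, model, control_fits, responder_fits) {
  stopifnot(inherits(spec, "simulation_spec"))
  Wc <- fits_to_weights(control_fits, model)
  Wr <- fits_to_weights(responder_fits, model)
  if (ncol(Wc) == 0) abort("control base pool is empty")
  if (spec$n_responders > 0 && ncol(Wr) == 0) {
    abort("responder base pool is empty")
  }
  tr <- model$classes == "treatment"
  draw <- function(W, responder, replicate, role, idx) {
    pair <- sample.int(ncol(W), 2, replace = TRUE)
    w <- interp_weights(W[, pair[1]], W[, pair[2]], spec$deviation_fraction)
    tibble::tibble(replicate = replicate, role = role, tumor = idx,
                   is_responder = responder,
                   qt_true = sum(w[tr]),
                   counts = list(synth_counts(model$P, w)))
  }
  withr::with_seed(spec$seed, {
    purrr::map_dfr(seq_len(spec$cohorts_per_setting), function(r) {
      dplyr::bind_rows(
        purrr::map_dfr(seq_len(spec$n_cohort), function(i)
          draw(Wc, FALSE, r, "reference", i)),
        purrr::map_dfr(seq_len(spec$n_cohort), function(i)
          draw(Wc, FALSE, r, "null", i)),
        purrr::map_dfr(seq_len(spec$n_cohort), function(i) {
          if (i <= spec$n_responders) draw(Wr, TRUE, r, "treatment", i)
          else draw(Wc, FALSE, r, "treatment", i)
        })
      )
    })
  })
}

tumor_sim_metrics <- function(counts, model, settings) {
  wf <- fit_weights(model$P, counts, max_iter = settings$max_iter,
                    tol = settings$tol)
  tr <- model$classes == "treatment"
  qt <- sum(wf$weights[tr])
  cov <- weight_covariance(model$P, counts, wf$weights)
  u <- as.numeric(tr)
  sigma <- sqrt(max(drop(t(u) %*% cov %*% u), 0))
  z <- if (qt <= 0) 0 else if (sigma == 0) Inf else qt / sigma
  cells <- grid_cells(model$grid)
  first_v <- model$grid$visits[1]
  last_v <- dplyr::last(model$grid$visits)
  per_visit <- function(v) {
    sel <- cells$visit == v
    list(n = sum(counts[sel]),
         mean = if (sum(counts[sel]) > 0)
           sum(cells$bin_mid[sel] * counts[sel]) / sum(counts[sel])
         else NA_real_,
         p95 = if (sum(counts[sel]) > 0)
           dist_quantile(cells$bin_mid[sel], counts[sel], 0.95)
         else NA_real_)
  }
  a <- per_visit(first_v); b <- per_visit(last_v)
  tibble::tibble(z = z, p = pnorm(z, lower.tail = FALSE),
                 d_volume = b$n - a$n, d_mean = b$mean - a$mean,
                 d_p95 = b$p95 - a$p95)
}

#' True/false positive rates of response detection across methods
#'
#' Scores simulated cohorts with the per-tumor LPM Z test, a cohort-level
#' LPM test (Bonferroni minimum p across the cohort's tumors), and Welch
#' t-tests on per-tumor changes (last visit minus first) in volume, mean
#' ADC and 95th-percentile ADC against the paired reference control
#' cohort. True positive rates come from the treatment cohorts (per-tumor
#' LPM: fraction of truly responding tumors detected; cohort-level
#' methods: fraction of treatment cohorts detected); false positive rates
#' come from the null cohorts.
#'
#' @param cohorts Output of [build_sim_cohorts()].
#' @param model The `lpm_model` used for fitting.
#' @param thresholds p-value thresholds (default 0.05, 0.01, 0.001).
#' @param settings [lpm_settings()].
#' @return A tidy tibble: `method`, `level`, `threshold`, `tpr`, `fpr`,
#'   `n_true`, `n_null`.
#' @export
evaluate_tpr <- function(cohorts, model,
                         thresholds = c(0.05, 0.01, 0.001),
                         settings = lpm_settings()) {
  metrics <- cohorts |>
    dplyr::mutate(m = purrr::map(.data$counts, tumor_sim_metrics,
                                 model = model, settings = settings)) |>
    tidyr::unnest("m")

  welch_p <- function(x, y) {
    if (length(x) < 2 || length(y) < 2 ||
        (var(x) == 0 && var(y) == 0)) return(NA_real_)
    t.test(y, x, var.equal = FALSE)$p.value
  }
  cohort_tests <- metrics |>
    dplyr::group_by(.data$replicate) |>
    dplyr::group_map(function(d, key) {
      ref <- dplyr::filter(d, .data$role == "reference")
      purrr::map_dfr(c("null", "treatment"), function(role) {
        coh <- dplyr::filter(d, .data$role == .env$role)
        tibble::tibble(
          replicate = key$replicate, role = role,
          p_lpm_cohort = min(1, nrow(coh) * min(coh$p)),
          p_t_volume = welch_p(ref$d_volume, coh$d_volume),
          p_t_mean = welch_p(ref$d_mean, coh$d_mean),
          p_t_p95 = welch_p(ref$d_p95, coh$d_p95))
      })
    }) |>
    dplyr::bind_rows()

  purrr::map_dfr(thresholds, function(thr) {
    tum_true <- metrics |>
      dplyr::filter(.data$role == "treatment", .data$is_responder)
    tum_null <- metrics |> dplyr::filter(.data$role == "null")
    coh_true <- dplyr::filter(cohort_tests, .data$role == "treatment")
    coh_null <- dplyr::filter(cohort_tests, .data$role == "null")
    rate <- function(p) if (length(p[!is.na(p)]) == 0) NA_real_
                        else mean(p < thr, na.rm = TRUE)
    dplyr::bind_rows(
      tibble::tibble(method = "lpm_tumor", level = "tumor",
                     threshold = thr,
                     tpr = rate(tum_true$p), fpr = rate(tum_null$p),
                     n_true = nrow(tum_true), n_null = nrow(tum_null)),
      purrr::map_dfr(c(lpm_cohort = "p_lpm_cohort",
                       t_volume = "p_t_volume", t_mean = "p_t_mean",
                       t_p95 = "p_t_p95"),
                     function(col) {
                       tibble::tibble(threshold = thr,
                                      tpr = rate(coh_true[[col]]),
                                      fpr = rate(coh_null[[col]]),
                                      n_true = nrow(coh_true),
                                      n_null = nrow(coh_null))
                     }, .id = "method") |>
        dplyr::mutate(level = "cohort", .after = "method")
    )
  })
}

#' @rdname evaluate_tpr
#' @param data A TPR table from [evaluate_tpr()] (optionally with extra
#'   setting columns from a sweep).
#' @export
plot_tpr <- function(data) {
  ggplot(data, aes(x = factor(.data$threshold), y = .data$tpr,
                   colour = .data$method, group = .data$method)) +
    geom_line() + geom_point() +
    scale_x_discrete(limits = rev(levels(factor(data$threshold)))) +
    labs(x = "p-value threshold", y = "true positive rate",
         colour = NULL, title = "Detection power vs significance threshold") +
    theme_minimal()
}
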