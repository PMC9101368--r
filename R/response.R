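#' Per-cell class posteriors for a fitted tumor
#'
#' Combines the fitted control and treatment expectations with Bayes'
#' theorem to give, per (ADC bin, visit) cell, the probability that a count
#' in that cell belongs to treatment-specific rather than control-like
#' behaviour. Cells with zero model mass have undefined posteriors and are
#' flagged `supported = FALSE`.
#'
#' @param model An `lpm_model` with both classes.
#' @param fit A [lpm_fit_tumor()] result against `model`.
#' @return A tibble over grid cells with `m_control`, `m_treatment`,
#'   `p_control`, `p_treatment` and `supported`.
#' @export
posterior_maps <- function(model, fit) {
  stopifnot(inherits(fit, "tumor_fit"))
  tr <- model$classes == "treatment"
  m_t <- as.vector(model$P[, tr, drop = FALSE] %*% fit$weights[tr])
  m_c <- as.vector(model$P[, !tr, drop = FALSE] %*% fit$weights[!tr])
  m <- m_t + m_c
  supported <- m > 0
  grid_cells(model$grid) |>
    dplyr::mutate(m_control = m_c, m_treatment = m_t,
                  p_control = ifelse(supported, m_c / m, NA_real_),
                  p_treatment = ifelse(supported, m_t / m, NA_real_),
                  supported = supported)
}

assess_fit <- function(fit, z_threshold = 3) {
  tr <- fit$classes == "treatment"
  qt <- sum(fit$weights[tr])
  qc <- sum(fit$weights[!tr])
  u <- as.numeric(tr)
  var_qt <- drop(t(u) %*% fit$covariance %*% u)
  sigma <- sqrt(max(var_qt, 0))
  z <- if (qt <= 0) 0 else if (sigma == 0) Inf else qt / sigma
  p <- pnorm(z, lower.tail = FALSE)
  tibble::tibble(tumor_id = fit$tumor_id, cohort = fit$cohort,
                 total = fit$total, q_treatment = qt, q_control = qc,
                 sigma = sigma, z = z, p_value = p,
                 responder = z > z_threshold,
                 chi2_per_df = fit$chi2_per_df, excess = fit$excess)
}

#' Assess treatment response for a cohort of tumors
#'
#' Fits each tumor's histogram against a trained model (weights only) and
#' derives the per-tumor response readouts: the treatment-attributed voxel
#' count QT (a lower bound on affected volume), its propagated standard
#' error from the weight covariance, the Z-score QT/sigma, a one-sided
#' normal p-value, and the responder call at the Z threshold. When a voxel
#' volume is supplied, summary parameters of the affected and unaffected
#' sub-distributions at the last visit are appended.
#'
#' @param data Histogram tibble (one or more tumors on the model grid).
#' @param model A full `lpm_model` (control + treatment components).
#' @param z_threshold Responder threshold on the Z-score (default 3).
#' @param voxel_vol Optional voxel volume in mm\eqn{^3} for volume columns.
#' @param settings [lpm_settings()].
#' @return A tibble with one row per tumor; the underlying `tumor_fit`
#'   objects are kept in the `fit` list-column.
#' @export
lpm_assess <- function(data, model, z_threshold = 3, voxel_vol = NULL,
                       settings = lpm_settings()) {
  data <- check_hist_tbl(data)
  ids <- unique(data$tumor_id)
  rows <- purrr::map_dfr(ids, function(id) {
    fit <- lpm_fit_tumor(model, dplyr::filter(data, .data$tumor_id == id),
                         settings = settings)
    row <- assess_fit(fit, z_threshold = z_threshold)
    row$visits_used <- paste(model$grid$visits, collapse = "+")
    row$fit <- list(fit)
    if (!is.null(voxel_vol)) {
      dec <- decompose_fit(model, fit)
      last <- dec |> dplyr::filter(.data$visit ==
                                     dplyr::last(model$grid$visits))
      row$affected_volume_mm3 <- sum(last$affected) * voxel_vol
      sa <- if (sum(last$affected) > 0) {
        summary_params(last, mass = "affected", voxel_vol = voxel_vol)
      } else tibble::tibble(mean_adc = NA_real_, p95_adc = NA_real_)
      su <- summary_params(last, mass = "unaffected", voxel_vol = voxel_vol)
      row$mean_affected <- sa$mean_adc; row$p95_affected <- sa$p95_adc
      row$mean_unaffected <- su$mean_adc; row$p95_unaffected <- su$p95_adc
    }
    row
  })
  rows
}

decompose_fit <- function(model, fit) {
  tr <- model$classes == "treatment"
  affected <- as.vector(model$P[, tr, drop = FALSE] %*% fit$weights[tr])
  unaffected <- as.vector(model$P[, !tr, drop = FALSE] %*% fit$weights[!tr])
  grid_cells(model$grid) |>
    dplyr::mutate(tumor_id = fit$tumor_id, observed = fit$observed,
                  affected = affected, unaffected = unaffected,
                  expected = affected + unaffected) |>
    dplyr::select("tumor_id", "visit", "bin", "bin_low", "bin_high",
                  "bin_mid", "observed", "affected", "unaffected",
                  "expected")
}

#' Decompose tumor distributions into affected and unaffected parts
#'
#' Splits each tumor's fitted expectation into the treatment-attributed
#' sub-distribution (`affected` = \eqn{\sum_t P(A,V|t) Q_t}) and the
#' control-like sub-distribution (`unaffected` = \eqn{\sum_c P(A,V|c) Q_c});
#' the two sum bin-wise to the fitted expectation, and their integrals are
#' QT and QC.
#'
#' @inheritParams lpm_assess
#' @return A tibble over (tumor, visit, bin) with `observed`, `affected`,
#'   `unaffected` and `expected` columns.
#' @export
lpm_decompose <- function(data, model, settings = lpm_settings()) {
  data <- check_hist_tbl(data)
  purrr::map_dfr(unique(data$tumor_id), function(id) {
    fit <- lpm_fit_tumor(model, dplyr::filter(data, .data$tumor_id == id),
                         settings = settings)
    decompose_fit(model, fit)
  })
}

#' Summary parameters of an ADC distribution
#'
#' Computes the conventional summary parameters (mean ADC, 95th percentile
#' and volume) of a binned distribution — the whole-tumor histogram or an
#' LPM-decomposed sub-distribution. The mean is the mass-weighted bin
#' centre; the 95th percentile interpolates the inverse CDF through the
#' (bin centre, cumulative fraction) points; the volume is the total mass
#' times the voxel volume.
#'
#' @param data A (optionally grouped) data frame with a `bin_mid` column
#'   and a mass column.
#' @param mass Name of the mass column (e.g. `"count"`, `"affected"`).
#' @param voxel_vol Voxel volume in mm\eqn{^3}.
#' @return A tibble with `mean_adc`, `p95_adc` (mm\eqn{^2}/s) and `volume`
#'   (mm\eqn{^3}), one row per group.
#' @export
summary_params <- function(data, mass = "count", voxel_vol = 1) {
  stopifnot("bin_mid" %in% names(data), mass %in% names(data))
  data |>
    dplyr::summarise(
      mean_adc = {
        w <- .data[[mass]]
        if (sum(w) <= 0) abort("distribution has zero total mass")
        sum(.data$bin_mid * w) / sum(w)
      },
      p95_adc = dist_quantile(.data$bin_mid, .data[[mass]], 0.95),
      volume = sum(.data[[mass]]) * .env$voxel_vol,
      .groups = "drop")
}

# inverse CDF through (bin centre, cumulative fraction) points
dist_quantile <- function(mids, w, p) {
  keep <- w > 0
  mids <- mids[keep]; w <- w[keep]
  cf <- cumsum(w) / sum(w)
  if (length(mids) == 1 || p <= cf[1]) return(mids[1])
  approx(cf, mids, xout = p, rule = 2, ties = "ordered")$y
}

#' Welch two-sample t-test comparator
#'
#' The conventional cohort-level comparison: a two-sided Welch t-test
#' between control and treated summary-parameter values.
#'
#' @param control_values,treated_values Numeric vectors (\eqn{\ge} 2 each).
#' @return The two-sided p-value.
#' @export
cohort_t_test <- function(control_values, treated_values) {
  if (length(control_values) < 2 || length(treated_values) < 2) {
    abort("at least 2 values per group are required")
  }
  if (var(control_values) == 0 && var(treated_values) == 0) {
    abort("zero variance in both groups")
  }
  t.test(treated_values, control_values, var.equal = FALSE)$p.value
}

#' Stacked per-tumor response bars
#'
#' Plots each tumor's affected (QT) and unaffected (QC) voxel counts with
#' the QT error bar, one bar per tumor.
#'
#' @param assessment The tibble returned by [lpm_assess()].
#' @return A ggplot.
#' @export
plot_assessment <- function(assessment) {
  long <- assessment |>
    dplyr::select("tumor_id", "cohort", "q_treatment", "q_control",
                  "sigma") |>
    tidyr::pivot_longer(c("q_treatment", "q_control"),
                        names_to = "part", values_to = "voxels") |>
    dplyr::mutate(part = ifelse(.data$part == "q_treatment",
                                "affected (QT)", "unaffected (QC)"))
  ggplot(long, aes(x = .data$tumor_id, y = .data$voxels,
                   fill = .data$part)) +
    geom_col(position = "stack", colour = "grey30", linewidth = 0.2) +
    geom_errorbar(data = assessment,
                  aes(x = .data$tumor_id,
                      ymin = pmax(.data$q_treatment - .data$sigma, 0),
                      ymax = .data$q_treatment + .data$sigma),
                  inherit.aes = FALSE, width = 0.3) +
    scale_fill_manual(values = c("affected (QT)" = "white",
                                 "unaffected (QC)" = "grey70")) +
    labs(x = NULL, y = "voxels", fill = NULL,
         title = "Per-tumor affected and unaffected volumes") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}
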