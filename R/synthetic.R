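#' Configuration of a synthetic multi-habitat ADC study
#'
#' Defines the ground truth for a simulated multi-visit ADC histogram
#' study: control tumors are mixtures of natural-history habitats
#' (discretised gamma-shaped modes with per-visit mass splits and
#' Dirichlet-distributed between-tumor weights), and responding treated
#' tumors additionally contain a treatment habitat — a high-ADC mode
#' appearing at later visits — with a known affected voxel count, so that
#' estimates of QT can be scored against truth.
#'
#' The defaults emulate a small preclinical radiotherapy study: 15 control
#' and 9 treated tumors, 2000 voxels per tumor imaged at two visits, two
#' viable low-ADC habitats with different growth trajectories plus a
#' necrotic mid-ADC habitat, and a treatment habitat at high ADC affecting
#' 30–70% of a responder's voxels.
#'
#' @param n_control,n_treated Cohort sizes.
#' @param voxels_per_tumor Voxels per tumor per visit (expected).
#' @param grid A [bin_grid()] (visits taken from it).
#' @param control_components Data frame with columns `mean`, `sd` (ADC in
#'   mm\eqn{^2}/s) and `split` (list of per-visit mass fractions).
#' @param treatment_component One-row data frame of the same shape.
#' @param weight_alpha Dirichlet concentration parameters for the
#'   between-tumor control habitat weights (length = control components).
#' @param responder_fraction Fraction of treated tumors that truly respond
#'   (F_true).
#' @param affected_range Range of the per-responder affected voxel
#'   fraction.
#' @param size_jitter Half-width of the uniform per-tumor size factor.
#' @return A list of class `truth_config`.
#' @export
truth_config <- function(n_control = 15, n_treated = 9,
                         voxels_per_tumor = 2000,
                         grid = bin_grid(visits = c("V1", "V2")),
                         control_components = default_control_components(),
                         treatment_component = default_treatment_component(),
                         weight_alpha = c(1.6, 1.4, 1.0),
                         responder_fraction = 1,
                         affected_range = c(0.3, 0.7),
                         size_jitter = 0.15) {
  stopifnot(responder_fraction >= 0, responder_fraction <= 1,
            voxels_per_tumor > 0,
            all(affected_range >= 0), all(affected_range <= 1),
            length(weight_alpha) == nrow(control_components))
  structure(list(n_control = n_control, n_treated = n_treated,
                 voxels_per_tumor = voxels_per_tumor, grid = grid,
                 control_components = control_components,
                 treatment_component = treatment_component,
                 weight_alpha = weight_alpha,
                 responder_fraction = responder_fraction,
                 affected_range = affected_range,
                 size_jitter = size_jitter),
            class = "truth_config")
}

#' @rdname truth_config
#' @export
default_control_components <- function() {
  tibble::tibble(
    name = c("viable_stable", "viable_growing", "necrotic"),
    mean = c(0.70e-3, 0.95e-3, 1.40e-3),
    sd   = c(0.12e-3, 0.15e-3, 0.18e-3),
    split = list(c(0.60, 0.40), c(0.40, 0.60), c(0.45, 0.55))
  )
}

#' @rdname truth_config
#' @export
default_treatment_component <- function() {
  tibble::tibble(name = "treatment_necrosis",
                 mean = 2.10e-3, sd = 0.15e-3,
                 split = list(c(0, 1)))
}

# gamma density with given mean/sd discretised on the bin mids of one visit
gamma_mode_pmf <- function(grid, mean, sd) {
  shape <- (mean / sd)^2
  scale <- sd^2 / mean
  d <- dgamma(bin_mids(grid), shape = shape, scale = scale)
  if (sum(d) <= 0) abort("habitat shape has no mass on the grid")
  d / sum(d)
}

component_pmf <- function(grid, mean, sd, split) {
  n_v <- length(grid$visits)
  if (length(split) != n_v) {
    abort("visit split length does not match the grid's visits")
  }
  shape <- gamma_mode_pmf(grid, mean, sd)
  as.vector(outer(shape, split / sum(split)))
}

#' Build the generative truth model from a configuration
#'
#' @param config A [truth_config()].
#' @return A list of class `truth_model` with the component PMFs as an
#'   `lpm_model` (`$model`) and the weight-generating configuration.
#' @export
make_truth_model <- function(config) {
  stopifnot(inherits(config, "truth_config"))
  g <- config$grid
  Pc <- vapply(seq_len(nrow(config$control_components)), function(i) {
    component_pmf(g, config$control_components$mean[i],
                  config$control_components$sd[i],
                  config$control_components$split[[i]])
  }, numeric(n_cells(g)))
  Pt <- vapply(seq_len(nrow(config$treatment_component)), function(i) {
    component_pmf(g, config$treatment_component$mean[i],
                  config$treatment_component$sd[i],
                  config$treatment_component$split[[i]])
  }, numeric(n_cells(g)))
  model <- new_lpm_model(cbind(Pc, Pt),
                         c(rep("control", ncol(Pc)),
                           rep("treatment", ncol(Pt))),
                         g, meta = list(stage = "truth"))
  structure(list(model = model, config = config), class = "truth_model")
}

draw_control_weights <- function(truth) {
  cfg <- truth$config
  total <- cfg$voxels_per_tumor * length(cfg$grid$visits) *
    runif(1, 1 - cfg$size_jitter, 1 + cfg$size_jitter)
  w <- as.vector(rdirichlet(1, cfg$weight_alpha))
  total * w
}

#' Sample a synthetic study with known ground truth
#'
#' Draws per-tumor habitat weights from the truth model, forms expected
#' counts over the (bin, visit) grid and samples each bin with Poisson
#' noise. Deterministic given the seed.
#'
#' @param truth A [make_truth_model()] result.
#' @param seed Integer seed.
#' @return A list with `histograms` (histogram tibble for all tumors) and
#'   `truth` (per-tumor tibble: `tumor_id`, `cohort`, `responder`,
#'   `qt_true`, `total_expected` and the generating `weights` list-column).
#' @export
sample_study <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "truth_model"))
  cfg <- truth$config
  P <- truth$model$P
  k_c <- sum(truth$model$classes == "control")
  withr::with_seed(seed, {
    rows <- list(); recs <- list()
    for (i in seq_len(cfg$n_control)) {
      qc <- draw_control_weights(truth)
      q <- c(qc, rep(0, ncol(P) - k_c))
      lam <- as.vector(P %*% q)
      id <- sprintf("C%02d", i)
      rows[[length(rows) + 1]] <-
        hist_tibble(rpois(length(lam), lam), cfg$grid, id, "control")
      recs[[length(recs) + 1]] <-
        tibble::tibble(tumor_id = id, cohort = "control", responder = FALSE,
                       qt_true = 0, total_expected = sum(q),
                       weights = list(q))
    }
    for (i in seq_len(cfg$n_treated)) {
      qc <- draw_control_weights(truth)
      responder <- runif(1) < cfg$responder_fraction
      qt <- 0
      if (responder) {
        a <- runif(1, cfg$affected_range[1], cfg$affected_range[2])
        qt <- a * cfg$voxels_per_tumor
      }
      q <- c(qc, rep(qt / (ncol(P) - k_c), ncol(P) - k_c))
      lam <- as.vector(P %*% q)
      id <- sprintf("T%02d", i)
      rows[[length(rows) + 1]] <-
        hist_tibble(rpois(length(lam), lam), cfg$grid, id, "treated")
      recs[[length(recs) + 1]] <-
        tibble::tibble(tumor_id = id, cohort = "treated",
                       responder = responder, qt_true = qt,
                       total_expected = sum(q), weights = list(q))
    }
    list(histograms = dplyr::bind_rows(rows), truth = dplyr::bind_rows(recs))
  })
}

#' Score estimated responses against ground truth
#'
#' @param assessment Tibble from [lpm_assess()].
#' @param truth Truth tibble from [sample_study()].
#' @param z_threshold Responder threshold used for the confusion matrix.
#' @return A list with `summary` (one-row tibble: bias, RMSE, median
#'   relative error among true responders, 2-sigma coverage, confusion
#'   counts) and `per_tumor`.
#' @export
recovery_report <- function(assessment, truth, z_threshold = 3) {
  if (!setequal(assessment$tumor_id, truth$tumor_id)) {
    abort("assessment and truth tumor ids do not match")
  }
  per <- dplyr::inner_join(
    assessment |> dplyr::select("tumor_id", "q_treatment", "sigma", "z"),
    truth |> dplyr::select("tumor_id", "responder", "qt_true"),
    by = "tumor_id") |>
    dplyr::mutate(error = .data$q_treatment - .data$qt_true,
                  covered = abs(.data$error) <= 2 * .data$sigma,
                  flagged = .data$z > z_threshold)
  resp <- dplyr::filter(per, .data$responder)
  summary <- tibble::tibble(
    n = nrow(per),
    bias = mean(per$error),
    rmse = sqrt(mean(per$error^2)),
    median_rel_error = if (nrow(resp)) {
      median(abs(resp$error) / resp$qt_true)
    } else NA_real_,
    coverage = mean(per$covered),
    tp = sum(per$flagged & per$responder),
    fp = sum(per$flagged & !per$responder),
    fn = sum(!per$flagged & per$responder),
    tn = sum(!per$flagged & !per$responder)
  )
  list(summary = summary, per_tumor = per)
}
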