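#' Training settings for linear Poisson models
#'
#' Collects the tunable controls of EM training, leave-one-out (LOO) model
#' selection and sufficiency checking.
#'
#' @param restarts Random EM restarts per fit (default 20).
#' @param max_iter,tol EM convergence controls (default 2000 iterations,
#'   relative log-likelihood change below 1e-8).
#' @param sufficiency_threshold A model order is sufficient when the median
#'   held-out \eqn{\sqrt{\chi^2/d.f.}} is at or below this value (default
#'   1.2; selection curves flatten near 1 for a correct model family).
#' @param outlier_sd A held-out fit counts as a LOO outlier when it exceeds
#'   the mean of the LOO fits by this many of their SDs (default 3).
#' @param chi2_floor Minimum pooled expected count for the chi-square
#'   statistic (default 5).
#' @param merge_cosine Post-fit merge threshold for near-duplicate
#'   components (cosine similarity; default 0.999).
#' @return A list of class `lpm_settings`.
#' @export
lpm_settings <- function(restarts = 20L, max_iter = 2000L, tol = 1e-8,
                         sufficiency_threshold = 1.2, outlier_sd = 3,
                         chi2_floor = 5, merge_cosine = 0.999) {
  structure(list(restarts = as.integer(restarts),
                 max_iter = as.integer(max_iter), tol = tol,
                 sufficiency_threshold = sufficiency_threshold,
                 outlier_sd = outlier_sd, chi2_floor = chi2_floor,
                 merge_cosine = merge_cosine),
            class = "lpm_settings")
}

new_lpm_model <- function(P, classes, grid, meta = list()) {
  stopifnot(ncol(P) == length(classes))
  colnames(P) <- paste0(substr(classes, 1, 1), seq_along(classes))
  structure(list(P = P, classes = classes, grid = grid, meta = meta),
            class = "lpm_model")
}

#' @export
print.lpm_model <- function(x, ...) {
  cat(sprintf("<lpm_model> %d control + %d treatment component(s), %d cells\n",
              sum(x$classes == "control"), sum(x$classes == "treatment"),
              nrow(x$P)))
  if (!is.null(x$meta$sufficient)) {
    cat(sprintf("  sufficiency: %s (median LOO fit %.3f)\n",
                if (isTRUE(x$meta$sufficient)) "pass" else "FLAGGED",
                x$meta$median_loo_fit %||% NA_real_))
  }
  invisible(x)
}

model_k <- function(model) ncol(model$P)

# Cells where the pooled cohort shows excess counts over the best
# weights-only description by the frozen components. Free (treatment)
# components are confined to these cells so that they describe only
# additional behaviour not expressible by the control model, which pins
# the likelihood-degenerate treatment weight at its minimal (lower-bound)
# value.
residual_support <- function(P_fixed, H, settings) {
  expected <- rowSums(vapply(seq_len(ncol(H)), function(j) {
    fit_weights(P_fixed, H[, j], max_iter = settings$max_iter,
                tol = settings$tol)$expected
  }, numeric(nrow(H))))
  observed <- rowSums(H)
  # excess must clear the Poisson noise band (3 sigma), not merely be positive:
  # mild per-bin misfit of the control model stays in the control
  # residuals instead of leaking into the treatment components
  supp <- observed > expected + 3 * sqrt(expected) & observed > 0
  if (!any(supp)) supp <- observed > 0
  supp
}

# held-out score: weights-only refit, sqrt(chi2/df) with the weight count
# charged against the degrees of freedom
loo_score <- function(P, h, grid, settings) {
  wf <- fit_weights(P, h, max_iter = settings$max_iter, tol = settings$tol)
  gof <- chi2_per_df(h, wf$expected, n_params = ncol(P), grid = grid,
                     floor = settings$chi2_floor)
  sqrt(gof$value)
}

#' Leave-one-out model-order selection
#'
#' For each candidate component count, the model is trained with every
#' tumor held out in turn; the held-out tumor is scored by a weights-only
#' refit and its \eqn{\sqrt{\chi^2/d.f.}}. The selected order is the
#' smallest whose median held-out fit is below the sufficiency threshold
#' with no LOO outliers; if none qualifies, the best order seen is returned
#' with `sufficient = FALSE`.
#'
#' @param data A histogram tibble (all tumors share the implied grid).
#' @param k_range Candidate counts of free components.
#' @param settings An [lpm_settings()] list.
#' @param seed Integer seed controlling EM restarts.
#' @param P_fixed Optional frozen components (used when selecting the
#'   treatment part on top of a control model).
#' @param grid Optional [bin_grid()]; derived from `data` when `NULL`.
#' @return An object of class `lpm_selection`: a list with `selected_k`,
#'   `sufficient`, `summary` (per-k tibble) and `curves` (per held-out
#'   tumor fits, for plotting).
#' @export
lpm_select_k <- function(data, k_range = 1:6, settings = lpm_settings(),
                         seed = 1L, P_fixed = NULL, grid = NULL) {
  data <- check_hist_tbl(data)
  grid <- grid %||% as_bin_grid(data)
  H <- hist_matrix(data, grid)
  if (ncol(H) < 3) abort("leave-one-out selection needs at least 3 tumors")
  if (length(k_range) == 0) abort("k_range is empty")
  if (is.null(P_fixed)) k_range <- k_range[k_range >= 1]

  curves <- purrr::map_dfr(sort(unique(k_range)), function(k) {
    purrr::map_dfr(seq_len(ncol(H)), function(j) {
      fit <- if (k == 0) {
        list(P = P_fixed)
      } else {
        Htrain <- H[, -j, drop = FALSE]
        supp <- if (is.null(P_fixed)) NULL
                else residual_support(P_fixed, Htrain, settings)
        em_fit(Htrain, k_free = k, P_fixed = P_fixed,
               restarts = settings$restarts, seed = seed + 1000L * k + j,
               max_iter = settings$max_iter, tol = settings$tol,
               free_support = supp)
      }
      tibble::tibble(k = k, held_out = colnames(H)[j],
                     loo_fit = loo_score(fit$P, H[, j], grid, settings))
    })
  })

  summary <- curves |>
    dplyr::group_by(.data$k) |>
    dplyr::summarise(
      median_loo_fit = median(.data$loo_fit),
      mean_loo_fit = mean(.data$loo_fit),
      sd_loo_fit = sd(.data$loo_fit),
      n_outliers = sum(.data$loo_fit >
                         mean(.data$loo_fit) +
                         .env$settings$outlier_sd * sd(.data$loo_fit)),
      .groups = "drop") |>
    dplyr::mutate(sufficient = .data$median_loo_fit <=
                    .env$settings$sufficiency_threshold &
                    .data$n_outliers == 0)

  ok <- summary$k[summary$sufficient]
  if (length(ok)) {
    selected <- min(ok)
    sufficient <- TRUE
  } else {
    selected <- summary$k[which.min(summary$median_loo_fit)]
    sufficient <- FALSE
  }
  structure(list(selected_k = selected, sufficient = sufficient,
                 summary = summary, curves = curves),
            class = "lpm_selection")
}

#' @export
print.lpm_selection <- function(x, ...) {
  cat(sprintf("<lpm_selection> selected k = %d (%s)\n", x$selected_k,
              if (x$sufficient) "sufficient" else "no sufficient order found"))
  print(x$summary)
  invisible(x)
}

#' @rdname lpm_select_k
#' @param object,x An `lpm_selection`.
#' @param ... Unused.
#' @method autoplot lpm_selection
#' @export
autoplot.lpm_selection <- function(object, ...) {
  ggplot(object$curves, aes(x = .data$k, y = .data$loo_fit)) +
    geom_point(colour = "grey60", alpha = 0.7) +
    geom_line(data = object$summary,
              aes(y = .data$median_loo_fit), linewidth = 0.8) +
    geom_point(data = object$summary, aes(y = .data$median_loo_fit)) +
    labs(x = "number of model components",
         y = expression(sqrt(chi^2 / d.f.)),
         title = "Leave-one-out model selection") +
    theme_minimal()
}

# Bland-Altman style residual check: standardised residuals (obs-exp)/sqrt(exp)
# against expectation magnitude. For Poisson-consistent residuals each
# magnitude quintile should have mean ~0 and SD ~1.
bland_altman_check <- function(observed, expected, min_expected = 5) {
  keep <- expected >= min_expected
  r <- (observed[keep] - expected[keep]) / sqrt(expected[keep])
  e <- expected[keep]
  if (length(r) < 10) {
    return(list(pass = NA, quintiles = tibble::tibble()))
  }
  qv <- cut(rank(e, ties.method = "first"), breaks = 5, labels = FALSE)
  tab <- tibble::tibble(quintile = qv, r = r) |>
    dplyr::group_by(.data$quintile) |>
    dplyr::summarise(mean_r = mean(.data$r), sd_r = sd(.data$r),
                     n = dplyr::n(), .groups = "drop")
  pass <- all(abs(tab$mean_r) < 0.1) && all(tab$sd_r >= 0.8 & tab$sd_r <= 1.2)
  list(pass = pass, quintiles = tab)
}

model_sufficiency <- function(model, H, grid, settings, selection) {
  per_tumor <- purrr::map_dbl(seq_len(ncol(H)), function(j) {
    loo_score(model$P, H[, j], grid, settings)
  })
  obs_all <- numeric(0); exp_all <- numeric(0)
  for (j in seq_len(ncol(H))) {
    wf <- fit_weights(model$P, H[, j], max_iter = settings$max_iter,
                      tol = settings$tol)
    obs_all <- c(obs_all, H[, j]); exp_all <- c(exp_all, wf$expected)
  }
  ba <- bland_altman_check(obs_all, exp_all, min_expected = settings$chi2_floor)
  list(fit_value = median(per_tumor), per_tumor_fit = per_tumor,
       loo = selection$summary, bland_altman = ba,
       sufficient = selection$sufficient && !isFALSE(ba$pass))
}

#' Train the control part of a linear Poisson model
#'
#' Learns the probability-mass-function components that describe untreated
#' (natural-history) tumor behaviour from a cohort of control histograms.
#' The component count is chosen by leave-one-out selection unless `k` is
#' given. All returned components are labelled `"control"`.
#'
#' @param data Histogram tibble of the control cohort (\eqn{\ge} 3 tumors).
#' @param k Fixed component count; `NULL` (default) selects by LOO.
#' @param k_range Candidate counts when selecting.
#' @param settings [lpm_settings()].
#' @param seed Integer seed; training is bit-reproducible given the seed.
#' @param grid Optional [bin_grid()]; derived from `data` when `NULL`.
#' @return An `lpm_model` whose `meta` records the seed, selection curves
#'   and sufficiency report (`meta$sufficient` flags a model that failed
#'   the sufficiency criteria rather than erroring).
#' @export
lpm_train_control <- function(data, k = NULL, k_range = 1:6,
                              settings = lpm_settings(), seed = 1L,
                              grid = NULL) {
  data <- check_hist_tbl(data)
  grid <- grid %||% as_bin_grid(data)
  H <- hist_matrix(data, grid)
  if (ncol(H) < 3) abort("at least 3 control tumors are required")

  selection <- NULL
  if (is.null(k)) {
    selection <- lpm_select_k(data, k_range = k_range, settings = settings,
                              seed = seed, grid = grid)
    k <- selection$selected_k
  }
  fit <- em_fit(H, k_free = k, restarts = settings$restarts, seed = seed,
                max_iter = settings$max_iter, tol = settings$tol)
  merged <- merge_degenerate(fit$P, fit$Q, rep(TRUE, k),
                             threshold = settings$merge_cosine)
  classes <- rep("control", ncol(merged$P))
  model <- new_lpm_model(merged$P, classes, grid,
                         meta = list(seed = seed, restarts = settings$restarts,
                                     k_requested = k, stage = "control",
                                     loglik = fit$loglik,
                                     ll_history = fit$ll_history,
                                     restart_logliks = fit$restart_logliks))
  suff <- model_sufficiency(model, H, grid, settings,
                            selection %||% list(summary = NULL,
                                                sufficient = TRUE))
  model$meta$selection <- selection
  model$meta$sufficiency <- suff
  model$meta$sufficient <- suff$sufficient
  model$meta$median_loo_fit <- if (!is.null(selection)) {
    selection$summary$median_loo_fit[selection$summary$k == selection$selected_k]
  } else suff$fit_value
  model
}

#' Add treatment components to a trained control model
#'
#' Second training stage: the control component PMFs are frozen
#' (bit-for-bit unchanged) and only additional treatment-labelled
#' components plus all mixture weights are free, so treatment components
#' describe only behaviour not seen in controls. The treatment component
#' count is chosen by leave-one-out selection over the treated cohort
#' (candidate 0 means the control model already suffices).
#'
#' @param model A control `lpm_model` from [lpm_train_control()].
#' @param data Histogram tibble of the treated cohort (\eqn{\ge} 1 tumor;
#'   LOO selection needs \eqn{\ge} 3).
#' @param k Fixed treatment component count; `NULL` selects by LOO.
#' @param k_range Candidate treatment component counts (may include 0).
#' @param settings [lpm_settings()].
#' @param seed Integer seed.
#' @return A full `lpm_model` with the original control components followed
#'   by the new treatment components.
#' @export
lpm_add_treatment <- function(model, data, k = NULL, k_range = 0:4,
                              settings = lpm_settings(), seed = 1L) {
  stopifnot(inherits(model, "lpm_model"))
  data <- check_hist_tbl(data)
  grid <- as_bin_grid(data)
  if (!grids_equal(grid, model$grid)) {
    abort("treated histograms are on a different grid than the control model")
  }
  H <- hist_matrix(data, model$grid)
  if (ncol(H) < 1) abort("at least one treated tumor is required")

  selection <- NULL
  if (is.null(k)) {
    if (ncol(H) >= 3) {
      selection <- lpm_select_k(data, k_range = k_range, settings = settings,
                                seed = seed, P_fixed = model$P,
                                grid = model$grid)
      k <- selection$selected_k
    } else {
      k <- max(1L, min(k_range[k_range >= 1]))
    }
  }
  supp <- residual_support(model$P, H, settings)
  fit <- em_fit(H, k_free = k, P_fixed = model$P,
                restarts = settings$restarts, seed = seed,
                max_iter = settings$max_iter, tol = settings$tol,
                free_support = supp)
  k_fixed <- ncol(model$P)
  mergeable <- c(rep(FALSE, k_fixed), rep(TRUE, k))
  merged <- merge_degenerate(fit$P, fit$Q, mergeable,
                             threshold = settings$merge_cosine)
  k_new <- ncol(merged$P) - k_fixed
  classes <- c(model$classes, rep("treatment", k_new))
  full <- new_lpm_model(merged$P, classes, model$grid,
                        meta = list(seed = seed, restarts = settings$restarts,
                                    stage = "full", k_treatment = k_new,
                                    loglik = fit$loglik,
                                    ll_history = fit$ll_history,
                                    control_meta = model$meta))
  suff <- model_sufficiency(full, H, model$grid, settings,
                            selection %||% list(summary = NULL,
                                                sufficient = TRUE))
  full$meta$selection <- selection
  full$meta$sufficiency <- suff
  full$meta$sufficient <- suff$sufficient
  full$meta$median_loo_fit <- if (!is.null(selection)) {
    selection$summary$median_loo_fit[selection$summary$k ==
                                       selection$selected_k]
  } else suff$fit_value
  full
}

#' @rdname lpm_train_control
#' @param x,object An `lpm_model`.
#' @param ... Unused.
#' @method tidy lpm_model
#' @export
tidy.lpm_model <- function(x, ...) {
  cells <- grid_cells(x$grid)
  purrr::map_dfr(seq_len(ncol(x$P)), function(k) {
    dplyr::mutate(cells, component = colnames(x$P)[k],
                  class = x$classes[k], prob = x$P[, k])
  }) |>
    dplyr::select("component", "class", "visit", "bin", "bin_mid", "prob")
}

#' @rdname lpm_train_control
#' @method glance lpm_model
#' @export
glance.lpm_model <- function(x, ...) {
  tibble::tibble(
    k_total = ncol(x$P),
    k_control = sum(x$classes == "control"),
    k_treatment = sum(x$classes == "treatment"),
    loglik = x$meta$loglik %||% NA_real_,
    fit_value = x$meta$sufficiency$fit_value %||% NA_real_,
    sufficient = x$meta$sufficient %||% NA,
    seed = x$meta$seed %||% NA_integer_
  )
}

#' @rdname lpm_train_control
#' @method autoplot lpm_model
#' @export
autoplot.lpm_model <- function(object, ...) {
  tidy(object) |>
    ggplot(aes(x = .data$bin_mid * 1000, y = .data$prob,
               colour = .data$class, group = .data$component)) +
    geom_line() +
    facet_wrap(~visit) +
    labs(x = expression(ADC ~ (10^-3 ~ mm^2 / s)),
         y = "component probability mass",
         title = "Linear Poisson model components") +
    theme_minimal()
}
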