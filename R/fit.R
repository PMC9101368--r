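#' Fit one tumor's histogram against a fixed model
#'
#' With the component PMFs held fixed, only the non-negative mixture
#' weights are optimised (weights-only EM on the extended Poisson
#' likelihood). The weight covariance is the inverse observed Fisher
#' information at the optimum; a singular information matrix falls back to
#' a pseudo-inverse with a warning. At the EM fixed point the weights sum
#' to the total observed count wherever the model has support; counts in
#' bins with no model support are reported in `excess`.
#'
#' @param model An `lpm_model`.
#' @param data Histogram tibble containing exactly one tumor (or a counts
#'   vector over [grid_cells()] of the model grid).
#' @param settings [lpm_settings()] (convergence controls only).
#' @return An object of class `tumor_fit`: weights, covariance,
#'   chi-square per degree of freedom, expected counts and bookkeeping.
#' @export
lpm_fit_tumor <- function(model, data, settings = lpm_settings()) {
  stopifnot(inherits(model, "lpm_model"))
  if (is.data.frame(data)) {
    data <- check_hist_tbl(data)
    if (length(unique(data$tumor_id)) != 1) {
      abort("lpm_fit_tumor expects a single tumor; see lpm_assess for cohorts")
    }
    grid <- as_bin_grid(data)
    if (!grids_equal(grid, model$grid)) {
      abort("histogram grid does not match the model grid")
    }
    h <- as.vector(hist_matrix(data, model$grid))
    tumor_id <- data$tumor_id[1]
    cohort <- data$cohort[1]
  } else {
    h <- as.numeric(data)
    stopifnot(length(h) == nrow(model$P))
    tumor_id <- NA_character_
    cohort <- NA_character_
  }
  wf <- fit_weights(model$P, h, max_iter = settings$max_iter,
                    tol = settings$tol)
  if (wf$excess > 0) {
    warn(sprintf("%g counts fall in bins with no model support", wf$excess))
  }
  cov <- weight_covariance(model$P, h, wf$weights)
  if (isTRUE(attr(cov, "singular"))) {
    warn("singular Fisher information; weight covariance from pseudo-inverse")
  }
  gof <- chi2_per_df(h, wf$expected, n_params = ncol(model$P),
                     grid = model$grid, floor = settings$chi2_floor)
  structure(list(tumor_id = tumor_id, cohort = cohort,
                 weights = setNames(wf$weights, colnames(model$P)),
                 classes = model$classes, covariance = cov,
                 expected = wf$expected, observed = h,
                 total = sum(h), excess = wf$excess,
                 chi2_per_df = gof$value, df = gof$df,
                 loglik = wf$loglik, grid = model$grid),
            class = "tumor_fit")
}

#' @export
print.tumor_fit <- function(x, ...) {
  cat(sprintf("<tumor_fit> %s: total %g, QT %.1f, QC %.1f, chi2/df %.3f\n",
              x$tumor_id, x$total,
              sum(x$weights[x$classes == "treatment"]),
              sum(x$weights[x$classes == "control"]),
              x$chi2_per_df))
  invisible(x)
}

#' @rdname lpm_fit_tumor
#' @param x,object A `tumor_fit`.
#' @param ... Unused.
#' @method tidy tumor_fit
#' @export
tidy.tumor_fit <- function(x, ...) {
  tibble::tibble(component = names(x$weights), class = x$classes,
                 weight = unname(x$weights),
                 se = sqrt(pmax(diag(x$covariance), 0)))
}

#' @rdname lpm_fit_tumor
#' @method glance tumor_fit
#' @export
glance.tumor_fit <- function(x, ...) {
  tr <- x$classes == "treatment"
  tibble::tibble(tumor_id = x$tumor_id, total = x$total,
                 q_treatment = sum(x$weights[tr]),
                 q_control = sum(x$weights[!tr]),
                 chi2_per_df = x$chi2_per_df, df = x$df,
                 excess = x$excess)
}
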