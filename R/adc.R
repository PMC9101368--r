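#' Fit the apparent diffusion coefficient for one voxel
#'
#' Estimates D in the mono-exponential diffusion decay
#' \eqn{S = S_0 e^{-bD}} from signal intensities acquired at two or more
#' diffusion weightings. The default is linear least squares on the
#' log-signal (\eqn{\log S = \log S_0 - bD}), which is deterministic and
#' exact for noiseless data; `method = "nls"` refits the exponential model
#' by nonlinear least squares starting from the log-linear estimate.
#'
#' Negative fitted D (possible under noise) is clipped to 0 and flagged.
#'
#' @param b Numeric vector of b values in s/mm\eqn{^2} (non-negative, at
#'   least two distinct values).
#' @param signal Positive signal intensities, same length as `b`.
#' @param method `"loglinear"` (default) or `"nls"`.
#' @return A list with `adc` (mm\eqn{^2}/s), `s0`, and `clipped` (logical,
#'   `TRUE` when a negative fit was clipped to zero).
#' @examples
#' fit_adc_voxel(c(150, 500, 1000), 1000 * exp(-c(150, 500, 1000) * 1e-3))
#' @export
fit_adc_voxel <- function(b, signal, method = c("loglinear", "nls")) {
  method <- match.arg(method)
  b <- as.numeric(b); signal <- as.numeric(signal)
  if (length(b) != length(signal)) abort("b and signal lengths differ")
  if (any(b < 0)) abort("b values must be non-negative")
  if (any(signal <= 0) || anyNA(signal)) abort("signals must be positive")
  if (length(unique(b)) < 2) abort("at least 2 distinct b values are required")

  fit <- lm(log(signal) ~ b)
  d <- -unname(coef(fit)[2])
  s0 <- exp(unname(coef(fit)[1]))

  if (method == "nls") {
    nl <- tryCatch(
      nls(signal ~ s0 * exp(-b * d),
          start = list(s0 = s0, d = max(d, 1e-6)),
          control = list(warnOnly = TRUE)),
      error = function(e) NULL)
    if (!is.null(nl)) {
      d <- unname(coef(nl)["d"])
      s0 <- unname(coef(nl)["s0"])
    }
  }

  clipped <- d < 0
  list(adc = max(d, 0), s0 = s0, clipped = clipped)
}

#' Fit ADC values for a table of multi-b signals
#'
#' Data-frame interface to [fit_adc_voxel()]: rows are (voxel, b value)
#' signal measurements; any columns other than `b` and `signal` are treated
#' as voxel identifiers and the decay is fitted within each identifier
#' combination.
#'
#' @param data A data frame with columns `b`, `signal` and one or more id
#'   columns (e.g. `tumor_id`, `visit`, `voxel`).
#' @inheritParams fit_adc_voxel
#' @return A tibble with the id columns plus `adc`, `s0` and `clipped`.
#' @export
fit_adc <- function(data, method = c("loglinear", "nls")) {
  method <- match.arg(method)
  stopifnot(all(c("b", "signal") %in% names(data)))
  ids <- setdiff(names(data), c("b", "signal"))
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(ids))) |>
    dplyr::summarise(
      {
        f <- fit_adc_voxel(.data$b, .data$signal, method = .env$method)
        tibble::tibble(adc = f$adc, s0 = f$s0, clipped = f$clipped)
      },
      .groups = "drop"
    )
}

#' Bin ADC values into one visit's histogram
#'
#' Values are assigned to half-open bins `[low, high)` (last bin closed at
#' the top edge). Values outside the grid range are counted in an overflow
#' tally reported via the `overflow` attribute, never silently dropped, so
#' in-range counts + overflow always equals the number of input values.
#'
#' @param adc_values Numeric ADC values (mm\eqn{^2}/s).
#' @param grid A [bin_grid()].
#' @param visit Visit label (must be one of `grid$visits`).
#' @param tumor_id,cohort Optional identifiers carried into the output.
#' @return A histogram tibble (one row per bin of `visit`) with attribute
#'   `overflow` = number of out-of-range values.
#' @export
build_histogram <- function(adc_values, grid, visit,
                            tumor_id = NA_character_,
                            cohort = NA_character_) {
  if (!visit %in% grid$visits) {
    abort(sprintf("visit '%s' is not on the grid", visit))
  }
  if (length(adc_values) == 0) {
    warn("no ADC values supplied; returning a zero histogram")
  }
  idx <- findInterval(adc_values, grid$edges, rightmost.closed = TRUE)
  inside <- idx >= 1 & idx <= n_bins(grid)
  counts <- tabulate(idx[inside], nbins = n_bins(grid))
  out <- hist_tibble(rep(0, n_cells(grid)), grid, tumor_id, cohort) |>
    dplyr::filter(.data$visit == .env$visit) |>
    dplyr::mutate(count = as.numeric(counts))
  attr(out, "overflow") <- sum(!inside)
  out
}

#' Build multi-visit histograms from a raw ADC value table
#'
#' Converts the raw ADC CSV dialect (one voxel per row) into the histogram
#' table used by the modelling functions.
#'
#' @param data A data frame with columns `tumor_id`, `visit`, `adc_value`
#'   and optionally `cohort`.
#' @param grid A [bin_grid()].
#' @return A histogram tibble covering every (bin, visit) cell for every
#'   tumor, with attribute `overflow` (total out-of-range voxels).
#' @export
adc_to_histograms <- function(data, grid) {
  stopifnot(all(c("tumor_id", "visit", "adc_value") %in% names(data)))
  if (!"cohort" %in% names(data)) data$cohort <- NA_character_
  overflow <- 0L
  out <- data |>
    dplyr::group_by(.data$tumor_id, .data$cohort) |>
    dplyr::group_map(function(d, key) {
      counts <- numeric(n_cells(grid))
      cells <- grid_cells(grid)
      for (v in unique(as.character(d$visit))) {
        h <- build_histogram(d$adc_value[d$visit == v], grid, v)
        overflow <<- overflow + attr(h, "overflow")
        counts[cells$visit == v] <- h$count
      }
      hist_tibble(counts, grid, key$tumor_id, key$cohort)
    }) |>
    dplyr::bind_rows()
  attr(out, "overflow") <- overflow
  out
}

#' Restrict histograms to an ordered subset of visits
#'
#' Multi-visit models are trained on concatenations of visit histograms
#' (e.g. V1–V2 or V1–V3); this selects and orders the visits of a histogram
#' table accordingly. Counts are conserved: the new per-tumor total is the
#' sum of the selected per-visit totals.
#'
#' @param data A histogram tibble.
#' @param visit_subset Ordered character vector of visit labels to keep.
#' @return A histogram tibble whose implied grid has `visit_subset` as its
#'   visit order.
#' @export
assemble_tumor_histogram <- function(data, visit_subset) {
  data <- check_hist_tbl(data)
  visit_subset <- as.character(visit_subset)
  present <- unique(as.character(data$visit))
  miss <- setdiff(visit_subset, present)
  if (length(miss)) {
    abort(paste0("requested visit(s) not present: ",
                 paste(miss, collapse = ", ")))
  }
  data |>
    dplyr::filter(.data$visit %in% visit_subset) |>
    dplyr::mutate(visit = factor(.data$visit, levels = visit_subset)) |>
    dplyr::arrange(.data$tumor_id, .data$visit, .data$bin) |>
    dplyr::mutate(visit = as.character(.data$visit))
}

#' Voxel volume from acquisition geometry
#'
#' @param in_plane_x,in_plane_y In-plane voxel dimensions in mm.
#' @param slice_thickness Slice thickness in mm.
#' @return Voxel volume in mm\eqn{^3}.
#' @examples
#' voxel_volume(0.5, 0.5, 1.0)  # 0.25 mm^3
#' @export
voxel_volume <- function(in_plane_x, in_plane_y, slice_thickness) {
  if (any(c(in_plane_x, in_plane_y, slice_thickness) <= 0)) {
    abort("voxel dimensions must be strictly positive")
  }
  in_plane_x * in_plane_y * slice_thickness
}

#' Extract masked ADC values from NIfTI volumes
#'
#' Reads an ADC volume and a binary mask volume (requires the RNifti
#' package) and returns the ADC values of voxels inside the mask, ready for
#' [build_histogram()].
#'
#' @param adc_path Path to the ADC NIfTI volume (values in mm\eqn{^2}/s).
#' @param mask_path Path to a mask NIfTI volume (non-zero = inside tumor).
#' @return Numeric vector of masked ADC values.
#' @export
read_adc_nifti <- function(adc_path, mask_path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    abort("the RNifti package is required for NIfTI ingestion")
  }
  adc <- as.array(RNifti::readNifti(adc_path))
  mask <- as.array(RNifti::readNifti(mask_path))
  if (!identical(dim(adc), dim(mask))) {
    abort("ADC and mask volumes have different dimensions")
  }
  as.numeric(adc[mask != 0])
}
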