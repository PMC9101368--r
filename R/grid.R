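#' ADC bin grid
#'
#' Defines the histogram domain used throughout the package: a set of
#' strictly increasing ADC bin edges (mm\eqn{^2}/s) crossed with an ordered
#' set of imaging visits. Bins are half-open `[low, high)`; the last bin is
#' closed at the top edge. A multi-visit tumor histogram is a vector of
#' counts over every (bin, visit) cell of this grid.
#'
#' @param n_bins Number of uniform ADC bins.
#' @param adc_min,adc_max ADC range in mm\eqn{^2}/s covered by the bins.
#' @param visits Character vector of ordered visit labels.
#' @param edges Optional explicit bin edges (overrides `n_bins`/`adc_min`/
#'   `adc_max`); must be strictly increasing with at least two values.
#'
#' @details The default grid (100 uniform bins over \[0, 3e-3\] mm\eqn{^2}/s)
#'   keeps typical 10^3–10^4-voxel tumors at \eqn{\ge} 10 counts per occupied
#'   bin, which keeps the Poisson chi-square goodness-of-fit valid.
#'
#' @return An object of class `bin_grid`.
#' @examples
#' g <- bin_grid(visits = c("V1", "V2"))
#' g
#' @export
bin_grid <- function(n_bins = 100, adc_min = 0, adc_max = 3e-3,
                     visits = c("V1", "V2", "V3"), edges = NULL) {
  if (is.null(edges)) {
    stopifnot(n_bins >= 1, adc_max > adc_min)
    edges <- seq(adc_min, adc_max, length.out = n_bins + 1)
  }
  edges <- as.numeric(edges)
  if (length(edges) < 2 || any(diff(edges) <= 0)) {
    abort("bin edges must be strictly increasing with at least 2 values")
  }
  visits <- as.character(visits)
  if (length(visits) < 1 || anyDuplicated(visits)) {
    abort("at least one visit label is required and labels must be unique")
  }
  structure(list(edges = edges, visits = visits), class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("<bin_grid> %d bins over [%g, %g] mm^2/s; visits: %s\n",
              n_bins(x), min(x$edges), max(x$edges),
              paste(x$visits, collapse = ", ")))
  invisible(x)
}

#' @rdname bin_grid
#' @param grid A `bin_grid`.
#' @export
n_bins <- function(grid) length(grid$edges) - 1L

#' @rdname bin_grid
#' @export
bin_mids <- function(grid) (head(grid$edges, -1) + tail(grid$edges, -1)) / 2

#' @rdname bin_grid
#' @export
n_cells <- function(grid) n_bins(grid) * length(grid$visits)

#' Flattened (bin, visit) cell table for a grid
#'
#' Cells are ordered visit-major (all bins of the first visit, then the
#' second, ...); this is the canonical flattening used by the model matrices.
#'
#' @param grid A [bin_grid()].
#' @return A tibble with columns `visit`, `bin`, `bin_low`, `bin_high`,
#'   `bin_mid` and flat `cell` index.
#' @export
grid_cells <- function(grid) {
  nb <- n_bins(grid)
  tibble::tibble(
    visit   = rep(grid$visits, each = nb),
    bin     = rep(seq_len(nb), times = length(grid$visits)),
    bin_low = rep(head(grid$edges, -1), times = length(grid$visits)),
    bin_high = rep(tail(grid$edges, -1), times = length(grid$visits)),
    bin_mid = rep(bin_mids(grid), times = length(grid$visits)),
    cell    = seq_len(nb * length(grid$visits))
  )
}

grids_equal <- function(a, b) {
  isTRUE(all.equal(a$edges, b$edges)) && identical(a$visits, b$visits)
}

#' Recover the bin grid implied by a histogram table
#'
#' @param data A histogram tibble with `visit`, `bin_low`, `bin_high` columns
#'   (the histogram CSV dialect).
#' @return A [bin_grid()]; visit order follows first appearance in `data`.
#' @export
as_bin_grid <- function(data) {
  stopifnot(all(c("visit", "bin_low", "bin_high") %in% names(data)))
  lows <- sort(unique(data$bin_low))
  highs <- sort(unique(data$bin_high))
  edges <- c(lows, highs[length(highs)])
  bin_grid(edges = edges, visits = unique(as.character(data$visit)))
}

# histogram tibble (tumor_id, cohort, visit, bin, bin_low, bin_high, count)
# <-> dense cell x tumor count matrix in grid_cells() order
hist_matrix <- function(data, grid) {
  cells <- grid_cells(grid)
  ids <- unique(data$tumor_id)
  H <- matrix(0, nrow = nrow(cells), ncol = length(ids),
              dimnames = list(NULL, ids))
  key <- paste(cells$visit, cells$bin)
  idx <- match(paste(as.character(data$visit), data$bin), key)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    abort(sprintf("histogram row (visit %s, bin %s) is not on the grid",
                  data$visit[bad], data$bin[bad]))
  }
  j <- match(data$tumor_id, ids)
  H[cbind(idx, j)] <- data$count
  if (any(H < 0) || any(H != floor(H))) {
    abort("histogram counts must be non-negative integers")
  }
  H
}

hist_tibble <- function(counts, grid, tumor_id, cohort = NA_character_) {
  cells <- grid_cells(grid)
  dplyr::mutate(cells,
                tumor_id = tumor_id, cohort = cohort,
                count = as.numeric(counts)) |>
    dplyr::select("tumor_id", "cohort", "visit", "bin", "bin_low",
                  "bin_high", "count")
}

check_hist_tbl <- function(data) {
  need <- c("tumor_id", "visit", "bin", "bin_low", "bin_high", "count")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    abort(paste0("histogram table is missing columns: ",
                 paste(miss, collapse = ", ")))
  }
  if (!"cohort" %in% names(data)) data$cohort <- NA_character_
  data
}

cohort_of <- function(data) {
  data |>
    dplyr::distinct(.data$tumor_id, .data$cohort) |>
    dplyr::distinct(.data$tumor_id, .keep_all = TRUE)
}
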