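#' Read and write histogram tables
#'
#' The histogram CSV dialect has columns `tumor_id`, `cohort`, `visit`,
#' `bin_low`, `bin_high`, `count` (one row per occupied or empty bin).
#' On reading, the `bin` index is reconstructed from the implied grid.
#'
#' @param path File path.
#' @return `read_histograms()` returns a histogram tibble.
#' @export
read_histograms <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("tumor_id", "visit", "bin_low", "bin_high", "count")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    abort(sprintf("%s: missing column(s) %s", path,
                  paste(miss, collapse = ", ")))
  }
  if (!"cohort" %in% names(data)) data$cohort <- NA_character_
  grid <- as_bin_grid(data)
  lows <- head(grid$edges, -1)
  data |>
    dplyr::mutate(tumor_id = as.character(.data$tumor_id),
                  visit = as.character(.data$visit),
                  bin = match(.data$bin_low, lows)) |>
    dplyr::select("tumor_id", "cohort", "visit", "bin", "bin_low",
                  "bin_high", "count")
}

#' @rdname read_histograms
#' @param data A histogram tibble.
#' @export
write_histograms <- function(data, path) {
  data <- check_hist_tbl(data)
  readr::write_csv(
    dplyr::select(data, "tumor_id", "cohort", "visit", "bin_low",
                  "bin_high", "count"),
    path)
  invisible(path)
}

#' Serialize a linear Poisson model to JSON
#'
#' The JSON document records the grid (edges, visits), every component's
#' class label and dense probability vector, and the training metadata
#' needed for reproducibility (seed, restarts, selection summary).
#'
#' @param model An `lpm_model`.
#' @param path Output path.
#' @export
write_lpm_model <- function(model, path) {
  stopifnot(inherits(model, "lpm_model"))
  doc <- list(
    grid = list(edges = model$grid$edges, visits = model$grid$visits),
    components = purrr::map(seq_len(ncol(model$P)), function(k) {
      list(name = colnames(model$P)[k], class = model$classes[k],
           probs = model$P[, k])
    }),
    meta = list(seed = model$meta$seed, restarts = model$meta$restarts,
                stage = model$meta$stage, loglik = model$meta$loglik,
                sufficient = model$meta$sufficient,
                selection = if (!is.null(model$meta$selection)) {
                  model$meta$selection$summary
                })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_lpm_model
#' @export
read_lpm_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid <- bin_grid(edges = doc$grid$edges, visits = doc$grid$visits)
  comps <- doc$components
  if (is.data.frame(comps)) {
    P <- do.call(cbind, comps$probs)
    classes <- comps$class
  } else {
    P <- vapply(comps, function(cp) as.numeric(cp$probs),
                numeric(n_cells(grid)))
    classes <- vapply(comps, `[[`, character(1), "class")
  }
  meta <- doc$meta
  meta$selection <- NULL
  new_lpm_model(P, classes, grid, meta = meta)
}

#' Write a response assessment table
#'
#' Tab-separated output of [lpm_assess()] (list-columns dropped).
#'
#' @param assessment Tibble from [lpm_assess()].
#' @param path Output path.
#' @export
write_assessment <- function(assessment, path) {
  flat <- assessment[, !vapply(assessment, is.list, logical(1))]
  readr::write_tsv(flat, path)
  invisible(path)
}

#' @rdname write_assessment
#' @param truth Truth tibble from [sample_study()].
#' @export
write_truth <- function(truth, path) {
  flat <- truth[, !vapply(truth, is.list, logical(1))]
  readr::write_csv(flat, path)
  invisible(path)
}
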