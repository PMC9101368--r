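#' Run one step of the standard analysis workflow
#'
#' Binds the package's functions into the train → extend → assess →
#' simulate → power sequence behind a single configurable entry point
#' (also exposed by the `inst/cli/lpm.R` command-line script). All
#' randomness flows from the seeds named in the configuration, so a given
#' configuration and seed reproduce byte-identical artifacts.
#'
#' @param subcommand One of `"synthesize"`, `"fit-control"`,
#'   `"fit-treatment"`, `"assess"`, `"simulate-cohorts"`, `"power-z"`,
#'   `"power-cohort"`.
#' @param config A named list, or path to a YAML file, with the fields the
#'   subcommand needs (paths, grid spec, `k_range`, `restarts`, `seed`,
#'   `thresholds`, power inputs).
#' @param quiet Suppress the log lines written to `stderr`.
#' @return Invisibly, a named list of the artifact paths (or values)
#'   produced.
#' @export
run_workflow <- function(subcommand, config = list(), quiet = FALSE) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  log <- function(...) if (!quiet) message(sprintf(...))
  log("lpmadc %s | R %s | subcommand %s | config hash %s | seed %s",
      as.character(utils::packageVersion("lpmadc")),
      paste(R.version$major, R.version$minor, sep = "."),
      subcommand, rlang::hash(config), config$seed %||% "unset")

  cfg_grid <- function() {
    g <- config$grid %||% list()
    bin_grid(n_bins = g$n_bins %||% 100, adc_min = g$adc_min %||% 0,
             adc_max = g$adc_max %||% 3e-3,
             visits = g$visits %||% c("V1", "V2"))
  }
  cfg_settings <- function() {
    lpm_settings(restarts = config$restarts %||% 20L,
                 max_iter = config$max_iter %||% 2000L)
  }
  seed <- as.integer(config$seed %||% 1L)
  need <- function(field) {
    config[[field]] %||% abort(sprintf("config field '%s' is required", field))
  }

  switch(
    subcommand,
    "synthesize" = {
      cfg <- truth_config(
        n_control = config$n_control %||% 15,
        n_treated = config$n_treated %||% 9,
        voxels_per_tumor = config$voxels_per_tumor %||% 2000,
        grid = cfg_grid(),
        responder_fraction = config$responder_fraction %||% 1)
      study <- sample_study(make_truth_model(cfg), seed = seed)
      write_histograms(study$histograms, need("histograms_out"))
      write_truth(study$truth, need("truth_out"))
      log("wrote %s and %s", config$histograms_out, config$truth_out)
      invisible(list(histograms = config$histograms_out,
                     truth = config$truth_out))
    },
    "fit-control" = {
      data <- read_histograms(need("histograms"))
      ctrl <- dplyr::filter(data, .data$cohort ==
                              (config$control_cohort %||% "control"))
      visits <- config$visit_subset %||% unique(ctrl$visit)
      ctrl <- assemble_tumor_histogram(ctrl, visits)
      model <- lpm_train_control(ctrl,
                                 k = config$k,
                                 k_range = config$k_range %||% 1:6,
                                 settings = cfg_settings(), seed = seed)
      write_lpm_model(model, need("model_out"))
      log("control model: %d component(s), sufficient = %s",
          ncol(model$P), model$meta$sufficient)
      invisible(list(model = config$model_out))
    },
    "fit-treatment" = {
      model <- read_lpm_model(need("model"))
      data <- read_histograms(need("histograms"))
      trt <- dplyr::filter(data, .data$cohort !=
                             (config$control_cohort %||% "control"))
      trt <- assemble_tumor_histogram(trt, model$grid$visits)
      full <- lpm_add_treatment(model, trt,
                                k = config$k,
                                k_range = config$k_range %||% 0:4,
                                settings = cfg_settings(), seed = seed)
      write_lpm_model(full, need("model_out"))
      log("full model: %d control + %d treatment component(s)",
          sum(full$classes == "control"), sum(full$classes == "treatment"))
      invisible(list(model = config$model_out))
    },
    "assess" = {
      model <- read_lpm_model(need("model"))
      data <- read_histograms(need("histograms"))
      data <- assemble_tumor_histogram(data, model$grid$visits)
      out <- lpm_assess(data, model,
                        z_threshold = config$z_threshold %||% 3,
                        voxel_vol = config$voxel_volume,
                        settings = cfg_settings())
      write_assessment(out, need("assessment_out"))
      log("assessed %d tumor(s); %d responder(s) at Z > %g",
          nrow(out), sum(out$responder), config$z_threshold %||% 3)
      invisible(list(assessment = config$assessment_out))
    },
    "simulate-cohorts" = {
      model <- read_lpm_model(need("model"))
      data <- read_histograms(need("histograms"))
      data <- assemble_tumor_histogram(data, model$grid$visits)
      assessed <- lpm_assess(data, model, settings = cfg_settings())
      ctrl_name <- config$control_cohort %||% "control"
      control_fits <- assessed$fit[assessed$cohort == ctrl_name]
      responder_fits <- assessed$fit[assessed$cohort != ctrl_name &
                                       assessed$z > 3]
      if (!length(responder_fits)) {
        abort("no strongly responding tumors (Z > 3) to seed the simulation")
      }
      spec <- simulation_spec(
        n_cohort = config$n_cohort %||% 12,
        n_responders = config$n_responders %||% config$n_cohort %||% 12,
        cohorts_per_setting = config$cohorts_per_setting %||% 10,
        thresholds = config$thresholds %||% c(0.05, 0.01, 0.001),
        seed = seed)
      cohorts <- build_sim_cohorts(spec, model, control_fits, responder_fits)
      tpr <- evaluate_tpr(cohorts, model, thresholds = spec$thresholds,
                          settings = cfg_settings())
      readr::write_csv(tpr, need("tpr_out"))
      log("wrote TPR table to %s", config$tpr_out)
      invisible(list(tpr = config$tpr_out))
    },
    "power-z" = {
      z <- predict_z(need("q_total"), need("t_star"), need("c_star"))
      log("predicted Z = %.4f", z)
      invisible(list(z = as.numeric(z)))
    },
    "power-cohort" = {
      n <- min_cohort_for_confidence(need("f"), need("target"))
      log("minimum cohort size N = %d", n)
      invisible(list(n = n))
    },
    abort(sprintf("unknown subcommand '%s'", subcommand))
  )
}
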