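# One full pipeline run on the default study conditions, shared by the
# heavier statistical tests (training is the expensive step; the fitted
# model is deterministic given the seeds, so sharing it changes nothing).
acceptance_pipeline <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    st <- lpm_settings(restarts = 8, max_iter = 800, tol = 1e-7)
    truth <- make_truth_model(truth_config())
    study <- sample_study(truth, seed = 1)
    ctrl <- dplyr::filter(study$histograms, cohort == "control")
    trt <- dplyr::filter(study$histograms, cohort == "treated")
    cm <- lpm_train_control(ctrl, k_range = 1:6, settings = st, seed = 2)
    fm <- lpm_add_treatment(cm, trt, k_range = 0:3, settings = st, seed = 3)
    assess_ctrl <- suppressWarnings(lpm_assess(ctrl, fm, settings = st))
    assess_trt <- suppressWarnings(lpm_assess(trt, fm, settings = st))
    cache <<- list(settings = st, truth = truth, study = study,
                   ctrl = ctrl, trt = trt, control_model = cm,
                   full_model = fm, assess_ctrl = assess_ctrl,
                   assess_trt = assess_trt)
    cache
  }
})
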