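#' Pipeline configuration
#'
#' One serialisable object from which an end-to-end run is reproducible.
#' The defaults are a demonstration scale (8 phantoms on a 16x16x8 grid,
#' 12 timepoints, first-order + GLCM features, unfiltered) that completes
#' in seconds; study-like scales are reached by passing a larger
#' acquisition and the default [extraction_config()].
#'
#' @param n_subjects Cohort size.
#' @param acq,bolus Acquisition and bolus model.
#' @param fraction_range,attenuation,delay,noise_sd Cohort lesion and
#'   noise parameters (see [generate_cohort()]).
#' @param extraction An [extraction_config()].
#' @param selector A [selector_config()].
#' @param methods Selection methods to run (default all 13).
#' @param models Model names from [model_bank()] to use (default all 10).
#' @param cv_folds Cross-validation folds.
#' @param S_values,RT_grid Proportion-experiment grid (set `RT_grid =
#'   NULL` to skip the sweep).
#' @param seed Root seed; all stage seeds derive from it.
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 8L,
                            acq = acquisition_spec(n_timepoints = 12L,
                                                   n_slices = 8L,
                                                   height = 16L, width = 16L),
                            bolus = bolus_model(),
                            fraction_range = c(0.1, 0.5),
                            attenuation = 0.4, delay = 2, noise_sd = 1,
                            extraction = extraction_config(
                              families = c("firstorder", "glcm"),
                              log_sigmas = NULL, wavelet = FALSE),
                            selector = selector_config(),
                            methods = names(selector_types()),
                            models = names(model_bank()),
                            cv_folds = 5L,
                            S_values = c(3, 4, 5),
                            RT_grid = seq(0, 0.35, by = 0.05),
                            seed = 1L, out_dir = NULL) {
  structure(list(n_subjects = as.integer(n_subjects), acq = acq,
                 bolus = bolus, fraction_range = fraction_range,
                 attenuation = attenuation, delay = delay,
                 noise_sd = noise_sd, extraction = extraction,
                 selector = selector, methods = methods, models = models,
                 cv_folds = as.integer(cv_folds), S_values = S_values,
                 RT_grid = RT_grid, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes phantom generation, temporal smoothing, per-timepoint feature
#' extraction for the HA and mirrored NA regions, normalisation, the
#' t-test significance filter, the 13-method selection bank, the
#' ten-model evaluation grid with composite scores, and (when `RT_grid`
#' is set) the lesion-proportion sweep. Returns a report whose `summary`
#' component is deterministic given the configuration and seed.
#'
#' @param config A [pipeline_config()].
#' @param verbose Print stage progress.
#' @return A list with the cohort-level tables, the evaluation grid, the
#'   sweep result, a `summary` list and a `log` of stage timings.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list()
  tick <- function(stage, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
    log[[stage]] <<- round(as.numeric(difftime(Sys.time(), t0,
                                               units = "secs")), 3)
    if (verbose) message(sprintf("[%s] %.2fs", stage, log[[stage]]))
    res
  }

  cohort <- tick("phantom", generate_cohort(
    config$n_subjects, config$acq, config$bolus, config$fraction_range,
    config$attenuation, config$delay, config$noise_sd, seed = config$seed))

  cohort <- tick("preprocess", lapply(cohort, function(ph) {
    ph$volume <- smooth_time_series(ph$volume)
    ph
  }))

  sp <- c(config$acq$slice_thickness_mm, config$acq$spacing_mm,
          config$acq$spacing_mm)
  tab <- tick("features", {
    rows <- list()
    for (i in seq_along(cohort)) {
      ph <- cohort[[i]]
      rows[[paste0("s", i, "_HA")]] <-
        extract_series_features(ph$volume, ph$ha_mask, config$extraction, sp)
      rows[[paste0("s", i, "_NA")]] <-
        extract_series_features(ph$volume, ph$na_mask, config$extraction, sp)
    }
    vals <- do.call(rbind, rows)
    feature_table(vals, names(rows),
                  roles = rep(c("HA", "NA"), length(cohort)))
  })
  labels <- as.integer(tab$roles == "HA")

  sig <- tick("significance", {
    ntab <- suppressWarnings(normalize_features(tab))
    rep <- ttest_filter(ntab, labels)
    keep <- rep$name[rep$retained]
    list(report = rep, table = feature_table(
      ntab$values[, keep, drop = FALSE], ntab$sample_ids, ntab$roles))
  })

  sets <- tick("selection", {
    out <- list()
    for (m in config$methods) {
      out[[m]] <- select_features(m, sig$table, labels, config$selector,
                                  attributes = FALSE)
    }
    out
  })

  models <- model_bank()[config$models]
  grid <- tick("evaluate", evaluate_sets(sets, sig$table, labels, models,
                                         k = config$cv_folds,
                                         seed = config$seed))
  top6 <- top_k_union(sets, grid$cs, k = min(6L, sum(!is.na(grid$cs))))

  sweep <- NULL
  if (!is.null(config$RT_grid)) {
    sweep <- tick("proportion", sweep_rt(
      cohort, top6, config$S_values, config$RT_grid, config$extraction,
      config$selector, models, k = config$cv_folds, seed = config$seed))
  }

  summary <- list(
    n_subjects = config$n_subjects,
    n_samples = nrow(tab$values),
    n_features = ncol(tab$values),
    n_significant = sum(sig$report$retained),
    set_sizes = lapply(sets, function(s) nrow(s$members)),
    h_type = as.list(round(grid$h_type, 6)),
    cs = as.list(round(grid$cs, 6)),
    top6 = rank_top_k(grid$cs, k = min(6L, sum(!is.na(grid$cs)))),
    n_classifiers = grid$n_classifiers,
    n_rt_configs = if (is.null(sweep)) 0L else nrow(sweep),
    seed = config$seed)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(data.frame(sample = tab$sample_ids, role = tab$roles,
                                tab$values, check.names = FALSE),
                     file.path(config$out_dir, "features.csv"),
                     row.names = FALSE)
    utils::write.csv(sig$report,
                     file.path(config$out_dir, "significance.csv"),
                     row.names = FALSE)
    jsonlite::write_json(lapply(sets, function(s) s$members),
                         file.path(config$out_dir, "feature_sets.json"),
                         dataframe = "rows", digits = NA, pretty = TRUE)
    cs_tab <- data.frame(method = names(grid$cs),
                         type = unname(selector_types()[names(grid$cs)]),
                         cs = unname(grid$cs))
    utils::write.csv(cs_tab, file.path(config$out_dir, "cs_table.csv"),
                     row.names = FALSE)
    if (!is.null(sweep)) {
      utils::write.csv(sweep, file.path(config$out_dir, "rt_sweep.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(cohort = cohort, table = tab, significance = sig$report,
       sets = sets, grid = grid, top6 = top6, sweep = sweep,
       summary = summary, log = log)
}
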