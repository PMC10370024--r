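#' Default pipeline run configuration
#'
#' Nested configuration consumed by [run_pipeline()] and the command-line
#' wrapper. Sections: `generator` (arguments of [generator_config()]),
#' `preprocessing`, `timefreq` (arguments of [band_config()]), `tfpca`,
#' `stats`, and `output`. [validate_run_config()] rejects unknown keys at
#' any level and fills omitted ones from these defaults.
#'
#' @return nested list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    seed = 1L,
    generator = list(n_subjects = 40L, n_trials = 256L, n_blocks = 8L,
                     sampling_rate = 256, n_eeg = 16L, n_eog = 2L,
                     epoch_window_ms = c(-1000, 2000),
                     covariates = list(), behavior = list(),
                     amplitudes = list(), templates = list(), noise = list()),
    preprocessing = list(baseline_window = c(-150, 0), threshold_uv = 100,
                         post_window_ms = 1500, pre_window_ms = 800,
                         monitor_channels = NULL, min_epochs = 10L,
                         drop_epochs = integer()),
    timefreq = list(delta_cutoff_hz = 4, theta_cutoff_hz = 2, order = 3L,
                    downsample_to = 128, n_freq_bins = 65L,
                    crop_ms = c(-500, 1000)),
    tfpca = list(n_components = "scree", scale_loadings = TRUE,
                 delta_sensor = "Cz", theta_sensor = "FCz",
                 delta_override = NULL, theta_override = NULL),
    stats = list(robust = TRUE, age_screen_threshold = 0.05,
                 between = c("reexperiencing", "avoidance", "dysphoria",
                             "hyperarousal", "audit_c", "mtbi_severity")),
    output = list(write_epochs = FALSE)
  ), class = "run_config")
}

#' Validate a run configuration against the published schema
#'
#' Checks every key (recursively) against [default_run_config()]; unknown
#' keys are an error listing the offending paths. Omitted keys take their
#' default values. The generator sub-config is additionally validated by
#' [generator_config()].
#'
#' @param config nested list (e.g. parsed from YAML/JSON).
#' @return the merged, validated `run_config`.
#' @export
validate_run_config <- function(config) {
  ref <- default_run_config()
  bad <- character()
  walk <- function(cfg, refpart, path) {
    unknown <- setdiff(names(cfg), names(refpart))
    if (length(unknown))
      bad <<- c(bad, paste0(path, unknown))
    for (k in intersect(names(cfg), names(refpart))) {
      if (is.list(refpart[[k]]) && !is.null(names(refpart[[k]])) &&
          k != "monitor_channels" && is.list(cfg[[k]]))
        walk(cfg[[k]], refpart[[k]], paste0(path, k, "."))
    }
  }
  walk(config, ref, "")
  # generator sub-lists are free-form parameter lists validated downstream
  bad <- bad[!grepl("^generator\\.(covariates|behavior|amplitudes|templates|noise)\\.", bad)]
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  merged <- modifyList(unclass(ref), config)
  class(merged) <- "run_config"
  do.call(generator_config, merged$generator)  # errors on bad generator cfg
  merged
}

stage_hash <- function(...) digest::digest(list(...), algo = "md5")

#' Run the pipeline with file artifacts and resumable stages
#'
#' Executes simulate, preprocess, tfd, tfpca, score, behavior and stats
#' stages into a deterministic directory layout (covariates.csv,
#' trials.csv, erps.h5, tf_delta.h5/tf_theta.h5, tfpca_*.h5 + .json,
#' scores.csv, behavior.csv, models/*.json, run.log, config.lock.json).
#' Each stage records a content hash of its configuration and inputs; a
#' rerun skips stages whose hash matches and whose outputs exist, so
#' deleting one stage's outputs re-executes only from that stage onward.
#'
#' @param config a (possibly partial) run configuration; see
#'   [validate_run_config()].
#' @param out_dir artifact directory (created if needed).
#' @param stages subset of stages to run (`"all"` for the full chain).
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir, stages = "all") {
  cfg <- validate_run_config(config)
  all_stages <- c("simulate", "preprocess", "tfd", "tfpca", "score",
                  "behavior", "stats")
  if (identical(stages, "all")) stages <- all_stages
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "models"), showWarnings = FALSE)
  logf <- file.path(out_dir, "run.log")
  logmsg <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    sprintf(...))
    cat(line, "\n", file = logf, append = TRUE)
    message(line)
  }
  jsonlite::write_json(unclass(cfg), file.path(out_dir, "config.lock.json"),
                       auto_unbox = TRUE, null = "null", digits = NA,
                       pretty = TRUE)
  logmsg("pipeline start: package %s, seed %d",
         as.character(utils::packageVersion("erptfpca")), cfg$seed)

  fp <- function(...) file.path(out_dir, ...)
  gen <- do.call(generator_config, cfg$generator)

  run_stage <- function(name, outputs, hash, fun) {
    hfile <- fp(paste0(".", name, ".hash"))
    if (!name %in% stages) return(invisible())
    if (file.exists(hfile) && readLines(hfile)[1] == hash &&
        all(file.exists(fp(outputs)))) {
      logmsg("stage %s: up to date, skipped", name)
      return(invisible())
    }
    t0 <- Sys.time()
    fun()
    writeLines(hash, hfile)
    logmsg("stage %s: done in %.1f s", name,
           as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }

  h_sim <- stage_hash(cfg$generator, cfg$seed)
  run_stage("simulate", c("covariates.csv", "trials.csv"), h_sim, function() {
    cohort <- simulate_cohort(gen$n_subjects, gen, cfg$seed)
    trials <- simulate_behavior(cohort, gen, cfg$seed)
    trials <- simulate_trial_amplitudes(cohort, trials, gen, cfg$seed)
    write.csv(cohort, fp("covariates.csv"), row.names = FALSE)
    write.csv(trials, fp("trials.csv"), row.names = FALSE)
  })

  h_pre <- stage_hash(h_sim, cfg$preprocessing, cfg$output$write_epochs)
  run_stage("preprocess", "erps.h5", h_pre, function() {
    cohort <- read.csv(fp("covariates.csv"), stringsAsFactors = FALSE)
    trials <- read.csv(fp("trials.csv"), stringsAsFactors = FALSE)
    pp <- cfg$preprocessing
    erps <- vector("list", nrow(cohort))
    if (cfg$output$write_epochs)
      dir.create(fp("epochs"), showWarnings = FALSE)
    for (s in seq_len(nrow(cohort))) {
      ep <- simulate_subject_epochs(
        cohort[s, ], trials[trials$subject_id == cohort$subject_id[s], ],
        gen, seed = child_seed(cfg$seed, "epochs", s))
      if (cfg$output$write_epochs)
        write_epochs(ep, fp("epochs", paste0(cohort$subject_id[s], ".h5")))
      erps[[s]] <- preprocess_epochs(
        ep, baseline_window = pp$baseline_window,
        monitor_channels = pp$monitor_channels,
        threshold_uv = pp$threshold_uv,
        post_window_ms = pp$post_window_ms,
        pre_window_ms = pp$pre_window_ms,
        drop_epochs = pp$drop_epochs, min_epochs = pp$min_epochs)
    }
    write_erps(erps, fp("erps.h5"))
  })

  bands <- band_config(cfg$timefreq$delta_cutoff_hz, cfg$timefreq$theta_cutoff_hz,
                       cfg$timefreq$order, cfg$timefreq$downsample_to,
                       cfg$timefreq$n_freq_bins, cfg$timefreq$crop_ms)
  h_tfd <- stage_hash(h_pre, cfg$timefreq)
  run_stage("tfd", c("tf_delta.h5", "tf_theta.h5"), h_tfd, function() {
    erps <- read_erps(fp("erps.h5"))
    surfaces <- erp_band_surfaces(erps, bands)
    write_tf_stack(surfaces$delta, fp("tf_delta.h5"))
    write_tf_stack(surfaces$theta, fp("tf_theta.h5"))
  })

  h_pca <- stage_hash(h_tfd, cfg$tfpca[c("n_components", "scale_loadings",
                                         "delta_override", "theta_override")])
  run_stage("tfpca", c("tfpca_delta.h5", "tfpca_theta.h5",
                       "tfpca_delta.json", "tfpca_theta.json"), h_pca, function() {
    for (band in c("delta", "theta")) {
      X <- build_data_matrix(read_tf_stack(fp(paste0("tf_", band, ".h5"))))
      model <- fit_tfpca(X, cfg$tfpca$n_components, cfg$tfpca$scale_loadings)
      target <- if (band == "delta") "delta-RewP" else "theta-FRN"
      sel <- select_component(model, target,
                              override = cfg$tfpca[[paste0(band, "_override")]])
      write_tfpca_model(model, sel, fp(paste0("tfpca_", band, ".h5")),
                        fp(paste0("tfpca_", band, ".json")))
    }
  })

  h_score <- stage_hash(h_pca, cfg$tfpca[c("delta_sensor", "theta_sensor")])
  run_stage("score", "scores.csv", h_score, function() {
    sc <- list()
    for (band in c("delta", "theta")) {
      X <- build_data_matrix(read_tf_stack(fp(paste0("tf_", band, ".h5"))))
      mw <- read_tfpca_model(fp(paste0("tfpca_", band, ".h5")))
      target <- if (band == "delta") "delta-RewP" else "theta-FRN"
      sc[[band]] <- pc_weighted_scores(mw$model, X, mw$selected,
                                       cfg$tfpca[[paste0(band, "_sensor")]],
                                       target)
    }
    write.csv(rbind(sc$delta, sc$theta), fp("scores.csv"), row.names = FALSE)
  })

  h_beh <- stage_hash(h_sim, "behavior")
  run_stage("behavior", "behavior.csv", h_beh, function() {
    trials <- read.csv(fp("trials.csv"), stringsAsFactors = FALSE)
    write.csv(risky_choice_proportion(trials), fp("behavior.csv"),
              row.names = FALSE)
  })

  h_stats <- stage_hash(h_score, h_beh, cfg$stats)
  run_stage("stats", file.path("models", "theta.json"), h_stats, function() {
    cohort <- read.csv(fp("covariates.csv"), stringsAsFactors = FALSE)
    scores <- read.csv(fp("scores.csv"), stringsAsFactors = FALSE)
    behavior <- read.csv(fp("behavior.csv"), stringsAsFactors = FALSE)
    st <- cfg$stats
    sc_theta <- scores[scores$component == "theta-FRN", ]
    sc_delta <- scores[scores$component == "delta-RewP", ]
    screen <- screen_age(sc_theta, cohort, st$age_screen_threshold)
    extra <- if (screen$include_age) "age" else character()
    fits <- list(
      delta = fit_mixed_model(scores_long(sc_delta, cohort),
                              model_spec("dv", "outcome", st$between,
                                         robust = st$robust)),
      theta = fit_mixed_model(scores_long(sc_theta, cohort),
                              model_spec("dv", "outcome", st$between,
                                         covariates_extra = extra,
                                         robust = st$robust)),
      behavior = fit_mixed_model(behavior_long(behavior, cohort),
                                 model_spec("dv", "prev_outcome", st$between,
                                            robust = st$robust)))
    for (nm in names(fits))
      write_model_result(fits[[nm]], fp("models", paste0(nm, ".json")),
                         extras = if (nm == "theta") list(age_screen = screen))
  })

  logmsg("pipeline complete")
  invisible(out_dir)
}
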