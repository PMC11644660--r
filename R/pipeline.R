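#' Pipeline run configuration
#'
#' A single nested list drives an end-to-end run; all randomness flows from
#' one root `seed`, stage parameters default to the package defaults, and
#' the configuration round-trips losslessly through YAML or JSON. Unknown
#' keys are rejected to catch typos early.
#'
#' @param seed Root integer seed.
#' @param out Output directory.
#' @param simulate List: `n_subjects`, `duration`, `fps`, plus any
#'   [cohort_spec()] / [trace_spec()] overrides.
#' @param pulse List: `method`, `low`, `high`, `order`, `window_l`.
#' @param features List: `n_bins`.
#' @param train List: `model`, `modalities` (character subset of
#'   `c("video", "physical")`), `k`.
#' @param stages Character vector of stages to execute, in order, from
#'   `simulate`, `pulse`, `features`, `train`, `ablate`, `baselines`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, out = tempfile("pulsemodal_run_"),
                       simulate = list(), pulse = list(), features = list(),
                       train = list(), stages = c("simulate", "pulse",
                                                  "features", "train")) {
  defaults <- list(
    seed = as.integer(seed), out = out,
    simulate = list(n_subjects = 60L, duration = 60, fps = 30),
    pulse = list(method = "pos", low = 0.8, high = 2.0, order = 4L,
                 window_l = NULL),
    features = list(n_bins = 30L),
    train = list(model = "rf", modalities = c("video", "physical"), k = 5L),
    stages = stages
  )
  merge_known <- function(base, user, where) {
    unknown <- setdiff(names(user), names(base))
    if (length(unknown)) {
      stop(sprintf("unknown config key%s in %s: %s",
                   if (length(unknown) > 1) "s" else "", where,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    utils::modifyList(base, user)
  }
  allowed_sim <- c(names(defaults$simulate),
                   setdiff(names(formals(cohort_spec)), "seed"),
                   setdiff(names(formals(trace_spec)), "seed"))
  unknown_sim <- setdiff(names(simulate), allowed_sim)
  if (length(unknown_sim)) {
    stop("unknown config keys in simulate: ", paste(unknown_sim, collapse = ", "),
         call. = FALSE)
  }
  cfg <- defaults
  cfg$simulate <- utils::modifyList(cfg$simulate, simulate)
  cfg$pulse <- merge_known(cfg$pulse, pulse, "pulse")
  cfg$features <- merge_known(cfg$features, features, "features")
  cfg$train <- merge_known(cfg$train, train, "train")
  bad <- setdiff(cfg$stages, c("simulate", "pulse", "features", "train",
                               "ablate", "baselines"))
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "), call. = FALSE)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML or JSON file.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(run_config, raw)
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.sim_cohort_spec <- function(sim, seed) {
  args <- sim[intersect(names(sim), setdiff(names(formals(cohort_spec)), "seed"))]
  args$n_subjects <- sim$n_subjects
  args$seed <- seed
  do.call(cohort_spec, args)
}

#' Run the pipeline end to end
#'
#' Executes the requested stages in order: `simulate` generates a cohort
#' and one synthetic trace per subject at that subject's reference heart
#' rate; `pulse` extracts and bandpasses the pulse signal; `features`
#' derives the eleven-feature row per subject; `train` fits the
#' grid-searched model under cross-validation; `ablate` and `baselines`
#' produce the modality ablation and method comparison tables. Artifacts
#' are written under `config$out`, every CSV accompanied by the
#' configuration hash, and a `run.json` log records the seed, stages and
#' hash.
#'
#' @param config A [run_config()] (or a path readable by
#'   [read_run_config()]).
#' @return A list of in-memory results (`cohort`, `traces`, `pulses`,
#'   `features`, `cv`, `ablation`, `baselines` as applicable), invisibly,
#'   with the artifact directory in `$out`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- rlang::hash(unclass(config))
  res <- list(out = config$out, hash = cfg_hash)

  # validate trace parameters before any work: Nyquist etc.
  sim <- config$simulate
  trace_args <- sim[intersect(names(sim),
                              setdiff(names(formals(trace_spec)),
                                      c("seed", "duration", "fps", "hr")))]
  probe <- do.call(trace_spec, c(trace_args,
                                 list(duration = sim$duration, fps = sim$fps,
                                      seed = config$seed)))

  flt <- filter_spec(config$pulse$low, config$pulse$high, config$pulse$order)

  for (stage in config$stages) {
    if (stage == "simulate") {
      res$cohort <- sample_cohort(.sim_cohort_spec(sim, config$seed))
      res$traces <- lapply(seq_len(nrow(res$cohort)), function(i) {
        synth_rgb_trace(do.call(trace_spec, c(
          trace_args,
          list(duration = sim$duration, fps = sim$fps,
               hr = res$cohort$hr_reference[i],
               seed = (config$seed + 7919L * i) %% .Machine$integer.max)
        )))
      })
      write_cohort(res$cohort, file.path(config$out, "cohort.csv"))
      tr_dir <- file.path(config$out, "traces")
      dir.create(tr_dir, showWarnings = FALSE)
      for (i in seq_along(res$traces)) {
        write_trace(res$traces[[i]],
                    file.path(tr_dir, paste0(res$cohort$subject_id[i], ".csv")))
      }
    } else if (stage == "pulse") {
      if (is.null(res$traces)) stop("pulse stage needs traces (run simulate first)",
                                    call. = FALSE)
      res$pulses <- lapply(seq_along(res$traces), function(i) {
        extract_pulse(res$traces[[i]], method = config$pulse$method,
                      filter = flt, seed = config$seed,
                      window_l = config$pulse$window_l)
      })
    } else if (stage == "features") {
      if (is.null(res$pulses)) stop("features stage needs pulses", call. = FALSE)
      res$features <- purrr::map_dfr(seq_along(res$pulses), function(i) {
        dplyr::bind_cols(
          tibble::tibble(subject_id = res$cohort$subject_id[i]),
          extract_features(res$pulses[[i]], n_bins = config$features$n_bins)
        )
      })
      write_features(res$features, file.path(config$out, "features.csv"))
    } else if (stage == "train") {
      tab <- assemble_table(res$features, res$cohort,
                            video = "video" %in% config$train$modalities,
                            physical = "physical" %in% config$train$modalities)
      res$cv <- run_grid_search_cv(tab, model = config$train$model,
                                   k = config$train$k, seed = config$seed)
      jsonlite::write_json(
        c(list(hash = cfg_hash), as.list(glance(res$cv))),
        file.path(config$out, "report.json"), auto_unbox = TRUE, digits = NA
      )
    } else if (stage == "ablate") {
      res$ablation <- ablation_study(res$features, res$cohort,
                                     k = config$train$k, seed = config$seed)
      utils::write.csv(as.data.frame(tidy(res$ablation)),
                       file.path(config$out, "ablation.csv"), row.names = FALSE)
    } else if (stage == "baselines") {
      res$baselines <- compare_baselines(res$traces, res$cohort,
                                         seed = config$seed, filter = flt)
      utils::write.csv(as.data.frame(res$baselines),
                       file.path(config$out, "baselines.csv"), row.names = FALSE)
    }
  }

  jsonlite::write_json(
    list(hash = cfg_hash, seed = config$seed, stages = config$stages,
         package_version = as.character(utils::packageVersion("pulsemodal"))),
    file.path(config$out, "run.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(res)
}
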