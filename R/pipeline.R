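# Reproducible end-to-end runs: a YAML-configurable command surface
# binding simulation, training, threshold calibration, scoring, LOSO
# evaluation and weight export. Every run writes its fully resolved
# configuration next to its outputs so any artifact is reconstructible
# from config + seed.

#' Read/resolve a pipeline run configuration
#'
#' @param config A YAML file path or a named list. Recognized top-level
#'   sections: `synth` (arguments to [synth_config()]), `pipeline`
#'   (arguments to [pipeline_config()]), `train` (arguments to
#'   [train_config()]), `model`, `seed`.
#' @return Fully resolved list of class `run_config` with defaults
#'   filled in.
#' @export
resolve_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) {
    abort_actisleep("config must be a list or YAML path",
                    "actisleep_config_error")
  }
  known <- c("synth", "pipeline", "train", "model", "seed")
  bad <- setdiff(names(config), known)
  if (length(bad) > 0) {
    abort_actisleep(sprintf("unknown config field(s): %s",
                            paste(bad, collapse = ", ")),
                    "actisleep_config_error")
  }
  seed <- as.integer(config$seed %||% 1L)
  synth <- do.call(synth_config,
                   utils::modifyList(list(seed = seed),
                                     as.list(config$synth %||% list())))
  train <- do.call(train_config,
                   utils::modifyList(list(seed = seed),
                                     as.list(config$train %||% list())))
  pipe_args <- utils::modifyList(list(train = train, seed = seed),
                                 as.list(config$pipeline %||% list()))
  pipeline <- do.call(pipeline_config, pipe_args)
  structure(list(synth = synth, pipeline = pipeline,
                 model = config$model %||% "lightcnna", seed = seed),
            class = "run_config")
}

serialize_config <- function(rc) {
  list(
    seed = rc$seed,
    model = rc$model,
    synth = lapply(unclass(rc$synth), function(x) x),
    pipeline = list(
      decimation_factor = rc$pipeline$decimation_factor,
      threshold_mode = rc$pipeline$threshold_mode,
      fixed_threshold = rc$pipeline$fixed_threshold
    ),
    train = lapply(unclass(rc$pipeline$train), function(x) x)
  )
}

# Deterministic JSON: fixed precision, no scientific drift across runs.
write_summary_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(path)
}

#' Run a pipeline command
#'
#' Commands:
#' * `simulate`: generate a cohort and write per-subject recording and
#'   hypnogram CSVs.
#' * `train`: train lightCNNA on a simulated or on-disk cohort and
#'   write the weight container.
#' * `loso`: full leave-one-subject-out evaluation; writes
#'   `loso_folds.csv` and `summary.json`.
#' * `export`: flat text weight export for OS-less targets.
#'
#' Every command writes `resolved_config.yaml` into `out_dir`. Partial
#' results are written to temporaries and renamed, so a failed run
#' leaves no corrupt outputs.
#'
#' @param command One of `simulate`, `train`, `loso`, `export`.
#' @param config Path to a YAML config, or a named list (see
#'   [resolve_config()]).
#' @param out_dir Output directory (created if missing).
#' @param cohort_dir For `train`/`loso`: directory of CSVs from a prior
#'   `simulate` run; when `NULL` the cohort is regenerated from the
#'   config.
#' @param weights_path For `export`: weight container to flatten.
#' @return Invisible list of written artifact paths.
#' @export
run_pipeline <- function(command = c("simulate", "train", "loso", "export"),
                         config = list(), out_dir = ".",
                         cohort_dir = NULL, weights_path = NULL) {
  command <- match.arg(command)
  rc <- resolve_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(serialize_config(rc),
                   file.path(out_dir, "resolved_config.yaml"))
  artifacts <- c(config = file.path(out_dir, "resolved_config.yaml"))

  load_cohort <- function() {
    if (is.null(cohort_dir)) return(generate_cohort(rc$synth))
    ids <- sub("_accel\\.csv$", "",
               basename(list.files(cohort_dir, pattern = "_accel\\.csv$")))
    if (length(ids) == 0) {
      abort_actisleep(sprintf("no cohort CSVs found in %s", cohort_dir),
                      "actisleep_config_error")
    }
    rows <- lapply(sort(ids), function(id) {
      tibble(
        subject_id = id,
        recording = list(read_accel_csv(
          file.path(cohort_dir, paste0(id, "_accel.csv")))),
        hypnogram = list(read_hypnogram_csv(
          file.path(cohort_dir, paste0(id, "_hypnogram.csv"))))
      )
    })
    out <- dplyr::bind_rows(rows)
    class(out) <- c("acti_cohort", class(out))
    out
  }

  if (command == "simulate") {
    cohort <- generate_cohort(rc$synth)
    for (i in seq_len(nrow(cohort))) {
      id <- cohort$subject_id[i]
      write_accel_csv(cohort$recording[[i]],
                      file.path(out_dir, paste0(id, "_accel.csv")))
      write_hypnogram_csv(cohort$hypnogram[[i]],
                          file.path(out_dir, paste0(id, "_hypnogram.csv")))
    }
    artifacts <- c(artifacts, cohort = out_dir)
  } else if (command == "train") {
    cohort <- load_cohort()
    subjects <- prepare_subjects(cohort, rc$pipeline)
    fit <- lightcnna_train(lapply(subjects, function(s) s$windows),
                           config = rc$pipeline$train)
    wpath <- file.path(out_dir, "weights.json")
    tmp <- paste0(wpath, ".tmp")
    write_weights(fit$weights, tmp)
    file.rename(tmp, wpath)
    readr::write_csv(fit$history, file.path(out_dir, "history.csv"))
    artifacts <- c(artifacts, weights = wpath,
                   history = file.path(out_dir, "history.csv"))
  } else if (command == "loso") {
    cohort <- load_cohort()
    res <- loso_evaluate(cohort, model = rc$model, config = rc$pipeline)
    fpath <- file.path(out_dir, "loso_folds.csv")
    readr::write_csv(dplyr::mutate(res$folds,
                                   dplyr::across(dplyr::where(is.numeric),
                                                 ~ signif(.x, 10))),
                     fpath)
    spath <- file.path(out_dir, "summary.json")
    tmp <- paste0(spath, ".tmp")
    write_summary_json(list(
      model = res$model,
      n_subjects = nrow(res$folds),
      summary = res$summary,
      thresholds = res$thresholds,
      fold_fingerprints = res$fingerprints
    ), tmp)
    file.rename(tmp, spath)
    artifacts <- c(artifacts, folds = fpath, summary = spath)
  } else if (command == "export") {
    if (is.null(weights_path)) {
      abort_actisleep("export needs weights_path", "actisleep_config_error")
    }
    w <- read_weights(weights_path)
    fpath <- file.path(out_dir, "weights_flat.txt")
    export_flat_array(w, fpath)
    artifacts <- c(artifacts, flat = fpath)
  }
  invisible(artifacts)
}
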