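#' Default end-to-end pipeline configuration
#'
#' All stage parameters of the simulate -> preprocess -> decompose ->
#' featurize -> baseline -> evaluate pipeline, as a named list that can
#' also be read from a YAML file. Unknown keys are rejected by
#' [run_pipeline()].
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    persons = 16L, modes = 6L, separation = 1, steps_per_person = 30L,
    feet = c("l", "r"), speeds = "normal", seed = 1L,
    render = FALSE, passes = 4L, steps_per_pass = 8L,
    pad_to = 100L, min_gap = 5L, contact_rel = 0.005, min_area = 20L,
    K = 6L, rank = 12L,
    fraction = 0.3, repeats = 1000L, holdout = FALSE,
    standardized = FALSE,
    out_dir = "gaitdmd-run"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with any subset of [default_config()]'s keys.
#' @return Full config list (file values over defaults).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  merge_config(cfg)
}

#' @rdname read_config
#' @param cfg Named list overriding defaults.
#' @export
merge_config <- function(cfg = list()) {
  base <- default_config()
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  base[names(cfg)] <- cfg
  base
}

#' Run the full gait-identification pipeline
#'
#' Simulates a cohort, obtains per-step force signals (directly, or --
#' with `render = TRUE` -- by rendering full walkway pressure recordings
#' and running the preprocessing stack on them), fits Hankel DMD per
#' step, featurizes, builds baselines, and runs the Monte-Carlo
#' identification evaluation. All artifacts (cohort, features CSV,
#' baselines JSON, evaluation JSON, confusion CSV) are written to
#' `config$out_dir` together with a manifest recording the configuration
#' and artifact checksums; a rerun with the same config reproduces
#' identical checksums.
#'
#' @param config Config list (see [default_config()]) or a YAML path.
#' @return The output directory, invisibly; the manifest is
#'   `<out_dir>/manifest.json`.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- read_config(config)
  cfg <- merge_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  message("stage simulate: ", cfg$persons, " walkers, separation ",
          cfg$separation)
  cohort <- make_cohort(n_persons = cfg$persons, n_modes = cfg$modes,
                        separation = cfg$separation,
                        steps_per_person = cfg$steps_per_person,
                        seed = cfg$seed)
  if (isTRUE(cfg$render)) {
    steps <- .render_and_extract(cohort, cfg)
  } else {
    steps <- simulate_cohort_steps(cohort, feet = cfg$feet,
                                   speeds = cfg$speeds,
                                   seed = cfg$seed + 1L,
                                   n_frames = cfg$pad_to)
  }
  message("stage features: ", nrow(steps), " steps")
  features <- featurize_steps(steps, K = cfg$K,
                              rank_rule = rank_fixed(cfg$rank))
  gallery <- build_gallery(features)
  message("stage evaluate: ", cfg$repeats, " repeats @ fraction ",
          cfg$fraction)
  report <- evaluate_identification(features, fraction = cfg$fraction,
                                    n_repeats = cfg$repeats,
                                    seed = cfg$seed + 2L,
                                    holdout = cfg$holdout,
                                    standardized = cfg$standardized)
  paths <- c(
    cohort = file.path(cfg$out_dir, "cohort.json"),
    features = file.path(cfg$out_dir, "features.csv"),
    baselines = file.path(cfg$out_dir, "baselines.json"),
    evaluation = file.path(cfg$out_dir, "evaluation.json"),
    confusion = file.path(cfg$out_dir, "confusion.csv"))
  jsonlite::write_json(as.data.frame(cohort), paths["cohort"],
                       digits = NA, auto_unbox = TRUE)
  write_features_csv(features, paths["features"])
  jsonlite::write_json(as.data.frame(gallery), paths["baselines"],
                       digits = NA, auto_unbox = TRUE)
  jsonlite::write_json(list(summary = as.data.frame(report$summary),
                            fraction = report$fraction,
                            holdout = report$holdout,
                            seed = report$seed),
                       paths["evaluation"], digits = NA, auto_unbox = TRUE)
  readr::write_csv(report$confusion, paths["confusion"])
  manifest <- list(
    package = "gaitdmd",
    version = as.character(utils::packageVersion("gaitdmd")),
    config = cfg[order(names(cfg))],
    checksums = as.list(tools::md5sum(unname(paths))))
  names(manifest$checksums) <- basename(names(manifest$checksums))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  message("done: ", cfg$out_dir)
  invisible(cfg$out_dir)
}

# full-physics route: render pressure recordings per person and speed,
# then run the preprocessing stack to recover the step signals
.render_and_extract <- function(cohort, cfg) {
  persons <- unique(cohort$person)
  purrr::map_dfr(seq_along(persons), function(i) {
    prof <- person_profile(cohort, persons[i])
    rec <- simulate_recording(prof, n_passes = cfg$passes,
                              steps_per_pass = cfg$steps_per_pass,
                              seed = cfg$seed + 100L + i)
    steps <- extract_steps(rec, min_gap = cfg$min_gap,
                           contact_rel = cfg$contact_rel,
                           min_area = cfg$min_area, pad_to = cfg$pad_to)
    steps$person <- persons[i]
    steps$speed <- "normal"
    dplyr::select(steps, "person", "foot", "cycle",
                  dplyr::any_of("speed"), "signal")
  })
}
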