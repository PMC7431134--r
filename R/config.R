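## Run configuration: one flat JSON document per run, validated before any
## compute, with every field serializable and round-trippable. Unknown keys
## are rejected so typos fail fast with a field-level message.

.config_schema <- list(
  command = c("simulate", "reconstruct", "phase", "train", "predict",
              "evaluate"),
  top = c("command", "seed", "out_dir", "paths", "optics", "reg", "model",
          "train", "tiling", "simulate", "evaluate"),
  paths = c("sample", "background", "m0", "model", "input", "target",
            "prediction", "stats"),
  optics = c("wavelength", "na_detection", "na_illumination", "pixel_size",
             "z_step", "chi", "medium_index"),
  reg = c("tau_phase", "tau_abs", "method", "tv_iterations", "tv_penalty",
          "seed", "mode"),
  model = c("variant", "in_channels", "out_channels", "n_slices",
            "filters"),
  train = c("batch_size", "lr_min", "lr_max", "half_cycle_epochs",
            "patience", "max_epochs", "masked", "seed", "n_phantoms",
            "phantom_kind", "generator", "tile", "shape"),
  tiling = c("tile", "overlap_frac", "inference_tile", "inference_overlap",
             "foreground_fraction"),
  simulate = c("kind", "shape", "params", "photon_budget", "background",
               "residual_background", "dialect"),
  evaluate = c("window", "masked")
)

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop("unknown config field(s) in ", where, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
}

require_fields <- function(x, fields, where) {
  missing <- setdiff(fields, names(x))
  if (length(missing))
    stop("config is missing required field(s) in ", where, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
}

#' Validate and normalize a run configuration
#'
#' @param config A named list (typically parsed from JSON with
#'   [jsonlite::fromJSON()]) or a path to a JSON file.
#' @return Validated config list of class `run_config`, with defaults
#'   filled in (`seed` 1, empty sections).
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  stopifnot(is.list(config))
  check_keys(config, .config_schema$top, "top level")
  require_fields(config, "command", "top level")
  if (!config$command %in% .config_schema$command)
    stop("unknown command: ", config$command)
  for (sec in c("paths", "optics", "reg", "model", "train", "tiling",
                "simulate", "evaluate"))
    if (!is.null(config[[sec]]))
      check_keys(config[[sec]], .config_schema[[sec]], sec)
  config$seed <- as.integer(config$seed %||% 1L)
  config$out_dir <- config$out_dir %||% "."
  ## command-specific requirements, checked before any compute
  need_optics <- config$command %in% c("simulate", "phase")
  if (need_optics) {
    require_fields(config, "optics", "top level")
    require_fields(config$optics,
                   c("wavelength", "na_detection", "na_illumination",
                     "pixel_size", "z_step"), "optics")
  }
  if (config$command == "reconstruct")
    require_fields(config$paths %||% list(), c("sample", "background"),
                   "paths")
  if (config$command == "phase")
    require_fields(config$paths %||% list(), "m0", "paths")
  if (config$command == "predict")
    require_fields(config$paths %||% list(), c("model", "input"), "paths")
  if (config$command == "evaluate")
    require_fields(config$paths %||% list(), c("target", "prediction"),
                   "paths")
  class(config) <- c("run_config", "list")
  config
}

config_optics <- function(config) {
  o <- config$optics
  optics_config(wavelength = o$wavelength, na_detection = o$na_detection,
                na_illumination = o$na_illumination,
                pixel_size = o$pixel_size, z_step = o$z_step,
                chi = o$chi %||% (0.06 * pi),
                medium_index = o$medium_index %||% 1.0)
}

config_reg <- function(config) {
  r <- config$reg %||% list()
  reg_config(tau_phase = r$tau_phase %||% 1e-3,
             tau_abs = r$tau_abs %||% 1e-3,
             method = r$method %||% "Tikhonov",
             tv_iterations = r$tv_iterations %||% 50L,
             tv_penalty = r$tv_penalty %||% 1.0,
             seed = r$seed)
}

write_run_artifacts <- function(config, dir, log_lines) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- unclass(config)
  cfg$package_version <- as.character(utils::packageVersion("qpli"))
  jsonlite::write_json(cfg, file.path(dir, "config.resolved.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  writeLines(log_lines, file.path(dir, "run.log"))
}
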