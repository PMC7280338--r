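# JSON configuration. The shipped defaults live in inst/config/defaults.json;
# unknown keys are rejected with their location so typos surface immediately.

.config_schema <- list(
  sg = list(window_samples = "integer_or_null", poly_order = "integer"),
  quality = list(window_ms = "number"),
  classifiers = "classifier_list",
  export = list(streams = "character"),
  paths = list(root = "string_or_null", out = "string_or_null")
)

.check_keys <- function(obj, schema, where) {
  unknown <- setdiff(names(obj), names(schema))
  if (length(unknown))
    wg_validation_error(sprintf("unknown config key(s) at %s: %s", where,
                                paste(unknown, collapse = ", ")))
  for (k in names(obj)) {
    s <- schema[[k]]
    loc <- paste0(where, ".", k)
    if (is.list(s)) {
      if (!is.list(obj[[k]]))
        wg_validation_error(sprintf("config key %s must be an object", loc))
      .check_keys(obj[[k]], s, loc)
    } else if (identical(s, "classifier_list")) {
      for (i in seq_along(obj[[k]]))
        .check_keys(obj[[k]][[i]],
                    list(id = "string", entry_point = "string",
                         parameters = "parameter_list"),
                    sprintf("%s[%d]", loc, i))
    }
  }
  invisible(TRUE)
}

#' Load and validate a tool configuration
#'
#' Reads a JSON configuration (the packaged `defaults.json` when `path` is
#' `NULL`), validates it against the known key set — unknown keys are
#' rejected with their location — and checks parameter ranges. The result
#' drives the Savitzky-Golay settings, the quality window and the
#' classifier specifications used by the command-line interface.
#'
#' @param path Path to a JSON config file, or `NULL` for the defaults.
#' @return A validated config list of class `wg_config`.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("config", "defaults.json", package = "weargaze")
  if (!file.exists(path))
    wg_missing_input(sprintf("config file not found: %s", path))
  cfg <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    wg_parse_error(sprintf("invalid JSON in %s: %s", path,
                                           conditionMessage(e))))
  .check_keys(cfg, .config_schema, "$")
  if (!is.null(cfg$sg$window_samples)) {
    w <- cfg$sg$window_samples
    if (w < 3 || w %% 2 == 0)
      wg_validation_error("config $.sg.window_samples must be odd and >= 3")
  }
  if (!is.null(cfg$quality$window_ms) && cfg$quality$window_ms <= 0)
    wg_validation_error("config $.quality.window_ms must be positive")
  cfg$classifier_specs <- lapply(cfg$classifiers %||% list(), function(cl)
    classifier_spec(cl$id, cl$entry_point,
                    lapply(cl$parameters %||% list(), function(p)
                      list(name = p$name, value = p$value, min = p$min,
                           max = p$max,
                           user_settable = isTRUE(p$user_settable)))))
  structure(cfg, class = "wg_config")
}

# SG settings for a recording under a config (window derived from rate
# when not pinned in the config)
.config_sg <- function(cfg, rate_hz) {
  if (is.null(cfg$sg$window_samples)) .default_sg(rate_hz)
  else sg_settings(cfg$sg$window_samples, cfg$sg$poly_order %||% 2L)
}
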