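# Run configuration: one validated record through which every numeric
# convention (lambda, R grid, combination mode, ...) reaches the stages.

config_defaults <- function() {
  list(solver = "glpsol",
       min_methods = 2L,
       cell_line = "MCF7",
       lambda = 0.5,
       r_step = 1L,
       combine_mode = "additive",
       weight_fn = "abslog2",
       seed = 1L,
       log_level = "info")
}

#' Load and validate a run configuration
#'
#' Reads a YAML key-value file, fills defaults for missing keys, rejects
#' unknown keys and validates every value.  With `path = NULL` (or an
#' empty file) the defaults are returned.  The resolved configuration is
#' echoed through [log_msg()].
#'
#' @param path YAML file path, or NULL for defaults
#' @return object of class `run_config` (a named list)
#' @export
load_config <- function(path = NULL) {
  cfg <- config_defaults()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
  }
  validate_config(cfg)
  cfg <- structure(cfg, class = "run_config")
  log_msg("debug", "config: %s",
          paste(sprintf("%s=%s", names(cfg), unlist(cfg)), collapse = " "))
  cfg
}

validate_config <- function(cfg) {
  chk <- function(ok, key) if (!ok) stop("invalid config value for '",
                                         key, "'")
  chk(is.character(cfg$solver) && nzchar(cfg$solver), "solver")
  chk(is.numeric(cfg$min_methods) && cfg$min_methods >= 0 &&
        cfg$min_methods == round(cfg$min_methods), "min_methods")
  chk(is.character(cfg$cell_line) && nzchar(cfg$cell_line), "cell_line")
  chk(is.numeric(cfg$lambda) && cfg$lambda >= 0 && cfg$lambda <= 1,
      "lambda")
  chk(is.numeric(cfg$r_step) && cfg$r_step >= 1 &&
        cfg$r_step == round(cfg$r_step), "r_step")
  chk(cfg$combine_mode %in% c("additive", "saturating"), "combine_mode")
  chk(cfg$weight_fn %in% c("abslog2"), "weight_fn")
  chk(is.numeric(cfg$seed) && cfg$seed == round(cfg$seed), "seed")
  chk(cfg$log_level %in% c("debug", "info", "warning", "quiet"),
      "log_level")
  invisible(cfg)
}

#' Package logging
#'
#' Prints timestamped messages at or above the level set by
#' `options(cocktailnet.log_level = ...)` (default `"info"`).
#'
#' @param level one of `"debug"`, `"info"`, `"warning"`
#' @param fmt,... `sprintf` arguments
#' @export
log_msg <- function(level = "info", fmt, ...) {
  ranks <- c(debug = 1, info = 2, warning = 3, quiet = 4)
  threshold <- getOption("cocktailnet.log_level", "info")
  if (ranks[[level]] < ranks[[threshold]]) return(invisible(NULL))
  message(sprintf("[%s] %s %s", level, format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}
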