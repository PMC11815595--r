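#' Read a time-course CSV
#'
#' Expects the package's standard long format with header
#' `time_d,species,replicate,value`; species must be `biomass`, `sucrose`
#' or `kno3`, values non-negative.
#'
#' @param path File path.
#' @return A validated time-course tibble.
#' @export
read_timecourse_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dat <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           time_d = readr::col_double(),
                           species = readr::col_character(),
                           replicate = readr::col_integer(),
                           value = readr::col_double()))
  as_timecourse(dat)
}

#' Write a time-course dataset to CSV
#'
#' @param data A time-course tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_timecourse_csv <- function(data, path) {
  data <- as_timecourse(data)
  readr::write_csv(data[, c("time_d", "species", "replicate", "value")], path)
  invisible(path)
}

#' Write a fit report (JSON plus human-readable table)
#'
#' Writes a machine-readable JSON file with the estimated parameters, the
#' objective value, data-point and parameter counts, degrees of freedom and
#' residual variance, plus a plain-text table alongside it.
#'
#' @param fit A `vk_fit`.
#' @param path Output path for the JSON file (the text table gets the same
#'   path with extension `.txt`).
#' @return The JSON path, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "vk_fit"))
  g <- glance(fit)
  payload <- list(
    model = fit$model_type,
    parameters = as.list(unclass(fit$params)),
    objective = fit$objective,
    n = fit$n,
    p = fit$p,
    df = g$df,
    variance = g$variance,
    n_restarts = fit$n_restarts,
    seed = fit$seed,
    converged = fit$converged
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  txt <- sub("\\.json$", ".txt", path)
  if (identical(txt, path)) txt <- paste0(path, ".txt")
  lines <- c(
    sprintf("Model: %s", fit$model_type),
    sprintf("Weighted SSE: %.4g  n: %d  p: %d  df: %d  variance: %.4g",
            fit$objective, fit$n, fit$p, g$df, g$variance),
    "",
    utils::capture.output(print.data.frame(as.data.frame(tidy(fit)),
                                           row.names = FALSE))
  )
  writeLines(lines, txt)
  invisible(path)
}

#' Read a fit report back from JSON
#'
#' @param path Path to a JSON written by [write_fit_report()].
#' @return A list with the report fields; `parameters` is a `vk_params`.
#' @export
read_fit_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  rep$parameters <- as_kinetic_params(unlist(rep$parameters))
  rep
}

# ---- run configuration -----------------------------------------------------

config_schema <- function() {
  list(
    model_type = "character",
    params = "list", bounds = "list", init = "list",
    dt = "numeric", seed = "numeric", restarts = "numeric",
    weights = "list", feed = "list", design = "list",
    output = "character"
  )
}

#' Read and validate a YAML run configuration
#'
#' Known keys: `model_type`, `params` (named values), `bounds`
#' (`lower`/`upper` named lists), `init` (`x`, `s1`, `s2`, `v`), `dt`,
#' `seed`, `restarts`, `weights`, `feed` (the [feed_strategy()] fields),
#' `design` (per-control `min`/`max`/`levels` plus `t_end`, `v_max`) and
#' `output`. Unknown keys are rejected, as are physically meaningless
#' values (negative concentrations, non-positive `dt`).
#'
#' @param path Path to a YAML file.
#' @return The validated configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

#' Validate a configuration list against the documented schema
#'
#' @param cfg Configuration list (as from [read_run_config()]).
#' @return The configuration, invisibly usable, after checks.
#' @export
validate_config <- function(cfg) {
  schema <- config_schema()
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(cfg$model_type)) cfg$model_type <- model_type(cfg$model_type)
  if (!is.null(cfg$dt) && cfg$dt <= 0) stop("dt must be positive",
                                            call. = FALSE)
  if (!is.null(cfg$init)) {
    init <- cfg$init
    miss <- setdiff(c("x", "s1", "s2"), names(init))
    if (length(miss)) stop("init lacks: ", paste(miss, collapse = ", "),
                           call. = FALSE)
    validate_state(c(x = init$x, s1 = init$s1, s2 = init$s2,
                     v = init$v %||% 1))
  }
  if (!is.null(cfg$feed)) {
    do.call(feed_strategy, cfg$feed)  # constructor performs the checks
  }
  if (!is.null(cfg$bounds)) {
    if (!all(c("lower", "upper") %in% names(cfg$bounds))) {
      stop("bounds must provide lower and upper lists", call. = FALSE)
    }
  }
  if (!is.null(cfg$seed) && cfg$seed != round(cfg$seed)) {
    stop("seed must be an integer", call. = FALSE)
  }
  cfg
}

config_init <- function(cfg, default = vo_initial_state()) {
  if (is.null(cfg$init)) return(default)
  culture_state(cfg$init$x, cfg$init$s1, cfg$init$s2,
                cfg$init$v %||% unclass(default)[["v"]])
}

config_bounds <- function(cfg) {
  if (is.null(cfg$bounds)) return(vo_parameter_bounds())
  b <- vo_parameter_bounds()
  for (nm in names(cfg$bounds$lower)) b$lower[b$parameter == nm] <-
      cfg$bounds$lower[[nm]]
  for (nm in names(cfg$bounds$upper)) b$upper[b$parameter == nm] <-
      cfg$bounds$upper[[nm]]
  validate_bounds(b)
}

config_params <- function(cfg, default = vo_batch_params()) {
  if (is.null(cfg$params)) return(default)
  p <- unclass(default)
  for (nm in names(cfg$params)) {
    if (!nm %in% param_names()) stop("unknown parameter in config: ", nm,
                                     call. = FALSE)
    p[[nm]] <- cfg$params[[nm]]
  }
  as_kinetic_params(p)
}
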