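#' Run configuration files
#'
#' A run configuration is a flat, typed, human-editable JSON document with
#' one table per concern: `model` (the [model_params()] fields),
#' `experiment` (selector plus arguments), `composition` (initial
#' fractions), `stages` (staged parameter changes), `output_dir` and
#' `seed`. Configurations round-trip losslessly through
#' [save_config()] / [load_config()]; unknown keys are rejected with the
#' offending name.
#'
#' @param path file path.
#' @return `load_config()`: a validated list of class `abx_config` with
#'   elements `params` (an `abx_params`), `experiment`, `composition`,
#'   `stages`, `output_dir`, `seed`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  top_allowed <- c("model", "experiment", "composition", "stages",
                   "output_dir", "seed")
  bad <- setdiff(names(raw), top_allowed)
  if (length(bad)) stop("config error: unknown key(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  model_keys <- setdiff(names(formals(model_params)), c("init_fractions"))
  mb <- setdiff(names(raw$model), model_keys)
  if (length(mb)) stop("config error: unknown model key(s): ",
                       paste(mb, collapse = ", "), call. = FALSE)
  flatten1 <- function(x) if (is.list(x)) unlist(x, use.names = FALSE) else x
  params <- do.call(model_params, lapply(raw$model, flatten1))
  comp <- if (is.null(raw$composition) || length(raw$composition) == 0)
    lattice_composition()
  else lattice_composition(unlist(raw$composition))
  stages <- if (is.null(raw$stages) || length(raw$stages) == 0) NULL else {
    lapply(raw$stages, function(st) {
      if (!setequal(names(st), c("time", "set")))
        stop("config error: each stage needs exactly 'time' and 'set'", call. = FALSE)
      list(time = as.numeric(st$time), set = lapply(st$set, flatten1))
    })
  }
  structure(list(params = params,
                 experiment = raw$experiment,
                 composition = comp,
                 stages = stages,
                 output_dir = raw$output_dir %||% ".",
                 seed = as.integer(raw$seed %||% params$seed)),
            class = "abx_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname load_config
#' @param config an `abx_config` object (or a list with the same shape).
#' @export
save_config <- function(config, path) {
  p <- config$params
  model <- p[setdiff(names(formals(model_params)), c("init_fractions"))]
  model <- model[!vapply(model, is.null, logical(1))]
  doc <- list(model = model,
              experiment = config$experiment,
              composition = as.list(config$composition),
              stages = config$stages,
              output_dir = config$output_dir,
              seed = config$seed)
  doc <- doc[!vapply(doc, is.null, logical(1))]
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run metadata records
#'
#' Every CLI run writes a JSON metadata record (parameters, seed, package
#' version, wall time) next to its outputs so that any result can be
#' replayed exactly.
#'
#' @param params the `abx_params` used.
#' @param seed the run seed.
#' @param extra named list of additional fields.
#' @param path output path.
#' @keywords internal
write_run_metadata <- function(params, seed, path, extra = list()) {
  rec <- c(list(package = "spatabx",
                version = as.character(utils::packageVersion("spatabx")),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                seed = seed,
                params = params[setdiff(names(params), "init_fractions")]),
           extra)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
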