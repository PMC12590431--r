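# YAML run configuration: validation, defaults, resolution.

.default_config <- function() {
  list(
    space = list(speed = c(0, 5000), main = c(50, 400), pre_max = "main"),
    oracle = list(),                       # named overrides of oracle_params
    al = list(n_init = 30, n_iter = 78, pool_size = 4096, n_val = 100,
              retune_every = 1, tune_budget = 30),
    region = list(n_candidates = 5000, frac = 0.99, alpha = "auto",
                  lab_space = TRUE),
    maps = list(main = c(250, 300, 350, 400), speed = c(4000, 5000),
                pre = c(0, 50), n_speed = 11, n_pre = 11),
    seed = 1L)
}

.merge_config <- function(base, user, path = "") {
  for (k in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(base))
      stop("unknown configuration key: ", full)
    if (is.list(base[[k]]) && !is.null(names(base[[k]])) &&
        length(base[[k]]) > 0 && k != "oracle") {
      if (!is.list(user[[k]]))
        stop("configuration key ", full, " must be a mapping")
      base[[k]] <- .merge_config(base[[k]], user[[k]], full)
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' Load and validate a YAML run configuration
#'
#' Unknown keys are rejected; missing keys are filled with package
#' defaults. The resolved configuration echoes every effective setting.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return object of class `run_config` (nested list).
#' @export
load_config <- function(path = NULL) {
  cfg <- .default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    cfg <- .merge_config(cfg, user)
  }
  if (cfg$space$speed[1] >= cfg$space$speed[2] ||
      cfg$space$main[1] >= cfg$space$main[2])
    stop("config error: space bounds must satisfy lo < hi")
  ok_or <- setdiff(names(cfg$oracle),
                   names(oracle_params(calibrated = FALSE)))
  if (length(ok_or))
    stop("unknown oracle parameter(s) in config: ",
         paste(ok_or, collapse = ", "))
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' Resolve package objects from a run configuration
#'
#' @param cfg a [load_config()] result.
#' @return list with `space`, `params` (oracle) and `al` ([al_config()]).
#' @export
resolve_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  space <- design_space(speed = cfg$space$speed, main = cfg$space$main,
                        pre_max = cfg$space$pre_max)
  params <- do.call(oracle_params, cfg$oracle)
  al <- al_config(n_init = cfg$al$n_init, n_iter = cfg$al$n_iter,
                  pool_size = cfg$al$pool_size, n_val = cfg$al$n_val,
                  retune_every = cfg$al$retune_every,
                  tune_budget = cfg$al$tune_budget, seed = cfg$seed)
  list(space = space, params = params, al = al)
}

#' Write the resolved configuration back to YAML
#'
#' @param cfg a [load_config()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
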