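#' Default experiment configuration
#'
#' The canonical simulation design: the three bundled input functions, all
#' three-point imaging schedules from the candidate set
#' {24, 48, 96, 144, 192} h, reference Ki of 1, 5 and 20 10^-3 /h,
#' reference VT of 0.1, 0.2 and 0.5, TAC noise levels of 5, 10 and 15%,
#' and 1000 repetitions per condition.
#'
#' @param n_reps Repetitions per condition.
#' @param seed Master seed; every condition derives its own sub-seed from it.
#' @return A list of class `"patlaksim_config"`.
#' @examples
#' str(default_config())
#' @export
default_config <- function(n_reps = 1000, seed = 1) {
  structure(list(
    fixtures = c("huJ591-like", "trastuzumab-like", "pertuzumab-like"),
    input_functions = NULL,       # optional inline parameter sets
    candidate_times = c(24, 48, 96, 144, 192),
    schedule_size = 3,
    require_time = NULL,
    rki = c(1e-3, 5e-3, 20e-3),
    rvt = c(0.1, 0.2, 0.5),
    noise = c(0.05, 0.10, 0.15),
    n_reps = n_reps,
    seed = seed,
    half_life = 78.41),
    class = "patlaksim_config")
}

#' Load an experiment configuration file
#'
#' Reads a YAML or JSON configuration (chosen by file extension), fills
#' unspecified fields with the defaults of [default_config()] and
#' validates the result. An empty file yields the full default design.
#' Input functions may be referenced by bundled fixture name (`fixtures`)
#' or supplied inline as named parameter sets under `input_functions`,
#' each with `amp_fast`, `rate_fast`, `amp_slow`, `rate_slow`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated configuration list of class `"patlaksim_config"`.
#' @seealso [write_config()], [run_grid()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    "yaml" = , "yml" = yaml::read_yaml(path),
    "json" = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("config must be a .yaml, .yml or .json file", call. = FALSE))
  if (is.null(raw)) raw <- list()
  cfg <- default_config()
  unknown <- setdiff(names(raw), c(names(cfg), ""))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(raw)) cfg[[nm]] <- raw[[nm]]
  # a config that only supplies inline IFs should not drag in the fixtures
  if (!is.null(raw$input_functions) && is.null(raw$fixtures)) {
    cfg$fixtures <- character(0)
  }
  validate_config(cfg)
}

#' Write an experiment configuration file
#'
#' Serialises a configuration to YAML or JSON (chosen by extension) such
#' that [load_config()] restores it.
#'
#' @param config A configuration list.
#' @param path Output path ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  config <- validate_config(config)
  out <- unclass(config)
  out <- out[!vapply(out, is.null, logical(1))]
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    "yaml" = , "yml" = yaml::write_yaml(out, path),
    "json" = jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                                  pretty = TRUE),
    stop("config must be written as .yaml, .yml or .json", call. = FALSE))
  invisible(path)
}

# check axes and fixture references; returns the config with class set
validate_config <- function(config) {
  cfg <- unclass(config)
  need_pos <- function(x, nm) {
    if (!is.numeric(x) || length(x) < 1L || any(!is.finite(x)) || any(x <= 0)) {
      stop("config field '", nm, "' must be positive numeric", call. = FALSE)
    }
  }
  need_pos(cfg$candidate_times, "candidate_times")
  need_pos(cfg$rvt, "rvt")
  need_pos(cfg$half_life, "half_life")
  if (!is.numeric(cfg$rki) || any(!is.finite(cfg$rki)) || any(cfg$rki < 0)) {
    stop("config field 'rki' must be non-negative numeric", call. = FALSE)
  }
  if (!is.numeric(cfg$noise) || any(cfg$noise < 0) || any(cfg$noise >= 1)) {
    stop("config field 'noise' must be fractions in [0, 1)", call. = FALSE)
  }
  if (cfg$schedule_size < 2 || cfg$schedule_size > length(cfg$candidate_times)) {
    stop("schedule_size must be between 2 and the number of candidate times",
         call. = FALSE)
  }
  if (!is.null(cfg$require_time) &&
      !cfg$require_time %in% cfg$candidate_times) {
    stop("require_time must be one of the candidate times", call. = FALSE)
  }
  if (cfg$n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  available <- input_function_library()
  bad <- setdiff(cfg$fixtures, available)
  if (length(bad)) {
    stop("unknown fixture(s): ", paste(bad, collapse = ", "),
         "; available fixtures: ", paste(available, collapse = ", "),
         call. = FALSE)
  }
  if (length(cfg$fixtures) == 0L && length(cfg$input_functions) == 0L) {
    stop("config must name at least one fixture or inline input function",
         call. = FALSE)
  }
  structure(cfg, class = "patlaksim_config")
}

# named list of biexp objects from fixture names + inline parameter sets
resolve_input_functions <- function(config) {
  ifns <- lapply(config$fixtures, input_function_library)
  names(ifns) <- config$fixtures
  for (nm in names(config$input_functions)) {
    p <- config$input_functions[[nm]]
    ifns[[nm]] <- biexp(p$amp_fast, p$rate_fast, p$amp_slow, p$rate_slow,
                        label = nm)
  }
  ifns
}
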