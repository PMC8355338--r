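# Run configuration: defaults, file loading, validation.

#' Default run configuration
#'
#' Every configurable field of a simulation run with its default. Fields:
#' agent `variant` and its precisions `z`, `z_tf`, `z_sc` (`NA` = variant
#' default); the condition (`context`, `emotion`, `type`) or a `colour`
#' class selector covering several cells; `horizon`; the numerical settings
#' `learning_rate`, `max_iters`, `tol`, `epsilon`; action-selection `mode`;
#' replicate count `n`; `seed`; output paths `out_records`/`out_summary`
#' (`NA` = do not write).
#'
#' @return a named list of defaults.
#' @export
default_config <- function() {
  list(
    variant = "contextualising",
    z = NA_real_, z_tf = NA_real_, z_sc = NA_real_,
    context = "happy", emotion = "happy", type = "ambiguous",
    colour = NA_character_,
    horizon = 8L,
    learning_rate = 0.25, max_iters = 64L, tol = 1e-4, epsilon = 1e-16,
    mode = "map",
    n = 1L,
    seed = 1L,
    out_records = NA_character_, out_summary = NA_character_
  )
}

#' Load and validate a run configuration
#'
#' Reads a flat key-value YAML or JSON document, fills unset fields with
#' [default_config()] values, then applies `overrides` (e.g. parsed command
#' line flags) on top. Unknown keys and out-of-range values raise an error
#' naming the offending key. Supplying a contextualisation precision `z`
#' together with a variant that does not use it triggers a warning
#' (conflicting intent) but the value is honoured.
#'
#' @param path path to a YAML/JSON file, or `NULL` for defaults only.
#' @param overrides named list applied after the file (highest precedence).
#' @param echo if `TRUE`, print the fully resolved configuration to the
#'   message stream.
#' @return the resolved configuration list.
#' @export
load_config <- function(path = NULL, overrides = list(), echo = FALSE) {
  cfg <- default_config()
  if (!is.null(path)) {
    file_cfg <- tryCatch({
      if (grepl("\\.json$", path, ignore.case = TRUE)) {
        jsonlite::fromJSON(path, simplifyVector = TRUE)
      } else {
        yaml::read_yaml(path)
      }
    }, error = function(e) {
      stop_config("could not parse config file '", path, "': ",
                  conditionMessage(e))
    })
    if (is.null(file_cfg)) file_cfg <- list()
    # YAML 1.1 reads a bare `n` key as the boolean FALSE; map it back
    names(file_cfg)[names(file_cfg) %in% c("FALSE", "no")] <- "n"
    cfg <- merge_config(cfg, file_cfg)
  }
  cfg <- merge_config(cfg, overrides)
  validate_config(cfg)
  if (echo) {
    flat <- vapply(cfg, function(v) paste(format(v), collapse = ","), character(1))
    message("resolved config: ",
            paste(names(flat), flat, sep = "=", collapse = " "))
  }
  cfg
}

merge_config <- function(cfg, new) {
  if (!length(new)) return(cfg)
  unknown <- setdiff(names(new), names(cfg))
  if (length(unknown)) {
    stop_config("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  for (k in names(new)) if (!is.null(new[[k]])) cfg[[k]] <- new[[k]]
  cfg
}

validate_config <- function(cfg) {
  check <- function(ok, key, ...) {
    if (!ok) stop_config("config key `", key, "`: ", ...)
  }
  check(cfg$variant %in% c("contextualising", "non_contextualising",
                           "local_viewer", "global_viewer"),
        "variant", "unknown agent variant '", cfg$variant, "'")
  check(cfg$mode %in% c("map", "stochastic"), "mode", "must be map or stochastic")
  check(cfg$context %in% context_levels(), "context", "invalid level")
  check(cfg$emotion %in% c("happy", "sad"), "emotion", "invalid level")
  check(cfg$type %in% c("unambiguous", "ambiguous"), "type", "invalid level")
  check(is.na(cfg$colour) ||
          cfg$colour %in% c("green", "red", "blue", "grey"),
        "colour", "must be green, red, blue or grey")
  for (k in c("z", "z_tf", "z_sc")) {
    check(is.na(cfg[[k]]) || (is.numeric(cfg[[k]]) && cfg[[k]] >= 0), k,
          "must be a non-negative number")
  }
  check(is.numeric(cfg$horizon) && cfg$horizon >= 1, "horizon", "must be >= 1")
  check(is.numeric(cfg$learning_rate) && cfg$learning_rate > 0,
        "learning_rate", "must be positive")
  check(is.numeric(cfg$max_iters) && cfg$max_iters >= 1, "max_iters", "must be >= 1")
  check(is.numeric(cfg$tol) && cfg$tol > 0, "tol", "must be positive")
  check(is.numeric(cfg$epsilon) && cfg$epsilon > 0, "epsilon", "must be positive")
  check(is.numeric(cfg$n) && cfg$n >= 1, "n", "must be >= 1")
  check(is.numeric(cfg$seed), "seed", "must be an integer")
  if (!is.na(cfg$z) && cfg$variant != "contextualising") {
    warning("config: `z` is set but variant '", cfg$variant,
            "' does not use the contextualisation precision; value honoured",
            call. = FALSE)
  }
  invisible(cfg)
}

#' Build the condition rows selected by a configuration
#'
#' A `colour` selector expands to every cell of that class in
#' [enumerate_conditions()]; otherwise the single configured
#' context/emotion/type cell is used. Agent fields are copied onto each row.
#'
#' @param cfg a configuration from [load_config()].
#' @return a data frame suitable for [run_batch()].
#' @export
config_conditions <- function(cfg) {
  cells <- if (!is.na(cfg$colour)) {
    all <- enumerate_conditions()
    all[all$colour == cfg$colour, c("context", "emotion", "type")]
  } else {
    data.frame(context = cfg$context, emotion = cfg$emotion, type = cfg$type,
               stringsAsFactors = FALSE)
  }
  cells$variant <- cfg$variant
  cells$z <- cfg$z
  cells$z_tf <- cfg$z_tf
  cells$z_sc <- cfg$z_sc
  cells$mode <- cfg$mode
  cells$label <- paste(cells$context, cells$emotion, cells$type, sep = "/")
  rownames(cells) <- NULL
  cells
}
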