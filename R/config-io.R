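#' Serialize / load pipeline configuration as YAML
#'
#' Round-trips the declarative part of a [pipeline_config()]: input mode
#' and CSV path, the synthetic-generator settings (record count, seed,
#' group proportions, foreign-born fractions, cohort range, constant
#' weight), classifier overrides, MENA birthplace codes, the truncation
#' window, bootstrap draws, minimum cell size, and the global seed.
#' Programmatic objects (a custom Gompertz map or custom name
#' specifications) are R-level configuration: they are not serialized,
#' and the defaults are rebuilt on load.
#'
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @return `read_pipeline_config` returns a `pipeline_config`;
#'   `write_pipeline_config` returns `path` invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  sy <- config$synthetic
  out <- list(
    input_mode = config$input_mode,
    csv_path = config$csv_path,
    use_classifier = config$use_classifier,
    classifier = config$classifier,
    mena_codes = as.list(config$mena_codes),
    window = list(death_year_min = config$window$death_year_min,
                  death_year_max = config$window$death_year_max,
                  min_death_age = config$window$min_death_age),
    n_boot = config$n_boot, min_cell = config$min_cell,
    seed = config$seed,
    synthetic = if (is.null(sy)) NULL else list(
      n_records = sy$n_records, seed = sy$seed,
      group_proportions = as.list(sy$group_proportions),
      foreign_born_fraction_by_group = as.list(sy$foreign_born_fraction_by_group),
      cohort_range = sy$cohort_range,
      birth_year_probs = sy$birth_year_probs,
      weight = sy$weight
    )
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @param overrides named list merged over the file's values (e.g. from
#'   command-line flags).
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  raw[names(overrides)] <- overrides
  win <- do.call(truncation_window, raw$window %||% list())
  sy <- NULL
  if (!is.null(raw$synthetic)) {
    s <- raw$synthetic
    sy <- synthetic_config(
      n_records = s$n_records %||% 10000,
      seed = s$seed %||% raw$seed %||% 1,
      group_proportions = unlist(s$group_proportions %||%
                                   as.list(default_group_proportions())),
      foreign_born_fraction_by_group = unlist(
        s$foreign_born_fraction_by_group %||%
          as.list(default_foreign_born_fractions())),
      cohort_range = unlist(s$cohort_range %||% c(1890, 1940)),
      birth_year_probs = if (is.null(s$birth_year_probs)) NULL else
        unlist(s$birth_year_probs),
      window = win,
      weight = s$weight %||% 1
    )
  }
  pipeline_config(
    input_mode = raw$input_mode %||% "synthetic",
    synthetic = sy, csv_path = raw$csv_path,
    use_classifier = raw$use_classifier %||% TRUE,
    classifier = raw$classifier %||% list(),
    mena_codes = unlist(raw$mena_codes %||% as.list(mena_birthplace_codes())),
    window = win,
    n_boot = raw$n_boot %||% 1000, min_cell = raw$min_cell %||% 50,
    out_dir = overrides$out_dir %||% tempfile("menamort_run_"),
    seed = raw$seed %||% 1
  )
}
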