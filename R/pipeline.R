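RECORD_COLUMNS <- c("record_id", "given_name", "surname", "father_surname",
                    "mother_name", "sex", "birth_year", "death_year",
                    "death_age", "birthplace_code", "race_code",
                    "race_last_report_year", "weight")

#' Read / write person records as CSV
#'
#' Fixed dialect: UTF-8, comma-separated, quoted strings, one header row.
#' Reading validates that every required column is present and errors
#' naming any that is missing; optional columns (`group`, `foreign_born`
#' from the synthetic generator) are carried through when present.
#' Records are loaded as-is — filters such as the pre-1981 race-report
#' exclusion belong to the analysis stages, not to I/O.
#'
#' @param path CSV path.
#' @param records person-record tibble.
#' @return `read_records` returns the tibble; `write_records` returns
#'   `path` invisibly.
#' @export
read_records <- function(path) {
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(RECORD_COLUMNS, names(dat))
  if (length(miss) > 0) {
    stop("record file ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  if ("foreign_born" %in% names(dat)) dat$foreign_born <- as.logical(dat$foreign_born)
  dat
}

#' @rdname read_records
#' @export
write_records <- function(records, path) {
  miss <- setdiff(RECORD_COLUMNS, names(records))
  if (length(miss) > 0) {
    stop("records are missing required column(s): ", paste(miss, collapse = ", "))
  }
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Exactly one input mode is active: `synthetic` (records generated from
#' `synthetic`) or `csv` (records loaded from `csv_path`). The global
#' `seed` drives every stage (generation, classifier training, bootstrap
#' CIs).
#'
#' @param input_mode `"synthetic"` or `"csv"`.
#' @param synthetic a [synthetic_config()] (synthetic mode).
#' @param csv_path record CSV path (csv mode).
#' @param use_classifier if `FALSE`, group assignment uses the records'
#'   ground-truth `group` column and the classifier stages are skipped
#'   (useful for measuring classification-induced attenuation).
#' @param classifier list of overrides passed to [train_name_model()]
#'   (e.g. `list(epochs = 4, max_vocab = 150)`).
#' @param mena_codes birthplace codes labelled MENA.
#' @param window a [truncation_window()].
#' @param n_boot bootstrap draws for e65 CIs, default 1000.
#' @param min_cell minimum records per (group, sex, nativity) cell for a
#'   mortality fit, default 50.
#' @param out_dir output directory.
#' @param seed global seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input_mode = c("synthetic", "csv"),
                            synthetic = NULL, csv_path = NULL,
                            use_classifier = TRUE, classifier = list(),
                            mena_codes = mena_birthplace_codes(),
                            window = truncation_window(),
                            n_boot = 1000, min_cell = 50,
                            out_dir = tempfile("menamort_run_"), seed = 1) {
  input_mode <- match.arg(input_mode)
  if (input_mode == "synthetic" && is.null(synthetic)) {
    synthetic <- synthetic_config(seed = seed)
  }
  if (input_mode == "csv" && is.null(csv_path)) {
    stop("csv input mode requires `csv_path`")
  }
  structure(list(
    input_mode = input_mode, synthetic = synthetic, csv_path = csv_path,
    use_classifier = use_classifier, classifier = classifier,
    mena_codes = mena_codes, window = window,
    n_boot = n_boot, min_cell = min_cell, out_dir = out_dir, seed = seed
  ), class = "pipeline_config")
}

race_to_group <- function(race_code) {
  map <- c(white = "white", black = "black", asian = "api",
           hispanic = "hispanic", other = "other")
  out <- unname(map[race_code])
  out[is.na(out)] <- "other"
  out
}

#' Run the end-to-end analysis pipeline
#'
#' Stage order: load or generate records; build the classifier training
#' set; train the name classifier; score every record and assign
#' `group = "mena"` where the record is classified MENA or born in a MENA
#' country (recording the prior race-code shares of the classified set);
#' apply the truncation window; compute descriptive statistics; fit the
#' truncated Gompertz model per (group, sex) with a foreign-born
#' indicator; derive nativity hazard ratios, e65 by nativity, and the
#' fixed-effects linear robustness table. Every table carries the config
#' hash and seed; per-stage record counts go to the run log.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the tables (`table1`, `table2`,
#'   `table3`, `appendix_fe`, `classifier_metrics`, `prior_shares`), the
#'   records, the model, and the output directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- rlang::hash(config[setdiff(names(config), "out_dir")])
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  say("run ", cfg_hash, " seed ", config$seed)
  records <- stage("load", {
    if (config$input_mode == "synthetic") {
      generate_cohort(config$synthetic)
    } else {
      read_records(config$csv_path)
    }
  })
  say("records in: ", nrow(records))

  model <- NULL
  metrics <- NULL
  if (config$use_classifier) {
    training <- stage("build_training_set", {
      build_training_set(records, config$mena_codes)
    })
    say("training names: ", nrow(training), " (", sum(training$label), " positive)")
    model <- stage("train", {
      args <- c(list(labelled = training, seed = config$seed), config$classifier)
      do.call(train_name_model, args)
    })
    metrics <- model$metrics
    say(sprintf("classifier held-out F1 %.3f", metrics$f1))
    scores <- stage("classify", {
      predict_name_proba(model, bpe_join(records$given_name, records$surname))
    })
    is_mena <- scores >= model$threshold |
      records$birthplace_code %in% config$mena_codes
    prior_shares <- records[is_mena, ] |>
      dplyr::count(.data$race_code) |>
      dplyr::mutate(share = .data$n / sum(.data$n))
    records$group_assigned <- ifelse(is_mena, "mena",
                                     race_to_group(records$race_code))
    say("classified MENA: ", sum(is_mena))
  } else {
    if (!"group" %in% names(records)) {
      stop("use_classifier = FALSE requires a ground-truth `group` column")
    }
    records$group_assigned <- records$group
    prior_shares <- records[records$group == "mena", ] |>
      dplyr::count(.data$race_code) |>
      dplyr::mutate(share = .data$n / sum(.data$n))
    say("classifier skipped; ground-truth groups used")
  }
  if (!"foreign_born" %in% names(records)) {
    records$foreign_born <- !startsWith(records$birthplace_code, "US")
  }

  truncated <- stage("apply_truncation", apply_truncation(records, config$window))
  say("records after truncation: ", nrow(truncated))

  table1 <- stage("descriptive_stats", {
    descriptive_stats(truncated, c("group_assigned", "sex", "foreign_born"))
  })

  cells <- truncated |>
    dplyr::count(.data$group_assigned, .data$sex, .data$foreign_born) |>
    tidyr::pivot_wider(names_from = "foreign_born", values_from = "n",
                       values_fill = 0)
  fit_ok <- cells[["TRUE"]] >= config$min_cell & cells[["FALSE"]] >= config$min_cell

  table2 <- table3 <- appendix <- list()
  for (i in which(fit_ok)) {
    g <- cells$group_assigned[i]; s <- cells$sex[i]
    sub <- truncated[truncated$group_assigned == g & truncated$sex == s, ]
    res <- stage(paste0("fit_", g, "_", s), {
      obs <- death_observations(sub, config$window)
      fit <- fit_gompertz(obs)
      eff <- nativity_effect(fit, n_boot = config$n_boot, seed = config$seed)
      fe <- fe_linear_check(sub)
      list(fit = fit, eff = eff, fe = fe)
    })
    say(sprintf("fit %s/%s: n=%d HR=%.3f", g, s, nrow(sub), res$eff$hr))
    table2[[length(table2) + 1]] <- tibble::tibble(
      group = g, sex = s,
      hr = res$eff$hr, hr_lower = res$eff$hr_lower, hr_upper = res$eff$hr_upper,
      delta_e65 = res$eff$delta_e65, delta_lower = res$eff$delta_lower,
      delta_upper = res$eff$delta_upper
    )
    table3[[length(table3) + 1]] <- tibble::tibble(
      group = g, sex = s,
      e65_native = res$eff$e65_native,
      e65_native_lower = res$eff$e65_native_lower,
      e65_native_upper = res$eff$e65_native_upper,
      e65_foreign = res$eff$e65_foreign,
      e65_foreign_lower = res$eff$e65_foreign_lower,
      e65_foreign_upper = res$eff$e65_foreign_upper
    )
    appendix[[length(appendix) + 1]] <- dplyr::mutate(res$fe, group = g, sex = s)
  }
  table2 <- dplyr::bind_rows(table2)
  table3 <- dplyr::bind_rows(table3)
  appendix <- dplyr::bind_rows(appendix)

  bundle <- list(
    table1 = table1, table2 = table2, table3 = table3,
    appendix_fe = appendix, classifier_metrics = metrics,
    prior_shares = prior_shares, records = records, truncated = truncated,
    model = model, config_hash = cfg_hash, seed = config$seed,
    out_dir = config$out_dir, log = log_lines
  )
  stage("write_tables", write_tables(bundle, config$out_dir))
  say("outputs written to ", config$out_dir)
  writeLines(c(log_lines, paste0("# config ", cfg_hash, " seed ", config$seed)),
             file.path(config$out_dir, "run_log.txt"))
  invisible(bundle)
}

#' Write the pipeline's output tables
#'
#' Emits `table1.csv` (descriptives), `table2.csv` (nativity hazard
#' ratios and e65 effects), `table3.csv` (e65 by nativity),
#' `appendix_fe.csv`, `classifier_metrics.csv`, `prior_shares.csv`, plus
#' the serialized model and vocabulary when present. Each CSV carries a
#' comment-free header row; the config hash and seed are recorded in the
#' run log.
#'
#' @param bundle a [run_pipeline()] result (or compatible list).
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_tables <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, f) {
    if (!is.null(x) && nrow(x) > 0) {
      readr::write_csv(x, file.path(dir, f), progress = FALSE)
    }
  }
  wr(bundle$table1, "table1.csv")
  wr(bundle$table2, "table2.csv")
  wr(bundle$table3, "table3.csv")
  wr(bundle$appendix_fe, "appendix_fe.csv")
  wr(bundle$classifier_metrics, "classifier_metrics.csv")
  wr(bundle$prior_shares, "prior_shares.csv")
  if (!is.null(bundle$model)) {
    write_name_model(bundle$model, file.path(dir, "name_model.txt"))
    write_bpe_vocab(bundle$model$vocab, file.path(dir, "bpe_vocab.txt"))
  }
  invisible(dir)
}

#' Histogram of death ages by group
#'
#' Basic truncated death-age histograms, one facet per assigned group.
#'
#' @param truncated truncated record tibble with a `group_assigned` (or
#'   `group`) column.
#' @return a ggplot object.
#' @export
plot_death_ages <- function(truncated) {
  gcol <- if ("group_assigned" %in% names(truncated)) "group_assigned" else "group"
  ggplot2::ggplot(truncated,
                  ggplot2::aes(x = .data$death_age)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey30") +
    ggplot2::facet_wrap(stats::as.formula(paste("~", gcol)), scales = "free_y") +
    ggplot2::labs(x = "Age at death (completed years)", y = "Deaths") +
    ggplot2::theme_minimal()
}
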