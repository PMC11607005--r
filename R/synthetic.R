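#' Observation window for doubly truncated death records
#'
#' Deaths are observable only when the calendar year of death falls in
#' `[death_year_min, death_year_max]` (inclusive) and the completed age at
#' death is at least `min_death_age`. The defaults are the high-coverage
#' window of social-security death files: deaths in 1988-2005 at ages 65+.
#'
#' @param death_year_min,death_year_max calendar bounds (inclusive).
#' @param min_death_age minimum completed age at death (years).
#' @return a `truncation_window` list.
#' @export
truncation_window <- function(death_year_min = 1988, death_year_max = 2005,
                              min_death_age = 65) {
  stopifnot(death_year_min <= death_year_max, min_death_age >= 0)
  structure(list(death_year_min = death_year_min,
                 death_year_max = death_year_max,
                 min_death_age = min_death_age),
            class = "truncation_window")
}

# Default mortality regime: for each (group, sex), a Gompertz baseline
# (a0, b0) and a foreign-born log-hazard beta_fb, calibrated once so the
# U.S.-born and foreign-born conditional life expectancies at 65 match a
# realistic over-65 differential for U.S. ethno-racial groups.
default_e65_regime <- function() {
  tibble::tribble(
    ~group,     ~sex,     ~e65_native, ~e65_foreign, ~hr,
    "white",    "male",   81.59,       82.75,        0.85,
    "api",      "male",   82.26,       84.29,        0.75,
    "black",    "male",   79.67,       80.06,        0.95,
    "hispanic", "male",   82.07,       84.50,        0.72,
    "mena",     "male",   82.26,       85.39,        0.64,
    "other",    "male",   80.13,       80.06,        1.01,
    "white",    "female", 86.60,       87.46,        0.88,
    "api",      "female", 87.34,       88.22,        0.88,
    "black",    "female", 85.25,       88.64,        0.65,
    "hispanic", "female", 87.05,       89.65,        0.67,
    "mena",     "female", 86.42,       88.66,        0.71,
    "other",    "female", 85.18,       84.19,        1.14
  )
}

.menamort_cache <- new.env(parent = emptyenv())

#' Default Gompertz parameter map by group, nativity, and sex
#'
#' Calibrates, once per session, the default per-(group, sex) Gompertz
#' baselines from the package's e65 regime via
#' [calibrate_gompertz_e65()], and expands them to one row per
#' (group, nativity, sex) with the foreign-born rows carrying the
#' log-hazard shift `bz = log(hr)`.
#'
#' @param origin age origin, default 65.
#' @return tibble with columns `group`, `sex`, `foreign_born`, `a0`,
#'   `b0`, `bz`.
#' @export
default_gompertz_map <- function(origin = 65) {
  key <- paste0("gmap_", origin)
  if (!is.null(.menamort_cache[[key]])) return(.menamort_cache[[key]])
  reg <- default_e65_regime()
  rows <- lapply(seq_len(nrow(reg)), function(i) {
    cal <- calibrate_gompertz_e65(reg$e65_native[i], reg$e65_foreign[i],
                                  reg$hr[i], origin = origin)
    tibble::tibble(
      group = reg$group[i], sex = reg$sex[i],
      foreign_born = c(FALSE, TRUE),
      a0 = cal$a0, b0 = cal$b0, bz = c(0, cal$beta_fb)
    )
  })
  out <- dplyr::bind_rows(rows)
  .menamort_cache[[key]] <- out
  out
}

# Realized group shares and foreign-born fractions of an over-65
# social-security-style death file.
default_group_proportions <- function() {
  c(white = 0.7266, black = 0.1700, hispanic = 0.0554,
    api = 0.0348, other = 0.0067, mena = 0.0065)
}

default_foreign_born_fractions <- function() {
  c(white = 0.064, black = 0.030, hispanic = 0.540,
    api = 0.741, other = 0.112, mena = 0.61)
}

us_state_codes <- function() {
  c("US-NY", "US-PA", "US-OH", "US-IL", "US-TX", "US-CA", "US-MI", "US-MA",
    "US-GA", "US-NC", "US-MO", "US-NJ", "US-AL", "US-MS", "US-TN", "US-WI")
}

foreign_birthplace_codes <- function() {
  list(
    mena = c("SY", "LB", "EG", "IR", "MA", "JO", "IQ", "PS", "YE", "DZ"),
    white = c("IT", "DE", "PL", "GB", "IE", "RU", "SE", "NO"),
    black = c("JM", "HT", "NG", "TT", "BB"),
    api = c("CN", "JP", "PH", "KR", "IN", "VN"),
    hispanic = c("MX", "CU", "DO", "SV", "GT", "CO"),
    other = c("FJ", "GY", "MU", "SR")
  )
}

#' MENA birthplace codes used for training labels
#' @return character vector of country codes treated as MENA birthplaces.
#' @export
mena_birthplace_codes <- function() foreign_birthplace_codes()$mena

#' Configuration for the synthetic person-record generator
#'
#' @param n_records number of records to generate.
#' @param seed integer seed controlling all randomness.
#' @param group_proportions named fractions over groups (sum to 1).
#' @param foreign_born_fraction_by_group named fractions in `[0, 1]`.
#' @param cohort_range inclusive birth-year interval, default `c(1890, 1940)`.
#' @param birth_year_probs optional named probability vector over the
#'   years of `cohort_range` (default uniform), to emulate cohort skew.
#' @param gompertz_map tibble as returned by [default_gompertz_map()].
#' @param name_specs named list of [name_spec()] objects per group.
#' @param window a [truncation_window()].
#' @param weight constant person-weight carried by every record, default 1.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_records = 10000, seed = 1,
                             group_proportions = default_group_proportions(),
                             foreign_born_fraction_by_group = default_foreign_born_fractions(),
                             cohort_range = c(1890, 1940),
                             birth_year_probs = NULL,
                             gompertz_map = default_gompertz_map(),
                             name_specs = default_name_specs(),
                             window = truncation_window(),
                             weight = 1) {
  if (abs(sum(group_proportions) - 1) > 1e-9) {
    stop("group_proportions must sum to 1 (got ", sum(group_proportions), ")")
  }
  if (any(group_proportions < 0)) stop("group_proportions must be nonnegative")
  fb <- foreign_born_fraction_by_group
  if (any(fb < 0 | fb > 1)) stop("foreign-born fractions must lie in [0, 1]")
  if (!all(names(group_proportions) %in% names(fb))) {
    stop("foreign_born_fraction_by_group must cover every group")
  }
  if (!all(names(group_proportions) %in% names(name_specs))) {
    stop("name_specs must cover every group")
  }
  stopifnot(length(cohort_range) == 2, cohort_range[1] <= cohort_range[2])
  if (!is.null(birth_year_probs)) {
    yrs <- seq(cohort_range[1], cohort_range[2])
    stopifnot(length(birth_year_probs) == length(yrs))
  }
  structure(list(
    n_records = n_records, seed = seed,
    group_proportions = group_proportions,
    foreign_born_fraction_by_group = fb,
    cohort_range = cohort_range, birth_year_probs = birth_year_probs,
    gompertz_map = gompertz_map, name_specs = name_specs,
    window = window, weight = weight
  ), class = "synthetic_config")
}

#' Generate a synthetic person-record cohort
#'
#' Draws, for each record: group, sex, nativity, birth year (uniform over
#' the cohort range unless configured), names from the group's character
#' process, and a continuous death age from the (group, nativity, sex)
#' Gompertz parameters measured from the window's minimum death age —
#' i.e. the cohort is the population surviving to that age. The recorded
#' `death_age` is the completed (floored) age and
#' `death_year = birth_year + death_age + Bernoulli(fractional part)`, so
#' `death_year - birth_year` stays within one year of `death_age` as in
#' administrative files. No truncation is applied here; see
#' [apply_truncation()].
#'
#' Records carry their generating `group` and `foreign_born` flags (the
#' ground truth a real death file lacks) alongside the administrative
#' fields: MENA records are race-coded mostly `white` (85%) or `asian`
#' (13%), mirroring how MENA ancestry is folded into other categories,
#' and `race_last_report_year` spans 1962-2005 so some records predate
#' the 1981 coding change.
#'
#' @param config a [synthetic_config()].
#' @return tibble of person records, one row each.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_records
  groups <- names(config$group_proportions)
  grp <- sample(groups, n, replace = TRUE, prob = config$group_proportions)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  fb <- stats::rbinom(n, 1, config$foreign_born_fraction_by_group[grp]) == 1
  yrs <- seq(config$cohort_range[1], config$cohort_range[2])
  birth_year <- if (is.null(config$birth_year_probs)) {
    if (length(yrs) == 1) rep(yrs, n) else sample(yrs, n, replace = TRUE)
  } else {
    sample(yrs, n, replace = TRUE, prob = config$birth_year_probs)
  }

  given <- surname <- father_surname <- mother_name <- character(n)
  birthplace <- race <- character(n)
  death_cont <- numeric(n)
  fbp <- foreign_birthplace_codes()
  origin <- config$window$min_death_age

  for (g in sort(unique(grp))) {
    idx <- which(grp == g)
    m <- length(idx)
    nm <- generate_names(g, m, seed = NULL, specs = config$name_specs)
    given[idx] <- nm$given_name
    surname[idx] <- nm$surname
    extra <- generate_names(g, m, seed = NULL, specs = config$name_specs)
    same_f <- stats::runif(m) < 0.95
    father_surname[idx] <- ifelse(same_f, nm$surname, extra$surname)
    mother <- generate_names(g, m, seed = NULL, specs = config$name_specs)
    mother_name[idx] <- paste(mother$given_name, mother$surname)

    f_idx <- idx[fb[idx]]; n_idx <- idx[!fb[idx]]
    codes <- fbp[[g]] %||% fbp$other
    if (length(f_idx) > 0) birthplace[f_idx] <- sample(codes, length(f_idx), replace = TRUE)
    if (length(n_idx) > 0) birthplace[n_idx] <- sample(us_state_codes(), length(n_idx), replace = TRUE)

    race[idx] <- if (g == "mena") {
      sample(c("white", "asian", "other"), m, replace = TRUE,
             prob = c(0.85, 0.13, 0.02))
    } else {
      c(white = "white", black = "black", api = "asian",
        hispanic = "hispanic", other = "other")[g]
    }

    for (s in c("female", "male")) {
      for (f in c(FALSE, TRUE)) {
        sel <- idx[sex[idx] == s & fb[idx] == f]
        if (length(sel) == 0) next
        row <- config$gompertz_map[config$gompertz_map$group == g &
                                   config$gompertz_map$sex == s &
                                   config$gompertz_map$foreign_born == f, ]
        if (nrow(row) != 1) {
          stop("gompertz_map has ", nrow(row), " rows for (", g, ", ", s,
               ", foreign_born=", f, "); need exactly 1")
        }
        death_cont[sel] <- simulate_death_age(length(sel), row$a0, row$b0,
                                              row$bz, origin = origin)
      }
    }
  }

  death_age <- floor(death_cont)
  frac <- death_cont - death_age
  death_year <- birth_year + death_age + stats::rbinom(n, 1, frac)
  rr_year <- sample(1962:2005, n, replace = TRUE)

  tibble::tibble(
    record_id = sprintf("R%07d", seq_len(n)),
    given_name = given, surname = surname,
    father_surname = father_surname, mother_name = mother_name,
    sex = sex, birth_year = birth_year,
    death_year = death_year, death_age = death_age,
    birthplace_code = birthplace, race_code = race,
    race_last_report_year = rr_year,
    weight = rep(config$weight, n),
    group = grp, foreign_born = fb
  )
}

#' Restrict records to the observation window
#'
#' Pure filter: retains exactly the records with
#' `death_year_min <= death_year <= death_year_max` and
#' `death_age >= min_death_age` (all bounds inclusive); order preserved,
#' no record modified.
#'
#' @param records person-record tibble.
#' @param window a [truncation_window()].
#' @return the retained subset of `records`.
#' @export
apply_truncation <- function(records, window = truncation_window()) {
  stopifnot(all(c("death_year", "death_age") %in% names(records)))
  keep <- records$death_year >= window$death_year_min &
    records$death_year <= window$death_year_max &
    records$death_age >= window$min_death_age
  records[keep, , drop = FALSE]
}
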