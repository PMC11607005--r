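# Simulate a two-nativity truncated cohort on the administrative-record
# path (continuous draw -> floored age -> Bernoulli death year -> window
# filter), as the acceptance designs require.
simulate_two_group_design <- function(n_per_group, a0, b0, beta_fb, seed,
                                      cohort_range = c(1890, 1940),
                                      window = truncation_window()) {
  set.seed(seed)
  n <- 2 * n_per_group
  fb <- rep(c(0, 1), each = n_per_group)
  by <- sample(cohort_range[1]:cohort_range[2], n, replace = TRUE)
  tcont <- simulate_death_age(n, a0, b0, bz = beta_fb * fb,
                              origin = window$min_death_age)
  da <- floor(tcont)
  dy <- by + da + stats::rbinom(n, 1, tcont - da)
  rec <- tibble::tibble(
    birth_year = by, death_year = dy, death_age = da,
    foreign_born = fb == 1, weight = 1
  )
  apply_truncation(rec, window)
}

# Labelled corpus from two built-in name groups (or one group twice, for
# the no-signal case).
labelled_name_corpus <- function(n_per_class, pos_group = "mena",
                                 neg_group = "white", seed = 1) {
  pos <- generate_names(pos_group, n_per_class, seed = seed)
  neg <- generate_names(neg_group, n_per_class, seed = seed + 1000)
  tibble::tibble(
    name = c(paste0(pos$given_name, "_", pos$surname),
             paste0(neg$given_name, "_", neg$surname)),
    label = rep(c(1L, 0L), each = n_per_class)
  )
}

# A small trained separable model, built once per test run and memoised.
.fixture_env <- new.env()
get_separable_model <- function() {
  if (is.null(.fixture_env$model)) {
    lab <- labelled_name_corpus(1500, seed = 11)
    .fixture_env$labelled <- lab
    .fixture_env$model <- train_name_model(lab, max_vocab = 150, epochs = 4,
                                           seed = 11)
  }
  list(model = .fixture_env$model, labelled = .fixture_env$labelled)
}
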