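test_that("name generation is seeded, group-specific, and total", {
  a <- generate_names("mena", 3, seed = 1)
  b <- generate_names("mena", 3, seed = 1)
  expect_identical(a, b)
  expect_equal(nrow(a), 3)
  expect_identical(generate_names("white", 0, seed = 1)$given_name, character(0))
  expect_error(generate_names("klingon", 2, seed = 1), "klingon")

  # MENA chains put visible mass on the kh/gh clusters
  big <- generate_names("mena", 400, seed = 3)
  frac_kh <- mean(grepl("kh|gh", paste(big$given_name, big$surname)))
  wh <- generate_names("white", 400, seed = 3)
  frac_kh_w <- mean(grepl("kh|gh", paste(wh$given_name, wh$surname)))
  expect_gt(frac_kh, 0.25)
  expect_lt(frac_kh_w, 0.05)
})

test_that("cohort generation is reproducible and honors its mixture", {
  props <- c(mena = 0.5, white = 0.5)
  fbf <- c(mena = 0.61, white = 0.1)
  cfg <- synthetic_config(n_records = 1000, seed = 7, group_proportions = props,
                          foreign_born_fraction_by_group = fbf)
  r1 <- generate_cohort(cfg)
  r2 <- generate_cohort(cfg)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 1000)

  # realized MENA foreign-born share within binomial error of 0.61
  mena <- r1[r1$group == "mena", ]
  p_hat <- mean(mena$foreign_born)
  expect_lt(abs(p_hat - 0.61), 3 * sqrt(0.61 * 0.39 / nrow(mena)))

  # administrative rounding invariant
  expect_true(all(abs(r1$death_year - r1$birth_year - r1$death_age) <= 1))
  expect_true(all(r1$death_age >= 65))
  expect_true(all(r1$weight >= 0))

  # degenerate mixture
  cfg1 <- synthetic_config(n_records = 50, seed = 2,
                           group_proportions = c(mena = 1),
                           foreign_born_fraction_by_group = c(mena = 0.5))
  expect_true(all(generate_cohort(cfg1)$group == "mena"))

  # invalid configurations are rejected
  expect_error(synthetic_config(group_proportions = c(mena = 0.6, white = 0.5)),
               "sum to 1")
  expect_error(synthetic_config(group_proportions = c(mena = 1),
                                foreign_born_fraction_by_group = c(mena = 1.2)),
               "\\[0, 1\\]")
})

test_that("truncation is an inclusive pure filter", {
  rec <- tibble::tibble(
    record_id = c("a", "b", "c", "d", "e"),
    death_year = c(1987, 1988, 2005, 2006, 1995),
    death_age = c(70, 65, 80, 70, 64)
  )
  out <- apply_truncation(rec, truncation_window())
  expect_identical(out$record_id, c("b", "c"))
  # input unmodified, retained rows identical
  expect_identical(rec$record_id, c("a", "b", "c", "d", "e"))
  expect_identical(out, rec[rec$record_id %in% c("b", "c"), ])
})

test_that("retained death ages follow the doubly truncated density", {
  a0 <- 0.012; b0 <- 0.13
  cfg <- synthetic_config(
    n_records = 10000, seed = 31,
    group_proportions = c(mena = 1),
    foreign_born_fraction_by_group = c(mena = 0),
    cohort_range = c(1920, 1920),
    gompertz_map = tibble::tibble(
      group = "mena", sex = rep(c("male", "female"), each = 2),
      foreign_born = rep(c(FALSE, TRUE), 2), a0 = a0, b0 = b0, bz = 0
    )
  )
  tr <- apply_truncation(generate_cohort(cfg), truncation_window())
  # single 1920 cohort: deaths observable at years 1988-2005. Compare the
  # interior completed ages 69..84 (always fully observed) against the
  # brute-force normalized Gompertz cell masses.
  ages <- 69:84
  sub <- tr$death_age[tr$death_age %in% ages]
  S <- function(x) oracle_survival(x, a0, b0)
  cell <- vapply(ages, function(k) S(k) - S(k + 1), numeric(1))
  cell <- cell / sum(cell)
  p_hat <- as.numeric(table(factor(sub, levels = ages))) / length(sub)
  se <- sqrt(cell * (1 - cell) / length(sub))
  expect_true(all(abs(p_hat - cell) < 4 * pmax(se, 1e-4)))
})

test_that("generated records carry coherent administrative fields", {
  cfg <- synthetic_config(n_records = 800, seed = 12,
                          group_proportions = c(mena = 0.5, api = 0.5),
                          foreign_born_fraction_by_group = c(mena = 0.6, api = 0.7))
  r <- generate_cohort(cfg)
  # foreign-born iff non-US birthplace code
  expect_identical(r$foreign_born, !startsWith(r$birthplace_code, "US"))
  # MENA records are race-coded mostly white, never "mena"
  mena <- r[r$group == "mena", ]
  expect_true(all(mena$race_code %in% c("white", "asian", "other")))
  expect_gt(mean(mena$race_code == "white"), 0.7)
  # some records predate the 1981 race-coding change, some do not
  expect_true(any(r$race_last_report_year < 1981))
  expect_true(any(r$race_last_report_year >= 1981))
  # parent fields: fathers mostly share the child's surname
  expect_gt(mean(r$father_surname == r$surname), 0.9)
  expect_true(all(nchar(r$mother_name) > 0))
})
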