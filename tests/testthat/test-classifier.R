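test_that("training-set construction follows the labelling rules", {
  rec <- tibble::tibble(
    given_name = sprintf("g%02d", 1:12),
    surname = sprintf("s%02d", 1:12),
    father_surname = sprintf("f%02d", 1:12),
    mother_name = sprintf("m%02d mm%02d", 1:12, 1:12),
    birthplace_code = c(rep("SY", 4), rep("IT", 6), "US-OH", "US-NY"),
    race_last_report_year = rep(1990, 12)
  )
  out <- build_training_set(rec, mena_codes = "SY")
  # 10 foreign-born records, each contributing child + father + mother
  expect_equal(nrow(out), 30)
  expect_equal(sum(out$label), 12)
  # U.S.-born names never enter, whatever they look like
  expect_false(any(grepl("g11|g12", out$name)))

  # pre-1981 race reports are excluded entirely
  rec$race_last_report_year <- 1975
  expect_error(build_training_set(rec, mena_codes = "SY"), "1981")
})

test_that("metrics follow the confusion-table arithmetic and conventions", {
  # TP = 79, FN = 21, FP = 13 (plus 87 true negatives)
  scores <- c(rep(1, 79), rep(0, 21), rep(1, 13), rep(0, 87))
  labels <- c(rep(1, 100), rep(0, 100))
  m <- evaluate_classifier(scores, labels, threshold = 0.5)
  expect_equal(m$precision, 79 / 92, tolerance = 1e-12)
  expect_equal(m$recall, 0.79)
  expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall))

  perfect <- evaluate_classifier(c(0.9, 0.9, 0.1), c(1, 1, 0))
  expect_equal(perfect[c("precision", "recall", "f1")],
               tibble::tibble(precision = 1, recall = 1, f1 = 1))

  allneg <- evaluate_classifier(c(0.1, 0.2, 0.3), c(1, 0, 1))
  expect_equal(allneg$recall, 0)
  expect_false(allneg$precision_defined)
})

test_that("raising the threshold never raises recall nor lowers precision", {
  # recall monotonicity holds for any score set
  set.seed(33)
  scores <- stats::runif(500)
  labels <- stats::rbinom(500, 1, stats::plogis(4 * scores - 2))
  sw <- threshold_sweep(scores, labels, thresholds = seq(0.1, 0.9, 0.1))
  expect_true(all(diff(sw$recall) <= 1e-12))

  # precision monotonicity holds when the positive rate is nondecreasing
  # in the score (calibrated scores); build that case exactly
  bins <- seq(0.1, 0.9, 0.2)
  scores2 <- rep(bins, each = 100)
  labels2 <- unlist(lapply(bins, function(b) {
    rep(c(1L, 0L), c(round(100 * b), 100 - round(100 * b)))
  }))
  sw2 <- threshold_sweep(scores2, labels2, thresholds = seq(0.05, 0.95, 0.1))
  expect_true(all(diff(sw2$recall) <= 1e-12))
  expect_true(all(diff(sw2$precision[sw2$precision_defined]) >= -1e-12))
})

test_that("training is deterministic and errors on degenerate input", {
  lab <- labelled_name_corpus(150, seed = 3)
  m1 <- train_name_model(lab, max_vocab = 90, epochs = 2, seed = 5)
  m2 <- train_name_model(lab, max_vocab = 90, epochs = 2, seed = 5)
  expect_identical(m1$metrics, m2$metrics)
  expect_identical(m1$par, m2$par)

  single <- lab[lab$label == 1, ]
  expect_error(train_name_model(single), "single class")
})

test_that("predictions are probabilities, total, and robust to spelling variants", {
  fx <- get_separable_model()
  model <- fx$model

  p <- predict_name_proba(model, c("khalil_khoury", "", "x!!9q"))
  expect_true(all(p >= 0 & p <= 1))
  expect_length(predict_name_proba(model, character(0)), 0)

  # single-character perturbations of high-scoring names mostly stay positive
  pos_names <- fx$labelled$name[fx$labelled$label == 1]
  sc <- predict_name_proba(model, pos_names)
  high <- pos_names[sc >= 0.9][1:100]
  set.seed(17)
  perturbed <- vapply(high, function(nm) {
    ch <- strsplit(nm, "")[[1]]
    i <- sample(which(!(ch %in% c("_", " "))), 1)
    ch[i] <- sample(letters, 1)
    paste(ch, collapse = "")
  }, character(1))
  p_pert <- predict_name_proba(model, perturbed)
  expect_gte(mean(p_pert >= model$threshold), 0.9)
})

test_that("model serialization preserves predictions exactly", {
  fx <- get_separable_model()
  f <- withr::local_tempfile(fileext = ".txt")
  write_name_model(fx$model, f)
  m2 <- read_name_model(f)
  nm <- fx$labelled$name[1:50]
  expect_identical(predict_name_proba(m2, nm), predict_name_proba(fx$model, nm))
  expect_identical(m2$threshold, fx$model$threshold)
})
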