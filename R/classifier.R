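#' Build the labelled training set for the name classifier
#'
#' Follows the construction used for administrative death files:
#' restrict to foreign-born records; label a record positive iff its
#' birthplace is in `mena_codes`; drop records whose last racial-identity
#' report predates 1981 (the coding system before then had no usable
#' categories); and augment with each record's parent names under the
#' child's label (the father contributes his surname, the mother her full
#' name). Duplicate name strings are retained.
#'
#' @param records person-record tibble.
#' @param mena_codes character vector of birthplace codes labelled MENA;
#'   default [mena_birthplace_codes()].
#' @param min_report_year exclusion cutoff for `race_last_report_year`,
#'   default 1981.
#' @return tibble with columns `name` (full-name string) and `label`
#'   (0/1).
#' @export
build_training_set <- function(records, mena_codes = mena_birthplace_codes(),
                               min_report_year = 1981) {
  need <- c("given_name", "surname", "father_surname", "mother_name",
            "birthplace_code", "race_last_report_year")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) stop("records lack column(s): ", paste(miss, collapse = ", "))
  fb <- !startsWith(records$birthplace_code, "US")
  keep <- fb & records$race_last_report_year >= min_report_year
  r <- records[keep, , drop = FALSE]
  if (nrow(r) == 0) {
    stop("no usable training records (need foreign-born records with ",
         "race_last_report_year >= ", min_report_year, "); supply more input")
  }
  label <- as.integer(r$birthplace_code %in% mena_codes)
  tibble::tibble(
    name = c(bpe_join(r$given_name, r$surname),
             bpe_normalize(r$father_surname),
             bpe_normalize(r$mother_name)),
    label = rep(label, 3)
  )
}

# token -> id table for a vocab (inventory plus specials); pad uses id 1,
# which is masked everywhere.
token_index <- function(vocab) {
  unique(c(vocab$token_inventory, BPE_START, BPE_STOP, BPE_UNK))
}

# tokenized names -> padded id matrix + mask
encode_batch <- function(tok_ids, max_len = NULL) {
  L <- lengths(tok_ids)
  T <- max_len %||% max(L)
  B <- length(tok_ids)
  ids <- matrix(1L, B, T)
  mask <- matrix(0, B, T)
  for (i in seq_len(B)) {
    li <- min(L[i], T)
    ids[i, seq_len(li)] <- tok_ids[[i]][seq_len(li)]
    mask[i, seq_len(li)] <- 1
  }
  list(ids = ids, mask = mask)
}

tokens_to_ids <- function(vocab, names_chr) {
  tokens <- bpe_tokenize(vocab, names_chr)
  index <- token_index(vocab)
  lapply(tokens, function(tk) {
    id <- match(tk, index)
    id[is.na(id)] <- match(BPE_UNK, index)
    id
  })
}

#' Train the gated recurrent name classifier
#'
#' Learns (or reuses) a BPE vocabulary on the labelled names, makes a
#' seeded stratified train/test split, and trains a single-layer gated
#' recurrent unit on binary cross-entropy with Adam. The seed controls
#' the split, the weight initialization, and the batch order, so two runs
#' with the same data and seed produce identical models and metrics.
#'
#' @param labelled tibble with columns `name`, `label` (0/1), e.g. from
#'   [build_training_set()].
#' @param vocab optional [learn_bpe()] vocabulary; learned from the
#'   labelled names when `NULL`.
#' @param max_vocab vocabulary size when learning, default 512.
#' @param embedding_dim,hidden_dim network sizes, defaults 32 and 64.
#' @param epochs,batch_size,lr training schedule, defaults 10, 256, 3e-3.
#' @param test_fraction held-out fraction for metrics, default 0.2.
#' @param threshold decision threshold, default 0.5.
#' @param class_weighting if `TRUE`, weight the loss by inverse class
#'   frequency (for heavily imbalanced training sets). Default `FALSE`.
#' @param seed integer seed, default 1.
#' @return an object of class `name_model` with the parameters, vocab,
#'   threshold, and held-out `metrics` (see [evaluate_classifier()]).
#' @export
train_name_model <- function(labelled, vocab = NULL, max_vocab = 512,
                             embedding_dim = 32, hidden_dim = 64,
                             epochs = 10, batch_size = 256, lr = 3e-3,
                             test_fraction = 0.2, threshold = 0.5,
                             class_weighting = FALSE, seed = 1) {
  stopifnot(all(c("name", "label") %in% names(labelled)))
  y_all <- as.integer(labelled$label)
  if (length(unique(y_all)) < 2) {
    stop("training data contain a single class; need both labels")
  }
  if (is.null(vocab)) vocab <- learn_bpe(labelled$name, max_vocab = max_vocab)
  tok <- tokens_to_ids(vocab, labelled$name)

  set.seed(seed)
  n <- nrow(labelled)
  test_idx <- unlist(lapply(split(seq_len(n), y_all), function(ix) {
    sample(ix, round(length(ix) * test_fraction))
  }), use.names = FALSE)
  train_idx <- setdiff(seq_len(n), test_idx)
  if (length(unique(y_all[train_idx])) < 2) {
    stop("training split contains a single class; need both labels")
  }

  V <- length(token_index(vocab))
  par <- gru_init(V, embedding_dim, hidden_dim, seed = seed)
  st <- adam_init(par)
  cw <- if (class_weighting) {
    freq <- table(factor(y_all[train_idx], levels = 0:1)) / length(train_idx)
    1 / (2 * as.numeric(freq))
  } else c(1, 1)

  for (ep in seq_len(epochs)) {
    ord <- sample(train_idx)
    nb <- ceiling(length(ord) / batch_size)
    for (bi in seq_len(nb)) {
      sel <- ord[((bi - 1) * batch_size + 1):min(bi * batch_size, length(ord))]
      enc <- encode_batch(tok[sel])
      y <- y_all[sel]
      sw <- cw[y + 1] / length(sel)
      fwd <- gru_forward(par, enc$ids, enc$mask, keep_cache = TRUE)
      loss <- -sum(sw * (y * log(pmax(fwd$p, 1e-12)) +
                           (1 - y) * log(pmax(1 - fwd$p, 1e-12))))
      if (!is.finite(loss)) {
        stop("non-finite training loss at epoch ", ep, ", batch ", bi,
             " (p range ", paste(signif(range(fwd$p), 3), collapse = "-"), ")")
      }
      grad <- gru_backward(par, fwd, enc$ids, enc$mask, y, sw)
      upd <- adam_step(par, grad, st, lr = lr)
      par <- upd$par; st <- upd$st
    }
  }

  model <- structure(list(
    par = par, vocab = vocab, threshold = threshold,
    embedding_dim = embedding_dim, hidden_dim = hidden_dim,
    seed = seed, epochs = epochs
  ), class = "name_model")
  p_test <- predict_name_proba(model, labelled$name[test_idx])
  model$metrics <- evaluate_classifier(p_test, y_all[test_idx], threshold)
  model
}

#' @export
print.name_model <- function(x, ...) {
  cat("Gated recurrent name classifier (GRU)\n")
  cat(sprintf("  embedding %d, hidden %d, vocab %d tokens, threshold %.2f\n",
              x$embedding_dim, x$hidden_dim, length(token_index(x$vocab)),
              x$threshold))
  if (!is.null(x$metrics)) {
    cat(sprintf("  held-out: precision %.3f, recall %.3f, F1 %.3f (n = %d)\n",
                x$metrics$precision, x$metrics$recall, x$metrics$f1,
                x$metrics$n_test))
  }
  invisible(x)
}

#' Predicted MENA probability for full names
#'
#' Deterministic forward pass of the trained classifier; the predicted
#' class is `probability >= threshold`.
#'
#' @param model a [train_name_model()] result.
#' @param full_names character vector.
#' @param batch_size forward batch size, default 512.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict_name_proba <- function(model, full_names, batch_size = 512) {
  stopifnot(inherits(model, "name_model"))
  if (length(full_names) == 0) return(numeric(0))
  tok <- tokens_to_ids(model$vocab, full_names)
  out <- numeric(length(full_names))
  starts <- seq(1, length(full_names), by = batch_size)
  for (s in starts) {
    sel <- s:min(s + batch_size - 1, length(full_names))
    enc <- encode_batch(tok[sel])
    out[sel] <- gru_forward(model$par, enc$ids, enc$mask)$p
  }
  out
}

#' Precision, recall, and F1 at a decision threshold
#'
#' Zero-denominator conventions: when no positive predictions are made,
#' precision is reported as 0 with `precision_defined = FALSE`; likewise
#' recall when there are no true positives in the data. F1 is
#' `2PR/(P+R)` where `P+R > 0` and 0 otherwise.
#'
#' @param scores predicted probabilities (or a `name_model`, in which
#'   case `labels` must be a tibble with `name`, `label`).
#' @param labels 0/1 vector aligned with `scores`.
#' @param threshold decision threshold, default 0.5.
#' @return one-row tibble: `precision`, `recall`, `f1`, `n_test`,
#'   `threshold`, `precision_defined`, `recall_defined`.
#' @export
evaluate_classifier <- function(scores, labels, threshold = 0.5) {
  if (inherits(scores, "name_model")) {
    stopifnot(all(c("name", "label") %in% names(labels)))
    model <- scores
    scores <- predict_name_proba(model, labels$name)
    labels <- as.integer(labels$label)
  }
  stopifnot(length(scores) == length(labels), length(scores) > 0)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  p_def <- (tp + fp) > 0
  r_def <- (tp + fn) > 0
  precision <- if (p_def) tp / (tp + fp) else 0
  recall <- if (r_def) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  tibble::tibble(
    precision = precision, recall = recall, f1 = f1,
    n_test = length(labels), threshold = threshold,
    precision_defined = p_def, recall_defined = r_def
  )
}

#' Precision/recall curve over a threshold grid
#'
#' @param scores predicted probabilities.
#' @param labels 0/1 vector.
#' @param thresholds grid, default `seq(0.05, 0.95, by = 0.05)`.
#' @return tibble with one row per threshold.
#' @export
threshold_sweep <- function(scores, labels, thresholds = seq(0.05, 0.95, 0.05)) {
  dplyr::bind_rows(lapply(thresholds, function(th) {
    evaluate_classifier(scores, labels, th)
  }))
}

#' Bag-of-character-bigrams logistic baseline
#'
#' A deliberately simple reference classifier: ridge-penalized logistic
#' regression (glmnet, fixed small lambda) on counts of boundary-marked
#' character bigrams of the normalized name. Used as an independent
#' yardstick for the sequence model — a healthy recurrent classifier
#' should not materially underperform it on separable data.
#'
#' @param labelled tibble with `name`, `label`.
#' @param test_fraction,seed split settings matching
#'   [train_name_model()].
#' @param threshold decision threshold, default 0.5.
#' @param lambda ridge penalty, default 1e-4.
#' @return list with the fitted glmnet object, the bigram feature
#'   universe, and held-out `metrics`.
#' @export
bigram_baseline <- function(labelled, test_fraction = 0.2, seed = 1,
                            threshold = 0.5, lambda = 1e-4) {
  y_all <- as.integer(labelled$label)
  if (length(unique(y_all)) < 2) stop("need both classes")
  bigrams <- function(x) {
    x <- paste0("^", bpe_normalize(x), "$")
    lapply(strsplit(x, ""), function(ch) {
      if (length(ch) < 2) character(0) else paste0(ch[-length(ch)], ch[-1])
    })
  }
  bg <- bigrams(labelled$name)
  universe <- sort(unique(unlist(bg, use.names = FALSE)), method = "radix")
  ij <- do.call(rbind, lapply(seq_along(bg), function(i) {
    j <- match(bg[[i]], universe)
    if (length(j) == 0) return(NULL)
    cbind(i = i, j = j)
  }))
  X <- Matrix::sparseMatrix(i = ij[, "i"], j = ij[, "j"], x = 1,
                            dims = c(length(bg), length(universe)))
  set.seed(seed)
  n <- nrow(labelled)
  test_idx <- unlist(lapply(split(seq_len(n), y_all), function(ix) {
    sample(ix, round(length(ix) * test_fraction))
  }), use.names = FALSE)
  train_idx <- setdiff(seq_len(n), test_idx)
  fit <- glmnet::glmnet(X[train_idx, , drop = FALSE], y_all[train_idx],
                        family = "binomial", alpha = 0, lambda = lambda,
                        standardize = FALSE)
  p <- as.numeric(stats::predict(fit, X[test_idx, , drop = FALSE],
                                 type = "response"))
  list(fit = fit, universe = universe,
       metrics = evaluate_classifier(p, y_all[test_idx], threshold))
}
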