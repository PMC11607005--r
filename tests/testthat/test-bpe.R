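test_that("BPE learns the most frequent pair first, deterministically", {
  corpus <- c("khalil khan", "khaled khoury")
  # brute-force pair counting oracle over the two normalized strings
  count_pairs <- function(strings) {
    tab <- list()
    for (s in strings) {
      ch <- strsplit(s, "")[[1]]
      if (length(ch) < 2) next
      for (i in seq_len(length(ch) - 1)) {
        k <- paste(ch[i], ch[i + 1], sep = "\x1f")
        tab[[k]] <- (tab[[k]] %||% 0) + 1
      }
    }
    unlist(tab)
  }
  `%||%` <- function(x, y) if (is.null(x)) y else x
  pc <- count_pairs(corpus)
  top <- names(pc)[which.max(pc)]
  expect_identical(top, "k\x1fh")   # "kh" occurs 4 times

  v <- learn_bpe(corpus, max_vocab = length(unique(strsplit(paste(corpus, collapse = ""), "")[[1]])) + 1)
  expect_identical(v$merges[[1]], c("k", "h"))
  expect_length(v$merges, 1)

  v2 <- learn_bpe(corpus, max_vocab = 100)
  v3 <- learn_bpe(corpus, max_vocab = 100)
  expect_identical(v2$merges, v3$merges)
})

test_that("degenerate corpora and invalid sizes are handled", {
  expect_length(learn_bpe("a", max_vocab = 50)$merges, 0)
  expect_error(learn_bpe(character(0)), "empty corpus")
  expect_error(learn_bpe("", max_vocab = 50), "empty corpus")
  expect_error(learn_bpe(c("khalil", "khan"), max_vocab = 2), "alphabet")
})

test_that("tokenization applies merges, brackets, and round-trips", {
  v <- learn_bpe(c("khalil khan", "khaled khoury"), max_vocab = 100)
  tk <- bpe_tokenize(v, "khalil")[[1]]
  expect_identical(tk[1], "<s>")
  expect_identical(tk[length(tk)], "</s>")
  expect_true(startsWith(tk[2], "kh"))

  expect_identical(bpe_tokenize(v, "")[[1]], c("<s>", "</s>"))

  tk_unk <- bpe_tokenize(v, "qzx")[[1]]
  expect_true("<unk>" %in% tk_unk)

  # round trip and length bound over random strings on the training alphabet
  set.seed(4)
  alpha <- v$alphabet
  for (i in 1:100) {
    s <- paste(sample(setdiff(alpha, " "), sample(1:14, 1), replace = TRUE),
               collapse = "")
    tk <- bpe_tokenize(v, s)[[1]]
    body <- setdiff(tk, c("<s>", "</s>"))
    expect_identical(paste(tk[-c(1, length(tk))], collapse = ""), s)
    expect_lte(length(tk), nchar(s) + 2)
  }
})

test_that("normalization lowercases, strips accents and digits, keeps ' and -", {
  expect_identical(bpe_normalize("  Kh'alil-El  2nd "), "kh'alil-el nd")
  expect_identical(bpe_normalize("JOSE"), "jose")
})

test_that("vocabulary serialization round-trips bit-exactly", {
  lab <- labelled_name_corpus(150, seed = 8)
  v <- learn_bpe(lab$name, max_vocab = 120)
  f <- withr::local_tempfile(fileext = ".txt")
  write_bpe_vocab(v, f)
  v2 <- read_bpe_vocab(f)
  expect_identical(v2$merges, v$merges)
  expect_identical(v2$alphabet, v$alphabet)
  expect_identical(v2$token_inventory, v$token_inventory)
  expect_identical(bpe_tokenize(v2, lab$name[1:20]), bpe_tokenize(v, lab$name[1:20]))
})
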