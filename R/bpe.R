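# Special tokens of the name tokenizer.
BPE_SEP <- "_"        # joins given name and surname (base character)
BPE_START <- "<s>"
BPE_STOP <- "</s>"
BPE_UNK <- "<unk>"

#' Normalize a full-name string for tokenization
#'
#' Lowercases, transliterates accents to ASCII where possible, strips
#' digits, keeps hyphens and apostrophes (they carry name signal),
#' collapses internal whitespace to single spaces, and trims. Given name
#' and surname are joined by the `"_"` separator before normalization by
#' the callers.
#'
#' @param x character vector.
#' @return normalized character vector.
#' @export
bpe_normalize <- function(x) {
  x <- tolower(x)
  conv <- iconv(x, from = "UTF-8", to = "ASCII//TRANSLIT")
  x <- ifelse(is.na(conv), x, conv)
  x <- gsub("[0-9]", "", x)
  x <- gsub("[^a-z' _-]", " ", x)
  x <- gsub("[ ]+", " ", x)
  trimws(x)
}

# Join given/surname into the canonical training string.
bpe_join <- function(given, surname) {
  paste0(bpe_normalize(given), BPE_SEP, bpe_normalize(surname))
}

# Flat corpus representation: all symbol sequences concatenated with a
# control-character boundary marker between strings; pair operations
# ignore pairs spanning a marker. Pair keys join left/right with another
# control character so multi-character tokens cannot collide.
.BOUND <- "\x1e"
.PAIRSEP <- "\x1f"

corpus_flatten <- function(seqs) {
  unlist(lapply(seqs, function(s) c(s, .BOUND)), use.names = FALSE)
}

# Rebuild per-string token sequences from the flat vector; `n_strings`
# fixes the output length so empty strings keep their slot.
corpus_unflatten <- function(v, n_strings) {
  idx <- cumsum(v == .BOUND)
  keep <- v != .BOUND
  res <- rep(list(character(0)), n_strings)
  if (any(keep)) {
    grp <- split(v[keep], idx[keep] + 1)
    res[as.integer(names(grp))] <- grp
  }
  res
}

# Count adjacent pairs in the flat representation, weighted per position.
pair_counts <- function(v, w) {
  n <- length(v)
  if (n < 2) return(numeric(0))
  left <- v[-n]; right <- v[-1]
  ok <- left != .BOUND & right != .BOUND
  if (!any(ok)) return(numeric(0))
  key <- paste(left[ok], right[ok], sep = .PAIRSEP)
  tapply(w[-n][ok], key, sum)
}

# Merge every non-overlapping occurrence of (left, right) left-to-right.
apply_merge_flat <- function(v, left, right, merged) {
  n <- length(v)
  if (n < 2) return(v)
  hit <- which(v[-n] == left & v[-1] == right)
  if (length(hit) == 0) return(v)
  if (length(hit) > 1 && left == right) {  # overlapping runs, e.g. "aaa"
    keep <- logical(length(hit))
    last <- -2L
    for (i in seq_along(hit)) {
      if (hit[i] > last + 1L) { keep[i] <- TRUE; last <- hit[i] }
    }
    hit <- hit[keep]
  }
  v[hit] <- merged
  v[-(hit + 1L)]
}

#' Learn a byte-pair-encoding vocabulary from a name corpus
#'
#' Standard BPE training on normalized full-name strings: starting from
#' single characters, iteratively merge the most frequent adjacent token
#' pair until the token inventory reaches `max_vocab` or no pair occurs
#' at least twice. Ties are broken lexicographically on the
#' `(left, right)` pair (C-locale radix order) so training is
#' deterministic.
#'
#' @param corpus character vector of full-name strings (already joined
#'   with the `"_"` separator, e.g. via `paste0(given, "_", surname)`).
#' @param max_vocab maximum token-inventory size (base characters plus
#'   merged clusters), default 512.
#' @return an object of class `bpe_vocab` with the ordered merge list and
#'   the token inventory (plus the start/stop/unknown specials).
#' @export
learn_bpe <- function(corpus, max_vocab = 512) {
  corpus <- bpe_normalize(corpus)
  corpus <- corpus[nzchar(corpus)]
  if (length(corpus) == 0) stop("empty corpus after normalization")
  tab <- table(corpus)
  strings <- names(tab)
  w_str <- as.numeric(tab)
  seqs <- strsplit(strings, "")
  alphabet <- sort(unique(unlist(seqs, use.names = FALSE)), method = "radix")
  if (max_vocab < length(alphabet)) {
    stop("max_vocab (", max_vocab, ") is smaller than the base alphabet (",
         length(alphabet), ")")
  }
  v <- corpus_flatten(seqs)
  string_of <- function(v) pmin(cumsum(v == .BOUND) + 1L, length(w_str))
  w <- w_str[string_of(v)]

  merges <- list()
  inventory <- alphabet
  while (length(inventory) < max_vocab) {
    pc <- pair_counts(v, w)
    if (length(pc) == 0 || max(pc) < 2) break
    best <- sort(names(pc)[pc == max(pc)], method = "radix")[1]
    parts <- strsplit(best, .PAIRSEP, fixed = TRUE)[[1]]
    merged <- paste0(parts[1], parts[2])
    v <- apply_merge_flat(v, parts[1], parts[2], merged)
    w <- w_str[string_of(v)]
    merges[[length(merges) + 1]] <- parts
    if (!(merged %in% inventory)) inventory <- c(inventory, merged)
  }
  structure(list(
    merges = merges,
    token_inventory = inventory,
    alphabet = alphabet,
    max_vocab = max_vocab,
    specials = c(start = BPE_START, stop = BPE_STOP, unk = BPE_UNK,
                 sep = BPE_SEP)
  ), class = "bpe_vocab")
}

#' @export
print.bpe_vocab <- function(x, ...) {
  cat("BPE vocabulary: ", length(x$alphabet), " base characters + ",
      length(x$merges), " merges (max_vocab ", x$max_vocab, ")\n", sep = "")
  if (length(x$merges) > 0) {
    shown <- utils::head(vapply(x$merges, paste, character(1), collapse = "+"), 8)
    cat("  first merges:", paste(shown, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tokenize full names with a learned BPE vocabulary
#'
#' Normalizes each input, maps characters outside the base alphabet to
#' the unknown token, applies the learned merges in order, and brackets
#' the result with start/stop tokens. Concatenating the non-special
#' tokens reproduces the normalized input (round trip) whenever no
#' unknown character occurs.
#'
#' @param vocab a [learn_bpe()] vocabulary.
#' @param full_names character vector of full-name strings.
#' @return list of character vectors (token sequences), one per input.
#' @export
bpe_tokenize <- function(vocab, full_names) {
  stopifnot(inherits(vocab, "bpe_vocab"))
  norm <- bpe_normalize(full_names)
  seqs <- strsplit(norm, "")
  seqs <- lapply(seqs, function(s) {
    s[!(s %in% vocab$alphabet)] <- BPE_UNK
    s
  })
  v <- corpus_flatten(seqs)
  for (m in vocab$merges) {
    v <- apply_merge_flat(v, m[1], m[2], paste0(m[1], m[2]))
  }
  res <- corpus_unflatten(v, length(full_names))
  lapply(res, function(s) c(BPE_START, s, BPE_STOP))
}

#' Write / read a BPE vocabulary as plain text
#'
#' One merge per line (tab-separated pair), preceded by header lines
#' carrying the base alphabet and `max_vocab`; reloads bit-exactly.
#'
#' @param vocab a `bpe_vocab`.
#' @param path file path.
#' @return `read_bpe_vocab` returns the vocabulary; `write_bpe_vocab`
#'   returns `path` invisibly.
#' @export
write_bpe_vocab <- function(vocab, path) {
  stopifnot(inherits(vocab, "bpe_vocab"))
  lines <- c(
    "#menamort-bpe v1",
    paste0("#max_vocab\t", vocab$max_vocab),
    paste0("#alphabet\t", paste(vocab$alphabet, collapse = "\t")),
    vapply(vocab$merges, paste, character(1), collapse = "\t")
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_bpe_vocab
#' @export
read_bpe_vocab <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 3 || lines[1] != "#menamort-bpe v1") {
    stop("not a menamort BPE vocabulary file: ", path)
  }
  max_vocab <- as.integer(strsplit(lines[2], "\t", fixed = TRUE)[[1]][2])
  alphabet <- strsplit(lines[3], "\t", fixed = TRUE)[[1]][-1]
  merge_lines <- lines[-(1:3)]
  merge_lines <- merge_lines[nzchar(merge_lines)]
  merges <- strsplit(merge_lines, "\t", fixed = TRUE)
  inventory <- alphabet
  for (m in merges) {
    mg <- paste0(m[1], m[2])
    if (!(mg %in% inventory)) inventory <- c(inventory, mg)
  }
  structure(list(
    merges = merges, token_inventory = inventory, alphabet = alphabet,
    max_vocab = max_vocab,
    specials = c(start = BPE_START, stop = BPE_STOP, unk = BPE_UNK,
                 sep = BPE_SEP)
  ), class = "bpe_vocab")
}
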