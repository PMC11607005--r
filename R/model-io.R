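#' Serialize a trained name model to a single plain-text file
#'
#' Writes the network parameters (full double precision), the decision
#' threshold, and the BPE vocabulary into one text file; [read_name_model()]
#' reloads it bit-exactly.
#'
#' @param model a `name_model`.
#' @param path file path.
#' @return `path`, invisibly; `read_name_model` returns the model.
#' @export
write_name_model <- function(model, path) {
  stopifnot(inherits(model, "name_model"))
  num <- function(x) sprintf("%.17g", x)
  lines <- c(
    "#menamort-model v1",
    paste0("#threshold\t", num(model$threshold)),
    paste0("#dims\t", model$embedding_dim, "\t", model$hidden_dim),
    paste0("#seed\t", model$seed, "\t#epochs\t", model$epochs)
  )
  for (k in names(model$par)) {
    p <- model$par[[k]]
    if (is.matrix(p)) {
      lines <- c(lines, paste0("#param\t", k, "\t", nrow(p), "\t", ncol(p)),
                 paste(num(as.numeric(p)), collapse = "\t"))
    } else {
      lines <- c(lines, paste0("#param\t", k, "\t", length(p), "\t0"),
                 paste(num(as.numeric(p)), collapse = "\t"))
    }
  }
  lines <- c(lines, "#vocab")
  vtmp <- tempfile()
  write_bpe_vocab(model$vocab, vtmp)
  lines <- c(lines, readLines(vtmp, encoding = "UTF-8"))
  unlink(vtmp)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_name_model
#' @export
read_name_model <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (lines[1] != "#menamort-model v1") stop("not a menamort model file: ", path)
  threshold <- as.numeric(strsplit(lines[2], "\t", fixed = TRUE)[[1]][2])
  dims <- as.integer(strsplit(lines[3], "\t", fixed = TRUE)[[1]][-1])
  meta <- strsplit(lines[4], "\t", fixed = TRUE)[[1]]
  par <- list()
  i <- 5
  while (i <= length(lines) && startsWith(lines[i], "#param")) {
    hd <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    k <- hd[2]; nr <- as.integer(hd[3]); nc <- as.integer(hd[4])
    vals <- as.numeric(strsplit(lines[i + 1], "\t", fixed = TRUE)[[1]])
    par[[k]] <- if (nc > 0) matrix(vals, nr, nc) else
      if (nr == 1) vals else as.numeric(vals)
    i <- i + 2
  }
  stopifnot(lines[i] == "#vocab")
  vtmp <- tempfile()
  writeLines(lines[(i + 1):length(lines)], vtmp, useBytes = TRUE)
  vocab <- read_bpe_vocab(vtmp)
  unlink(vtmp)
  par$b_out <- as.numeric(par$b_out)
  structure(list(
    par = par, vocab = vocab, threshold = threshold,
    embedding_dim = dims[1], hidden_dim = dims[2],
    seed = as.integer(meta[2]), epochs = as.integer(meta[4])
  ), class = "name_model")
}
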