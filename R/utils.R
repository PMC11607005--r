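`%||%` <- function(x, y) if (is.null(x)) y else x

# smallest value on ties, per the documented mode tie-break
integer_mode <- function(x, w = NULL) {
  if (length(x) == 0) return(NA_real_)
  if (is.null(w)) w <- rep(1, length(x))
  tab <- tapply(w, x, sum)
  vals <- as.numeric(names(tab))
  vals[which(tab == max(tab))[1]]
}

#' @importFrom rlang .data
#' @importFrom stats runif rbinom rnorm setNames quantile sd lm coef vcov
#' @importFrom utils head
NULL
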