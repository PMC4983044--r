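#' @importFrom stats rnbinom rpois rlnorm qlnorm pnorm rnorm runif setNames
#' @importFrom utils read.delim write.table head tail
#' @importFrom methods is
NULL

BASES <- c("A", "C", "G", "T")

# base sampling probabilities for a target GC fraction
base_probs <- function(gc) {
  stopifnot(gc >= 0, gc <= 1)
  setNames(c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2), BASES)
}

random_bases <- function(n, gc) {
  sample(BASES, n, replace = TRUE, prob = base_probs(gc))
}

revcomp_chars <- function(x) {
  rev(unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[x]))
}

revcomp_string <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Round half-up
#'
#' Rounds away from the banker's rule used by [base::round()]: 0.5 always
#' rounds up in magnitude, matching how percentages are typically printed in
#' genome-annotation summary tables.
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_strand <- function(strand) {
  if (!all(strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
}

# 5' start of a feature in transcription direction
feature_tss_side <- function(start, end, strand) {
  ifelse(strand == "+", start, end)
}
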