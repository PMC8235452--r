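#' Half-up rounding
#'
#' Rounds to the printed precision the way tabulated percentages are
#' conventionally rounded (0.5 always rounds away from zero), unlike base
#' `round()`'s round-half-even.  Used for all reported percentage columns.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits (default 0).
#' @return Rounded numeric vector.
#' @examples
#' roundHalfUp(0.5)          # 1, where round(0.5) is 0
#' roundHalfUp(88.45, 1)     # 88.5
#' @export
roundHalfUp <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Percentages of a count vector
#'
#' Converts counts to percentages of their total, computing the ratio on
#' unrounded values and then rounding half-up to the requested precision.
#'
#' @param counts numeric vector of counts (names are preserved).
#' @param digits decimal digits of the reported percentage (default 0).
#' @return Numeric vector of percentages summing to ~100 before rounding.
#' @examples
#' percentOfTotal(c(nonsyn = 1281, splice = 12, other = 155))
#' @export
percentOfTotal <- function(counts, digits = 0) {
  if (!length(counts)) return(numeric(0))
  total <- sum(counts)
  if (total == 0) stop("percentOfTotal: total count is zero")
  roundHalfUp(100 * counts / total, digits)
}

# log(sum(exp(x))) without overflow; -Inf-safe
.logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# "chrom:pos:ref:alt" string keys
.vkey <- function(chrom, pos, ref, alt) paste(chrom, pos, ref, alt, sep = ":")

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
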