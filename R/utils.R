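# Small shared helpers.

#' Round half away from zero
#'
#' Percentages in the report tables are rounded half-up (5 rounds away from
#' zero), the convention of the clinical literature, rather than R's default
#' round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places to keep.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(0.125, 76.65), 2)
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Percentage of count over denominator, rounded half-up; NA where the
# denominator is empty.
pct <- function(count, total, digits = 1) {
  total <- rep_len(total, length(count))
  out <- rep(NA_real_, length(count))
  ok <- !is.na(total) & total > 0
  out[ok] <- round_half_up(100 * count[ok] / total[ok], digits)
  out
}

# Largest-remainder (Hamilton) rounding of a composition's percentages:
# each count's share of `total` at `digits` decimals, adjusted so the
# percentages sum to exactly 100. This is the convention of distribution
# rows in the clinical survey literature, where a 39.8/30.5/29.7 split is
# preferred to a 39.8/30.5/29.6 one that sums to 99.9.
pct_lr <- function(counts, total = sum(counts), digits = 1) {
  if (total <= 0) return(rep(NA_real_, length(counts)))
  scale <- 10^digits
  raw <- 100 * counts / total * scale
  base <- floor(raw)
  short <- round(100 * scale - sum(base))
  if (short > 0) {
    top <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[top] <- base[top] + 1
  }
  unname(base / scale)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# stop() with sprintf-style formatting, no call in the condition.
abort_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
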