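## Intraclass correlation for paired readouts.
##
## The primary estimator is the classical Fisher intraclass correlation:
## the product-moment correlation of the pairs entered symmetrically (each
## pair contributes both orderings), i.e. with the grand mean and grand
## variance of the pooled 2n values in place of per-column moments.  It is
## the one-way random-effects ANOVA estimator in its symmetric-pairs form,
## exactly symmetric under swapping the members of every pair.

#' Fisher intraclass correlation of paired readouts
#'
#' @param x,y Numeric vectors of paired readouts (same length, >= 2 pairs,
#'   finite).
#' @param type `"fisher"` (default) for the classical symmetric-pairs
#'   estimator; `"anova"` for the one-way random-effects mean-square form
#'   `(MSB - MSW) / (MSB + MSW)`, provided for sensitivity analysis.
#' @return The ICC in `[-1, 1]`, or `NA_real_` when the pooled variance is
#'   zero (agreement undefined), signalled with a warning.
#' @details For `type = "fisher"`, with grand mean `m` of the pooled `2n`
#'   values and pooled variance `s2 = sum((x-m)^2 + (y-m)^2) / (2n)`, the
#'   estimate is `sum((x-m)*(y-m)) / (n * s2)`.  Identical readouts give 1;
#'   two pairs `(1,2), (2,1)` give the minimal value -1.
#' @export
#' @examples
#' fisher_icc(1:3, 1:3)            # 1
#' fisher_icc(c(1, 2), c(2, 1))    # -1
fisher_icc <- function(x, y, type = c("fisher", "anova")) {
  type <- match.arg(type)
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2L) {
    warning("fisher_icc(): fewer than 2 finite pairs; ICC undefined")
    return(NA_real_)
  }
  m <- mean(c(x, y))
  ss <- sum((x - m)^2 + (y - m)^2)
  if (ss == 0) {
    warning("fisher_icc(): zero total variance; ICC undefined")
    return(NA_real_)
  }
  if (type == "fisher") {
    return(2 * sum((x - m) * (y - m)) / ss)
  }
  ## one-way ANOVA form (pairs as groups of size 2)
  pm <- (x + y) / 2
  msw <- sum((x - pm)^2 + (y - pm)^2) / n
  msb <- 2 * sum((pm - m)^2) / (n - 1)
  if (msb + msw == 0) {
    warning("fisher_icc(): zero total variance; ICC undefined")
    return(NA_real_)
  }
  (msb - msw) / (msb + msw)
}
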