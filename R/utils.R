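#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor pt p.adjust shapiro.test t.test wilcox.test
#'   kruskal.test ks.test lm coef quantile rnorm rpois rbinom rbeta runif
#'   rlnorm rmultinom rgamma sd var uniroot anova aov simulate complete.cases
#'   setNames pf median r2dtable
#' @importFrom utils combn read.table write.table head modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic per-stage substream of a master seed; keeps results below
# 2^31 - 1 so they remain valid R integer seeds.
stage_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(k)) %% (2^31 - 1))
}

abort_field <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

check_scalar_count <- function(x, field, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x != round(x) || x < min)
    abort_field(field, sprintf("must be a single integer >= %s", min))
  as.integer(x)
}

check_fraction <- function(x, field, lo = 0, hi = 1, open_lo = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) ||
      x < lo || x > hi || (open_lo && x <= lo))
    abort_field(field, sprintf("must be a number in %s%s, %s]",
                               if (open_lo) "(" else "[", lo, hi))
  as.numeric(x)
}
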