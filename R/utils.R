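#' @importFrom stats median pchisq quantile rexp rnorm runif sd setNames
#'   wilcox.test rlnorm
#' @importFrom utils read.delim write.table
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

# Stop with a sprintf-style message, without the call in the condition.
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort("`%s` must be a single finite number", name)
  }
  if (strict_lower && x <= lower) {
    abort("`%s` must be > %s (got %s)", name, lower, x)
  }
  if (!strict_lower && x < lower) {
    abort("`%s` must be >= %s (got %s)", name, lower, x)
  }
  if (x > upper) abort("`%s` must be <= %s (got %s)", name, upper, x)
  invisible(x)
}

# Deterministic per-unit seed stream: unit i of a master seed gets its own
# 31-bit seed, so growing the number of units never reshuffles earlier ones.
derive_seed <- function(master_seed, index) {
  master_seed <- as.numeric(master_seed)
  # Weyl-style sequence; constants coprime with 2^31.
  (master_seed * 2654435761 + index * 40503 + 7919) %% 2147483647
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
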