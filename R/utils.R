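#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef median pchisq pnorm predict quantile rbinom rexp
#'   rlnorm rnorm runif sd setNames t.test wilcox.test
#' @importFrom utils head write.table read.delim
#' @importFrom survival Surv coxph coxph.control coxph.fit survfit survdiff
NULL

# Run code with a temporary RNG state so package randomness never leaks into
# (or depends on) the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Derive a stream-specific child seed so independent stages of a pipeline can
# share one master seed without sharing a stream. Kept below 2^31 - 1.
child_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + stream * 9973) %% 2147483629
}

#' Rank-based AUC (Mann-Whitney with ties counted one half)
#'
#' @param score numeric predictor, higher means more positive-like.
#' @param positive logical, TRUE for positives.
#' @return AUC in \[0, 1\].
#' @keywords internal
auc_rank <- function(score, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC undefined: need at least one positive and one negative")
  }
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' log2(x + 1) transform of a numeric vector or matrix
#' @param x non-negative numeric.
#' @export
log2p1 <- function(x) log2(x + 1)

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
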