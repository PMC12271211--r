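# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG state
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's `.Random.seed`
#' afterwards, so seeded generators never perturb global random state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# sample() that never surprises on length-1 x
sample_from <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size = size, replace = replace, prob = prob)]
}

stop_if <- function(cond, ...) if (cond) stop(sprintf(...), call. = FALSE)

#' Reconstruct triplicate values from a reported mean and standard deviation
#'
#' Many published assay tables report only per-group `mean +/- sd` for n = 3.
#' `replicates_from_summary()` returns the unique symmetric triple
#' `mean + sd * c(-1, 0, 1)`, whose sample mean and sample standard deviation
#' (n - 1 denominator) equal the reported values exactly. Useful to feed
#' printed summaries into functions that operate on replicate values, such as
#' [two_sample_ttest()] or [classify_promoters()].
#'
#' @param mean reported group mean.
#' @param sd reported sample standard deviation.
#' @param n number of replicates; only `n = 3` is supported.
#' @return numeric vector of length `n`.
#' @examples
#' x <- replicates_from_summary(104.8, 5.9)
#' c(mean(x), sd(x))
#' @export
replicates_from_summary <- function(mean, sd, n = 3) {
  stop_if(n != 3, "replicates_from_summary() supports n = 3 only")
  stop_if(sd < 0, "sd must be non-negative")
  mean + sd * c(-1, 0, 1)
}
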