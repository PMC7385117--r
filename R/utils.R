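#' Length of the longest strictly increasing subsequence
#'
#' Patience-sorting algorithm, O(n log n). Used by [colinearity_stats()] to
#' score gene-order conservation within a scaffold pair.
#'
#' @param x Numeric vector with no ties (within-scaffold ordinal ranks).
#' @return Integer scalar, the LIS length (0 for empty input).
#' @examples
#' lis_length(c(1, 3, 2, 4))  # 3: e.g. 1, 2, 4
#' @export
lis_length <- function(x) {
  n <- length(x)
  if (n == 0L) return(0L)
  tails <- numeric(0)
  for (v in x) {
    # first pile whose top is >= v (strict increase)
    j <- findInterval(v - 0.5, tails) + 1L
    if (j > length(tails)) tails <- c(tails, v) else tails[j] <- v
  }
  length(tails)
}

# stop unless all columns present
check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# deterministic seeded evaluation without touching the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
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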