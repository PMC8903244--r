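# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
pm_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "pm_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Split a master seed into named substreams
#'
#' Deterministically derives independent integer seeds for the covariate,
#' outcome, IER and MCMC random-number streams from one master seed, so a
#' stage can be re-run or varied without disturbing the others.
#'
#' @param seed Master integer seed.
#' @param n Number of substreams.
#' @return Integer vector of length `n`, each below 2^31.
#' @noRd
pm_sub_seeds <- function(seed, n = 4L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  sample.int(2147483646L, n)
}

is_flag_true <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  tolower(trimws(as.character(x))) %in% c("true", "t", "yes", "y", "1")
}
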