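# Internal helpers: seeded RNG scoping, substream derivation, argument checks.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package operations do not
#' disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible per-trial substream seed from a root seed and a
# counter, independent of call order.  Kept below 2^31 - 1.
substream_seed <- function(root_seed, counter) {
  as.integer((as.double(root_seed) * 48271 + as.double(counter) * 16807) %%
               2147483647)
}

stop_arg <- function(msg) {
  stop(errorCondition(msg, class = c("mubci_argument_error", "error")))
}
stop_config <- function(msg) {
  stop(errorCondition(msg, class = c("mubci_config_error", "error")))
}
stop_validation <- function(msg) {
  stop(errorCondition(msg, class = c("mubci_validation_error", "error")))
}
stop_io <- function(msg) {
  stop(errorCondition(msg, class = c("mubci_io_error", "error")))
}
stop_channel <- function(msg) {
  stop(errorCondition(msg, class = c("mubci_channel_error",
                                     "mubci_validation_error", "error")))
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_arg(sprintf("`%s` must be a finite numeric scalar", name))
  if (strict_lower && x <= lower)
    stop_arg(sprintf("`%s` must be > %g", name, lower))
  if (!strict_lower && x < lower)
    stop_arg(sprintf("`%s` must be >= %g", name, lower))
  if (x > upper)
    stop_arg(sprintf("`%s` must be <= %g", name, upper))
  invisible(x)
}

# Centered moving average with truncated (partial) windows at the edges.
# `width` is in samples; even widths are rounded up to the next odd value.
moving_average <- function(x, width) {
  width <- as.integer(width)
  if (width <= 1L) return(x)
  if (width %% 2L == 0L) width <- width + 1L
  half <- (width - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
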