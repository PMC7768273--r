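# internal helpers shared across modules

#' Derive a reproducible sub-seed for a named pipeline stage
#'
#' A single top-level seed fans out to per-stage sub-seeds so that adding a
#' stage never perturbs the random streams of earlier stages. The mapping is
#' a fixed multiplicative hash of the stage name folded into the seed, kept
#' below 2^31 - 1.
#'
#' @param seed Integer top-level seed.
#' @param stage Character scalar naming the stage (e.g. "synth", "flipflop").
#' @param index Optional non-negative integer for per-replicate sub-streams.
#' @return An integer seed.
#' @export
split_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (cp in utf8ToInt(stage)) h <- (h * 131 + cp) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 48271 + h + 7919 * index) %% 2147483647)
}

# centered moving average with symmetrically shrinking windows at the ends
# (width 1, 3, ..., w), NA-tolerant: NA inputs stay NA, neighbours of an NA
# are averaged over the non-NA values in their window.
moving_average <- function(x, w) {
  stopifnot(w >= 1, w %% 2 == 1)
  n <- length(x)
  if (n == 0L) return(x)
  h <- (w - 1L) %/% 2L
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(x[i])) next
    k <- min(h, i - 1L, n - i)
    win <- x[(i - k):(i + k)]
    out[i] <- mean(win, na.rm = TRUE)
  }
  out
}

run_lengths <- function(x) {
  r <- rle(as.character(x))
  tibble::tibble(
    value = r$values,
    length = r$lengths,
    start = cumsum(c(1L, r$lengths[-length(r$lengths)])),
    end = cumsum(r$lengths)
  )
}

assert_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort(sprintf("`%s` must be a finite numeric scalar", name))
  if (positive && x <= 0) abort(sprintf("`%s` must be positive", name))
  invisible(x)
}
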