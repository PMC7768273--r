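# Bout extraction and summary statistics for 4-stage hypnograms.

#' Bout table and summary statistics from a 4-stage hypnogram
#'
#' Bouts are maximal runs of consecutive same-label epochs. NRt (`t`) bouts
#' separated only by manual-arousal wake runs of at most `arousal_merge`
#' epochs count as a single bout (the interrupting wake epochs keep their
#' `W` label and are not part of the bout's length). Each t-bout's origin is
#' the sleep state immediately preceding it.
#'
#' Summary metrics: bout counts per state; short (`<= rem_short` epochs) and
#' long REM bout counts; long NRt bouts (`>= nrt_long` epochs); NRt density
#' per origin state, in bouts per minute spent in the origin state; NRt
#' amount as a percentage of total sleep time (N + R + t epochs); and mean
#' NRt bout duration by origin (epochs and seconds). Densities with zero
#' time in the origin state are reported as `NA` (undefined), never
#' infinite.
#'
#' @param hyp 4-stage hypnogram: tibble with `epoch_index` and `label`
#'   (W/N/R/t), e.g. the output of [score_4stage()].
#' @param epoch_s Epoch length in seconds (default 5).
#' @param arousal_merge Maximum arousal length, in epochs, absorbed inside a
#'   t-bout (scoring rule 4; default 3).
#' @param rem_short Threshold (epochs) separating short from long REM bouts
#'   (default 15, i.e. 75 s).
#' @param nrt_long Minimum length (epochs) of a "long" NRt bout (default 3).
#' @return Object of class `bout_table`: list with tibbles `bouts` (state,
#'   start, length, origin) and `summary` (one row), plus the inputs used.
#' @export
bout_stats <- function(hyp, epoch_s = 5, arousal_merge = 3,
                       rem_short = 15, nrt_long = 3) {
  lab <- as.character(hyp$label)
  stopifnot(all(lab %in% c("W", "N", "R", "t")))
  runs <- run_lengths(lab)

  # merge t-runs separated only by short W runs (rule 4)
  bouts <- list()
  i <- 1L
  while (i <= nrow(runs)) {
    st <- runs$value[i]
    if (st != "t") {
      bouts[[length(bouts) + 1L]] <-
        list(state = st, start = runs$start[i], length = runs$length[i],
             origin = NA_character_)
      i <- i + 1L
      next
    }
    start <- runs$start[i]
    len <- runs$length[i]
    origin <- if (i > 1L && runs$value[i - 1L] %in% c("N", "R"))
      runs$value[i - 1L] else NA_character_
    j <- i
    while (j + 2L <= nrow(runs) && runs$value[j + 1L] == "W" &&
           runs$length[j + 1L] <= arousal_merge && runs$value[j + 2L] == "t") {
      # the interrupting arousal stays on record as a wake bout
      bouts[[length(bouts) + 1L]] <-
        list(state = "W", start = runs$start[j + 1L],
             length = runs$length[j + 1L], origin = NA_character_)
      len <- len + runs$length[j + 2L]
      j <- j + 2L
    }
    bouts[[length(bouts) + 1L]] <-
      list(state = "t", start = start, length = len, origin = origin)
    i <- j + 1L
  }
  bt <- dplyr::bind_rows(lapply(bouts, tibble::as_tibble))
  bt <- bt[order(bt$start), , drop = FALSE]

  n_ep <- function(s) sum(lab == s)
  mins <- function(s) n_ep(s) * epoch_s / 60
  tb <- bt[bt$state == "t", , drop = FALSE]
  dens <- function(org) {
    cnt <- sum(!is.na(tb$origin) & tb$origin == org)
    m <- mins(org)
    if (m == 0) { if (cnt > 0) NA_real_ else 0 } else cnt / m
  }
  mean_dur <- function(org) {
    v <- tb$length[!is.na(tb$origin) & tb$origin == org]
    if (!length(v)) NA_real_ else mean(v)
  }
  tst_ep <- n_ep("N") + n_ep("R") + n_ep("t")
  rem <- bt[bt$state == "R", , drop = FALSE]
  summary <- tibble::tibble(
    n_bouts_w = sum(bt$state == "W"), n_bouts_n = sum(bt$state == "N"),
    n_bouts_r = nrow(rem), n_bouts_t = nrow(tb),
    rem_short_bouts = sum(rem$length <= rem_short),
    rem_long_bouts = sum(rem$length > rem_short),
    nrt_long_bouts = sum(tb$length >= nrt_long),
    nrt_density_from_n = dens("N"), nrt_density_from_r = dens("R"),
    nrt_pct_tst = if (tst_ep > 0) 100 * n_ep("t") / tst_ep else NA_real_,
    nrt_mean_dur_from_n_epochs = mean_dur("N"),
    nrt_mean_dur_from_r_epochs = mean_dur("R"),
    nrt_mean_dur_from_n_s = mean_dur("N") * epoch_s,
    nrt_mean_dur_from_r_s = mean_dur("R") * epoch_s,
    epochs_w = n_ep("W"), epochs_n = n_ep("N"),
    epochs_r = n_ep("R"), epochs_t = n_ep("t")
  )
  out <- list(bouts = bt, summary = summary, epoch_s = epoch_s,
              arousal_merge = arousal_merge)
  class(out) <- "bout_table"
  out
}

#' @export
print.bout_table <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Bout table: %d W / %d N / %d R / %d t bouts\n",
              s$n_bouts_w, s$n_bouts_n, s$n_bouts_r, s$n_bouts_t))
  cat(sprintf("  NRt density from N: %s bouts/min; from R: %s bouts/min; NRt %% TST: %s\n",
              format(s$nrt_density_from_n, digits = 3),
              format(s$nrt_density_from_r, digits = 3),
              format(s$nrt_pct_tst, digits = 3)))
  invisible(x)
}

#' @export
tidy.bout_table <- function(x, ...) x$bouts

#' @export
glance.bout_table <- function(x, ...) x$summary
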