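# Spectral preprocessing: epoch band powers and the 2-D state-space trajectory.
#
# The EEG is analysed in consecutive 5-s epochs. Each epoch is Fourier
# transformed (single rectangular-window periodogram) and power is summed in
# sixteen contiguous 2-Hz bands spanning 1-33 Hz. The state-space embedding
# per epoch is
#   x = log10( power(7-9 Hz) / power(1-9 Hz) )   (theta ratio, always <= 0)
#   y = log10( power(1-19 Hz) )                  (log total low-band power)
# both smoothed with a centred 5-epoch moving average.

#' Definition of the sixteen 2-Hz analysis bands
#'
#' @return A tibble with columns `band` (column name, e.g. `"band_7_9"`),
#'   `lo`, `hi` (Hz, lower inclusive, upper exclusive).
#' @export
band_defs <- function() {
  lo <- seq(1, 31, by = 2)
  tibble::tibble(band = sprintf("band_%d_%d", lo, lo + 2), lo = lo, hi = lo + 2)
}

band_cols <- function() band_defs()$band

#' Compute per-epoch spectral band powers from a raw EEG trace
#'
#' Splits the signal into consecutive `epoch_s`-second epochs (a trailing
#' partial epoch is discarded), computes a rectangular-window periodogram per
#' epoch, and sums power over each 2-Hz band from 1 to 33 Hz. Epochs
#' containing non-finite samples are rejected (marked invalid, powers `NA`)
#' and listed in the `qc` attribute; all-zero epochs are flagged invalid.
#'
#' @param signal Numeric vector of EEG samples, or a 2-column data frame
#'   (time, value).
#' @param fs Sampling rate in Hz; must be at least 66 Hz (to resolve 33 Hz)
#'   and in practice >= 100 Hz.
#' @param epoch_s Epoch length in seconds (default 5).
#' @return A tibble with `epoch_index`, the sixteen `band_*` columns and a
#'   logical `valid` column. Attribute `qc` is a tibble of rejected epochs.
#' @export
compute_band_powers <- function(signal, fs, epoch_s = 5) {
  if (is.data.frame(signal)) {
    if (ncol(signal) < 2) abort("data-frame `signal` must have (time, value) columns")
    signal <- as.numeric(signal[[2]])
  }
  assert_scalar_num(fs, "fs", positive = TRUE)
  if (fs / 2 < 33) abort("sampling rate too low to resolve the 33 Hz band edge")
  n_ep <- floor(length(signal) / (fs * epoch_s))
  if (n_ep < 1) abort("signal shorter than one epoch")
  nper <- round(fs * epoch_s)
  bands <- band_defs()
  out <- matrix(NA_real_, n_ep, nrow(bands), dimnames = list(NULL, bands$band))
  valid <- logical(n_ep)
  qc <- character(0)
  freqs <- (seq_len(nper) - 1) * fs / nper
  bin_idx <- lapply(seq_len(nrow(bands)), function(b)
    which(freqs >= bands$lo[b] & freqs < bands$hi[b]))
  for (e in seq_len(n_ep)) {
    seg <- signal[((e - 1) * nper + 1):(e * nper)]
    if (any(!is.finite(seg))) {
      qc <- c(qc, sprintf("epoch %d: non-finite samples, rejected", e))
      next
    }
    pw <- Mod(fft(seg))^2 / nper
    bp <- vapply(bin_idx, function(ix) sum(pw[ix]), 0)
    out[e, ] <- bp
    if (all(bp == 0)) {
      qc <- c(qc, sprintf("epoch %d: all-zero band power, flagged invalid", e))
    } else {
      valid[e] <- TRUE
    }
  }
  res <- tibble::as_tibble(out)
  res <- dplyr::bind_cols(tibble::tibble(epoch_index = seq_len(n_ep)), res,
                          tibble::tibble(valid = valid))
  attr(res, "qc") <- qc
  attr(res, "fs") <- fs
  res
}

validate_band_powers <- function(powers) {
  miss <- setdiff(band_cols(), names(powers))
  if (length(miss)) abort(paste("missing band columns:", paste(miss, collapse = ", ")))
  bp <- as.matrix(powers[band_cols()])
  if (any(bp[is.finite(bp)] < 0)) abort("band powers must be non-negative")
  if (!"valid" %in% names(powers)) {
    powers$valid <- apply(bp, 1, function(r) all(is.finite(r)) && any(r > 0))
  }
  powers
}

#' Compute the smoothed 2-D state-space trajectory from epoch band powers
#'
#' Per epoch, `x = log10(P(7-9)/P(1-9))` and `y = log10(P(1-19))`; band sums
#' are taken before the log transform. Both coordinates are then smoothed
#' with a centred moving average of `smooth_window` epochs whose window
#' shrinks symmetrically at the recording edges. Epochs with zero 1-9 Hz
#' power (or flagged invalid upstream) get `NA` coordinates and
#' `valid = FALSE`; they are never interpolated.
#'
#' @param powers Tibble from [compute_band_powers()] (or the same layout).
#' @param smooth_window Width of the centred moving average, in epochs
#'   (odd; default 5).
#' @param relative Logical; if `TRUE`, band powers are first normalised to
#'   each epoch's total 1-33 Hz power. Ratios are unaffected; only `y`
#'   changes meaning. Default `FALSE` (absolute power).
#' @return A tibble with `epoch_index`, `x`, `y`, `valid`, plus unsmoothed
#'   `x_raw`, `y_raw` columns.
#' @export
compute_trajectory <- function(powers, smooth_window = 5, relative = FALSE) {
  powers <- validate_band_powers(powers)
  if (sum(powers$valid) < smooth_window)
    abort("need at least `smooth_window` valid epochs")
  bp <- as.matrix(powers[band_cols()])
  if (relative) {
    tot <- rowSums(bp)
    bp <- bp / ifelse(tot > 0, tot, NA_real_)
  }
  defs <- band_defs()
  ix_79  <- which(defs$lo >= 7 & defs$hi <= 9)
  ix_19a <- which(defs$lo >= 1 & defs$hi <= 9)    # 1-9 Hz
  ix_119 <- which(defs$lo >= 1 & defs$hi <= 19)   # 1-19 Hz
  p79  <- rowSums(bp[, ix_79, drop = FALSE])
  p19a <- rowSums(bp[, ix_19a, drop = FALSE])
  p119 <- rowSums(bp[, ix_119, drop = FALSE])
  valid <- powers$valid & is.finite(p19a) & p19a > 0 & is.finite(p119) & p119 > 0
  x_raw <- ifelse(valid, log10(p79 / p19a), NA_real_)
  y_raw <- ifelse(valid, log10(p119), NA_real_)
  x_raw[valid & p79 == 0] <- NA_real_   # log10(0): flag rather than -Inf
  valid <- valid & is.finite(x_raw)
  x_raw[!valid] <- NA_real_
  tibble::tibble(
    epoch_index = powers$epoch_index,
    x = moving_average(x_raw, smooth_window),
    y = moving_average(y_raw, smooth_window),
    x_raw = x_raw, y_raw = y_raw,
    valid = valid
  )
}
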