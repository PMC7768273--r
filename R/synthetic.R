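# Labelled synthetic recordings with the statistical structure the NRt
# analysis assumes: three state-space clusters (wake off the N-R axis),
# bounded random walks within clusters (so trajectories reverse and
# self-intersect), a directed transition corridor between the NREM and REM
# clusters, geometric dwell times, and a "drug" condition that raises the
# rate and duration of NRt bouts originating in REM sleep. Emission is at
# the state-space / band-power level: the coordinate pair is inverted to a
# 16-band power vector, which is what the analysis pipeline consumes.

#' Configuration for the synthetic-recording generator
#'
#' Defaults describe a rat-like recording in 5-s epochs: NREM bouts of
#' about 5 min, REM bouts of about 2 min, wake bouts of about 2 min, brief
#' arousals, complete NREM-to-REM transitions lasting about 10 epochs, and
#' rare failed excursions from REM. Cluster means are in state-space
#' coordinates (x = log10 theta ratio, y = log10 total 1-19 Hz power).
#'
#' @param n_mean,r_mean,w_mean Cluster means `c(x, y)`.
#' @param walk_phi,walk_sd Within-cluster AR(1) walk: autocorrelation and
#'   per-epoch innovation SD.
#' @param walk_phi_r,walk_sd_r REM-cluster walk parameters; REM EEG is the
#'   more labile state (phasic theta fluctuation), so its cluster is given
#'   a faster, wider walk by default.
#' @param obs_sd Independent per-epoch observation noise on both
#'   coordinates, emulating the spectral-estimation variance of single
#'   5-s periodograms; this is what makes trajectories jiggle and
#'   self-intersect within state clusters.
#' @param corridor_margin Fraction of the N-to-R axis covered by the
#'   cluster ends of the corridor (transitions start/end at this fraction).
#' @param corridor_jitter Lateral SD of per-epoch corridor jitter.
#' @param trans_bow Maximum lateral bow of a complete transition's path, as
#'   a fraction of the cluster separation (paths arc to one side rather
#'   than following the axis exactly).
#' @param exc_bow Range of lateral loop amplitudes for failed excursions
#'   (out and back on opposite sides, so the trajectory loops rather than
#'   retracing itself -- transitionary trajectories are directed and avoid
#'   self-intersection).
#' @param corridor_spread Lateral SD of the per-traversal entry/exit
#'   offset: different traversals depart from and arrive at different
#'   points on the cluster edges facing the corridor.
#' @param dwell_w,dwell_n,dwell_r Mean dwell times in epochs (geometric).
#' @param dwell_min_w,dwell_min_n,dwell_min_r Minimum dwell times in
#'   epochs; NREM consolidates for at least a minute before a REM
#'   transition can occur.
#' @param arousal_hazard Per-sleep-epoch probability of a brief arousal.
#' @param arousal_mean Mean arousal length in epochs (1-3 typical).
#' @param trans_len_mean,trans_len_min,trans_len_max Complete-transition
#'   duration (epochs; truncated geometric).
#' @param exc_len_mean,exc_len_min,exc_len_max Failed-excursion duration
#'   (epochs; truncated geometric).
#' @param p_n_to_r Probability that an ending NREM bout transitions to REM
#'   (rather than wake).
#' @param exc_hazard_n,exc_hazard_r Per-epoch hazard of a failed excursion
#'   from NREM / from REM.
#' @param exc_depth Range of corridor fractions reached by failed
#'   excursions.
#' @param drug Named list of condition multipliers:
#'   `r_exc_mult` (REM-origin excursion rate), `dur_mult` (NRt bout
#'   duration), `wake_mult` (propensity of leaving sleep to wake).
#' @return List of class `synth_config`.
#' @export
synth_config <- function(n_mean = c(-0.55, 3.0), r_mean = c(-0.12, 2.2),
                         w_mean = c(-0.62, 2.55),
                         walk_phi = 0.5, walk_sd = 0.04,
                         walk_phi_r = 0.3, walk_sd_r = 0.06,
                         obs_sd = 0.025,
                         corridor_margin = 0.25, corridor_jitter = 0.004,
                         trans_bow = 0.015, exc_bow = c(0.006, 0.012),
                         corridor_spread = 0.008,
                         dwell_w = 18, dwell_n = 45, dwell_r = 30,
                         dwell_min_w = 2, dwell_min_n = 12, dwell_min_r = 6,
                         arousal_hazard = 1 / 200, arousal_mean = 2,
                         trans_len_mean = 12, trans_len_min = 6,
                         trans_len_max = 18,
                         exc_len_mean = 6, exc_len_min = 4,
                         exc_len_max = 10,
                         p_n_to_r = 0.7,
                         exc_hazard_n = 1 / 500, exc_hazard_r = 1 / 2000,
                         exc_depth = c(0.38, 0.6),
                         drug = list(r_exc_mult = 6, dur_mult = 2,
                                     wake_mult = 0.7)) {
  cfg <- as.list(environment())
  # clusters must be visibly disjoint: >= 6 pooled stationary SDs apart
  stat_sd <- walk_sd / sqrt(1 - walk_phi^2)
  sep <- sqrt(sum((cfg$n_mean - cfg$r_mean)^2))
  if (sep < 6 * stat_sd)
    abort("N and R cluster means closer than 6 pooled walk SDs")
  # the corridor must not enter the 2-SD core of either cluster
  if (corridor_margin * sep < 2 * stat_sd)
    abort("corridor margin intrudes into a cluster core; increase corridor_margin")
  class(cfg) <- "synth_config"
  cfg
}

rgeom1 <- function(mean_len, min_len = 1L) {
  min_len + stats::rgeom(1, 1 / max(mean_len - min_len + 1, 1.0001))
}

#' Generate a labelled synthetic recording
#'
#' Simulates the epoch state sequence from the configured dwell and hazard
#' structure, emits state-space coordinates (cluster walks and corridor
#' traversals), and inverts them to 16-band power vectors. Ground-truth
#' 4-stage labels mark every corridor epoch (complete transitions and
#' failed excursions) as `t`; the 3-stage hypnogram labels those epochs as
#' the manual scorer would (NREM for transitions and NREM-origin
#' excursions, REM for REM-origin excursions).
#'
#' @param cfg `synth_config`.
#' @param n_epochs Number of 5-s epochs (>= 200).
#' @param seed RNG seed; the recording is reproducible from it.
#' @param condition `"baseline"` or `"drug"` (applies the drug multipliers).
#' @return Object of class `synth_recording`: list with `band_powers`
#'   (pipeline input), `trajectory` (ground-truth raw coordinates),
#'   `hypnogram3`, `hypnogram4` (ground truth), and `condition`.
#' @export
generate_recording <- function(cfg, n_epochs, seed, condition = c("baseline", "drug")) {
  stopifnot(inherits(cfg, "synth_config"))
  condition <- match.arg(condition)
  if (n_epochs < 200) abort("n_epochs must be at least 200")
  set.seed(seed)
  drug <- condition == "drug"
  exc_hazard_r <- cfg$exc_hazard_r * if (drug) cfg$drug$r_exc_mult else 1
  dur_mult <- if (drug) cfg$drug$dur_mult else 1
  wake_mult <- if (drug) cfg$drug$wake_mult else 1

  axis <- cfg$r_mean - cfg$n_mean
  sep <- sqrt(sum(axis^2))
  perp <- c(-axis[2], axis[1]) / sep

  lab3 <- character(n_epochs); lab4 <- character(n_epochs)
  xy <- matrix(NA_real_, n_epochs, 2)
  state <- "W"                      # macro state: W / N / R
  dev <- c(0, 0)                    # AR(1) deviation from the cluster mean
  dwell_left <- rgeom1(cfg$dwell_w, cfg$dwell_min_w)
  i <- 1L
  emit_cluster <- function(mean_xy, rem = FALSE) {
    phi <- if (rem) cfg$walk_phi_r else cfg$walk_phi
    s <- if (rem) cfg$walk_sd_r else cfg$walk_sd
    dev <<- phi * dev + rnorm(2, 0, s)
    mean_xy + dev
  }
  emit_corridor_run <- function(fracs, lateral, l3, entry_dev = c(0, 0)) {
    # writes a corridor traversal starting at epoch i; the walk's current
    # deviation decays over the first epochs so the trajectory is
    # continuous at corridor entry
    L <- min(length(fracs), n_epochs - i + 1L)
    for (k in seq_len(L)) {
      carry <- entry_dev * max(0, 1 - (k - 1) / 4)
      p <- cfg$n_mean + fracs[k] * axis +
        (lateral[k] + rnorm(1, 0, cfg$corridor_jitter)) * perp + carry
      xy[i, ] <<- p; lab3[i] <<- l3; lab4[i] <<- "t"; i <<- i + 1L
    }
    L
  }
  while (i <= n_epochs) {
    if (state == "W") {
      xy[i, ] <- emit_cluster(cfg$w_mean)
      lab3[i] <- "W"; lab4[i] <- "W"
      dwell_left <- dwell_left - 1L; i <- i + 1L
      if (dwell_left <= 0) { state <- "N"; dev <- c(0, 0); dwell_left <- rgeom1(cfg$dwell_n, cfg$dwell_min_n) }
      next
    }
    m <- if (state == "N") cfg$n_mean else cfg$r_mean
    # brief arousal?
    if (runif(1) < cfg$arousal_hazard) {
      alen <- min(rgeom1(cfg$arousal_mean), 3L)
      sdev <- dev
      for (k in seq_len(min(alen, n_epochs - i + 1L))) {
        xy[i, ] <- emit_cluster(cfg$w_mean)
        lab3[i] <- "W"; lab4[i] <- "W"; i <- i + 1L
      }
      dev <- sdev
      next
    }
    # failed excursion?
    hz <- if (state == "N") cfg$exc_hazard_n else exc_hazard_r
    if (runif(1) < hz) {
      L <- min(rgeom1(cfg$exc_len_mean * dur_mult, cfg$exc_len_min),
               ceiling(cfg$exc_len_max * dur_mult))
      depth <- runif(1, cfg$exc_depth[1], cfg$exc_depth[2])
      f0 <- if (state == "N") cfg$corridor_margin else 1 - cfg$corridor_margin
      f1 <- if (state == "N") depth else 1 - depth
      half <- ceiling(L / 2)
      fr <- c(seq(f0, f1, length.out = half),
              rev(seq(f0, f1, length.out = L - half + 1L))[-1])
      # loop: enter on one side of the axis, return on the other, so the
      # loop closes inside the cluster rather than at the corridor mouth
      amp <- sample(c(-1, 1), 1) * runif(1, cfg$exc_bow[1], cfg$exc_bow[2]) * sep
      off <- rnorm(1, 0, cfg$corridor_spread) * sep
      lat <- off + amp * cos(pi * seq_along(fr) / (length(fr) + 1L))
      emit_corridor_run(fr, lat, l3 = state, entry_dev = dev)
      # the walk resumes from the corridor exit point (continuity)
      if (i > 1L) dev <- xy[i - 1L, ] - m
      next
    }
    # end of bout?
    dwell_left <- dwell_left - 1L
    xy[i, ] <- emit_cluster(m, rem = state == "R")
    lab3[i] <- state; lab4[i] <- state; i <- i + 1L
    if (dwell_left <= 0) {
      if (state == "N") {
        if (runif(1) < cfg$p_n_to_r / (cfg$p_n_to_r + (1 - cfg$p_n_to_r) * wake_mult)) {
          L <- min(rgeom1(cfg$trans_len_mean * dur_mult, cfg$trans_len_min),
                   ceiling(cfg$trans_len_max * dur_mult))
          fr <- seq(cfg$corridor_margin, 1 - cfg$corridor_margin, length.out = L)
          amp <- runif(1, -cfg$trans_bow, cfg$trans_bow) * sep
          u <- seq_along(fr) / (length(fr) + 1L)
          off <- rnorm(2, 0, cfg$corridor_spread) * sep
          lat <- off[1] * (1 - u) + off[2] * u + amp * sin(pi * u)
          emit_corridor_run(fr, lat, l3 = "N", entry_dev = dev)
          state <- "R"
          dev <- if (i > 1L) xy[i - 1L, ] - cfg$r_mean else c(0, 0)
          dwell_left <- rgeom1(cfg$dwell_r, cfg$dwell_min_r)
        } else {
          state <- "W"; dev <- c(0, 0); dwell_left <- rgeom1(cfg$dwell_w, cfg$dwell_min_w)
        }
      } else {
        state <- "W"; dev <- c(0, 0); dwell_left <- rgeom1(cfg$dwell_w, cfg$dwell_min_w)
      }
    }
  }

  # independent spectral-estimation noise per epoch, on top of the
  # state-dependent slow components
  xy <- xy + matrix(rnorm(2 * n_epochs, 0, cfg$obs_sd), n_epochs, 2)
  # the theta ratio is a subset-band ratio, so x < 0 always; clamp walk
  # overshoots just below zero before inverting to band powers
  xy[, 1] <- pmin(xy[, 1], -0.005)
  powers <- coords_to_band_powers(xy[, 1], xy[, 2])
  powers$epoch_index <- seq_len(n_epochs)
  powers$valid <- TRUE
  powers <- powers[c("epoch_index", band_cols(), "valid")]
  out <- list(
    band_powers = powers,
    trajectory = tibble::tibble(epoch_index = seq_len(n_epochs),
                                x = xy[, 1], y = xy[, 2], valid = TRUE),
    hypnogram3 = tibble::tibble(epoch_index = seq_len(n_epochs), label = lab3),
    hypnogram4 = tibble::tibble(epoch_index = seq_len(n_epochs), label = lab4),
    condition = condition, cfg = cfg, seed = seed
  )
  class(out) <- "synth_recording"
  out
}

#' @export
print.synth_recording <- function(x, ...) {
  tab <- table(x$hypnogram4$label)
  cat(sprintf("Synthetic recording (%s, seed %d): %d epochs\n",
              x$condition, x$seed, nrow(x$band_powers)))
  cat("  ground-truth epochs:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

# invert a state-space coordinate pair to a 16-band power vector:
# y fixes total 1-19 Hz power, x the 7-9 / 1-9 ratio; the remaining degrees
# of freedom get lognormal noise.
coords_to_band_powers <- function(x, y) {
  n <- length(x)
  p119 <- 10^y
  share <- 0.75                       # fraction of 1-19 Hz power below 9 Hz
  p19a <- share * p119
  p79 <- 10^x * p19a
  rest_low <- p19a - p79              # bands 1-3, 3-5, 5-7
  w_low <- matrix(stats::rlnorm(3 * n, 0, 0.3), n, 3)
  w_low <- w_low / rowSums(w_low)
  high <- p119 - p19a                 # bands 9-11 .. 17-19
  w_high <- matrix(stats::rlnorm(5 * n, 0, 0.3), n, 5)
  w_high <- w_high / rowSums(w_high)
  topw <- matrix(stats::rlnorm(7 * n, 0, 0.3), n, 7)
  topw <- topw / rowSums(topw)
  top <- 0.05 * p119                  # bands 19-21 .. 31-33
  m <- cbind(w_low * rest_low, p79, w_high * high, topw * top)
  colnames(m) <- band_cols()
  tibble::as_tibble(m)
}

#' Synthesize a raw EEG trace matching target epoch band powers
#'
#' Per epoch, builds the discrete Fourier spectrum directly: target band
#' power is split evenly over the frequency bins of each 2-Hz band, phases
#' are random, and the conjugate-symmetric spectrum is inverted to a real
#' signal. Recomputing band powers from the result recovers the targets to
#' numerical precision (out-of-band bins are zero).
#'
#' @param powers Band-power tibble (layout of [compute_band_powers()]).
#' @param fs Sampling rate in Hz (>= 100).
#' @param seed RNG seed for the phases.
#' @param epoch_s Epoch length in seconds (default 5).
#' @return Numeric vector of `fs * epoch_s * nrow(powers)` samples.
#' @export
generate_raw_eeg <- function(powers, fs, seed = 1, epoch_s = 5) {
  if (fs < 100) abort("fs must be at least 100 Hz")
  set.seed(seed)
  powers <- validate_band_powers(powers)
  bp <- as.matrix(powers[band_cols()])
  n <- round(fs * epoch_s)
  freqs <- (seq_len(n) - 1) * fs / n
  defs <- band_defs()
  bin_idx <- lapply(seq_len(nrow(defs)), function(b)
    which(freqs >= defs$lo[b] & freqs < defs$hi[b] & seq_len(n) <= n / 2))
  out <- numeric(n * nrow(bp))
  for (e in seq_len(nrow(bp))) {
    X <- complex(length.out = n)
    for (b in seq_along(bin_idx)) {
      ix <- bin_idx[[b]]
      if (!length(ix) || !is.finite(bp[e, b]) || bp[e, b] <= 0) next
      amp <- sqrt(bp[e, b] * n / length(ix))
      ph <- runif(length(ix), 0, 2 * pi)
      X[ix] <- amp * exp(1i * ph)
      X[n - ix + 2] <- Conj(X[ix])     # Hermitian partner (ix >= 2 always)
    }
    out[((e - 1) * n + 1):(e * n)] <- Re(fft(X, inverse = TRUE)) / n
  }
  out
}
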