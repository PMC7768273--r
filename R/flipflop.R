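# Leaky integrate-and-fire flip-flop switch: two mutually inhibitory pools
# of 25 tonically active neurons plus a 10-neuron input pool carrying a
# linearly ramping REM-state drive. Nondimensional units: spike threshold 1,
# resting potential 0, time rescaled by the membrane time constant.
#
#   dv_i/dt = -v_i + I_applied + sum_j W_ji s_j(t)
#
# with an alpha synapse: each presynaptic spike at t_n contributes
# alpha^2 (t - t_n) exp(-alpha (t - t_n)) to s_j. Integration is
# fixed-step Euler; the alpha kernel is integrated exactly as the
# two-variable linear filter z' = -alpha z (+ alpha^2 at spikes),
# s' = z - alpha s.

#' Pool index layout of the flip-flop network
#' @keywords internal
pool_index <- function(n_input = 10, n_r = 25, n_n = 25) {
  list(input = seq_len(n_input),
       R = n_input + seq_len(n_r),
       N = n_input + n_r + seq_len(n_n),
       n = n_input + n_r + n_n)
}

#' Build a randomized flip-flop network
#'
#' Cross-pool inhibitory connections are drawn independently with
#' probability `p_connect`; weights are uniform on `[0, 1]` divided by the
#' pool-specific divisor `d` (so N-to-R magnitudes lie in `[0, 1/d_n_to_r]`,
#' 0.48 at the default 2.1) and negated. Within-pool weights are exactly
#' zero (no auto-inhibition). Input-pool connections to the ramp target pool
#' have probability 1 and constant magnitude `input_weight`: excitatory onto
#' the R pool (`scenario = "ramp_r"`) or inhibitory onto the N pool
#' (`scenario = "ramp_n"`).
#'
#' @param seed RNG seed; the network is reproducible from it.
#' @param d_n_to_r,d_r_to_n Weight divisors for the two inhibitory
#'   projections (defaults 2.1 and 2.5, the selected operating point).
#' @param p_connect Cross-pool connection probability (default 0.5).
#' @param input_weight Magnitude of input-pool connection weights
#'   (default 0.025).
#' @param scenario `"ramp_r"` (excite R pool) or `"ramp_n"` (inhibit N
#'   pool).
#' @param n_input,n_r,n_n Pool sizes (defaults 10, 25, 25).
#' @return Object of class `flipflop_network`: list with the weight matrix
#'   `W` (`W[j, i]` = weight from neuron j to neuron i), pool indices, and
#'   the build parameters.
#' @export
flipflop_network <- function(seed, d_n_to_r = 2.1, d_r_to_n = 2.5,
                             p_connect = 0.5, input_weight = 0.025,
                             scenario = c("ramp_r", "ramp_n"),
                             n_input = 10, n_r = 25, n_n = 25) {
  scenario <- match.arg(scenario)
  for (nm in c("d_n_to_r", "d_r_to_n", "input_weight"))
    assert_scalar_num(get(nm), nm, positive = TRUE)
  if (n_input < 1 || n_r < 1 || n_n < 1) abort("pool sizes must be positive")
  if (p_connect < 0 || p_connect > 1) abort("`p_connect` must be in [0, 1]")
  set.seed(seed)
  pools <- pool_index(n_input, n_r, n_n)
  W <- matrix(0, pools$n, pools$n)
  mask_nr <- matrix(runif(n_n * n_r) < p_connect, n_n, n_r)
  W[pools$N, pools$R] <- -mask_nr * matrix(runif(n_n * n_r), n_n, n_r) / d_n_to_r
  mask_rn <- matrix(runif(n_r * n_n) < p_connect, n_r, n_n)
  W[pools$R, pools$N] <- -mask_rn * matrix(runif(n_r * n_n), n_r, n_n) / d_r_to_n
  if (scenario == "ramp_r") W[pools$input, pools$R] <- input_weight
  else W[pools$input, pools$N] <- -input_weight
  out <- list(W = W, pools = pools, seed = seed,
              params = list(d_n_to_r = d_n_to_r, d_r_to_n = d_r_to_n,
                            p_connect = p_connect, input_weight = input_weight,
                            scenario = scenario))
  class(out) <- "flipflop_network"
  out
}

#' @export
print.flipflop_network <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "Flip-flop network: %d input / %d R / %d N neurons (%s)\n",
    length(x$pools$input), length(x$pools$R), length(x$pools$N), p$scenario))
  cat(sprintf("  weight divisors d(N->R) = %.2f, d(R->N) = %.2f; p_connect = %.2f\n",
              p$d_n_to_r, p$d_r_to_n, p$p_connect))
  invisible(x)
}

#' Ramp specification for the REM-state drive
#'
#' The drive is held at zero for `hold` iterations and then increases
#' linearly at `rate` per iteration for the rest of the simulation.
#'
#' @param hold Iterations at zero drive (default 2000).
#' @param rate Drive increment per iteration (default 0.06).
#' @param total Total iterations (default 8000).
#' @return A list of class `ramp_spec`.
#' @export
ramp_spec <- function(hold = 2000, rate = 0.06, total = 8000) {
  structure(list(hold = hold, rate = rate, total = total), class = "ramp_spec")
}

#' Simulate a flip-flop network
#'
#' Fixed-step Euler integration of the LIF membrane equation with alpha
#' synapses. Each neuron receives its pool's bias current plus a white-noise
#' current of amplitude `noise_amp` (added per step as
#' `noise_amp * sqrt(dt) * N(0, 1)`); input-pool neurons additionally
#' receive the ramp current. Spikes occur at threshold 1 with reset to 0.
#' N-pool membrane voltages start uniformly spread below threshold so every
#' run begins in an N state. Pool spike rates are averaged every
#' `epoch_iters` iterations and smoothed with a centred `smooth_epochs`
#' moving average before taking the R-minus-N difference.
#'
#' @param net `flipflop_network`.
#' @param seed Seed for the simulation noise (independent of the network
#'   seed).
#' @param ramp `ramp_spec`, or `NULL` for no ramping drive (tuning runs).
#' @param noise_amp Noise-current amplitude (default 1.5).
#' @param bias Named vector of bias currents `c(input =, r =, n =)`
#'   (defaults 0, 2, 2).
#' @param bias_delta Named vector `c(r =, n =)` of condition-specific bias
#'   changes (inhibition experiments; defaults 0).
#' @param dt Euler step, nondimensional time per iteration (default 0.01).
#' @param alpha Synapse speed constant (default 2).
#' @param tau_ref Absolute refractory period in nondimensional time
#'   (default 0.25); the membrane is held at rest after each spike, capping
#'   single-neuron firing rates at `1 / tau_ref`. Set to 0 for the
#'   textbook LIF whose interspike interval is `log(I / (I - 1))`.
#' @param n_iter Total iterations (default from `ramp`, or 8000).
#' @param epoch_iters Iterations per output epoch (default 20).
#' @param smooth_epochs Rate-smoothing window in epochs (default 3).
#' @param keep_spikes Return the full spike raster (default TRUE).
#' @return Object of class `flipflop_sim`: list with `rates` (tibble
#'   `epoch`, `rate_r`, `rate_n`, `rate_diff`), `spikes` (tibble `neuron`,
#'   `time`), and the simulation parameters.
#' @export
simulate_flipflop <- function(net, seed, ramp = ramp_spec(), noise_amp = 1.5,
                              bias = c(input = 0, r = 2, n = 2),
                              bias_delta = c(r = 0, n = 0),
                              dt = 0.01, alpha = 2, tau_ref = 0.25,
                              n_iter = NULL,
                              epoch_iters = 20, smooth_epochs = 3,
                              keep_spikes = TRUE) {
  stopifnot(inherits(net, "flipflop_network"))
  n_iter <- n_iter %||% (if (!is.null(ramp)) ramp$total else 8000L)
  pools <- net$pools
  n <- pools$n
  b <- numeric(n)
  b[pools$input] <- bias[["input"]]
  b[pools$R] <- bias[["r"]] + bias_delta[["r"]]
  b[pools$N] <- bias[["n"]] + bias_delta[["n"]]
  ramp_i <- numeric(n_iter)
  if (!is.null(ramp) && ramp$total > ramp$hold) {
    k <- (ramp$hold + 1L):n_iter
    ramp_i[k] <- ramp$rate * (k - ramp$hold)
  }
  set.seed(seed)
  v <- numeric(n)
  v[pools$N] <- runif(length(pools$N), 0, 0.95)  # start in an N state
  z <- numeric(n); s <- numeric(n)
  n_epochs <- n_iter %/% epoch_iters
  counts <- matrix(0L, n_epochs, n)
  spk_n <- integer(0); spk_t <- numeric(0)
  Wt <- t(net$W)
  sqdt <- sqrt(dt)
  inp <- pools$input
  alpha2 <- alpha^2
  ref_iters <- max(0L, as.integer(round(tau_ref / dt)))
  ref_left <- integer(n)
  for (it in seq_len(n_iter)) {
    I <- b + as.numeric(Wt %*% s)
    I[inp] <- I[inp] + ramp_i[it]
    v <- v + dt * (I - v) + noise_amp * sqdt * rnorm(n)
    if (any(!is.finite(v)))
      abort(sprintf("non-finite membrane potential at iteration %d", it))
    if (ref_iters > 0L && any(ref_left > 0L)) {
      refr <- ref_left > 0L
      v[refr] <- 0
      ref_left[refr] <- ref_left[refr] - 1L
    }
    spk <- v >= 1
    if (any(spk)) {
      v[spk] <- 0
      if (ref_iters > 0L) ref_left[spk] <- ref_iters
      ep <- (it - 1L) %/% epoch_iters + 1L
      if (ep <= n_epochs) counts[ep, spk] <- counts[ep, spk] + 1L
      if (keep_spikes) {
        w <- which(spk)
        spk_n <- c(spk_n, w); spk_t <- c(spk_t, rep(it * dt, length(w)))
      }
    }
    z <- z * (1 - alpha * dt)
    if (any(spk)) z[spk] <- z[spk] + alpha2
    s <- s + dt * (z - alpha * s)
  }
  rate_r <- rowMeans(counts[, pools$R, drop = FALSE])
  rate_n <- rowMeans(counts[, pools$N, drop = FALSE])
  diff <- moving_average(rate_r, smooth_epochs) -
    moving_average(rate_n, smooth_epochs)
  out <- list(
    rates = tibble::tibble(epoch = seq_len(n_epochs), rate_r = rate_r,
                           rate_n = rate_n, rate_diff = diff),
    spikes = if (keep_spikes) tibble::tibble(neuron = spk_n, time = spk_t) else NULL,
    params = list(seed = seed, noise_amp = noise_amp, bias = bias,
                  bias_delta = bias_delta, dt = dt, alpha = alpha,
                  tau_ref = tau_ref,
                  n_iter = n_iter, epoch_iters = epoch_iters,
                  smooth_epochs = smooth_epochs,
                  ramp = if (is.null(ramp)) NULL else unclass(ramp)),
    network = net$params
  )
  class(out) <- "flipflop_sim"
  out
}

#' @export
print.flipflop_sim <- function(x, ...) {
  cat(sprintf("Flip-flop simulation: %d iterations -> %d epochs\n",
              x$params$n_iter, nrow(x$rates)))
  cat(sprintf("  rate difference (R - N): median %.3f, range [%.3f, %.3f]\n",
              stats::median(x$rates$rate_diff), min(x$rates$rate_diff),
              max(x$rates$rate_diff)))
  invisible(x)
}

#' Score a simulated rate difference into N / NRt / R states
#'
#' Epochs below `thr_n` are N, above `thr_r` are R, and NRt in between. A
#' state change is only accepted once the new state persists for at least
#' `persistence` consecutive epochs; shorter runs are absorbed into the
#' current state.
#'
#' @param x `flipflop_sim` object or numeric rate-difference vector.
#' @param thr_n,thr_r Scoring thresholds (`thr_n < thr_r`).
#' @param persistence Minimum run length accepted as a state change
#'   (default 2).
#' @return Character vector of per-epoch states in `{"N", "NRt", "R"}`.
#' @export
score_switch <- function(x, thr_n, thr_r, persistence = 2) {
  diff <- if (inherits(x, "flipflop_sim")) x$rates$rate_diff else as.numeric(x)
  if (!(thr_n < thr_r)) abort("`thr_n` must be below `thr_r`")
  raw <- ifelse(diff < thr_n, "N", ifelse(diff > thr_r, "R", "NRt"))
  n <- length(raw)
  out <- character(n)
  cur <- raw[1]
  # accept the initial state only once it persists; until then stay with the
  # first epoch's class
  for (t in seq_len(n)) {
    if (raw[t] != cur) {
      run_end <- t
      while (run_end < n && raw[run_end + 1L] == raw[t]) run_end <- run_end + 1L
      if (run_end - t + 1L >= persistence) cur <- raw[t]
    }
    out[t] <- cur
  }
  out
}

#' Derive N and R scoring thresholds from pooled baseline rate differences
#'
#' Locates the two dominant modes and the intervening trough of the pooled
#' rate-difference distribution (kernel density estimate). The N threshold
#' is the midpoint of the trough and the left (N) mode, the R threshold the
#' midpoint of the trough and the right (R) mode.
#'
#' @param diffs Numeric vector of pooled baseline rate differences.
#' @param min_peak_frac A local maximum counts as a mode if its density
#'   exceeds this fraction of the global maximum (default 0.04).
#' @param prominence A mode pair is accepted when both peaks stand at
#'   least this factor above the intervening trough (default 2); this
#'   rejects the shallow wiggles a kernel estimate shows on unimodal data.
#' @param bw Optional kernel bandwidth passed to [stats::density()]. By
#'   default the standard bandwidth is tried first and then halved twice,
#'   since the minority (REM) mode can be narrow relative to the dominant
#'   one.
#' @return List with `thr_n`, `thr_r`, `mode_n`, `mode_r`, `trough`.
#' @export
derive_thresholds <- function(diffs, min_peak_frac = 0.04, prominence = 2,
                              bw = NULL) {
  diffs <- diffs[is.finite(diffs)]
  if (length(diffs) < 50) abort("need at least 50 rate-difference samples")
  bw0 <- if (is.null(bw)) stats::bw.nrd0(diffs) else bw
  bws <- if (is.null(bw)) bw0 * c(1, 0.5, 0.25) else bw
  for (b in bws) {
    d <- density(diffs, bw = b, n = 1024)
    y <- d$y; x <- d$x
    loc_max <- which(diff(sign(diff(y))) == -2) + 1L
    loc_max <- loc_max[y[loc_max] >= min_peak_frac * max(y)]
    if (length(loc_max) < 2) next
    # best pair: global mode plus the most prominent remaining mode
    main <- loc_max[which.max(y[loc_max])]
    best <- NULL
    for (m in setdiff(loc_max, main)) {
      # genuine state modes are well separated; skip satellite wiggles
      if (abs(x[m] - x[main]) < sd(diffs)) next
      rng <- sort(c(main, m))
      trough_i <- rng[1] + which.min(y[rng[1]:rng[2]]) - 1L
      if (min(y[main], y[m]) >= prominence * y[trough_i]) {
        if (is.null(best) || y[m] > y[best$m]) best <- list(m = m, trough_i = trough_i)
      }
    }
    if (is.null(best)) next
    top <- sort(c(main, best$m))
    trough_i <- best$trough_i
    mode_n <- x[top[1]]; mode_r <- x[top[2]]; trough <- x[trough_i]
    return(list(thr_n = (trough + mode_n) / 2, thr_r = (trough + mode_r) / 2,
                mode_n = mode_n, mode_r = mode_r, trough = trough, bw = b))
  }
  abort("switch not bistable at these parameters: rate-difference distribution is unimodal")
}
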