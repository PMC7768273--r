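# Parameter-tuning sweeps and the pool-inhibition experiment grid for the
# flip-flop switch, with the per-run switching metrics used to compare
# conditions (NRt density by origin state, latency to the R state).

#' Per-run switching metrics from a scored state sequence
#'
#' @param states Character vector of scored epoch states (`N`/`NRt`/`R`).
#' @return One-row tibble: `nrt_density_r` and `nrt_density_n` (NRt bouts
#'   per epoch of the origin state; `NA` when no time was spent in the
#'   origin state), `latency_r` (first R epoch, censored at the run length),
#'   `latency_censored`, `first_state`, bout counts and epoch totals.
#' @export
switch_metrics <- function(states) {
  runs <- run_lengths(states)
  nrt <- runs[runs$value == "NRt", , drop = FALSE]
  origin <- vapply(seq_len(nrow(nrt)), function(k) {
    i <- match(nrt$start[k], runs$start)
    if (i > 1L) runs$value[i - 1L] else NA_character_
  }, character(1))
  ep_r <- sum(states == "R"); ep_n <- sum(states == "N")
  dens <- function(cnt, ep) if (ep == 0) { if (cnt > 0) NA_real_ else 0 } else cnt / ep
  first_r <- match("R", states)
  tibble::tibble(
    nrt_density_r = dens(sum(!is.na(origin) & origin == "R"), ep_r),
    nrt_density_n = dens(sum(!is.na(origin) & origin == "N"), ep_n),
    latency_r = if (is.na(first_r)) length(states) else first_r,
    latency_censored = is.na(first_r),
    first_state = states[1],
    n_nrt_bouts = nrow(nrt), epochs_r = ep_r, epochs_n = ep_n,
    epochs_nrt = sum(states == "NRt")
  )
}

summarize_cell <- function(diffs, min_peak_frac = 0.05) {
  th <- tryCatch(derive_thresholds(diffs, min_peak_frac = min_peak_frac),
                 error = function(e) NULL)
  d <- density(diffs, n = 1024)
  at <- function(x0) d$y[which.min(abs(d$x - x0))]
  if (is.null(th)) {
    tibble::tibble(bimodal = FALSE, n_peak = max(d$y), trough = NA_real_,
                   r_peak = NA_real_, mode_n = d$x[which.max(d$y)],
                   mode_r = NA_real_)
  } else {
    tibble::tibble(bimodal = TRUE, n_peak = at(th$mode_n),
                   trough = at(th$trough), r_peak = at(th$mode_r),
                   mode_n = th$mode_n, mode_r = th$mode_r)
  }
}

#' Sweep the cross-pool synaptic weight divisors
#'
#' For each combination of the N-to-R and R-to-N weight divisors, runs
#' `reps` ramp-free simulations (connectivity resampled per repetition) and
#' summarizes the pooled R-minus-N rate-difference histogram: the N-mode,
#' trough, and R-mode density heights, and whether the distribution is
#' bimodal (a bistable, spontaneously switching configuration).
#'
#' @param d_n_to_r,d_r_to_n Divisor grids (defaults 1.8 to 2.8 by 0.1;
#'   121 cells).
#' @param reps Simulations per cell (default 25).
#' @param seed Top-level seed.
#' @param n_iter Iterations per simulation (default 8000).
#' @param execute If `FALSE`, return the enumerated run design (one row per
#'   scheduled simulation) without running anything.
#' @param ... Passed to [simulate_flipflop()].
#' @return Tibble with one row per grid cell (or per run when
#'   `execute = FALSE`).
#' @export
tune_weights <- function(d_n_to_r = seq(1.8, 2.8, by = 0.1),
                         d_r_to_n = seq(1.8, 2.8, by = 0.1),
                         reps = 25, seed = 1, n_iter = 8000,
                         execute = TRUE, ...) {
  design <- tidyr::expand_grid(d_n_to_r = d_n_to_r, d_r_to_n = d_r_to_n,
                               rep = seq_len(reps))
  design$run_id <- seq_len(nrow(design))
  if (!execute) return(design)
  cells <- dplyr::distinct(design[c("d_n_to_r", "d_r_to_n")])
  res <- purrr::pmap_dfr(cells, function(d_n_to_r, d_r_to_n) {
    diffs <- unlist(lapply(seq_len(reps), function(r) {
      s <- split_seed(seed, sprintf("tune_w_%g_%g", d_n_to_r, d_r_to_n), r)
      net <- flipflop_network(s, d_n_to_r = d_n_to_r, d_r_to_n = d_r_to_n)
      sim <- simulate_flipflop(net, split_seed(s, "sim"), ramp = NULL,
                               n_iter = n_iter, keep_spikes = FALSE, ...)
      sim$rates$rate_diff
    }))
    dplyr::bind_cols(tibble::tibble(d_n_to_r = d_n_to_r, d_r_to_n = d_r_to_n,
                                    n_runs = reps), summarize_cell(diffs))
  })
  res
}

#' Sweep the excitatory bias currents
#'
#' As [tune_weights()], with the weight divisors fixed at the operating
#' point (2.1, 2.5) and the N- and R-pool bias currents swept (defaults 1.5
#' to 2.5 by 0.1; 121 cells).
#'
#' @param bias_r,bias_n Bias-current grids.
#' @inheritParams tune_weights
#' @return Tibble with one row per grid cell (or per run when
#'   `execute = FALSE`).
#' @export
tune_bias <- function(bias_r = seq(1.5, 2.5, by = 0.1),
                      bias_n = seq(1.5, 2.5, by = 0.1),
                      reps = 25, seed = 1, n_iter = 8000,
                      execute = TRUE, ...) {
  design <- tidyr::expand_grid(bias_r = bias_r, bias_n = bias_n,
                               rep = seq_len(reps))
  design$run_id <- seq_len(nrow(design))
  if (!execute) return(design)
  cells <- dplyr::distinct(design[c("bias_r", "bias_n")])
  res <- purrr::pmap_dfr(cells, function(bias_r, bias_n) {
    diffs <- unlist(lapply(seq_len(reps), function(r) {
      s <- split_seed(seed, sprintf("tune_b_%g_%g", bias_r, bias_n), r)
      net <- flipflop_network(s)
      sim <- simulate_flipflop(net, split_seed(s, "sim"), ramp = NULL,
                               bias = c(input = 0, r = bias_r, n = bias_n),
                               n_iter = n_iter, keep_spikes = FALSE, ...)
      sim$rates$rate_diff
    }))
    dplyr::bind_cols(tibble::tibble(bias_r = bias_r, bias_n = bias_n,
                                    n_runs = reps), summarize_cell(diffs))
  })
  res
}

#' Run the pool-inhibition experiment grid
#'
#' Builds `n_networks` randomized flip-flop circuits and, for each input
#' scenario, simulates the four conditions -- baseline, R-pool inhibition,
#' N-pool inhibition, combined inhibition -- implemented as reductions of
#' the excitatory bias current (`inhib_delta`) in the inhibited pool(s).
#' Noise seeds are shared across conditions within a network and scenario
#' (paired design). Scoring thresholds are derived once per call from
#' pooled ramp-free baseline simulations. Networks whose baseline (ramped)
#' run is R-dominant from onset -- first scored epoch R -- are excluded
#' before the conditions are compared.
#'
#' @param n_networks Number of randomized connectivity matrices
#'   (default 60).
#' @param scenarios Input scenarios to run (default both).
#' @param conditions Condition subset (default all four).
#' @param seed Top-level seed.
#' @param inhib_delta Bias-current change applied to inhibited pools
#'   (default -0.5).
#' @param n_threshold_runs Ramp-free runs pooled for threshold derivation
#'   (default 12).
#' @param thresholds Optional precomputed `list(thr_n =, thr_r =)`.
#' @param net_params Named list of extra arguments for
#'   [flipflop_network()] (weight divisors, input weight, ...).
#' @param ... Passed to [simulate_flipflop()].
#' @return Object of class `flipflop_experiment`: list with `metrics` (one
#'   row per retained network x scenario x condition), `excluded` (network
#'   ids dropped per scenario), and `thresholds`.
#' @export
run_experiments <- function(n_networks = 60,
                            scenarios = c("ramp_r", "ramp_n"),
                            conditions = c("baseline", "r_inhib", "n_inhib",
                                           "both_inhib"),
                            seed = 1, inhib_delta = -0.5,
                            n_threshold_runs = 12, thresholds = NULL,
                            net_params = list(), ...) {
  deltas <- list(baseline = c(r = 0, n = 0),
                 r_inhib = c(r = inhib_delta, n = 0),
                 n_inhib = c(r = 0, n = inhib_delta),
                 both_inhib = c(r = inhib_delta, n = inhib_delta))
  net_seeds <- vapply(seq_len(n_networks), function(i)
    split_seed(seed, "net", i), integer(1))
  if (is.null(thresholds)) {
    pooled <- unlist(lapply(seq_len(min(n_threshold_runs, n_networks)),
                            function(i) {
      net <- do.call(flipflop_network,
                     c(list(net_seeds[i], scenario = "ramp_r"), net_params))
      simulate_flipflop(net, split_seed(seed, "thr", i), ramp = NULL,
                        keep_spikes = FALSE, ...)$rates$rate_diff
    }))
    th <- derive_thresholds(pooled)
    thresholds <- list(thr_n = th$thr_n, thr_r = th$thr_r)
  }
  rows <- list(); excluded <- list()
  for (sc in scenarios) {
    for (i in seq_len(n_networks)) {
      net <- do.call(flipflop_network,
                     c(list(net_seeds[i], scenario = sc), net_params))
      sim_seed <- split_seed(seed, paste0("sim_", sc), i)
      run_one <- function(cond) {
        sim <- simulate_flipflop(net, sim_seed, bias_delta = deltas[[cond]],
                                 keep_spikes = FALSE, ...)
        st <- score_switch(sim, thresholds$thr_n, thresholds$thr_r)
        dplyr::bind_cols(tibble::tibble(network = i, scenario = sc,
                                        condition = cond),
                         switch_metrics(st))
      }
      base <- run_one("baseline")
      if (base$first_state == "R") {
        excluded[[length(excluded) + 1L]] <-
          tibble::tibble(network = i, scenario = sc)
        next
      }
      rows[[length(rows) + 1L]] <- base
      for (cond in setdiff(conditions, "baseline"))
        rows[[length(rows) + 1L]] <- run_one(cond)
    }
  }
  out <- list(metrics = dplyr::bind_rows(rows),
              excluded = if (length(excluded)) dplyr::bind_rows(excluded)
                         else tibble::tibble(network = integer(),
                                             scenario = character()),
              thresholds = thresholds, seed = seed,
              inhib_delta = inhib_delta)
  class(out) <- "flipflop_experiment"
  out
}

#' @export
print.flipflop_experiment <- function(x, ...) {
  cat(sprintf(
    "Flip-flop inhibition experiments: %d runs (%d networks excluded)\n",
    nrow(x$metrics), nrow(x$excluded)))
  cat(sprintf("  thresholds: thr_n = %.3f, thr_r = %.3f\n",
              x$thresholds$thr_n, x$thresholds$thr_r))
  invisible(x)
}

#' Paired condition-vs-baseline effects from an experiment grid
#'
#' @param x `flipflop_experiment` object.
#' @param metric Metric column to compare (default `"nrt_density_r"`).
#' @return Tibble of paired per-network differences (condition minus
#'   baseline) per scenario and condition.
#' @export
experiment_effects <- function(x, metric = "nrt_density_r") {
  m <- x$metrics
  base <- m[m$condition == "baseline", c("network", "scenario", metric)]
  names(base)[3] <- "baseline"
  other <- m[m$condition != "baseline",
             c("network", "scenario", "condition", metric)]
  names(other)[4] <- "value"
  dplyr::mutate(dplyr::inner_join(other, base, by = c("network", "scenario")),
                diff = .data$value - .data$baseline, metric = metric)
}
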