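test_that("network construction is reproducible and obeys its constraints", {
  n1 <- flipflop_network(123)
  n2 <- flipflop_network(123)
  expect_identical(n1$W, n2$W)
  p <- n1$pools
  expect_true(all(n1$W[p$N, p$N] == 0))
  expect_true(all(n1$W[p$R, p$R] == 0))
  expect_true(all(n1$W[p$N, p$R] <= 0))
  expect_true(all(n1$W[p$R, p$N] <= 0))
  expect_true(all(n1$W[p$input, p$R] == n1$params$input_weight))
  expect_true(all(abs(n1$W[p$N, p$R]) <= 1 / 2.1 + 1e-12))
  expect_error(flipflop_network(1, n_r = 0), "pool sizes")
  expect_error(flipflop_network(1, p_connect = 2), "p_connect")
})

test_that("realized connection counts match the binomial expectation", {
  counts <- vapply(1:200, function(s) {
    net <- flipflop_network(s)
    sum(net$W[net$pools$N, net$pools$R] != 0)
  }, 0)
  # 625 possible connections at p = 0.5: mean 312.5, SD 12.5
  expect_lt(abs(mean(counts) - 312.5), 3 * 12.5 / sqrt(200))
})

test_that("single LIF interspike interval approaches log(I/(I-1))", {
  sim <- simulate_flipflop(single_neuron_net(), 1, ramp = NULL, noise_amp = 0,
                           bias = c(input = 0, r = 2, n = 2), tau_ref = 0,
                           dt = 0.001, n_iter = 20000)
  isi <- diff(sim$spikes$time)
  expect_lt(abs(mean(isi) - log(2)) / log(2), 0.02)
})

test_that("simulations are bit-identical from a fixed seed", {
  net <- flipflop_network(3)
  s1 <- simulate_flipflop(net, 99)
  s2 <- simulate_flipflop(net, 99)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$rates, s2$rates)
})

test_that("an 8000-iteration run binned every 20 iterations has 400 epochs", {
  net <- flipflop_network(2)
  sim <- simulate_flipflop(net, 5, keep_spikes = FALSE)
  expect_equal(nrow(sim$rates), 400L)
})

test_that("switch scoring follows the thresholds and the persistence rule", {
  expect_true(all(score_switch(rep(-1, 20), thr_n = 0, thr_r = 1) == "N"))
  # a single-epoch spike above thr_r inside an N run is absorbed
  d <- rep(-1, 20); d[10] <- 2
  expect_true(all(score_switch(d, 0, 1) == "N"))
  # alternating 3-epoch blocks: hand-enumerated reference
  d <- rep(c(-1, -1, -1, 2, 2, 2), 3)
  expect_identical(score_switch(d, 0, 1), rep(c("N", "N", "N", "R", "R", "R"), 3))
  # NRt band between the thresholds
  d <- c(-1, -1, 0.5, 0.5, 2, 2)
  expect_identical(score_switch(d, 0, 1), c("N", "N", "NRt", "NRt", "R", "R"))
  expect_error(score_switch(d, 1, 0), "thr_n")
})

test_that("thresholds are mode/trough midpoints of a bimodal distribution", {
  set.seed(10)
  m <- c(rnorm(5000, -5, 0.5), rnorm(5000, 5, 0.5))
  th <- derive_thresholds(m)
  expect_equal(th$thr_n, -2.5, tolerance = 0.15)
  expect_equal(th$thr_r, 2.5, tolerance = 0.15)
  # midpoint arithmetic holds exactly on the detected extrema
  expect_equal(th$thr_n, (th$trough + th$mode_n) / 2)
  expect_equal(th$thr_r, (th$trough + th$mode_r) / 2)
  m2 <- c(rnorm(7000, -5, 0.5), rnorm(3000, 5, 1))
  th2 <- derive_thresholds(m2)
  expect_equal(th2$mode_n, -5, tolerance = 0.3)
  expect_equal(th2$mode_r, 5, tolerance = 0.6)
})

test_that("a unimodal rate-difference distribution raises the bistability error", {
  set.seed(12)
  expect_error(derive_thresholds(rnorm(10000)), "not bistable")
})

test_that("noise-free switch is stable without ramp and flips once with it", {
  pool <- unlist(lapply(1:8, function(i) {
    net <- flipflop_network(split_seed(1, "net", i))
    simulate_flipflop(net, split_seed(1, "thr", i), ramp = NULL,
                      keep_spikes = FALSE)$rates$rate_diff
  }))
  th <- derive_thresholds(pool)
  for (sc in c("ramp_r", "ramp_n")) {
    # a drive strong enough to cross the inhibition gap deterministically
    net <- flipflop_network(1, input_weight = 0.08, scenario = sc)
    quiet <- simulate_flipflop(net, 2, ramp = NULL, noise_amp = 0,
                               keep_spikes = FALSE)
    states_q <- rle(score_switch(quiet, th$thr_n, th$thr_r))$values
    expect_identical(states_q, "N")
    driven <- simulate_flipflop(net, 2, noise_amp = 0, keep_spikes = FALSE)
    states_d <- rle(score_switch(driven, th$thr_n, th$thr_r))$values
    expect_identical(states_d, c("N", "NRt", "R"))
  }
})

test_that("with noise at the operating point, failed transitions occur", {
  pool <- unlist(lapply(1:6, function(i) {
    net <- flipflop_network(split_seed(2, "net", i))
    simulate_flipflop(net, split_seed(2, "sim", i), ramp = NULL,
                      keep_spikes = FALSE)$rates$rate_diff
  }))
  th <- derive_thresholds(pool)
  n_failed <- 0
  for (i in 1:6) {
    net <- flipflop_network(split_seed(2, "net", i))
    sim <- simulate_flipflop(net, split_seed(2, "sim", i), ramp = NULL,
                             keep_spikes = FALSE)
    st <- rle(score_switch(sim, th$thr_n, th$thr_r))$values
    # N>NRt>N or R>NRt>R triples are failed transitions
    if (length(st) >= 3)
      n_failed <- n_failed + sum(st[seq_len(length(st) - 2)] == st[seq_len(length(st) - 2) + 2] &
                                   st[seq_len(length(st) - 2) + 1] == "NRt")
  }
  expect_gt(n_failed, 0)
})

test_that("tuning design enumerates the full grid", {
  design <- tune_weights(reps = 25, execute = FALSE)
  expect_equal(nrow(design), 3025L)
  expect_equal(nrow(dplyr::distinct(design[c("d_n_to_r", "d_r_to_n")])), 121L)
  design_b <- tune_bias(reps = 25, execute = FALSE)
  expect_equal(nrow(design_b), 3025L)
})

test_that("a strongly asymmetric weighting cell is N-dominated", {
  cell <- tune_weights(d_n_to_r = 1.8, d_r_to_n = 2.8, reps = 2, seed = 4,
                       n_iter = 4000)
  expect_lt(cell$mode_n, 0)
  diffs <- unlist(lapply(1:2, function(r) {
    s <- split_seed(4, sprintf("tune_w_%g_%g", 1.8, 2.8), r)
    net <- flipflop_network(s, d_n_to_r = 1.8, d_r_to_n = 2.8)
    simulate_flipflop(net, split_seed(s, "sim"), ramp = NULL, n_iter = 4000,
                      keep_spikes = FALSE)$rates$rate_diff
  }))
  expect_gt(mean(diffs < 0), 0.9)
})

test_that("switch metrics: densities, origins and censored latency", {
  st <- c("N", "N", "NRt", "NRt", "R", "R", "NRt", "NRt", "R", "R")
  m <- switch_metrics(st)
  expect_equal(m$latency_r, 5L)
  expect_false(m$latency_censored)
  expect_equal(m$n_nrt_bouts, 2L)
  expect_equal(m$nrt_density_n, 1 / 2)   # one N-origin bout, two N epochs
  expect_equal(m$nrt_density_r, 1 / 4)   # one R-origin bout, four R epochs
  m2 <- switch_metrics(rep("N", 400))
  expect_equal(m2$latency_r, 400L)
  expect_true(m2$latency_censored)
})
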