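test_that("the generator is deterministic given the seed", {
  r1 <- generate_recording(synth_config(), 500, seed = 33)
  r2 <- generate_recording(synth_config(), 500, seed = 33)
  expect_identical(r1$band_powers, r2$band_powers)
  expect_identical(r1$hypnogram4, r2$hypnogram4)
})

test_that("generated band powers are a valid 16-band non-negative table", {
  rec <- generate_recording(synth_config(), 400, seed = 2)
  bp <- as.matrix(rec$band_powers[band_defs()$band])
  expect_equal(ncol(bp), 16L)
  expect_true(all(bp > 0))
  # the emitted coordinates invert exactly through the spectral module
  tr <- compute_trajectory(rec$band_powers)
  expect_equal(tr$x_raw, rec$trajectory$x, tolerance = 1e-10)
  expect_equal(tr$y_raw, rec$trajectory$y, tolerance = 1e-10)
})

test_that("ground-truth labels are internally consistent", {
  rec <- generate_recording(synth_config(), 2000, seed = 14)
  g4 <- rec$hypnogram4$label; g3 <- rec$hypnogram3$label
  # 4-stage differs from 3-stage only by relabelling sleep epochs to t
  changed <- which(g4 != g3)
  expect_true(all(g4[changed] == "t"))
  expect_true(all(g3[changed] %in% c("N", "R")))
  # every t bout's origin is the preceding state
  r <- rle(g4)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  torigins <- r$values[which(r$values == "t") - 1]
  expect_true(all(torigins %in% c("N", "R", "W") | is.na(torigins)))
})

test_that("invalid corridor geometry is rejected at configuration time", {
  expect_error(synth_config(corridor_margin = 0.01), "corridor margin")
  expect_error(synth_config(n_mean = c(-0.2, 2.4), r_mean = c(-0.12, 2.2)),
               "6 pooled")
})

test_that("noise-free limit: trajectory is piecewise deterministic and recoverable", {
  cfg <- synth_config(walk_sd = 1e-9, walk_sd_r = 1e-9, obs_sd = 0,
                      corridor_jitter = 0, corridor_spread = 0,
                      trans_bow = 1e-9, exc_bow = c(1e-10, 2e-10),
                      arousal_hazard = 0)
  rec <- generate_recording(cfg, 600, seed = 5)
  g4 <- rec$hypnogram4$label
  # in-cluster epochs sit exactly at the cluster means
  ni <- which(g4 == "N")
  expect_lt(max(abs(rec$trajectory$x[ni] - cfg$n_mean[1])), 1e-6)
  expect_lt(max(abs(rec$trajectory$y[ni] - cfg$n_mean[2])), 1e-6)
  # with exact geometry handed to the scorer, labels are fully recovered
  sep <- sqrt(sum((cfg$r_mean - cfg$n_mean)^2))
  b <- make_bounds(cfg$n_mean, cfg$r_mean, h = 0.12 * sep)
  sp <- make_nrt_space(b, half_width = 0.2)
  sc <- score_4stage(compute_trajectory(rec$band_powers), rec$hypnogram3, b, sp)
  agree <- mean((sc$label == "t") == (g4 == "t"))
  expect_gte(agree, 0.97)
})

test_that("baseline REM-origin NRt rate matches the configured hazard", {
  cfg <- synth_config(exc_hazard_r = 1 / 250)
  tot_bouts <- 0; tot_repochs <- 0
  for (s in 1:12) {
    rec <- generate_recording(cfg, 1200, seed = 400 + s)
    bs <- bout_stats(rec$hypnogram4)
    tb <- bs$bouts
    tot_bouts <- tot_bouts + sum(tb$state == "t" & !is.na(tb$origin) &
                                   tb$origin == "R")
    tot_repochs <- tot_repochs + bs$summary$epochs_r
  }
  rate <- tot_bouts / tot_repochs
  se <- sqrt(tot_bouts) / tot_repochs
  expect_lt(abs(rate - 1 / 250), 4 * se + 0.1 / 250)
})

test_that("the drug condition multiplies the REM-origin NRt rate about 6-fold", {
  cfg <- synth_config(exc_hazard_r = 1 / 250)
  dens <- sapply(1:20, function(s) {
    vapply(c("baseline", "drug"), function(cond) {
      rec <- generate_recording(cfg, 1500, seed = 100 + s, condition = cond)
      bout_stats(rec$hypnogram4)$summary$nrt_density_from_r
    }, 0)
  })
  ratio <- mean(dens["drug", ], na.rm = TRUE) / mean(dens["baseline", ], na.rm = TRUE)
  expect_gt(ratio, 4); expect_lt(ratio, 8)
})

test_that("raw EEG synthesis round-trips through the spectral module", {
  rec <- generate_recording(synth_config(), 220, seed = 9)
  target <- rec$band_powers[1:20, ]
  sig <- generate_raw_eeg(target, fs = 200, seed = 1)
  back <- compute_band_powers(sig, fs = 200)
  tm <- as.matrix(target[band_defs()$band]); bm <- as.matrix(back[band_defs()$band])
  rel <- abs(bm / rowSums(bm) - tm / rowSums(tm))
  expect_lt(max(rel), 0.10)
})

test_that("single-band targets concentrate the round-trip power in that band", {
  row <- rep(0, 16); row[6] <- 4
  sig <- generate_raw_eeg(make_powers(row, n_epochs = 3), fs = 200, seed = 2)
  back <- compute_band_powers(sig, fs = 200)
  m <- as.matrix(back[band_defs()$band])
  expect_gte(min(m[, 6] / rowSums(m)), 0.95)
})

test_that("all-zero power targets give an all-zero signal", {
  sig <- generate_raw_eeg(make_powers(rep(0, 16), n_epochs = 2), fs = 100, seed = 3)
  expect_true(all(sig == 0))
})
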