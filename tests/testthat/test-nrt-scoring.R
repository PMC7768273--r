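test_that("a unit segment cross is found at (0.5, 0.5) with 4 bounding epochs", {
  tr <- make_traj(x = c(0, 1, 0, 1), y = c(0, 1, 1, 0))
  ev <- find_intersections(tr, window = 5)
  expect_equal(nrow(ev), 1L)
  expect_equal(c(ev$x, ev$y), c(0.5, 0.5))
  expect_equal(sort(c(ev$e1, ev$e2, ev$e3, ev$e4)), 1:4)
})

test_that("a monotone trajectory has no intersections", {
  tr <- make_traj(x = 1:50, y = (1:50) * 0.3)
  expect_equal(nrow(find_intersections(tr)), 0L)
})

test_that("degenerate (repeated-point) segments are skipped, not crashed", {
  tr <- make_traj(x = c(0, 0, 1, 0, 1), y = c(0, 0, 1, 1, 0))
  ev <- find_intersections(tr)
  expect_gte(attr(ev, "skipped"), 1L)
})

test_that("intersection finder matches the brute-force all-pairs oracle", {
  set.seed(11)
  for (k in 1:6) {
    tr <- make_traj(x = cumsum(rnorm(200)), y = cumsum(rnorm(200)))
    ev <- find_intersections(tr)
    oracle <- brute_intersections(tr)
    expect_equal(nrow(ev), nrow(oracle))
    if (nrow(ev)) {
      o1 <- ev[order(ev$e1, ev$e3), ]
      o2 <- oracle[order(oracle[, "i"], oracle[, "j"]), , drop = FALSE]
      expect_equal(o1$e1, unname(o2[, "i"]))
      expect_equal(o1$e3, unname(o2[, "j"]))
      expect_equal(o1$x, unname(o2[, "x"]), tolerance = 1e-9)
      expect_equal(o1$y, unname(o2[, "y"]), tolerance = 1e-9)
    }
  }
})

make_events_for <- function(epochs) {
  # events whose four bounding epochs enumerate `epochs` (padded cyclically)
  idx <- rep(epochs, length.out = ceiling(length(epochs) / 4) * 4)
  m <- matrix(idx, ncol = 4, byrow = TRUE)
  tibble::tibble(x = 0, y = 0, e1 = m[, 1], e2 = m[, 2], e3 = m[, 3], e4 = m[, 4])
}

test_that("state boundary of four square-corner points is that square", {
  tr <- make_traj(x = c(0, 1, 1, 0, 10, 10, 11, 11),
                  y = c(0, 0, 1, 1, 0, 1, 0, 1))
  hyp <- make_hyp(c(rep("N", 4), rep("R", 4)))
  ev <- make_events_for(1:8)
  b <- fit_state_boundaries(ev, tr, hyp)
  expect_equal(nrow(b$N$polygon), 4L)
  area <- function(p) { n <- nrow(p); i2 <- c(2:n, 1)
    abs(sum(p$x * p$y[i2] - p$x[i2] * p$y)) / 2 }
  expect_equal(area(b$N$polygon), 1)
  expect_equal(b$N$excluded_points, 0L)
})

test_that("an extreme point among a large cluster is excluded by the 5-SD trim", {
  set.seed(5)
  n <- 40
  tr <- make_traj(x = c(rnorm(n, 0, 0.05), 50, rnorm(4, 10, 0.05)),
                  y = c(rnorm(n, 0, 0.05), 0, rnorm(4, 0, 0.05)))
  hyp <- make_hyp(c(rep("N", n + 1), rep("R", 4)))
  b <- fit_state_boundaries(make_events_for(1:(n + 5)), tr, hyp)
  expect_equal(b$N$excluded_points, 1L)
  expect_true(all(b$N$polygon$x < 10))
})

test_that("5-SD exclusion count matches a direct recomputation on 500 points", {
  set.seed(9)
  n <- 500
  x <- rt(n, df = 3) * 0.1; y <- rt(n, df = 3) * 0.1
  tr <- make_traj(x = c(x, 10, 10.5, 10.2, 10.4), y = c(y, 0, 0.4, 0.1, 0.3))
  hyp <- make_hyp(c(rep("N", n), rep("R", 4)))
  b <- fit_state_boundaries(make_events_for(1:(n + 4)), tr, hyp)
  d <- sqrt((x - mean(x))^2 + (y - mean(y))^2)
  expect_equal(b$N$excluded_points, sum(d > mean(d) + 5 * sd(d)))
  inside <- sleepswitch:::point_in_polygon(b$N$points$x, b$N$points$y, b$N$polygon)
  expect_true(all(inside))
})

test_that("too little control sleep is a hard error", {
  tr <- make_traj(x = c(0, 1, 10, 10.5), y = c(0, 1, 0, 0.5))
  hyp <- make_hyp(c("N", "N", "R", "R"))
  expect_error(fit_state_boundaries(make_events_for(1:4), tr, hyp),
               "insufficient control sleep")
})

test_that("overlapping state clusters are rejected", {
  set.seed(2)
  tr <- make_traj(x = rnorm(40, 0, 1), y = rnorm(40, 0, 1))
  hyp <- make_hyp(rep(c("N", "R"), 20))
  expect_error(fit_state_boundaries(make_events_for(1:40), tr, hyp), "overlap")
})

# --- NRt space ---------------------------------------------------------

straight_transition_fixture <- function() {
  # 4 in-N epochs, 5 corridor epochs, 4 in-R epochs, on the x axis
  x <- c(0.1, -0.1, 0.1, -0.1, 2, 4, 5, 6, 8, 10.1, 9.9, 10.1, 9.9)
  y <- c(0.1, -0.1, -0.1, 0.1, 0.3, -0.3, 0.3, -0.3, 0.3, 0.1, -0.1, -0.1, 0.1)
  list(traj = make_traj(x, y),
       hyp = make_hyp(c(rep("N", 4), rep("N", 5), rep("R", 4))),
       bounds = make_bounds(c(0, 0), c(10, 0), h = 1))
}

test_that("NRt space of one straight transition is the hull of its points", {
  f <- straight_transition_fixture()
  sp <- define_nrt_space(f$traj, f$hyp, f$bounds)
  expect_equal(sp$n_transitions, 1L)
  expect_true(all(sleepswitch:::point_in_polygon(c(2, 4, 5, 6, 8),
                                                 c(0.3, -0.3, 0.3, -0.3, 0.3),
                                                 sp$hull)))
})

test_that("NRt space of two parallel transitions contains the band between them", {
  x <- c(0.1, -0.1, 0.1, 2, 5, 8, 10.1, 9.9, 10.1,
         -0.1, 0.1, -0.1, 2, 5, 8, 9.9, 10.1, 9.9)
  y <- c(0, 0, 0, 2, 2, 2, 0, 0, 0,
         0, 0, 0, -2, -2, -2, 0, 0, 0)
  hyp <- make_hyp(rep(c(rep("N", 3), rep("N", 3), rep("R", 3)), 2))
  b <- make_bounds(c(0, 0), c(10, 0), h = 1)
  sp <- define_nrt_space(make_traj(x, y), hyp, b)
  expect_equal(sp$n_transitions, 2L)
  expect_true(all(sleepswitch:::in_nrt_space(c(4, 5, 6), c(0, 0, 0), sp)))
})

test_that("no complete transitions is a hard error with guidance", {
  f <- straight_transition_fixture()
  hyp_w <- f$hyp; hyp_w$label[6] <- "W"    # arousal interrupts the transition
  expect_error(define_nrt_space(f$traj, hyp_w, f$bounds), "extend the control")
})

# --- 4-stage scoring ---------------------------------------------------

test_that("a trajectory that never leaves its polygons is scored unchanged", {
  set.seed(4)
  n <- 60
  lab <- rep(c("N", "R", "W"), each = 20)
  x <- ifelse(lab == "N", 0, ifelse(lab == "R", 10, 5)) + runif(n, -0.5, 0.5)
  y <- ifelse(lab == "W", 8, 0) + runif(n, -0.5, 0.5)
  b <- make_bounds(c(0, 0), c(10, 0), h = 1)
  sp <- make_nrt_space(b)
  sc <- score_4stage(make_traj(x, y), make_hyp(lab), b, sp)
  expect_identical(sc$label, lab)
})

scorer_fixture <- function(exc_len, ending = c("return", "arousal", "transition")) {
  ending <- match.arg(ending)
  b <- make_bounds(c(0, 0), c(10, 0), h = 1)
  sp <- make_nrt_space(b)
  pre <- list(x = c(0, 0.1, -0.1, 0), y = c(0, 0.1, -0.1, 0), lab = rep("N", 4))
  exc <- list(x = seq(3, 7, length.out = exc_len), y = rep(0.2, exc_len),
              lab = rep("N", exc_len))
  post <- switch(ending,
    return = list(x = c(0.1, -0.1, 0.1), y = c(0, 0, 0), lab = rep("N", 3)),
    arousal = list(x = c(5, 5, 0.1, -0.1, 0.1), y = c(8, 8, 0, 0, 0),
                   lab = c("W", "W", "N", "N", "N")),
    transition = list(x = c(10.1, 9.9, 10.1), y = c(0, 0, 0), lab = rep("R", 3)))
  list(traj = make_traj(c(pre$x, exc$x, post$x), c(pre$y, exc$y, post$y)),
       hyp = make_hyp(c(pre$lab, exc$lab, post$lab)),
       bounds = b, space = sp, exc_idx = 4 + seq_len(exc_len))
}

test_that("one-epoch excursions ending in return or arousal are not NRt (rule 3)", {
  for (ending in c("return", "arousal")) {
    f <- scorer_fixture(1, ending)
    sc <- score_4stage(f$traj, f$hyp, f$bounds, f$space)
    expect_identical(sc$label, f$hyp$label)
  }
})

test_that("multi-epoch excursions toward REM through NRt space are scored t", {
  for (ending in c("return", "arousal", "transition")) {
    f <- scorer_fixture(4, ending)
    sc <- score_4stage(f$traj, f$hyp, f$bounds, f$space)
    expect_true(all(sc$label[f$exc_idx] == "t"))
    expect_true(all(sc$label[f$hyp$label == "W"] == "W"))
  }
})

test_that("excursions from NREM moving away from REM are rejected (rule 5)", {
  f <- scorer_fixture(4, "return")
  # widen NRt space symmetrically so the direction rule, not rule 6, decides
  f$space$hull <- tibble::tibble(x = c(-8, 10, 10, -8), y = c(-2, -2, 2, 2))
  sc_fwd <- score_4stage(f$traj, f$hyp, f$bounds, f$space)
  expect_true(all(sc_fwd$label[f$exc_idx] == "t"))
  f$traj$x[f$exc_idx] <- -f$traj$x[f$exc_idx]   # same excursion, away from R
  sc <- score_4stage(f$traj, f$hyp, f$bounds, f$space)
  expect_identical(sc$label, f$hyp$label)
})

test_that("excursions that do not pass through NRt space are rejected (rule 6)", {
  f <- scorer_fixture(4, "return")
  f$traj$y[f$exc_idx] <- 6     # right of N, but far off the corridor band
  sc <- score_4stage(f$traj, f$hyp, f$bounds, f$space)
  expect_identical(sc$label, f$hyp$label)
})

test_that("an excursion without two preceding in-boundary epochs is rejected (rule 1)", {
  f <- scorer_fixture(4, "return")
  f$hyp$label[1:3] <- "W"; f$traj$x[1:3] <- 5; f$traj$y[1:3] <- 8
  # only one in-boundary N epoch precedes the excursion
  sc <- score_4stage(f$traj, f$hyp, f$bounds, f$space)
  expect_identical(sc$label, f$hyp$label)
})

test_that("scored t epochs lie between the boundaries, never on wake epochs", {
  rec <- generate_recording(synth_config(), 2000, seed = 8)
  res <- score_recording(rec$band_powers, rec$hypnogram3, 1:1000)
  sc <- res$scored
  ti <- which(sc$label == "t")
  expect_gt(length(ti), 0)
  # t epochs are outside both state polygons in the effective (two-epoch
  # persistence) sense; isolated single-epoch polygon dips inside an
  # excursion remain part of it
  eff <- sleepswitch:::effective_region(sc$region, sc$label3)
  expect_true(all(eff[ti] == "out"))
  # and every t-containing excursion passes through NRt space
  runs <- sleepswitch:::run_lengths(sc$label == "t")
  runs <- runs[runs$value == "TRUE", ]
  for (k in seq_len(nrow(runs))) {
    ix <- runs$start[k]:runs$end[k]
    inside <- sleepswitch:::in_nrt_space(res$trajectory$x[ix],
                                         res$trajectory$y[ix], res$nrt_space)
    expect_true(length(inside) == 1 || any(inside[-length(inside)] & inside[-1]))
  }
  expect_false(any(sc$label3[ti] == "W"))
})

test_that("wake abundance is bit-identical between 3- and 4-stage scoring", {
  rec <- generate_recording(synth_config(), 2000, seed = 8)
  res <- score_recording(rec$band_powers, rec$hypnogram3, 1:1000)
  expect_identical(mean(rec$hypnogram3$label == "W"),
                   mean(res$scored$label == "W"))
})
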