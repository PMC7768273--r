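# shared builders and independent oracles for the test suite

# band-power tibble from a matrix (rows = epochs) or a single row recycled
make_powers <- function(bp, n_epochs = NULL) {
  if (is.null(dim(bp))) {
    stopifnot(!is.null(n_epochs))
    bp <- matrix(bp, n_epochs, 16, byrow = TRUE)
  }
  colnames(bp) <- band_defs()$band
  out <- tibble::as_tibble(bp)
  out$epoch_index <- seq_len(nrow(bp))
  out$valid <- TRUE
  out[c("epoch_index", band_defs()$band, "valid")]
}

make_traj <- function(x, y) {
  tibble::tibble(epoch_index = seq_along(x), x = x, y = y, valid = TRUE)
}

make_hyp <- function(labels) {
  tibble::tibble(epoch_index = seq_along(labels), label = labels)
}

# square polygon (counter-clockwise) centred at (cx, cy) with half-width h
square_poly <- function(cx, cy, h) {
  tibble::tibble(x = cx + h * c(-1, 1, 1, -1), y = cy + h * c(-1, -1, 1, 1))
}

# hand-built state boundaries / NRt space for isolated scorer tests
make_bounds <- function(n_center = c(0, 0), r_center = c(10, 0), h = 1) {
  out <- list(
    N = list(polygon = square_poly(n_center[1], n_center[2], h),
             centroid = c(x = n_center[1], y = n_center[2]),
             excluded_points = 0L),
    R = list(polygon = square_poly(r_center[1], r_center[2], h),
             centroid = c(x = r_center[1], y = r_center[2]),
             excluded_points = 0L),
    outlier_sd = 5)
  class(out) <- "state_boundaries"
  out
}

make_nrt_space <- function(bounds, half_width = 2) {
  nc <- bounds$N$centroid; rc <- bounds$R$centroid
  hull <- tibble::tibble(
    x = c(nc["x"], rc["x"], rc["x"], nc["x"]),
    y = c(nc["y"] - half_width, rc["y"] - half_width,
          rc["y"] + half_width, nc["y"] + half_width))
  out <- list(hull = hull, points = hull,
              n_polygon = bounds$N$polygon, r_polygon = bounds$R$polygon,
              n_transitions = 1L)
  class(out) <- "nrt_space"
  out
}

# independent brute-force segment-pair intersection oracle: solves the
# 2x2 linear system for every candidate pair, strict interior crossing
brute_intersections <- function(traj, window = 5) {
  n <- nrow(traj); out <- list()
  for (i in seq_len(max(0, n - 3))) {
    for (j in (i + 2):min(n - 1, i + window - 2)) {
      p <- c(traj$x[i], traj$y[i]); r <- c(traj$x[i + 1] - p[1], traj$y[i + 1] - p[2])
      q <- c(traj$x[j], traj$y[j]); s <- c(traj$x[j + 1] - q[1], traj$y[j + 1] - q[2])
      den <- r[1] * s[2] - r[2] * s[1]
      if (abs(den) < 1e-14) next
      t <- ((q[1] - p[1]) * s[2] - (q[2] - p[2]) * s[1]) / den
      u <- ((q[1] - p[1]) * r[2] - (q[2] - p[2]) * r[1]) / den
      if (t > 0 && t < 1 && u > 0 && u < 1)
        out[[length(out) + 1]] <- c(i = i, j = j, x = p[1] + t * r[1],
                                    y = p[2] + t * r[2])
    }
  }
  if (length(out)) do.call(rbind, out) else
    matrix(numeric(0), 0, 4, dimnames = list(NULL, c("i", "j", "x", "y")))
}

# one-neuron "network" for single-cell simulations
single_neuron_net <- function() {
  structure(list(W = matrix(0, 1, 1),
                 pools = list(input = integer(0), R = 1L, N = integer(0), n = 1L),
                 params = list()),
            class = "flipflop_network")
}

# run-length recount oracle for bout tables (no arousal merging)
rle_bout_oracle <- function(labels) {
  r <- rle(labels)
  tibble::tibble(state = r$values, length = r$lengths)
}
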