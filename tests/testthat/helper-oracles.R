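# Shared fixtures and independent oracles, built in code at test time.

# Brute-force single-source shortest path by iterated edge relaxation
# (Bellman-Ford style) over the 8-connected lattice. Independent of the
# package's Dijkstra-based implementation.
bf_activation_times <- function(field, pacing_node, dx) {
  n <- nrow(field)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      for (di in -1:1) {
        for (dj in -1:1) {
          if (di == 0 && dj == 0) next
          ii <- i + di; jj <- j + dj
          if (ii < 1 || ii > n || jj < 1 || jj > n) next
          a <- field[i, j]; b <- field[ii, jj]
          hm <- 2 * a * b / (a + b)
          from <- c(from, (j - 1) * n + i)
          to <- c(to, (jj - 1) * n + ii)
          w <- c(w, sqrt(di^2 + dj^2) * dx / hm)
        }
      }
    }
  }
  dist <- rep(Inf, n * n)
  dist[(pacing_node[2] - 1) * n + pacing_node[1]] <- 0
  repeat {
    changed <- FALSE
    for (k in seq_along(from)) {
      cand <- dist[from[k]] + w[k]
      if (cand < dist[to[k]]) {
        dist[to[k]] <- cand
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  matrix(dist, n, n)
}

# Piecewise-linear beat with known Q/R/S/end geometry (times in ms = sample
# indices at 1 kHz). Returns the beat plus the constructed landmark truth;
# the endpoint truth is derived in closed form from the 10%-of-peak-to-peak
# threshold crossing on the linear recovery limb.
make_pwl_beat <- function(t_on = 30, t_r = 40, t_s = 60, t_end = 100,
                          r_amp = 3, s_amp = -4, total_ms = 150,
                          end_frac = 0.1) {
  knots_t <- c(0, t_on, t_r, t_s, t_end, total_ms)
  knots_v <- c(0, 0, r_amp, s_amp, 0, 0)
  tt <- 0:total_ms
  v <- approx(knots_t, knots_v, xout = tt)$y
  beat <- structure(
    list(samples = v, fs = 1000, stimulus_ms = 0, channel = 1L,
         beat_index = 1L, heart_id = "T", condition = "BL", site_index = 1L,
         cycle_length = 500),
    class = "beat_complex")
  theta_end <- end_frac * (r_amp - s_amp)
  # first integer time after t_s with |v| strictly below the threshold
  cross <- t_s + (abs(s_amp) - theta_end) / abs(s_amp) * (t_end - t_s)
  end_true <- ceiling(cross)
  if (abs(s_amp) * (t_end - end_true) / (t_end - t_s) >= theta_end) {
    end_true <- end_true + 1
  }
  list(beat = beat, t_on = t_on, t_r = t_r, t_s = t_s, t_end = t_end,
       r_amp = r_amp, s_amp = s_amp, end_true = end_true)
}

# Small, fast simulation configuration for unit tests (not the study
# defaults): coarse lattice, short recordings.
tiny_config <- function(...) {
  args <- list(grid_n = 24L, dx = 0.5, cycle_length = 500,
               n_beats = 2L, seed = 42L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simulation_config, args)
}

with_seed_test <- function(seed, code) withr::with_seed(seed, code)

# absolute-tolerance comparison (expect_equal's tolerance is relative)
expect_within <- function(x, y, tol) {
  expect_lte(max(abs(x - y)), tol)
}

expect_same_file <- function(a, b) {
  expect_identical(unname(tools::md5sum(a)), unname(tools::md5sum(b)))
}
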