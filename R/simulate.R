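#' Build a conduction-velocity field
#'
#' Node-wise conduction velocity on the `grid_n` x `grid_n` tissue lattice:
#' `cv = base_cv * sqrt(c) * exp(g)` with `g ~ Normal(0, heterogeneity_sd^2)`
#' i.i.d., the square-root dependence on the coupling factor `c` coming from
#' continuous cable theory. Independently, conduction-block micro-patches —
#' discs of radius `patch_radius_mm` whose velocity is set to `cv_floor`
#' (never exactly zero, keeping travel times finite) — are seeded from the
#' same uniform draw so that each node lies inside a patch with probability
#' about `patch_block_prob`; with `patch_radius_mm < dx` this reduces to
#' independent single-node blocks. Supplying `g`/`u` lets callers freeze the
#' spatial random structure while varying `c` (the same tissue at different
#' degrees of uncoupling), which is how the dose-response simulation works.
#'
#' @param config A [simulation_config()].
#' @param c Coupling factor; defaults to `config$coupling_factor`.
#' @param g Optional pre-drawn standard-normal matrix `[grid_n x grid_n]`.
#' @param u Optional pre-drawn uniform(0,1) matrix for block patches.
#' @return Matrix `[grid_n x grid_n]` of velocities (mm/ms), class
#'   `velocity_field`.
#' @export
build_velocity_field <- function(config, c = config$coupling_factor,
                                 g = NULL, u = NULL) {
  n <- config$grid_n
  sdv <- resolve_heterogeneity(config, c)
  pblk <- resolve_block_prob(config, c)
  if (is.null(g)) g <- matrix(rnorm(n * n), n, n)
  if (is.null(u)) u <- matrix(runif(n * n), n, n)
  cv <- config$base_cv * sqrt(c) * exp(sdv * g)
  if (pblk > 0) {
    cv[block_patch_mask(u, pblk, config$patch_radius_mm, config$dx)] <-
      config$cv_floor
  }
  structure(cv, class = c("velocity_field", "matrix", "array"))
}

# Disc-shaped conduction-block patches: patch centres are seeded per node at
# a rate chosen so the expected covered fraction is `pblk`, then dilated to
# radius r. Radii below dx reduce to independent per-node blocks.
block_patch_mask <- function(u, pblk, radius_mm, dx) {
  r_nodes <- radius_mm / dx
  offs <- expand.grid(di = -floor(r_nodes):floor(r_nodes),
                      dj = -floor(r_nodes):floor(r_nodes))
  offs <- offs[offs$di^2 + offs$dj^2 <= r_nodes^2, , drop = FALSE]
  if (nrow(offs) <= 1) return(u < pblk)
  p_seed <- min(1, pblk / nrow(offs))
  seeds <- u < p_seed
  n <- nrow(u)
  mask <- matrix(FALSE, n, n)
  for (k in seq_len(nrow(offs))) {
    di <- offs$di[k]; dj <- offs$dj[k]
    si <- max(1, 1 - di):min(n, n - di)
    sj <- max(1, 1 - dj):min(n, n - dj)
    mask[si + di, sj + dj] <- mask[si + di, sj + dj] | seeds[si, sj]
  }
  mask
}

#' Activation map by exact shortest-path propagation
#'
#' Activation time at every lattice node is the exact single-source shortest
#' path from the pacing node over the 8-connected node graph, with edge cost
#' equal to the Euclidean edge length divided by the harmonic mean of the two
#' endpoint velocities. This eikonal-style propagation reproduces wavefront
#' geometry (including detours around conduction blocks) without an ionic
#' model.
#'
#' @param field A velocity matrix from [build_velocity_field()], mm/ms.
#' @param pacing_node Integer `(row, col)` of the paced node.
#' @param dx Node spacing, mm.
#' @return List with `times` (ms matrix, 0 at the pacing node) and
#'   `pacing_node`; class `activation_map`.
#' @export
compute_activation_map <- function(field, pacing_node = c(1L, 1L), dx = 0.5) {
  n <- nrow(field)
  stopifnot(ncol(field) == n, all(field > 0), dx > 0)
  pr <- as.integer(pacing_node[1]); pc <- as.integer(pacing_node[2])
  if (pr < 1 || pr > n || pc < 1 || pc > n) {
    stop("index error: pacing_node out of bounds", call. = FALSE)
  }
  edges <- lattice_edges(n)
  cv <- as.numeric(field)
  hmean <- 2 * cv[edges$from] * cv[edges$to] / (cv[edges$from] + cv[edges$to])
  w <- edges$len * dx / hmean
  g <- igraph::make_empty_graph(n = n * n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(edges$from, edges$to))
  src <- (pc - 1L) * n + pr
  d <- igraph::distances(g, v = src, weights = w, algorithm = "dijkstra")
  times <- matrix(as.numeric(d), n, n)
  structure(list(times = times, pacing_node = c(pr, pc)),
            class = "activation_map")
}

# Undirected 8-connected lattice edge list for an n x n grid,
# column-major vertex ids. len is in units of dx.
lattice_edges <- function(n) {
  idx <- matrix(seq_len(n * n), n, n)
  from <- c(as.vector(idx[-n, ]),          # down
            as.vector(idx[, -n]),          # right
            as.vector(idx[-n, -n]),        # down-right diagonal
            as.vector(idx[-1, -n]))        # up-right diagonal
  to   <- c(as.vector(idx[-1, ]),
            as.vector(idx[, -1]),
            as.vector(idx[-1, -1]),
            as.vector(idx[-n, -1]))
  len <- c(rep(1, (n - 1) * n), rep(1, n * (n - 1)),
           rep(sqrt(2), 2 * (n - 1) * (n - 1)))
  list(from = from, to = to, len = len)
}

#' Transmembrane action-potential template
#'
#' Piecewise-smooth stylized action potential: resting at `rest` for
#' `t < 0`; from `t = 0` a logistic upstroke of duration about
#' `upstroke_tau` rising `amp` mV (rescaled so the potential is exactly
#' `rest` at `t = 0`); a plateau; then a smooth half-cosine repolarization
#' completing at `t = apd` and returning to rest. The maximal upstroke rate
#' scales as `1/upstroke_tau`.
#'
#' @param t Time since local activation, ms (vector or matrix; may be
#'   negative).
#' @param upstroke_tau Upstroke duration, ms.
#' @param apd Action-potential duration, ms.
#' @param rest,amp Resting potential and AP amplitude, mV.
#' @param plateau_frac Fraction of `apd` before the repolarization ramp.
#' @return Membrane potential, mV, same shape as `t`.
#' @export
ap_waveform <- function(t, upstroke_tau = 5, apd = 250, rest = -80,
                        amp = 100, plateau_frac = 0.6) {
  s <- upstroke_tau / 4.39  # 10-90% rise time of a logistic is 4.39 scales
  c0 <- upstroke_tau / 2
  L0 <- plogis(-c0 / s)
  tp <- plateau_frac * apd
  v <- t
  v[] <- rest
  act <- which(t >= 0 & t < apd)  # elsewhere the template is at rest
  ta <- t[act]
  up <- (plogis((ta - c0) / s) - L0) / (1 - L0)
  rp <- rep.int(1, length(ta))
  ramp <- ta > tp
  rp[ramp] <- 0.5 * (1 + cos(pi * (ta[ramp] - tp) / (apd - tp)))
  v[act] <- rest + amp * up * rp
  v
}

#' Analytic time derivative of [ap_waveform()]
#'
#' @inheritParams ap_waveform
#' @return dVm/dt in mV/ms, same shape as `t`.
#' @export
ap_dvdt <- function(t, upstroke_tau = 5, apd = 250, rest = -80,
                    amp = 100, plateau_frac = 0.6) {
  s <- upstroke_tau / 4.39
  c0 <- upstroke_tau / 2
  L0 <- plogis(-c0 / s)
  tp <- plateau_frac * apd
  d <- t
  d[] <- 0
  act <- which(t >= 0 & t < apd)  # derivative vanishes outside the AP
  ta <- t[act]
  L <- plogis((ta - c0) / s)
  up <- (L - L0) / (1 - L0)
  dup <- L * (1 - L) / (s * (1 - L0))
  rp <- rep.int(1, length(ta))
  drp <- numeric(length(ta))
  ramp <- ta > tp
  z <- pi * (ta[ramp] - tp) / (apd - tp)
  rp[ramp] <- 0.5 * (1 + cos(z))
  drp[ramp] <- -0.5 * pi / (apd - tp) * sin(z)
  d[act] <- amp * (dup * rp + up * drp)
  d
}

#' Forward-model a noise-free single-beat EGM recording
#'
#' Extracellular potential at electrode e:
#' `phi_e(t) = k * sum_i I_i(t) / r_ie`, where
#' `I_i(t) = dVm_i/dt - mean_j dVm_j/dt` is the zero-sum-corrected current
#' source of tissue node i and `r_ie` is the 3-D distance from the node to
#' the electrode (grid height included). The zero-sum correction conserves
#' total membrane current, which removes DC content and yields the biphasic
#' R-then-S morphology of a passing wavefront: far-field sources carry
#' below-average weight (negative effective weight), near-field sources
#' above-average weight.
#'
#' The gain combines the calibrated `amp_scale` with a bulk-conductivity
#' factor `(1 + sigma_ratio) / (1 + sigma_ratio * coupling)`: blocking gap
#' junctions removes the intracellular pathway from the bulk tissue
#' conductivity, so the same source current produces larger extracellular
#' deflections in uncoupled tissue (the factor is 1 at full coupling).
#'
#' The beat is evaluated from the stimulus until all nodes have repolarized,
#' truncated at one cycle length, and placed at each stimulus time of the
#' pacing protocol (paced beats at fixed cycle length are identical up to
#' noise, which is added separately).
#'
#' @param act An `activation_map` from [compute_activation_map()].
#' @param grid An [electrode_grid()] with `height > 0`.
#' @param config A [simulation_config()].
#' @param apd Action-potential duration for this site's region, ms.
#' @param upstroke_tau Local upstroke duration, ms (already widened for
#'   uncoupling by the caller).
#' @param coupling Coupling factor of the simulated tissue, used for the
#'   bulk-conductivity gain.
#' @param site_index,condition,dose_ml,heart_id Recording metadata.
#' @param fs Sampling rate, Hz.
#' @return A noise-free [egm_recording()].
#' @export
forward_egm <- function(act, grid, config, apd = config$apd_v,
                        upstroke_tau = config$upstroke_tau, coupling = 1,
                        site_index = 1L, condition = "BL", dose_ml = 0,
                        heart_id = "H01", fs = 1000) {
  if (grid$height <= 0) {
    stop("singularity error: electrode height must be > 0", call. = FALSE)
  }
  n <- nrow(act$times)
  node_xy <- cbind(
    x = rep((seq_len(n) - 1) * config$dx, each = n),  # column-major ids
    y = rep((seq_len(n) - 1) * config$dx, times = n)
  )
  el <- electrode_positions(grid)
  r <- sqrt(outer(el[, 1], node_xy[, 1], "-")^2 +
            outer(el[, 2], node_xy[, 2], "-")^2 + grid$height^2)
  W <- 1 / r                                  # [electrodes x nodes]
  act_v <- as.numeric(act$times)
  dt <- 1000 / fs
  beat_ms <- min(config$cycle_length, max(act_v) + apd + 40)
  tt <- seq(0, beat_ms, by = dt)
  # sources: [nodes x time]; analytic derivative of the AP template
  S <- ap_dvdt(outer(act_v, tt, function(a, t) t - a),
               upstroke_tau = upstroke_tau, apd = apd,
               rest = config$ap_rest, amp = config$ap_amp,
               plateau_frac = config$plateau_frac)
  gain <- config$amp_scale *
    (1 + config$sigma_ratio) / (1 + config$sigma_ratio * coupling)
  phi_beat <- gain * (W %*% S - rowSums(W) %o% colMeans(S))

  pacing <- pacing_protocol(cycle_length = config$cycle_length,
                            n_beats = config$n_beats, strict = FALSE)
  total <- ceiling((max(pacing$stimulus_times) + config$cycle_length) * fs / 1000)
  samples <- matrix(0, nrow = nrow(el), ncol = total)
  for (st in pacing$stimulus_times) {
    i0 <- round(st * fs / 1000) + 1L
    cols <- i0:(i0 + ncol(phi_beat) - 1L)
    keep <- cols <= total
    samples[, cols[keep]] <- samples[, cols[keep]] + phi_beat[, keep]
  }
  egm_recording(samples = samples, fs = fs, grid = grid, pacing = pacing,
                site_index = site_index, condition = condition,
                dose_ml = dose_ml, heart_id = heart_id)
}

#' Add acquisition artefacts and noise
#'
#' Adds, in order: a two-sample biphasic stimulus artefact (+`stim_amp_mV`
#' then -`stim_amp_mV`) at each stimulus time on every channel; i.i.d.
#' Gaussian noise of SD `noise_sd_mV`; and 0.5 Hz sinusoidal baseline wander
#' of amplitude `wander_amp_mV` with a random phase per channel.
#' Deterministic given the RNG state.
#'
#' @param rec A noise-free [egm_recording()].
#' @param config A [simulation_config()].
#' @return The corrupted recording.
#' @export
add_artifacts_and_noise <- function(rec, config) {
  x <- rec$samples
  nch <- nrow(x); nt <- ncol(x)
  if (config$stim_amp_mV != 0) {
    for (st in rec$pacing$stimulus_times) {
      i0 <- round(st * rec$fs / 1000) + 1L
      if (i0 <= nt) x[, i0] <- x[, i0] + config$stim_amp_mV
      if (i0 + 1L <= nt) x[, i0 + 1L] <- x[, i0 + 1L] - config$stim_amp_mV
    }
  }
  if (config$noise_sd_mV > 0) {
    x <- x + matrix(rnorm(nch * nt, sd = config$noise_sd_mV), nch, nt)
  }
  if (config$wander_amp_mV > 0) {
    tt <- (seq_len(nt) - 1) / rec$fs
    phase <- runif(nch, 0, 2 * pi)
    x <- x + config$wander_amp_mV *
      sin(outer(rep(2 * pi * 0.5, nch), tt) + phase)
  }
  rec$samples <- x
  rec
}
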