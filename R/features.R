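#' Acquisition-band preprocessing
#'
#' Zero-phase (forward-backward) 2nd-order Butterworth high-pass at the
#' acquisition band's lower corner (0.3 Hz by default), removing DC offset
#' and slow baseline drift without group delay, plus an optional mains notch.
#' Recordings not sampled at 1 kHz are resampled first; sampling rates below
#' 600 Hz cannot honour the 0.3-500 Hz band and are rejected.
#'
#' @param rec An [egm_recording()].
#' @param acfg An [analysis_config()].
#' @return The filtered recording.
#' @export
preprocess <- function(rec, acfg = analysis_config()) {
  validate_recording(rec)
  if (rec$fs < 600) {
    stop("sampling error: fs ", rec$fs, " Hz cannot honour the 0.3-500 Hz band",
         call. = FALSE)
  }
  if (rec$fs != 1000) {
    p <- 1000; q <- rec$fs
    k <- gcd_int(p, q)
    res <- t(apply(rec$samples, 1, function(ch) {
      signal::resample(ch, p = p / k, q = q / k)
    }))
    rec$samples <- res
    rec$fs <- 1000
  }
  hp <- signal::butter(2, acfg$hp_cutoff_hz / (rec$fs / 2), type = "high")
  pad <- round(rec$fs / acfg$hp_cutoff_hz)  # one corner period of padding
  rec$samples <- t(apply(rec$samples, 1, function(ch) {
    filtfilt_padded(hp, ch - mean(ch), pad)
  }))
  if (!is.null(acfg$notch_hz)) {
    bs <- signal::butter(2, c(acfg$notch_hz - 2, acfg$notch_hz + 2) / (rec$fs / 2),
                         type = "stop")
    rec$samples <- t(apply(rec$samples, 1, function(ch) {
      filtfilt_padded(bs, ch, round(rec$fs / acfg$notch_hz) * 4)
    }))
  }
  rec
}

# Zero-phase filtering with odd-reflection end padding, which suppresses the
# start/end transients of the slow high-pass corner.
filtfilt_padded <- function(filt, x, pad) {
  n <- length(x)
  p <- min(n - 1L, pad)
  left <- 2 * x[1] - x[(p + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - p)]
  y <- signal::filtfilt(filt, c(left, x, right))
  y[(p + 1L):(p + n)]
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Detect pacing stimulus times
#'
#' If the recording carries pacing metadata, those times are returned
#' verbatim. Otherwise stimuli are detected from the synchronous
#' high-derivative artefact they leave on all channels: samples where
#' `|dV/dt|` exceeds `stim_threshold_factor` times the per-channel median
#' absolute derivative in at least `stim_sync_frac` of the channels at the
#' same sample are flagged, flagged samples are clustered within
#' `stim_cluster_ms`, and clusters are accepted greedily by synchronous
#' channel count subject to a minimum separation of `stim_min_sep_ms` — the
#' separation rule discards the activation complex trailing each stimulus,
#' whose fast deflections are never as synchronous across the grid as the
#' artefact itself.
#'
#' @param rec An [egm_recording()].
#' @param acfg An [analysis_config()].
#' @param use_metadata Return `rec$pacing$stimulus_times` when present.
#' @return Stimulus times, ms.
#' @export
detect_stimuli <- function(rec, acfg = analysis_config(), use_metadata = TRUE) {
  if (use_metadata && length(rec$pacing$stimulus_times)) {
    return(rec$pacing$stimulus_times)
  }
  x <- rec$samples
  d <- t(apply(x, 1, central_diff, fs = rec$fs))
  thr <- apply(abs(d), 1, median) * acfg$stim_threshold_factor
  hits <- abs(d) > thr  # [channels x time]
  count <- colSums(hits)
  need <- ceiling(acfg$stim_sync_frac * nrow(x))
  cand <- which(count >= need)
  if (!length(cand)) stop("detection error: no stimuli found", call. = FALSE)
  gap <- acfg$stim_cluster_ms * rec$fs / 1000
  cl_id <- cumsum(c(1, diff(cand) > gap))
  clusters <- split(cand, cl_id)
  centres <- vapply(clusters, function(ix) ix[which.max(count[ix])], numeric(1))
  scores <- vapply(clusters, function(ix) max(count[ix]), numeric(1))
  ord <- order(scores, decreasing = TRUE)
  sep <- acfg$stim_min_sep_ms * rec$fs / 1000
  accepted <- numeric(0)
  for (k in ord) {
    if (!length(accepted) || all(abs(centres[k] - accepted) >= sep)) {
      accepted <- c(accepted, centres[k])
    }
  }
  sort((accepted - 1) * 1000 / rec$fs)
}

central_diff <- function(v, fs) {
  n <- length(v)
  dt <- 1000 / fs  # ms per sample
  d <- numeric(n)
  if (n >= 3) d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt)
  if (n >= 2) {
    d[1] <- (v[2] - v[1]) / dt
    d[n] <- (v[n] - v[n - 1]) / dt
  }
  d
}

#' Segment a recording into per-channel beat windows
#'
#' One window per (channel, stimulus), running from the stimulus to the next
#' stimulus (the last beat extends one cycle length); windows tile the paced
#' portion of the recording without overlap. Beats truncated by the
#' recording edge to less than `min_beat_ms` are dropped. The window keeps
#' all samples; the post-stimulus blanking is applied later, during landmark
#' search only.
#'
#' @param rec An [egm_recording()].
#' @param stim_times Stimulus times, ms (e.g. from [detect_stimuli()]).
#' @param acfg An [analysis_config()].
#' @return List of `beat_complex` objects.
#' @export
segment_beats <- function(rec, stim_times = detect_stimuli(rec),
                          acfg = analysis_config()) {
  stopifnot(length(stim_times) >= 1)
  fs <- rec$fs
  nt <- ncol(rec$samples)
  ends_ms <- c(stim_times[-1], stim_times[length(stim_times)] +
                 rec$pacing$cycle_length)
  beats <- list()
  for (b in seq_along(stim_times)) {
    i0 <- round(stim_times[b] * fs / 1000) + 1L
    i1 <- min(round(ends_ms[b] * fs / 1000), nt)
    if (i0 > nt) next
    if ((i1 - i0 + 1) * 1000 / fs < acfg$min_beat_ms) next
    for (ch in seq_len(nrow(rec$samples))) {
      beats[[length(beats) + 1L]] <- structure(
        list(samples = rec$samples[ch, i0:i1], fs = fs, stimulus_ms = 0,
             channel = ch, beat_index = b, heart_id = rec$heart_id,
             condition = rec$condition, site_index = rec$site_index,
             cycle_length = rec$pacing$cycle_length),
        class = "beat_complex")
    }
  }
  beats
}

#' Locate morphology landmarks on one beat
#'
#' Operational landmark definitions (all thresholds from the
#' [analysis_config()]):
#' * activation `act_t`: time of the most negative central-difference
#'   derivative after the post-stimulus blanking;
#' * R point: maximum sample between onset and activation;
#' * onset: earliest time before the R point where `|dV/dt|` exceeds
#'   `onset_factor` times a robust (lower-quartile) noise scale of the
#'   derivative for at least `onset_sustain_ms`;
#' * Q point: minimum sample between onset and R (equal to onset on a
#'   monotone rise);
#' * S point: minimum sample within `s_search_ms` after activation;
#' * endpoint: earliest time after S where `|V|` stays below `end_frac` of
#'   the peak-to-peak for `end_quiet_ms`, else the window end.
#'
#' Beats whose peak-to-peak is below `flat_mV` carry no activation complex
#' and return `NULL` (the no-complex flag).
#'
#' @param beat A `beat_complex` from [segment_beats()].
#' @param acfg An [analysis_config()].
#' @return A list of landmark times (ms, relative to the stimulus),
#'   amplitudes (mV), `act_t` and `dvdt_max`, or `NULL` for a flat beat.
#' @export
locate_landmarks <- function(beat, acfg = analysis_config()) {
  v <- beat$samples
  n <- length(v)
  fs <- beat$fs
  dt <- 1000 / fs
  d <- central_diff(v, fs)
  # first index whose central difference is free of the 2-sample artefact
  i0 <- max(3L, floor(acfg$blank_ms / dt) + 2L)
  if (i0 >= n - 2) return(NULL)
  win <- i0:n
  if (diff(range(v[win])) < acfg$flat_mV) return(NULL)

  act_i <- win[which.min(d[win])]
  r_prov <- win[1] - 1L + which.max(v[win[1]:act_i])
  # robust noise scale of the derivative from its lower quartile (for a
  # centred Gaussian, P(|d| <= 0.3186 sd) = 0.25); unlike the median-based
  # MAD this stays a noise estimate when the complex occupies much of the
  # window
  theta_on <- acfg$onset_factor *
    quantile(abs(d), 0.25, names = FALSE) / 0.3186
  need <- max(1L, ceiling(acfg$onset_sustain_ms / dt))
  onset_i <- find_sustained_onset(abs(d), theta_on, i0, r_prov, need)
  r_i <- onset_i - 1L + which.max(v[onset_i:act_i])
  q_i <- onset_i - 1L + which.min(v[onset_i:r_i])
  s_hi <- min(n, act_i + round(acfg$s_search_ms / dt))
  s_i <- act_i - 1L + which.min(v[act_i:s_hi])
  if (s_i <= r_i) s_i <- min(r_i + 1L, n)
  p2p <- diff(range(v[win]))
  theta_end <- acfg$end_frac * p2p
  quiet <- max(1L, round(acfg$end_quiet_ms / dt))
  end_i <- find_endpoint(abs(v), theta_end, s_i, n, quiet)

  ms <- function(i) (i - 1) * dt
  list(onset_t = ms(onset_i), q_t = ms(q_i), r_t = ms(r_i), s_t = ms(s_i),
       end_t = ms(end_i), q_amp = v[q_i], r_amp = v[r_i], s_amp = v[s_i],
       end_amp = v[end_i], act_t = ms(act_i), dvdt_max = -d[act_i],
       onset_i = onset_i, q_i = q_i, r_i = r_i, s_i = s_i, end_i = end_i,
       act_i = act_i)
}

find_sustained_onset <- function(absd, theta, lo, hi, need) {
  if (hi <= lo) return(lo)
  above <- absd[lo:hi] > theta
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= need)
  if (!length(ok)) return(lo)
  lo - 1L + starts[ok[1]]
}

find_endpoint <- function(absv, theta, from, n, quiet) {
  if (from >= n) return(n)
  inside <- absv[(from + 1L):n] < theta
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & (r$lengths >= quiet | ends == length(inside)))
  if (!length(ok)) return(n)
  from + starts[ok[1]]
}

#' Maximal downstroke rate and activation latency
#'
#' `dvdt_max` is the maximal magnitude of the negative slope `-(dV/dt)`
#' (central differences) over the activation complex; its time marks local
#' activation, and the latency is that time relative to the pacing stimulus
#' (time zero of the beat window).
#'
#' @param beat A `beat_complex`.
#' @param landmarks Output of [locate_landmarks()].
#' @return List with `dvdt_max` (mV/ms) and `stim_to_dvdt_latency` (ms).
#' @export
dvdt_and_latency <- function(beat, landmarks) {
  list(dvdt_max = landmarks$dvdt_max,
       stim_to_dvdt_latency = landmarks$act_t - beat$stimulus_ms)
}

#' Fractionation index of one activation complex
#'
#' Number of distinct negative-slope deflections between onset and endpoint:
#' maximal runs of `dV/dt < -frac_threshold * dvdt_max` separated by at
#' least `frac_gap_ms`. A clean biphasic RS complex has a single downstroke
#' and scores 1; wavefront break-up around conduction blocks produces
#' multiple separated downstrokes and higher counts.
#'
#' @param beat A `beat_complex`.
#' @param landmarks Output of [locate_landmarks()].
#' @param acfg An [analysis_config()].
#' @return Integer count (>= 1 whenever a complex was detected).
#' @export
fractionation_index <- function(beat, landmarks, acfg = analysis_config()) {
  d <- central_diff(beat$samples, beat$fs)
  ix <- landmarks$onset_i:landmarks$end_i
  below <- d[ix] < -acfg$frac_threshold * landmarks$dvdt_max
  if (!any(below)) return(1L)
  gap <- max(1L, round(acfg$frac_gap_ms * beat$fs / 1000))
  r <- rle(below)
  # gaps shorter than frac_gap_ms do not separate deflections
  if (length(r$lengths) > 2) {
    interior <- 2:(length(r$lengths) - 1)
    merge <- !r$values[interior] & r$lengths[interior] < gap
    r$values[interior][merge] <- TRUE
    below <- inverse.rle(r)
    r <- rle(below)
  }
  sum(r$values)
}

#' Extract the full feature vector of one beat
#'
#' The nineteen time-domain morphology features plus the
#' stimulus-to-(-dV/dt)max latency. Intervals are differences of landmark
#' times (exact in samples, so `qs_interval = qr_interval + rs_interval`
#' identically); gradients are amplitude differences over intervals; widths
#' are zero-crossing-bounded widths of the deflections containing the R and
#' S points; `amplitude = r_point - s_point`; `rs_ratio = r_point / s_point`.
#' Degenerate zero-length denominators yield `NA` and set the `flagged`
#' attribute.
#'
#' @param beat A `beat_complex`.
#' @param landmarks Optional pre-computed [locate_landmarks()] output.
#' @param acfg An [analysis_config()].
#' @return Named list of the 20 features of [feature_names()], or `NULL`
#'   when the beat carries no complex.
#' @export
extract_features <- function(beat, landmarks = NULL, acfg = analysis_config()) {
  if (is.null(landmarks)) landmarks <- locate_landmarks(beat, acfg)
  if (is.null(landmarks)) return(NULL)
  lm <- landmarks
  v <- beat$samples
  dt <- 1000 / beat$fs
  flagged <- FALSE
  safe_div <- function(num, den) {
    if (!is.finite(den) || den == 0) { flagged <<- TRUE; return(NA_real_) }
    num / den
  }
  qr <- lm$r_t - lm$q_t
  rs <- lm$s_t - lm$r_t
  qs <- lm$s_t - lm$q_t
  dur <- lm$end_t - lm$q_t
  rw <- deflection_width(v, lm$r_i, dt, lm$onset_i, lm$end_i)
  sw <- deflection_width(v, lm$s_i, dt, lm$onset_i, lm$end_i)
  lat <- dvdt_and_latency(beat, lm)
  out <- list(
    rs_interval = rs, qr_interval = qr, qs_interval = qs, egm_duration = dur,
    q_point = lm$q_amp, r_point = lm$r_amp, s_point = lm$s_amp,
    endpoint_amplitude = lm$end_amp,
    rs_gradient = safe_div(lm$s_amp - lm$r_amp, rs),
    qr_gradient = safe_div(lm$r_amp - lm$q_amp, qr),
    s_endpoint_gradient = safe_div(lm$end_amp - lm$s_amp, lm$end_t - lm$s_t),
    fractionation_index = as.numeric(fractionation_index(beat, lm, acfg)),
    r_width = rw, s_width = sw,
    rs_ratio = safe_div(lm$r_amp, lm$s_amp),
    rs_width_ratio = safe_div(rw, sw),
    rs_width_over_duration = safe_div(rw + sw, dur),
    dvdt_max = lat$dvdt_max, amplitude = lm$r_amp - lm$s_amp,
    stim_to_dvdt_latency = lat$stim_to_dvdt_latency
  )
  attr(out, "flagged") <- flagged
  out
}

# Width (ms) of the deflection containing index i, bounded by the nearest
# zero crossings on each side within the complex [lo, hi] (complex edges if
# none); at least one sample. Bounding inside the complex keeps
# r_width + s_width <= egm_duration up to the shared crossing sample.
deflection_width <- function(v, i, dt, lo = 1L, hi = length(v)) {
  s <- sign(v[i])
  if (s == 0) return(dt)
  opp <- which(sign(v[lo:hi]) != s) + lo - 1L
  left <- opp[opp < i]
  right <- opp[opp > i]
  li <- if (length(left)) max(left) else lo
  ri <- if (length(right)) min(right) else hi
  max(ri - li, 1L) * dt
}

#' Extract a per-beat feature table from a set of recordings
#'
#' Runs the full morphology pipeline — preprocessing, stimulus times, beat
#' segmentation, landmarks, features — over every recording and returns the
#' long-format study table: six key columns plus the twenty features of
#' [feature_names()], one row per analysable beat x channel. Beats flagged
#' no-complex are excluded (not zero-filled).
#'
#' @param recordings A list of [egm_recording()]s, or an `egm_study`.
#' @param acfg An [analysis_config()].
#' @param preprocessed Set `TRUE` if the recordings are already filtered.
#' @return A tibble.
#' @export
extract_study_features <- function(recordings, acfg = analysis_config(),
                                   preprocessed = FALSE) {
  if (inherits(recordings, "egm_study")) recordings <- recordings$recordings
  if (inherits(recordings, "egm_recording")) recordings <- list(recordings)
  rows <- vector("list", 0L)
  for (rec in recordings) {
    if (!preprocessed) rec <- preprocess(rec, acfg)
    stim <- detect_stimuli(rec, acfg)
    beats <- segment_beats(rec, stim, acfg)
    for (beat in beats) {
      f <- extract_features(beat, acfg = acfg)
      if (is.null(f)) next
      rows[[length(rows) + 1L]] <- c(
        list(heart_id = beat$heart_id, condition = beat$condition,
             site_index = beat$site_index, channel = beat$channel,
             beat_index = beat$beat_index, cycle_length = beat$cycle_length),
        f)
    }
  }
  if (!length(rows)) {
    cols <- c(study_key_columns(), feature_names())
    tbl <- as.data.frame(matrix(numeric(0), nrow = 0, ncol = length(cols)))
    names(tbl) <- cols
    return(tibble::as_tibble(tbl))
  }
  dplyr::bind_rows(lapply(rows, tibble::as_tibble))
}
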