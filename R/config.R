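#' Simulation configuration
#'
#' Parameters of the synthetic EGM generator. The tissue is a square lattice
#' of `grid_n` x `grid_n` nodes spaced `dx` mm apart; conduction velocity at
#' full coupling is `base_cv` mm/ms and scales with the square root of the
#' coupling factor, as in continuous cable theory. Uncoupling additionally
#' (i) adds log-normal spatial heterogeneity to the velocity field,
#' (ii) sprinkles near-zero-velocity micro-patches, and (iii) widens the
#' local action-potential upstroke by `1/sqrt(c)`, which lowers the maximal
#' downstroke rate seen in the electrogram.
#'
#' `heterogeneity_sd` and `patch_block_prob` default to `NULL`, meaning they
#' scale with the degree of uncoupling: `0.6 * (1 - c)` and `0.08 * (1 - c)`
#' respectively, so a fully coupled tissue is homogeneous.
#'
#' @param grid_n Nodes per side of the tissue lattice.
#' @param dx Node spacing, mm.
#' @param base_cv Conduction velocity at full coupling, mm/ms.
#' @param coupling_factor Baseline coupling factor `c` in (0, 1].
#' @param c_drug Coupling factor reached at the maximal drug effect.
#' @param heterogeneity_sd Log-scale SD of the velocity multiplier field, or
#'   `NULL` for the uncoupling-scaled default.
#' @param patch_block_prob Per-node probability of lying inside a
#'   conduction-block micro-patch, or `NULL` for the uncoupling-scaled
#'   default.
#' @param patch_radius_mm Radius of a block micro-patch, mm. Patches are
#'   discs (conduction discontinuities have mm-scale spatial extent; a
#'   wavefront must detour around them, which is what breaks complexes into
#'   multiple deflections); a radius below `dx` reduces to independent
#'   single-node blocks.
#' @param cv_floor Velocity assigned inside block patches, mm/ms (> 0).
#' @param ap_rest Resting potential, mV.
#' @param ap_amp Action-potential amplitude, mV.
#' @param upstroke_tau Upstroke duration at full coupling, ms.
#' @param apd_v,apd_a Action-potential duration for ventricular and atrial
#'   sites, ms.
#' @param plateau_frac Fraction of the APD spent at plateau before the
#'   repolarization ramp.
#' @param amp_scale Forward-model gain; the default is calibrated so that the
#'   mean baseline peak-to-peak electrogram amplitude under the default
#'   configuration is about 6.5 mV.
#' @param sigma_ratio Ratio of intracellular to interstitial bulk
#'   conductivity. Blocking gap junctions removes the intracellular pathway
#'   from the bulk tissue conductivity, so extracellular deflections grow by
#'   `(1 + sigma_ratio) / (1 + sigma_ratio * c)` as coupling `c` falls.
#' @param stim_amp_mV Stimulus-artefact amplitude, mV.
#' @param noise_sd_mV Additive Gaussian noise SD, mV.
#' @param wander_amp_mV Amplitude of 0.5 Hz sinusoidal baseline wander, mV.
#' @param cycle_length Pacing cycle length, ms.
#' @param n_beats Beats per recording.
#' @param site_jitter_mm SD of the random per-site catheter translation, mm.
#' @param site_rot_sd SD of the random per-site catheter rotation, radians.
#' @param d50_ml,hill Midpoint (ml) and slope of the Hill mapping from
#'   cumulative dose to coupling factor.
#' @param seed Integer seed for the generator's single RNG stream.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(grid_n = 80L, dx = 0.5, base_cv = 0.6,
                              coupling_factor = 1, c_drug = 0.35,
                              heterogeneity_sd = NULL, patch_block_prob = NULL,
                              patch_radius_mm = 1.5, cv_floor = 1e-3,
                              ap_rest = -80, ap_amp = 100, upstroke_tau = 5,
                              apd_v = 250, apd_a = 150, plateau_frac = 0.6,
                              amp_scale = 0.00546, sigma_ratio = 2,
                              stim_amp_mV = 5, noise_sd_mV = 0.03,
                              wander_amp_mV = 0.2,
                              cycle_length = 750, n_beats = 4L,
                              site_jitter_mm = 2, site_rot_sd = 0.15,
                              d50_ml = 25, hill = 3, seed = 1L) {
  cfg <- list(
    grid_n = as.integer(grid_n), dx = dx, base_cv = base_cv,
    coupling_factor = coupling_factor, c_drug = c_drug,
    heterogeneity_sd = heterogeneity_sd, patch_block_prob = patch_block_prob,
    patch_radius_mm = patch_radius_mm,
    cv_floor = cv_floor, ap_rest = ap_rest, ap_amp = ap_amp,
    upstroke_tau = upstroke_tau, apd_v = apd_v, apd_a = apd_a,
    plateau_frac = plateau_frac, amp_scale = amp_scale,
    sigma_ratio = sigma_ratio,
    stim_amp_mV = stim_amp_mV, noise_sd_mV = noise_sd_mV,
    wander_amp_mV = wander_amp_mV, cycle_length = cycle_length,
    n_beats = as.integer(n_beats), site_jitter_mm = site_jitter_mm,
    site_rot_sd = site_rot_sd, d50_ml = d50_ml, hill = hill,
    seed = as.integer(seed)
  )
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  with(cfg, {
    if (!(coupling_factor > 0 && coupling_factor <= 1)) {
      stop("validation error: coupling_factor must be in (0, 1]", call. = FALSE)
    }
    if (!(c_drug > 0 && c_drug <= 1)) {
      stop("validation error: c_drug must be in (0, 1]", call. = FALSE)
    }
    if (base_cv <= 0) stop("validation error: base_cv must be > 0", call. = FALSE)
    if (grid_n < 3) stop("validation error: grid_n must be >= 3", call. = FALSE)
    if (noise_sd_mV < 0) stop("validation error: noise_sd_mV must be >= 0", call. = FALSE)
    if (!is.null(heterogeneity_sd) && heterogeneity_sd < 0) {
      stop("validation error: heterogeneity_sd must be >= 0", call. = FALSE)
    }
    if (!is.null(patch_block_prob) &&
        (patch_block_prob < 0 || patch_block_prob >= 1)) {
      stop("validation error: patch_block_prob must be in [0, 1)", call. = FALSE)
    }
    if (cv_floor <= 0) stop("validation error: cv_floor must be > 0", call. = FALSE)
    if (patch_radius_mm < 0) {
      stop("validation error: patch_radius_mm must be >= 0", call. = FALSE)
    }
    if (upstroke_tau <= 0) stop("validation error: upstroke_tau must be > 0", call. = FALSE)
    if (sigma_ratio < 0) stop("validation error: sigma_ratio must be >= 0", call. = FALSE)
    if (d50_ml <= 0 || hill <= 0) {
      stop("validation error: d50_ml and hill must be > 0", call. = FALSE)
    }
  })
  invisible(cfg)
}

# Effective heterogeneity / block probability for a given coupling factor.
resolve_heterogeneity <- function(cfg, c) {
  if (is.null(cfg$heterogeneity_sd)) 0.6 * (1 - c) else cfg$heterogeneity_sd
}

resolve_block_prob <- function(cfg, c) {
  if (is.null(cfg$patch_block_prob)) 0.08 * (1 - c) else cfg$patch_block_prob
}

#' Analysis configuration
#'
#' Operational thresholds of the morphology pipeline. Each landmark and
#' detection rule is exposed as a named parameter so alternative definitions
#' can be tested.
#'
#' @param hp_cutoff_hz High-pass corner of the zero-phase acquisition-band
#'   filter, Hz.
#' @param notch_hz Mains notch centre frequency, Hz, or `NULL` to disable.
#' @param stim_threshold_factor Stimulus detection threshold as a multiple of
#'   the median absolute derivative.
#' @param stim_sync_frac Fraction of channels that must cross the stimulus
#'   threshold at the same sample.
#' @param stim_cluster_ms Clustering window for flagged samples, ms.
#' @param stim_min_sep_ms Minimum separation between accepted stimuli, ms;
#'   among conflicting clusters the one with the larger synchronous channel
#'   count wins, which rejects activation complexes trailing each stimulus.
#' @param blank_ms Post-stimulus blanking applied to the landmark search, ms.
#' @param min_beat_ms Beats shorter than this are dropped at recording edges.
#' @param onset_factor Onset threshold as a multiple of the robust noise
#'   scale of the derivative.
#' @param onset_sustain_ms Minimum time the derivative must stay above the
#'   onset threshold, ms.
#' @param end_frac Endpoint threshold as a fraction of peak-to-peak.
#' @param end_quiet_ms Time the signal must stay inside the endpoint
#'   threshold, ms.
#' @param s_search_ms Search window after activation for the S trough, ms.
#' @param flat_mV Peak-to-peak below which a beat is flagged no-complex, mV.
#' @param frac_threshold Fractionation threshold as a fraction of the beat's
#'   maximal downstroke rate.
#' @param frac_gap_ms Minimum gap separating two counted deflections, ms.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(hp_cutoff_hz = 0.3, notch_hz = NULL,
                            stim_threshold_factor = 10, stim_sync_frac = 0.5,
                            stim_cluster_ms = 5, stim_min_sep_ms = 250,
                            blank_ms = 2, min_beat_ms = 50,
                            onset_factor = 5, onset_sustain_ms = 2,
                            end_frac = 0.1, end_quiet_ms = 10,
                            s_search_ms = 100, flat_mV = 0.1,
                            frac_threshold = 0.1, frac_gap_ms = 1) {
  cfg <- list(
    hp_cutoff_hz = hp_cutoff_hz, notch_hz = notch_hz,
    stim_threshold_factor = stim_threshold_factor,
    stim_sync_frac = stim_sync_frac, stim_cluster_ms = stim_cluster_ms,
    stim_min_sep_ms = stim_min_sep_ms, blank_ms = blank_ms,
    min_beat_ms = min_beat_ms, onset_factor = onset_factor,
    onset_sustain_ms = onset_sustain_ms, end_frac = end_frac,
    end_quiet_ms = end_quiet_ms, s_search_ms = s_search_ms,
    flat_mV = flat_mV, frac_threshold = frac_threshold,
    frac_gap_ms = frac_gap_ms
  )
  stopifnot(cfg$hp_cutoff_hz > 0, cfg$blank_ms >= 0, cfg$flat_mV >= 0,
            cfg$frac_threshold > 0, cfg$frac_threshold < 1,
            cfg$stim_sync_frac > 0, cfg$stim_sync_frac <= 1)
  class(cfg) <- "analysis_config"
  cfg
}

#' Load simulation and analysis configuration from YAML or JSON
#'
#' Absent keys fall back to the package defaults; every supplied parameter is
#' validated against its type invariants. The document may contain top-level
#' keys `simulation:` and `analysis:`, or a flat mixture of both parameter
#' sets.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return List with elements `simulation` ([simulation_config()]) and
#'   `analysis` ([analysis_config()]).
#' @export
load_config <- function(path) {
  stopifnot(file.exists(path))
  ext <- tolower(tools::file_ext(path))
  doc <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format: ", ext, call. = FALSE)
  )
  if (is.null(doc)) doc <- list()
  sim_keys <- names(formals(simulation_config))
  ana_keys <- names(formals(analysis_config))
  sim_args <- doc[["simulation"]]
  ana_args <- doc[["analysis"]]
  if (is.null(sim_args) && is.null(ana_args)) {
    unknown <- setdiff(names(doc), c(sim_keys, ana_keys))
    if (length(unknown)) {
      stop("validation error: unknown config keys: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    sim_args <- doc[intersect(names(doc), sim_keys)]
    ana_args <- doc[intersect(names(doc), ana_keys)]
  }
  list(
    simulation = do.call(simulation_config, as.list(sim_args)),
    analysis = do.call(analysis_config, as.list(ana_args))
  )
}

# Run `code` with a temporarily seeded RNG, restoring the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
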