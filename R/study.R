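#' Simulate a paired baseline / uncoupled mapping study
#'
#' Emulates the acquisition layout of an ex vivo whole-heart mapping
#' experiment: 16 catheter placements ("sites"), sites 1-12 ventricular
#' (long APD), 13-16 atrial (short APD), each recorded once at baseline
#' (coupling factor 1) and once under the gap-junction uncoupler (coupling
#' factor `c_drug`), with identical electrode placement and pacing in both
#' conditions. Per site the catheter gets a small random translation and
#' rotation about the tissue centre; the tissue's spatial random structure
#' (heterogeneity field and block-patch draw) is shared between the two
#' conditions, so the drug recording is the same tissue, uncoupled.
#' Uncoupling also widens the local upstroke by `1/sqrt(c)`, lowering the
#' maximal electrogram downstroke rate.
#'
#' All randomness comes from one RNG stream seeded with `seed`, so a study
#' is byte-reproducible.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @param n_sites Number of catheter placements (16 in the standard layout).
#' @return List with `recordings` (list of `2 * n_sites`
#'   [egm_recording()]s, baseline first within each site), `config`, `seed`;
#'   class `egm_study`.
#' @export
simulate_paired_study <- function(config = simulation_config(),
                                  seed = config$seed, n_sites = 16L) {
  stopifnot(config$coupling_factor == 1, config$c_drug <= 1)
  with_seed(seed, {
    act_unit <- unit_activation_map(config)
    recordings <- vector("list", 2L * n_sites)
    for (site in seq_len(n_sites)) {
      grid <- site_grid(config)
      apd <- if (site_region(site) == "LV") config$apd_v else config$apd_a
      gmat <- matrix(rnorm(config$grid_n^2), config$grid_n, config$grid_n)
      umat <- matrix(runif(config$grid_n^2), config$grid_n, config$grid_n)
      for (k in 1:2) {
        cond <- c("BL", "CBX")[k]
        cc <- if (cond == "BL") 1 else config$c_drug
        act <- site_activation(config, cc, gmat, umat, act_unit)
        rec <- forward_egm(
          act, grid, config, apd = apd,
          upstroke_tau = config$upstroke_tau / sqrt(cc), coupling = cc,
          site_index = site, condition = cond,
          dose_ml = if (cond == "BL") 0 else 50, heart_id = "H01"
        )
        rec <- add_artifacts_and_noise(rec, config)
        recordings[[(site - 1L) * 2L + k]] <- rec
      }
    }
    structure(list(recordings = recordings, config = config, seed = seed),
              class = "egm_study")
  })
}

# Activation map for a unit (1 mm/ms) uniform field; for any uniform field
# the map is this divided by the velocity, which skips the per-site
# shortest-path solve in homogeneous (fully coupled) conditions.
unit_activation_map <- function(config) {
  unit <- matrix(1, config$grid_n, config$grid_n)
  compute_activation_map(unit, pacing_node = c(1L, 1L), dx = config$dx)
}

site_activation <- function(config, cc, gmat, umat, act_unit) {
  if (resolve_heterogeneity(config, cc) == 0 &&
      resolve_block_prob(config, cc) == 0) {
    act <- act_unit
    act$times <- act_unit$times / (config$base_cv * sqrt(cc))
    return(act)
  }
  field <- build_velocity_field(config, c = cc, g = gmat, u = umat)
  compute_activation_map(field, pacing_node = c(1L, 1L), dx = config$dx)
}

# Random per-site catheter placement: the 4x4 grid centred over the tissue,
# jittered and rotated.
site_grid <- function(config) {
  extent <- (config$grid_n - 1) * config$dx
  centre <- extent / 2
  span <- 3 * 3  # 4x4 grid at 3 mm pitch
  jitter <- rnorm(2, sd = config$site_jitter_mm)
  electrode_grid(
    rows = 4L, cols = 4L, pitch = 3, height = 0.5,
    origin = c(centre - span / 2 + jitter[1], centre - span / 2 + jitter[2]),
    angle = rnorm(1, sd = config$site_rot_sd)
  )
}

#' Map cumulative uncoupler dose to coupling factor
#'
#' Hill-type dose-effect relation
#' `c(d) = 1 - (1 - c_drug) * d^h / (d50^h + d^h)`: no effect at zero dose,
#' half the maximal uncoupling at `d50`, saturating at `c_drug`.
#'
#' @param dose_ml Cumulative dose, ml (non-negative).
#' @param c_drug Coupling factor at maximal effect.
#' @param d50_ml Half-effect dose, ml.
#' @param hill Hill slope.
#' @return Coupling factor(s) in (0, 1].
#' @export
dose_to_coupling <- function(dose_ml, c_drug = 0.35, d50_ml = 25, hill = 3) {
  stopifnot(all(dose_ml >= 0), c_drug > 0, c_drug <= 1, d50_ml > 0, hill > 0)
  effect <- dose_ml^hill / (d50_ml^hill + dose_ml^hill)
  effect[dose_ml == 0] <- 0
  1 - (1 - c_drug) * effect
}

#' Simulate recordings along an uncoupler dose escalation
#'
#' One recording per cumulative dose at a single fixed catheter placement.
#' The tissue's spatial random structure is frozen across doses, so
#' successive recordings show the same tissue at a progressively lower
#' coupling factor given by [dose_to_coupling()].
#'
#' @param config A [simulation_config()].
#' @param doses_ml Non-negative, increasing cumulative doses, ml.
#' @param seed Integer seed; defaults to `config$seed`.
#' @param site_index Catheter site used for the escalation.
#' @return List with `recordings` (one per dose), `doses_ml`, `coupling`,
#'   `config`, `seed`; class `egm_dose_series`.
#' @export
simulate_dose_response <- function(config = simulation_config(),
                                   doses_ml = seq(0, 50, by = 5),
                                   seed = config$seed, site_index = 1L) {
  stopifnot(all(doses_ml >= 0), !is.unsorted(doses_ml, strictly = TRUE))
  with_seed(seed, {
    act_unit <- unit_activation_map(config)
    grid <- site_grid(config)
    apd <- if (site_region(site_index) == "LV") config$apd_v else config$apd_a
    gmat <- matrix(rnorm(config$grid_n^2), config$grid_n, config$grid_n)
    umat <- matrix(runif(config$grid_n^2), config$grid_n, config$grid_n)
    cc <- dose_to_coupling(doses_ml, config$c_drug, config$d50_ml, config$hill)
    recordings <- vector("list", length(doses_ml))
    for (k in seq_along(doses_ml)) {
      act <- site_activation(config, cc[k], gmat, umat, act_unit)
      rec <- forward_egm(
        act, grid, config, apd = apd,
        upstroke_tau = config$upstroke_tau / sqrt(cc[k]), coupling = cc[k],
        site_index = site_index,
        condition = if (doses_ml[k] == 0) "BL" else "CBX",
        dose_ml = doses_ml[k], heart_id = "H01"
      )
      recordings[[k]] <- add_artifacts_and_noise(rec, config)
    }
    structure(list(recordings = recordings, doses_ml = doses_ml,
                   coupling = cc, config = config, seed = seed),
              class = "egm_dose_series")
  })
}
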