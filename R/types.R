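#' Electrode grid geometry
#'
#' Describes a rectangular multielectrode grid catheter lying over the tissue
#' plane, by default the 4x4 high-density grid used for epicardial mapping.
#' Channel 1 sits at the origin corner and channels are numbered row-major
#' across the grid.
#'
#' @param rows,cols Grid dimensions (electrode count = `rows * cols`).
#' @param pitch Inter-electrode spacing in mm.
#' @param height Electrode height above the tissue plane in mm; must be
#'   strictly positive for the forward model (a contact electrode is modelled
#'   a small distance above the current sources).
#' @param origin Numeric length-2, xy position (mm) of electrode 1 before
#'   rotation.
#' @param angle Rotation of the grid about its centroid, radians.
#' @return An object of class `electrode_grid`.
#' @export
electrode_grid <- function(rows = 4L, cols = 4L, pitch = 3, height = 0.5,
                           origin = c(0, 0), angle = 0) {
  stopifnot(rows >= 1, cols >= 1, pitch > 0, height >= 0,
            length(origin) == 2, is.finite(angle))
  structure(
    list(rows = as.integer(rows), cols = as.integer(cols), pitch = pitch,
         height = height, origin = as.numeric(origin), angle = angle),
    class = "electrode_grid"
  )
}

#' Electrode xy positions in mm
#'
#' Row-major channel order: channel 1 at the origin corner, then across the
#' first row. Rotation is applied about the grid centroid.
#'
#' @param grid An [electrode_grid()].
#' @return Matrix `[n_electrodes x 2]` of xy coordinates (mm).
#' @export
electrode_positions <- function(grid) {
  stopifnot(inherits(grid, "electrode_grid"))
  xy <- expand.grid(
    col = seq_len(grid$cols) - 1L,
    row = seq_len(grid$rows) - 1L
  )
  # expand.grid varies col fastest -> row-major channel order
  x <- grid$origin[1] + xy$col * grid$pitch
  y <- grid$origin[2] + xy$row * grid$pitch
  if (grid$angle != 0) {
    cx <- mean(range(x)); cy <- mean(range(y))
    ca <- cos(grid$angle); sa <- sin(grid$angle)
    xr <- cx + ca * (x - cx) - sa * (y - cy)
    yr <- cy + sa * (x - cx) + ca * (y - cy)
    x <- xr; y <- yr
  }
  cbind(x = x, y = y)
}

#' Pacing protocol
#'
#' @param cycle_length Pacing cycle length in ms. The acquisition protocol
#'   uses cycle lengths 300, 400, 500, 660, 750, 1000 or 1500 ms; other
#'   values are accepted with `strict = FALSE`.
#' @param n_beats Number of stimuli.
#' @param start_ms Time of the first stimulus (ms from recording start).
#' @param stimulus_times Explicit stimulus times (ms), overriding
#'   `n_beats`/`start_ms`. Must be strictly increasing.
#' @param pacing_site_label Free-text label of the pacing site.
#' @param strict Enforce membership of `cycle_length` in the standard set.
#' @return An object of class `pacing_protocol`.
#' @export
pacing_protocol <- function(cycle_length = 750, n_beats = 4L, start_ms = 20,
                            stimulus_times = NULL,
                            pacing_site_label = "LV base", strict = TRUE) {
  standard <- c(300, 400, 500, 660, 750, 1000, 1500)
  if (strict && !cycle_length %in% standard) {
    stop("cycle_length ", cycle_length, " is not one of the standard cycle ",
         "lengths (", paste(standard, collapse = ", "),
         "); use strict = FALSE to override", call. = FALSE)
  }
  if (is.null(stimulus_times)) {
    stimulus_times <- start_ms + (seq_len(n_beats) - 1) * cycle_length
  }
  stopifnot(length(stimulus_times) >= 1, !is.unsorted(stimulus_times, strictly = TRUE))
  if (length(stimulus_times) > 1) {
    gaps <- diff(stimulus_times)
    if (any(abs(gaps - cycle_length) > 1)) {
      stop("consecutive stimulus times must differ by cycle_length within 1 ms",
           call. = FALSE)
    }
  }
  structure(
    list(cycle_length = cycle_length, stimulus_times = as.numeric(stimulus_times),
         pacing_site_label = pacing_site_label),
    class = "pacing_protocol"
  )
}

#' Region for a recording site
#'
#' Sites 1-12 lie on the left-ventricular epicardium, 13-16 on the
#' left-atrial epicardium.
#'
#' @param site_index Integer in 1..16.
#' @return `"LV"` or `"LA"`.
#' @export
site_region <- function(site_index) {
  stopifnot(site_index >= 1, site_index <= 16)
  ifelse(site_index <= 12, "LV", "LA")
}

#' Multichannel unipolar EGM recording
#'
#' @param samples Numeric matrix `[channels x time]`, mV.
#' @param fs Sampling rate, Hz.
#' @param grid An [electrode_grid()]; `nrow(samples)` must equal its
#'   electrode count.
#' @param pacing A [pacing_protocol()].
#' @param site_index Recording site 1..16.
#' @param condition `"BL"` (baseline) or `"CBX"` (uncoupled).
#' @param dose_ml Cumulative drug dose in ml (0 at baseline).
#' @param heart_id Identifier of the heart the recording belongs to.
#' @return An object of class `egm_recording`.
#' @export
egm_recording <- function(samples, fs = 1000, grid = electrode_grid(),
                          pacing = pacing_protocol(), site_index = 1L,
                          condition = c("BL", "CBX"), dose_ml = 0,
                          heart_id = "H01") {
  condition <- match.arg(condition)
  rec <- structure(
    list(samples = samples, fs = fs, grid = grid, pacing = pacing,
         site_index = as.integer(site_index),
         region = site_region(site_index), condition = condition,
         dose_ml = dose_ml, heart_id = heart_id),
    class = "egm_recording"
  )
  validate_recording(rec)
  rec
}

#' Validate an EGM recording
#'
#' Checks the container invariants: positive sampling rate, channel count
#' equal to the grid electrode count, finite samples, and consistency of
#' region with site index.
#'
#' @param rec An `egm_recording`.
#' @return `rec`, invisibly; errors otherwise.
#' @export
validate_recording <- function(rec) {
  stopifnot(inherits(rec, "egm_recording"))
  if (!is.matrix(rec$samples) || !is.numeric(rec$samples)) {
    stop("samples must be a numeric [channels x time] matrix", call. = FALSE)
  }
  if (rec$fs <= 0) stop("fs must be positive", call. = FALSE)
  n_el <- rec$grid$rows * rec$grid$cols
  if (nrow(rec$samples) != n_el) {
    stop("shape error: ", nrow(rec$samples), " channels but grid has ",
         n_el, " electrodes", call. = FALSE)
  }
  if (anyNA(rec$samples) || any(!is.finite(rec$samples))) {
    stop("samples contain NA or non-finite values", call. = FALSE)
  }
  if (rec$region != site_region(rec$site_index)) {
    stop("region inconsistent with site_index", call. = FALSE)
  }
  if (!rec$condition %in% c("BL", "CBX")) stop("unknown condition", call. = FALSE)
  invisible(rec)
}

#' @export
print.egm_recording <- function(x, ...) {
  cat(sprintf(
    "<egm_recording> %s site %d (%s) %s, %d ch x %d samples @ %g Hz, CL %g ms\n",
    x$heart_id, x$site_index, x$region, x$condition,
    nrow(x$samples), ncol(x$samples), x$fs, x$pacing$cycle_length))
  invisible(x)
}

#' @export
print.electrode_grid <- function(x, ...) {
  cat(sprintf("<electrode_grid> %dx%d, pitch %g mm, height %g mm\n",
              x$rows, x$cols, x$pitch, x$height))
  invisible(x)
}
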