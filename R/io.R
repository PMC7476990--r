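#' Write an EGM recording to disk
#'
#' Two self-contained single-record formats are supported.
#'
#' `csv`: metadata as `#key=value` header lines (fs, grid geometry, pacing,
#' condition, site, dose), one header row of channel names `ch01..chNN`, then
#' one row per sample with one column per channel. Values are written with
#' full decimal precision (`%.17g`), so a csv round trip is bit-exact.
#'
#' `wfdb`: a WFDB-style record — a plain-text `.hea` header (signal lines
#' plus the same metadata as `#key=value` comment lines) and an interleaved
#' little-endian 16-bit `.dat` file at a gain of `adc_gain` adu/mV. Round
#' trips are exact up to the ADC quantization step `1/adc_gain` mV.
#'
#' @param rec An [egm_recording()].
#' @param path Output path. For `wfdb`, the record base name (with or
#'   without the `.hea` extension).
#' @param format `"csv"` or `"wfdb"`.
#' @param adc_gain ADC gain for `wfdb`, adu per mV.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("csv", "wfdb"),
                            adc_gain = 200) {
  format <- match.arg(format)
  validate_recording(rec)
  if (format == "csv") write_recording_csv(rec, path)
  else write_recording_wfdb(rec, path, adc_gain)
  invisible(path)
}

#' Read an EGM recording written by [write_recording()]
#'
#' @param path Path to the `.csv` file or WFDB record base name / `.hea`.
#' @param format `"csv"` or `"wfdb"`.
#' @return An [egm_recording()].
#' @export
read_recording <- function(path, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  if (format == "csv") read_recording_csv(path) else read_recording_wfdb(path)
}

recording_meta_lines <- function(rec) {
  g <- rec$grid; p <- rec$pacing
  num <- function(x) sprintf("%.17g", x)
  c(
    paste0("#fs=", num(rec$fs)),
    paste0("#rows=", g$rows), paste0("#cols=", g$cols),
    paste0("#pitch=", num(g$pitch)), paste0("#height=", num(g$height)),
    paste0("#origin=", paste(num(g$origin), collapse = ",")),
    paste0("#angle=", num(g$angle)),
    paste0("#cycle_length=", num(p$cycle_length)),
    paste0("#stimulus_times=", paste(num(p$stimulus_times), collapse = ",")),
    paste0("#pacing_site_label=", p$pacing_site_label),
    paste0("#site_index=", rec$site_index),
    paste0("#condition=", rec$condition),
    paste0("#dose_ml=", num(rec$dose_ml)),
    paste0("#heart_id=", rec$heart_id)
  )
}

parse_meta <- function(lines) {
  kv <- sub("^#", "", lines)
  eq <- regexpr("=", kv, fixed = TRUE)
  keys <- substr(kv, 1, eq - 1)
  vals <- substr(kv, eq + 1, nchar(kv))
  setNames(as.list(vals), keys)
}

required_meta <- c("fs", "rows", "cols", "pitch", "height", "cycle_length",
                   "stimulus_times", "condition", "site_index", "dose_ml")

meta_to_recording <- function(meta, samples) {
  missing <- setdiff(required_meta, names(meta))
  if (length(missing)) {
    stop("metadata error: missing header keys: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  nums <- function(k) as.numeric(strsplit(meta[[k]], ",", fixed = TRUE)[[1]])
  grid <- electrode_grid(
    rows = as.integer(meta$rows), cols = as.integer(meta$cols),
    pitch = as.numeric(meta$pitch), height = as.numeric(meta$height),
    origin = if (!is.null(meta$origin)) nums("origin") else c(0, 0),
    angle = if (!is.null(meta$angle)) as.numeric(meta$angle) else 0
  )
  pacing <- pacing_protocol(
    cycle_length = as.numeric(meta$cycle_length),
    stimulus_times = nums("stimulus_times"),
    pacing_site_label = meta$pacing_site_label %||% "unknown",
    strict = FALSE
  )
  egm_recording(
    samples = samples, fs = as.numeric(meta$fs), grid = grid, pacing = pacing,
    site_index = as.integer(meta$site_index), condition = meta$condition,
    dose_ml = as.numeric(meta$dose_ml), heart_id = meta$heart_id %||% "H01"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_recording_csv <- function(rec, path) {
  nch <- nrow(rec$samples)
  header <- paste(sprintf("ch%02d", seq_len(nch)), collapse = ",")
  # one row per sample, columns are channels; %.17g is repr-faithful
  body <- apply(rec$samples, 2, function(col) {
    paste(sprintf("%.17g", col), collapse = ",")
  })
  con <- file(path, open = "wb")  # "wb": byte-identical output across platforms
  on.exit(close(con))
  writeLines(c(recording_meta_lines(rec), header, body), con, sep = "\n")
  invisible(path)
}

read_recording_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta <- parse_meta(lines[is_meta])
  rest <- lines[!is_meta]
  if (length(rest) < 1) stop("metadata error: no channel header row", call. = FALSE)
  ch_names <- strsplit(rest[1], ",", fixed = TRUE)[[1]]
  body <- rest[-1]
  vals <- strsplit(body, ",", fixed = TRUE)
  samples <- matrix(as.numeric(unlist(vals, use.names = FALSE)),
                    nrow = length(ch_names), ncol = length(body))
  meta_to_recording(meta, samples)
}

write_recording_wfdb <- function(rec, path, adc_gain = 200) {
  base <- sub("\\.hea$", "", path)
  rec_name <- basename(base)
  nch <- nrow(rec$samples); nsamp <- ncol(rec$samples)
  adu <- round(rec$samples * adc_gain)
  if (any(abs(adu) > 32767)) {
    stop("I/O error: signal exceeds 16-bit range at gain ", adc_gain,
         call. = FALSE)
  }
  sig_lines <- sprintf("%s.dat 16 %g(0)/mV 16 0 %d 0 0 ch%02d",
                       rec_name, adc_gain, as.integer(adu[, 1]), seq_len(nch))
  hea <- c(sprintf("%s %d %.17g %d", rec_name, nch, rec$fs, nsamp),
           sig_lines, recording_meta_lines(rec))
  con <- file(paste0(base, ".hea"), open = "wb")
  writeLines(hea, con, sep = "\n"); close(con)
  con <- file(paste0(base, ".dat"), open = "wb")
  writeBin(as.integer(adu), con, size = 2, endian = "little")
  close(con)
  invisible(base)
}

read_recording_wfdb <- function(path) {
  base <- sub("\\.hea$", "", path)
  hea_path <- paste0(base, ".hea")
  if (!file.exists(hea_path)) stop("file not found: ", hea_path, call. = FALSE)
  lines <- readLines(hea_path)
  is_meta <- startsWith(lines, "#")
  meta <- parse_meta(lines[is_meta])
  head_fields <- strsplit(lines[1], " +")[[1]]
  nch <- as.integer(head_fields[2])
  nsamp <- as.integer(head_fields[4])
  sig_lines <- lines[!is_meta][1 + seq_len(nch)]
  gains <- vapply(sig_lines, function(l) {
    as.numeric(sub("^\\S+\\s+\\S+\\s+([0-9.eE+-]+)\\(.*$", "\\1", l))
  }, numeric(1), USE.NAMES = FALSE)
  dat_path <- paste0(base, ".dat")
  adu <- readBin(dat_path, what = "integer", size = 2, endian = "little",
                 signed = TRUE, n = nch * nsamp)
  samples <- matrix(as.numeric(adu), nrow = nch) / gains
  meta_to_recording(meta, samples)
}

# --- feature tables ---------------------------------------------------------

study_key_columns <- function() {
  c("heart_id", "condition", "site_index", "channel", "beat_index",
    "cycle_length")
}

#' Canonical feature names
#'
#' The nineteen morphology features in their conventional reporting order,
#' followed by the stimulus-to-(-dV/dt)max latency.
#'
#' @return Character vector of length 20.
#' @export
feature_names <- function() {
  c("rs_interval", "qr_interval", "qs_interval", "egm_duration",
    "q_point", "r_point", "s_point", "endpoint_amplitude",
    "rs_gradient", "qr_gradient", "s_endpoint_gradient",
    "fractionation_index", "r_width", "s_width",
    "rs_ratio", "rs_width_ratio", "rs_width_over_duration",
    "dvdt_max", "amplitude", "stim_to_dvdt_latency")
}

#' Write / read a per-beat feature table
#'
#' Long-format CSV with one row per beat x channel: six key columns
#' (heart_id, condition, site_index, channel, beat_index, cycle_length)
#' followed by the twenty feature columns of [feature_names()], in a fixed
#' order so that two writes of the same table are byte-identical.
#'
#' @param table A tibble as produced by [extract_study_features()].
#' @param path CSV path.
#' @return `path` (write) or the tibble (read).
#' @export
write_feature_table <- function(table, path) {
  cols <- c(study_key_columns(), feature_names())
  missing <- setdiff(cols, names(table))
  if (length(missing)) {
    stop("schema error: missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(table), cols)
  if (length(extra)) {
    stop("schema error: unknown feature columns: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(table)[, cols, drop = FALSE]
  num_cols <- vapply(df, is.numeric, logical(1))
  df[num_cols] <- lapply(df[num_cols], function(x) sprintf("%.17g", x))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(cols, collapse = ","), con, sep = "\n")
  if (nrow(df)) {
    writeLines(do.call(paste, c(as.list(df), sep = ",")), con, sep = "\n")
  }
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  cols <- c(study_key_columns(), feature_names())
  extra <- setdiff(names(df), cols)
  if (length(extra)) {
    stop("schema error: unknown feature columns: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("schema error: missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- df[, cols, drop = FALSE]
  num <- setdiff(cols, c("heart_id", "condition"))
  df[num] <- lapply(df[num], as.numeric)
  df$site_index <- as.integer(df$site_index)
  df$channel <- as.integer(df$channel)
  df$beat_index <- as.integer(df$beat_index)
  tibble::as_tibble(df)
}
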