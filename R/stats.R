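#' Per-feature summary of one condition
#'
#' Arithmetic mean and sample SD (n-1 denominator) of every feature, pooling
#' all beats across hearts, sites and channels; `NA` (undefined-marker)
#' values are excluded feature-wise.
#'
#' @param table A feature tibble from [extract_study_features()].
#' @param condition `"BL"` or `"CBX"`.
#' @return Tibble with columns `feature`, `mean`, `sd`, `n`.
#' @export
summarize_condition <- function(table, condition) {
  sub <- table[table$condition == condition, , drop = FALSE]
  if (nrow(sub) < 2) {
    stop("empty-summary error: fewer than 2 beats in condition ", condition,
         call. = FALSE)
  }
  feats <- feature_names()
  tibble::tibble(
    feature = feats,
    mean = vapply(feats, function(f) mean(sub[[f]], na.rm = TRUE), numeric(1),
                  USE.NAMES = FALSE),
    sd = vapply(feats, function(f) sd(sub[[f]], na.rm = TRUE), numeric(1),
                USE.NAMES = FALSE),
    n = vapply(feats, function(f) sum(!is.na(sub[[f]])), numeric(1),
               USE.NAMES = FALSE)
  )
}

#' Percent change from baseline
#'
#' `100 * (cbx_mean - bl_mean) / |bl_mean|`. The absolute value in the
#' denominator keeps the sign of the change meaningful for features whose
#' baseline mean is negative (a deepening S wave is a negative change).
#' Full precision is returned; round to 2 decimals for reporting.
#'
#' @param bl_mean Baseline mean (non-zero).
#' @param cbx_mean Drug-condition mean.
#' @return Percent change (vectorised); `NA` where `bl_mean` is 0.
#' @export
percent_change <- function(bl_mean, cbx_mean) {
  out <- 100 * (cbx_mean - bl_mean) / abs(bl_mean)
  out[bl_mean == 0] <- NA_real_
  out
}

#' Welch's unequal-variance t-test
#'
#' Two-sided unpaired t-test with Welch-Satterthwaite degrees of freedom,
#' the default comparison between baseline and drug beats (which are not
#' paired one-to-one). Degenerate inputs follow the conventions: two
#' zero-variance samples with equal means give p = 1; zero variance with
#' unequal means gives p = 0 with a warning. Student and paired variants
#' are available through `var_equal`/`paired`.
#'
#' @param x,y Numeric samples (each n >= 2).
#' @param var_equal Use the pooled-variance Student test instead.
#' @param paired Paired test (requires equal lengths).
#' @return List with `t`, `df`, `p`.
#' @export
welch_t_test <- function(x, y, var_equal = FALSE, paired = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (!paired && sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
    }
    warning("zero-variance samples with unequal means; p set to 0")
    return(list(t = sign(mean(x) - mean(y)) * Inf,
                df = length(x) + length(y) - 2, p = 0))
  }
  ht <- t.test(x, y, var.equal = var_equal, paired = paired)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Baseline-versus-drug comparison table
#'
#' The study's statistical arm: one row per feature (nineteen morphology
#' features plus latency, in the canonical order), with condition means and
#' SDs, a two-sided t-test (Welch by default), percent change from baseline,
#' and a significance flag at `alpha`. No multiple-testing correction is
#' applied by default; `adjust = "BH"` switches the significance flag to
#' Benjamini-Hochberg-adjusted p-values.
#'
#' @param table A feature tibble with both conditions present.
#' @param var_equal,paired Passed to [welch_t_test()].
#' @param alpha Significance level.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Tibble with one row per feature; columns `feature`, `bl_mean`,
#'   `bl_sd`, `cbx_mean`, `cbx_sd`, `t_stat`, `df`, `p_value`,
#'   `percent_change`, `significant`.
#' @export
compare_conditions <- function(table, var_equal = FALSE, paired = FALSE,
                               alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  for (cond in c("BL", "CBX")) {
    if (!any(table$condition == cond)) {
      stop("missing condition: ", cond, call. = FALSE)
    }
  }
  bl <- table[table$condition == "BL", , drop = FALSE]
  cbx <- table[table$condition == "CBX", , drop = FALSE]
  feats <- intersect(feature_names(), names(table))
  rows <- lapply(feats, function(f) {
    xb <- bl[[f]][!is.na(bl[[f]])]
    xc <- cbx[[f]][!is.na(cbx[[f]])]
    ht <- welch_t_test(xb, xc, var_equal = var_equal, paired = paired)
    tibble::tibble(
      feature = f,
      bl_mean = mean(xb), bl_sd = sd(xb),
      cbx_mean = mean(xc), cbx_sd = sd(xc),
      t_stat = ht$t, df = ht$df, p_value = ht$p,
      percent_change = percent_change(mean(xb), mean(xc))
    )
  })
  out <- dplyr::bind_rows(rows)
  p_eff <- if (adjust == "BH") p.adjust(out$p_value, method = "BH") else out$p_value
  out$significant <- p_eff < alpha
  out
}

#' Write a comparison table as CSV
#'
#' Fixed column order and full-precision values, so two writes of the same
#' comparison are byte-identical.
#'
#' @param comparison Output of [compare_conditions()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(comparison, path) {
  cols <- c("feature", "bl_mean", "bl_sd", "cbx_mean", "cbx_sd",
            "t_stat", "df", "p_value", "percent_change", "significant")
  df <- as.data.frame(comparison)[, cols, drop = FALSE]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(cols, collapse = ","), con, sep = "\n")
  writeLines(do.call(paste, c(as.list(df), sep = ",")), con, sep = "\n")
  invisible(path)
}

#' Four-parameter logistic dose-response fit
#'
#' Least-squares fit of the sigmoid
#' `L(d) = A + (B - A) / (1 + (d50 / d)^h)` (with `L(0) = A` exactly) to
#' per-dose latency means, optionally weighted by `1/sd^2`. `A` is the
#' zero-dose (baseline) asymptote, `B` the saturating delay, `d50` the
#' half-effect dose and `h` the Hill slope. The fit is run from a multi-start
#' grid over `d50` and `h` (Levenberg-Marquardt on a log parameterization of
#' the positive parameters) and the best converged start is returned.
#'
#' @param doses Increasing doses, ml (>= 5 points).
#' @param latency_means Mean latency per dose, ms.
#' @param latency_sds Optional per-dose SDs for `1/sd^2` weighting.
#' @return List with `doses`, `latency_mean`, `latency_sd`, parameters `A`,
#'   `B`, `d50`, `h`, `rmse` and `fitted`; class `dose_response_fit`.
#' @export
fit_dose_response <- function(doses, latency_means, latency_sds = NULL) {
  stopifnot(length(doses) >= 5, length(latency_means) == length(doses),
            !is.unsorted(doses, strictly = TRUE), all(doses >= 0))
  w <- if (!is.null(latency_sds) && all(latency_sds > 0)) {
    1 / latency_sds^2
  } else {
    rep(1, length(doses))
  }
  f4pl <- function(d, A, B, ld50, lh) {
    # plogis form of 1/(1 + (d50/d)^h); log(0) = -Inf gives exactly A at d = 0
    A + (B - A) * plogis(exp(lh) * (suppressWarnings(log(d)) - ld50))
  }
  span <- diff(range(latency_means))
  if (span == 0) {
    A <- latency_means[1]
    return(structure(list(doses = doses, latency_mean = latency_means,
                          latency_sd = latency_sds, A = A, B = A,
                          d50 = median(doses[doses > 0]), h = 1, rmse = 0,
                          fitted = rep(A, length(doses))),
                     class = "dose_response_fit"))
  }
  pos <- doses[doses > 0]
  starts <- expand.grid(
    ld50 = log(quantile(pos, c(0.25, 0.5, 0.75), names = FALSE)),
    lh = log(c(0.5, 1, 2, 3, 5))
  )
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ f4pl(d, A, B, ld50, lh),
        data = data.frame(d = doses, y = latency_means),
        start = list(A = min(latency_means), B = max(latency_means),
                     ld50 = starts$ld50[i], lh = starts$lh[i]),
        weights = w,
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                             ptol = 1e-15)
      ),
      error = function(e) NULL)
    if (is.null(fit)) next
    dev <- sum(w * resid(fit)^2)
    if (is.null(best) || dev < best$dev) best <- list(fit = fit, dev = dev)
  }
  if (is.null(best)) {
    stop("fit error: dose-response fit did not converge from any start ",
         "(doses: ", paste(doses, collapse = ", "), ")", call. = FALSE)
  }
  cf <- coef(best$fit)
  fitted_vals <- f4pl(doses, cf["A"], cf["B"], cf["ld50"], cf["lh"])
  structure(
    list(doses = doses, latency_mean = latency_means,
         latency_sd = latency_sds,
         A = unname(cf["A"]), B = unname(cf["B"]),
         d50 = exp(unname(cf["ld50"])), h = exp(unname(cf["lh"])),
         rmse = sqrt(mean((fitted_vals - latency_means)^2)),
         fitted = fitted_vals),
    class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(
    "<dose_response_fit> A = %.2f ms, B = %.2f ms, d50 = %.2f ml, h = %.2f, rmse = %.3g ms\n",
    x$A, x$B, x$d50, x$h, x$rmse))
  invisible(x)
}

#' Per-dose latency summary of a dose series
#'
#' Extracts features from every recording of an `egm_dose_series` and
#' returns the mean and SD of the stimulus-to-(-dV/dt)max latency at each
#' dose, pooled over channels and beats.
#'
#' @param series Output of [simulate_dose_response()].
#' @param acfg An [analysis_config()].
#' @return Tibble with `dose_ml`, `latency_mean`, `latency_sd`, `n`.
#' @export
dose_latency_summary <- function(series, acfg = analysis_config()) {
  stopifnot(inherits(series, "egm_dose_series"))
  rows <- lapply(seq_along(series$doses_ml), function(k) {
    tbl <- extract_study_features(list(series$recordings[[k]]), acfg)
    lat <- tbl$stim_to_dvdt_latency
    tibble::tibble(dose_ml = series$doses_ml[k],
                   latency_mean = mean(lat, na.rm = TRUE),
                   latency_sd = sd(lat, na.rm = TRUE),
                   n = sum(!is.na(lat)))
  })
  dplyr::bind_rows(rows)
}
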