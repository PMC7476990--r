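#' Published per-feature reference summary
#'
#' Printed per-feature baseline and carbenoxolone means, SDs, p-values and
#' percentage changes from a published ex vivo whole-heart gap-junction
#' uncoupling study (automated EGM analysis of 5492 beats from porcine and
#' human hearts), shipped as a plain-text table. These are worked-example
#' inputs for the statistics layer — e.g. checking that [percent_change()]
#' applied to the printed condition means reproduces the printed percentage
#' column — not quantities this package's simulations are expected to
#' reproduce.
#'
#' Units: intervals and widths ms, amplitudes mV, gradients mV/ms,
#' `dvdt_max` mV/ms; `fractionation_index` and ratios dimensionless.
#'
#' @return Tibble with columns `feature`, `bl_mean`, `bl_sd`, `cbx_mean`,
#'   `cbx_sd`, `p_printed`, `pct_change_printed`.
#' @export
reference_feature_summary <- function() {
  path <- system.file("extdata", "reference_feature_summary.csv",
                      package = "egmorph", mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  tibble::as_tibble(df)
}
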