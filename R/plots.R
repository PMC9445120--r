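#' Bias and variability bar plot across imaging schedules
#'
#' Grouped bar plot of percent bias and percent variability of Ki or VT per
#' imaging-time combination, one panel pair per call, in the spirit of the
#' per-schedule summaries of sparse-sampling simulation studies. Schedules
#' containing the earliest candidate time point are drawn first.
#'
#' @param summary A [run_grid()] summary restricted to one input function,
#'   one reference parameter pair and one noise level (extra rows are
#'   aggregated by schedule with a warning).
#' @param parameter `"ki"` or `"vt"`.
#' @return The matrix of plotted values, invisibly.
#' @export
plot_bias_variability <- function(summary, parameter = c("ki", "vt")) {
  parameter <- match.arg(parameter)
  key <- paste(summary$t1_h, summary$t2_h, summary$t3_h, sep = "-")
  bias_col <- paste0("bias_", parameter, "_pct")
  var_col <- paste0("variability_", parameter, "_pct")
  if (anyDuplicated(key)) {
    warning("multiple rows per schedule; aggregating by mean")
  }
  bias <- tapply(summary[[bias_col]], key, mean)
  vari <- tapply(summary[[var_col]], key, mean)
  ord <- order(names(bias))
  m <- rbind(bias = bias[ord], variability = vari[ord])
  op <- graphics::par(mar = c(7, 4, 3, 1))
  on.exit(graphics::par(op))
  graphics::barplot(m, beside = TRUE, las = 2,
                    col = c("steelblue", "grey70"),
                    ylab = paste0("% of reference ", toupper(parameter)),
                    main = paste("Bias and variability of",
                                 toupper(parameter), "by schedule"),
                    legend.text = c("bias (%)", "variability (%)"))
  invisible(m)
}
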