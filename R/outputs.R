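# Report rendering: summary tables mirroring the scenario-grid layout and
# per-setting histograms of the hazard-ratio estimates on a log axis.

#' Render summary tables and histograms for a batch of settings
#'
#' Writes (a) `hr_summary.tsv` -- one row per setting with the parameter
#' tuple, median HR, 95% reference interval, min;max and percentage of
#' significant replicates; (b) `incidence_summary.tsv` -- the same layout
#' for the exposure-specific incidence rates; and (c) one histogram of the
#' replicate HR estimates per setting with a logarithmic x axis
#' (`hist_<setting>.pdf`).
#'
#' @param summaries A list of (or single) [summarize_setting()] results.
#' @param results A list of the corresponding [run_setting()] tables
#'   (needed for the histograms); may be `NULL` to skip them.
#' @param dir Output directory, created if missing.
#' @return Character vector of the files written, invisibly.
#' @export
render_outputs <- function(summaries, results = NULL, dir = ".") {
  if (inherits(summaries, "setting_summary")) summaries <- list(summaries)
  if (is.data.frame(results)) results <- list(results)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- do.call(rbind, lapply(summaries, as.data.frame))
  tab <- tab[order(tab$setting_id), , drop = FALSE]

  fmt <- function(x, d = 2) formatC(x, format = "f", digits = d)
  hr_tab <- data.frame(
    setting = tab$setting_id,
    p1 = tab$p1, p2 = tab$p2, p3 = tab$p3, p4 = tab$p4,
    lambda = tab$lambda_reeval,
    HR = fmt(tab$median_hr),
    RI95 = sprintf("(%s;%s)", fmt(tab$ri_low), fmt(tab$ri_high)),
    min_max = sprintf("(%s;%s)", fmt(tab$hr_min), fmt(tab$hr_max)),
    pct_significant = fmt(tab$pct_significant, 1))
  ir_tab <- data.frame(
    setting = tab$setting_id,
    p1 = tab$p1, p2 = tab$p2, p3 = tab$p3, p4 = tab$p4,
    lambda = tab$lambda_reeval,
    IR_tacrolimus = fmt(tab$median_ir_tacro, 3),
    RI95_tacrolimus = sprintf("(%s;%s)", fmt(tab$ir_tacro_ri_low, 3),
                              fmt(tab$ir_tacro_ri_high, 3)),
    min_max_tacrolimus = sprintf("(%s;%s)", fmt(tab$ir_tacro_min, 3),
                                 fmt(tab$ir_tacro_max, 3)),
    IR_TCS = fmt(tab$median_ir_tcs, 3),
    RI95_TCS = sprintf("(%s;%s)", fmt(tab$ir_tcs_ri_low, 3),
                       fmt(tab$ir_tcs_ri_high, 3)),
    min_max_TCS = sprintf("(%s;%s)", fmt(tab$ir_tcs_min, 3),
                          fmt(tab$ir_tcs_max, 3)))

  f_hr <- file.path(dir, "hr_summary.tsv")
  f_ir <- file.path(dir, "incidence_summary.tsv")
  utils::write.table(hr_tab, f_hr, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ir_tab, f_ir, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  written <- c(f_hr, f_ir)

  for (res in results) {
    sid <- res$setting_id[1L]
    f <- file.path(dir, sprintf("hist_%s.pdf", sid))
    grDevices::pdf(f, width = 6, height = 4.5)
    tryCatch(plot_hr_histogram(res$hr, main = sprintf("Setting %s", sid)),
             finally = grDevices::dev.off())
    written <- c(written, f)
  }
  invisible(written)
}

#' Histogram of hazard-ratio estimates on a logarithmic x axis
#'
#' @param hr Replicate hazard-ratio point estimates.
#' @param main Plot title.
#' @param breaks Number of bins (equal width on the log scale).
#' @export
plot_hr_histogram <- function(hr, main = "", breaks = 30) {
  hr <- hr[is.finite(hr) & hr > 0]
  lx <- log(hr)
  h <- graphics::hist(lx, breaks = breaks, plot = FALSE)
  graphics::plot(h, xaxt = "n", main = main,
                 xlab = "Hazard ratio (log scale)", ylab = "Replicates",
                 col = "grey80", border = "grey40")
  at <- pretty(exp(h$breaks), n = 6)
  at <- at[at > 0]
  graphics::axis(1, at = log(at), labels = format(at, drop0trailing = TRUE))
  graphics::abline(v = 0, lty = 2)
  invisible(h)
}
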