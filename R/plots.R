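# Simple static displays of tract-level group results.

#' Plot adjusted tract means as percent difference from controls
#'
#' Diamond-and-bar display of covariate-adjusted group means with 95%
#' confidence intervals, expressed as percent difference from the HC
#' adjusted mean, one panel row per tract.
#'
#' @param analysis Output of [tract_group_analysis()] (its `results`
#'   attribute is used).
#' @param groups Groups to display (default: all non-HC).
#' @param main Plot title.
#' @return Invisibly, the plotted data frame.
#' @export
plot_tract_effects <- function(analysis, groups = NULL, main = "") {
  fits <- attr(analysis, "results")
  rows <- list()
  for (tr in names(fits)) {
    am <- fits[[tr]]$adjusted_means
    hc <- am$mean[am$group == "HC"]
    if (length(hc) != 1) next
    am <- am[am$group != "HC", ]
    rows[[tr]] <- data.frame(
      tract = tr, group = am$group,
      pct = effect_size_percent(am$mean, hc),
      lo = effect_size_percent(am$ci_hi, hc),
      hi = effect_size_percent(am$ci_lo, hc))
  }
  d <- do.call(rbind, rows)
  if (!is.null(groups)) d <- d[d$group %in% groups, ]
  tracts <- unique(d$tract)
  grps <- unique(d$group)
  off <- seq(-0.25, 0.25, length.out = length(grps))
  y <- match(d$tract, tracts) + off[match(d$group, grps)]
  graphics::plot(NA, xlim = range(c(d$lo, d$hi, 0)),
                 ylim = c(0.5, length(tracts) + 0.5),
                 yaxt = "n", xlab = "% difference from HC", ylab = "",
                 main = main)
  graphics::axis(2, at = seq_along(tracts), labels = tracts, las = 1,
                 cex.axis = 0.7)
  graphics::abline(v = 0, lty = 2, col = "grey")
  cols <- grDevices::hcl.colors(length(grps), "Dark 3")
  graphics::segments(d$lo, y, d$hi, y, col = cols[match(d$group, grps)])
  graphics::points(d$pct, y, pch = 18, cex = 1.2,
                   col = cols[match(d$group, grps)])
  graphics::legend("topright", legend = grps, col = cols, pch = 18,
                   bty = "n", cex = 0.8)
  invisible(d)
}
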