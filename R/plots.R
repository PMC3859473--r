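#' Expected versus observed threatened species per order
#'
#' Scatter of the null-expected threatened count against the observed count,
#' one point per tested order, with the identity line; orders flagged as
#' over- or under-represented are highlighted.
#'
#' @param report output of [representation_report()].
#' @param ... passed to [graphics::plot()].
#' @return the report, invisibly.
#' @export
plot_representation <- function(report, ...) {
  r <- report[report$classification != "not_held", , drop = FALSE]
  col <- ifelse(r$classification == "over_represented", "firebrick",
                ifelse(r$classification == "under_represented", "steelblue",
                       "grey40"))
  graphics::plot(r$expected_w, r$w_observed, col = col, pch = 19,
                 xlab = "expected threatened species (random collection)",
                 ylab = "observed threatened species", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(report)
}

#' Attainment-probability and ratio curves for a class
#'
#' Two stacked panels: the species-averaged probability of reaching the
#' threshold as a function of cluster radius, and the probability-to-distance
#' ratio with the optimal radius marked.
#'
#' @param curves per-species `cluster_curve` list for one class/threshold.
#' @param ratio matching `ratio_curve`.
#' @return invisible NULL.
#' @export
plot_cluster_curves <- function(curves, ratio) {
  grid <- ratio$curve$radius_km
  P <- vapply(curves, function(cv) cv$curve$p, numeric(length(grid)))
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  graphics::plot(grid, rowMeans(P), type = "l",
                 xlab = "cluster radius (km)",
                 ylab = sprintf("mean P(N >= %d)", ratio$m),
                 main = sprintf("%s, m = %d (%d species)",
                                ratio$class_name, ratio$m, ratio$n_species))
  graphics::plot(grid, ratio$curve$ratio, type = "l",
                 xlab = "cluster radius (km)", ylab = "probability / distance")
  graphics::abline(v = grid[which.max(ratio$curve$ratio)], lty = 2)
  invisible(NULL)
}
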