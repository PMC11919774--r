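#' Forest plot of per-site effect sizes and the pooled estimate
#'
#' Squares mark per-site unbiased d (area proportional to weight), the
#' diamond the pooled fixed-effects estimate; bars are 95% confidence
#' intervals.
#'
#' @param meta a `meta_result`.
#' @param xlab x-axis label.
#' @param main plot title.
#' @return the forest table, invisibly.
#' @export
plot_forest <- function(meta, xlab = "standardized difference (unbiased d)",
                        main = NULL) {
  tab <- forest_table(meta)
  k <- nrow(tab)
  ys <- rev(seq_len(k))
  xlim <- range(c(tab$ci_lower, tab$ci_upper, 0))
  graphics::plot(NA, xlim = xlim, ylim = c(0.5, k + 0.5), yaxt = "n",
                 xlab = xlab, ylab = "",
                 main = main %||% sprintf("channel: %s", meta$channel))
  graphics::abline(v = 0, col = "gray60", lty = 2)
  graphics::axis(2, at = ys, labels = tab$site, las = 1)
  site_rows <- seq_len(k - 1)
  graphics::segments(tab$ci_lower, ys, tab$ci_upper, ys)
  graphics::points(tab$d[site_rows], ys[site_rows], pch = 15,
                   cex = 0.6 + 1.6 * sqrt(tab$weight_pct[site_rows] / 100))
  graphics::points(tab$d[k], ys[k], pch = 18, cex = 2)
  invisible(tab)
}

#' Plot estimated marginal means per diagnostic group
#'
#' @param glm_res a `glm_result` from [cross_disorder_glm()].
#' @param main plot title.
#' @return the marginal-mean table, invisibly.
#' @export
plot_marginal_means <- function(glm_res, main = NULL) {
  em <- glm_res$emmeans
  xs <- seq_len(nrow(em))
  graphics::plot(xs, em$emmean, pch = 16, xaxt = "n",
                 ylim = range(c(em$ci_lower, em$ci_upper)),
                 xlab = "", ylab = "estimated marginal mean salience score",
                 main = main %||% sprintf("channel: %s (age %.2f)",
                                          glm_res$channel, glm_res$ref_age))
  graphics::axis(1, at = xs, labels = as.character(em$diagnosis))
  graphics::arrows(xs, em$ci_lower, xs, em$ci_upper, angle = 90, code = 3,
                   length = 0.04)
  hc <- which(as.character(em$diagnosis) == "HC")
  if (length(hc)) graphics::abline(h = em$emmean[hc], lty = 2, col = "gray50")
  invisible(em)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
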