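#' Plot a per-gene decay fit
#'
#' Observed bitscores against evolutionary distance, the fitted curve
#' \eqn{ae^{-bt}}, a shaded prediction interval, and (optionally) the
#' detectability threshold as a dashed line with the target species'
#' distances marked - the standard per-gene diagnostic display.
#'
#' @param x a `decay_fit` with usable parameters.
#' @param threshold optional [bitscore_threshold()] object or bitscore.
#' @param targets optional named numeric vector of target distances to
#'   mark (species -> t).
#' @param level prediction-interval level.
#' @param param_uncertainty include parameter uncertainty in the band.
#' @param t_max right edge of the distance axis; defaults to 1.1 x the
#'   largest of the fitted and target distances.
#' @param ... passed to [plot()].
#' @export
plot.decay_fit <- function(x, threshold = NULL, targets = NULL,
                           level = 0.99, param_uncertainty = TRUE,
                           t_max = NULL, ...) {
  .check_usable(x, allow = c("ok", "degenerate"))
  if (is.null(t_max))
    t_max <- 1.1 * max(x$data$t, if (!is.null(targets)) targets else 0)
  tt <- seq(0, t_max, length.out = 200)
  pi <- prediction_interval(x, tt, level = level,
                            param_uncertainty = param_uncertainty)
  ylim <- c(0, max(x$data$score, pi$pi_high, na.rm = TRUE))
  plot(x$data$t, x$data$score, xlim = c(0, t_max), ylim = ylim,
       xlab = "evolutionary distance (substitutions/site)",
       ylab = "bitscore", pch = 19, col = "steelblue",
       main = sprintf("%s   a = %.3g, b = %.3g, r2 = %.2f",
                      x$gene_id, x$a, x$b, x$r2_log), ...)
  polygon(c(tt, rev(tt)), c(pi$pi_low, rev(pi$pi_high)),
          col = grDevices::adjustcolor("steelblue", 0.2), border = NA)
  lines(tt, pi$mean, col = "steelblue", lwd = 2)
  points(x$data$t, x$data$score, pch = 19, col = "steelblue")
  if (!is.null(threshold))
    abline(h = .threshold_bits(threshold), lty = 2)
  if (!is.null(targets)) {
    abline(v = targets, lty = 3, col = "grey40")
    axis(3, at = targets, labels = names(targets), cex.axis = 0.7)
  }
  invisible(x)
}
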