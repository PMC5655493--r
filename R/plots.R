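# Diagnostic plots (base graphics).

#' Plot a fitted FPCA model
#'
#' Panels: mean function, covariance diagonal with and without noise, and
#' the leading eigenfunctions.
#'
#' @param x a \code{gw_fpca}.
#' @param k_max number of eigenfunctions to draw.
#' @param ... ignored.
#' @export
plot.gw_fpca <- function(x, k_max = 3L, ...) {
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  g <- x$mean$grid
  graphics::plot(g, x$mean$values, type = "l", xlab = "gestational week",
                 ylab = "weight (kg)", main = "mean function")
  graphics::matplot(g, cbind(x$covariance$v_hat, x$covariance$diag_smooth),
                    type = "l", lty = c(1, 2), col = c(1, 2),
                    xlab = "gestational week", ylab = "variance (kg^2)",
                    main = "diagonal: V-hat and G-tilde")
  k <- min(k_max, ncol(x$eigen$functions))
  graphics::matplot(g, x$eigen$functions[, seq_len(k), drop = FALSE],
                    type = "l", xlab = "gestational week",
                    ylab = "eigenfunction", main = "leading components")
  invisible(x)
}

#' Plot a reconstructed trajectory
#'
#' @param x a \code{gw_traj}.
#' @param observations optional data frame with \code{t} and \code{y} to
#'   overlay the subject's records.
#' @param ... ignored.
#' @export
plot.gw_traj <- function(x, observations = NULL, ...) {
  ylim <- range(x$simultaneous_lo, x$simultaneous_hi,
                observations$y %||% x$values)
  graphics::plot(x$grid, x$values, type = "l", ylim = ylim,
                 xlab = "gestational week", ylab = "weight (kg)",
                 main = paste("subject", x$subject_id))
  graphics::lines(x$grid, x$pointwise_lo, lty = 2)
  graphics::lines(x$grid, x$pointwise_hi, lty = 2)
  graphics::lines(x$grid, x$simultaneous_lo, lty = 3)
  graphics::lines(x$grid, x$simultaneous_hi, lty = 3)
  if (!is.null(observations)) {
    graphics::points(observations$t, observations$y, pch = 19)
  }
  invisible(x)
}
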