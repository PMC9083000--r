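# Quick-look base-graphics plots of EZ growth and energy-variation curves,
# mirroring the two-panel layout (EZ vs time; dU vs relative distance)
# used for each geometry.

#' @export
plot.ez_profile <- function(x, ..., xlab = "t (µs)", ylab = "EZ (nm)",
                            type = "l") {
  plot(x$t * 1e6, x$ez * 1e9, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Plot EZ growth and energy variation for a set of results
#'
#' Draws the two standard panels side by side: probe displacement versus
#' time and electrostatic energy variation versus relative distance, one
#' curve per result.
#'
#' @param results An [run_scenarios()] result set (or a list of
#'   [run_scenario()] results).
#' @param main Overall title.
#' @param col Colours recycled over the results.
#' @return Invisibly, `results`.
#' @export
plot_result_set <- function(results, main = NULL,
                            col = c("blue", "red", "goldenrod", "purple")) {
  ok <- Filter(function(r) inherits(r, "ez_result"), results)
  if (length(ok) == 0) .stop_invalid("no successful results to plot")
  col <- rep_len(col, length(ok))
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op))
  tmax <- max(vapply(ok, function(r) max(r$ez$t), 0)) * 1e6
  ezmax <- max(vapply(ok, function(r) max(r$ez$ez), 0)) * 1e9
  plot(NULL, xlim = c(0, tmax), ylim = c(0, ezmax * 1.05),
       xlab = "t (µs)", ylab = "EZ (nm)", main = main %||% "EZ growth")
  for (i in seq_along(ok))
    graphics::lines(ok[[i]]$ez$t * 1e6, ok[[i]]$ez$ez * 1e9, col = col[i])
  dmax <- max(vapply(ok, function(r) max(r$energy$relative_distance_nm), 0))
  dUmin <- min(vapply(ok, function(r) min(r$energy$dU_kBT), 0))
  plot(NULL, xlim = c(0, dmax), ylim = c(dUmin * 1.05, 0),
       xlab = "relative distance (nm)",
       ylab = expression(Delta * U ~ (k[B] * T)),
       main = "Energy variation")
  for (i in seq_along(ok))
    graphics::lines(ok[[i]]$energy$relative_distance_nm,
                    ok[[i]]$energy$dU_kBT, col = col[i])
  graphics::legend("bottomleft", legend = names(ok) %||%
                     vapply(ok, function(r) r$id, ""),
                   col = col, lty = 1, cex = 0.7, bty = "n")
  invisible(results)
}
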