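#' Per-droplet two-channel amplitudes for one well
#'
#' A `droplet_set` holds the raw analysis substrate of droplet digital PCR:
#' the end-point fluorescence amplitude of every accepted droplet in both
#' optical channels of a two-colour droplet reader. Channel 1 is plotted
#' vertically and channel 2 horizontally in the conventional 2-D amplitude
#' chart.
#'
#' @param ch1,ch2 Numeric vectors of equal length: fluorescence amplitudes
#'   (arbitrary instrument units) in channels 1 and 2, one entry per droplet.
#' @param well_id Text label for the well.
#' @return An object of class `droplet_set` with fields `well_id`, `ch1`,
#'   `ch2` and `n_accepted` (the common length of the amplitude vectors).
#' @examples
#' d <- droplet_set(ch1 = c(1000, 5200, 980), ch2 = c(900, 880, 4100))
#' d$n_accepted
#' @export
droplet_set <- function(ch1, ch2, well_id = "well") {
  if (!is.numeric(ch1) || !is.numeric(ch2)) {
    stop_ddplexr("amplitudes must be numeric", "ddplexr_invalid")
  }
  if (length(ch1) != length(ch2)) {
    stop_ddplexr(
      sprintf(
        "channel amplitude vectors differ in length (%d vs %d)",
        length(ch1), length(ch2)
      ),
      "ddplexr_invalid"
    )
  }
  if (anyNA(ch1) || anyNA(ch2) || !all(is.finite(ch1)) || !all(is.finite(ch2))) {
    stop_ddplexr("all amplitudes must be finite", "ddplexr_invalid")
  }
  structure(
    list(
      well_id = as.character(well_id)[1],
      ch1 = as.numeric(ch1),
      ch2 = as.numeric(ch2),
      n_accepted = length(ch1)
    ),
    class = "droplet_set"
  )
}

#' @export
print.droplet_set <- function(x, ...) {
  cat(sprintf(
    "<droplet_set> well '%s': %d accepted droplets\n", x$well_id, x$n_accepted
  ))
  if (x$n_accepted > 0) {
    cat(sprintf(
      "  ch1 amplitude range: %.1f .. %.1f\n  ch2 amplitude range: %.1f .. %.1f\n",
      min(x$ch1), max(x$ch1), min(x$ch2), max(x$ch2)
    ))
  }
  invisible(x)
}

#' Plot a well in the 2-D amplitude plane
#'
#' Scatter of channel-1 (vertical) against channel-2 (horizontal) amplitudes,
#' optionally overlaying the separation-line grid used for classification.
#'
#' @param x A [droplet_set()].
#' @param grid Optional [separation_grid()] drawn as dashed lines.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.droplet_set <- function(x, grid = NULL, ...) {
  graphics::plot(
    x$ch2, x$ch1,
    xlab = "Ch2 amplitude", ylab = "Ch1 amplitude",
    main = x$well_id, pch = 16, cex = 0.3,
    col = grDevices::adjustcolor("navy", alpha.f = 0.4), ...
  )
  if (!is.null(grid)) {
    graphics::abline(h = grid$ch1_lines, v = grid$ch2_lines,
                     lty = 2, col = "red3")
  }
  invisible(x)
}
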