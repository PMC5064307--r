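#' Separation-line grid for amplitude-band classification
#'
#' A `separation_grid` holds the separation-line positions that partition
#' each fluorescence channel into amplitude bands. For a channel carrying
#' two amplitude-coded targets there are three ascending lines and four
#' bands: band 0 = negative, band 1 = low-amplitude target, band 2 =
#' high-amplitude target, band 3 = double-positive (both same-channel
#' targets, sitting above the two single-positive clusters because the
#' fluorescence of co-occupied droplets adds). A channel with one target has
#' a single line (bands 0/1); a channel with no target has none.
#'
#' @param ch1_lines,ch2_lines Numeric vectors of strictly ascending line
#'   positions for channel 1 (drawn horizontally in the 2-D plot) and
#'   channel 2 (drawn vertically). Allowed lengths are 0, 1 or 3,
#'   corresponding to 0, 1 or 2 targets on the channel.
#' @param provenance One of `"automatic"`, `"manual"`, `"mixed"` — how the
#'   line positions were obtained.
#' @return An object of class `separation_grid`.
#' @seealso [propose_grid()] for automatic placement, [set_line()] for
#'   manual correction, [classify()] to apply the grid.
#' @export
separation_grid <- function(ch1_lines = numeric(), ch2_lines = numeric(),
                            provenance = "manual") {
  check_lines <- function(lines, axis) {
    lines <- as.numeric(lines)
    if (!length(lines) %in% c(0L, 1L, 3L)) {
      stop_ddplexr(
        sprintf("%s must hold 0, 1 or 3 lines, got %d", axis, length(lines)),
        "ddplexr_invalid"
      )
    }
    if (length(lines) && (anyNA(lines) || !all(is.finite(lines)))) {
      stop_ddplexr(sprintf("%s lines must be finite", axis), "ddplexr_invalid")
    }
    if (length(lines) > 1 && any(diff(lines) <= 0)) {
      stop_ddplexr(sprintf("%s lines must be strictly ascending", axis),
                   "ddplexr_invalid")
    }
    lines
  }
  provenance <- match.arg(provenance, c("automatic", "manual", "mixed"))
  structure(
    list(
      ch1_lines = check_lines(ch1_lines, "ch1_lines"),
      ch2_lines = check_lines(ch2_lines, "ch2_lines"),
      provenance = provenance
    ),
    class = "separation_grid"
  )
}

#' @export
print.separation_grid <- function(x, ...) {
  fmt <- function(l) if (length(l)) paste(round(l, 1), collapse = ", ") else "-"
  cat(sprintf("<separation_grid> (%s)\n  ch1 lines: %s\n  ch2 lines: %s\n",
              x$provenance, fmt(x$ch1_lines), fmt(x$ch2_lines)))
  invisible(x)
}

#' Amplitude band of a value relative to a set of separation lines
#'
#' Returns, for each amplitude, the number of lines at or below it
#' (half-open convention: an amplitude exactly on a line belongs to the
#' upper band). With three lines this yields bands 0..3; with one line,
#' bands 0/1; with no lines every amplitude is band 0. The mapping is
#' monotone non-decreasing in amplitude.
#'
#' @param amplitude Numeric vector of fluorescence values.
#' @param lines Strictly ascending numeric vector of line positions.
#' @return Integer vector of band indices, same length as `amplitude`.
#' @examples
#' band_of(c(-50, 2500, 6000), lines = c(2000, 4000, 6000))
#' @export
band_of <- function(amplitude, lines) {
  if (length(lines) > 1 && any(diff(lines) <= 0)) {
    stop_ddplexr("lines must be strictly ascending", "ddplexr_invalid")
  }
  if (length(lines) == 0) {
    return(integer(length(amplitude)))
  }
  findInterval(amplitude, lines)
}

#' Manually move one separation line
#'
#' Programmatic counterpart of interactive line correction: replaces a
#' single line position, enforcing that the line list stays strictly
#' ascending. The grid provenance becomes `"mixed"` when an automatic grid
#' is edited and stays `"manual"`/`"mixed"` otherwise.
#'
#' @param grid A [separation_grid()].
#' @param channel Channel whose line to move, `1` or `2`.
#' @param index Which line to move, 1-based (1 = lowest line).
#' @param position New amplitude position.
#' @return A new `separation_grid`.
#' @export
set_line <- function(grid, channel, index, position) {
  stopifnot(inherits(grid, "separation_grid"))
  if (!channel %in% c(1, 2)) {
    stop_ddplexr("channel must be 1 or 2", "ddplexr_invalid")
  }
  if (!is_number(position)) {
    stop_ddplexr("position must be a finite number", "ddplexr_invalid")
  }
  field <- if (channel == 1) "ch1_lines" else "ch2_lines"
  lines <- grid[[field]]
  if (!is_count(index, min = 1) || index > length(lines)) {
    stop_ddplexr(
      sprintf("channel %d has %d lines; index %s is out of range",
              channel, length(lines), format(index)),
      "ddplexr_invalid"
    )
  }
  if (index > 1 && position <= lines[index - 1]) {
    stop_ddplexr(
      sprintf("position %.6g conflicts with lower neighbour line %d at %.6g",
              position, index - 1, lines[index - 1]),
      "ddplexr_line_order"
    )
  }
  if (index < length(lines) && position >= lines[index + 1]) {
    stop_ddplexr(
      sprintf("position %.6g conflicts with upper neighbour line %d at %.6g",
              position, index + 1, lines[index + 1]),
      "ddplexr_line_order"
    )
  }
  lines[index] <- position
  grid[[field]] <- lines
  grid$provenance <- if (grid$provenance == "automatic") "mixed" else grid$provenance
  grid
}
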