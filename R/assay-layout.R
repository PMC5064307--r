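#' Assay layout: which target sits at which amplitude level
#'
#' An amplitude-coded multiplex assay encodes up to two targets per
#' fluorescence channel by running them at different primer/probe
#' concentrations, so their positive droplet clusters sit at distinct
#' amplitude levels (`"low"` and `"high"`); droplets containing both
#' same-channel targets form a third cluster above the two. The layout maps
#' each target name to its (channel, level) slot, which in turn defines
#' which grid cells are positive for that target.
#'
#' @param targets Data frame (or list coercible to one) with columns
#'   `name`, `channel` (1 or 2) and `level` (`"low"` or `"high"`); at most
#'   4 targets, at most 2 per channel, (channel, level) pairs unique.
#' @param assay_name Text label for the assay.
#' @return An object of class `assay_layout`.
#' @examples
#' # a 4-plex in the style of an endogene + three GM event assay
#' assay_layout_4plex(c("hmgA", "MON810", "MON863", "DP98140"), "MTQ1")
#' @export
assay_layout <- function(targets, assay_name = "assay") {
  targets <- as.data.frame(targets, stringsAsFactors = FALSE)
  required <- c("name", "channel", "level")
  if (!all(required %in% names(targets))) {
    stop_ddplexr("targets need columns name, channel, level", "ddplexr_invalid")
  }
  targets <- targets[required]
  targets$name <- as.character(targets$name)
  targets$channel <- as.integer(targets$channel)
  targets$level <- as.character(targets$level)
  if (nrow(targets) < 1 || nrow(targets) > 4) {
    stop_ddplexr("a layout holds 1 to 4 targets", "ddplexr_invalid")
  }
  if (anyDuplicated(targets$name)) {
    stop_ddplexr("target names must be unique", "ddplexr_invalid")
  }
  if (!all(targets$channel %in% 1:2)) {
    stop_ddplexr("channel must be 1 or 2", "ddplexr_invalid")
  }
  if (!all(targets$level %in% c("low", "high"))) {
    stop_ddplexr("level must be 'low' or 'high'", "ddplexr_invalid")
  }
  if (any(table(targets$channel) > 2)) {
    stop_ddplexr("at most 2 targets per channel", "ddplexr_invalid")
  }
  if (anyDuplicated(paste(targets$channel, targets$level))) {
    stop_ddplexr("(channel, level) slots must be unique", "ddplexr_invalid")
  }
  structure(
    list(assay_name = as.character(assay_name)[1], targets = targets),
    class = "assay_layout"
  )
}

#' @rdname assay_layout
#' @param names Four target names assigned, in order, to slots
#'   (channel 1, low), (channel 1, high), (channel 2, low), (channel 2, high).
#' @export
assay_layout_4plex <- function(names, assay_name = "4plex") {
  stopifnot(length(names) == 4)
  assay_layout(
    data.frame(
      name = as.character(names),
      channel = c(1L, 1L, 2L, 2L),
      level = c("low", "high", "low", "high"),
      stringsAsFactors = FALSE
    ),
    assay_name = assay_name
  )
}

#' @export
print.assay_layout <- function(x, ...) {
  cat(sprintf("<assay_layout> '%s' (%d targets)\n", x$assay_name,
              nrow(x$targets)))
  print(x$targets, row.names = FALSE)
  invisible(x)
}

layout_target <- function(layout, target_name) {
  i <- match(target_name, layout$targets$name)
  if (is.na(i)) {
    stop_ddplexr(sprintf("unknown target '%s' in assay '%s'", target_name,
                         layout$assay_name), "ddplexr_invalid")
  }
  layout$targets[i, ]
}

n_bands_on <- function(layout, channel) {
  2L^sum(layout$targets$channel == channel)
}

positive_bands <- function(layout, target_name) {
  tg <- layout_target(layout, target_name)
  n_on_channel <- sum(layout$targets$channel == tg$channel)
  if (n_on_channel == 2) {
    if (tg$level == "low") c(1L, 3L) else c(2L, 3L)
  } else {
    1L
  }
}

#' Grid cells positive for one target
#'
#' A droplet is positive for a target exactly when its band on the target's
#' channel includes that target: bands {1, 3} for the low-amplitude target,
#' {2, 3} for the high-amplitude one (band 3 is the same-channel double
#' positive); any band on the other channel. For a 4-plex this is 8 of the
#' 16 cells.
#'
#' @param layout An [assay_layout()].
#' @param target_name Name of a target in the layout.
#' @return Two-column integer matrix of (channel-1 band, channel-2 band)
#'   cell coordinates.
#' @export
positive_cells <- function(layout, target_name) {
  stopifnot(inherits(layout, "assay_layout"))
  tg <- layout_target(layout, target_name)
  bands <- positive_bands(layout, target_name)
  other_channel <- if (tg$channel == 1) 2L else 1L
  other_bands <- 0:(n_bands_on(layout, other_channel) - 1L)
  cells <- if (tg$channel == 1) {
    expand.grid(band1 = bands, band2 = other_bands)
  } else {
    expand.grid(band1 = other_bands, band2 = bands)
  }
  m <- as.matrix(cells[order(cells$band1, cells$band2), ])
  dimnames(m) <- list(NULL, c("band1", "band2"))
  m
}

#' Number of target presence combinations in a droplet
#'
#' With `n` targets a droplet can hold any non-empty subset of them, giving
#' `2^n - 1` distinct positive combinations (clusters) plus the one negative
#' cluster — 15 positive and 16 total for a 4-plex.
#'
#' @param n_targets Number of multiplexed targets (1..8).
#' @return The count of positive presence combinations, `2^n_targets - 1`.
#' @examples
#' count_combinations(4) # 15
#' @export
count_combinations <- function(n_targets) {
  if (!is_count(n_targets, min = 1) || n_targets > 8) {
    stop_ddplexr("n_targets must be an integer in 1..8", "ddplexr_invalid")
  }
  as.integer(2^n_targets - 1)
}
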