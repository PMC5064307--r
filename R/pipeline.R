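#' Full analysis of one well: lines, classification, quantification
#'
#' Convenience wrapper chaining [propose_grid()] (unless a grid is given),
#' [classify()] and [quantify_multiplex()].
#'
#' @param droplets A [droplet_set()].
#' @param layout An [assay_layout()].
#' @param quant A [quant_config()].
#' @param grid Optional [separation_grid()]; when `NULL` the grid is
#'   proposed automatically from this well's amplitudes. Wells without a
#'   full complement of clusters (for example near the detection limit, or
#'   with an absent target) cannot anchor automatic placement — pass a grid
#'   derived from a positive control instead.
#' @param control List from [lines_control()], used when proposing.
#' @return Object of class `well_analysis` with `$grid`, `$clusters` and
#'   `$results` (the per-target data frame).
#' @export
analyze_well <- function(droplets, layout, quant = quant_config(),
                         grid = NULL, control = lines_control()) {
  if (is.null(grid)) {
    grid <- propose_grid(droplets, layout, control = control)
  }
  clusters <- classify(droplets, grid)
  results <- quantify_multiplex(clusters, layout, config = quant,
                                well_id = droplets$well_id)
  structure(list(grid = grid, clusters = clusters, results = results),
            class = "well_analysis")
}

#' @export
print.well_analysis <- function(x, ...) {
  print(x$grid)
  cat("\n")
  print(x$results[c("well", "target", "positives", "total",
                    "copies_per_reaction", "ci_low", "ci_high", "detected")],
        row.names = FALSE, digits = 6)
  invisible(x)
}
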