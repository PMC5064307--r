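#' Quantification settings
#'
#' @param droplet_volume_nL Volume of one droplet in nanolitres; 0.85 nL is
#'   the value used for the QX100/QX200 droplet reader.
#' @param reaction_volume_uL Reaction volume in microlitres; copy numbers
#'   "per reaction" are reported at this scale (default 20 uL).
#' @param ci_level Confidence level for the interval on the concentration.
#' @param detection_min_droplets A target counts as detected in a well when
#'   at least this many droplets are positive (default 3).
#' @param ci_method Interval strategy on the positive fraction: `"wilson"`
#'   (Wilson score, default) or `"normal"` (Wald approximation). Either
#'   bound is transformed to the concentration scale through the Poisson
#'   link, which is monotone, so coverage is preserved.
#' @return An object of class `quant_config`.
#' @export
quant_config <- function(droplet_volume_nL = 0.85, reaction_volume_uL = 20,
                         ci_level = 0.95, detection_min_droplets = 3,
                         ci_method = c("wilson", "normal")) {
  stopifnot(
    is_number(droplet_volume_nL), droplet_volume_nL > 0,
    is_number(reaction_volume_uL), reaction_volume_uL > 0,
    is_number(ci_level), ci_level > 0, ci_level < 1,
    is_count(detection_min_droplets, min = 1)
  )
  structure(
    list(
      droplet_volume_nL = droplet_volume_nL,
      reaction_volume_uL = reaction_volume_uL,
      ci_level = ci_level,
      detection_min_droplets = as.integer(detection_min_droplets),
      ci_method = match.arg(ci_method)
    ),
    class = "quant_config"
  )
}

# Wilson score interval on a binomial proportion, no continuity correction.
wilson_interval <- function(positives, total, level) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- positives / total
  denom <- 1 + z^2 / total
  centre <- (p + z^2 / (2 * total)) / denom
  half <- z * sqrt(p * (1 - p) / total + z^2 / (4 * total^2)) / denom
  c(max(0, centre - half), min(1, centre + half))
}

normal_interval <- function(positives, total, level) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- positives / total
  half <- z * sqrt(p * (1 - p) / total)
  c(max(0, p - half), min(1, p + half))
}

#' Poisson absolute quantification of one target in one well
#'
#' Converts positive/total droplet counts into an absolute concentration by
#' Poisson partition statistics. With positive fraction `p = positives /
#' total`, the mean target copies per droplet is `lambda = -ln(1 - p)`; the
#' concentration is `lambda / droplet volume` (copies per microlitre of
#' reaction mix) and `copies per reaction = copies/uL x reaction volume`.
#' The confidence interval is computed on `p` (Wilson score by default) and
#' both bounds are pushed through the same transform.
#'
#' A saturated well (`positives == total`) has no finite estimate: `lambda`
#' and the upper bound are `Inf`, the result is flagged `saturated = TRUE`,
#' and such rows should be excluded from downstream statistics.
#'
#' @param positives Number of droplets positive for the target.
#' @param total Number of accepted droplets (>= 1).
#' @param config A [quant_config()].
#' @param target_name Target label carried into the result.
#' @param well_id Well label carried into the result.
#' @return One-row data frame with columns `well`, `target`, `positives`,
#'   `total`, `p_hat`, `lambda`, `copies_per_uL`, `copies_per_reaction`,
#'   `ci_low`, `ci_high`, `detected`, `saturated`.
#' @examples
#' estimate_target(10000, 20000)$copies_per_reaction # -ln(0.5)/0.00085*20
#' @export
estimate_target <- function(positives, total, config = quant_config(),
                            target_name = "target", well_id = "well") {
  stopifnot(inherits(config, "quant_config"))
  if (!is_count(total, min = 1)) {
    stop_ddplexr("total must be an integer >= 1", "ddplexr_invalid")
  }
  if (!is_count(positives) || positives > total) {
    stop_ddplexr("positives must be an integer in 0..total", "ddplexr_invalid")
  }
  p <- positives / total
  vol_uL <- config$droplet_volume_nL / 1000
  saturated <- positives == total
  lambda <- if (saturated) Inf else -log1p(-p)
  copies_per_uL <- lambda / vol_uL
  copies_per_reaction <- copies_per_uL * config$reaction_volume_uL
  ci_p <- switch(config$ci_method,
    wilson = wilson_interval(positives, total, config$ci_level),
    normal = normal_interval(positives, total, config$ci_level)
  )
  ci_copies <- ifelse(ci_p >= 1, Inf, -log1p(-ci_p)) / vol_uL *
    config$reaction_volume_uL
  data.frame(
    well = well_id,
    target = target_name,
    positives = as.integer(positives),
    total = as.integer(total),
    p_hat = p,
    lambda = lambda,
    copies_per_uL = copies_per_uL,
    copies_per_reaction = copies_per_reaction,
    ci_low = ci_copies[1],
    ci_high = ci_copies[2],
    detected = positives >= config$detection_min_droplets,
    saturated = saturated,
    stringsAsFactors = FALSE
  )
}

#' Quantify all targets of a multiplex assay from a classified grid
#'
#' For each target in the layout, sums droplet counts over its positive
#' cells ([positive_cells()]) and applies [estimate_target()] with the
#' well's total accepted droplets.
#'
#' @param grid A `cluster_grid` from [classify()].
#' @param layout An [assay_layout()].
#' @param config A [quant_config()].
#' @param well_id Well label carried into the results.
#' @return Data frame with one row per target, ordered as in the layout.
#' @export
quantify_multiplex <- function(grid, layout, config = quant_config(),
                               well_id = "well") {
  stopifnot(inherits(grid, "cluster_grid"), inherits(layout, "assay_layout"))
  if (grid$total < 1) {
    stop_ddplexr("cannot quantify an empty well", "ddplexr_invalid")
  }
  expected_dim <- c(n_bands_on(layout, 1), n_bands_on(layout, 2))
  if (!all(dim(grid$counts) == expected_dim)) {
    stop_ddplexr(
      sprintf("cluster grid is %d x %d but layout '%s' expects %d x %d bands",
              nrow(grid$counts), ncol(grid$counts), layout$assay_name,
              expected_dim[1], expected_dim[2]),
      "ddplexr_invalid"
    )
  }
  rows <- lapply(layout$targets$name, function(tn) {
    cells <- positive_cells(layout, tn)
    pos <- sum(grid$counts[cbind(cells[, "band1"] + 1L, cells[, "band2"] + 1L)])
    estimate_target(pos, grid$total, config = config, target_name = tn,
                    well_id = well_id)
  })
  do.call(rbind, rows)
}
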