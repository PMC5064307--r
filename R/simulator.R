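#' Per-channel amplitude model for the droplet simulator
#'
#' The simulator renders each channel's end-point fluorescence as a baseline
#' (negative) level plus an additive increment per same-channel target
#' present in the droplet, with Gaussian cluster noise. Defaults are
#' instrument-like but otherwise arbitrary amplitude units: the analysis
#' never depends on absolute amplitudes, only on cluster separation.
#'
#' @param baseline_mean,baseline_sd Mean and SD of the negative cluster.
#' @param low_increment,high_increment Amplitude added by the low- and
#'   high-level target; `high_increment > low_increment > 0`. A droplet
#'   holding both targets sits at baseline + both increments, above the two
#'   single-positive clusters.
#' @param cluster_sd Gaussian SD of occupied (positive) clusters.
#' @return Named list of channel parameters.
#' @export
channel_model <- function(baseline_mean = 800, baseline_sd = 60,
                          low_increment = 2200, high_increment = 4800,
                          cluster_sd = 150) {
  stopifnot(is_number(baseline_mean),
            is_number(baseline_sd), baseline_sd > 0,
            is_number(low_increment), low_increment > 0,
            is_number(high_increment), high_increment > low_increment,
            is_number(cluster_sd), cluster_sd > 0)
  list(baseline_mean = baseline_mean, baseline_sd = baseline_sd,
       low_increment = low_increment, high_increment = high_increment,
       cluster_sd = cluster_sd)
}

#' Configuration of the synthetic droplet simulator
#'
#' Fixes the ground-truth concentrations and the amplitude/noise/rain model
#' used by [simulate_well()]. Target occupancy is drawn from the full
#' Poisson law (a droplet may hold several copies); the rendered amplitude
#' depends only on presence/absence per target, matching end-point
#' chemistry.
#'
#' @param copies_per_reaction Named numeric vector (>= 0) of true target
#'   copies per reaction, names matching the assay layout (up to 4).
#' @param n_droplets Accepted droplets per well (default 15000).
#' @param droplet_volume_nL,reaction_volume_uL Partition volumes (defaults
#'   0.85 nL and 20 uL).
#' @param channels List of two [channel_model()]s (channel 1, channel 2).
#' @param rain_fraction Proportion of positive droplets rendered as "rain":
#'   instead of sitting in their cluster they get, on each channel where
#'   they are positive, an amplitude drawn uniformly between the channel
#'   baseline and their full cluster mean. Default 0.
#' @param seed Integer seed making [simulate_well()] reproducible;
#'   `NULL` leaves the random stream untouched.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(copies_per_reaction, n_droplets = 15000,
                              droplet_volume_nL = 0.85,
                              reaction_volume_uL = 20,
                              channels = list(channel_model(), channel_model()),
                              rain_fraction = 0, seed = NULL) {
  if (is.null(names(copies_per_reaction)) ||
      any(!nzchar(names(copies_per_reaction)))) {
    stop_ddplexr("copies_per_reaction must be a named vector",
                 "ddplexr_invalid")
  }
  if (!is.numeric(copies_per_reaction) || any(copies_per_reaction < 0) ||
      length(copies_per_reaction) > 4) {
    stop_ddplexr("copies_per_reaction must hold up to 4 non-negative values",
                 "ddplexr_invalid")
  }
  stopifnot(is_count(n_droplets, min = 1),
            is_number(droplet_volume_nL), droplet_volume_nL > 0,
            is_number(reaction_volume_uL), reaction_volume_uL > 0,
            is.list(channels), length(channels) == 2,
            is_number(rain_fraction), rain_fraction >= 0, rain_fraction < 1)
  if (!is.null(seed) && !is_count(seed)) {
    stop_ddplexr("seed must be a non-negative integer", "ddplexr_invalid")
  }
  structure(
    list(
      copies_per_reaction = copies_per_reaction,
      n_droplets = as.integer(n_droplets),
      droplet_volume_nL = droplet_volume_nL,
      reaction_volume_uL = reaction_volume_uL,
      channels = channels,
      rain_fraction = rain_fraction,
      seed = seed
    ),
    class = "simulation_config"
  )
}

#' Mean copies per droplet implied by a per-reaction copy number
#'
#' Inverts the concentration relation: `lambda = (copies_per_reaction /
#' reaction volume) x droplet volume` (volumes in consistent units). With
#' the default 0.85 nL droplets and 20 uL reactions, 1000 copies per
#' reaction give lambda = 0.0425.
#'
#' @param copies_per_reaction Copies per reaction (>= 0), vectorised.
#' @param config A [simulation_config()] supplying the volumes.
#' @return Mean target copies per droplet.
#' @export
lambda_from_copies <- function(copies_per_reaction, config) {
  stopifnot(inherits(config, "simulation_config"))
  (copies_per_reaction / config$reaction_volume_uL) *
    (config$droplet_volume_nL / 1000)
}

#' Simulate one multiplex ddPCR well with ground truth
#'
#' For every droplet and target, a copy count is drawn from the Poisson law
#' with the target's per-droplet mean; each channel's amplitude is the
#' baseline plus the increments of the same-channel targets present plus
#' Gaussian noise (baseline SD for empty droplets, cluster SD for occupied
#' ones). A `rain_fraction` subset of positive droplets is instead rendered
#' at a uniform intermediate amplitude on each of its positive channels.
#' Identical seeds give bit-identical output.
#'
#' @param config A [simulation_config()]; every layout target must appear in
#'   its `copies_per_reaction`.
#' @param layout An [assay_layout()].
#' @param seed Overrides `config$seed` when given.
#' @param well_id Label for the simulated well.
#' @return List of class `simulated_well` with `$droplets` (a
#'   [droplet_set()]) and `$truth`, a `ground_truth` object holding the
#'   per-droplet copy matrix, the true band per channel (derived from which
#'   same-channel targets have >= 1 copy) and the rain flags.
#' @export
simulate_well <- function(config, layout, seed = config$seed,
                          well_id = "sim_well") {
  stopifnot(inherits(config, "simulation_config"),
            inherits(layout, "assay_layout"))
  missing_targets <- setdiff(layout$targets$name,
                             names(config$copies_per_reaction))
  if (length(missing_targets) > 0) {
    stop_ddplexr(
      sprintf("no simulated concentration for target(s): %s",
              paste(missing_targets, collapse = ", ")),
      "ddplexr_invalid"
    )
  }
  draw <- function() simulate_well_impl(config, layout, well_id)
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

simulate_well_impl <- function(config, layout, well_id) {
  n <- config$n_droplets
  tg <- layout$targets
  lambda <- lambda_from_copies(
    config$copies_per_reaction[tg$name], config
  )
  copies <- vapply(lambda, function(l) stats::rpois(n, l), integer(n))
  if (is.null(dim(copies))) copies <- matrix(copies, nrow = n)
  colnames(copies) <- tg$name
  present <- copies > 0
  any_positive <- rowSums(present) > 0
  rain <- any_positive & stats::runif(n) < config$rain_fraction

  amps <- vector("list", 2)
  bands <- vector("list", 2)
  for (ch in 1:2) {
    cm <- config$channels[[ch]]
    on_ch <- which(tg$channel == ch)
    mean_amp <- rep(cm$baseline_mean, n)
    band <- integer(n)
    two_targets <- length(on_ch) == 2
    for (j in on_ch) {
      inc <- if (tg$level[j] == "low") cm$low_increment else cm$high_increment
      mean_amp <- mean_amp + inc * present[, j]
      band <- band + (if (two_targets) {
        if (tg$level[j] == "low") 1L else 2L
      } else 1L) * present[, j]
    }
    occupied <- mean_amp > cm$baseline_mean
    sd_amp <- ifelse(occupied, cm$cluster_sd, cm$baseline_sd)
    amp <- stats::rnorm(n, mean_amp, sd_amp)
    u <- stats::runif(n)
    is_rain_here <- rain & occupied
    amp[is_rain_here] <- cm$baseline_mean +
      u[is_rain_here] * (mean_amp[is_rain_here] - cm$baseline_mean)
    amps[[ch]] <- amp
    bands[[ch]] <- band
  }

  truth <- structure(
    list(copies = copies, band_ch1 = bands[[1]], band_ch2 = bands[[2]],
         rain = rain),
    class = "ground_truth"
  )
  structure(
    list(
      droplets = droplet_set(ch1 = amps[[1]], ch2 = amps[[2]],
                             well_id = well_id),
      truth = truth
    ),
    class = "simulated_well"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %d droplets, %d target(s); %d positive, %d rain\n",
    nrow(x$copies), ncol(x$copies), sum(rowSums(x$copies > 0) > 0),
    sum(x$rain)
  ))
  invisible(x)
}

#' Droplets truly positive for a target
#'
#' @param truth A `ground_truth` object.
#' @param target_name Target column of the copy matrix.
#' @return Count of droplets carrying at least one copy.
#' @export
true_positive_droplets <- function(truth, target_name) {
  stopifnot(inherits(truth, "ground_truth"))
  if (!target_name %in% colnames(truth$copies)) {
    stop_ddplexr(sprintf("unknown target '%s'", target_name),
                 "ddplexr_invalid")
  }
  sum(truth$copies[, target_name] > 0)
}

#' Simulate and quantify a dilution series
#'
#' Simulates one well per (level, replicate) and quantifies each with the
#' Poisson machinery. The separation grid is established once on a positive
#' control well simulated at the undiluted concentrations and is then
#' applied to every series well — mirroring bench practice, where thresholds
#' are placed on a positive control first because wells near the detection
#' limit have empty clusters and cannot anchor automatic placement.
#'
#' Asymmetric designs (one target diluted in a constant high background of
#' the others) are obtained by restricting `scale_targets`.
#'
#' @param config A [simulation_config()] at the undiluted concentrations;
#'   its `seed` (or the `seed` argument) drives all derived per-well seeds.
#' @param layout An [assay_layout()].
#' @param dilution_factors Positive factors applied to the scaled targets,
#'   one level per factor.
#' @param replicates_per_level Wells per level.
#' @param scale_targets Targets the factors apply to (default: all).
#' @param seed Master seed; per-well seeds are derived as
#'   `seed + 1000 * level + replicate`.
#' @param quant A [quant_config()].
#' @param control_grid Optional [separation_grid()] to use instead of the
#'   control-well proposal.
#' @return Object of class `dilution_series` with `$results` (long data
#'   frame: `level_id`, `target`, `assigned_copies`, `replicate`,
#'   `measured_copies`, `positive_droplets`, `detected`) and `$grid`.
#' @seealso [dilution_levels()] to regroup the results per target for
#'   [determine_aloq()] / [determine_alod()].
#' @export
simulate_dilution_series <- function(config, layout, dilution_factors,
                                     replicates_per_level,
                                     scale_targets = NULL,
                                     seed = config$seed,
                                     quant = quant_config(),
                                     control_grid = NULL) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(layout, "assay_layout"),
            is.numeric(dilution_factors), length(dilution_factors) >= 1,
            all(dilution_factors > 0),
            is_count(replicates_per_level, min = 1))
  scale_targets <- scale_targets %||% layout$targets$name
  unknown <- setdiff(scale_targets, layout$targets$name)
  if (length(unknown) > 0) {
    stop_ddplexr(sprintf("scale_targets not in layout: %s",
                         paste(unknown, collapse = ", ")), "ddplexr_invalid")
  }
  if (is.null(seed)) {
    stop_ddplexr("a seed is required for a reproducible dilution series",
                 "ddplexr_invalid")
  }
  if (is.null(control_grid)) {
    control <- simulate_well(config, layout, seed = seed,
                             well_id = "control")
    control_grid <- propose_grid(control$droplets, layout)
  }
  rows <- list()
  for (i in seq_along(dilution_factors)) {
    f <- dilution_factors[i]
    copies_i <- config$copies_per_reaction
    copies_i[scale_targets] <- copies_i[scale_targets] * f
    config_i <- config
    config_i$copies_per_reaction <- copies_i
    level_id <- sprintf("L%02d", i)
    for (r in seq_len(replicates_per_level)) {
      well <- simulate_well(config_i, layout, seed = seed + 1000L * i + r,
                            well_id = sprintf("%s_r%02d", level_id, r))
      res <- quantify_multiplex(classify(well$droplets, control_grid),
                                layout, config = quant,
                                well_id = well$droplets$well_id)
      rows[[length(rows) + 1L]] <- data.frame(
        level_id = level_id,
        target = res$target,
        assigned_copies = unname(copies_i[res$target]),
        replicate = r,
        measured_copies = res$copies_per_reaction,
        positive_droplets = res$positives,
        detected = res$detected,
        stringsAsFactors = FALSE
      )
    }
  }
  structure(
    list(results = do.call(rbind, rows), grid = control_grid,
         dilution_factors = dilution_factors),
    class = "dilution_series"
  )
}

#' Regroup a simulated dilution series into per-target levels
#'
#' @param series A `dilution_series` from [simulate_dilution_series()].
#' @param target_name Target to extract.
#' @return List of [dilution_level()] objects, one per level.
#' @export
dilution_levels <- function(series, target_name) {
  stopifnot(inherits(series, "dilution_series"))
  df <- series$results[series$results$target == target_name, ]
  if (nrow(df) == 0) {
    stop_ddplexr(sprintf("unknown target '%s' in series", target_name),
                 "ddplexr_invalid")
  }
  lapply(split(df, df$level_id), function(g) {
    dilution_level(
      level_id = g$level_id[1],
      assigned_copies = g$assigned_copies[1],
      replicate_values = g$measured_copies,
      replicate_positive_droplets = g$positive_droplets
    )
  })
}
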