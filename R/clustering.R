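#' Control parameters for automatic line placement
#'
#' @param resolution_floor Minimum amplitude spread (max - min) required to
#'   attempt line placement; below it the data are treated as a single
#'   cluster and an "insufficient cluster structure" error is raised. Also
#'   used as the minimum separation required between cluster centres in the
#'   k-means fallback. Amplitude units are instrument-specific, so this is
#'   configurable; the default suits typical droplet-reader scales where
#'   cluster spacings are in the thousands.
#' @param valley_ratio A kernel-density mode is merged into its taller
#'   neighbour unless the density valley between them drops below
#'   `valley_ratio` times the lower peak. Guards mode counting against
#'   sampling jitter in sparse clusters.
#' @param grid_n Number of grid points for the kernel density estimate.
#' @param bw Kernel bandwidth specification passed to [stats::density()];
#'   the default `"nrd0"` is Silverman's rule of thumb.
#' @return A named list of control parameters.
#' @export
lines_control <- function(resolution_floor = 1000, valley_ratio = 0.5,
                          grid_n = 512, bw = "nrd0") {
  stopifnot(is_number(resolution_floor), resolution_floor > 0,
            is_number(valley_ratio), valley_ratio > 0, valley_ratio < 1,
            is_count(grid_n, min = 16))
  list(resolution_floor = resolution_floor, valley_ratio = valley_ratio,
       grid_n = grid_n, bw = bw)
}

# Local maxima of the smoothed density, after merging peaks that are not
# separated by a sufficiently deep valley (relative prominence rule).
find_density_modes <- function(y, valley_ratio) {
  dy <- diff(y)
  peaks <- which(diff(sign(dy)) < 0) + 1L
  # include endpoints when the density is falling away from them
  if (length(y) > 1) {
    if (y[1] > y[2]) peaks <- c(1L, peaks)
    if (y[length(y)] > y[length(y) - 1]) peaks <- c(peaks, length(y))
  }
  peaks <- sort(unique(peaks))
  while (length(peaks) > 1) {
    valleys <- vapply(seq_len(length(peaks) - 1), function(i) {
      min(y[peaks[i]:peaks[i + 1]])
    }, numeric(1))
    lower_peak <- pmin(y[peaks[-length(peaks)]], y[peaks[-1]])
    shallow <- which(valleys > valley_ratio * lower_peak)
    if (length(shallow) == 0) break
    # merge the pair with the least prominent separation first
    i <- shallow[which.max((valleys / lower_peak)[shallow])]
    drop <- if (y[peaks[i]] <= y[peaks[i + 1]]) i else i + 1L
    peaks <- peaks[-drop]
  }
  peaks
}

# Midpoint of the (possibly flat) density minimum between two mode indices.
valley_position <- function(d, i1, i2) {
  seg <- d$y[i1:i2]
  m <- min(seg)
  flat <- which(seg <= m + 1e-12 * max(seg, 1e-300))
  d$x[i1 + flat[ceiling(length(flat) / 2)] - 1L]
}

#' Propose separation-line positions along one channel
#'
#' Places `n_bands - 1` strictly ascending separation lines between the
#' amplitude clusters of a single channel. The primary method smooths a 1-D
#' Gaussian kernel density estimate of the amplitudes (Silverman bandwidth,
#' 512-point grid) and counts its modes after merging modes not separated by
#' a deep valley; if exactly `n_bands` modes remain, each line is placed at
#' the density minimum between consecutive modes. Otherwise the method falls
#' back to 1-D k-means with `k = n_bands` and deterministic initialisation
#' (first at the data quantiles, then — if the solution collapses onto one
#' cluster — at centres equally spaced over the amplitude range), placing
#' each line at the midpoint between consecutive sorted centres, i.e. "in
#' the middle between the clusters".
#'
#' @param amplitudes Numeric vector of at least 50 fluorescence values.
#' @param n_bands Number of amplitude bands the channel should be split
#'   into: 4 for a channel carrying two amplitude-coded targets, 2 for one.
#' @param control List from [lines_control()].
#' @return Numeric vector of `n_bands - 1` ascending line positions, with
#'   attribute `"method"` recording whether `"density"` valleys or the
#'   `"kmeans"` fallback produced them.
#' @export
propose_lines_1d <- function(amplitudes, n_bands = 4,
                             control = lines_control()) {
  if (!is.numeric(amplitudes) || length(amplitudes) < 50) {
    stop_ddplexr("at least 50 amplitudes are required", "ddplexr_invalid")
  }
  if (anyNA(amplitudes) || !all(is.finite(amplitudes))) {
    stop_ddplexr("amplitudes must be finite", "ddplexr_invalid")
  }
  if (!is_count(n_bands, min = 2)) {
    stop_ddplexr("n_bands must be an integer >= 2", "ddplexr_invalid")
  }
  spread <- diff(range(amplitudes))
  if (spread < control$resolution_floor) {
    stop_ddplexr(
      sprintf(paste0(
        "insufficient cluster structure: amplitude spread %.4g is below the ",
        "resolution floor %.4g; the data look like a single cluster - set ",
        "separation lines manually"
      ), spread, control$resolution_floor),
      "ddplexr_insufficient_structure"
    )
  }
  d <- stats::density(amplitudes, bw = control$bw, n = control$grid_n)
  modes <- find_density_modes(d$y, control$valley_ratio)
  if (length(modes) == n_bands) {
    lines <- vapply(seq_len(n_bands - 1), function(i) {
      valley_position(d, modes[i], modes[i + 1])
    }, numeric(1))
    if (all(diff(lines) > 0)) {
      attr(lines, "method") <- "density"
      return(lines)
    }
  }
  # fallback: deterministic 1-D k-means
  k <- n_bands
  probs <- (2 * seq_len(k) - 1) / (2 * k)
  inits <- list(
    quantile = stats::quantile(amplitudes, probs = probs, names = FALSE),
    spread = min(amplitudes) + spread * probs
  )
  for (init in inits) {
    if (anyDuplicated(init)) next
    km <- tryCatch(
      suppressWarnings(stats::kmeans(amplitudes, centers = matrix(init),
                                     iter.max = 100, algorithm = "Lloyd")),
      error = function(e) NULL
    )
    if (is.null(km)) next
    centers <- sort(as.numeric(km$centers))
    if (length(centers) == k && min(diff(centers)) >= control$resolution_floor) {
      lines <- (centers[-1] + centers[-k]) / 2
      attr(lines, "method") <- "kmeans"
      return(lines)
    }
  }
  stop_ddplexr(
    sprintf(paste0(
      "insufficient cluster structure: %d density modes found where %d bands ",
      "were requested and the k-means fallback could not resolve %d separated ",
      "clusters - set separation lines manually"
    ), length(modes), n_bands, k),
    "ddplexr_insufficient_structure"
  )
}

#' Automatically propose a full separation grid for a well
#'
#' Applies [propose_lines_1d()] independently to each channel's amplitudes.
#' The number of lines per channel follows the assay layout: two targets on
#' a channel need 3 lines (4 bands), one target 1 line, an unused channel
#' none.
#'
#' @param droplets A [droplet_set()].
#' @param layout An [assay_layout()] declaring which targets occupy which
#'   channel.
#' @param control List from [lines_control()].
#' @return A [separation_grid()] with provenance `"automatic"`.
#' @export
propose_grid <- function(droplets, layout, control = lines_control()) {
  stopifnot(inherits(droplets, "droplet_set"), inherits(layout, "assay_layout"))
  if (droplets$n_accepted == 0) {
    stop_ddplexr("cannot propose lines for an empty droplet set",
                 "ddplexr_invalid")
  }
  lines_for <- function(amps, n_targets, axis) {
    if (n_targets == 0) return(numeric())
    tryCatch(
      propose_lines_1d(amps, n_bands = 2^n_targets, control = control),
      ddplexr_insufficient_structure = function(e) {
        stop_ddplexr(sprintf("channel %s: %s", axis, conditionMessage(e)),
                     "ddplexr_insufficient_structure")
      }
    )
  }
  n1 <- sum(layout$targets$channel == 1)
  n2 <- sum(layout$targets$channel == 2)
  separation_grid(
    ch1_lines = lines_for(droplets$ch1, n1, "1"),
    ch2_lines = lines_for(droplets$ch2, n2, "2"),
    provenance = "automatic"
  )
}

#' Classify droplets into the amplitude-band grid
#'
#' Assigns every droplet to exactly one cell of the band grid via
#' [band_of()] on each channel. For a 4-plex this is the 16-cluster model:
#' 15 positive cells plus the all-negative cell (0,0). Cell counts always
#' sum to the number of accepted droplets and the result does not depend on
#' droplet order.
#'
#' @param droplets A [droplet_set()].
#' @param grid A [separation_grid()].
#' @return An object of class `cluster_grid` with `counts` (matrix of
#'   droplet counts, rows = channel-1 bands, columns = channel-2 bands) and
#'   `total`.
#' @export
classify <- function(droplets, grid) {
  stopifnot(inherits(droplets, "droplet_set"), inherits(grid, "separation_grid"))
  b1 <- band_of(droplets$ch1, grid$ch1_lines)
  b2 <- band_of(droplets$ch2, grid$ch2_lines)
  nb1 <- length(grid$ch1_lines) + 1L
  nb2 <- length(grid$ch2_lines) + 1L
  counts <- table(factor(b1, levels = 0:(nb1 - 1)),
                  factor(b2, levels = 0:(nb2 - 1)))
  counts <- matrix(as.integer(counts), nrow = nb1, ncol = nb2,
                   dimnames = list(ch1_band = 0:(nb1 - 1),
                                   ch2_band = 0:(nb2 - 1)))
  structure(
    list(counts = counts, total = droplets$n_accepted),
    class = "cluster_grid"
  )
}

#' @export
print.cluster_grid <- function(x, ...) {
  cat(sprintf("<cluster_grid> %d droplets in %d x %d bands\n",
              x$total, nrow(x$counts), ncol(x$counts)))
  print(x$counts)
  invisible(x)
}
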