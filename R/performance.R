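#' Relative standard deviation of replicate measurements
#'
#' The repeatability metric: `100 * sd / mean` (sample standard deviation,
#' n - 1 denominator), in percent.
#'
#' @param values Numeric vector of at least 2 measurements with non-zero
#'   mean.
#' @return RSD in percent.
#' @examples
#' rsd(c(90, 100, 110)) # 10
#' @export
rsd <- function(values) {
  if (!is.numeric(values) || length(values) < 2) {
    stop_ddplexr("rsd needs at least 2 values", "ddplexr_invalid")
  }
  m <- mean(values)
  if (m == 0) {
    stop_ddplexr("rsd is undefined for zero mean", "ddplexr_invalid")
  }
  100 * stats::sd(values) / m
}

#' Flag replicate outliers by the 1.5 x IQR rule
#'
#' Flags values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`. Quartiles use linear
#' interpolation at position `(n - 1) * q` ([stats::quantile()] type 7); the
#' convention matters for small replicate sets and is fixed here so the rule
#' is reproducible.
#'
#' @param values Numeric vector of at least 4 measurements.
#' @return Logical vector, `TRUE` where the value is an outlier.
#' @examples
#' iqr_outliers(c(1, 2, 3, 4, 100)) # only 100 flagged
#' @export
iqr_outliers <- function(values) {
  if (!is.numeric(values) || length(values) < 4) {
    stop_ddplexr("iqr_outliers needs at least 4 values", "ddplexr_invalid")
  }
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  values < q[1] - 1.5 * iqr | values > q[2] + 1.5 * iqr
}

#' One level of a dilution series
#'
#' Bundles, for one dilution level of one target, the assigned (expected)
#' copies per reaction with the replicate measurements and their
#' positive-droplet counts.
#'
#' @param level_id Text label for the level.
#' @param assigned_copies Expected target copies per reaction (>= 0).
#' @param replicate_values Measured copies per reaction, one per replicate.
#' @param replicate_positive_droplets Optional parallel vector of
#'   positive-droplet counts (needed for the detection rule).
#' @return An object of class `dilution_level`.
#' @export
dilution_level <- function(level_id, assigned_copies, replicate_values,
                           replicate_positive_droplets = NULL) {
  stopifnot(is_number(assigned_copies), assigned_copies >= 0,
            is.numeric(replicate_values), length(replicate_values) >= 1)
  if (!is.null(replicate_positive_droplets) &&
      length(replicate_positive_droplets) != length(replicate_values)) {
    stop_ddplexr("positive-droplet counts must parallel replicate values",
                 "ddplexr_invalid")
  }
  structure(
    list(
      level_id = as.character(level_id)[1],
      assigned_copies = assigned_copies,
      replicate_values = as.numeric(replicate_values),
      replicate_positive_droplets =
        if (is.null(replicate_positive_droplets)) NULL
        else as.numeric(replicate_positive_droplets)
    ),
    class = "dilution_level"
  )
}

check_levels <- function(levels) {
  if (inherits(levels, "dilution_level")) levels <- list(levels)
  if (length(levels) == 0 ||
      !all(vapply(levels, inherits, logical(1), "dilution_level"))) {
    stop_ddplexr("levels must be a non-empty list of dilution_level objects",
                 "ddplexr_invalid")
  }
  levels
}

#' Absolute limit of quantification from a dilution series
#'
#' The aLOQ is the lowest copy number within the dynamic range that is still
#' quantified with acceptable precision: the smallest mean measured copy
#' number among levels whose replicate RSD is at or below `max_rsd`
#' (default 25%). Optionally, 1.5 x IQR outliers are removed per level
#' before the rule is applied (only for levels with at least 4 replicates).
#'
#' @param levels List of [dilution_level()] objects (>= 2 replicates each).
#' @param max_rsd RSD acceptance threshold in percent.
#' @param remove_outliers Drop [iqr_outliers()] per level first?
#' @return An object of class `aloq_estimate`: `$aloq` (copies per reaction,
#'   or `NA` when no level passes) and `$levels`, a per-level diagnostic
#'   data frame with columns `level_id`, `n`, `n_outliers`, `mean`, `rsd`,
#'   `pass`.
#' @examples
#' lv <- list(
#'   dilution_level("A", 100, c(90, 100, 110)),
#'   dilution_level("B", 20, c(10, 20, 30))
#' )
#' determine_aloq(lv)$aloq # 100
#' @export
determine_aloq <- function(levels, max_rsd = 25, remove_outliers = FALSE) {
  levels <- check_levels(levels)
  diag <- do.call(rbind, lapply(levels, function(lv) {
    vals <- lv$replicate_values
    n_out <- 0L
    if (remove_outliers && length(vals) >= 4) {
      out <- iqr_outliers(vals)
      n_out <- sum(out)
      vals <- vals[!out]
    }
    if (length(vals) < 2) {
      stop_ddplexr(sprintf("level '%s' has fewer than 2 usable replicates",
                           lv$level_id), "ddplexr_invalid")
    }
    data.frame(level_id = lv$level_id, n = length(vals), n_outliers = n_out,
               mean = mean(vals), rsd = rsd(vals),
               stringsAsFactors = FALSE)
  }))
  diag$pass <- diag$rsd <= max_rsd
  aloq <- if (any(diag$pass)) min(diag$mean[diag$pass]) else NA_real_
  structure(list(aloq = aloq, max_rsd = max_rsd, levels = diag),
            class = "aloq_estimate")
}

#' @export
print.aloq_estimate <- function(x, ...) {
  if (is.na(x$aloq)) {
    cat(sprintf("aLOQ: undefined (no level with RSD <= %g%%)\n", x$max_rsd))
  } else {
    cat(sprintf("aLOQ: %.4g copies per reaction (RSD <= %g%%)\n",
                x$aloq, x$max_rsd))
  }
  print(x$levels, row.names = FALSE)
  invisible(x)
}

#' Absolute limit of detection from a dilution series
#'
#' A replicate is positive when its positive-droplet count reaches
#' `min_positive_droplets` (default 3, "at least three positive droplets").
#' A level detects when at most `max_negative_replicates` replicates are
#' negative — the default of 1 generalises the 14-of-15-replicates rule to
#' any replicate count. The aLOD is the smallest mean measured copy number
#' among detecting levels.
#'
#' @param levels List of [dilution_level()] objects carrying
#'   positive-droplet counts.
#' @param min_positive_droplets Positive-droplet threshold per replicate.
#' @param max_negative_replicates Maximum negative replicates a detecting
#'   level may have.
#' @return An object of class `alod_estimate`: `$alod` (copies per
#'   reaction, or `NA`) and `$levels` diagnostics (`level_id`, `n`,
#'   `n_positive`, `mean`, `detects`).
#' @export
determine_alod <- function(levels, min_positive_droplets = 3,
                           max_negative_replicates = 1) {
  levels <- check_levels(levels)
  stopifnot(is_count(min_positive_droplets, min = 1),
            is_count(max_negative_replicates))
  diag <- do.call(rbind, lapply(levels, function(lv) {
    if (is.null(lv$replicate_positive_droplets)) {
      stop_ddplexr(sprintf("level '%s' lacks positive-droplet counts",
                           lv$level_id), "ddplexr_invalid")
    }
    pos <- lv$replicate_positive_droplets >= min_positive_droplets
    data.frame(level_id = lv$level_id, n = length(pos),
               n_positive = sum(pos), mean = mean(lv$replicate_values),
               detects = (length(pos) - sum(pos)) <= max_negative_replicates,
               stringsAsFactors = FALSE)
  }))
  alod <- if (any(diag$detects)) min(diag$mean[diag$detects]) else NA_real_
  structure(list(alod = alod, levels = diag), class = "alod_estimate")
}

#' @export
print.alod_estimate <- function(x, ...) {
  if (is.na(x$alod)) {
    cat("aLOD: undefined (no detecting level)\n")
  } else {
    cat(sprintf("aLOD: %.4g copies per reaction\n", x$alod))
  }
  print(x$levels, row.names = FALSE)
  invisible(x)
}

#' Signed percent bias of a measurement against a reference
#'
#' `100 * (measured - reference) / reference`, the trueness metric used to
#' compare multiplex against simplex quantification (acceptance threshold
#' 25% for trueness; the multiplex/simplex comparison here stays within
#' 20%).
#'
#' @param reference Reference copies (> 0).
#' @param measured Measured copies.
#' @return Percent bias, signed.
#' @examples
#' percent_bias(67576, 62109) # -8.09...
#' @export
percent_bias <- function(reference, measured) {
  if (!is.numeric(reference) || any(reference <= 0)) {
    stop_ddplexr("reference must be > 0", "ddplexr_invalid")
  }
  100 * (measured - reference) / reference
}

#' Proficiency-test z-score
#'
#' `z = (measured - assigned) / sigma` against the robust mean and standard
#' deviation for proficiency assessment; the result passes when `|z| < 2`
#' (strict inequality, so z = 2.0 exactly fails).
#'
#' @param measured Measured GM content (%).
#' @param assigned Assigned (robust mean) GM content (%).
#' @param sigma Standard deviation for proficiency assessment (> 0).
#' @return List with `z` and logical `pass`.
#' @export
z_score <- function(measured, assigned, sigma) {
  if (!is_number(sigma) || sigma <= 0) {
    stop_ddplexr("sigma must be > 0", "ddplexr_invalid")
  }
  z <- (measured - assigned) / sigma
  # strict |z| < 2, stable at the boundary against floating-point round-off
  list(z = z, pass = abs(z) < 2 - 1e-9)
}

#' Linearity of measured against assigned copies
#'
#' Ordinary least squares of measured on assigned copy numbers, on the
#' linear scale by default (the scale of the dynamic-range evaluation);
#' set `log10 = TRUE` to fit on decadic log scale instead. `r_squared` is
#' the squared Pearson correlation.
#'
#' @param assigned,measured Paired numeric vectors (>= 3 points; assigned
#'   values must not all be equal; with `log10 = TRUE` all values must be
#'   positive).
#' @param log10 Fit on log10-transformed axes?
#' @return List with `slope`, `intercept`, `r_squared`.
#' @export
linearity <- function(assigned, measured, log10 = FALSE) {
  if (length(assigned) != length(measured) || length(assigned) < 3) {
    stop_ddplexr("linearity needs >= 3 paired points", "ddplexr_invalid")
  }
  if (length(unique(assigned)) < 2) {
    stop_ddplexr("assigned values are all equal", "ddplexr_invalid")
  }
  if (log10) {
    if (any(assigned <= 0) || any(measured <= 0)) {
      stop_ddplexr("log10 fit needs strictly positive values",
                   "ddplexr_invalid")
    }
    assigned <- log10(assigned)
    measured <- log10(measured)
  }
  fit <- stats::lm(measured ~ assigned)
  cf <- stats::coef(fit)
  list(slope = unname(cf[2]), intercept = unname(cf[1]),
       r_squared = stats::cor(assigned, measured)^2)
}

#' Conversion factor between copy-number ratio and mass fraction
#'
#' GM content can be expressed as a copy-number ratio (event copies /
#' endogene copies) or as a mass fraction; the two are related by a
#' dimensionless factor. The consensus value is 0.5; because of differing
#' parental DNA contributions in endosperm the event-specific factor is
#' around 0.4 when the GM parent was male and around 0.6 when female.
#'
#' @param origin One of `"consensus"`, `"male_parent"`, `"female_parent"`,
#'   `"custom"`.
#' @param value Required for `origin = "custom"`: a factor in (0, 1].
#' @return An object of class `conversion_factor` with `value` and `origin`.
#' @export
conversion_factor <- function(origin = c("consensus", "male_parent",
                                         "female_parent", "custom"),
                              value = NULL) {
  origin <- match.arg(origin)
  value <- switch(origin,
    consensus = 0.5,
    male_parent = 0.4,
    female_parent = 0.6,
    custom = value
  )
  if (!is_number(value) || value <= 0 || value > 1) {
    stop_ddplexr("conversion factor must lie in (0, 1]", "ddplexr_invalid")
  }
  structure(list(value = value, origin = origin), class = "conversion_factor")
}

#' Convert GM content between mass fraction and copy-number ratio
#'
#' Directional convention: `copies% = mass% * factor` and
#' `mass% = copies% / factor`, so the two directions are exact inverses for
#' any factor.
#'
#' @param value GM content in percent.
#' @param factor A [conversion_factor()] or a bare number in (0, 1].
#' @param direction `"mass_to_copies"` or `"copies_to_mass"`.
#' @return GM content in percent on the requested scale.
#' @examples
#' convert_units(1.0, conversion_factor("male_parent"), "mass_to_copies") # 0.4
#' @export
convert_units <- function(value, factor,
                          direction = c("mass_to_copies", "copies_to_mass")) {
  direction <- match.arg(direction)
  if (is.numeric(factor)) factor <- conversion_factor("custom", value = factor)
  stopifnot(inherits(factor, "conversion_factor"))
  switch(direction,
    mass_to_copies = value * factor$value,
    copies_to_mass = value / factor$value
  )
}

#' False-positive droplet rate for an absent target
#'
#' "Rain" droplets — intermediate-amplitude droplets trailing below a
#' high-amplitude positive cluster — can fall into the band of the
#' same-channel low-amplitude target and register as false positives when
#' that target is absent. The metric is the false-positive droplet count
#' expressed as a percentage of the positive droplets of the co-channel
#' high-amplitude target that generates the rain.
#'
#' @param fp_positives Droplets counted positive for the absent target.
#' @param paired_high_positives Positive droplets of the co-channel
#'   high-amplitude target (>= 1).
#' @return Rate in percent.
#' @export
false_positive_rate <- function(fp_positives, paired_high_positives) {
  if (!is_count(paired_high_positives, min = 1)) {
    stop_ddplexr("paired_high_positives must be an integer >= 1",
                 "ddplexr_invalid")
  }
  if (!is_count(fp_positives)) {
    stop_ddplexr("fp_positives must be a non-negative integer",
                 "ddplexr_invalid")
  }
  100 * fp_positives / paired_high_positives
}

#' Assemble a method-performance report from replicate data
#'
#' Applies the full validation rule set to a long replicate table: per-level
#' repeatability (RSD) with optional 1.5 x IQR outlier flags, aLOQ
#' ([determine_aloq()]), aLOD ([determine_alod()]), and linearity of
#' measured against assigned copies over the quantified range. Optional
#' blocks add trueness ([percent_bias()] against reference values),
#' proficiency [z_score()]s, and GM labelling flags
#' ([gm_labelling_flags()]).
#'
#' @param replicates Data frame with columns `level_id`, `target`,
#'   `assigned_copies`, `measured_copies`, `positive_droplets` (one row per
#'   replicate; `positive_droplets` may be `NA` if no detection rule is
#'   needed).
#' @param max_rsd,remove_outliers Passed to [determine_aloq()].
#' @param min_positive_droplets,max_negative_replicates Passed to
#'   [determine_alod()].
#' @param bias Optional data frame with columns `target`, `reference`,
#'   `measured`.
#' @param z Optional data frame with columns `sample`, `measured`,
#'   `assigned`, `sigma`.
#' @param gm Optional data frame with columns `sample`, `gm_percent`.
#' @return Object of class `performance_report` with elements `$levels`
#'   (per target and level: n, mean, RSD, outlier count), `$limits` (per
#'   target: aLOQ, aLOD, with a flag when a noisy series yields
#'   aLOD > aLOQ), `$linearity`, and optional `$bias`, `$z`, `$gm`.
#' @export
performance_report <- function(replicates, max_rsd = 25,
                               remove_outliers = FALSE,
                               min_positive_droplets = 3,
                               max_negative_replicates = 1,
                               bias = NULL, z = NULL, gm = NULL) {
  required <- c("level_id", "target", "assigned_copies", "measured_copies",
                "positive_droplets")
  if (!is.data.frame(replicates) || !all(required %in% names(replicates))) {
    stop_ddplexr(sprintf("replicate table needs columns: %s",
                         paste(required, collapse = ", ")),
                 "ddplexr_format")
  }
  targets <- unique(replicates$target)
  per_target <- lapply(targets, function(tn) {
    df <- replicates[replicates$target == tn, ]
    levels <- lapply(split(df, df$level_id), function(g) {
      dilution_level(
        level_id = g$level_id[1],
        assigned_copies = g$assigned_copies[1],
        replicate_values = g$measured_copies,
        replicate_positive_droplets =
          if (all(is.na(g$positive_droplets))) NULL else g$positive_droplets
      )
    })
    aloq <- determine_aloq(levels, max_rsd = max_rsd,
                           remove_outliers = remove_outliers)
    alod <- tryCatch(
      determine_alod(levels, min_positive_droplets = min_positive_droplets,
                     max_negative_replicates = max_negative_replicates),
      ddplexr_invalid = function(e) NULL
    )
    lin <- tryCatch(
      linearity(df$assigned_copies, df$measured_copies),
      ddplexr_invalid = function(e) NULL
    )
    list(target = tn, aloq = aloq, alod = alod, linearity = lin)
  })
  levels_tbl <- do.call(rbind, lapply(per_target, function(pt) {
    cbind(target = pt$target, pt$aloq$levels, stringsAsFactors = FALSE)
  }))
  limits <- do.call(rbind, lapply(per_target, function(pt) {
    alod <- if (is.null(pt$alod)) NA_real_ else pt$alod$alod
    data.frame(
      target = pt$target, aloq = pt$aloq$aloq, alod = alod,
      alod_above_aloq = !is.na(alod) && !is.na(pt$aloq$aloq) &&
        alod > pt$aloq$aloq,
      stringsAsFactors = FALSE
    )
  }))
  lin_tbl <- do.call(rbind, lapply(per_target, function(pt) {
    if (is.null(pt$linearity)) return(NULL)
    data.frame(target = pt$target, slope = pt$linearity$slope,
               intercept = pt$linearity$intercept,
               r_squared = pt$linearity$r_squared, stringsAsFactors = FALSE)
  }))
  bias_tbl <- NULL
  if (!is.null(bias)) {
    stopifnot(all(c("target", "reference", "measured") %in% names(bias)))
    bias_tbl <- data.frame(
      target = bias$target, reference = bias$reference,
      measured = bias$measured,
      bias_percent = percent_bias(bias$reference, bias$measured),
      stringsAsFactors = FALSE
    )
  }
  z_tbl <- NULL
  if (!is.null(z)) {
    stopifnot(all(c("sample", "measured", "assigned", "sigma") %in% names(z)))
    zs <- mapply(function(m, a, s) z_score(m, a, s)$z,
                 z$measured, z$assigned, z$sigma)
    z_tbl <- data.frame(sample = z$sample, measured = z$measured,
                        assigned = z$assigned, sigma = z$sigma, z = zs,
                        pass = abs(zs) < 2 - 1e-9, stringsAsFactors = FALSE)
  }
  gm_tbl <- NULL
  if (!is.null(gm)) {
    stopifnot(all(c("sample", "gm_percent") %in% names(gm)))
    gm_tbl <- cbind(sample = gm$sample, gm_labelling_flags(gm$gm_percent))
  }
  structure(
    list(levels = levels_tbl, limits = limits, linearity = lin_tbl,
         bias = bias_tbl, z = z_tbl, gm = gm_tbl,
         settings = list(max_rsd = max_rsd, remove_outliers = remove_outliers,
                         min_positive_droplets = min_positive_droplets,
                         max_negative_replicates = max_negative_replicates)),
    class = "performance_report"
  )
}

#' @export
print.performance_report <- function(x, ...) {
  cat("<performance_report>\nLimits (copies per reaction):\n")
  print(x$limits, row.names = FALSE, digits = 4)
  if (!is.null(x$linearity)) {
    cat("Linearity:\n")
    print(x$linearity, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Write a performance report as a tab-delimited validation file
#'
#' Sections (levels, limits, linearity, bias, z-scores, GM flags) are
#' written one after another, each introduced by a `#` section header line.
#'
#' @param report A [performance_report()].
#' @param file Path to write to.
#' @return Invisibly, `file`.
#' @export
write_performance_report <- function(report, file) {
  stopifnot(inherits(report, "performance_report"))
  con <- base::file(file, open = "wt")
  on.exit(close(con))
  sections <- list(
    levels = report$levels, limits = report$limits,
    linearity = report$linearity, bias = report$bias,
    z_scores = report$z, gm_flags = report$gm
  )
  for (name in names(sections)) {
    tbl <- sections[[name]]
    if (is.null(tbl)) next
    writeLines(sprintf("# %s", name), con)
    num <- vapply(tbl, is.numeric, logical(1))
    tbl[num] <- lapply(tbl[num], signif, digits = 6)
    utils::write.table(tbl, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(file)
}

#' Labelling threshold flags for GM content
#'
#' Marks GM percentages against the 0.9% labelling threshold and the 0.1%
#' screening threshold for unauthorised events. Flags only; no regulatory
#' decision logic.
#'
#' @param gm_percent Numeric vector of GM contents in percent.
#' @return Data frame with `gm_percent`, `exceeds_0_9`, `exceeds_0_1`.
#' @export
gm_labelling_flags <- function(gm_percent) {
  data.frame(
    gm_percent = gm_percent,
    exceeds_0_9 = gm_percent >= 0.9,
    exceeds_0_1 = gm_percent >= 0.1
  )
}
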