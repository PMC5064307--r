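#' Read a raw per-droplet amplitude export
#'
#' Parses the comma-separated per-well export of raw droplet fluorescence
#' (one row per droplet, one amplitude column per channel) into a
#' [droplet_set()]. Amplitude columns are located by header token match, not
#' by position, because exports vary in column order; extra columns (for
#' example an instrument cluster call) are ignored.
#'
#' A header is matched for channel *k* when, after lower-casing and removal
#' of non-alphanumeric characters, it contains both the channel token
#' (default `"ch1"` / `"ch2"`) and the amplitude token (default
#' `"amplitude"`). The tokens are configurable because instrument software
#' versions differ in their exact header wording.
#'
#' @param file Path or connection to the comma-separated export. A header
#'   row is required; decimal separator is `"."`.
#' @param well_id Label for the well; defaults to the file name without
#'   extension when `file` is a path.
#' @param ch1_token,ch2_token,amplitude_token Header tokens (case and
#'   punctuation insensitive) used to locate the two amplitude columns.
#' @return A [droplet_set()] with one entry per data row, order preserved.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("Ch1 Amplitude,Ch2 Amplitude", "1000,900", "5200,880"), f)
#' read_amplitude_export(f, well_id = "A01")
#' @export
read_amplitude_export <- function(file, well_id = NULL,
                                  ch1_token = "ch1", ch2_token = "ch2",
                                  amplitude_token = "amplitude") {
  if (is.null(well_id)) {
    well_id <- if (is.character(file)) {
      sub("\\.[^.]*$", "", basename(file))
    } else {
      "well"
    }
  }
  df <- tryCatch(
    utils::read.csv(file, check.names = FALSE, colClasses = "character",
                    strip.white = TRUE),
    error = function(e) {
      stop_ddplexr(
        sprintf("cannot parse amplitude export: %s", conditionMessage(e)),
        "ddplexr_format"
      )
    }
  )
  norm <- function(x) gsub("[^a-z0-9]", "", tolower(x))
  headers <- names(df)
  nh <- norm(headers)
  locate <- function(ch_token) {
    hit <- which(grepl(norm(ch_token), nh, fixed = TRUE) &
                   grepl(norm(amplitude_token), nh, fixed = TRUE))
    if (length(hit) == 0) {
      stop_ddplexr(
        sprintf(
          "no amplitude column matching tokens '%s' + '%s' in header: %s",
          ch_token, amplitude_token, paste(headers, collapse = ", ")
        ),
        "ddplexr_format"
      )
    }
    hit[1]
  }
  i1 <- locate(ch1_token)
  i2 <- locate(ch2_token)
  if (nrow(df) == 0) {
    stop_ddplexr("amplitude export contains a header but no droplet rows",
                 "ddplexr_empty_input")
  }
  parse_col <- function(i) {
    raw <- df[[i]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val))
    if (length(bad) > 0) {
      stop_ddplexr(
        sprintf("non-numeric amplitude '%s' in column '%s', data row %d",
                raw[bad[1]], headers[i], bad[1]),
        "ddplexr_parse"
      )
    }
    val
  }
  droplet_set(ch1 = parse_col(i1), ch2 = parse_col(i2), well_id = well_id)
}

#' Write a droplet set in the raw amplitude export dialect
#'
#' Writes the same comma-separated format [read_amplitude_export()] reads,
#' so simulated wells can be round-tripped through the file-based workflow.
#'
#' @param droplets A [droplet_set()].
#' @param file Path or connection to write to.
#' @return Invisibly, `file`.
#' @export
write_amplitude_export <- function(droplets, file) {
  stopifnot(inherits(droplets, "droplet_set"))
  df <- data.frame(`Ch1 Amplitude` = droplets$ch1,
                   `Ch2 Amplitude` = droplets$ch2,
                   check.names = FALSE)
  utils::write.table(df, file, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(file)
}

results_columns <- c(
  "well", "target", "positives", "total", "p_hat", "lambda",
  "copies_per_uL", "copies_per_reaction", "ci_low", "ci_high",
  "detected", "saturated"
)

#' Write per-target quantification results as a tab-delimited table
#'
#' One data row per (well, target), long format, header written once.
#' Integer fields are written exactly; floating fields are rendered with a
#' fixed number of significant digits (default 4) so a written table can be
#' re-read with [read_results_table()] to that documented precision.
#'
#' @param results Data frame of quantification results as produced by
#'   [quantify_multiplex()] or [estimate_target()] (rows may be stacked
#'   across wells).
#' @param file Path or connection to write to.
#' @param digits Significant digits used for floating-point fields.
#' @return Invisibly, `file`.
#' @export
write_results_table <- function(results, file, digits = 4) {
  if (!is.data.frame(results) || nrow(results) == 0) {
    stop_ddplexr("results must be a non-empty data frame", "ddplexr_invalid")
  }
  missing_cols <- setdiff(results_columns, names(results))
  if (length(missing_cols) > 0) {
    stop_ddplexr(
      sprintf("results table lacks columns: %s",
              paste(missing_cols, collapse = ", ")),
      "ddplexr_invalid"
    )
  }
  out <- results[results_columns]
  for (col in c("p_hat", "lambda", "copies_per_uL", "copies_per_reaction",
                "ci_low", "ci_high")) {
    out[[col]] <- signif(out[[col]], digits)
  }
  out$detected <- ifelse(out$detected, "yes", "no")
  out$saturated <- ifelse(out$saturated, "yes", "no")
  status <- tryCatch(
    utils::write.table(out, file, sep = "\t", quote = FALSE,
                       row.names = FALSE),
    error = function(e) {
      stop_ddplexr(sprintf("cannot write results table: %s",
                           conditionMessage(e)), "ddplexr_io")
    }
  )
  invisible(file)
}

#' Read back a tab-delimited results table
#'
#' Inverse of [write_results_table()]: integer fields are recovered exactly,
#' floating fields to the precision they were written with.
#'
#' @param file Path or connection.
#' @return Data frame with the standard result columns; `detected` and
#'   `saturated` are logical.
#' @export
read_results_table <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE,
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(results_columns, names(df))
  if (length(missing_cols) > 0) {
    stop_ddplexr(
      sprintf("results table lacks columns: %s",
              paste(missing_cols, collapse = ", ")),
      "ddplexr_format"
    )
  }
  df$detected <- df$detected == "yes"
  df$saturated <- df$saturated == "yes"
  df$positives <- as.integer(df$positives)
  df$total <- as.integer(df$total)
  df
}

#' Write simulator ground truth as a tab-delimited table
#'
#' One row per droplet: per-target copy counts, the true amplitude band per
#' channel, and the rain flag.
#'
#' @param truth A `ground_truth` object from [simulate_well()].
#' @param file Path or connection.
#' @return Invisibly, `file`.
#' @export
write_ground_truth <- function(truth, file) {
  stopifnot(inherits(truth, "ground_truth"))
  df <- as.data.frame(truth$copies)
  names(df) <- paste0("copies_", colnames(truth$copies))
  df$band_ch1 <- truth$band_ch1
  df$band_ch2 <- truth$band_ch2
  df$rain <- ifelse(truth$rain, "yes", "no")
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
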