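# Shared fixtures: a canonical 4-plex layout (endogene + three GM events,
# two targets per channel) and simulator configurations built in code.

quad_layout <- function() {
  assay_layout_4plex(c("hmgA", "MON810", "MON863", "DP98140"),
                     assay_name = "MTQ1")
}

quad_sim <- function(copies = 500, seed = NULL, ...) {
  if (length(copies) == 1) {
    copies <- stats::setNames(rep(copies, 4), quad_layout()$targets$name)
  }
  simulation_config(copies_per_reaction = copies, seed = seed, ...)
}

write_amplitude_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

# cluster_grid built by hand for quantification tests
manual_cluster_grid <- function(counts) {
  structure(list(counts = counts, total = sum(counts)),
            class = "cluster_grid")
}
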