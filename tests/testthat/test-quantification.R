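# Brute-force oracle: enumerate all 16 cells and test the band rule directly.
enumerate_positive_cells <- function(channel, level) {
  cells <- expand.grid(band1 = 0:3, band2 = 0:3)
  band <- if (channel == 1) cells$band1 else cells$band2
  keep <- if (level == "low") band %in% c(1, 3) else band %in% c(2, 3)
  as.matrix(cells[keep, c("band1", "band2")])
}

cell_key <- function(m) sort(paste(m[, 1], m[, 2]))

test_that("positive cells match exhaustive enumeration of the band rule", {
  layout <- quad_layout()
  for (i in seq_len(4)) {
    tg <- layout$targets[i, ]
    got <- positive_cells(layout, tg$name)
    expect_equal(nrow(got), 8)
    expect_identical(cell_key(got),
                     cell_key(enumerate_positive_cells(tg$channel, tg$level)))
  }
  expect_error(positive_cells(layout, "nope"), class = "ddplexr_invalid")
})

test_that("positive-cell sets pairwise overlap in 4 cells and exclude (0,0)", {
  layout <- quad_layout()
  sets <- lapply(layout$targets$name,
                 function(tn) cell_key(positive_cells(layout, tn)))
  pairs <- combn(4, 2)
  for (k in seq_len(ncol(pairs))) {
    expect_length(intersect(sets[[pairs[1, k]]], sets[[pairs[2, k]]]), 4)
  }
  expect_false("0 0" %in% unlist(sets))
})

test_that("presence combinations follow 2^n - 1", {
  # independent oracle: count non-empty subsets of an n-set by enumeration
  n_subsets <- function(n) {
    sum(vapply(1:n, function(k) choose(n, k), numeric(1)))
  }
  expect_identical(count_combinations(4), 15L)
  expect_identical(count_combinations(1), 1L)
  expect_identical(count_combinations(3), 7L)
  for (n in 1:8) expect_equal(count_combinations(n), n_subsets(n))
  expect_error(count_combinations(0), class = "ddplexr_invalid")
})

test_that("Poisson estimates match the closed form", {
  qc <- quant_config()
  r0 <- estimate_target(0, 10000, qc)
  expect_equal(r0$lambda, 0)
  expect_equal(r0$copies_per_reaction, 0)
  expect_equal(r0$ci_low, 0)
  expect_false(r0$detected)

  r1 <- estimate_target(10000, 20000, qc)
  expect_equal(r1$p_hat, 0.5)
  expect_equal(r1$lambda, -log(0.5))
  expect_equal(r1$copies_per_uL, -log(0.5) / 0.00085)
  expect_equal(r1$copies_per_reaction, -log(0.5) / 0.00085 * 20)

  r2 <- estimate_target(1000, 15000, qc)
  expect_equal(r2$lambda, -log(14 / 15))
  expect_equal(r2$copies_per_uL, 81.17, tolerance = 1e-4)
  expect_equal(r2$copies_per_reaction, 1623.4, tolerance = 1e-4)
})

test_that("Wilson bounds agree with prop.test and transform monotonically", {
  qc <- quant_config()
  for (case in list(c(7, 10000), c(700, 10000), c(9999, 10000))) {
    pos <- case[1]; tot <- case[2]
    r <- estimate_target(pos, tot, qc)
    ref <- prop.test(pos, tot, correct = FALSE)$conf.int
    vol <- 0.00085
    expect_equal(r$ci_low, -log(1 - ref[1]) / vol * 20, tolerance = 1e-8)
    expect_equal(r$ci_high, -log(1 - ref[2]) / vol * 20, tolerance = 1e-8)
    expect_lte(r$ci_low, r$copies_per_reaction)
    expect_gte(r$ci_high, r$copies_per_reaction)
  }
  # normal-approximation strategy is available and also brackets the estimate
  qn <- quant_config(ci_method = "normal")
  rn <- estimate_target(700, 10000, qn)
  expect_lt(rn$ci_low, rn$copies_per_reaction)
  expect_gt(rn$ci_high, rn$copies_per_reaction)
})

test_that("saturated wells are flagged with non-finite estimates, not errors", {
  r <- estimate_target(10000, 10000)
  expect_true(r$saturated)
  expect_identical(r$lambda, Inf)
  expect_identical(r$ci_high, Inf)
  expect_true(is.finite(r$ci_low))
})

test_that("estimate validation and invariants hold", {
  expect_error(estimate_target(1, 0), class = "ddplexr_invalid")
  expect_error(estimate_target(11, 10), class = "ddplexr_invalid")
  expect_error(estimate_target(-1, 10), class = "ddplexr_invalid")

  # lambda strictly increasing in positives at fixed total
  lam <- vapply(0:100, function(p) estimate_target(p, 1000)$lambda, numeric(1))
  expect_true(all(diff(lam) > 0))

  # detection threshold is inclusive at 3 droplets
  expect_false(estimate_target(2, 1000)$detected)
  expect_true(estimate_target(3, 1000)$detected)

  # doubling droplet volume halves the concentration (scale equivariance)
  a <- estimate_target(500, 10000, quant_config(droplet_volume_nL = 0.85))
  b <- estimate_target(500, 10000, quant_config(droplet_volume_nL = 1.70))
  expect_equal(a$copies_per_uL, 2 * b$copies_per_uL)
})

test_that("multiplex quantification sums the right cells per target", {
  layout <- quad_layout()
  counts <- matrix(0L, 4, 4)
  counts[1, 1] <- 9000L # (0,0)
  counts[2, 1] <- 500L  # (1,0): ch1 low only
  counts[3, 1] <- 300L  # (2,0): ch1 high only
  counts[4, 1] <- 200L  # (3,0): ch1 double positive
  grid <- manual_cluster_grid(counts)
  res <- quantify_multiplex(grid, layout)
  expect_equal(res$target, layout$targets$name)

  low <- res[res$target == "hmgA", ]     # (channel 1, low)
  high <- res[res$target == "MON810", ]  # (channel 1, high)
  expect_equal(low$positives, 700L)      # bands {1,3}: 500 + 200
  expect_equal(high$positives, 500L)     # bands {2,3}: 300 + 200
  expect_equal(low$copies_per_reaction, -log(0.93) / 0.00085 * 20,
               tolerance = 1e-10)
  expect_equal(low$copies_per_reaction, 1707.5, tolerance = 1e-4)
  expect_equal(high$copies_per_reaction, -log(0.95) / 0.00085 * 20,
               tolerance = 1e-10)
  expect_equal(high$copies_per_reaction, 1206.9, tolerance = 1e-4)
  expect_equal(res$positives[res$target %in% c("MON863", "DP98140")],
               c(0L, 0L))

  # only the negative cell populated -> all four targets at zero
  neg <- manual_cluster_grid(matrix(c(100L, rep(0L, 15)), 4, 4))
  expect_true(all(quantify_multiplex(neg, layout)$lambda == 0))

  # a grid whose shape contradicts the layout is rejected
  duplex <- assay_layout(data.frame(name = c("a", "b"), channel = c(1, 1),
                                    level = c("low", "high")))
  expect_error(quantify_multiplex(grid, duplex), class = "ddplexr_invalid")
})

test_that("grid positives equal true positive droplets when classification is clean", {
  layout <- quad_layout()
  # tight clusters, no rain: classification should be exact
  w <- simulate_well(quad_sim(copies = 800), layout, seed = 31)
  ana <- analyze_well(w$droplets, layout)
  for (tn in layout$targets$name) {
    expect_equal(ana$results$positives[ana$results$target == tn],
                 true_positive_droplets(w$truth, tn))
  }
})
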