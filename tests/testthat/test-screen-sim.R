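test_that("internalization rates follow the designer efficiency ladder", {
  m <- uptake_model()
  # canonical signals: reference rate
  expect_equal(internalization_rate("PAAYAALAAV", m), 1)
  expect_equal(internalization_rate("PAEAAALLAV", m), 1)
  # FXNPXY and YXXXphiN: about half
  expect_equal(internalization_rate("PAFANPAYAV", m), 0.5)
  expect_equal(internalization_rate("ARYRRSLNHK", m), 0.5)
  # atypical spacers: 4-spacer nearly as efficient, 2- and 5-spacer halved
  expect_equal(internalization_rate("AEAAAALLAA", m), 0.9)
  expect_equal(internalization_rate("AEAALLAAAA", m), 0.5)
  expect_equal(internalization_rate("AEAAAAALLA", m), 0.5)
  # bare dileucine is weak; no signal at all is baseline
  expect_equal(internalization_rate("AAALLAAA", m), m$weak_dileucine_rate)
  expect_equal(internalization_rate("AAAAAAAA", m), m$baseline_rate)
  expect_equal(internalization_rate("GGSGGSGG", m), m$baseline_rate)
})

test_that("proline and downstream-DD modifiers boost dileucine rates, capped at 1", {
  m <- uptake_model()
  bare <- internalization_rate("AAAPLLAAA", m)      # P at -1 of LL
  expect_equal(bare, min(1, m$weak_dileucine_rate * m$proline_boost))
  dd <- internalization_rate("AAALLAADDA", m)       # DD downstream
  expect_equal(dd, min(1, m$weak_dileucine_rate * m$dd_boost))
  both <- internalization_rate("AAAPLLAADDA", m)
  expect_equal(both, min(1, m$weak_dileucine_rate * m$proline_boost * m$dd_boost))
  # canonical dileucine is already at the cap
  expect_equal(internalization_rate("AEAAAPLLDDA", m), 1)
})

test_that("limiting cases of the two-colour model behave as designed", {
  # near-total quenching and negligible uptake: green -> 0, red tracks E
  m0 <- uptake_model(quench_efficiency = 1 - 1e-9, rate_constant = 1e-9,
                     measurement_noise = 0, expression_dispersion = 0.3)
  cells <- simulate_cells(c(null = 1e-9), m0, n_cells = 200, seed = 1)
  expect_lt(max(cells$green), 1e-6)
  expect_equal(cells$red, cells$expression *
                 (1 - (1 - exp(-1e-9 * 1e-9 * 40 *
                   pmin(1, 2 * m0$saturation_scale /
                          (m0$saturation_scale + cells$expression))))),
               tolerance = 1e-6)
  # saturating uptake: red -> 0, green tracks E
  m1 <- uptake_model(rate_constant = 1000, measurement_noise = 0,
                     saturation_scale = 1e9)
  cells1 <- simulate_cells(c(fast = 1), m1, n_cells = 200, seed = 2)
  expect_lt(max(cells1$red / cells1$expression), 1e-6)
  expect_equal(cells1$green, cells1$expression, tolerance = 1e-6)
})

test_that("mean green/red ratio increases with internalization rate", {
  m <- uptake_model()
  grid <- c(0.05, 0.1, 0.25, 0.5, 0.9, 1)
  means <- vapply(grid, function(r) {
    cells <- simulate_cells(stats::setNames(r, "x"), m, n_cells = 4000,
                            seed = 100 + round(1000 * r))
    mean(log(cells$green / cells$red))
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("higher-rate constructs have stochastically larger ratios", {
  m <- uptake_model()
  cells <- simulate_cells(c(lo = 0.05, hi = 0.5), m, n_cells = 20000, seed = 5)
  r_lo <- sort(log(cells$green / cells$red)[cells$construct_id == "lo"])
  r_hi <- sort(log(cells$green / cells$red)[cells$construct_id == "hi"])
  qs <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(stats::quantile(r_hi, qs) > stats::quantile(r_lo, qs)))
})

test_that("gating excludes out-of-window cells and keeps populations disjoint", {
  m <- uptake_model()
  cells <- simulate_cells(c(a = 0.05, b = 1), m, n_cells = 5000, seed = 3)
  gates <- gate_config()
  g <- apply_gates(cells, gates)
  expect_identical(nrow(g$plus) + nrow(g$minus) + nrow(g$ungated) +
                     nrow(g$excluded), nrow(cells))
  key <- function(df) paste(df$construct_id, df$green, df$red)
  expect_length(intersect(key(g$plus), key(g$minus)), 0L)
  # percentile deciles: sizes close to 10% of in-window cells
  n_win <- nrow(cells) - nrow(g$excluded)
  expect_lt(abs(nrow(g$plus) - 0.1 * n_win), 0.02 * n_win + 2)
  expect_lt(abs(nrow(g$minus) - 0.1 * n_win), 0.02 * n_win + 2)
})

test_that("degenerate gate configurations behave sensibly", {
  cells <- data.frame(construct_id = "c", rate = 1,
                      expression = rep(1, 10), green = rep(4, 10),
                      red = rep(1, 10))
  # identical ratios: percentile thresholds put every cell in the plus gate
  g <- apply_gates(cells, gate_config(expression_window = c(0, 1)))
  expect_identical(nrow(g$plus), 10L)
  expect_identical(nrow(g$minus), 0L)
  # a window excluding everything empties both gates
  g2 <- apply_gates(cells, gate_config(expression_window = c(0, 1),
                                       plus_gate = 100, minus_gate = 0.001,
                                       percentile = FALSE))
  expect_identical(nrow(g2$minus), 0L)
  expect_error(apply_gates(cells[0, ], gate_config()), "empty")
  expect_error(gate_config(plus_gate = 0.1, minus_gate = 0.9), "disjoint")
})

test_that("screen scoring reports precision and recall against planted truth", {
  m <- uptake_model()
  rates <- c(sig1 = 1, sig2 = 1, null1 = m$baseline_rate,
             null2 = m$baseline_rate)
  truth <- c(sig1 = TRUE, sig2 = TRUE, null1 = FALSE, null2 = FALSE)
  res <- simulate_screen(rates, truth, m, n_cells = 4000, seed = 7)
  expect_true(all(res$recovered_plus %in% c("sig1", "sig2")))
  expect_equal(res$precision, 1.0)
  expect_equal(res$recall, 1.0)
  # determinism under a fixed seed
  res2 <- simulate_screen(rates, truth, m, n_cells = 4000, seed = 7)
  expect_identical(res$plus_tally, res2$plus_tally)
  expect_identical(res$precision, res2$precision)
})

test_that("an empty plus-gate recovery signals undefined precision", {
  m <- uptake_model()
  rates <- c(a = 0.5, b = 0.5)
  truth <- c(a = TRUE, b = TRUE)
  expect_warning(
    res <- simulate_screen(rates, truth, m, n_cells = 50, seed = 1,
                           min_cells = 10000L),
    "undefined")
  expect_true(is.na(res$precision))
  expect_equal(res$recall, 0.0)
})
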