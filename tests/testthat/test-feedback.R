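test_that("injection adds exactly the specified rate term", {
  net <- toy_cached()
  i_src <- match("casp3", net$species$id)
  i_tgt <- match("nfkb", net$species$id)
  set.seed(21)
  for (rep in 1:5) {
    st <- runif(nrow(net$species), 0, 0.3)
    d0 <- network_derivative(net, st)
    k <- runif(1, 0.1, 5)
    neg <- inject_feedback(net, feedback_spec("caspase3_active", "negative", k))
    dn <- network_derivative(neg, st)
    delta <- dn - d0
    expect_equal(unname(delta[i_tgt]), -k * st[i_src] * st[i_tgt],
                 tolerance = 1e-12)
    expect_true(all(delta[-i_tgt] == 0))
    pos <- inject_feedback(net, feedback_spec("caspase3_active", "positive", k))
    dp <- network_derivative(pos, st)
    expect_equal(unname((dp - d0)[i_tgt]), k * st[i_src], tolerance = 1e-12)
  }
  # zero strength is a null injection
  z <- inject_feedback(net, feedback_spec("caspase8_active", "negative", 0))
  st <- runif(nrow(net$species), 0, 0.3)
  expect_equal(network_derivative(z, st), network_derivative(net, st))
})

test_that("injections are additive in the derivative", {
  net <- toy_cached()
  s1 <- feedback_spec("caspase3_active", "negative", 0.7)
  s2 <- feedback_spec("caspase8_active", "positive", 2e-5)
  both <- inject_feedback(inject_feedback(net, s1), s2)
  st <- runif(nrow(net$species), 0, 0.3)
  d_base <- network_derivative(net, st)
  d1 <- network_derivative(inject_feedback(net, s1), st) - d_base
  d2 <- network_derivative(inject_feedback(net, s2), st) - d_base
  expect_equal(network_derivative(both, st) - d_base, d1 + d2,
               tolerance = 1e-12)
})

test_that("death time matches a fine-grid trajectory crossing oracle", {
  net <- toy_cached()
  m <- apoptosis_metrics(net, probe_dose = 1e-2)
  expect_true(m$apoptotic)
  expect_gt(m$initial_death_time, 0)
  # oracle: locate the 50%-of-final-level crossing on a 10x finer grid
  exec <- match("casp3", net$species$id)
  t_end <- 48 * 3600
  tr <- simulate_network(net, 1e-2, t_end,
                         times = seq(0, t_end, length.out = 20000L))
  cross <- which(tr$states[, exec] >= 0.5 * m$steady_level)[1]
  step <- t_end / 1999 # the metric's own reporting step
  expect_lt(abs(tr$times[cross] - m$initial_death_time), step)
})

test_that("a sub-threshold probe dose yields flagged undefined metrics", {
  net <- toy_cached()
  m <- apoptosis_metrics(net, probe_dose = 5e-4)
  expect_false(m$apoptotic)
  expect_true(is.na(m$initial_death_time))
  expect_true(is.na(m$steady_level))
})

test_that("stronger negative feedback never delays death; positive lowers the plateau", {
  net <- toy_cached()
  base <- apoptosis_metrics(net)
  thr <- 0.5 * base$steady_level
  ks <- c(0.01, 0.05, 0.2)
  times <- vapply(ks, function(k)
    apoptosis_metrics(inject_feedback(
      net, feedback_spec("caspase3_active", "negative", k)),
      threshold = thr)$initial_death_time, 0)
  expect_true(all(diff(c(base$initial_death_time, times)) <= 0))
  kp <- c(1e-6, 5e-6, 2e-5)
  levels <- vapply(kp, function(k)
    apoptosis_metrics(inject_feedback(
      net, feedback_spec("caspase3_active", "positive", k)))$steady_level, 0)
  expect_true(all(diff(c(base$steady_level, levels)) <= 0))
})

test_that("calibrated range is the contiguous prefix within the 20% limit", {
  net <- toy_cached()
  tpl <- feedback_spec("caspase3_active", "negative", 1)
  grid <- 10^seq(-2, 0.5, by = 0.5)
  rng <- calibrate_range(net, tpl, scan_grid = grid)
  expect_identical(rng$metric, "initial_death_time")
  expect_equal(rng$lo, grid[1])
  base <- rng$baseline
  ok <- which(rng$metric_values >= 0.8 * base)
  expect_equal(rng$hi, grid[max(ok)])
  # the point just past hi (if scanned) violates the limit
  past <- match(rng$hi, grid) + 1L
  if (past <= length(grid) && !is.na(rng$metric_values[past]))
    expect_lt(rng$metric_values[past], 0.8 * base)
  # a 3x finer grid places hi within one coarse step
  fine <- 10^seq(-2, 0.5, by = 1 / 6)
  rng_f <- calibrate_range(net, tpl, scan_grid = fine)
  expect_lte(abs(log10(rng_f$hi) - log10(rng$hi)), 0.5 + 1e-9)
  # positive feedback bounds the steady level instead
  rng_p <- calibrate_range(net, feedback_spec("caspase3_active", "positive", 1),
                           decades = c(-7, -4))
  expect_identical(rng_p$metric, "steady_level")
  expect_true(is.finite(rng_p$hi))
})

test_that("zero tolerance collapses the admissible range to unchanged metrics", {
  net <- toy_cached()
  tpl <- feedback_spec("caspase3_active", "negative", 1)
  rng <- calibrate_range(net, tpl, limit_fraction = 0,
                         scan_grid = c(1e-3, 1e-2, 1e-1, 1))
  # only strengths whose metric has not decreased at all survive
  if (is.finite(rng$hi)) {
    kept <- rng$metric_values[seq_len(match(rng$hi, rng$grid))]
    expect_true(all(kept >= rng$baseline))
  } else {
    expect_true(is.na(rng$hi))
  }
})

test_that("HD scan at strength zero reproduces the baseline bit for bit", {
  net <- toy_cached()
  cfg <- fast_config()
  ids <- c("kp_c8", "ki_c8", "kd_iap", "ka_c3b", "kd_dec")
  spec <- build_spectrum(net, ids, cfg)
  mut <- boolean_spectrum(ids, as.logical(spec$flags))
  scan <- hd_strength_scan(net, feedback_spec("caspase3_active", "negative", 1),
                           strengths = c(0, 0.3), mut, config = cfg)
  expect_equal(attr(scan, "baseline_hd"), 0)
  expect_equal(scan$hd[scan$strength == 0], 0) # exact null point
})
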