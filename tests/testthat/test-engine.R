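test_that("initialization converts percent concentrations to agent counts", {
  g <- make_regular_layout()
  p <- sim_params()
  set.seed(1)
  w <- initialize_world(p, g)
  total_px <- 972 * 684
  expect_equal(nrow(w$pos$MnSOD), round(0.00769 * total_px))  # 5113
  expect_equal(nrow(w$pos$CuZnSOD), round(0.00914 * total_px))
  expect_equal(nrow(w$pos$GpxMito), round(0.003 * total_px))
  expect_equal(nrow(w$pos$GpxCyto), round(0.00549 * total_px))
  expect_equal(nrow(w$pos$H2O2), 10000)
  expect_equal(nrow(w$pos$O2minus), 0)
  # placement respects the compartments and the injection square
  expect_true(all(compartment_of(w$pos$MnSOD, g) > 0))
  expect_true(all(compartment_of(w$pos$GpxMito, g) > 0))
  expect_true(all(compartment_of(w$pos$CuZnSOD, g) == 0))
  expect_true(all(compartment_of(w$pos$GpxCyto, g) == 0))
  inj <- w$pos$H2O2
  expect_true(all(abs(inj[, 1] - 972 / 2) <= 54 & abs(inj[, 2] - 684 / 2) <= 54))
  # Mn-SOD apportionment across equal-area mitochondria is near-even
  per_mito <- count_in_mito(w$pos$MnSOD, g)
  expect_true(max(per_mito) - min(per_mito) <= 1)

  w0 <- initialize_world(update_params(p, initial_h2o2 = 0), g)
  expect_equal(nrow(w0$pos$H2O2), 0)
  wz <- initialize_world(update_params(p, enzyme_mult = c(MnSOD = 0,
    CuZnSOD = 0, GpxMito = 0, GpxCyto = 0)), g)
  expect_equal(nrow(wz$pos$MnSOD) + nrow(wz$pos$CuZnSOD) +
               nrow(wz$pos$GpxMito) + nrow(wz$pos$GpxCyto), 0)
  expect_error(initialize_world(update_params(p, injection_side = 5000), g),
               "injection")
})

test_that("a world with no ROS sources stays empty", {
  fx <- make_mini_fixture(initial_h2o2 = 0, n_steps = 50,
                          leak = leak_rule(a0 = 0, a1 = 0))
  r <- run_simulation(fx$params, fx$geometry, seed = 2)
  expect_true(all(r$metrics$n_o2minus == 0))
  expect_true(all(r$metrics$n_h2o2 == 0))
  expect_true(all(r$metrics$reactive_fraction == 0))
})

test_that("runs are bit-identical under a fixed seed", {
  fx <- make_mini_fixture(n_steps = 60)
  r1 <- run_simulation(fx$params, fx$geometry, seed = 42)
  r2 <- run_simulation(fx$params, fx$geometry, seed = 42)
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$mito_o2, r2$mito_o2)
  expect_identical(r1$counters, r2$counters)
  r3 <- run_simulation(fx$params, fx$geometry, seed = 43)
  expect_false(identical(r1$metrics, r3$metrics))
})

test_that("replicate summaries are consistent with the stored series", {
  fx <- make_mini_fixture(n_steps = 40, n_replicates = 3)
  res <- run_replicates(fx$params, fx$geometry)
  expect_length(res$runs, 3)
  fr <- vapply(res$runs, function(r) r$metrics$reactive_fraction, numeric(40))
  expect_equal(res$summary$mean, rowMeans(fr))
  expect_equal(res$summary$sd, apply(fr, 1, sd))
  expect_equal(res$final_fractions, fr[40, ])
  # replicate i reproduces a direct run at base_seed + i - 1
  direct <- run_simulation(fx$params, fx$geometry, fx$params$base_seed + 1L)
  expect_identical(res$runs[[2]]$metrics, direct$metrics)
  # single replicate: mean equals the series, sd identically zero
  res1 <- run_replicates(update_params(fx$params, n_replicates = 1),
                         fx$geometry)
  expect_equal(res1$summary$mean, res1$runs[[1]]$metrics$reactive_fraction)
  expect_true(all(res1$summary$sd == 0))
})

test_that("event counters satisfy exact count bookkeeping over a run", {
  fx <- make_mini_fixture(n_steps = 150)
  r <- run_simulation(fx$params, fx$geometry, seed = 3)
  cnt <- r$counters
  final <- r$metrics[nrow(r$metrics), ]
  expect_equal(final$n_o2minus,
               cnt[["leaked"]] - cnt[["dismutated"]] - cnt[["o2_decayed"]])
  expect_equal(final$n_h2o2,
               cnt[["injected"]] + cnt[["h2o2_created"]] -
                 cnt[["reduced"]] - cnt[["h2o2_decayed"]])
  # 1:1 dismutation conserves O2- loss = H2O2 gain
  expect_equal(cnt[["dismutated"]], cnt[["h2o2_created"]])
})

test_that("with all sinks and sources disabled the total agent count is conserved", {
  fx <- make_mini_fixture(n_steps = 200,
                          leak = leak_rule(a0 = 0, a1 = 0),
                          decay = c(O2minus = 0, H2O2 = 0, enzyme = 0),
                          respiration_rate = 0,
                          enzyme_mult = c(MnSOD = 0, CuZnSOD = 0,
                                          GpxMito = 0, GpxCyto = 0))
  r <- run_simulation(fx$params, fx$geometry, seed = 4)
  expect_true(all(r$metrics$n_h2o2 == 300))
  expect_true(all(r$metrics$n_o2minus == 0))
})

test_that("an unstressed cell stays quiescent (no spontaneous whole-cell RIRR)", {
  fx <- make_mini_fixture(initial_h2o2 = 0, n_steps = 1000, n_replicates = 2)
  res <- run_replicates(fx$params, fx$geometry)
  # mean reactive fraction below 5% at rest, over the whole run and over
  # its tail; windows rather than the single final step because one
  # fluctuating mitochondrion quantizes an instantaneous reading to 11%
  expect_lt(mean(res$summary$mean), 5)
  expect_lt(mean(res$summary$mean[901:1000]), 5)
})

test_that("enzymes remain confined to their home compartments over a full run", {
  fx <- make_mini_fixture(n_steps = 120)
  r <- run_simulation(fx$params, fx$geometry, seed = 5)
  w <- r$world
  g <- w$geometry
  expect_true(all(compartment_of(w$pos$MnSOD, g) > 0))
  expect_true(all(compartment_of(w$pos$GpxMito, g) > 0))
  expect_true(all(compartment_of(w$pos$CuZnSOD, g) == 0))
  expect_true(all(compartment_of(w$pos$GpxCyto, g) == 0))
  for (sp in names(w$pos)) {
    pos <- w$pos[[sp]]
    if (nrow(pos) == 0) next
    expect_true(all(pos[, 1] >= 0 & pos[, 1] < g$grid_width &
                    pos[, 2] >= 0 & pos[, 2] < g$grid_height))
  }
})
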