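test_that("probability aggregation applies the inexcitable-exclusion rule", {
  mk <- function(outcomes) {
    data.frame(ina_scale = 0.5, sigma_scale = 1, fib_density = 0.5,
               replicate = seq_along(outcomes), seed = seq_along(outcomes),
               outcome = outcomes, n_cycles = 0L, mean_apd = 300,
               min_rvi = 100)
  }
  # 7 blocked of 10
  t1 <- mk(c(rep("BLOCK_NO_REENTRY", 7), rep("NO_BLOCK", 3)))
  p1 <- compute_pb(t1, "ina_scale")
  expect_equal(p1$p_block, 0.7)
  expect_equal(p1$N, 10)

  # 2 inexcitable, 4 blocked: P = 4 / 8
  t2 <- mk(c(rep("INEXCITABLE", 2), rep("BLOCK_NO_REENTRY", 4),
             rep("NO_BLOCK", 4)))
  p2 <- compute_pb(t2, "ina_scale")
  expect_equal(p2$p_block, 0.5)
  expect_equal(p2$N, 8)
  expect_equal(p2$n_excluded, 2)

  # all inexcitable: masked, not an error
  t3 <- mk(rep("INEXCITABLE", 5))
  p3 <- compute_pb(t3, "ina_scale")
  expect_true(is.na(p3$p_block))
  expect_equal(p3$N, 0)

  # no block anywhere: all-zero map
  t4 <- mk(rep("NO_BLOCK", 10))
  expect_equal(compute_pb(t4, "ina_scale")$p_block, 0)

  # re-entrant outcomes count as blocked and as re-entry
  t5 <- mk(c("REENTRY_SUSTAINED", "REENTRY_NONSUSTAINED", "NO_BLOCK",
             "BLOCK_NO_REENTRY"))
  p5 <- compute_pb(t5, "ina_scale")
  expect_equal(p5$p_block, 0.75)
  expect_equal(p5$p_reentry, 0.5)
  expect_equal(p5$p_sustained, 0.25)
})

test_that("per-row fibrosis seeds are reproducible and distinct", {
  s1 <- infarctsim:::fibrosis_seed(1, 0.5, 3)
  expect_identical(s1, infarctsim:::fibrosis_seed(1, 0.5, 3))
  expect_false(s1 == infarctsim:::fibrosis_seed(1, 0.55, 3))
  expect_false(s1 == infarctsim:::fibrosis_seed(1, 0.5, 4))
  expect_false(s1 == infarctsim:::fibrosis_seed(2, 0.5, 3))
})

test_that("a degenerate one-point sweep yields one classified row and caches it", {
  spec <- sweep_spec(ina_scales = 1.0, sigma_scales = 1.0,
                     fib_densities = 0, n_seeds = 1L, ci = 320)
  cache <- file.path(tempdir(), "sweep-cache-test")
  tab <- run_sweep(spec, template = coarse_infarct(),
                   config = sim_config(), root_seed = 1, t_post = 600,
                   cache_dir = cache)
  expect_equal(nrow(tab), 1)
  # unremodeled control: the premature beat propagates everywhere
  expect_equal(tab$outcome, "NO_BLOCK")
  # resuming from cache returns the identical row without recomputation
  t0 <- system.time(tab2 <- run_sweep(spec, template = coarse_infarct(),
                                      config = sim_config(), root_seed = 1,
                                      t_post = 600, cache_dir = cache))[3]
  expect_identical(tab$outcome, tab2$outcome)
  expect_lt(t0, 2)
})

test_that("sweep rows fail independently without aborting", {
  # a sheet with no scar makes classification fail on every row (no
  # protocol sites for the isthmus), but the sweep must return rows
  spec <- sweep_spec(ina_scales = 1, sigma_scales = 1, fib_densities = 0.5,
                     n_seeds = 1L)
  tab <- suppressWarnings(
    run_sweep(spec, template = build_sheet(4, 400), t_post = 200))
  expect_equal(nrow(tab), 1)
  expect_equal(tab$outcome, "ERROR")
})
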