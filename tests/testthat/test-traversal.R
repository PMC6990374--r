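test_that("an open isthmus conducts and a saturated one is disconnected", {
  g <- traversal_template(h_um = 400)
  tr0 <- isthmus_traversal(g, t_max = 300)
  expect_true(tr0$traversed)
  # exit no earlier than straight-line travel at the healthy CV
  cy <- g$scar_center[2]
  hl <- g$scar$scar_half_length_mm
  expect_gt(tr0$t_exit, (cy + hl) / 0.7)

  g9 <- generate_fibrosis(g, 0.9, seed = 1)
  tr9 <- isthmus_traversal(g9, t_max = 300)
  expect_false(tr9$traversed)
  # the dead wavefront ends the run long before the time cap
  expect_lt(tr9$t_stop, 300)
})

test_that("traversal is seed-deterministic", {
  g <- traversal_template(h_um = 400)
  a <- isthmus_traversal(generate_fibrosis(g, 0.45, seed = 12), t_max = 300)
  b <- isthmus_traversal(generate_fibrosis(g, 0.45, seed = 12), t_max = 300)
  expect_identical(a$traversed, b$traversed)
  expect_identical(a$t_exit, b$t_exit)
})
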