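test_that("sheet construction yields the expected element counts", {
  expect_equal(prod(dim(build_sheet(40, 200)$labels)), 40000)
  expect_equal(prod(dim(build_sheet(40, 400)$labels)), 10000)
  expect_equal(prod(dim(build_sheet(1, 200)$labels)), 25)
  expect_error(build_sheet(1, 300), "integer")
})

test_that("the idealized scar carves a channel of the right width that spans bottom to top", {
  g <- infarct_template()
  lab <- g$labels
  # channel exactly 4 mm / 0.2 mm = 20 element columns wide
  bz_cols <- which(apply(lab == TISSUE_LABELS[["BZ"]], 1, any))
  expect_length(bz_cols, 20)
  expect_true(all(diff(bz_cols) == 1))
  # scar exists and stays off the stimulated bottom row
  expect_gt(sum(lab == TISSUE_LABELS[["SCAR"]]), 0)
  expect_false(any(lab[, 1] == TISSUE_LABELS[["SCAR"]]))
  # a conducting path exists bottom-to-top (healthy margins + channel)
  expect_true(bz_percolates(g))
  # label conservation
  expect_equal(sum(label_counts(g)), g$nx * g$ny)
})

test_that("narrow channels and missing margins are rejected", {
  expect_error(add_idealized_scar(build_sheet(40, 200),
                                  scar_spec(isthmus_width_mm = 0.2)),
               "2 elements")
  expect_error(add_idealized_scar(build_sheet(40, 200),
                                  scar_spec(scar_depth_mm = 17)),
               "margin")
})

test_that("fibrosis density is exact, confined to the border zone, and seed-deterministic", {
  g <- infarct_template()
  n_bz <- sum(g$labels == TISSUE_LABELS[["BZ"]])

  g0 <- generate_fibrosis(g, 0, seed = 1)
  expect_identical(g0$labels, g$labels)

  for (d in c(0.05, 0.5, 0.9)) {
    gf <- generate_fibrosis(g, d, seed = 7)
    n_fib <- sum(gf$labels == TISSUE_LABELS[["FIBROTIC"]])
    expect_equal(n_fib, round(d * n_bz))
    # realized fraction within 1/n_bz of request
    expect_lt(abs(n_fib / n_bz - d), 1 / n_bz + 1e-12)
    # fibrosis only where the pre-fibrosis label was BZ
    expect_true(all(g$labels[gf$labels == TISSUE_LABELS[["FIBROTIC"]]] ==
                      TISSUE_LABELS[["BZ"]]))
    # label conservation
    expect_equal(sum(label_counts(gf)), g$nx * g$ny)
  }

  a <- generate_fibrosis(g, 0.5, seed = 42)
  b <- generate_fibrosis(g, 0.5, seed = 42)
  c2 <- generate_fibrosis(g, 0.5, seed = 43)
  expect_identical(a$labels, b$labels)
  expect_false(identical(a$labels, c2$labels))

  expect_error(generate_fibrosis(g, 0.95, seed = 1), "0.9")
})

test_that("fibrosis sampling leaves the caller's RNG stream untouched", {
  set.seed(123)
  r1 <- runif(1)
  set.seed(123)
  invisible(generate_fibrosis(infarct_template(), 0.3, seed = 9))
  r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("channel percolation is monotonically non-increasing in fibrosis density", {
  g <- traversal_template()
  densities <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  frac <- vapply(densities, function(d) {
    mean(vapply(1:6, function(r) {
      bz_percolates(generate_fibrosis(g, d, seed = 100 * d + r))
    }, logical(1)))
  }, numeric(1))
  expect_true(all(diff(frac) <= 0))
})
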