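# Algebraic contracts of the building blocks: channel split/concat
# conservation, sigmoid-gate bounds, residual identities, and equivalence of
# the C2S2 forward pass with a straight-line reference composition.

test_that("channel split follows the ceiling/floor rule and round-trips", {
  x <- rand_fm(4, 4, 64, 2, seed = 1)
  halves <- c2s2_split(x)
  expect_equal(dim(halves[[1]])[3], 32)
  expect_equal(dim(halves[[2]])[3], 32)

  x5 <- rand_fm(4, 4, 5, 2, seed = 2)
  h5 <- c2s2_split(x5)
  expect_equal(dim(h5[[1]])[3], 3)
  expect_equal(dim(h5[[2]])[3], 2)

  x8 <- rand_fm(4, 4, 8, 2, seed = 3)
  h8 <- c2s2_split(x8)
  expect_identical(cnatnet:::fm_concat(h8[[1]], h8[[2]]), x8)

  expect_error(c2s2_split(rand_fm(4, 4, 1, 1)), "at least 2 channels")
})

test_that("C2S2 with identity branches and merge reproduces the input", {
  x <- rand_fm(5, 5, 8, 2, seed = 4)
  m <- c2s2_block(8, 8, n_units = 1, unit_kind = "standard",
                  merge_channels = 4, stem = FALSE, merge = FALSE)
  cnatnet:::zero_weights(m)  # residual bottlenecks become identities
  expect_equal(forward(m, x), x, tolerance = 1e-12)
})

test_that("C2S2 pre-merge concatenation conserves branch channels", {
  m <- c2s2_block(8, 12, n_units = 1, merge_channels = 6, merge = FALSE)
  x <- rand_fm(6, 6, 8, 1, seed = 5)
  y <- forward(m, x)
  expect_equal(dim(y)[3], 12)  # two 6-channel branches concatenated
  m2 <- c2s2_block(8, 10, n_units = 1, merge_channels = 4)
  y2 <- forward(m2, rand_fm(6, 6, 8, 1, seed = 6))
  expect_equal(dim(y2)[3], 10)
})

test_that("C2S2 forward equals a straight-line reference composition", {
  set.seed(7)
  m <- c2s2_block(16, 16, n_units = 2, unit_kind = "ghost")
  x <- rand_fm(8, 8, 16, 1, seed = 8)
  y <- forward(m, x)
  # reference: stem -> split -> branch stacks -> concat -> merge, step by step
  s <- forward(m$children$stem, x)
  halves <- cnatnet:::fm_split_at(s, m$c_split)
  b1 <- halves[[1]]
  for (u in m$children$branch1$children) b1 <- forward(u, b1)
  b2 <- halves[[2]]
  for (u in m$children$branch2$children) b2 <- forward(u, b2)
  ref <- forward(m$children$merge, cnatnet:::fm_concat(b1, b2))
  expect_equal(y, ref, tolerance = 1e-6)
})

test_that("C2S2 stride and channel contracts hold", {
  m <- c2s2_block(8, 16, stride = 2)
  y <- forward(m, rand_fm(8, 8, 8, 1, seed = 9))
  expect_equal(dim(y), c(4, 4, 16, 1))
  expect_error(forward(c2s2_block(8, 16), rand_fm(4, 4, 6, 1)),
               "expected 8 input channels, received 6")
  expect_error(c2s2_block(8, 4, merge_channels = 6), "must not exceed")
  expect_error(c2s2_block(8, 8, n_units = 0), "n_units")
})

test_that("ABlock gate is bounded and obeys the closed-form cases", {
  x <- rand_fm(5, 5, 4, 2, seed = 10)
  zero_gate <- list(w = array(0, c(1, 1, 4, 4)), b = numeric(4))
  expect_equal(ablock_forward(x, zero_gate), 0.5 * x, tolerance = 1e-12)

  sat_gate <- list(w = array(0, c(1, 1, 4, 4)), b = rep(20, 4))
  expect_equal(ablock_forward(x, sat_gate), x, tolerance = 1e-6)

  z <- array(0, c(5, 5, 4, 2))
  rnd_gate <- list(w = array(rnorm(16), c(1, 1, 4, 4)), b = rnorm(4))
  expect_equal(ablock_forward(z, rnd_gate), z)

  m <- ablock(4)
  g <- forward(m$children$gate, x)
  s <- cnatnet:::sigmoid(g)
  expect_true(all(s > 0 & s < 1))
  expect_true(all(abs(forward(m, x)) <= abs(x)))
})

test_that("AnC2f fuses shortcut and main branch by addition", {
  x <- rand_fm(5, 5, 6, 2, seed = 11)
  # main branch forced to zero: zero-weight non-residual refinement units
  m <- anc2f_block(6, 6, n_ablocks = 2, stem = FALSE)
  cnatnet:::zero_weights(m)
  expect_equal(forward(m, x), x, tolerance = 1e-12)

  # one pure gate unit with zero gate and identity stem: x + 0.5 x
  m2 <- anc2f_block(6, 6, n_ablocks = 1, refine = FALSE, stem = FALSE)
  cnatnet:::zero_weights(m2)
  expect_equal(forward(m2, x), 1.5 * x, tolerance = 1e-12)

  # stride-1 residual shape contract
  m3 <- anc2f_block(6, 6, n_ablocks = 2)
  expect_equal(dim(forward(m3, x)), dim(x))
  expect_error(anc2f_block(6, 6, n_ablocks = 0), "n_ablocks")
})

test_that("ghost bottleneck honours residual, width and stride contracts", {
  x <- rand_fm(6, 6, 8, 2, seed = 12)
  m <- ghost_bottleneck_block(8, 8)
  cnatnet:::zero_weights(m)
  expect_equal(forward(m, x), x, tolerance = 1e-12)

  m2 <- ghost_bottleneck_block(8, 12)
  expect_equal(dim(forward(m2, x))[3], 12)
  expect_error(ghost_bottleneck_block(8, 8, stride = 3), "stride")

  # ghost unit is strictly cheaper than a standard bottleneck at equal widths
  for (c in c(8, 16, 32)) {
    pg <- oracle_param_count(ghost_bottleneck_block(c, c))
    pb <- oracle_param_count(bottleneck_block(c, c, e = 0.5))
    expect_lt(pg, pb)
  }
})

test_that("DWClassify head meets its shape, pooling and zero contracts", {
  x <- rand_fm(6, 6, 8, 3, seed = 13)
  m <- dwclassify_head(8, 2)
  lg <- forward(m, x)
  expect_equal(dim(lg), c(3, 2))

  # spatially constant input: identical logits for any map size
  for (hw in list(c(4, 4), c(7, 5), c(12, 12))) {
    xc <- array(rep(seq_len(8), each = hw[1] * hw[2]), c(hw, 8, 1))
    lg_c <- forward(m, xc)
    if (hw[1] == 4) base <- lg_c else expect_equal(lg_c, base, tolerance = 1e-10)
  }

  mz <- dwclassify_head(8, 3)
  cnatnet:::zero_weights(mz)
  lz <- forward(mz, x)
  expect_equal(lz, matrix(0, 3, 3), ignore_attr = TRUE)
  p <- exp(lz) / rowSums(exp(lz))
  expect_equal(as.numeric(p), rep(1 / 3, 9))

  expect_error(dwclassify_head(8, 1), "num_classes")
  expect_error(forward(m, rand_fm(4, 4, 6, 1)), "expected 8 input channels")
})

test_that("forward passes stay finite on standard-normal inputs", {
  makers <- list(
    function() conv_unit(4, 8, 3),
    function() bottleneck_block(4, 4),
    function() ghost_bottleneck_block(4, 4),
    function() c2f_block(4, 8, n = 2),
    function() c2s2_block(4, 8, n_units = 2),
    function() anc2f_block(4, 8, n_ablocks = 2),
    function() dwclassify_head(4, 2),
    function() dense_head(4, 2, hidden = 16))
  for (i in seq_along(makers)) {
    withr::with_seed(100 + i, {
      m <- makers[[i]]()
      y <- forward(m, rand_fm(8, 8, 4, 2), training = TRUE)
      expect_true(all(is.finite(y)))
    })
  }
})
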