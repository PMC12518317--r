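# Backpropagation is verified against a central finite-difference oracle for
# every layer and block type; this is what makes the training pipeline
# trustworthy.

test_that("analytic gradients match finite differences for all block types", {
  makers <- list(
    convunit = function() conv_unit(4, 6, 3),
    convunit_s2 = function() conv_unit(4, 6, 3, stride = 2),
    depthwise = function() conv_unit(4, 4, 3, groups = 4),
    bottleneck = function() bottleneck_block(4, 4),
    ghost = function() ghost_bottleneck_block(4, 4),
    ghost_s2 = function() ghost_bottleneck_block(4, 6, stride = 2),
    c2f = function() c2f_block(4, 6, n = 2),
    c2s2 = function() c2s2_block(4, 8, n_units = 2),
    ablock = function() ablock(4),
    anc2f = function() anc2f_block(4, 6, n_ablocks = 2),
    dwclassify = function() dwclassify_head(4, 3),
    densehead = function() dense_head(4, 3, hidden = 8))
  for (nm in names(makers)) {
    err <- fd_gradcheck(makers[[nm]], seed = match(nm, names(makers)))
    expect_lt(err, 1e-6, label = paste0(nm, " max relative gradient error"))
  }
})

test_that("cross-entropy loss gradient matches finite differences", {
  withr::with_seed(5, {
    lg <- matrix(rnorm(8), 4, 2)
    lab <- c(1L, 2L, 2L, 1L)
    l <- cnatnet:::softmax_xent(lg, lab)
    eps <- 1e-6
    for (i in seq_along(lg)) {
      lp <- lg; lp[i] <- lp[i] + eps
      lm <- lg; lm[i] <- lm[i] - eps
      g_num <- (cnatnet:::softmax_xent(lp, lab)$loss -
                  cnatnet:::softmax_xent(lm, lab)$loss) / (2 * eps)
      expect_equal(l$grad[i], g_num, tolerance = 1e-5)
    }
  })
})
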