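# Analytic parameter/FLOP accounting against hand arithmetic and the
# brute-force enumeration oracle.

test_that("C2S2 parameter formula matches hand-verified values", {
  expect_equal(params_c2s2(list(c_split = 1, k = 1, c_merge = 1, c_out = 1)), 3)
  expect_equal(params_c2s2(list(c_split = 32, k = 3, c_merge = 64,
                                c_out = 128)), 26624)
  expect_equal(params_c2s2(list(c_split = 16, k = 3, c_merge = 32,
                                c_out = 64)), 6656)
  expect_error(params_c2s2(list(c_split = 0, k = 3, c_merge = 1, c_out = 1)),
               "positive")
})

test_that("depthwise-separable parameter and FLOP formulas agree", {
  expect_equal(params_dw(1, 1, 1), 2)
  expect_equal(params_dw(64, 3, 2), 704)
  expect_equal(params_dw(128, 3, 1000), 129152)
  expect_equal(flops_dw(1, 1, 64, 3, 2), 704)
  expect_equal(flops_dw(7, 7, 64, 3, 2), 34496)
  expect_equal(flops_dw(2, 2, 1, 1, 1), 8)
  expect_error(params_dw(-1, 3, 2), "positive")
  # identity: FLOPs = H * W * params, property-checked over random args
  withr::with_seed(21, {
    for (i in 1:50) {
      a <- sample(1:64, 5, replace = TRUE)
      expect_identical(flops_dw(a[1], a[2], a[3], a[4], a[5]),
                       a[1] * a[2] * params_dw(a[3], a[4], a[5]))
    }
  })
})

test_that("whole-model sums match hand arithmetic and scale linearly", {
  empty <- layer_spec(1, 1, 1)[0, ]
  expect_equal(params_model(empty), 0)
  expect_equal(flops_model(empty), 0)
  l1 <- layer_spec(3, 16, 3, has_bias = TRUE)
  expect_equal(params_model(l1), 448)
  expect_equal(params_model(rbind(l1, layer_spec(16, 32, 3, has_bias = TRUE))),
               5088)
  l2 <- layer_spec(3, 16, 3, h = 8, w = 8)
  expect_equal(flops_model(l2), 27648)
  l2big <- l2; l2big$h <- 16; l2big$w <- 16
  expect_equal(flops_model(l2big), 4 * flops_model(l2))
})

test_that("analytic counts are non-decreasing in every argument", {
  base <- c(h = 4, w = 5, c_in = 8, k = 3, c_out = 6)
  f0 <- flops_dw(base["h"], base["w"], base["c_in"], base["k"], base["c_out"])
  for (j in seq_along(base)) {
    b <- base; b[j] <- b[j] + 2
    expect_gte(flops_dw(b["h"], b["w"], b["c_in"], b["k"], b["c_out"]), f0)
  }
  p0 <- params_c2s2(list(c_split = 4, k = 3, c_merge = 8, c_out = 16))
  for (fld in c("c_split", "k", "c_merge", "c_out")) {
    sp <- list(c_split = 4, k = 3, c_merge = 8, c_out = 16)
    sp[[fld]] <- sp[[fld]] + 2
    expect_gte(params_c2s2(sp), p0)
  }
})

test_that("enumeration oracle counts single layers exactly", {
  withr::with_seed(31, {
    conv <- cnatnet:::nn_conv2d(3, 16, 3)
    expect_equal(oracle_param_count(conv), 432)
    expect_equal(params_model(layer_spec(3, 16, 3)), 432)
    unit <- conv_unit(3, 16, 3)  # conv + batch-norm scale and shift
    expect_equal(oracle_param_count(unit), 432 + 32)
    convb <- cnatnet:::nn_conv2d(3, 16, 3, bias = TRUE)
    both <- cnatnet:::nn_seq(list(convb, cnatnet:::nn_batchnorm(16)))
    expect_equal(oracle_param_count(both), 432 + 16 + 32)
    expect_equal(oracle_param_count(cnatnet:::nn_seq(list())), 0)
  })
})

test_that("analytic totals equal enumeration on random bias-free conv stacks", {
  withr::with_seed(41, {
    for (rep in 1:100) {
      depth <- sample(1:5, 1)
      cs <- sample(1:24, depth + 1, replace = TRUE)
      ks <- sample(c(1L, 3L, 5L), depth, replace = TRUE)
      specs <- do.call(rbind, lapply(seq_len(depth), function(l)
        layer_spec(cs[l], cs[l + 1], ks[l])))
      stack <- cnatnet:::nn_seq(lapply(seq_len(depth), function(l)
        cnatnet:::nn_conv2d(cs[l], cs[l + 1], ks[l])))
      expect_identical(as.numeric(params_model(specs)),
                       as.numeric(oracle_param_count(stack)))
    }
  })
})

test_that("network profile is additive and renders rounded M/B totals", {
  net <- build_variant("M9", scale = "n", num_classes = 2, input_size = 64,
                       seed = 2)
  pr <- profile_network(net)
  expect_equal(sum(pr$per_block$params), pr$params_analytic)
  expect_equal(sum(pr$per_block$flops), pr$flops_analytic)
  expect_equal(sum(pr$per_block$params_oracle), pr$params_oracle)
  expect_equal(format_millions(6412345), "6.4 M")
  expect_equal(format_billions(1712345678), "1.7 B")
  # analytic = oracle in the bias-free/norm-free regime
  withr::with_seed(42, {
    stack <- cnatnet:::nn_seq(list(cnatnet:::nn_conv2d(3, 8, 3),
                                   cnatnet:::nn_conv2d(8, 4, 1)))
    pr2 <- profile_network(stack, input_size = 16)
    expect_equal(pr2$params_analytic, pr2$params_oracle)
  })
})

test_that("deploy-convention count folds exactly one scale per norm channel", {
  unit <- conv_unit(5, 12, 3)
  expect_equal(oracle_param_count(unit) - oracle_param_count(unit, deploy = TRUE),
               12)
})
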