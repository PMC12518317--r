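# Network assembly: variant factory, scale presets, shape contracts, and
# build determinism.

test_that("variant flags match the ablation grid and reject unknown ids", {
  expect_equal(variant_flags("M1"),
               c(c2s2 = FALSE, anc2f = FALSE, dwclassify = FALSE))
  expect_equal(variant_flags("M9"),
               c(c2s2 = TRUE, anc2f = TRUE, dwclassify = TRUE))
  expect_equal(variant_flags("M7"),
               c(c2s2 = TRUE, anc2f = FALSE, dwclassify = TRUE))
  expect_equal(variant_flags("M6"),
               c(c2s2 = TRUE, anc2f = TRUE, dwclassify = FALSE))
  expect_error(variant_flags("M5"), "M1, M2, M3, M4, M6, M7, M8, M9")
  expect_error(variant_flags("bogus"), "valid variants")
})

test_that("scale presets carry the published multipliers", {
  expect_equal(scale_preset("n"),
               list(depth_mult = 0.33, width_mult = 0.25, max_channels = 1024L))
  expect_equal(scale_preset("s"),
               list(depth_mult = 0.33, width_mult = 0.50, max_channels = 1024L))
  expect_equal(scale_preset("m"),
               list(depth_mult = 0.67, width_mult = 0.75, max_channels = 768L))
  expect_error(scale_preset("xl"), "valid scales")
})

test_that("every variant builds and runs a 64-px forward pass", {
  x <- rand_fm(64, 64, 3, 1, seed = 51, sd = 0.3)
  for (v in c("M1", "M2", "M3", "M4", "M6", "M7", "M8", "M9")) {
    net <- build_variant(v, scale = "n", num_classes = 2, input_size = 64,
                         seed = 1)
    lg <- forward(net, x)
    expect_equal(dim(lg), c(1, 2), label = v)
    expect_true(all(is.finite(lg)), label = v)
  }
})

test_that("the assembled network maps a 224-px batch to a logit matrix", {
  net <- build_cnatnet(network_config(scale = "n", num_classes = 4,
                                      input_size = 224), seed = 3)
  x <- rand_fm(224, 224, 3, 2, seed = 52, sd = 0.3)
  lg <- forward(net, x)
  expect_equal(dim(lg), c(2, 4))
  expect_error(network_config(scale = "n", input_size = 100),
               "divisible by the total stride")
})

test_that("changing the class count changes only head parameters", {
  n2 <- build_variant("M9", scale = "n", num_classes = 2, input_size = 64,
                      seed = 1)
  n7 <- build_variant("M9", scale = "n", num_classes = 7, input_size = 64,
                      seed = 1)
  backbone <- function(net)
    sum(vapply(net$children[setdiff(names(net$children), "head")],
               oracle_param_count, 0))
  expect_identical(backbone(n2), backbone(n7))
  expect_gt(oracle_param_count(n7$children$head),
            oracle_param_count(n2$children$head))
})

test_that("disabling all flags reproduces the M1 factory parameter-for-parameter", {
  a <- build_variant("M1", scale = "n", num_classes = 2, input_size = 64,
                     seed = 9)
  b <- build_cnatnet(network_config(scale = "n", num_classes = 2,
                                    input_size = 64, use_c2s2 = FALSE,
                                    use_anc2f = FALSE,
                                    use_dwclassify = FALSE), seed = 9)
  expect_identical(state_dict(a), state_dict(b))
})

test_that("builds are deterministic under a seed", {
  a <- build_variant("M9", scale = "n", num_classes = 2, input_size = 64,
                     seed = 4)
  b <- build_variant("M9", scale = "n", num_classes = 2, input_size = 64,
                     seed = 4)
  expect_identical(state_dict(a), state_dict(b))
  expect_identical(oracle_param_count(a), oracle_param_count(b))
})

test_that("ablation parameter ordering follows the published directions", {
  p <- vapply(c(M1 = "M1", M2 = "M2", M3 = "M3", M4 = "M4", M7 = "M7",
                M9 = "M9"),
              function(v) oracle_param_count(
                build_variant(v, scale = "s", num_classes = 1000, seed = 1)),
              0)
  expect_lt(p[["M2"]], p[["M1"]])
  expect_lt(p[["M4"]], p[["M1"]])
  expect_gt(p[["M3"]], p[["M1"]])
  expect_lt(p[["M7"]], min(p[["M2"]], p[["M4"]]))
  expect_lt(p[["M9"]], p[["M3"]])
})
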