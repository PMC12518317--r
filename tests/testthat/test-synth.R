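# Synthetic filament-scene generator: determinism, class-separability by
# construction, exact stratified splits, and augmentation contracts.

test_that("identical spec and seed render bit-identical images", {
  sp <- scene_spec("premium", "cluster", n_filaments = 8, seed = 77)
  a <- render_scene(sp, size = 64)
  b <- render_scene(sp, size = 64)
  expect_identical(a, b)
  # a different seed changes the scene
  c <- render_scene(scene_spec("premium", "cluster", n_filaments = 8,
                               seed = 78), size = 64)
  expect_false(identical(as.numeric(a), as.numeric(c)))
})

test_that("monomer scenes contain exactly one connected filament stroke", {
  ap <- grade_appearance("premium")
  ap$break_prob <- 0
  for (seed in 1:5) {
    img <- render_scene(scene_spec("premium", "monomer", seed = seed), ap)
    expect_equal(attr(img, "n_filaments"), 1L)
    lab <- EBImage::bwlabel(attr(img, "mask"))
    expect_equal(max(lab), 1)
  }
})

test_that("scene specs enforce the level/filament-count invariants", {
  expect_error(scene_spec("premium", "monomer", n_filaments = 3),
               "exactly 1")
  expect_error(scene_spec("normal", "cluster", n_filaments = 2),
               "at least 5")
  expect_error(render_scene(scene_spec("premium", "monomer"), size = 8),
               "size")
})

test_that("grades are separated in hue/saturation across many seeded pairs", {
  gap <- function(img, ap) {
    px <- matrix(img, ncol = 3)
    hsv <- grDevices::rgb2hsv(px[, 1], px[, 2], px[, 3], maxColorValue = 1)
    m <- hsv[2, ] > 0.3 & hsv[3, ] > 0.2
    c(hue = mean(hsv[1, m]) * 360, sat = mean(hsv[2, m]))
  }
  stats <- t(vapply(1:50, function(s) {
    p <- render_scene(scene_spec("premium", "monomer", seed = s,
                                 background = "clean"))
    n <- render_scene(scene_spec("normal", "monomer", seed = s,
                                 background = "clean"))
    c(gap(p), gap(n))
  }, numeric(4)))
  hue_gap <- mean(stats[, 3]) - mean(stats[, 1])
  # configured ranges: premium hue 2-16, normal 30-46 degrees
  expect_gt(hue_gap, 14)
  expect_gt(mean(stats[, 2]) - mean(stats[, 4]), 0.2)
})

test_that("splits are exact, stratified and disjoint", {
  m <- plan_manifest(synth_config(n_images = 1000, seed = 3))
  expect_equal(unname(table(m$split)[c("train", "val", "test")]),
               table(factor(c(rep("train", 700), rep("val", 200),
                              rep("test", 100))))[c("train", "val", "test")],
               ignore_attr = TRUE)
  tab <- table(m$split, paste(m$grade, m$level))
  expect_true(all(tab >= 1))
  expect_false(any(duplicated(m$path)))
  # a non-decimal total still apportions exactly by largest remainder
  m2 <- plan_manifest(synth_config(n_images = 157, seed = 4))
  expect_equal(sort(as.numeric(table(m2$split))), c(16, 31, 110))
  expect_error(plan_manifest(synth_config(n_images = 12, seed = 1)),
               "too small")
})

test_that("generated datasets are reproducible and complete on disk", {
  d1 <- file.path(tempdir(), "cnat_rep1")
  d2 <- file.path(tempdir(), "cnat_rep2")
  m1 <- generate_dataset(synth_config(out_dir = d1, n_images = 40, seed = 5))
  m2 <- generate_dataset(synth_config(out_dir = d2, n_images = 40, seed = 5))
  cols <- names(m1)
  expect_identical(as.data.frame(m1)[cols], as.data.frame(m2)[cols])
  for (i in seq_len(nrow(m1))) {
    expect_identical(png::readPNG(file.path(d1, m1$path[i])),
                     png::readPNG(file.path(d2, m2$path[i])))
  }
  rm <- read_manifest(d1)
  expect_equal(rm$path, m1$path)
  expect_true(all(file.exists(file.path(d1, rm$path))))
})

test_that("the hue-threshold baseline separates the default dataset", {
  man <- shared_dataset("color")
  hb <- hue_baseline_accuracy(man)
  expect_gt(hb$accuracy, 0.9)
})

test_that("augmentations obey identity, involution and size contracts", {
  img <- render_scene(scene_spec("normal", "monomer", seed = 9), size = 64)
  attributes(img)[c("mask", "n_filaments")] <- NULL

  expect_identical(augment_image(augment_image(img, "hflip"), "hflip"), img)
  expect_equal(augment_image(img, c("rotate", "brightness"),
                             params = list(angle = 0, factor = 1)), img)
  r <- augment_image(img, "rotate", params = list(angle = 7.3))
  expect_equal(dim(r), dim(img))
  a <- augment_image(img, "affine", seed = 2)
  expect_equal(dim(a), dim(img))
  expect_error(augment_image(img, "cutmix"), "unknown augmentation")
  # seeded draws are reproducible
  expect_identical(augment_image(img, c("rotate", "affine"), seed = 3),
                   augment_image(img, c("rotate", "affine"), seed = 3))
})

test_that("90-degree rotation matches an explicit coordinate-remap oracle", {
  withr::with_seed(13, {
    img <- array(runif(8 * 8 * 3), c(8, 8, 3))
    r <- augment_image(img, "rotate", params = list(angle = 90))
    # counter-clockwise: output row r' = W + 1 - c, column c' = r
    oracle <- array(0, dim(img))
    for (rr in 1:8) for (cc in 1:8)
      oracle[8 + 1 - cc, rr, ] <- img[rr, cc, ]
    expect_identical(r, oracle)
    # four quarter-turns return the original
    r4 <- img
    for (q in 1:4) r4 <- augment_image(r4, "rotate", params = list(angle = 90))
    expect_identical(r4, img)
  })
})
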