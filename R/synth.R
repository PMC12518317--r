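# Procedural synthetic safflower-filament scenes. Filaments are rendered as
# random cubic Bezier strokes with grade-conditional colour, stroke width,
# width jitter and integrity breaks, over clean, cluttered or occluded
# backgrounds, under two lighting regimes, at two viewing distances. The
# generator stands in for a private field-acquired dataset: it reproduces
# the dataset's *structure* (grade x level x acquisition strata, 7:2:1
# stratified splits), not real safflower statistics.

#' Grade-conditional appearance parameters
#'
#' Premium filaments are bright, saturated red-orange, evenly thick and
#' intact; normal-grade filaments are dimmer, duller, of inconsistent
#' thickness and frequently broken. Under the default `cue = "color"` the
#' two grades have disjoint hue and saturation ranges, so the classes are
#' separable by construction from colour statistics alone. Under
#' `cue = "structure"` both grades share one colour range and differ only in
#' localized integrity cues (width jitter and breaks).
#'
#' @param grade `"premium"` or `"normal"`.
#' @param cue `"color"` or `"structure"`.
#' @return a list: `hue` (degrees), `sat`, `val` ranges, `width_mean` and
#'   `width_jitter` (pixels at the 64-px reference size), `curvature`,
#'   `break_prob`.
#' @export
grade_appearance <- function(grade = c("premium", "normal"),
                             cue = c("color", "structure")) {
  grade <- match.arg(grade)
  cue <- match.arg(cue)
  if (cue == "color") {
    if (grade == "premium")
      list(hue = c(2, 16), sat = c(0.75, 0.95), val = c(0.75, 0.95),
           width_mean = 2.4, width_jitter = 0.25, curvature = 0.35,
           break_prob = 0.05)
    else
      list(hue = c(30, 46), sat = c(0.35, 0.55), val = c(0.45, 0.65),
           width_mean = 1.8, width_jitter = 0.8, curvature = 0.6,
           break_prob = 0.35)
  } else {
    shared <- list(hue = c(18, 30), sat = c(0.55, 0.75), val = c(0.6, 0.8))
    if (grade == "premium")
      c(shared, list(width_mean = 2.6, width_jitter = 0.1, curvature = 0.35,
                     break_prob = 0, fragmented = FALSE, spot_rate = 0))
    else
      # damaged fibre: dash-like integrity breaks, irregular width, and
      # dark blemish spots scattered along the stroke
      c(shared, list(width_mean = 2.6, width_jitter = 0.7, curvature = 0.5,
                     break_prob = 1, fragmented = TRUE, spot_rate = 0.12))
  }
}

#' Scene specification
#'
#' @param grade `"premium"` or `"normal"`.
#' @param level `"cluster"` (>= 5 filaments) or `"monomer"` (exactly 1).
#' @param n_filaments filament count; defaults to 1 for monomer and 12 for
#'   cluster scenes.
#' @param lighting `"natural"` or `"supplementary"`.
#' @param background `"clean"`, `"cluttered"` or `"occluded"`.
#' @param view `"close"` or `"distant"`.
#' @param seed integer scene seed; the spec plus seed fully determines every
#'   rendered byte.
#' @return a validated `cnat_scene_spec` list.
#' @export
scene_spec <- function(grade, level, n_filaments = NULL,
                       lighting = c("natural", "supplementary"),
                       background = c("clean", "cluttered", "occluded"),
                       view = c("close", "distant"), seed = 1L) {
  grade <- match.arg(grade, c("premium", "normal"))
  level <- match.arg(level, c("cluster", "monomer"))
  if (is.null(n_filaments)) n_filaments <- if (level == "monomer") 1L else 12L
  n_filaments <- as.integer(n_filaments)
  if (level == "monomer" && n_filaments != 1L)
    stop("scene_spec: monomer scenes must have exactly 1 filament")
  if (level == "cluster" && n_filaments < 5L)
    stop("scene_spec: cluster scenes need at least 5 filaments")
  spec <- list(grade = grade, level = level, n_filaments = n_filaments,
               lighting = match.arg(lighting),
               background = match.arg(background),
               view = match.arg(view), seed = as.integer(seed))
  class(spec) <- "cnat_scene_spec"
  spec
}

hsv_to_rgb <- function(h, s, v) {
  as.numeric(grDevices::col2rgb(grDevices::hsv(h / 360, s, v))) / 255
}

runif_in <- function(r) stats::runif(1, r[1], r[2])

# stamp a soft disk of colour col at (cy, cx) radius w onto canvas/mask
stamp_disk <- function(canvas, mask, cy, cx, w, col, alpha = 0.95) {
  d <- dim(canvas)
  r <- ceiling(w + 0.5)
  y0 <- max(1, floor(cy - r)); y1 <- min(d[1], ceiling(cy + r))
  x0 <- max(1, floor(cx - r)); x1 <- min(d[2], ceiling(cx + r))
  if (y0 > y1 || x0 > x1) return(list(canvas = canvas, mask = mask))
  ys <- y0:y1
  xs <- x0:x1
  dist <- sqrt(outer((ys - cy)^2, (xs - cx)^2, `+`))
  a <- alpha * pmin(1, pmax(0, w - dist + 0.5))
  for (ch in 1:3)
    canvas[ys, xs, ch] <- canvas[ys, xs, ch] * (1 - a) + col[ch] * a
  mask[ys, xs] <- mask[ys, xs] | (a > 0.3)
  list(canvas = canvas, mask = mask)
}

draw_background <- function(size, background) {
  base <- c(0.82, 0.78, 0.70)  # desaturated beige board
  gx <- matrix(seq(-0.03, 0.03, length.out = size), size, size)
  canvas <- array(0, c(size, size, 3))
  for (ch in 1:3)
    canvas[, , ch] <- base[ch] + gx + matrix(stats::rnorm(size^2, 0, 0.012),
                                             size, size)
  if (background %in% c("cluttered", "occluded")) {
    nblob <- sample(6:12, 1)
    for (i in seq_len(nblob)) {
      cy <- stats::runif(1, 1, size); cx <- stats::runif(1, 1, size)
      ry <- stats::runif(1, size / 16, size / 5)
      rx <- stats::runif(1, size / 16, size / 5)
      g <- stats::runif(1, 0.45, 0.75)
      col <- g * c(1, 1, 1) + c(0, stats::runif(1, 0, 0.08), 0)  # grey-green
      ys <- seq_len(size); xs <- seq_len(size)
      m <- outer(((ys - cy) / ry)^2, ((xs - cx) / rx)^2, `+`) <= 1
      a <- 0.5 * m
      for (ch in 1:3)
        canvas[, , ch] <- canvas[, , ch] * (1 - a) + col[ch] * a
    }
  }
  pmin(pmax(canvas, 0), 1)
}

draw_filament <- function(canvas, mask, appearance, size, view_factor) {
  ap <- appearance
  col <- hsv_to_rgb(runif_in(ap$hue), runif_in(ap$sat), runif_in(ap$val))
  len_frac <- if (view_factor < 1) stats::runif(1, 0.3, 0.55)
              else stats::runif(1, 0.5, 0.9)
  # cubic Bezier control points: random chord plus curvature perturbations
  p0 <- stats::runif(2, 0.08 * size, 0.92 * size)
  ang <- stats::runif(1, 0, 2 * pi)
  chord <- len_frac * size
  p3 <- pmin(pmax(p0 + chord * c(sin(ang), cos(ang)), 2), size - 1)
  perp <- c(cos(ang), -sin(ang))
  amp <- ap$curvature * chord
  p1 <- p0 + (p3 - p0) / 3 + perp * stats::rnorm(1, 0, amp / 2)
  p2 <- p0 + 2 * (p3 - p0) / 3 + perp * stats::rnorm(1, 0, amp / 2)
  npts <- max(24L, as.integer(2.5 * chord))
  t <- seq(0, 1, length.out = npts)
  bez <- function(a, b, c_, d)
    (1 - t)^3 * a + 3 * (1 - t)^2 * t * b + 3 * (1 - t) * t^2 * c_ + t^3 * d
  cy <- bez(p0[1], p1[1], p2[1], p3[1])
  cx <- bez(p0[2], p1[2], p2[2], p3[2])
  scale <- size / 64
  jit <- cumsum(stats::rnorm(npts, 0, 0.12))
  jit <- jit - mean(jit)
  w <- pmax(0.55, ap$width_mean * view_factor * scale *
              (1 + ap$width_jitter * jit))
  keep <- rep(TRUE, npts)
  if (isTRUE(ap$fragmented)) {
    # periodic gaps along the whole stroke: dense local integrity evidence
    per <- stats::runif(1, 0.35, 0.5)
    duty <- stats::runif(1, 0.35, 0.5)
    ph <- stats::runif(1)
    keep <- ((t + ph) %% per) / per < duty
  } else if (stats::runif(1) < ap$break_prob) {
    for (b in seq_len(sample(1:3, 1))) {
      g0 <- stats::runif(1, 0.1, 0.8)
      g1 <- g0 + stats::runif(1, 0.08, 0.2)
      keep[t >= g0 & t <= g1] <- FALSE
    }
  }
  for (i in which(keep)) {
    res <- stamp_disk(canvas, mask, cy[i], cx[i], w[i], col)
    canvas <- res$canvas; mask <- res$mask
  }
  spot_rate <- ap$spot_rate %||% 0
  if (spot_rate > 0) {
    kept <- which(keep)
    n_spots <- 2L + stats::rpois(1, spot_rate * length(kept) / 2.5)
    dark <- c(0.16, 0.09, 0.06)  # oxidised blemish
    for (s in seq_len(n_spots)) {
      i <- sample(kept, 1)
      res <- stamp_disk(canvas, mask, cy[i], cx[i],
                        stats::runif(1, 1.5, 2.3), dark)
      canvas <- res$canvas; mask <- res$mask
    }
  }
  list(canvas = canvas, mask = mask)
}

#' Render a synthetic filament scene
#'
#' Draws `n_filaments` grade-conditioned Bezier strokes over the specified
#' background, applies the occluder (for occluded backgrounds) and the
#' lighting gain/colour shift. Identical spec and seed give a bit-identical
#' image.
#'
#' @param spec a [scene_spec()].
#' @param appearance a [grade_appearance()] list (defaults to the spec's
#'   grade under the colour cue).
#' @param size image side in pixels (>= 64 recommended; >= 16 enforced).
#' @return an `size x size x 3` RGB array in `[0, 1]`, with attributes
#'   `mask` (logical filament-coverage matrix, pre-occlusion) and
#'   `n_filaments`.
#' @export
render_scene <- function(spec, appearance = NULL, size = 64L) {
  stopifnot(inherits(spec, "cnat_scene_spec"))
  if (size < 16L) stop("render_scene: size must be >= 16")
  if (is.null(appearance)) appearance <- grade_appearance(spec$grade)
  with_seed(spec$seed, {
    canvas <- draw_background(size, spec$background)
    mask <- matrix(FALSE, size, size)
    vf <- if (spec$view == "close") 1.25 else 0.7
    for (f in seq_len(spec$n_filaments)) {
      res <- draw_filament(canvas, mask, appearance, size, vf)
      canvas <- res$canvas; mask <- res$mask
    }
    if (spec$background == "occluded") {
      # opaque band across a random edge region
      bw <- as.integer(stats::runif(1, 0.12, 0.25) * size)
      side <- sample(1:4, 1)
      occ <- c(0.35, 0.3, 0.28) + stats::runif(3, 0, 0.05)
      idx <- seq_len(bw)
      if (side == 2) idx <- size - idx + 1L
      if (side <= 2) for (ch in 1:3) canvas[idx, , ch] <- occ[ch]
      else {
        if (side == 4) idx <- size - idx + 1L
        for (ch in 1:3) canvas[, idx, ch] <- occ[ch]
      }
    }
    gain <- if (spec$lighting == "natural") 1.0 else 1.12
    shift <- if (spec$lighting == "natural") c(0.015, 0, -0.01)
             else c(-0.01, 0, 0.03)
    for (ch in 1:3) canvas[, , ch] <- canvas[, , ch] * gain + shift[ch]
    canvas <- pmin(pmax(canvas, 0), 1)
    attr(canvas, "mask") <- mask
    attr(canvas, "n_filaments") <- spec$n_filaments
    canvas
  })
}

# --- dataset planning and generation ---------------------------------------

#' Synthetic dataset configuration
#'
#' Defaults define the package's reference desk-scale dataset: 160 images of
#' 64 x 64 px, both task levels, a mildly premium-leaning class balance
#' (11:10, the direction of the source dataset's strata totals), colour as
#' the discriminating cue, and a 7:2:1 train/val/test split.
#'
#' @param out_dir output directory (required by [generate_dataset()]).
#' @param n_images total image count (>= 12).
#' @param size image side in pixels.
#' @param seed master seed; per-image seeds are derived as
#'   `(seed %% 94906249) * 131 + 2 * i`, so records are order-independent.
#' @param ratio train/val/test weights.
#' @param p_premium,p_monomer marginal class/level proportions.
#' @param cue `"color"` or `"structure"` (see [grade_appearance()]).
#' @param scenario `"full"` draws lighting/background/view per the
#'   acquisition strata; `"controlled"` fixes them (natural light, clean
#'   background, close view) to isolate the grade cue.
#' @return a `cnat_synth_config` list.
#' @export
synth_config <- function(out_dir = NULL, n_images = 160L, size = 64L,
                         seed = 1L, ratio = c(7, 2, 1),
                         p_premium = 11 / 21, p_monomer = 0.5,
                         cue = c("color", "structure"),
                         scenario = c("full", "controlled")) {
  cue <- match.arg(cue)
  scenario <- match.arg(scenario)
  if (n_images < 12L)
    stop("n_images too small: need at least 12 for a stratified 7:2:1 split")
  if (any(ratio <= 0) || length(ratio) != 3L)
    stop("ratio must be three positive weights")
  structure(list(out_dir = out_dir, n_images = as.integer(n_images),
                 size = as.integer(size), seed = as.integer(seed),
                 ratio = ratio, p_premium = p_premium,
                 p_monomer = p_monomer, cue = cue, scenario = scenario),
            class = "cnat_synth_config")
}

# apportion n into integer counts proportional to w (largest remainder;
# ties broken by position)
largest_remainder <- function(n, w) {
  q <- n * w / sum(w)
  f <- floor(q)
  rem <- n - sum(f)
  if (rem > 0) {
    ord <- order(q - f, seq_along(q), decreasing = c(TRUE, FALSE),
                 method = "radix")
    f[ord[seq_len(rem)]] <- f[ord[seq_len(rem)]] + 1
  }
  as.integer(f)
}

image_seed <- function(master, i) {
  as.integer((as.double(master %% 94906249L) * 131 + 2 * i) %% 2147483647)
}

#' Plan a dataset manifest without rendering
#'
#' Computes the deterministic record table: one row per image with its
#' grade, level, acquisition scenario, split and derived seed. Splits are
#' exact under largest-remainder rounding, globally and stratified so every
#' grade x level cell appears in every split; the three split sets are
#' disjoint by construction.
#'
#' @param config a [synth_config()].
#' @return a data frame with columns `path`, `grade`, `level`, `lighting`,
#'   `background`, `view`, `split`, `n_filaments`, `seed`.
#' @export
plan_manifest <- function(config) {
  stopifnot(inherits(config, "cnat_synth_config"))
  n <- config$n_images
  cells <- expand.grid(grade = c("premium", "normal"),
                       level = c("cluster", "monomer"),
                       stringsAsFactors = FALSE)
  wcell <- c(config$p_premium, 1 - config$p_premium) %o%
    c(1 - config$p_monomer, config$p_monomer)
  cell_n <- largest_remainder(n, as.numeric(wcell))
  # cells with zero marginal weight (e.g. single-level datasets) are dropped
  # from stratification entirely
  nonzero <- as.numeric(wcell) > 0
  cells <- cells[nonzero, , drop = FALSE]
  cell_n <- cell_n[nonzero]
  if (any(cell_n < 3L))
    stop("n_images too small to place every grade x level cell in every split")
  ratio <- config$ratio / sum(config$ratio)
  split_target <- largest_remainder(n, ratio)
  # per-cell largest remainder, then move single records between splits
  # until column totals match the global targets (never emptying a cell)
  alloc <- t(vapply(cell_n, largest_remainder, integer(3), w = ratio))
  repeat {
    tot <- colSums(alloc)
    over <- which(tot > split_target)
    if (!length(over)) break
    under <- which(tot < split_target)[1L]
    s <- over[1L]
    donor <- which(alloc[, s] == max(alloc[, s]))[1L]
    alloc[donor, s] <- alloc[donor, s] - 1L
    alloc[donor, under] <- alloc[donor, under] + 1L
  }
  if (any(alloc < 1L))
    stop("n_images too small to place every grade x level cell in every split")

  splits <- c("train", "val", "test")
  rows <- vector("list", nrow(cells))
  i0 <- 0L
  for (ci in seq_len(nrow(cells))) {
    nc <- cell_n[ci]
    lab <- rep(splits, times = alloc[ci, ])
    lab <- with_seed(image_seed(config$seed, 1000000L + ci), sample(lab))
    idx <- i0 + seq_len(nc)
    seeds <- vapply(idx, image_seed, 0L, master = config$seed)
    sc <- t(vapply(seeds, function(s) with_seed(s, {
      nf <- if (cells$level[ci] == "monomer") 1L else sample(8:18, 1)
      if (config$scenario == "controlled")
        c(lighting = "natural", background = "clean", view = "close",
          nf = as.character(nf))
      else
        c(lighting = sample(c("natural", "supplementary"), 1,
                            prob = c(35, 23)),
          background = sample(c("clean", "cluttered", "occluded"), 1,
                              prob = c(33, 17, 15)),
          view = sample(c("close", "distant"), 1, prob = c(33, 25)),
          nf = as.character(nf))
    }), character(4)))
    rows[[ci]] <- data.frame(
      path = file.path("images", sprintf("%s_%s_%05d.png",
                                         cells$grade[ci], cells$level[ci], idx)),
      grade = cells$grade[ci], level = cells$level[ci],
      lighting = sc[, "lighting"], background = sc[, "background"],
      view = sc[, "view"], split = lab,
      n_filaments = as.integer(sc[, "nf"]), seed = seeds,
      stringsAsFactors = FALSE)
    i0 <- i0 + nc
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  attr(manifest, "config") <- config
  class(manifest) <- c("cnat_manifest", "data.frame")
  manifest
}

#' Generate a synthetic filament dataset on disk
#'
#' Renders every planned scene to PNG and writes the CSV manifest
#' (`manifest.csv`, header `path,grade,level,lighting,background,view,split`
#' plus bookkeeping columns) and the generation config (`config.yaml`) into
#' `config$out_dir`. Fully deterministic for a given config.
#'
#' @param config a [synth_config()] with `out_dir` set.
#' @return the manifest data frame, invisibly, with attribute `dir`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "cnat_synth_config"))
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  manifest <- plan_manifest(config)
  img_dir <- file.path(config$out_dir, "images")
  ok <- dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(img_dir))
    stop("cannot create output directory ", img_dir)
  for (r in seq_len(nrow(manifest))) {
    spec <- scene_spec(manifest$grade[r], manifest$level[r],
                       n_filaments = manifest$n_filaments[r],
                       lighting = manifest$lighting[r],
                       background = manifest$background[r],
                       view = manifest$view[r], seed = manifest$seed[r])
    img <- render_scene(spec, grade_appearance(spec$grade, config$cue),
                        size = config$size)
    png::writePNG(img, file.path(config$out_dir, manifest$path[r]))
  }
  utils::write.csv(manifest, file.path(config$out_dir, "manifest.csv"),
                   row.names = FALSE)
  yaml::write_yaml(unclass(config)[setdiff(names(config), "out_dir")],
                   file.path(config$out_dir, "config.yaml"))
  attr(manifest, "dir") <- config$out_dir
  invisible(manifest)
}

#' Read a dataset manifest from disk
#' @param path the `manifest.csv` file (or its directory).
#' @return a `cnat_manifest` data frame with attribute `dir`.
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.csv")
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  attr(m, "dir") <- dirname(path)
  class(m) <- c("cnat_manifest", "data.frame")
  m
}

manifest_dir <- function(manifest, dir = NULL) {
  d <- dir %||% attr(manifest, "dir")
  if (is.null(d)) stop("manifest has no directory attribute; pass dir=")
  d
}

load_images <- function(manifest, dir = NULL) {
  d <- manifest_dir(manifest, dir)
  imgs <- lapply(manifest$path, function(p) {
    f <- file.path(d, p)
    if (!file.exists(f)) stop("image missing on disk: ", f)
    img <- png::readPNG(f)
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3L))
    img[, , 1:3, drop = FALSE]
  })
  sz <- dim(imgs[[1L]])
  x <- array(0, c(sz[1L], sz[2L], 3L, length(imgs)))
  for (i in seq_along(imgs)) x[, , , i] <- imgs[[i]]
  x
}

# --- augmentation -----------------------------------------------------------

clamp01 <- function(x) pmin(pmax(x, 0), 1)

rotate90_ccw <- function(img) {
  d <- dim(img)
  aperm(img, c(2L, 1L, 3L))[d[2L]:1L, , , drop = FALSE]
}

eb_from <- function(img) EBImage::Image(aperm(img, c(2L, 1L, 3L)),
                                        colormode = "Color")
eb_to <- function(eb) aperm(as.array(eb), c(2L, 1L, 3L))

bg_col_of <- function(img) {
  grDevices::rgb(stats::median(img[, , 1]), stats::median(img[, , 2]),
                 stats::median(img[, , 3]))
}

#' Augment an image
#'
#' Applies the training-time augmentations in the given order: random (or
#' specified) rotation, horizontal flip, brightness scaling and small affine
#' warps. Output dimensions always equal input dimensions; rotation and
#' affine fill exposed regions with the image's median (background) colour.
#' Exact multiples of 90 degrees are applied as exact pixel permutations.
#'
#' @param img an `H x W x 3` array in `[0, 1]`.
#' @param ops character vector drawn from
#'   `c("rotate", "hflip", "brightness", "affine")`.
#' @param seed optional seed for the randomly drawn parameters.
#' @param params optional list overriding draws: `angle` (degrees,
#'   counter-clockwise), `factor` (brightness), `shear`, `shift`.
#' @return the augmented image, same dimensions.
#' @export
augment_image <- function(img, ops, seed = NULL, params = list()) {
  known <- c("rotate", "hflip", "brightness", "affine")
  bad <- setdiff(ops, known)
  if (length(bad))
    stop("unknown augmentation op(s): ", paste(bad, collapse = ", "))
  run <- function() {
    for (op in ops) img <<- switch(op,
      hflip = img[, dim(img)[2L]:1L, , drop = FALSE],
      brightness = {
        f <- params$factor %||% stats::runif(1, 0.8, 1.2)
        clamp01(img * f)
      },
      rotate = {
        a <- params$angle %||% stats::runif(1, -15, 15)
        if (a %% 360 == 0) img
        else if (a %% 90 == 0) {
          out <- img
          for (q in seq_len((a %% 360) / 90)) out <- rotate90_ccw(out)
          out
        } else {
          d <- dim(img)
          # EBImage rotates clockwise for positive angles in its x/y frame
          eb <- EBImage::rotate(eb_from(img), -a, output.dim = d[c(2L, 1L)],
                                bg.col = bg_col_of(img))
          clamp01(eb_to(eb))
        }
      },
      affine = {
        d <- dim(img)
        sh <- params$shear %||% stats::runif(2, -0.08, 0.08)
        tr <- params$shift %||% stats::runif(2, -0.05, 0.05) * d[1:2]
        m <- matrix(c(1, sh[1], tr[1], sh[2], 1, tr[2]), 3L, 2L)
        eb <- EBImage::affine(eb_from(img), m, output.dim = d[c(2L, 1L)],
                              bg.col = bg_col_of(img))
        clamp01(eb_to(eb))
      })
    img
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# --- colour-threshold baseline ---------------------------------------------

#' Hue-threshold baseline classifier
#'
#' A deliberately trivial classifier: mask the filaments by saturation and
#' brightness (the background and clutter are desaturated by construction),
#' average the hue over the mask, and call the image premium when the mean
#' hue is below the red/yellow cut. Its accuracy on a default-config dataset
#' certifies that the classes are separable by construction, so any network
#' failure is the network's fault, not the data's.
#'
#' @param manifest a `cnat_manifest`.
#' @param dir dataset directory (defaults to the manifest's).
#' @param hue_cut decision threshold in degrees.
#' @param sat_min,val_min mask thresholds.
#' @return a list with `accuracy` and the per-image `hue` and `predicted`.
#' @export
hue_baseline_accuracy <- function(manifest, dir = NULL, hue_cut = 23,
                                  sat_min = 0.3, val_min = 0.2) {
  d <- manifest_dir(manifest, dir)
  hue <- vapply(manifest$path, function(p) {
    img <- png::readPNG(file.path(d, p))
    r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
    hsv <- grDevices::rgb2hsv(as.numeric(r), as.numeric(g), as.numeric(b),
                              maxColorValue = 1)
    m <- hsv[2, ] > sat_min & hsv[3, ] > val_min
    if (!any(m)) return(NA_real_)
    mean(hsv[1, m]) * 360
  }, 0, USE.NAMES = FALSE)
  pred <- ifelse(is.na(hue), "normal",
                 ifelse(hue < hue_cut, "premium", "normal"))
  list(accuracy = mean(pred == manifest$grade), hue = hue, predicted = pred)
}
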