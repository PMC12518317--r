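# Network assembly: stem -> four downsampling stages (C2S2 or C2f fusion in
# stages 1-2, AnC2f or C2f in stages 3-4) -> classification head (DWClassify
# or the dense baseline head), plus the n/s/m scale presets and the ablation
# variant factory.

STAGE_BASE_WIDTHS <- c(128L, 256L, 512L, 1024L)
STAGE_BASE_DEPTHS <- c(3L, 6L, 6L, 3L)
STEM_BASE_WIDTH <- 64L

#' Scale presets for the n/s/m model sizes
#'
#' Depth and width multipliers and the cap on resolved stage widths, following
#' the C2f classification lineage the architecture builds on.
#'
#' @param scale one of `"n"`, `"s"`, `"m"`.
#' @return a list with `depth_mult`, `width_mult`, `max_channels`.
#' @export
scale_preset <- function(scale) {
  presets <- list(n = list(depth_mult = 0.33, width_mult = 0.25, max_channels = 1024L),
                  s = list(depth_mult = 0.33, width_mult = 0.50, max_channels = 1024L),
                  m = list(depth_mult = 0.67, width_mult = 0.75, max_channels = 768L))
  if (!is.character(scale) || length(scale) != 1L || !scale %in% names(presets))
    stop("unknown scale '", paste(scale, collapse = ","),
         "'; valid scales: n, s, m")
  presets[[scale]]
}

# resolved width: scaled, rounded to a multiple of 8, capped at max_channels
resolve_width <- function(base, width_mult, max_channels) {
  w <- as.integer(max(8L, round(base * width_mult / 8) * 8))
  min(w, as.integer(max_channels))
}

resolve_depth <- function(base, depth_mult) {
  as.integer(max(1L, round(base * depth_mult)))
}

#' Network configuration
#'
#' @param scale one of `"n"`, `"s"`, `"m"`; sets multipliers unless
#'   overridden.
#' @param num_classes output classes (>= 2).
#' @param input_size input image side; must be divisible by the total
#'   stride (32).
#' @param use_c2s2,use_anc2f,use_dwclassify module-presence flags (the
#'   ablation switches).
#' @param n_ablocks stacked attention units per AnC2f block.
#' @param depth_mult,width_mult,max_channels override the preset.
#' @return a `cnat_config` list.
#' @export
network_config <- function(scale = "s", num_classes = 2L, input_size = 224L,
                           use_c2s2 = TRUE, use_anc2f = TRUE,
                           use_dwclassify = TRUE, n_ablocks = 2L,
                           depth_mult = NULL, width_mult = NULL,
                           max_channels = NULL) {
  p <- scale_preset(scale)
  cfg <- list(scale = scale,
              depth_mult = depth_mult %||% p$depth_mult,
              width_mult = width_mult %||% p$width_mult,
              max_channels = max_channels %||% p$max_channels,
              num_classes = as.integer(num_classes),
              input_size = as.integer(input_size),
              use_c2s2 = isTRUE(use_c2s2),
              use_anc2f = isTRUE(use_anc2f),
              use_dwclassify = isTRUE(use_dwclassify),
              n_ablocks = as.integer(n_ablocks))
  if (cfg$num_classes < 2L) stop("num_classes must be >= 2")
  if (cfg$depth_mult <= 0 || cfg$width_mult <= 0)
    stop("multipliers must be positive")
  if (cfg$input_size %% 32L != 0L)
    stop("input_size ", cfg$input_size,
         " is not divisible by the total stride (32)")
  class(cfg) <- "cnat_config"
  cfg
}

#' Assemble a CNATNet (or ablation variant) from a configuration
#'
#' The backbone is a stride-2 stem convolution followed by four stages, each
#' a stride-2 downsampling convolution plus a fusion block: C2S2 (or C2f when
#' disabled) in stages 1-2, AnC2f (or C2f) in stages 3-4. The head is
#' DWClassify or, when disabled, the dense convolutional baseline head.
#'
#' @param cfg a [network_config()].
#' @param seed optional integer; when given, weight initialisation is seeded
#'   so identical configs build identical networks.
#' @return a `cnat_network` module.
#' @export
build_cnatnet <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "cnat_config"))
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(set_rng_state(old))
    set.seed(as.integer(seed))
  }
  widths <- vapply(STAGE_BASE_WIDTHS, resolve_width, 0L,
                   width_mult = cfg$width_mult,
                   max_channels = cfg$max_channels)
  depths <- vapply(STAGE_BASE_DEPTHS, resolve_depth, 0L,
                   depth_mult = cfg$depth_mult)
  w0 <- resolve_width(STEM_BASE_WIDTH, cfg$width_mult, cfg$max_channels)

  ch <- list(stem = conv_unit(3L, w0, k = 3L, stride = 2L))
  prev <- w0
  for (i in 1:4) {
    wi <- widths[i]
    ch[[paste0("down", i)]] <- conv_unit(prev, wi, k = 3L, stride = 2L)
    blk <-
      if (i <= 2L) {
        if (cfg$use_c2s2) c2s2_block(wi, wi, n_units = depths[i],
                                     unit_kind = "ghost")
        else c2f_block(wi, wi, n = depths[i], shortcut = TRUE)
      } else {
        if (cfg$use_anc2f) anc2f_block(wi, wi, n_ablocks = cfg$n_ablocks)
        else c2f_block(wi, wi, n = depths[i], shortcut = TRUE)
      }
    ch[[paste0("stage", i)]] <- blk
    prev <- wi
  }
  ch$head <- if (cfg$use_dwclassify) dwclassify_head(prev, cfg$num_classes)
             else dense_head(prev, cfg$num_classes)

  m <- new_module("network", children = ch, config = cfg)
  class(m) <- c("cnat_network", "cnat_seq", "cnat_module")
  m
}

# --- ablation variant factory ----------------------------------------------

VARIANT_FLAGS <- list(
  M1 = c(c2s2 = FALSE, anc2f = FALSE, dwclassify = FALSE),
  M2 = c(c2s2 = TRUE,  anc2f = FALSE, dwclassify = FALSE),
  M3 = c(c2s2 = FALSE, anc2f = TRUE,  dwclassify = FALSE),
  M4 = c(c2s2 = FALSE, anc2f = FALSE, dwclassify = TRUE),
  M6 = c(c2s2 = TRUE,  anc2f = TRUE,  dwclassify = FALSE),
  M7 = c(c2s2 = TRUE,  anc2f = FALSE, dwclassify = TRUE),
  M8 = c(c2s2 = FALSE, anc2f = TRUE,  dwclassify = TRUE),
  M9 = c(c2s2 = TRUE,  anc2f = TRUE,  dwclassify = TRUE))

#' Module-presence flags of an ablation variant
#'
#' Variants M1-M9 toggle the three bespoke modules; the full model is M9 and
#' the attention-free baseline is M1 (M5 is not defined in the grid).
#'
#' @param variant a variant id, e.g. `"M1"` or `"M9"`.
#' @return a named logical vector `(c2s2, anc2f, dwclassify)`.
#' @export
variant_flags <- function(variant) {
  if (!is.character(variant) || length(variant) != 1L ||
      !variant %in% names(VARIANT_FLAGS))
    stop("unknown variant '", paste(variant, collapse = ","),
         "'; valid variants: ", paste(names(VARIANT_FLAGS), collapse = ", "))
  VARIANT_FLAGS[[variant]]
}

#' Build an ablation variant
#'
#' @param variant variant id (see [variant_flags()]).
#' @param scale scale preset tag.
#' @param num_classes output classes.
#' @param input_size input image side.
#' @param seed optional initialisation seed.
#' @param ... further arguments to [network_config()].
#' @return a `cnat_network`.
#' @export
build_variant <- function(variant, scale = "s", num_classes = 2L,
                          input_size = 224L, seed = NULL, ...) {
  fl <- variant_flags(variant)
  cfg <- network_config(scale = scale, num_classes = num_classes,
                        input_size = input_size,
                        use_c2s2 = fl[["c2s2"]],
                        use_anc2f = fl[["anc2f"]],
                        use_dwclassify = fl[["dwclassify"]], ...)
  net <- build_cnatnet(cfg, seed = seed)
  net$variant <- variant
  net
}

# --- methods ----------------------------------------------------------------

#' @export
print.cnat_network <- function(x, ...) {
  cfg <- x$config
  fl <- c(cfg$use_c2s2, cfg$use_anc2f, cfg$use_dwclassify)
  cat("CNATNet",
      if (!is.null(x$variant)) paste0("variant ", x$variant) else "",
      sprintf("(scale %s, %d classes, input %dx%d)\n", cfg$scale,
              cfg$num_classes, cfg$input_size, cfg$input_size))
  cat(sprintf("  modules: C2S2=%s AnC2f=%s DWClassify=%s\n",
              fl[1], fl[2], fl[3]))
  cat(sprintf("  parameters: %s raw / %s deploy (norm-folded)\n",
              format(oracle_param_count(x), big.mark = ","),
              format(oracle_param_count(x, deploy = TRUE), big.mark = ",")))
  invisible(x)
}

#' Predict grades or logits from a network
#'
#' @param object a `cnat_network`.
#' @param x an `H x W x C x N` image batch in `[0, 1]`, or a single
#'   `H x W x C` array.
#' @param type `"class"` (default), `"prob"`, or `"logit"`.
#' @param classes optional character vector naming the classes, in logit
#'   order.
#' @param batch_size forward-pass batch size.
#' @param ... unused.
#' @return a factor, probability matrix, or logit matrix with one row per
#'   image.
#' @export
predict.cnat_network <- function(object, x,
                                 type = c("class", "prob", "logit"),
                                 classes = NULL, batch_size = 32L, ...) {
  type <- match.arg(type)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  x <- as_feature_map(x)
  n <- dim(x)[4L]
  out <- NULL
  for (at in seq(1L, n, by = batch_size)) {
    idx <- at:min(at + batch_size - 1L, n)
    logits <- forward(object, x[, , , idx, drop = FALSE], training = FALSE)
    out <- rbind(out, logits)
  }
  if (type == "logit") return(out)
  p <- exp(out - apply(out, 1L, max))
  p <- p / rowSums(p)
  if (type == "prob") {
    colnames(p) <- classes
    return(p)
  }
  k <- max.col(p, ties.method = "first")
  if (is.null(classes)) k else factor(classes[k], levels = classes)
}

# --- RNG state helpers ------------------------------------------------------

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}

with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed(as.integer(seed))
  expr
}
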