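# Building blocks of CNATNet: the standard conv-norm-activation unit,
# Bottleneck and GhostBottleneck, the cascaded split-and-concatenate C2S2
# block, the sigmoid-gated ABlock, the attention-enhanced cross-stage AnC2f
# block, and the depthwise-separable DWClassify head. Each block implements
# forward() and an exact hand-written backward().

#' Convolution unit: convolution, batch normalization, SiLU
#'
#' The elementary unit every block is built from. The convolution carries no
#' bias (the batch-norm shift subsumes it); activation can be disabled for
#' projection layers.
#'
#' @param c_in,c_out input/output channel counts.
#' @param k odd kernel size.
#' @param stride 1 or 2.
#' @param groups channel groups (`c_in` gives a depthwise convolution).
#' @param act apply SiLU after normalization.
#' @return a module.
#' @export
conv_unit <- function(c_in, c_out, k = 3L, stride = 1L, groups = 1L,
                      act = TRUE) {
  ch <- list(conv = nn_conv2d(c_in, c_out, k, stride, groups = groups),
             bn = nn_batchnorm(c_out))
  if (act) ch$act <- nn_act("silu")
  m <- new_module("convunit", children = ch,
                  c_in = as.integer(c_in), c_out = as.integer(c_out))
  class(m) <- c("cnat_convunit", "cnat_seq", "cnat_module")
  m
}

#' Residual bottleneck
#'
#' Two stacked conv units (`c_in -> e*c_out -> c_out`, 3x3) with an identity
#' shortcut when `shortcut = TRUE` and the widths match.
#'
#' @param c_in,c_out channel counts.
#' @param shortcut add the input back when shapes allow.
#' @param e hidden-width expansion ratio.
#' @param k kernel size of both convolutions.
#' @return a module.
#' @export
bottleneck_block <- function(c_in, c_out, shortcut = TRUE, e = 0.5, k = 3L) {
  c_mid <- max(1L, as.integer(round(c_out * e)))
  new_module("bottleneck",
             children = list(cv1 = conv_unit(c_in, c_mid, k),
                             cv2 = conv_unit(c_mid, c_out, k)),
             c_in = as.integer(c_in), c_out = as.integer(c_out),
             add = isTRUE(shortcut) && c_in == c_out)
}

#' @export
forward.cnat_bottleneck <- function(m, x, training = FALSE) {
  y <- forward(m$children$cv2,
               forward(m$children$cv1, x, training), training)
  if (m$add) y + x else y
}

#' @export
backward.cnat_bottleneck <- function(m, dout) {
  dx <- backward(m$children$cv1, backward(m$children$cv2, dout))
  if (m$add) dx + dout else dx
}

#' Ghost convolution
#'
#' Produces half of its output channels by a primary convolution and the
#' other half by a cheap depthwise transform of the primary features
#' (ghost ratio 0.5), then concatenates both halves.
#'
#' @param c_in,c_out channel counts; `c_out` must be even.
#' @param k primary kernel size; `dw_k` cheap depthwise kernel size.
#' @return a module.
#' @export
ghost_conv <- function(c_in, c_out, k = 1L, dw_k = 3L) {
  if (c_out %% 2L != 0L) stop("ghost_conv: c_out must be even")
  ch <- c_out %/% 2L
  new_module("ghostconv",
             children = list(
               primary = conv_unit(c_in, ch, k),
               cheap = conv_unit(ch, ch, dw_k, groups = ch)),
             c_in = as.integer(c_in), c_out = as.integer(c_out))
}

#' @export
forward.cnat_ghostconv <- function(m, x, training = FALSE) {
  p <- forward(m$children$primary, x, training)
  g <- forward(m$children$cheap, p, training)
  fm_concat(p, g)
}

#' @export
backward.cnat_ghostconv <- function(m, dout) {
  ch <- m$c_out %/% 2L
  parts <- fm_split_at(dout, ch)
  dp <- parts[[1L]] + backward(m$children$cheap, parts[[2L]])
  backward(m$children$primary, dp)
}

#' Ghost bottleneck
#'
#' Two stacked ghost convolutions (expand then project) with an optional
#' stride-2 depthwise stage in between; a residual connection is applied when
#' `stride = 1` and input/output widths match.
#'
#' @param c_in,c_out channel counts (even).
#' @param stride 1 or 2.
#' @param dw_k depthwise kernel size.
#' @return a module.
#' @export
ghost_bottleneck_block <- function(c_in, c_out, stride = 1L, dw_k = 3L) {
  if (!(stride %in% c(1L, 2L)))
    stop("ghost_bottleneck: stride must be 1 or 2")
  ch <- list(gc1 = ghost_conv(c_in, c_out))
  if (stride == 2L)
    ch$dw <- conv_unit(c_out, c_out, dw_k, stride = 2L, groups = c_out,
                       act = FALSE)
  ch$gc2 <- ghost_conv(c_out, c_out)
  new_module("ghostbneck", children = ch,
             c_in = as.integer(c_in), c_out = as.integer(c_out),
             add = stride == 1L && c_in == c_out)
}

#' @export
forward.cnat_ghostbneck <- function(m, x, training = FALSE) {
  y <- x
  for (ch in m$children) y <- forward(ch, y, training)
  if (m$add) y + x else y
}

#' @export
backward.cnat_ghostbneck <- function(m, dout) {
  dx <- dout
  for (ch in rev(m$children)) dx <- backward(ch, dx)
  if (m$add) dx + dout else dx
}

# --- channel split / concat -------------------------------------------------

fm_concat <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1L]])
  ctot <- sum(vapply(parts, fm_channels, 0L))
  out <- array(0, dim = c(d[1L], d[2L], ctot, d[4L]))
  at <- 0L
  for (p in parts) {
    cp <- fm_channels(p)
    out[, , at + seq_len(cp), ] <- p
    at <- at + cp
  }
  out
}

fm_split_at <- function(x, c1) {
  list(x[, , seq_len(c1), , drop = FALSE],
       x[, , -seq_len(c1), , drop = FALSE])
}

#' Split a feature map channel-wise into two branches
#'
#' Channels are divided 50/50; for odd counts the extra channel goes to the
#' first branch (ceiling/floor rule). Concatenating the halves back along the
#' channel axis recovers the input exactly.
#'
#' @param x an `H x W x C x N` feature map with `C >= 2`.
#' @return a list of two feature maps.
#' @export
c2s2_split <- function(x) {
  x <- as_feature_map(x)
  ctot <- fm_channels(x)
  if (ctot < 2L)
    stop("c2s2_split: need at least 2 channels, got ", ctot)
  fm_split_at(x, as.integer(ceiling(ctot / 2)))
}

# --- C2S2 -------------------------------------------------------------------

#' Cascaded split-and-concatenate block (C2S2)
#'
#' A stem convolution widens the input to twice the branch width; the result
#' is split channel-wise into two parallel branches, each refined by a stack
#' of GhostBottleneck or standard Bottleneck units; the branch outputs are
#' concatenated and projected to `c_out` by a 1x1 merge convolution.
#'
#' @param c_in,c_out channel counts.
#' @param n_units bottleneck units stacked per branch.
#' @param unit_kind `"ghost"` or `"standard"`.
#' @param merge_channels branch width (defaults to `c_out / 2`); must not
#'   exceed `c_out`.
#' @param kernel odd kernel size of the branch units.
#' @param stride stem stride (1 preserves, 2 halves spatial dims).
#' @param stem,merge set `FALSE` to make the stem/merge an identity (the stem
#'   then requires `c_in == 2 * merge_channels`); mainly for algebraic tests.
#' @return a module.
#' @export
c2s2_block <- function(c_in, c_out, n_units = 1L,
                       unit_kind = c("ghost", "standard"),
                       merge_channels = NULL, kernel = 3L, stride = 1L,
                       stem = TRUE, merge = TRUE) {
  unit_kind <- match.arg(unit_kind)
  if (is.null(merge_channels)) merge_channels <- max(1L, c_out %/% 2L)
  if (merge_channels > c_out)
    stop("c2s2: merge_channels must not exceed out_channels")
  if (n_units < 1L) stop("c2s2: n_units must be >= 1")
  c_split <- as.integer(merge_channels)
  wide <- 2L * c_split
  if (!stem && c_in != wide)
    stop("c2s2: identity stem requires in_channels == 2 * merge_channels")
  mk_units <- function(cs) {
    lapply(seq_len(n_units), function(i)
      if (unit_kind == "ghost") ghost_bottleneck_block(cs, cs, dw_k = kernel)
      else bottleneck_block(cs, cs, shortcut = TRUE, e = 0.5, k = kernel))
  }
  ch <- list()
  if (stem)
    ch$stem <- conv_unit(c_in, wide, k = if (stride == 2L) 3L else 1L,
                         stride = stride)
  ch$branch1 <- nn_seq(mk_units(c_split))
  ch$branch2 <- nn_seq(mk_units(c_split))
  if (merge) ch$merge <- conv_unit(wide, c_out, k = 1L)
  new_module("c2s2", children = ch,
             c_in = as.integer(c_in), c_out = as.integer(c_out),
             c_split = c_split, has_stem = stem, has_merge = merge)
}

#' @export
forward.cnat_c2s2 <- function(m, x, training = FALSE) {
  check_channels(as_feature_map(x), m$c_in, "c2s2")
  s <- if (m$has_stem) forward(m$children$stem, x, training) else x
  halves <- fm_split_at(s, m$c_split)
  y <- fm_concat(forward(m$children$branch1, halves[[1L]], training),
                 forward(m$children$branch2, halves[[2L]], training))
  if (m$has_merge) forward(m$children$merge, y, training) else y
}

#' @export
backward.cnat_c2s2 <- function(m, dout) {
  dy <- if (m$has_merge) backward(m$children$merge, dout) else dout
  parts <- fm_split_at(dy, m$c_split)
  ds <- fm_concat(backward(m$children$branch1, parts[[1L]]),
                  backward(m$children$branch2, parts[[2L]]))
  if (m$has_stem) backward(m$children$stem, ds) else ds
}

# --- C2f (attention-free cross-stage fusion, the baseline block) ------------

#' Cross-stage partial fusion block (C2f style)
#'
#' The attention-free fusion block used by the M1 baseline: a 1x1 convolution
#' widens to `2c`, the result is split, one half passes through `n` residual
#' bottlenecks whose intermediate outputs are all concatenated, and a final
#' 1x1 convolution projects to `c_out`.
#'
#' @param c_in,c_out channel counts.
#' @param n number of bottleneck units.
#' @param shortcut residual connections inside the bottlenecks.
#' @param e hidden ratio (`c = e * c_out`).
#' @return a module.
#' @export
c2f_block <- function(c_in, c_out, n = 1L, shortcut = TRUE, e = 0.5) {
  c <- max(1L, as.integer(c_out * e))
  new_module("c2f",
             children = list(
               cv1 = conv_unit(c_in, 2L * c, k = 1L),
               bnecks = nn_seq(lapply(seq_len(n), function(i)
                 bottleneck_block(c, c, shortcut, e = 1.0, k = 3L))),
               cv2 = conv_unit((2L + n) * c, c_out, k = 1L)),
             c_in = as.integer(c_in), c_out = as.integer(c_out),
             c_hidden = c, n = as.integer(n))
}

#' @export
forward.cnat_c2f <- function(m, x, training = FALSE) {
  y <- forward(m$children$cv1, x, training)
  halves <- fm_split_at(y, m$c_hidden)
  ys <- list(halves[[1L]], halves[[2L]])
  b <- halves[[2L]]
  for (bn in m$children$bnecks$children) {
    b <- forward(bn, b, training)
    ys[[length(ys) + 1L]] <- b
  }
  forward(m$children$cv2, do.call(fm_concat, ys), training)
}

#' @export
backward.cnat_c2f <- function(m, dout) {
  dcat <- backward(m$children$cv2, dout)
  c <- m$c_hidden
  n <- m$n
  g <- lapply(seq_len(n + 2L), function(i)
    dcat[, , (i - 1L) * c + seq_len(c), , drop = FALSE])
  db <- g[[n + 2L]]
  for (i in rev(seq_len(n)))
    db <- backward(m$children$bnecks$children[[i]], db) + g[[i + 1L]]
  backward(m$children$cv1, fm_concat(g[[1L]], db))
}

# --- ABlock and AnC2f -------------------------------------------------------

#' Sigmoid-gated attention block (ABlock)
#'
#' Computes `sigmoid(Conv1x1(x)) * x`: a 1x1 convolution (with bias)
#' produces one attention weight per spatial position and channel; the
#' sigmoid bounds every weight strictly inside (0, 1), so the output
#' magnitude never exceeds the input elementwise.
#'
#' @param c channel count of the gated feature map.
#' @return a module.
#' @export
ablock <- function(c) {
  new_module("ablock",
             children = list(gate = nn_conv2d(c, c, k = 1L, bias = TRUE)),
             c_in = as.integer(c), c_out = as.integer(c))
}

#' @export
forward.cnat_ablock <- function(m, x, training = FALSE) {
  x <- as_feature_map(x)
  g <- forward(m$children$gate, x, training)
  if (fm_channels(g) != fm_channels(x))
    stop("ablock: gate produced a different channel count")
  s <- sigmoid(g)
  if (training) m$cache <- list(x = x, s = s)
  s * x
}

#' @export
backward.cnat_ablock <- function(m, dout) {
  cc <- m$cache
  dg <- dout * cc$x * cc$s * (1 - cc$s)
  dout * cc$s + backward(m$children$gate, dg)
}

#' Attention-enhanced cross-stage fusion block (AnC2f)
#'
#' A stem 1x1 convolution produces base features that flow through two paths:
#' an identity shortcut, and a main branch of `n_ablocks` stacked units (each
#' a refinement bottleneck followed by a sigmoid-gated ABlock). The two paths
#' are fused by element-wise addition, so zeroing the main branch passes the
#' shortcut through unchanged.
#'
#' @param c_in,c_out channel counts.
#' @param n_ablocks stacked attention units (>= 1).
#' @param use_shortcut include the identity path.
#' @param refine include the bottleneck in each unit (pure stacked gates when
#'   `FALSE`).
#' @param stem set `FALSE` for an identity stem (requires `c_in == c_out`).
#' @return a module.
#' @export
anc2f_block <- function(c_in, c_out, n_ablocks = 2L, use_shortcut = TRUE,
                        refine = TRUE, stem = TRUE) {
  if (n_ablocks < 1L) stop("anc2f: n_ablocks must be >= 1")
  if (!stem && c_in != c_out)
    stop("anc2f: identity stem requires c_in == c_out")
  units <- lapply(seq_len(n_ablocks), function(i) {
    u <- list()
    if (refine)
      u$bneck <- bottleneck_block(c_out, c_out, shortcut = FALSE, e = 0.5)
    u$gate <- ablock(c_out)
    nn_seq(u)
  })
  ch <- list()
  if (stem) ch$cv1 <- conv_unit(c_in, c_out, k = 1L)
  ch$units <- nn_seq(units)
  new_module("anc2f", children = ch,
             c_in = as.integer(c_in), c_out = as.integer(c_out),
             use_shortcut = isTRUE(use_shortcut), has_stem = stem)
}

#' @export
forward.cnat_anc2f <- function(m, x, training = FALSE) {
  check_channels(as_feature_map(x), m$c_in, "anc2f")
  f <- if (m$has_stem) forward(m$children$cv1, x, training) else x
  y <- forward(m$children$units, f, training)
  if (m$use_shortcut) f + y else y
}

#' @export
backward.cnat_anc2f <- function(m, dout) {
  df <- backward(m$children$units, dout)
  if (m$use_shortcut) df <- df + dout
  if (m$has_stem) backward(m$children$cv1, df) else df
}

# --- classification heads ---------------------------------------------------

# replicate (edge) padding, used by the depthwise stage of DWClassify so that
# spatially constant inputs stay constant for any map size
pad_edge <- function(x, p) {
  d <- dim(x)
  hi <- c(rep(1L, p), seq_len(d[1L]), rep(d[1L], p))
  wi <- c(rep(1L, p), seq_len(d[2L]), rep(d[2L], p))
  x[hi, wi, , , drop = FALSE]
}

unpad_edge_grad <- function(dout, p) {
  d <- dim(dout)
  h <- d[1L] - 2L * p
  w <- d[2L] - 2L * p
  hg <- c(rep(1L, p), seq_len(h), rep(h, p))
  wg <- c(rep(1L, p), seq_len(w), rep(w, p))
  dx <- array(0, dim = c(h, w, d[3L], d[4L]))
  for (i in seq_len(d[1L]))
    for (j in seq_len(d[2L]))
      dx[hg[i], wg[j], , ] <- dx[hg[i], wg[j], , ] + dout[i, j, , ]
  dx
}

#' Depthwise-separable classification head (DWClassify)
#'
#' Decouples spatial and channel-wise feature extraction: a depthwise `k x k`
#' convolution filters each channel independently (edge-padded, so constant
#' maps stay constant), a 1x1 pointwise convolution mixes channels down to
#' the class logits, and global average pooling reduces the map to one logit
#' vector per batch item.
#'
#' @param c_in input channel count.
#' @param num_classes number of classes (>= 2).
#' @param k odd depthwise kernel size.
#' @return a module.
#' @export
dwclassify_head <- function(c_in, num_classes, k = 3L) {
  if (num_classes < 2L) stop("dwclassify: num_classes must be >= 2")
  dw <- conv_unit(c_in, c_in, k, groups = c_in)
  dw$children$conv$pad <- 0L  # padding handled by pad_edge in forward
  new_module("dwclassify",
             children = list(
               dw = dw,
               pw = nn_conv2d(c_in, num_classes, k = 1L, bias = TRUE),
               pool = nn_gap()),
             c_in = as.integer(c_in),
             num_classes = as.integer(num_classes),
             k = as.integer(k), pad = (as.integer(k) - 1L) %/% 2L)
}

#' @export
forward.cnat_dwclassify <- function(m, x, training = FALSE) {
  check_channels(as_feature_map(x), m$c_in, "dwclassify")
  xp <- pad_edge(x, m$pad)
  y <- forward(m$children$dw, xp, training)
  y <- forward(m$children$pw, y, training)
  forward(m$children$pool, y, training)
}

#' @export
backward.cnat_dwclassify <- function(m, dout) {
  dy <- backward(m$children$pool, dout)
  dy <- backward(m$children$pw, dy)
  dxp <- backward(m$children$dw, dy)
  unpad_edge_grad(dxp, m$pad)
}

#' Dense convolutional classification head (ablation baseline)
#'
#' The conventional head the ablation baseline uses in place of DWClassify:
#' a 1x1 convolution to a wide embedding, global average pooling, and a fully
#' connected layer to the class logits.
#'
#' @param c_in input channel count.
#' @param num_classes number of classes (>= 2).
#' @param hidden embedding width.
#' @return a module.
#' @export
dense_head <- function(c_in, num_classes, hidden = 1280L) {
  if (num_classes < 2L) stop("dense_head: num_classes must be >= 2")
  m <- new_module("densehead",
                  children = list(
                    conv = conv_unit(c_in, hidden, k = 1L),
                    pool = nn_gap(),
                    fc = nn_linear(hidden, num_classes)),
                  c_in = as.integer(c_in),
                  num_classes = as.integer(num_classes),
                  hidden = as.integer(hidden))
  class(m) <- c("cnat_densehead", "cnat_seq", "cnat_module")
  m
}

# --- functional wrappers matching the block contracts -----------------------

#' Apply a C2S2 block built from a configuration record
#'
#' @param x feature map whose channel count must match `cfg$in_channels`.
#' @param cfg a list with fields `in_channels`, `out_channels`, `n_units`,
#'   `unit_kind`, `merge_channels`, `kernel` (and optionally `stride`).
#' @param training forward mode.
#' @return the fused feature map.
#' @export
c2s2_forward <- function(x, cfg, training = FALSE) {
  m <- c2s2_block(cfg$in_channels, cfg$out_channels,
                  n_units = cfg$n_units %||% 1L,
                  unit_kind = cfg$unit_kind %||% "ghost",
                  merge_channels = cfg$merge_channels,
                  kernel = cfg$kernel %||% 3L,
                  stride = cfg$stride %||% 1L)
  forward(m, x, training)
}

#' Apply a sigmoid-gated attention modulation with given gate weights
#'
#' @param x feature map.
#' @param gate_weights a list with `w` (`1 x 1 x C x C` array) and `b`
#'   (length-`C` bias), or an [ablock()] module.
#' @return `sigmoid(gate(x)) * x`.
#' @export
ablock_forward <- function(x, gate_weights) {
  x <- as_feature_map(x)
  c <- fm_channels(x)
  if (inherits(gate_weights, "cnat_module")) {
    m <- gate_weights
  } else {
    m <- ablock(c)
    m$children$gate$w <- array(gate_weights$w, dim = c(1L, 1L, c, c))
    m$children$gate$b <- as.double(gate_weights$b)
  }
  forward(m, x)
}

#' Apply an AnC2f block built from a configuration record
#'
#' @param x feature map matching `cfg$in_channels`.
#' @param cfg list with `in_channels`, `out_channels`, `n_ablocks`,
#'   `use_shortcut`.
#' @param training forward mode.
#' @return the fused feature map (`shortcut + main`).
#' @export
anc2f_forward <- function(x, cfg, training = FALSE) {
  m <- anc2f_block(cfg$in_channels, cfg$out_channels,
                   n_ablocks = cfg$n_ablocks %||% 2L,
                   use_shortcut = cfg$use_shortcut %||% TRUE)
  forward(m, x, training)
}

#' Apply a ghost bottleneck built from a configuration record
#' @param x feature map.
#' @param cfg list with `in_channels`, `out_channels`, optional `stride`.
#' @param training forward mode.
#' @return the transformed feature map.
#' @export
ghost_bottleneck_forward <- function(x, cfg, training = FALSE) {
  m <- ghost_bottleneck_block(cfg$in_channels, cfg$out_channels,
                              stride = cfg$stride %||% 1L)
  forward(m, x, training)
}

#' Apply a DWClassify head built from a configuration record
#' @param x feature map matching `cfg$in_channels`.
#' @param cfg list with `in_channels`, `num_classes`, optional `kernel`.
#' @param training forward mode.
#' @return an `N x num_classes` logit matrix.
#' @export
dwclassify_forward <- function(x, cfg, training = FALSE) {
  m <- dwclassify_head(cfg$in_channels, cfg$num_classes,
                       k = cfg$kernel %||% 3L)
  forward(m, x, training)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
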