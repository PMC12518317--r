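# Analytic parameter/FLOP accounting and the brute-force enumeration oracle.
# The analytic formulas count convolution weights (plus declared biases)
# only, as is conventional for architecture tables; the enumeration oracle
# counts every learnable scalar of an assembled network, optionally with
# batch-norm folded into the preceding convolution (the deploy-time
# convention architecture tables are printed in).

# validates and returns the counts as doubles, so products of large counts
# stay exact (up to 2^53) instead of overflowing integer arithmetic
check_positive <- function(...) {
  vals <- as.double(c(...))
  if (any(!is.finite(vals)) || any(vals < 1))
    stop("all counts must be positive integers, got: ",
         paste(vals, collapse = ", "))
  invisible(vals)
}

#' Analytic parameter count of a C2S2 block
#'
#' `sum_{i=1,2}(C_split * K * K * C_split) + C_merge * C_out`: the two
#' branch convolutions operating within their channel partitions plus the
#' merge projection.
#'
#' @param spec list with `c_split`, `k`, `c_merge`, `c_out` (positive
#'   counts).
#' @return an exact integer-valued count.
#' @export
params_c2s2 <- function(spec) {
  v <- check_positive(spec$c_split, spec$k, spec$c_merge, spec$c_out)
  2 * (v[1] * v[2] * v[2] * v[1]) + v[3] * v[4]
}

#' Analytic parameter count of a depthwise-separable stage
#'
#' `C_in * K * K` for the depthwise filters plus `C_in * C_out` for the
#' pointwise mixing.
#'
#' @param c_in,k,c_out positive counts.
#' @return an exact count.
#' @export
params_dw <- function(c_in, k, c_out) {
  v <- check_positive(c_in, k, c_out)
  v[1] * v[2] * v[2] + v[1] * v[3]
}

#' Analytic FLOPs of a depthwise-separable stage
#'
#' `H * W * (C_in * K * K + C_in * C_out)` multiply-accumulates: the
#' per-position cost replicated over the output map, identically
#' `h * w * params_dw(c_in, k, c_out)`.
#'
#' @param h,w output spatial dimensions.
#' @param c_in,k,c_out positive counts.
#' @return an exact count.
#' @export
flops_dw <- function(h, w, c_in, k, c_out) {
  v <- check_positive(h, w)
  v[1] * v[2] * params_dw(c_in, k, c_out)
}

#' Layer record for whole-model accounting
#'
#' @param c_in,c_out channel counts.
#' @param k kernel size.
#' @param h,w output spatial dimensions.
#' @param has_bias whether a bias vector is counted.
#' @return a one-row data frame.
#' @export
layer_spec <- function(c_in, c_out, k, h = 1, w = 1, has_bias = FALSE) {
  v <- check_positive(c_in, c_out, k, h, w)
  data.frame(c_in = v[1], c_out = v[2], k = v[3], h = v[4], w = v[5],
             has_bias = has_bias)
}

#' Total learnable parameters over a stack of convolution layers
#'
#' `sum_l C_in K^2 C_out + C_out`, the bias term included only for layers
#' declaring one.
#'
#' @param layers a data frame of [layer_spec()] rows (possibly empty).
#' @return an exact count.
#' @export
params_model <- function(layers) {
  if (is.null(layers) || nrow(layers) == 0L) return(0)
  with(layers, sum(c_in * k * k * c_out + ifelse(has_bias, c_out, 0)))
}

#' Total multiply-accumulate count over a stack of convolution layers
#'
#' `sum_l H_l W_l C_in K^2 C_out` (products only; double for the
#' multiply-add convention).
#'
#' @param layers a data frame of [layer_spec()] rows.
#' @return an exact count.
#' @export
flops_model <- function(layers) {
  if (is.null(layers) || nrow(layers) == 0L) return(0)
  with(layers, sum(h * w * c_in * k * k * c_out))
}

#' Count every learnable scalar of a network by enumeration
#'
#' Walks the module tree and sums the lengths of all learnable arrays
#' (convolution and linear weights and biases, normalization scale and
#' shift; running statistics are not learnable). With `deploy = TRUE`,
#' batch-norm parameters are counted as folded into the preceding
#' convolution (scale merges into the weights, shift becomes a bias), the
#' convention deployment-oriented architecture tables are printed in.
#'
#' @param network any module or assembled network.
#' @param deploy count in the norm-folded deploy convention.
#' @return an exact count.
#' @export
oracle_param_count <- function(network, deploy = FALSE) {
  total <- 0
  module_walk(network, function(mm) {
    for (f in param_fields(mm)) total <<- total + length(mm[[f]])
    if (deploy && mm$type == "batchnorm") total <<- total - mm$c
  })
  total
}

# --- shape tracing ----------------------------------------------------------

conv_out_dim <- function(sz, k, stride, pad) (sz + 2 * pad - k) %/% stride + 1

# Returns list(layers = data.frame of conv/linear layers with output dims,
# hw = c(h, w) after the module).
trace_module <- function(m, hw) {
  layers <- NULL
  add <- function(c_in, c_out, k, h, w, bias)
    layers <<- rbind(layers, layer_spec(c_in, c_out, k, h, w, bias))
  rec <- function(mm, hw) {
    switch(mm$type,
      conv2d = {
        h <- conv_out_dim(hw[1], mm$k, mm$stride, mm$pad)
        w <- conv_out_dim(hw[2], mm$k, mm$stride, mm$pad)
        add(mm$c_in %/% mm$groups, mm$c_out, mm$k, h, w, !is.null(mm$b))
        c(h, w)
      },
      linear = {
        add(mm$c_in, mm$c_out, 1, 1, 1, !is.null(mm$b))
        hw
      },
      gap = c(1, 1),
      batchnorm = hw,
      act = hw,
      ablock = rec(mm$children$gate, hw),
      c2s2 = {
        h2 <- if (mm$has_stem) rec(mm$children$stem, hw) else hw
        rec(mm$children$branch1, h2)
        rec(mm$children$branch2, h2)
        if (mm$has_merge) rec(mm$children$merge, h2) else h2
      },
      c2f = {
        h2 <- rec(mm$children$cv1, hw)
        rec(mm$children$bnecks, h2)
        rec(mm$children$cv2, h2)
      },
      anc2f = {
        h2 <- if (mm$has_stem) rec(mm$children$cv1, hw) else hw
        rec(mm$children$units, h2)
      },
      ghostconv = {
        h2 <- rec(mm$children$primary, hw)
        rec(mm$children$cheap, h2)
      },
      dwclassify = {
        # depthwise stage is edge-padded to preserve dims
        add(1, mm$c_in, mm$k, hw[1], hw[2], FALSE)
        rec(mm$children$dw$children$bn, hw)
        rec(mm$children$pw, hw)
        c(1, 1)
      },
      { # seq-like composites: bottleneck, ghostbneck, convunit, seq, network
        h2 <- hw
        for (ch in module_children(mm)) h2 <- rec(ch, h2)
        h2
      })
  }
  hw_out <- rec(m, hw)
  list(layers = layers, hw = hw_out)
}

#' Format a raw count in millions / billions to one decimal
#' @param x a count.
#' @return a string such as `"6.4 M"`.
#' @export
format_millions <- function(x) sprintf("%.1f M", round(x / 1e6, 1))

#' @rdname format_millions
#' @export
format_billions <- function(x) sprintf("%.1f B", round(x / 1e9, 1))

#' Profile an assembled network
#'
#' Traces every convolution and linear layer at the given input resolution
#' and reports analytic parameter and multiply-accumulate totals, the
#' enumeration-oracle counts (raw and norm-folded deploy convention), and a
#' per-block breakdown over the network's top-level blocks.
#'
#' @param network a `cnat_network` (or any module).
#' @param input_size input image side (defaults to the network's configured
#'   size).
#' @return a `cnat_profile` list with elements `params_analytic`,
#'   `params_oracle`, `params_deploy`, `flops_analytic`, `per_block`,
#'   `input_size` and formatted `rendered` strings.
#' @export
profile_network <- function(network, input_size = NULL) {
  if (is.null(input_size))
    input_size <- if (!is.null(network$config)) network$config$input_size
                  else stop("input_size required for a bare module")
  check_positive(input_size)
  hw <- c(input_size, input_size)
  kids <- module_children(network)
  if (length(kids) == 0L) kids <- list(module = network)
  if (is.null(names(kids))) names(kids) <- sprintf("block%d", seq_along(kids))
  per <- NULL
  for (nm in names(kids)) {
    tr <- trace_module(kids[[nm]], hw)
    per <- rbind(per, data.frame(
      block = nm,
      params = params_model(tr$layers),
      flops = flops_model(tr$layers),
      params_oracle = oracle_param_count(kids[[nm]]),
      stringsAsFactors = FALSE))
    hw <- tr$hw
  }
  out <- list(params_analytic = sum(per$params),
              params_oracle = oracle_param_count(network),
              params_deploy = oracle_param_count(network, deploy = TRUE),
              flops_analytic = sum(per$flops),
              per_block = per,
              input_size = input_size)
  out$rendered <- c(params = format_millions(out$params_deploy),
                    params_raw = format_millions(out$params_oracle),
                    flops = format_billions(out$flops_analytic))
  class(out) <- "cnat_profile"
  out
}

#' @export
print.cnat_profile <- function(x, ...) {
  cat(sprintf("Network profile at %dx%d input\n",
              x$input_size, x$input_size))
  cat(sprintf("  params: %s analytic (conv weights+biases), %s oracle raw, %s oracle deploy (%s)\n",
              format(x$params_analytic, big.mark = ","),
              format(x$params_oracle, big.mark = ","),
              format(x$params_deploy, big.mark = ","),
              x$rendered[["params"]]))
  cat(sprintf("  MACs:   %s (%s)\n",
              format(x$flops_analytic, big.mark = ","),
              x$rendered[["flops"]]))
  df <- x$per_block
  df$params <- format(df$params, big.mark = ",")
  df$flops <- format(df$flops, big.mark = ",")
  df$params_oracle <- format(df$params_oracle, big.mark = ",")
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a profile as JSON
#' @param profile a `cnat_profile`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_profile_json <- function(profile, path) {
  jsonlite::write_json(unclass(profile), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}
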