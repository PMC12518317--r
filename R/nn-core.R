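#' @useDynLib cnatnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Minimal layer system. A module is an environment tagged with a type; it
# holds its learnable arrays, their gradient accumulators, forward caches and
# (for composites) a named list of children. forward()/backward() dispatch on
# the type. Backward returns the gradient w.r.t. the module input and
# accumulates parameter gradients in place (cleared by zero_grad()).
# ---------------------------------------------------------------------------

new_module <- function(type, ...) {
  m <- list2env(list(...), parent = emptyenv())
  m$type <- type
  class(m) <- c(paste0("cnat_", type), "cnat_module")
  m
}

#' Create a feature map array
#'
#' Feature maps throughout the package are `H x W x C x N` numeric arrays:
#' R's native image-array convention (as returned by [png::readPNG()]) with a
#' batch dimension appended. All values must be finite.
#'
#' @param values numeric vector or array of length `h*w*c*n`.
#' @param h,w,c,n positive integer dimensions.
#' @return a 4-d numeric array of dimension `c(h, w, c, n)`.
#' @export
feature_map <- function(values, h, w, c, n = 1L) {
  stopifnot(h >= 1, w >= 1, c >= 1, n >= 1)
  x <- array(as.double(values), dim = c(h, w, c, n))
  if (!all(is.finite(x))) stop("feature_map: values must be finite")
  x
}

as_feature_map <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) != 4L)
    stop("expected an H x W x C x N feature-map array, got dim ",
         paste(d, collapse = "x"))
  x
}

fm_channels <- function(x) dim(x)[3L]

check_channels <- function(x, expected, where) {
  got <- fm_channels(x)
  if (got != expected)
    stop(sprintf("%s: expected %d input channels, received %d",
                 where, expected, got))
  invisible(x)
}

# --- parameter initialisation ----------------------------------------------

kaiming_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

# --- primitive modules ------------------------------------------------------

#' @keywords internal
nn_conv2d <- function(c_in, c_out, k = 3L, stride = 1L, pad = NULL,
                      groups = 1L, bias = FALSE) {
  stopifnot(c_in >= 1, c_out >= 1, k >= 1, k %% 2 == 1)
  if (!(stride %in% c(1L, 2L))) stop("conv2d: stride must be 1 or 2")
  if (c_in %% groups != 0 || c_out %% groups != 0)
    stop("conv2d: channel counts must be divisible by groups")
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  cg <- c_in %/% groups
  w <- kaiming_init(c(k, k, cg, c_out), fan_in = cg * k * k)
  new_module("conv2d",
             c_in = as.integer(c_in), c_out = as.integer(c_out),
             k = as.integer(k), stride = as.integer(stride),
             pad = as.integer(pad), groups = as.integer(groups),
             w = w, b = if (bias) numeric(c_out) else NULL,
             dw = NULL, db = NULL, cache = NULL)
}

#' @keywords internal
nn_batchnorm <- function(c, eps = 1e-5, momentum = 0.1) {
  new_module("batchnorm",
             c = as.integer(c), eps = eps, momentum = momentum,
             gamma = rep(1, c), beta = numeric(c),
             running_mean = numeric(c), running_var = rep(1, c),
             dgamma = NULL, dbeta = NULL, cache = NULL)
}

#' @keywords internal
nn_linear <- function(c_in, c_out, bias = TRUE) {
  new_module("linear",
             c_in = as.integer(c_in), c_out = as.integer(c_out),
             w = matrix(stats::rnorm(c_in * c_out, sd = sqrt(1 / c_in)),
                        c_in, c_out),
             b = if (bias) numeric(c_out) else NULL,
             dw = NULL, db = NULL, cache = NULL)
}

nn_act <- function(kind = c("silu", "sigmoid")) {
  new_module("act", kind = match.arg(kind), cache = NULL)
}

nn_gap <- function() new_module("gap", cache = NULL)

# --- per-channel reductions over H x W x C x N ------------------------------

channel_stat <- function(x, f) {
  d <- dim(x)
  m <- matrix(x, d[1L] * d[2L], d[3L] * d[4L])
  rowMeans(matrix(f(m), d[3L], d[4L]))
}

channel_sum <- function(x) {
  d <- dim(x)
  m <- matrix(x, d[1L] * d[2L], d[3L] * d[4L])
  rowSums(matrix(colSums(m), d[3L], d[4L]))
}

# broadcast a length-C vector over an H x W x C x N array
bc <- function(v, d) rep(rep(v, each = d[1L] * d[2L]), times = d[4L])

# --- forward / backward -----------------------------------------------------

#' Run a module forward
#'
#' @param m a block or layer created by one of the `*_block()`/head
#'   constructors or [build_cnatnet()].
#' @param x an `H x W x C x N` feature-map array.
#' @param training logical; use batch statistics and cache intermediates for
#'   backpropagation (`TRUE`) or running statistics (`FALSE`).
#' @return the transformed feature map (or an `N x num_classes` logit matrix
#'   for classification heads).
#' @export
forward <- function(m, x, training = FALSE) UseMethod("forward")

#' @export
forward.default <- function(m, x, training = FALSE)
  stop("not a cnat_module")

backward <- function(m, dout) UseMethod("backward")

#' @export
forward.cnat_conv2d <- function(m, x, training = FALSE) {
  x <- as_feature_map(x)
  check_channels(x, m$c_in, "conv2d")
  y <- .conv2d_fwd_cpp(x, m$w, m$b, m$stride, m$pad, m$groups)
  if (training) m$cache <- x
  y
}

#' @export
backward.cnat_conv2d <- function(m, dout) {
  g <- .conv2d_bwd_cpp(m$cache, m$w, dout, !is.null(m$b),
                       m$stride, m$pad, m$groups)
  m$dw <- if (is.null(m$dw)) g$dw else m$dw + g$dw
  if (!is.null(m$b)) m$db <- if (is.null(m$db)) g$db else m$db + g$db
  g$dx
}

#' @export
forward.cnat_batchnorm <- function(m, x, training = FALSE) {
  x <- as_feature_map(x)
  check_channels(x, m$c, "batchnorm")
  d <- dim(x)
  if (training) {
    mu <- channel_stat(x, colMeans)
    ex2 <- channel_stat(x * x, colMeans)
    v <- pmax(ex2 - mu^2, 0)
    m$running_mean <- (1 - m$momentum) * m$running_mean + m$momentum * mu
    m$running_var <- (1 - m$momentum) * m$running_var + m$momentum * v
  } else {
    mu <- m$running_mean
    v <- m$running_var
  }
  ivar <- 1 / sqrt(v + m$eps)
  xhat <- (x - bc(mu, d)) * bc(ivar, d)
  y <- xhat * bc(m$gamma, d) + bc(m$beta, d)
  if (training) m$cache <- list(xhat = xhat, ivar = ivar, d = d)
  y
}

#' @export
backward.cnat_batchnorm <- function(m, dout) {
  cc <- m$cache
  d <- cc$d
  M <- d[1L] * d[2L] * d[4L]
  dgamma <- channel_sum(dout * cc$xhat)
  dbeta <- channel_sum(dout)
  m$dgamma <- if (is.null(m$dgamma)) dgamma else m$dgamma + dgamma
  m$dbeta <- if (is.null(m$dbeta)) dbeta else m$dbeta + dbeta
  dxhat <- dout * bc(m$gamma, d)
  s1 <- channel_sum(dxhat)
  s2 <- channel_sum(dxhat * cc$xhat)
  (dxhat - bc(s1 / M, d) - cc$xhat * bc(s2 / M, d)) * bc(cc$ivar, d)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' @export
forward.cnat_act <- function(m, x, training = FALSE) {
  if (m$kind == "silu") {
    s <- sigmoid(x)
    y <- x * s
    if (training) m$cache <- list(x = x, s = s)
  } else {
    y <- sigmoid(x)
    if (training) m$cache <- list(y = y)
  }
  y
}

#' @export
backward.cnat_act <- function(m, dout) {
  cc <- m$cache
  if (m$kind == "silu") {
    dout * (cc$s * (1 + cc$x * (1 - cc$s)))
  } else {
    dout * cc$y * (1 - cc$y)
  }
}

#' @export
forward.cnat_gap <- function(m, x, training = FALSE) {
  d <- dim(x)
  mm <- matrix(x, d[1L] * d[2L], d[3L] * d[4L])
  y <- matrix(colMeans(mm), d[4L], d[3L], byrow = TRUE)  # N x C
  if (training) m$cache <- d
  y
}

#' @export
backward.cnat_gap <- function(m, dout) {
  d <- m$cache
  hw <- d[1L] * d[2L]
  # dout is N x C; spread uniformly over spatial positions
  array(rep(as.double(t(dout)) / hw, each = hw), dim = d)
}

#' @export
forward.cnat_linear <- function(m, x, training = FALSE) {
  y <- x %*% m$w
  if (!is.null(m$b)) y <- sweep(y, 2L, m$b, `+`)
  if (training) m$cache <- x
  y
}

#' @export
backward.cnat_linear <- function(m, dout) {
  dw <- crossprod(m$cache, dout)
  m$dw <- if (is.null(m$dw)) dw else m$dw + dw
  if (!is.null(m$b)) {
    db <- colSums(dout)
    m$db <- if (is.null(m$db)) db else m$db + db
  }
  dout %*% t(m$w)
}

# --- sequential composite ---------------------------------------------------

nn_seq <- function(children) {
  # children must be addressable by name for state-dict round-trips
  if (length(children) && is.null(names(children)))
    names(children) <- sprintf("u%d", seq_along(children))
  new_module("seq", children = children)
}

#' @export
forward.cnat_seq <- function(m, x, training = FALSE) {
  for (ch in m$children) x <- forward(ch, x, training)
  x
}

#' @export
backward.cnat_seq <- function(m, dout) {
  for (ch in rev(m$children)) dout <- backward(ch, dout)
  dout
}

# --- parameter bookkeeping --------------------------------------------------

module_children <- function(m) {
  if (!is.null(m$children)) m$children else list()
}

# Walk the module tree, applying fn(module) to every module (post-order).
module_walk <- function(m, fn) {
  for (ch in module_children(m)) module_walk(ch, fn)
  fn(m)
  invisible(NULL)
}

param_fields <- function(m) {
  switch(m$type,
         conv2d = if (is.null(m$b)) "w" else c("w", "b"),
         linear = if (is.null(m$b)) "w" else c("w", "b"),
         batchnorm = c("gamma", "beta"),
         character(0))
}

grad_field <- function(f) {
  c(w = "dw", b = "db", gamma = "dgamma", beta = "dbeta")[[f]]
}

#' Collect references to all learnable parameters of a module tree
#' @keywords internal
parameters <- function(m) {
  out <- list()
  module_walk(m, function(mm) {
    for (f in param_fields(mm))
      out[[length(out) + 1L]] <<- list(module = mm, field = f)
  })
  out
}

zero_grad <- function(m) {
  module_walk(m, function(mm) {
    for (f in param_fields(mm)) assign(grad_field(f), NULL, envir = mm)
  })
  invisible(NULL)
}

#' Extract all weights of a network as a nested named list
#'
#' The state dict contains every learnable array plus batch-norm running
#' statistics; [load_state_dict()] restores it into a structurally identical
#' network (e.g. one rebuilt from the same configuration).
#'
#' @param m a module or network.
#' @return a named list of numeric arrays.
#' @export
state_dict <- function(m) {
  fields <- function(mm) c(param_fields(mm),
                           if (mm$type == "batchnorm")
                             c("running_mean", "running_var"))
  sd <- list()
  rec <- function(mm, prefix) {
    for (f in fields(mm)) sd[[paste0(prefix, f)]] <<- mm[[f]]
    kids <- module_children(mm)
    if (length(kids) && is.null(names(kids)))
      stop("internal error: module with unnamed children")
    for (nm in names(kids)) rec(kids[[nm]], paste0(prefix, nm, "."))
  }
  rec(m, "")
  sd
}

#' Restore weights produced by [state_dict()]
#' @param m a structurally identical module or network.
#' @param sd a state dict.
#' @return `m`, invisibly, with weights replaced.
#' @export
load_state_dict <- function(m, sd) {
  fields <- function(mm) c(param_fields(mm),
                           if (mm$type == "batchnorm")
                             c("running_mean", "running_var"))
  rec <- function(mm, prefix) {
    for (f in fields(mm)) {
      key <- paste0(prefix, f)
      if (is.null(sd[[key]])) stop("state dict is missing ", key)
      cur <- mm[[f]]
      if (!identical(dim(cur), dim(sd[[key]])) ||
          length(cur) != length(sd[[key]]))
        stop("state dict shape mismatch at ", key)
      assign(f, sd[[key]], envir = mm)
    }
    kids <- module_children(mm)
    for (nm in names(kids)) rec(kids[[nm]], paste0(prefix, nm, "."))
  }
  rec(m, "")
  invisible(m)
}

# Set every learnable array (not running stats) to zero; used in tests to
# exercise identity/residual contracts.
zero_weights <- function(m) {
  module_walk(m, function(mm) {
    for (f in param_fields(mm)) {
      if (f == "gamma") next  # keep BN as pure shift so zeroing beta = zero out
      assign(f, mm[[f]] * 0, envir = mm)
    }
  })
  invisible(m)
}

# --- losses -----------------------------------------------------------------

# softmax cross-entropy; labels are 1-based class indices
softmax_xent <- function(logits, labels) {
  n <- nrow(logits)
  z <- logits - apply(logits, 1L, max)
  ez <- exp(z)
  p <- ez / rowSums(ez)
  idx <- cbind(seq_len(n), labels)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, grad = dlogits / n, prob = p)
}
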