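# Training and coarse-to-fine evaluation: Adam over softmax cross-entropy,
# train-split-only augmentation, per-epoch history, best-by-validation
# checkpointing, confusion-matrix metrics and latency measurement.

CLASSES <- c("premium", "normal")  # premium is the positive class

#' Training hyperparameters
#'
#' Defaults mirror the reference training configuration: Adam, learning rate
#' 0.001, batch size 32, 300 epochs, cross-entropy loss. The desk preset for
#' CPU-scale experiments is `epochs = 30` at 64-px inputs.
#'
#' @param optimizer only `"adam"` is provided.
#' @param learning_rate positive step size.
#' @param batch_size positive minibatch size.
#' @param epochs positive epoch count.
#' @param seed integer training seed (shuffling, augmentation draws).
#' @param loss only `"cross_entropy"` is provided.
#' @param augment apply random augmentations to the train split.
#' @param early_stop_acc optional validation-accuracy level at which
#'   training stops early (the epoch still completes and is recorded).
#' @return a `cnat_hyperparams` list.
#' @export
hyperparams <- function(optimizer = "adam", learning_rate = 0.001,
                        batch_size = 32L, epochs = 300L, seed = 1L,
                        loss = "cross_entropy", augment = TRUE,
                        early_stop_acc = NULL) {
  optimizer <- match.arg(optimizer, "adam")
  loss <- match.arg(loss, "cross_entropy")
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1)
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 loss = loss, augment = isTRUE(augment),
                 early_stop_acc = early_stop_acc),
            class = "cnat_hyperparams")
}

# --- Adam -------------------------------------------------------------------

adam_state <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) p$module[[p$field]] * 0),
       v = lapply(params, function(p) p$module[[p$field]] * 0))
}

adam_step <- function(params, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$module[[grad_field(p$field)]]
    if (is.null(g)) next
    st$m[[i]] <- beta1 * st$m[[i]] + (1 - beta1) * g
    st$v[[i]] <- beta2 * st$v[[i]] + (1 - beta2) * g * g
    upd <- (st$m[[i]] / bc1) / (sqrt(st$v[[i]] / bc2) + eps)
    assign(p$field, p$module[[p$field]] - lr * upd, envir = p$module)
  }
  st
}

# --- label handling ---------------------------------------------------------

label_index <- function(grades, classes = CLASSES) {
  bad <- which(!grades %in% classes)
  if (length(bad))
    stop("record ", bad[1L], " has grade '", grades[bad[1L]],
         "' outside {", paste(classes, collapse = ", "), "}")
  match(grades, classes)
}

train_augment <- function(img) {
  ops <- character(0)
  if (stats::runif(1) < 0.5) ops <- c(ops, "hflip")
  if (stats::runif(1) < 0.7) ops <- c(ops, "rotate")
  if (stats::runif(1) < 0.7) ops <- c(ops, "brightness")
  if (stats::runif(1) < 0.3) ops <- c(ops, "affine")
  if (!length(ops)) return(img)
  augment_image(img, ops)
}

batch_accuracy <- function(logits, labels) {
  mean(max.col(logits, ties.method = "first") == labels)
}

#' Train a network on a manifest
#'
#' Runs seeded minibatch training with Adam and cross-entropy over the
#' manifest's train split, evaluating on the val split after every epoch,
#' applying random augmentations to the train split only, and keeping the
#' weights of the best validation-accuracy epoch.
#'
#' @param network a `cnat_network` whose class count matches the label set.
#' @param manifest a `cnat_manifest` with non-empty train and val splits.
#' @param hp a [hyperparams()].
#' @param dir dataset directory (defaults to the manifest's).
#' @param verbose print per-epoch progress.
#' @return a `cnat_fit`: the network (best weights loaded), `history` data
#'   frame (epoch, train_loss, train_acc, val_loss, val_acc), `best_epoch`,
#'   `best_val_acc`, `hp`, `classes`.
#' @export
cnat_train <- function(network, manifest, hp = hyperparams(), dir = NULL,
                       verbose = FALSE) {
  stopifnot(inherits(network, "cnat_network"))
  tr <- manifest[manifest$split == "train", , drop = FALSE]
  va <- manifest[manifest$split == "val", , drop = FALSE]
  if (nrow(tr) == 0L) stop("manifest has an empty train split")
  if (nrow(va) == 0L) stop("manifest has an empty val split")
  if (network$config$num_classes != length(CLASSES))
    stop("network num_classes (", network$config$num_classes,
         ") does not match the label set size (", length(CLASSES), ")")
  d <- manifest_dir(manifest, dir)
  xtr <- load_images(tr, d)
  xva <- load_images(va, d)
  ytr <- label_index(tr$grade)
  yva <- label_index(va$grade)

  ps <- parameters(network)
  st <- adam_state(ps)
  hist <- NULL
  best <- list(acc = -Inf, epoch = 0L, state = NULL)
  with_seed(hp$seed, {
    for (ep in seq_len(hp$epochs)) {
      idx <- sample(nrow(tr))
      ep_loss <- 0; ep_acc <- 0; nb <- 0L
      for (at in seq(1L, length(idx), by = hp$batch_size)) {
        bi <- idx[at:min(at + hp$batch_size - 1L, length(idx))]
        xb <- xtr[, , , bi, drop = FALSE]
        if (hp$augment)
          for (j in seq_along(bi))
            xb[, , , j] <- train_augment(xb[, , , j, drop = TRUE])
        lg <- forward(network, xb, training = TRUE)
        l <- softmax_xent(lg, ytr[bi])
        zero_grad(network)
        backward(network, l$grad)
        st <- adam_step(ps, st, hp$learning_rate)
        ep_loss <- ep_loss + l$loss
        ep_acc <- ep_acc + batch_accuracy(lg, ytr[bi])
        nb <- nb + 1L
      }
      calibrate_bn(network, xtr, hp$batch_size)
      vl <- predict_logits(network, xva, hp$batch_size)
      vloss <- softmax_xent(vl, yva)$loss
      vacc <- batch_accuracy(vl, yva)
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                     train_acc = ep_acc / nb,
                                     val_loss = vloss, val_acc = vacc))
      if (vacc > best$acc) {
        best$acc <- vacc
        best$epoch <- ep
        best$state <- state_dict(network)
      }
      if (verbose)
        message(sprintf("epoch %3d  train %.3f/%.1f%%  val %.3f/%.1f%%",
                        ep, ep_loss / nb, 100 * ep_acc / nb, vloss,
                        100 * vacc))
      if (!is.null(hp$early_stop_acc) && vacc >= hp$early_stop_acc) break
    }
  })
  load_state_dict(network, best$state)
  structure(list(network = network, history = hist,
                 best_epoch = best$epoch, best_val_acc = best$acc,
                 hp = hp, classes = CLASSES),
            class = "cnat_fit")
}

#' Re-estimate batch-norm running statistics
#'
#' Replaces every batch-norm layer's running mean/variance with the average
#' of the batch statistics over the given images (cumulative mean across
#' batches, weights untouched). Training updates the running statistics as a
#' lagging exponential average while the weights are still moving, so they
#' are re-estimated before each validation pass and before deployment.
#'
#' @param network a `cnat_network` (or any module).
#' @param x an `H x W x 3 x N` image batch, normally the train split.
#' @param batch_size forward-pass batch size.
#' @return the network, invisibly.
#' @export
calibrate_bn <- function(network, x, batch_size = 32L) {
  n <- dim(x)[4L]
  k <- 0L
  set_mom <- function(mom)
    module_walk(network, function(mm)
      if (mm$type == "batchnorm") mm$momentum <- mom)
  old <- list()
  module_walk(network, function(mm)
    if (mm$type == "batchnorm") old[[length(old) + 1L]] <<- mm$momentum)
  for (at in seq(1L, n, by = batch_size)) {
    k <- k + 1L
    set_mom(1 / k)  # cumulative mean of batch statistics
    invisible(forward(network, x[, , , at:min(at + batch_size - 1L, n),
                                 drop = FALSE], training = TRUE))
  }
  i <- 0L
  module_walk(network, function(mm)
    if (mm$type == "batchnorm") {
      i <<- i + 1L
      mm$momentum <- old[[i]]
    })
  invisible(network)
}

predict_logits <- function(network, x, batch_size = 32L) {
  n <- dim(x)[4L]
  out <- NULL
  for (at in seq(1L, n, by = batch_size)) {
    i <- at:min(at + batch_size - 1L, n)
    out <- rbind(out, forward(network, x[, , , i, drop = FALSE],
                              training = FALSE))
  }
  out
}

#' @export
print.cnat_fit <- function(x, ...) {
  cat(sprintf("cnatnet fit: %d epochs, best val ACC %.1f%% (epoch %d)\n",
              nrow(x$history), 100 * x$best_val_acc, x$best_epoch))
  invisible(x)
}

#' @export
summary.cnat_fit <- function(object, ...) {
  print(object)
  h <- object$history
  cat(sprintf("  final train loss %.4f, train ACC %.1f%%\n",
              h$train_loss[nrow(h)], 100 * h$train_acc[nrow(h)]))
  print(object$network)
  invisible(object)
}

#' Plot training curves
#' @param x a `cnat_fit`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.cnat_fit <- function(x, ...) {
  h <- x$history
  graphics::par(mfrow = c(1, 2))
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "cross-entropy", ...)
  graphics::legend("topright", c("train", "val"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  graphics::matplot(h$epoch, cbind(h$train_acc, h$val_acc), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "ACC", ylim = c(0, 1), ...)
  invisible(x)
}

#' @export
predict.cnat_fit <- function(object, x, ...) {
  predict(object$network, x, classes = object$classes, ...)
}

# --- metrics ----------------------------------------------------------------

#' Accuracy and confusion counts from predictions
#'
#' Accuracy is `(TP + TN) / (TP + TN + FP + FN)` with `"premium"` as the
#' positive class.
#'
#' @param predicted,actual character vectors of grades.
#' @return a `cnat_metrics` list: `acc`, `confusion` (tp, tn, fp, fn), `n`.
#' @export
metrics_from_predictions <- function(predicted, actual) {
  pos <- CLASSES[1L]
  tp <- sum(predicted == pos & actual == pos)
  tn <- sum(predicted != pos & actual != pos)
  fp <- sum(predicted == pos & actual != pos)
  fn <- sum(predicted != pos & actual == pos)
  metrics_from_counts(tp, tn, fp, fn)
}

#' @rdname metrics_from_predictions
#' @param tp,tn,fp,fn non-negative confusion counts.
#' @export
metrics_from_counts <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  n <- tp + tn + fp + fn
  structure(list(acc = (tp + tn) / n,
                 confusion = c(tp = tp, tn = tn, fp = fp, fn = fn),
                 n = n),
            class = "cnat_metrics")
}

#' @export
print.cnat_metrics <- function(x, ...) {
  cat(sprintf("ACC %.4f over %d samples (tp %d, tn %d, fp %d, fn %d)",
              x$acc, x$n, x$confusion["tp"], x$confusion["tn"],
              x$confusion["fp"], x$confusion["fn"]))
  if (!is.null(x$latency_ms)) cat(sprintf("; latency %.2f ms", x$latency_ms))
  cat("\n")
  invisible(x)
}

#' Evaluate a network on one split of a manifest
#'
#' @param network a `cnat_network` (or a `cnat_fit`).
#' @param manifest a `cnat_manifest`.
#' @param split `"train"`, `"val"` or `"test"`.
#' @param dir dataset directory.
#' @param level optional level filter (`"cluster"` or `"monomer"`).
#' @return a `cnat_metrics`.
#' @export
evaluate_network <- function(network, manifest, split = "test", dir = NULL,
                             level = NULL) {
  if (inherits(network, "cnat_fit")) network <- network$network
  sub <- manifest[manifest$split == split, , drop = FALSE]
  if (!is.null(level)) sub <- sub[sub$level == level, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("no records in split '", split, "'",
         if (!is.null(level)) paste0(" at level '", level, "'"))
  x <- load_images(sub, manifest_dir(manifest, dir))
  pred <- as.character(predict(network, x, classes = CLASSES))
  metrics_from_predictions(pred, sub$grade)
}

#' Coarse-to-fine evaluation
#'
#' Evaluates the cluster-level model on the cluster scenes of the test split
#' and the monomer-level model on the monomer scenes, independently.
#'
#' @param network_cluster,network_monomer networks (or fits) for the two
#'   task levels; pass the same object to use one model for both.
#' @param manifest a `cnat_manifest` whose test split contains both levels.
#' @param dir dataset directory.
#' @return a list with `cluster` and `monomer` `cnat_metrics`.
#' @export
coarse_to_fine_eval <- function(network_cluster, network_monomer, manifest,
                                dir = NULL) {
  test <- manifest[manifest$split == "test", , drop = FALSE]
  for (lev in c("cluster", "monomer"))
    if (!any(test$level == lev))
      stop("test split contains no '", lev, "' scenes")
  list(cluster = evaluate_network(network_cluster, manifest, "test", dir,
                                  level = "cluster"),
       monomer = evaluate_network(network_monomer, manifest, "test", dir,
                                  level = "monomer"))
}

#' Average per-image inference latency
#'
#' Runs single-image forward passes and reports total time over sample
#' count, in milliseconds, after discarding warm-up passes. Informational
#' only: the value is hardware-dependent.
#'
#' @param network a `cnat_network`.
#' @param images an `H x W x 3 x N` batch.
#' @param warmup untimed initial passes.
#' @return latency in ms.
#' @export
measure_latency <- function(network, images, warmup = 2L) {
  if (length(dim(images)) == 3L) dim(images) <- c(dim(images), 1L)
  n <- dim(images)[4L]
  if (n < 1L) stop("measure_latency: need at least one image")
  stopifnot(warmup >= 0)
  for (i in seq_len(min(warmup, n)))
    forward(network, images[, , , i, drop = FALSE], training = FALSE)
  t0 <- proc.time()[["elapsed"]]
  for (i in seq_len(n))
    forward(network, images[, , , i, drop = FALSE], training = FALSE)
  1000 * (proc.time()[["elapsed"]] - t0) / n
}

# --- checkpointing ----------------------------------------------------------

#' Save a network (or fit) checkpoint
#'
#' Stores the network configuration, variant tag and full state dict; the
#' network is rebuilt from the configuration on load, so checkpoints are
#' portable across sessions.
#'
#' @param object a `cnat_network` or `cnat_fit`.
#' @param path output `.rds` file.
#' @return the path, invisibly.
#' @export
save_checkpoint <- function(object, path) {
  fit <- NULL
  if (inherits(object, "cnat_fit")) {
    fit <- object[c("history", "best_epoch", "best_val_acc", "hp", "classes")]
    object <- object$network
  }
  saveRDS(list(config = object$config, variant = object$variant,
               state = state_dict(object), fit = fit), path)
  invisible(path)
}

#' Load a checkpoint saved by [save_checkpoint()]
#' @param path the `.rds` file.
#' @return a `cnat_network` or, if the checkpoint came from a fit, a
#'   `cnat_fit`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  net <- build_cnatnet(ck$config)
  net$variant <- ck$variant
  load_state_dict(net, ck$state)
  if (is.null(ck$fit)) return(net)
  structure(c(list(network = net), ck$fit), class = "cnat_fit")
}
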