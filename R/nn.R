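## Minimal reverse-mode neural-network layers for 3D video encoders.
##
## Activation tensors are arrays with dim = (H, W, T, N, C): spatial height and
## width, time, batch, channels. Keeping channels last makes the per-channel
## reshape used by batch norm and the im2col matrix layout free of copies.
## Layers are mutable environments; a forward pass caches what the matching
## backward pass needs, so each layer instance belongs to exactly one model.

new_layer <- function(class, ...) {
  e <- new.env(parent = emptyenv())
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  class(e) <- c(class, "nn_layer")
  e
}

#' @noRd
ly_forward <- function(layer, x, train = FALSE) UseMethod("ly_forward")
#' @noRd
ly_backward <- function(layer, gy) UseMethod("ly_backward")
#' @noRd
ly_params <- function(layer) UseMethod("ly_params")
#' @export
ly_params.default <- function(layer) character(0)

## He-normal initialization; relies on the caller having seeded the RNG.
he_init <- function(n, fan_in) {
  stats::rnorm(n, sd = sqrt(2 / fan_in))
}

## ---- 3D convolution -------------------------------------------------------

nn_conv3d <- function(in_ch, out_ch, kernel = c(3L, 3L, 3L), stride = c(1L, 1L, 1L),
                      pad = NULL, bias = TRUE) {
  kernel <- as.integer(kernel); stride <- as.integer(stride)
  if (is.null(pad)) pad <- (kernel - 1L) %/% 2L
  pad <- as.integer(pad)
  fan_in <- prod(kernel) * in_ch
  W <- matrix(he_init(fan_in * out_ch, fan_in), nrow = fan_in, ncol = out_ch)
  b <- if (bias) numeric(out_ch) else NULL
  new_layer("nn_conv3d", in_ch = in_ch, out_ch = out_ch, kernel = kernel,
            stride = stride, pad = pad, W = W, b = b)
}

#' @export
ly_forward.nn_conv3d <- function(layer, x, train = FALSE) {
  xd <- dim(x)
  stopifnot(length(xd) == 5L, xd[5L] == layer$in_ch)
  cols <- im2col3d(x, as.integer(xd), layer$kernel, layer$stride, layer$pad)
  y <- cols %*% layer$W
  if (!is.null(layer$b)) y <- sweep(y, 2L, layer$b, "+")
  od <- c((xd[1:3] + 2L * layer$pad - layer$kernel) %/% layer$stride + 1L,
          xd[4L], layer$out_ch)
  dim(y) <- od
  if (train) { layer$cols <- cols; layer$xdim <- xd } else { layer$cols <- NULL; layer$xdim <- xd }
  y
}

#' @export
ly_backward.nn_conv3d <- function(layer, gy) {
  gm <- gy
  dim(gm) <- c(prod(dim(gy)[1:4]), dim(gy)[5L])
  if (!is.null(layer$cols)) {
    layer$gW <- crossprod(layer$cols, gm)
  } else {
    layer$gW <- NULL  # eval-mode backward (saliency): data gradient only
  }
  if (!is.null(layer$b)) layer$gb <- colSums(gm)
  gcols <- gm %*% t(layer$W)
  col2im3d(gcols, as.integer(layer$xdim), layer$kernel, layer$stride, layer$pad)
}

#' @export
ly_params.nn_conv3d <- function(layer) if (is.null(layer$b)) "W" else c("W", "b")

## ---- Batch normalization over (H, W, T, N) per channel --------------------

nn_batchnorm3d <- function(ch, eps = 1e-5, momentum = 0.1) {
  new_layer("nn_batchnorm3d", ch = ch, eps = eps, momentum = momentum,
            W = rep(1, ch), b = numeric(ch),       # gamma, beta
            run_mean = numeric(ch), run_var = rep(1, ch))
}

#' @export
ly_forward.nn_batchnorm3d <- function(layer, x, train = FALSE) {
  xd <- dim(x)
  P <- prod(xd[1:4])
  xm <- x; dim(xm) <- c(P, xd[5L])
  if (train) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2L, mu)
    v <- colMeans(xc * xc)
    layer$run_mean <- (1 - layer$momentum) * layer$run_mean + layer$momentum * mu
    layer$run_var <- (1 - layer$momentum) * layer$run_var + layer$momentum * v * P / max(P - 1, 1)
  } else {
    mu <- layer$run_mean
    v <- layer$run_var
    xc <- sweep(xm, 2L, mu)
  }
  invstd <- 1 / sqrt(v + layer$eps)
  xhat <- sweep(xc, 2L, invstd, "*")
  y <- sweep(sweep(xhat, 2L, layer$W, "*"), 2L, layer$b, "+")
  dim(y) <- xd
  layer$xhat <- if (train) xhat else NULL
  layer$invstd <- invstd
  layer$train_mode <- train
  layer$xdim <- xd
  y
}

#' @export
ly_backward.nn_batchnorm3d <- function(layer, gy) {
  xd <- layer$xdim
  P <- prod(xd[1:4])
  gm <- gy; dim(gm) <- c(P, xd[5L])
  if (isTRUE(layer$train_mode)) {
    xhat <- layer$xhat
    layer$gW <- colSums(gm * xhat)
    layer$gb <- colSums(gm)
    s1 <- colMeans(gm)
    s2 <- colMeans(gm * xhat)
    gx <- sweep(gm, 2L, s1) - sweep(xhat, 2L, s2, "*")
    gx <- sweep(gx, 2L, layer$W * layer$invstd, "*")
  } else {
    layer$gW <- NULL; layer$gb <- NULL
    gx <- sweep(gm, 2L, layer$W * layer$invstd, "*")
  }
  dim(gx) <- xd
  gx
}

#' @export
ly_params.nn_batchnorm3d <- function(layer) c("W", "b")

## ---- ReLU -----------------------------------------------------------------

nn_relu <- function() new_layer("nn_relu")

#' @export
ly_forward.nn_relu <- function(layer, x, train = FALSE) {
  y <- x * (x > 0)
  layer$mask <- (x > 0)
  y
}

#' @export
ly_backward.nn_relu <- function(layer, gy) gy * layer$mask

## ---- Global average pooling over (H, W, T) --------------------------------

nn_gap <- function() new_layer("nn_gap")

#' @export
ly_forward.nn_gap <- function(layer, x, train = FALSE) {
  xd <- dim(x)
  S <- prod(xd[1:3])
  xm <- x; dim(xm) <- c(S, xd[4L] * xd[5L])
  y <- matrix(colMeans(xm), nrow = xd[4L], ncol = xd[5L])
  layer$xdim <- xd
  y
}

#' @export
ly_backward.nn_gap <- function(layer, gy) {
  xd <- layer$xdim
  S <- prod(xd[1:3])
  gx <- array(rep(as.numeric(gy) / S, each = S), dim = xd)
  gx
}

## ---- Fully connected (input: N x in matrix) -------------------------------

nn_linear <- function(in_dim, out_dim) {
  W <- matrix(he_init(in_dim * out_dim, in_dim), nrow = in_dim, ncol = out_dim)
  new_layer("nn_linear", W = W, b = numeric(out_dim))
}

#' @export
ly_forward.nn_linear <- function(layer, x, train = FALSE) {
  layer$x <- x
  sweep(x %*% layer$W, 2L, layer$b, "+")
}

#' @export
ly_backward.nn_linear <- function(layer, gy) {
  layer$gW <- crossprod(layer$x, gy)
  layer$gb <- colSums(gy)
  gy %*% t(layer$W)
}

#' @export
ly_params.nn_linear <- function(layer) c("W", "b")

## ---- Residual basic block (3D ResNet) -------------------------------------

nn_resblock <- function(in_ch, out_ch, stride = c(1L, 1L, 1L)) {
  stride <- as.integer(stride)
  down <- NULL
  if (any(stride != 1L) || in_ch != out_ch) {
    down <- list(nn_conv3d(in_ch, out_ch, kernel = c(1L, 1L, 1L), stride = stride,
                           pad = c(0L, 0L, 0L), bias = FALSE),
                 nn_batchnorm3d(out_ch))
  }
  new_layer("nn_resblock",
            conv1 = nn_conv3d(in_ch, out_ch, stride = stride, bias = FALSE),
            bn1 = nn_batchnorm3d(out_ch),
            relu1 = nn_relu(),
            conv2 = nn_conv3d(out_ch, out_ch, bias = FALSE),
            bn2 = nn_batchnorm3d(out_ch),
            relu2 = nn_relu(),
            down = down)
}

#' @export
ly_forward.nn_resblock <- function(layer, x, train = FALSE) {
  out <- ly_forward(layer$conv1, x, train)
  out <- ly_forward(layer$bn1, out, train)
  out <- ly_forward(layer$relu1, out, train)
  out <- ly_forward(layer$conv2, out, train)
  out <- ly_forward(layer$bn2, out, train)
  sc <- x
  if (!is.null(layer$down)) {
    sc <- ly_forward(layer$down[[1L]], x, train)
    sc <- ly_forward(layer$down[[2L]], sc, train)
  }
  ly_forward(layer$relu2, out + sc, train)
}

#' @export
ly_backward.nn_resblock <- function(layer, gy) {
  g <- ly_backward(layer$relu2, gy)
  gsc <- g
  gmain <- ly_backward(layer$bn2, g)
  gmain <- ly_backward(layer$conv2, gmain)
  gmain <- ly_backward(layer$relu1, gmain)
  gmain <- ly_backward(layer$bn1, gmain)
  gmain <- ly_backward(layer$conv1, gmain)
  if (!is.null(layer$down)) {
    gsc <- ly_backward(layer$down[[2L]], gsc)
    gsc <- ly_backward(layer$down[[1L]], gsc)
  }
  gmain + gsc
}

## Residual blocks expose sub-layers rather than raw parameter names.
#' @export
ly_params.nn_resblock <- function(layer) character(0)

sublayers <- function(layer) {
  if (inherits(layer, "nn_resblock")) {
    out <- list(layer$conv1, layer$bn1, layer$conv2, layer$bn2)
    if (!is.null(layer$down)) out <- c(out, layer$down)
    out
  } else {
    list(layer)
  }
}

## ---- Sequential plumbing --------------------------------------------------

nn_seq_forward <- function(layers, x, train = FALSE, keep = NULL) {
  kept <- NULL
  for (i in seq_along(layers)) {
    x <- ly_forward(layers[[i]], x, train)
    if (!is.null(keep) && i == keep) kept <- x
  }
  if (is.null(keep)) x else list(out = x, kept = kept)
}

## Backward from the top down to (and excluding) layer `stop_at`; returns the
## gradient flowing *into* layer stop_at + 1, i.e. w.r.t. the output of stop_at.
nn_seq_backward <- function(layers, gy, stop_at = 0L) {
  for (i in rev(seq_along(layers))) {
    if (i <= stop_at) break
    gy <- ly_backward(layers[[i]], gy)
  }
  gy
}

## Flat list of (layer, parameter-name) slots across a list of layers.
nn_param_slots <- function(layers) {
  slots <- list()
  for (layer in layers) {
    for (sl in sublayers(layer)) {
      for (nm in ly_params(sl)) slots[[length(slots) + 1L]] <- list(layer = sl, name = nm)
    }
  }
  slots
}

nn_get_state <- function(layers) {
  lapply(nn_param_slots(layers), function(s) s$layer[[s$name]])
}

nn_set_state <- function(layers, state) {
  slots <- nn_param_slots(layers)
  stopifnot(length(slots) == length(state))
  for (i in seq_along(slots)) {
    sl <- slots[[i]]
    stopifnot(length(sl$layer[[sl$name]]) == length(state[[i]]))
    cur <- state[[i]]
    dim(cur) <- dim(sl$layer[[sl$name]])
    sl$layer[[sl$name]] <- cur
  }
  invisible(layers)
}

## Running batch-norm statistics are part of a checkpoint but not optimized.
nn_get_buffers <- function(layers) {
  out <- list()
  for (layer in layers) for (sl in sublayers(layer)) {
    if (inherits(sl, "nn_batchnorm3d"))
      out[[length(out) + 1L]] <- list(mean = sl$run_mean, var = sl$run_var)
  }
  out
}

nn_set_buffers <- function(layers, bufs) {
  i <- 0L
  for (layer in layers) for (sl in sublayers(layer)) {
    if (inherits(sl, "nn_batchnorm3d")) {
      i <- i + 1L
      sl$run_mean <- bufs[[i]]$mean
      sl$run_var <- bufs[[i]]$var
    }
  }
  invisible(layers)
}

## ---- Adam -----------------------------------------------------------------

adam_new <- function(slots, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$slots <- slots
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st$t <- 0L
  st$m <- lapply(slots, function(s) array(0, dim = dim(s$layer[[s$name]]) %||% length(s$layer[[s$name]])))
  st$v <- st$m
  st
}

adam_step <- function(opt) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  bc1 <- 1 - b1^opt$t; bc2 <- 1 - b2^opt$t
  for (i in seq_along(opt$slots)) {
    sl <- opt$slots[[i]]
    g <- sl$layer[[paste0("g", sl$name)]]
    if (is.null(g)) next
    opt$m[[i]] <- b1 * opt$m[[i]] + (1 - b1) * g
    opt$v[[i]] <- b2 * opt$v[[i]] + (1 - b2) * g * g
    mhat <- opt$m[[i]] / bc1
    vhat <- opt$v[[i]] / bc2
    sl$layer[[sl$name]] <- sl$layer[[sl$name]] - opt$lr * mhat / (sqrt(vhat) + opt$eps)
  }
  invisible(opt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
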