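#' Video encoders and heads
#'
#' The default encoder is an 18-layer 3D residual network (the "r3d_18"
#' architecture): a stem convolution with a 3x7x7 kernel (time x height x
#' width) and spatial stride 2, four stages of two basic residual blocks with
#' 64/128/256/512 channels (stages 2-4 halving every dimension), global
#' average pooling, and a 512-dimensional representation \eqn{h}. A reduced
#' encoder with the same contract (512-dimensional output) but far fewer
#' filters is provided for CPU-scale experiments.
#'
#' @param in_ch Number of input channels (grayscale clips are replicated to 3).
#' @param seed Optional integer seed fixing the random initialization.
#' @return An object of class `echo_encoder`: a list with elements `layers`
#'   (the layer stack), `repr_dim` (always 512), `last_conv` (index of the
#'   last convolution block, used by Grad-CAM), and `arch`.
#' @examples
#' enc <- encoder_tiny(seed = 1)
#' h <- encoder_forward(enc, array(runif(3 * 4 * 16 * 16), c(16, 16, 4, 1, 3)))
#' dim(h)  # 1 x 512
#' @export
encoder_r3d18 <- function(in_ch = 3L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  layers <- list(
    nn_conv3d(in_ch, 64L, kernel = c(7L, 7L, 3L), stride = c(2L, 2L, 1L),
              pad = c(3L, 3L, 1L), bias = FALSE),
    nn_batchnorm3d(64L),
    nn_relu(),
    nn_resblock(64L, 64L),
    nn_resblock(64L, 64L),
    nn_resblock(64L, 128L, stride = c(2L, 2L, 2L)),
    nn_resblock(128L, 128L),
    nn_resblock(128L, 256L, stride = c(2L, 2L, 2L)),
    nn_resblock(256L, 256L),
    nn_resblock(256L, 512L, stride = c(2L, 2L, 2L)),
    nn_resblock(512L, 512L),
    nn_gap()
  )
  structure(list(layers = layers, repr_dim = 512L, last_conv = 11L,
                 arch = "r3d_18", in_ch = in_ch),
            class = "echo_encoder")
}

#' @rdname encoder_r3d18
#' @param width Base channel width of the reduced encoder.
#' @export
encoder_tiny <- function(in_ch = 3L, width = 8L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  layers <- list(
    nn_conv3d(in_ch, width, stride = c(2L, 2L, 1L), bias = FALSE),
    nn_batchnorm3d(width),
    nn_relu(),
    nn_conv3d(width, 2L * width, stride = c(2L, 2L, 1L), bias = FALSE),
    nn_batchnorm3d(2L * width),
    nn_relu(),
    nn_conv3d(2L * width, 4L * width, stride = c(2L, 2L, 2L), bias = FALSE),
    nn_batchnorm3d(4L * width),
    nn_relu(),
    nn_gap(),
    nn_linear(4L * width, 512L)
  )
  structure(list(layers = layers, repr_dim = 512L, last_conv = 9L,
                 arch = "tiny", in_ch = in_ch, width = width),
            class = "echo_encoder")
}

#' @rdname encoder_r3d18
#' @param encoder An `echo_encoder`.
#' @param x Input tensor, dim (H, W, T, N, C).
#' @param train Logical; training mode (batch statistics, caches for backward).
#' @export
encoder_forward <- function(encoder, x, train = FALSE) {
  nn_seq_forward(encoder$layers, x, train = train)
}

#' Projection head g()
#'
#' Maps the 512-dimensional representation to a 128-dimensional embedding
#' through a 256-unit hidden layer with a ReLU activation, as used for the
#' contrastive objective.
#'
#' @param in_dim Representation dimension (512).
#' @param hidden Hidden width (256).
#' @param out_dim Embedding dimension (128).
#' @param seed Optional integer seed.
#' @return List of layers with class `echo_projector`.
#' @export
projector_mlp <- function(in_dim = 512L, hidden = 256L, out_dim = 128L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  structure(list(layers = list(nn_linear(in_dim, hidden), nn_relu(),
                               nn_linear(hidden, out_dim)),
                 out_dim = as.integer(out_dim)),
            class = "echo_projector")
}

#' Frame-reorder head
#'
#' A single fully connected layer mapping the representation \eqn{h} to
#' `factorial(K)` logits, one per possible frame ordering.
#'
#' @param k Clip length K.
#' @param in_dim Representation dimension.
#' @param seed Optional integer seed.
#' @export
reorder_head <- function(k = 4L, in_dim = 512L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  structure(list(layers = list(nn_linear(in_dim, factorial(k))),
                 k = as.integer(k), n_classes = factorial(k)),
            class = "echo_reorder_head")
}

#' Disease classification head: representation -> one pre-sigmoid logit.
#' @param in_dim Representation dimension.
#' @param seed Optional integer seed.
#' @export
disease_head <- function(in_dim = 512L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  structure(list(layers = list(nn_linear(in_dim, 1L))), class = "echo_disease_head")
}

## Convert a list of [0,1] clips (H x W x K arrays) into the 5-D input tensor,
## replicating the single grayscale channel to `ch` channels.
clips_to_tensor <- function(clips, ch = 3L) {
  d <- dim(clips[[1L]]$frames)
  n <- length(clips)
  x <- array(0, dim = c(d[1L], d[2L], d[3L], n, ch))
  for (i in seq_len(n)) {
    f <- clips[[i]]$frames
    for (c in seq_len(ch)) x[, , , i, c] <- f
  }
  x
}

## ---- Checkpoints ----------------------------------------------------------

#' Save / load model checkpoints
#'
#' A checkpoint stores the encoder and head weights, batch-norm running
#' statistics, the epoch it was taken at, its validation loss, and a
#' fingerprint of the producing configuration.
#'
#' @param encoder An `echo_encoder`.
#' @param heads Named list of head objects (may be empty).
#' @param epoch Epoch index the weights were taken at.
#' @param val_loss Validation loss at that epoch (NA if not tracked).
#' @param config The producing configuration (any list); stored with a
#'   digest-style fingerprint for integrity checks.
#' @return Object of class `echo_checkpoint`.
#' @export
make_checkpoint <- function(encoder, heads = list(), epoch = NA_integer_,
                            val_loss = NA_real_, config = list()) {
  structure(list(
    arch = encoder$arch,
    in_ch = encoder$in_ch,
    width = encoder$width,
    encoder_state = nn_get_state(encoder$layers),
    encoder_buffers = nn_get_buffers(encoder$layers),
    head_state = lapply(heads, function(h) nn_get_state(h$layers)),
    head_class = lapply(heads, class),
    epoch = epoch,
    val_loss = val_loss,
    config = config,
    fingerprint = config_fingerprint(config)
  ), class = "echo_checkpoint")
}

#' @rdname make_checkpoint
#' @param ckpt An `echo_checkpoint`.
#' @param path File path (.rds).
#' @export
save_checkpoint <- function(ckpt, path) {
  stopifnot(inherits(ckpt, "echo_checkpoint"))
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname make_checkpoint
#' @export
load_checkpoint <- function(path) {
  ckpt <- readRDS(path)
  stopifnot(inherits(ckpt, "echo_checkpoint"))
  if (!identical(ckpt$fingerprint, config_fingerprint(ckpt$config)))
    stop("checkpoint fingerprint does not match its stored config")
  ckpt
}

#' @rdname make_checkpoint
#' @export
restore_encoder <- function(ckpt) {
  enc <- if (identical(ckpt$arch, "tiny")) {
    encoder_tiny(in_ch = ckpt$in_ch, width = ckpt$width)
  } else {
    encoder_r3d18(in_ch = ckpt$in_ch)
  }
  nn_set_state(enc$layers, ckpt$encoder_state)
  nn_set_buffers(enc$layers, ckpt$encoder_buffers)
  enc
}

## Order-insensitive structural fingerprint of a configuration list.
config_fingerprint <- function(config) {
  txt <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE, digits = NA)
  # polynomial rolling hash over the serialized text; cheap, dependency-free
  h <- 0
  for (b in as.integer(charToRaw(as.character(txt)))) {
    h <- (h * 131 + b) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}
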