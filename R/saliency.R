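#' Grad-CAM over a 3D encoder
#'
#' Computes a gradient-weighted class-activation volume at the last
#' convolution block of the encoder for a 32-frame clip. Channel weights are
#' the gradients of the target logit global-average-pooled over all three
#' grid axes; the volume is the ReLU-rectified channel-weighted sum of the
#' block's activations. For the default 3D-ResNet18 on a 112 x 112 x 32 clip
#' the grid is 7 x 7 x 4 (height x width x time).
#'
#' @param encoder An `echo_encoder`.
#' @param head A `disease_head` (its pre-sigmoid logit is differentiated).
#' @param clip An `echo_clip`; clips shorter than `n_frames` are loop-padded
#'   (with a message).
#' @param n_frames Expected clip length (default 32).
#' @return Non-negative array (H' x W' x T'), the raw Grad-CAM grid.
#' @export
gradcam_volume <- function(encoder, head, clip, n_frames = 32L) {
  stopifnot(inherits(encoder, "echo_encoder"), inherits(clip, "echo_clip"))
  k <- dim(clip$frames)[3L]
  if (k < n_frames) {
    message("clip shorter than ", n_frames, " frames; loop-padding")
    idx <- ((seq_len(n_frames) - 1L) %% k) + 1L
    clip$frames <- clip$frames[, , idx, drop = FALSE]
  }
  x <- clips_to_tensor(list(clip), ch = encoder$in_ch)
  fw <- nn_seq_forward(encoder$layers, x, train = FALSE, keep = encoder$last_conv)
  acts <- fw$kept                                  # (H', W', T', 1, C)
  logit <- nn_seq_forward(head$layers, fw$out, train = FALSE)
  g_top <- matrix(0, nrow = nrow(logit), ncol = ncol(logit))
  g_top[1L, 1L] <- 1
  gh <- nn_seq_backward(head$layers, g_top)
  g_acts <- nn_seq_backward(encoder$layers, gh, stop_at = encoder$last_conv)
  d <- dim(acts)
  alpha <- apply(g_acts, 5L, mean)                 # GAP over (H', W', T')
  cam <- array(0, dim = d[1:3])
  for (c in seq_len(d[5L])) cam <- cam + alpha[c] * acts[, , , 1L, c]
  pmax(cam, 0)
}

#' Temporal max-projection of a saliency volume
#'
#' Interpolates the raw Grad-CAM grid to the input dimension (default
#' 112 x 112 x 32) with separable cubic splines, then takes the pixelwise
#' maximum along the temporal axis to obtain a single 2D heatmap.
#'
#' @param grid Non-negative array (H' x W' x T').
#' @param out_dim Target dimension, default `c(112, 112, 32)`.
#' @return List: `volume` (upsampled 3D array), `map` (2D max-projection).
#' @export
project_saliency <- function(grid, out_dim = c(112L, 112L, 32L)) {
  stopifnot(length(dim(grid)) == 3L, all(grid >= 0))
  vol <- zoom3(grid, out_dim)
  map <- apply(vol, c(1L, 2L), max)
  list(volume = vol, map = map)
}

## Separable cubic-spline resampling of a 3D grid (axis by axis), the spline
## analog of ndimage-style zoom with endpoints aligned to the grid corners.
zoom3 <- function(a, out_dim) {
  for (axis in 1:3) {
    d <- dim(a)
    n_in <- d[axis]
    n_out <- out_dim[axis]
    if (n_in == n_out) next
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    m <- matrix(ap, nrow = n_in)
    xout <- seq(1, n_in, length.out = n_out)
    res <- apply(m, 2L, function(col) {
      if (n_in == 1L) rep(col, n_out)
      else stats::spline(seq_len(n_in), col, xout = xout, method = "natural")$y
    })
    res <- array(res, dim = c(n_out, d[perm][-1L]))
    a <- aperm(res, order(perm))
  }
  a
}

#' Saliency heatmap for a fine-tuned model on one video
#'
#' Convenience wrapper: takes the first 32 frames of a video, computes the
#' Grad-CAM volume at the last convolution block, and returns both the raw
#' grid and the temporally max-projected 112 x 112 heatmap (or the video's
#' own resolution for non-default encoders).
#'
#' @param result A `finetune_result`.
#' @param video An `echo_video`.
#' @param n_frames Clip length (default 32).
#' @param out_dim Upsampling target; default matches the video resolution
#'   and `n_frames`.
#' @return List: `grid`, `volume`, `map`.
#' @export
saliency_map <- function(result, video, n_frames = 32L, out_dim = NULL) {
  clip <- eval_clip(video, n_frames)
  grid <- gradcam_volume(result$encoder, result$head, clip, n_frames = n_frames)
  if (is.null(out_dim))
    out_dim <- c(dim(video$frames)[1:2], n_frames)
  c(list(grid = grid), project_saliency(grid, out_dim))
}
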