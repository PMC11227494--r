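#' Video-level view classification by frame-probability averaging
#'
#' Samples `n_frames` frames from the video (without replacement; with
#' replacement when the video is shorter than `n_frames`), resizes each to
#' `frame_size` x `frame_size`, applies the supplied frame-level view
#' classifier, and averages the per-frame probability vectors into a single
#' video-level view prediction. The video is retained iff the argmax class is
#' `"PLAX"`. The pretrained clinical view classifier itself is not part of
#' this package; any function mapping a frame matrix to a named probability
#' vector can be plugged in.
#'
#' @param video An `echo_video`.
#' @param frame_classifier Function(frame_matrix) -> named numeric probability
#'   vector (non-negative, summing to 1 within 1e-6).
#' @param n_frames Number of frames to sample (default 10).
#' @param frame_size Classifier input resolution (default 224).
#' @param seed Optional integer seed for the frame sampling.
#' @return List of class `view_decision`: `video_id`, `mean_probs` (named),
#'   `selected_view`, `retained`.
#' @export
classify_view <- function(video, frame_classifier, n_frames = 10L,
                          frame_size = 224L, seed = NULL) {
  stopifnot(inherits(video, "echo_video"))
  TT <- dim(video$frames)[3L]
  if (TT < 1L) stop("video has no frames")
  if (!is.null(seed)) set.seed(seed)
  idx <- if (TT >= n_frames) sample.int(TT, n_frames)
         else sample.int(TT, n_frames, replace = TRUE)
  probs <- NULL
  for (t in idx) {
    fr <- resize_frame(video$frames[, , t], frame_size)
    p <- frame_classifier(fr)
    if (!is.numeric(p) || is.null(names(p)) || any(p < 0) ||
        abs(sum(p) - 1) > 1e-6)
      stop("frame_classifier must return a named probability vector summing to 1")
    probs <- if (is.null(probs)) p / n_frames else probs + p / n_frames
  }
  sel <- names(probs)[which.max(probs)]
  structure(list(video_id = video$video_id, mean_probs = probs,
                 selected_view = sel, retained = identical(sel, "PLAX")),
            class = "view_decision")
}

resize_frame <- function(frame, size) {
  if (all(dim(frame) == size)) return(frame)
  out <- EBImage::resize(EBImage::Image(frame), w = size, h = size)
  m <- EBImage::imageData(out)
  pmin(pmax(m, min(frame)), max(frame))
}

#' Threshold-and-convex-hull content masking
#'
#' Binarizes the union of all frames at a fixed intensity threshold
#' (>= `threshold`, default 200), finds the largest connected bright
#' component, takes the convex hull of its pixels, and zeroes every pixel
#' outside that hull in all frames. The hull is computed once per video from
#' the cross-frame union so the field of view does not jitter over time. This
#' removes annotation content outside the central ultrasound sector.
#'
#' @param video An `echo_video` with 8-bit intensities.
#' @param threshold Binarization threshold in \[0, 255\].
#' @return The masked `echo_video`; unchanged (with a warning) when no pixel
#'   reaches the threshold. The hull polygon is attached as attribute
#'   `"hull"` (two-column matrix of row/col vertices).
#' @export
binarize_and_hull_mask <- function(video, threshold = 200) {
  stopifnot(inherits(video, "echo_video"), threshold >= 0, threshold <= 255)
  d <- dim(video$frames)
  union_max <- apply(video$frames, c(1L, 2L), max)
  bin <- union_max >= threshold
  if (!any(bin)) {
    warning("no pixel reaches the binarization threshold; video returned unchanged")
    return(video)
  }
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bin * 1)))
  sizes <- tabulate(lab[lab > 0])
  biggest <- which.max(sizes)
  coords <- which(lab == biggest, arr.ind = TRUE)
  hull_idx <- grDevices::chull(coords[, 1L], coords[, 2L])
  hull <- coords[hull_idx, , drop = FALSE]
  inside <- points_in_convex_polygon(
    rep(seq_len(d[1L]), times = d[2L]),
    rep(seq_len(d[2L]), each = d[1L]),
    hull)
  mask <- matrix(inside, d[1L], d[2L])
  for (t in seq_len(d[3L])) video$frames[, , t] <- video$frames[, , t] * mask
  attr(video, "hull") <- hull
  video
}

## Vectorized inclusive point-in-convex-polygon test via edge cross products.
## `hull` rows must be vertices in hull order (chull order is fine).
points_in_convex_polygon <- function(px, py, hull) {
  k <- nrow(hull)
  if (k == 1L) return(px == hull[1L, 1L] & py == hull[1L, 2L])
  if (k == 2L) {
    # degenerate hull: points on the segment
    d <- (hull[2L, 1L] - hull[1L, 1L]) * (py - hull[1L, 2L]) -
         (hull[2L, 2L] - hull[1L, 2L]) * (px - hull[1L, 1L])
    on_line <- abs(d) < 1e-9
    within <- px >= min(hull[, 1L]) & px <= max(hull[, 1L]) &
              py >= min(hull[, 2L]) & py <= max(hull[, 2L])
    return(on_line & within)
  }
  pos <- rep(TRUE, length(px))
  neg <- rep(TRUE, length(px))
  for (i in seq_len(k)) {
    j <- if (i == k) 1L else i + 1L
    cr <- (hull[j, 1L] - hull[i, 1L]) * (py - hull[i, 2L]) -
          (hull[j, 2L] - hull[i, 2L]) * (px - hull[i, 1L])
    pos <- pos & (cr >= 0)
    neg <- neg & (cr <= 0)
  }
  pos | neg
}

#' Spatially downsample a video
#'
#' Bilinearly resizes every frame to `size` x `size`; intensities stay within
#' the original \[0, 255\] range.
#'
#' @param video An `echo_video` with H, W >= size/4.
#' @param size Target resolution (default 112).
#' @return The resized `echo_video`.
#' @export
downsample_video <- function(video, size = 112L) {
  stopifnot(inherits(video, "echo_video"))
  d <- dim(video$frames)
  if (d[1L] < size / 4 || d[2L] < size / 4) stop("input too small to resize to ", size)
  out <- array(0, dim = c(size, size, d[3L]))
  for (t in seq_len(d[3L])) out[, , t] <- resize_frame(video$frames[, , t], size)
  video$frames <- pmin(pmax(out, 0), 255)
  video
}

#' Filter a manifest by exclusion flags
#'
#' Removes every study carrying any of the given exclusion flags (e.g. the
#' low-flow, low-gradient AS flag `"llg_as"`); all other records pass through
#' unchanged.
#'
#' @param manifest A `cohort_manifest`.
#' @param excluded_flags Character vector of flags to exclude on.
#' @return The filtered `cohort_manifest` with attributes `"n_removed"` and
#'   `"n_kept"`.
#' @export
filter_manifest <- function(manifest, excluded_flags = character(0)) {
  stopifnot(is.data.frame(manifest))
  if (length(excluded_flags) == 0L) {
    attr(manifest, "n_removed") <- 0L
    attr(manifest, "n_kept") <- nrow(manifest)
    return(manifest)
  }
  flags <- strsplit(manifest$exclusion_flags, ";", fixed = TRUE)
  hit <- vapply(flags, function(f) any(f %in% excluded_flags), logical(1))
  out <- manifest[!hit, , drop = FALSE]
  rownames(out) <- NULL
  message(sum(hit), " of ", nrow(manifest), " studies excluded by flags {",
          paste(excluded_flags, collapse = ", "), "}")
  attr(out, "n_removed") <- sum(hit)
  attr(out, "n_kept") <- nrow(out)
  out
}

#' Full preprocessing chain for one video
#'
#' Threshold/convex-hull masking followed by downsampling, the standard
#' curation applied before model training.
#'
#' @inheritParams binarize_and_hull_mask
#' @inheritParams downsample_video
#' @return The preprocessed `echo_video`.
#' @export
preprocess_video <- function(video, threshold = 200, size = 112L) {
  downsample_video(binarize_and_hull_mask(video, threshold), size)
}
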