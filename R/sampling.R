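#' Study-level data splitting
#'
#' Shuffles study ids with the given seed and assigns the first
#' `floor(0.75 n)` to training, the next `floor(0.10 n)` to validation, and
#' the remainder to internal testing. All videos of a study inherit its
#' split, so no patient leaks across splits.
#'
#' @param study_ids Character vector of unique study ids (>= 3).
#' @param fractions Split fractions summing to 1 (default 0.75/0.10/0.15).
#' @param seed Integer seed.
#' @return Data frame (study_id, split) with class `split_assignment`;
#'   `split` is one of `"train"`, `"val"`, `"test"`.
#' @export
split_studies <- function(study_ids, fractions = c(0.75, 0.10, 0.15), seed = 1L) {
  if (anyDuplicated(study_ids)) stop("duplicate study ids in manifest")
  n <- length(study_ids)
  stopifnot(n >= 3L, length(fractions) == 3L, abs(sum(fractions) - 1) <= 1e-9)
  set.seed(seed)
  perm <- sample(study_ids)
  n_train <- floor(fractions[1L] * n)
  n_val <- floor(fractions[2L] * n)
  split <- rep("test", n)
  split[seq_len(n_train)] <- "train"
  if (n_val > 0L) split[n_train + seq_len(n_val)] <- "val"
  out <- data.frame(study_id = perm, split = split, stringsAsFactors = FALSE)
  attr(out, "seed") <- seed
  attr(out, "fractions") <- fractions
  class(out) <- c("split_assignment", "data.frame")
  out
}

#' Label titration: subsample the training studies
#'
#' Uniformly samples `floor(ratio * n)` studies without replacement. The floor
#' rule reproduces the standard titration series: of 5194 studies, 1%/5%/10%/
#' 25%/50%/100% give 51/259/519/1298/2597/5194; of 5311 they give
#' 53/265/531/1327/2655/5311.
#'
#' @param train_study_ids Character vector of training study ids.
#' @param ratio Fraction in (0, 1]; `ratio = 1` returns the full input set.
#' @param seed Integer seed.
#' @return Character vector of selected study ids.
#' @export
titrate <- function(train_study_ids, ratio, seed = 1L) {
  stopifnot(ratio > 0, ratio <= 1)
  n <- length(train_study_ids)
  k <- floor(ratio * n)
  if (k == 0L) stop("titration ratio ", ratio, " selects zero of ", n, " studies")
  if (ratio == 1) return(train_study_ids)
  set.seed(seed)
  sample(train_study_ids, k)
}

#' Enumerate multi-instance positive pairs
#'
#' Emits every unordered pair of distinct videos acquired in the same study:
#' a study with m videos contributes choose(m, 2) pairs; single-video studies
#' contribute none.
#'
#' @param manifest A `cohort_manifest`.
#' @return Data frame (study_id, video_id_a, video_id_b) with a < b.
#' @export
enumerate_positive_pairs <- function(manifest) {
  vids <- manifest_video_ids(manifest)
  rows <- list()
  for (sid in names(vids)) {
    v <- sort(vids[[sid]])
    m <- length(v)
    if (m < 2L) next
    cmb <- utils::combn(v, 2L)
    rows[[sid]] <- data.frame(study_id = sid, video_id_a = cmb[1L, ],
                              video_id_b = cmb[2L, ], stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(study_id = character(0), video_id_a = character(0),
                      video_id_b = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sample a clip of K consecutive frames
#'
#' The start index is uniform on \[0, T-K\]. Videos shorter than K are looped
#' (frame t maps to t mod T) to length K, preserving the periodic cardiac
#' motion. Intensities are rescaled from \[0, 255\] to \[0, 1\].
#'
#' @param video An `echo_video`.
#' @param k Clip length (4 for pretraining, 16 for fine-tuning, 32 for
#'   saliency).
#' @param seed Optional integer seed.
#' @return List of class `echo_clip`: `frames` (H x W x K, values in \[0,1\]),
#'   `video_id`, `start` (0-based start frame).
#' @export
sample_clip <- function(video, k = 4L, seed = NULL) {
  stopifnot(inherits(video, "echo_video"), k >= 1L)
  TT <- dim(video$frames)[3L]
  if (TT < 1L) stop("empty video")
  if (!is.null(seed)) set.seed(seed)
  if (TT >= k) {
    start <- sample.int(TT - k + 1L, 1L) - 1L
    idx <- start + seq_len(k)
  } else {
    start <- 0L
    idx <- ((seq_len(k) - 1L) %% TT) + 1L
  }
  structure(list(frames = video$frames[, , idx, drop = FALSE] / 255,
                 video_id = video$video_id, start = start),
            class = "echo_clip")
}

#' Lexicographic permutation ranking (Lehmer code)
#'
#' `permutation_rank()` maps a permutation of 0..K-1 to its 0-based
#' lexicographic rank in \[0, K!); `permutation_unrank()` is its inverse.
#' The frame-reorder pretext task uses these ranks as class indices.
#'
#' @param order Integer vector: a permutation of 0..K-1.
#' @return `permutation_rank()`: integer rank in \[0, K!).
#' @export
permutation_rank <- function(order) {
  k <- length(order)
  if (!setequal(order, 0:(k - 1L)) || anyDuplicated(order))
    stop("order must be a permutation of 0..K-1")
  rank <- 0
  for (i in seq_len(k - 1L)) {
    smaller <- sum(order[(i + 1L):k] < order[i])
    rank <- rank + smaller * factorial(k - i)
  }
  as.integer(rank)
}

#' @rdname permutation_rank
#' @param class_index Integer in \[0, K!).
#' @param k Permutation length K.
#' @return `permutation_unrank()`: the permutation of 0..K-1 with that rank.
#' @export
permutation_unrank <- function(class_index, k) {
  if (class_index < 0 || class_index >= factorial(k))
    stop("class_index must lie in [0, K!)")
  remaining <- 0:(k - 1L)
  out <- integer(k)
  idx <- class_index
  for (i in seq_len(k)) {
    f <- factorial(k - i)
    j <- idx %/% f
    out[i] <- remaining[j + 1L]
    remaining <- remaining[-(j + 1L)]
    idx <- idx %% f
  }
  out
}

#' Randomly shuffle the frames of a clip
#'
#' Draws a permutation uniformly from the K! orderings; output frame j is
#' input frame `order[j]`. The drawn ordering and its lexicographic rank form
#' the target of the frame-reorder pretext task.
#'
#' @param clip An `echo_clip` with K >= 2 frames.
#' @param seed Optional integer seed.
#' @return List: `clip` (shuffled), `label` (list with `order`, 0-based, and
#'   `class_index`).
#' @export
shuffle_clip <- function(clip, seed = NULL) {
  stopifnot(inherits(clip, "echo_clip"))
  k <- dim(clip$frames)[3L]
  stopifnot(k >= 2L)
  if (!is.null(seed)) set.seed(seed)
  ord <- sample.int(k) - 1L
  out <- clip
  out$frames <- clip$frames[, , ord + 1L, drop = FALSE]
  list(clip = out,
       label = list(order = ord, class_index = permutation_rank(ord)))
}

#' Augmentation configuration
#'
#' Clip-consistent geometric augmentation: random zero padding by up to
#' `max_pad` pixels per side in each spatial dimension followed by a random
#' size-preserving crop, a horizontal flip with probability `flip_prob`, and
#' a rotation drawn from `rotation_range` degrees with probability
#' `rotation_prob`. One parameter draw per clip, applied identically to every
#' frame, so the temporal structure the reorder task depends on is untouched.
#'
#' @param max_pad Maximum zero-padding in pixels per side (default 8).
#' @param flip_prob Horizontal flip probability (default 0.5).
#' @param rotation_range Rotation range in degrees (default c(-10, 10)).
#' @param rotation_prob Rotation probability (default 0.5).
#' @return List of class `augmentation_config`.
#' @export
augmentation_config <- function(max_pad = 8L, flip_prob = 0.5,
                                rotation_range = c(-10, 10), rotation_prob = 0.5) {
  stopifnot(flip_prob >= 0, flip_prob <= 1, rotation_prob >= 0, rotation_prob <= 1,
            max_pad >= 0)
  structure(list(max_pad = as.integer(max_pad), flip_prob = flip_prob,
                 rotation_range = rotation_range, rotation_prob = rotation_prob),
            class = "augmentation_config")
}

#' @rdname augmentation_config
#' @param clip An `echo_clip`.
#' @param config An `augmentation_config`.
#' @param seed Optional integer seed.
#' @return `augment_clip()`: the augmented `echo_clip` (same shape, values in
#'   \[0,1\]).
#' @export
augment_clip <- function(clip, config, seed = NULL) {
  stopifnot(inherits(clip, "echo_clip"), inherits(config, "augmentation_config"))
  if (!is.null(seed)) set.seed(seed)
  d <- dim(clip$frames)
  H <- d[1L]; W <- d[2L]; K <- d[3L]
  do_flip <- stats::runif(1) < config$flip_prob
  angle <- if (stats::runif(1) < config$rotation_prob)
    stats::runif(1, config$rotation_range[1L], config$rotation_range[2L]) else 0
  pad_h <- if (config$max_pad > 0L) sample(0:config$max_pad, 1L) else 0L
  pad_w <- if (config$max_pad > 0L) sample(0:config$max_pad, 1L) else 0L
  off_h <- if (pad_h > 0L) sample(0:(2L * pad_h), 1L) else 0L
  off_w <- if (pad_w > 0L) sample(0:(2L * pad_w), 1L) else 0L

  out <- clip$frames
  if (do_flip) out <- out[, W:1L, , drop = FALSE]
  if (angle != 0) {
    for (t in seq_len(K)) {
      img <- EBImage::rotate(EBImage::Image(out[, , t]), angle,
                             output.dim = c(H, W), bg.col = 0)
      out[, , t] <- pmin(pmax(EBImage::imageData(img), 0), 1)
    }
  }
  if (pad_h > 0L || pad_w > 0L) {
    padded <- array(0, dim = c(H + 2L * pad_h, W + 2L * pad_w, K))
    padded[pad_h + seq_len(H), pad_w + seq_len(W), ] <- out
    out <- padded[off_h + seq_len(H), off_w + seq_len(W), , drop = FALSE]
  }
  clip$frames <- out
  clip
}
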