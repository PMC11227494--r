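#' Pretraining configuration
#'
#' Defaults are the reference settings: clip length K = 4, temperature 0.5,
#' Adam with learning rate 0.1, batch size 392 clips, 300 epochs for the
#' multi-instance modes. The `encoder` knob selects the full 3D-ResNet18 or
#' the reduced encoder for CPU-scale runs.
#'
#' @param mode `"EchoCLR"` (multi-instance pairs + frame reordering),
#'   `"MI-SimCLR"` (pairs only), or `"SimCLR"` (two augmentations of a single
#'   video, no reordering).
#' @param k Clip length (default 4).
#' @param tau NT-Xent temperature (default 0.5).
#' @param lr Adam learning rate (default 0.1).
#' @param batch_size Number of clips per batch (must be even; default 392).
#' @param epochs Number of epochs (default 300).
#' @param encoder `"r3d18"` or `"tiny"`.
#' @param width Channel width of the reduced encoder.
#' @param augment An [augmentation_config()].
#' @param seed Integer seed fixing initialization and sampling.
#' @return List of class `pretrain_config`.
#' @export
pretrain_config <- function(mode = c("EchoCLR", "MI-SimCLR", "SimCLR"),
                            k = 4L, tau = 0.5, lr = 0.1, batch_size = 392L,
                            epochs = 300L, encoder = c("r3d18", "tiny"),
                            width = 8L, augment = augmentation_config(),
                            seed = 1L) {
  mode <- match.arg(mode)
  encoder <- match.arg(encoder)
  stopifnot(batch_size %% 2L == 0L, k >= 2L, tau > 0)
  structure(list(mode = mode, k = as.integer(k), tau = tau, lr = lr,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 encoder = encoder, width = as.integer(width), augment = augment,
                 seed = as.integer(seed)),
            class = "pretrain_config")
}

#' Epoch-budget matching across sampling schemes
#'
#' Multi-instance modes iterate positive pairs; plain contrastive pretraining
#' iterates videos. To equalize the number of optimization examples seen, the
#' single-video scheme runs `round(pair_epochs * pairs_per_epoch /
#' items_per_epoch)` epochs (e.g. 300 pair-epochs at 26 pairs vs 15 videos
#' per epoch gives 520).
#'
#' @param pairs_per_epoch Positive pairs per multi-instance epoch.
#' @param items_per_epoch Items (videos) per single-instance epoch.
#' @param pair_epochs Number of multi-instance epochs.
#' @return Matched epoch count (integer).
#' @export
match_epoch_budget <- function(pairs_per_epoch, items_per_epoch, pair_epochs) {
  stopifnot(pairs_per_epoch > 0, items_per_epoch > 0, pair_epochs > 0)
  as.integer(round(pair_epochs * pairs_per_epoch / items_per_epoch))
}

make_encoder <- function(kind, width = 8L, in_ch = 3L) {
  if (kind == "tiny") encoder_tiny(in_ch = in_ch, width = width)
  else encoder_r3d18(in_ch = in_ch)
}

#' Self-supervised pretraining
#'
#' Runs the configured pretraining mode on the studies in `manifest`. One
#' epoch visits every positive pair (multi-instance modes) or every video
#' (single-instance mode) once, in shuffled order. EchoCLR shuffles the
#' frames of each sampled clip and trains the sum of the NT-Xent contrastive
#' loss on the projector embeddings and the K!-way reorder cross-entropy on
#' the encoder representations; MI-SimCLR drops the reorder term; SimCLR
#' additionally replaces same-study pairs with two independent augmentations
#' of one clip.
#'
#' @param manifest A `cohort_manifest` restricted to the pretraining studies.
#' @param videos Named list of `echo_video` keyed by video id.
#' @param config A [pretrain_config()].
#' @return List of class `pretrain_result`: `checkpoint` (encoder + heads at
#'   the final epoch), `log` (data frame epoch/nt_xent/reorder/total),
#'   `projector`, `reorder_head`.
#' @export
pretrain <- function(manifest, videos, config) {
  stopifnot(inherits(config, "pretrain_config"))
  set.seed(config$seed)
  multi <- config$mode %in% c("EchoCLR", "MI-SimCLR")
  use_reorder <- config$mode == "EchoCLR"

  if (multi) {
    pairs <- enumerate_positive_pairs(manifest)
    if (nrow(pairs) == 0L)
      stop("no pairable studies (>= 2 videos) available for multi-instance pretraining")
  } else {
    vid_ids <- unlist(manifest_video_ids(manifest), use.names = FALSE)
    vid_ids <- intersect(vid_ids, names(videos))
  }

  enc <- make_encoder(config$encoder, config$width)
  proj <- projector_mlp(in_dim = enc$repr_dim)
  rhead <- if (use_reorder) reorder_head(k = config$k, in_dim = enc$repr_dim) else NULL

  slots <- c(nn_param_slots(enc$layers), nn_param_slots(proj$layers),
             if (use_reorder) nn_param_slots(rhead$layers))
  opt <- adam_new(slots, lr = config$lr)

  pairs_per_batch <- config$batch_size %/% 2L
  log <- data.frame(epoch = integer(0), nt_xent = numeric(0),
                    reorder = numeric(0), total = numeric(0))

  make_clip <- function(video_id, shuffle) {
    cl <- sample_clip(videos[[video_id]], k = config$k)
    cl <- augment_clip(cl, config$augment)
    if (shuffle) shuffle_clip(cl) else list(clip = cl, label = NULL)
  }

  for (epoch in seq_len(config$epochs)) {
    if (multi) {
      ord <- sample.int(nrow(pairs))
      starts <- seq(1L, length(ord), by = pairs_per_batch)
    } else {
      ord <- sample(vid_ids)
      starts <- seq(1L, length(ord), by = pairs_per_batch)
    }
    ep_con <- ep_re <- 0; n_steps <- 0L
    for (s in starts) {
      take <- ord[s:min(s + pairs_per_batch - 1L, length(ord))]
      if (length(take) < 2L) next  # NT-Xent needs >= 2 pairs
      clips <- vector("list", 2L * length(take))
      labels <- vector("list", 2L * length(take))
      for (i in seq_along(take)) {
        if (multi) {
          a <- make_clip(pairs$video_id_a[take[i]], use_reorder)
          b <- make_clip(pairs$video_id_b[take[i]], use_reorder)
        } else {
          base <- sample_clip(videos[[take[i]]], k = config$k)
          a <- list(clip = augment_clip(base, config$augment), label = NULL)
          b <- list(clip = augment_clip(base, config$augment), label = NULL)
        }
        clips[[2L * i - 1L]] <- a$clip; labels[[2L * i - 1L]] <- a$label
        clips[[2L * i]] <- b$clip; labels[[2L * i]] <- b$label
      }
      x <- clips_to_tensor(clips, ch = enc$in_ch)
      h <- nn_seq_forward(enc$layers, x, train = TRUE)
      z <- nn_seq_forward(proj$layers, h, train = TRUE)
      l_con <- nt_xent_loss(embedding_batch(z, tau = config$tau), grad = TRUE)
      gh <- nn_seq_backward(proj$layers, attr(l_con, "grad"))
      l_re <- NA_real_
      if (use_reorder) {
        logits <- nn_seq_forward(rhead$layers, h, train = TRUE)
        targets <- vapply(labels, function(l) l$class_index, numeric(1))
        l_re <- reorder_cross_entropy(logits, targets, grad = TRUE)
        gh <- gh + nn_seq_backward(rhead$layers, attr(l_re, "grad"))
      }
      nn_seq_backward(enc$layers, gh)
      adam_step(opt)
      ep_con <- ep_con + as.numeric(l_con)
      ep_re <- ep_re + if (use_reorder) as.numeric(l_re) else 0
      n_steps <- n_steps + 1L
    }
    log <- rbind(log, data.frame(
      epoch = epoch, nt_xent = ep_con / n_steps,
      reorder = if (use_reorder) ep_re / n_steps else NA_real_,
      total = (ep_con + ep_re) / n_steps))
  }

  heads <- list(projector = proj)
  if (use_reorder) heads$reorder <- rhead
  ckpt <- make_checkpoint(enc, heads = heads, epoch = config$epochs,
                          val_loss = NA_real_, config = unclass(config)[
                            c("mode", "k", "tau", "lr", "batch_size", "epochs",
                              "encoder", "width", "seed")])
  structure(list(checkpoint = ckpt, log = log, encoder = enc,
                 projector = proj, reorder_head = rhead),
            class = "pretrain_result")
}

#' Learning-rate grids for fine-tuning
#'
#' At titration ratios of 10% or less, self-supervised initializations search
#' \{0.1, 0.05, 0.001\} and random/Kinetics initializations
#' \{1e-4, 5e-5, 1e-5\}; above 10% the single values 0.1 and 1e-4 are used.
#'
#' @param init `"ssl"`, `"random"`, or `"kinetics"`.
#' @param ratio Titration ratio in (0, 1].
#' @return Numeric vector of candidate learning rates.
#' @export
lr_grid <- function(init, ratio) {
  small <- ratio <= 0.10
  if (init == "ssl") {
    if (small) c(0.1, 0.05, 0.001) else 0.1
  } else {
    if (small) c(1e-4, 5e-5, 1e-5) else 1e-4
  }
}

#' Select a learning rate from validation losses
#'
#' Returns the grid entry with minimal validation loss at the early-stopping
#' checkpoint; ties are broken toward the larger rate.
#'
#' @param grid Numeric vector of learning rates.
#' @param val_losses Numeric vector of validation losses, one per grid entry.
#' @return The selected learning rate.
#' @export
select_learning_rate <- function(grid, val_losses) {
  if (length(grid) == 0L) stop("empty learning-rate grid")
  stopifnot(length(grid) == length(val_losses))
  best <- min(val_losses)
  cand <- grid[val_losses == best]
  sel <- max(cand)
  if (length(cand) > 1L)
    message("validation-loss tie; selecting the larger rate ", sel)
  sel
}

#' Fine-tuning configuration
#'
#' @param init `"random"`, `"ssl"`, or `"kinetics"`.
#' @param checkpoint An `echo_checkpoint` (required for `init = "ssl"`).
#' @param kinetics_path Path to externally supplied Kinetics-400 encoder
#'   weights (an `echo_checkpoint` file); never downloaded implicitly.
#' @param kinetics_stats List with `mean` and `sd`, length-3 channel
#'   statistics used to standardize clips under the Kinetics initialization.
#' @param label Manifest column holding the 0/1 study label
#'   (e.g. `"lvh_label"`, `"severe_as_label"`).
#' @param clip_len Fine-tuning clip length (default 16).
#' @param max_epochs Maximum epochs (default 30).
#' @param patience Early-stopping patience in epochs (default 5).
#' @param lr Adam learning rate; default is the single-rate grid entry for
#'   the initialization and ratio.
#' @param batch_size Videos per batch (default 88).
#' @param ratio Titration ratio in (0, 1].
#' @param encoder,width Encoder architecture (must match the checkpoint for
#'   `init = "ssl"`).
#' @param augment An [augmentation_config()].
#' @param seed Integer seed.
#' @return List of class `finetune_config`.
#' @export
finetune_config <- function(init = c("random", "ssl", "kinetics"),
                            checkpoint = NULL, kinetics_path = NULL,
                            kinetics_stats = NULL, label = "lvh_label",
                            clip_len = 16L, max_epochs = 30L, patience = 5L,
                            lr = NULL, batch_size = 88L, ratio = 1.0,
                            encoder = c("r3d18", "tiny"), width = 8L,
                            augment = augmentation_config(), seed = 1L) {
  init <- match.arg(init)
  encoder <- match.arg(encoder)
  stopifnot(patience < max_epochs, ratio > 0, ratio <= 1)
  if (init == "ssl" && is.null(checkpoint))
    stop("init = 'ssl' requires a pretraining checkpoint")
  if (init == "kinetics" && is.null(kinetics_path))
    stop("init = 'kinetics' requires externally supplied weights (kinetics_path)")
  if (is.null(lr)) lr <- lr_grid(if (init == "ssl") "ssl" else init, ratio)[1L]
  structure(list(init = init, checkpoint = checkpoint, kinetics_path = kinetics_path,
                 kinetics_stats = kinetics_stats, label = label,
                 clip_len = as.integer(clip_len), max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), lr = lr,
                 batch_size = as.integer(batch_size), ratio = ratio,
                 encoder = encoder, width = as.integer(width), augment = augment,
                 seed = as.integer(seed)),
            class = "finetune_config")
}

standardize_channels <- function(x, stats) {
  for (c in seq_len(dim(x)[5L]))
    x[, , , , c] <- (x[, , , , c] - stats$mean[c]) / stats$sd[c]
  x
}

## Deterministic inference clip: the first `k` frames (loop-padded).
eval_clip <- function(video, k) {
  TT <- dim(video$frames)[3L]
  idx <- if (TT >= k) seq_len(k) else ((seq_len(k) - 1L) %% TT) + 1L
  structure(list(frames = video$frames[, , idx, drop = FALSE] / 255,
                 video_id = video$video_id, start = 0L),
            class = "echo_clip")
}

#' Supervised fine-tuning with early stopping
#'
#' Trains the disease head (and encoder) with binary cross-entropy on
#' clips of `clip_len` consecutive frames, using the standard augmentations.
#' Training studies are titrated to `config$ratio`; validation loss is
#' computed each epoch on the validation studies, and training stops when it
#' has not improved for `patience` consecutive epochs (or at `max_epochs`).
#' The returned checkpoint holds the weights of the epoch with minimum
#' validation loss.
#'
#' @param manifest A labeled `cohort_manifest`.
#' @param videos Named list of `echo_video`.
#' @param split A `split_assignment` over the manifest's studies.
#' @param config A [finetune_config()].
#' @return List of class `finetune_result`: `checkpoint`, `head`, `log`
#'   (epoch/train_loss/val_loss), `train_ids`, `lr`.
#' @export
finetune <- function(manifest, videos, split, config) {
  stopifnot(inherits(config, "finetune_config"))
  set.seed(config$seed)
  lab <- manifest[[config$label]]
  names(lab) <- manifest$study_id
  labeled <- manifest$study_id[!is.na(lab)]
  train_ids <- intersect(split$study_id[split$split == "train"], labeled)
  val_ids <- intersect(split$study_id[split$split == "val"], labeled)
  if (length(train_ids) == 0L || length(val_ids) == 0L)
    stop("train/val studies empty after label filtering")
  train_ids <- titrate(train_ids, config$ratio, seed = config$seed)
  if (length(unique(lab[train_ids])) < 2L)
    stop("titrated training set contains a single class")

  enc <- switch(config$init,
    random = make_encoder(config$encoder, config$width),
    ssl = restore_encoder(config$checkpoint),
    kinetics = restore_encoder(load_checkpoint(config$kinetics_path)))
  head <- disease_head(in_dim = enc$repr_dim)
  opt <- adam_new(c(nn_param_slots(enc$layers), nn_param_slots(head$layers)),
                  lr = config$lr)

  vids_by_study <- manifest_video_ids(manifest)
  train_videos <- data.frame(
    video_id = unlist(vids_by_study[train_ids], use.names = FALSE),
    study_id = rep(train_ids, lengths(vids_by_study[train_ids])),
    stringsAsFactors = FALSE)
  train_videos <- train_videos[train_videos$video_id %in% names(videos), ]

  maybe_std <- function(x) {
    if (config$init == "kinetics" && !is.null(config$kinetics_stats))
      standardize_channels(x, config$kinetics_stats) else x
  }

  v2s <- rep(names(vids_by_study), lengths(vids_by_study))
  names(v2s) <- unlist(vids_by_study, use.names = FALSE)

  val_loss_fn <- function() {
    scores <- predict_video_logits(enc, head, videos,
                                   unlist(vids_by_study[val_ids], use.names = FALSE),
                                   clip_len = config$clip_len, transform = maybe_std)
    y <- lab[v2s[names(scores)]]
    as.numeric(bce_with_logits(scores, as.numeric(y)))
  }

  best_val <- Inf; best_epoch <- 0L; best_state <- NULL; best_bufs <- NULL
  best_head <- NULL
  log <- data.frame(epoch = integer(0), train_loss = numeric(0), val_loss = numeric(0))
  since_best <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(nrow(train_videos))
    starts <- seq(1L, length(ord), by = config$batch_size)
    ep_loss <- 0; n_steps <- 0L
    for (s in starts) {
      take <- ord[s:min(s + config$batch_size - 1L, length(ord))]
      clips <- lapply(train_videos$video_id[take], function(v)
        augment_clip(sample_clip(videos[[v]], k = config$clip_len), config$augment))
      y <- as.numeric(lab[train_videos$study_id[take]])
      x <- maybe_std(clips_to_tensor(clips, ch = enc$in_ch))
      h <- nn_seq_forward(enc$layers, x, train = TRUE)
      logits <- nn_seq_forward(head$layers, h, train = TRUE)
      loss <- bce_with_logits(as.numeric(logits), y, grad = TRUE)
      gh <- nn_seq_backward(head$layers, attr(loss, "grad"))
      nn_seq_backward(enc$layers, gh)
      adam_step(opt)
      ep_loss <- ep_loss + as.numeric(loss); n_steps <- n_steps + 1L
    }
    vl <- val_loss_fn()
    log <- rbind(log, data.frame(epoch = epoch, train_loss = ep_loss / n_steps,
                                 val_loss = vl))
    if (vl < best_val) {
      best_val <- vl; best_epoch <- epoch; since_best <- 0L
      best_state <- nn_get_state(enc$layers)
      best_bufs <- nn_get_buffers(enc$layers)
      best_head <- nn_get_state(head$layers)
    } else {
      since_best <- since_best + 1L
      if (since_best >= config$patience) break
    }
  }

  nn_set_state(enc$layers, best_state)
  nn_set_buffers(enc$layers, best_bufs)
  nn_set_state(head$layers, best_head)
  ckpt <- make_checkpoint(enc, heads = list(disease = head), epoch = best_epoch,
                          val_loss = best_val,
                          config = unclass(config)[c("init", "label", "clip_len",
                            "max_epochs", "patience", "lr", "batch_size", "ratio",
                            "encoder", "width", "seed")])
  structure(list(checkpoint = ckpt, encoder = enc, head = head, log = log,
                 train_ids = train_ids, lr = config$lr),
            class = "finetune_result")
}

#' Video- and study-level inference
#'
#' Scores each video on its deterministic evaluation clip (first `clip_len`
#' frames, no augmentation) and aggregates scores per study by averaging.
#'
#' @param encoder,head Trained encoder and disease head (or pass a
#'   `finetune_result`'s components).
#' @param videos Named list of `echo_video`.
#' @param video_ids Video ids to score.
#' @param clip_len Clip length (default 16).
#' @param transform Optional function applied to the input tensor (e.g.
#'   channel standardization).
#' @return Named numeric vector of pre-sigmoid logits, one per video.
#' @export
predict_video_logits <- function(encoder, head, videos, video_ids,
                                 clip_len = 16L, transform = identity) {
  video_ids <- intersect(video_ids, names(videos))
  out <- numeric(0)
  batch <- 32L
  for (s in seq(1L, length(video_ids), by = batch)) {
    take <- video_ids[s:min(s + batch - 1L, length(video_ids))]
    clips <- lapply(take, function(v) eval_clip(videos[[v]], clip_len))
    x <- transform(clips_to_tensor(clips, ch = encoder$in_ch))
    h <- nn_seq_forward(encoder$layers, x, train = FALSE)
    logits <- nn_seq_forward(head$layers, h, train = FALSE)
    res <- as.numeric(logits)
    names(res) <- take
    out <- c(out, res)
  }
  out
}

#' @rdname predict_video_logits
#' @param manifest A `cohort_manifest`.
#' @param study_ids Studies to score.
#' @param label Manifest label column to attach.
#' @return `predict_study_scores()`: data frame (study_id, score, n_videos,
#'   label) with sigmoid scores pooled per study.
#' @export
predict_study_scores <- function(encoder, head, manifest, videos, study_ids,
                                 clip_len = 16L, label = "lvh_label",
                                 transform = identity) {
  vids_by_study <- manifest_video_ids(manifest)
  vids <- unlist(vids_by_study[study_ids], use.names = FALSE)
  v2s <- rep(names(vids_by_study), lengths(vids_by_study))
  names(v2s) <- unlist(vids_by_study, use.names = FALSE)
  logits <- predict_video_logits(encoder, head, videos, vids,
                                 clip_len = clip_len, transform = transform)
  scores <- 1 / (1 + exp(-logits))
  sid <- as.character(v2s[names(scores)])
  lab <- manifest[[label]]
  names(lab) <- manifest$study_id
  aggregate_study_predictions(scores, sid, labels = lab)
}

#' Validation metrics for pretraining quality
#'
#' `reorder_accuracy()` shuffles one clip per video and reports the top-1
#' accuracy of the reorder head (chance is 1/K!).
#' `retrieval_top1()` embeds both clips of every positive pair and reports
#' how often a clip's nearest neighbour (cosine, excluding itself) is its
#' partner (chance is 1/(2N-1)).
#'
#' @param pre A `pretrain_result`.
#' @param videos Named list of `echo_video`.
#' @param manifest Manifest of the evaluation studies.
#' @param seed Integer seed for clip sampling.
#' @return Accuracy in \[0, 1\].
#' @export
reorder_accuracy <- function(pre, videos, manifest, seed = 1L) {
  if (is.null(pre$reorder_head)) stop("pretraining run has no reorder head")
  set.seed(seed)
  vid_ids <- intersect(unlist(manifest_video_ids(manifest), use.names = FALSE),
                       names(videos))
  k <- pre$reorder_head$k
  correct <- 0L
  for (s in seq(1L, length(vid_ids), by = 32L)) {
    take <- vid_ids[s:min(s + 31L, length(vid_ids))]
    sh <- lapply(take, function(v) shuffle_clip(sample_clip(videos[[v]], k = k)))
    x <- clips_to_tensor(lapply(sh, `[[`, "clip"), ch = pre$encoder$in_ch)
    h <- nn_seq_forward(pre$encoder$layers, x, train = FALSE)
    logits <- nn_seq_forward(pre$reorder_head$layers, h, train = FALSE)
    pred <- max.col(logits) - 1L
    truth <- vapply(sh, function(z) z$label$class_index, integer(1))
    correct <- correct + sum(pred == truth)
  }
  correct / length(vid_ids)
}

#' @rdname reorder_accuracy
#' @export
retrieval_top1 <- function(pre, videos, manifest, seed = 1L) {
  set.seed(seed)
  pairs <- enumerate_positive_pairs(manifest)
  if (nrow(pairs) == 0L) stop("no positive pairs available")
  k <- pre$checkpoint$config$k %||% 4L
  ids <- as.character(rbind(pairs$video_id_a, pairs$video_id_b))
  zs <- list()
  for (s in seq(1L, length(ids), by = 32L)) {
    take <- ids[s:min(s + 31L, length(ids))]
    clips <- lapply(take, function(v) sample_clip(videos[[v]], k = k))
    x <- clips_to_tensor(clips, ch = pre$encoder$in_ch)
    h <- nn_seq_forward(pre$encoder$layers, x, train = FALSE)
    zs[[length(zs) + 1L]] <- nn_seq_forward(pre$projector$layers, h, train = FALSE)
  }
  z <- do.call(rbind, zs)
  s <- cosine_similarity_matrix(z)
  diag(s) <- -Inf
  nn <- max.col(s)
  partner <- as.integer(seq_len(nrow(z)) + c(1L, -1L))
  mean(nn == partner)
}
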