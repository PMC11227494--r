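test_that("epoch-budget matching equalizes examples seen", {
  expect_equal(match_epoch_budget(15, 15, 300), 300L)
  expect_equal(match_epoch_budget(26, 15, 300), 520L)
  for (p in c(5, 12, 40)) for (it in c(7, 15)) {
    e <- match_epoch_budget(p, it, 100)
    expect_lte(abs(e * it - 100 * p), it / 2 + 1e-9)
  }
  expect_error(match_epoch_budget(0, 10, 300))
})

test_that("learning-rate selection is argmin with larger-rate tie break", {
  expect_equal(select_learning_rate(c(0.1, 0.05, 0.001), c(0.68, 0.61, 0.70)),
               0.05)
  expect_equal(select_learning_rate(0.1, 0.5), 0.1)
  expect_message(sel <- select_learning_rate(c(0.1, 0.001), c(0.6, 0.6)), "larger")
  expect_equal(sel, 0.1)
  expect_error(select_learning_rate(numeric(0), numeric(0)), "empty")
})

test_that("learning-rate grids follow the titration-dependent scheme", {
  expect_equal(lr_grid("ssl", 0.05), c(0.1, 0.05, 0.001))
  expect_equal(lr_grid("ssl", 0.10), c(0.1, 0.05, 0.001))
  expect_equal(lr_grid("ssl", 0.25), 0.1)
  expect_equal(lr_grid("random", 0.01), c(1e-4, 5e-5, 1e-5))
  expect_equal(lr_grid("kinetics", 0.5), 1e-4)
})

make_smoke_cohort <- function(seed = 31) {
  tiny_cohort(n_studies = 8, frames = 12, effect = 1, seed = seed)
}

smoke_pretrain <- function(mode, epochs = 2, seed = 13) {
  co <- make_smoke_cohort()
  pc <- pretrain_config(mode = mode, encoder = "tiny", width = 4, lr = 3e-3,
                        batch_size = 8, epochs = epochs,
                        augment = augmentation_config(max_pad = 2), seed = seed)
  list(res = pretrain(co$manifest, co$videos, pc), cohort = co)
}

test_that("pretraining smoke runs log per-epoch losses for every mode", {
  for (mode in c("EchoCLR", "MI-SimCLR", "SimCLR")) {
    out <- smoke_pretrain(mode)
    log <- out$res$log
    expect_equal(nrow(log), 2L)
    expect_true(all(is.finite(log$nt_xent)))
    if (mode == "EchoCLR") {
      expect_true(all(is.finite(log$reorder)))
      expect_equal(log$total, log$nt_xent + log$reorder)
    } else {
      expect_true(all(is.na(log$reorder)))
      expect_equal(log$total, log$nt_xent)
    }
  }
})

test_that("pretraining is deterministic given the seed", {
  l1 <- smoke_pretrain("EchoCLR", seed = 17)$res$log
  l2 <- smoke_pretrain("EchoCLR", seed = 17)$res$log
  expect_identical(l1, l2)
  l3 <- smoke_pretrain("EchoCLR", seed = 18)$res$log
  expect_false(identical(l1$total, l3$total))
})

test_that("multi-instance pretraining refuses unpairable manifests", {
  co <- make_smoke_cohort()
  m <- co$manifest
  m$video_ids <- vapply(strsplit(m$video_ids, ";"), `[`, character(1), 1)
  pc <- pretrain_config(mode = "EchoCLR", encoder = "tiny", batch_size = 8,
                        epochs = 1, seed = 1)
  expect_error(pretrain(m, co$videos, pc), "pairable")
})

test_that("fine-tuning early-stops on patience and restores the best epoch", {
  co <- tiny_cohort(n_studies = 20, frames = 12, effect = 1, seed = 23)
  sp <- split_studies(co$manifest$study_id, fractions = c(0.5, 0.25, 0.25),
                      seed = 23)
  fc <- finetune_config(init = "random", label = "diseased", clip_len = 4L,
                        max_epochs = 6L, patience = 2L, batch_size = 8L,
                        ratio = 1.0, encoder = "tiny", width = 4, lr = 3e-3,
                        augment = augmentation_config(max_pad = 2), seed = 3)
  ft <- finetune(co$manifest, co$videos, sp, fc)
  log <- ft$log
  best <- which.min(log$val_loss)
  expect_equal(ft$checkpoint$epoch, best)
  expect_equal(ft$checkpoint$val_loss, min(log$val_loss))
  # completed epochs never exceed best + patience (or the cap)
  expect_lte(nrow(log), min(6L, best + 2L))
  # restored weights reproduce the best validation loss
  lab <- stats::setNames(co$manifest$diseased, co$manifest$study_id)
  val_ids <- sp$study_id[sp$split == "val"]
  preds <- predict_study_scores(ft$encoder, ft$head, co$manifest, co$videos,
                                val_ids, clip_len = 4L, label = "diseased")
  expect_true(all(preds$score >= 0 & preds$score <= 1))
})

test_that("fine-tuning validates its inputs", {
  co <- tiny_cohort(n_studies = 12, frames = 12, seed = 29, prevalence = 0)
  sp <- split_studies(co$manifest$study_id, seed = 29)
  fc <- finetune_config(init = "random", label = "diseased", clip_len = 4L,
                        encoder = "tiny", width = 4, ratio = 1.0, seed = 1)
  expect_error(finetune(co$manifest, co$videos, sp, fc), "single class")
  expect_error(finetune_config(init = "ssl"), "checkpoint")
  expect_error(finetune_config(init = "kinetics"), "kinetics_path")
  expect_error(finetune_config(patience = 30, max_epochs = 30))
})

test_that("kinetics-style initialization standardizes channels and loads weights", {
  co <- tiny_cohort(n_studies = 16, frames = 12, effect = 1, seed = 37)
  sp <- split_studies(co$manifest$study_id, fractions = c(0.5, 0.25, 0.25),
                      seed = 37)
  # externally supplied weights: a checkpoint file standing in for the
  # action-recognition pretrained encoder
  donor <- encoder_tiny(width = 4, seed = 5)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(make_checkpoint(donor, config = list(src = "external")), path)
  fc <- finetune_config(init = "kinetics", kinetics_path = path,
                        kinetics_stats = list(mean = c(0.43, 0.39, 0.38),
                                              sd = c(0.22, 0.22, 0.22)),
                        label = "diseased", clip_len = 4L, max_epochs = 2L,
                        patience = 1L, batch_size = 8L, ratio = 1.0,
                        encoder = "tiny", width = 4, lr = 1e-3,
                        augment = augmentation_config(max_pad = 1), seed = 7)
  ft <- finetune(co$manifest, co$videos, sp, fc)
  expect_s3_class(ft$checkpoint, "echo_checkpoint")
  expect_equal(nrow(ft$log) >= 1, TRUE)
})
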