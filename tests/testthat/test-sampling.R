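test_that("study splitting follows the 75/10/15 floor rule and partitions", {
  ids <- sprintf("s%04d", 1:1000)
  sp <- split_studies(ids, seed = 2)
  expect_equal(as.integer(table(sp$split)[c("train", "val", "test")]),
               c(750L, 100L, 150L))
  expect_setequal(sp$study_id, ids)
  sp2 <- split_studies(ids, seed = 2)
  expect_identical(sp, sp2)
  sp3 <- split_studies(ids, seed = 3)
  expect_false(identical(sp$split[order(sp$study_id)],
                         sp3$split[order(sp3$study_id)]))
  expect_error(split_studies(c("a", "a", "b")), "duplicate")
})

test_that("titration reproduces all twelve printed study counts", {
  for (case in list(list(n = 5194, want = c(51, 259, 519, 1298, 2597, 5194)),
                    list(n = 5311, want = c(53, 265, 531, 1327, 2655, 5311)))) {
    ids <- sprintf("s%d", seq_len(case$n))
    got <- vapply(c(0.01, 0.05, 0.10, 0.25, 0.50, 1.0),
                  function(r) length(titrate(ids, r, seed = 1)), numeric(1))
    expect_equal(got, case$want)
  }
  ids <- letters[1:10]
  expect_identical(titrate(ids, 1.0), ids)
  expect_error(titrate(ids, 0.01), "zero")
})

test_that("positive-pair enumeration matches the closed form on random manifests", {
  co <- tiny_cohort(n_studies = 3, seed = 2)
  m <- co$manifest
  m$video_ids[1] <- "a;b;c"
  m$video_ids[2] <- "d"
  m$video_ids[3] <- "e;f"
  pairs <- enumerate_positive_pairs(m)
  expect_equal(nrow(pairs), 3L + 0L + 1L)
  expect_setequal(paste(pairs$video_id_a, pairs$video_id_b),
                  c("a b", "a c", "b c", "e f"))

  set.seed(42)
  for (rep in 1:50) {
    sizes <- sample(1:5, sample(2:8, 1), replace = TRUE)
    man <- data.frame(
      study_id = sprintf("s%d", seq_along(sizes)),
      video_ids = vapply(seq_along(sizes), function(i)
        paste(sprintf("s%d_v%d", i, seq_len(sizes[i])), collapse = ";"),
        character(1)),
      stringsAsFactors = FALSE)
    got <- nrow(enumerate_positive_pairs(man))
    expect_equal(got, sum(choose(sizes, 2)))
  }
})

test_that("clip sampling covers whole-video, loop-pad and uniform-start cases", {
  v <- structure(list(study_id = "s", video_id = "v",
                      frames = array(rep(seq(0, 255, length.out = 4), each = 4),
                                     c(2, 2, 4)),
                      fps = 30, view = "PLAX"), class = "echo_video")
  cl <- sample_clip(v, k = 4, seed = 1)
  expect_equal(cl$start, 0L)
  expect_equal(cl$frames, v$frames / 255)
  expect_true(all(cl$frames >= 0 & cl$frames <= 1))

  v3 <- v; v3$frames <- v$frames[, , 1:3, drop = FALSE]
  cl3 <- sample_clip(v3, k = 4, seed = 1)
  expect_equal(cl3$frames[, , 4], v3$frames[, , 1] / 255)

  vv <- v; vv$frames <- array(runif(2 * 2 * 20, 0, 255), c(2, 2, 20))
  starts <- vapply(1:5000, function(s) sample_clip(vv, k = 16, seed = s)$start,
                   integer(1))
  expect_setequal(sort(unique(starts)), 0:4)
  expect_gt(stats::chisq.test(table(factor(starts, levels = 0:4)))$p.value, 0.01)
})

test_that("permutation ranking is the lexicographic Lehmer rank", {
  expect_identical(permutation_rank(c(0L, 1L, 2L, 3L)), 0L)
  expect_identical(permutation_rank(c(3L, 2L, 1L, 0L)), 23L)
  # exhaustive round trip at K = 4, and agreement with brute-force sort order
  all_perms <- lapply(0:23, permutation_unrank, k = 4)
  expect_identical(vapply(all_perms, permutation_rank, integer(1)), 0:23)
  lex <- order(vapply(all_perms, function(p) paste(p, collapse = ""), character(1)))
  expect_identical(lex, 1:24)
  expect_error(permutation_rank(c(0L, 0L, 1L)), "permutation")
  expect_error(permutation_unrank(24, 4), "class_index")
})

test_that("clip shuffling is invertible and uniform over orderings", {
  co <- tiny_cohort(n_studies = 2, seed = 5)
  cl <- sample_clip(co$videos[[1]], k = 4, seed = 3)
  sh <- shuffle_clip(cl, seed = 9)
  inv <- order(sh$label$order)  # positions of original frames
  expect_identical(sh$clip$frames[, , order(sh$label$order + 0L)], cl$frames)
  expect_true(sh$label$class_index >= 0 && sh$label$class_index < 24)

  counts <- integer(24)
  for (s in 1:24000) {
    idx <- shuffle_clip(cl, seed = s)$label$class_index
    counts[idx + 1] <- counts[idx + 1] + 1L
  }
  sigma <- sqrt(24000 * (1 / 24) * (23 / 24))
  expect_true(all(abs(counts - 1000) <= 3 * sigma))
})

test_that("augmentation is identity-able, involutive and clip-consistent", {
  co <- tiny_cohort(n_studies = 2, seed = 5)
  cl <- sample_clip(co$videos[[1]], k = 4, seed = 3)
  idcfg <- augmentation_config(max_pad = 0, flip_prob = 0, rotation_prob = 0)
  expect_identical(augment_clip(cl, idcfg, seed = 1)$frames, cl$frames)

  flip <- augmentation_config(max_pad = 0, flip_prob = 1, rotation_prob = 0)
  once <- augment_clip(cl, flip, seed = 1)
  twice <- augment_clip(once, flip, seed = 2)
  expect_identical(twice$frames, cl$frames)

  # clip consistency: a marker pixel moves identically in every frame
  mk <- cl
  mk$frames[, , ] <- 0
  mk$frames[10, 20, ] <- 1
  aug <- augment_clip(mk, augmentation_config(max_pad = 3, flip_prob = 0.5,
                                              rotation_prob = 0.5), seed = 7)
  pos <- lapply(seq_len(dim(aug$frames)[3]), function(t)
    which(aug$frames[, , t] == max(aug$frames[, , t]), arr.ind = TRUE)[1, ])
  expect_true(all(vapply(pos, identical, logical(1), pos[[1]])))
  expect_equal(dim(aug$frames), dim(cl$frames))
  expect_true(all(aug$frames >= 0 & aug$frames <= 1))
})

test_that("sampling operations are pure functions of (input, seed)", {
  co <- tiny_cohort(n_studies = 4, seed = 6)
  v <- co$videos[[1]]
  expect_identical(sample_clip(v, 4, seed = 2), sample_clip(v, 4, seed = 2))
  cfg <- augmentation_config()
  cl <- sample_clip(v, 4, seed = 2)
  expect_identical(augment_clip(cl, cfg, seed = 3), augment_clip(cl, cfg, seed = 3))
  expect_identical(shuffle_clip(cl, seed = 4), shuffle_clip(cl, seed = 4))
  expect_identical(titrate(co$manifest$study_id, 0.5, seed = 5),
                   titrate(co$manifest$study_id, 0.5, seed = 5))
})
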