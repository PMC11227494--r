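test_that("video generation is bit-reproducible and respects geometry", {
  cfg <- fixture_config(n_studies = 2, frame_size = 48, frames_per_video = 10,
                        motion_period = 8, seed = 3)
  v1 <- generate_video(cfg, diseased = TRUE, seed = 11)
  v2 <- generate_video(cfg, diseased = TRUE, seed = 11)
  expect_identical(v1$frames, v2$frames)
  expect_equal(dim(v1$frames), c(48, 48, 10))
  expect_true(all(v1$frames >= 0 & v1$frames <= 255))
  # pixels outside the fan are exactly zero: corners never touched
  expect_identical(unname(v1$frames[1, 1, ]), rep(0, 10))
  expect_identical(unname(v1$frames[1, 48, ]), rep(0, 10))
})

test_that("invalid fixture configs are rejected", {
  expect_error(fixture_config(frames_per_video = 0), "positive")
  expect_error(fixture_config(frame_size = 16), "at least 32")
  expect_error(fixture_config(prevalence = 1.5))
})

test_that("zero effect size yields indistinguishable diseased/healthy videos", {
  cfg <- fixture_config(n_studies = 2, frame_size = 32, frames_per_video = 4,
                        effect_size = 0, seed = 3)
  m_dis <- m_hea <- numeric(100)
  for (s in seq_len(100)) {
    m_dis[s] <- mean(generate_video(cfg, diseased = TRUE, seed = s)$frames)
    m_hea[s] <- mean(generate_video(cfg, diseased = FALSE, seed = s)$frames)
  }
  # identical seeds, effect-free code path: distributions coincide exactly
  expect_identical(m_dis, m_hea)
})

test_that("cardiac motion has the configured period (cross-correlation oracle)", {
  P <- 6L
  cfg <- fixture_config(n_studies = 2, frame_size = 48, frames_per_video = P + 1L,
                        motion_period = P, speckle = 0.3, seed = 3)
  hits <- 0L
  for (s in seq_len(20)) {
    v <- generate_video(cfg, diseased = FALSE, seed = s)
    f0 <- as.numeric(v$frames[, , 1])
    cors <- vapply(seq_len(P), function(lag)
      stats::cor(f0, as.numeric(v$frames[, , 1 + lag])), numeric(1))
    hits <- hits + (which.max(cors) == P)
  }
  expect_gte(hits, 18L)
})

test_that("cohort generation conserves prevalence and pairability", {
  co <- tiny_cohort(n_studies = 10, prevalence = 0.5, seed = 21)
  expect_equal(nrow(co$manifest), 10L)
  expect_equal(sum(co$manifest$diseased), 5L)
  expect_true(all(lengths(manifest_video_ids(co$manifest)) >= 2L))
  # every video id appears in exactly one study
  all_vids <- unlist(manifest_video_ids(co$manifest))
  expect_false(anyDuplicated(all_vids) > 0)
  expect_setequal(all_vids, names(co$videos))
})

test_that("AVI round-trip through disk is lossless at 8 bit", {
  co <- tiny_cohort(n_studies = 3, seed = 9)
  dir <- withr::local_tempdir()
  cfg <- fixture_config(n_studies = 3, frame_size = 32, frames_per_video = 12,
                        motion_period = 8, videos_per_study = c(2, 2),
                        effect_size = 1, prevalence = 0.5, seed = 9)
  co <- generate_cohort(cfg, out_dir = dir)
  for (v in names(co$paths)) {
    back <- read_avi(co$paths[[v]])
    expect_identical(back$frames,
                     array(as.integer(co$videos[[v]]$frames),
                           dim(co$videos[[v]]$frames)))
    expect_equal(back$fps, cfg$fps)
  }
  m2 <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(m2$study_id, co$manifest$study_id)
  expect_equal(m2$lvh_label, co$manifest$lvh_label)
})

test_that("unwritable output directory raises an I/O error", {
  cfg <- fixture_config(n_studies = 2, seed = 1)
  expect_error(generate_cohort(cfg, out_dir = "/proc/nonexistent/subdir"))
})

test_that("LVH labels follow the sex-specific LVMI thresholds", {
  expect_identical(assign_lvh_label(96, "female"), 1L)
  expect_identical(assign_lvh_label(95, "female"), 0L)
  expect_identical(assign_lvh_label(116, "male"), 1L)
  expect_identical(assign_lvh_label(115, "male"), 0L)
  expect_identical(assign_lvh_label(100, "male"), 0L)
  expect_identical(assign_lvh_label(NA_real_, "female"), NA_integer_)
  expect_identical(assign_lvh_label(100, NA_character_), NA_integer_)
  expect_error(assign_lvh_label(-1, "male"), "non-negative")
  expect_error(assign_lvh_label(100, "other"))
})

test_that("AS grades binarize to severe vs everything else", {
  expect_identical(binarize_as_grade("severe"), 1L)
  for (g in c("none", "mild", "mild-to-moderate", "moderate", "moderate-to-severe"))
    expect_identical(binarize_as_grade(g), 0L)
  expect_error(binarize_as_grade(""))
  expect_error(binarize_as_grade("critical"))
})

test_that("planted signal is learnable by the wall-thickness oracle", {
  co <- tiny_cohort(n_studies = 200, effect = 1, seed = 31)
  expect_gt(oracle_cohort_auroc(co), 0.9)
  co0 <- tiny_cohort(n_studies = 200, effect = 0, seed = 31)
  a0 <- oracle_cohort_auroc(co0)
  expect_gte(a0, 0.4)
  expect_lte(a0, 0.6)
})

test_that("study anatomy is deterministic per study and varies across studies", {
  a1 <- study_anatomy("studyA", 5)
  a2 <- study_anatomy("studyA", 5)
  b <- study_anatomy("studyB", 5)
  expect_identical(a1, a2)
  expect_false(identical(a1, b))
  expect_true(a1$r0_mult >= 0.85 && a1$r0_mult <= 1.15)
})
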