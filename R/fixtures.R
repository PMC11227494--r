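#' Synthetic echocardiogram-like cohort fixtures
#'
#' Real echocardiograms from the cohort this method was developed on are not
#' shareable, so the package ships a generator that emulates the statistical
#' structure the method relies on: multi-video studies (so that distinct
#' videos of one study can form contrastive positive pairs), a sector-fan
#' ultrasound geometry with multiplicative speckle, periodic cardiac motion
#' across frames, and a planted structural disease signal -- a thickened
#' ventricular wall ring -- at a controllable effect size and prevalence.
#'
#' `fixture_config()` collects the generator parameters. Defaults describe the
#' standard study conditions: 112x112 frames (the model input resolution),
#' 32 frames per video at 30 fps, 2-3 videos per study, disease prevalence
#' 0.25, a 16-frame motion period (about one cardiac cycle at this frame
#' rate), and a wall-thickness increment of 0.75 (the diseased wall is 75%
#' thicker than the healthy wall).
#'
#' @param n_studies Number of studies in the cohort.
#' @param videos_per_study Integer range (min, max) of videos per study.
#' @param frames_per_video Frames per video T.
#' @param frame_size Frame height/width in pixels (square frames, >= 32).
#' @param prevalence Fraction of diseased studies in \[0, 1\].
#' @param effect_size Relative wall-thickness increment for diseased studies
#'   (0 = no signal; 1 = doubled thickness).
#' @param speckle Speckle noise level in \[0, 1\]; 0 disables speckle, 1 is the
#'   full multiplicative gamma speckle.
#' @param motion_period Cardiac-cycle period in frames.
#' @param fps Frames per second.
#' @param missing_label_rate Fraction of studies whose LVMI measurement is
#'   missing (their LVH label is NA; they remain usable for pretraining).
#' @param exclusion_rate Fraction of studies flagged `"llg_as"` (a generic
#'   manifest exclusion flag; see [filter_manifest()]).
#' @param seed Integer seed fixing all randomness of the generator.
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(n_studies = 100L, videos_per_study = c(2L, 3L),
                           frames_per_video = 32L, frame_size = 112L,
                           prevalence = 0.25, effect_size = 0.75,
                           speckle = 1, motion_period = 16L, fps = 30,
                           missing_label_rate = 0.05, exclusion_rate = 0,
                           seed = 1L) {
  stopifnot(prevalence >= 0, prevalence <= 1,
            length(videos_per_study) == 2L, videos_per_study[1L] >= 1L,
            videos_per_study[1L] <= videos_per_study[2L],
            speckle >= 0, speckle <= 1, effect_size >= 0)
  if (frames_per_video < 1L) stop("frames_per_video must be positive")
  if (frame_size < 32L) stop("frame_size must be at least 32")
  structure(list(n_studies = as.integer(n_studies),
                 videos_per_study = as.integer(videos_per_study),
                 frames_per_video = as.integer(frames_per_video),
                 frame_size = as.integer(frame_size),
                 prevalence = prevalence, effect_size = effect_size,
                 speckle = speckle, motion_period = as.integer(motion_period),
                 fps = fps, missing_label_rate = missing_label_rate,
                 exclusion_rate = exclusion_rate, seed = as.integer(seed)),
            class = "fixture_config")
}

#' @rdname fixture_config
#' @param study_id Study identifier for the generated video.
#' @param video_id Video identifier.
#' @param config A `fixture_config`.
#' @param diseased Logical; plant the thickened-wall signal.
#' @param seed Integer seed; the same (config, seed) yields bit-identical
#'   frames.
#' @details `generate_video()` renders one grayscale video: a bright sector
#'   fan over an exactly-zero background, a bright fan border (mimicking the
#'   sector outline burned into clinical scans), tissue-level speckle, and a
#'   ventricular-wall ring whose radius oscillates sinusoidally with
#'   `motion_period`. Diseased studies get a wall thicker by
#'   `effect_size * base thickness`. The signal is geometric, not textural, so
#'   masking and downsampling cannot destroy it.
#' @return `generate_video()` returns an `echo_video`: list with `frames`
#'   (H x W x T integer array, values 0-255), `study_id`, `video_id`, `fps`,
#'   `view`.
#' @export
generate_video <- function(config, study_id = "s1", video_id = "s1_v1",
                           diseased = FALSE, seed = NULL, anatomy = NULL) {
  if (!inherits(config, "fixture_config")) stop("config must be a fixture_config")
  if (config$frames_per_video < 1L) stop("frames_per_video must be positive")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(anatomy)) anatomy <- study_anatomy(study_id, config$seed)
  S <- config$frame_size
  TT <- config$frames_per_video
  P <- config$motion_period

  ## sector-fan geometry: apex at top-center, half-angle 45 degrees
  yy <- matrix(seq_len(S), S, S)             # row = vertical position
  xx <- matrix(seq_len(S), S, S, byrow = TRUE)
  apex_y <- 2
  cx <- (S + 1) / 2
  dy <- yy - apex_y
  dx <- xx - cx
  rr <- sqrt(dx^2 + dy^2)
  ang <- atan2(dx, dy)                       # 0 = straight down
  half_angle <- pi / 4
  rmax <- 0.92 * S
  fan <- (abs(ang) <= half_angle) & (rr <= rmax) & (dy >= 0)
  border_w <- max(1, round(0.015 * S))
  edge <- fan & (
    (abs(ang) >= half_angle - border_w / pmax(rr, 1)) |
    (rr >= rmax - border_w)
  )

  ## ventricular wall ring: study-specific anatomy (cavity size, wall
  ## thickness, position) so that study identity is a real, continuous
  ## signal; the radius oscillates with period P from a video-specific
  ## cardiac phase (acquisition starts at an arbitrary point of the cycle)
  wall_base <- 0.055 * S * anatomy$wall_mult
  wall_t <- wall_base * (1 + if (diseased) config$effect_size else 0)
  r0 <- 0.28 * S * anatomy$r0_mult
  ring_cy <- apex_y + (0.5 + anatomy$cy_off) * S
  ring_cx <- cx + anatomy$cx_off * S
  rring <- sqrt((yy - ring_cy)^2 + (xx - ring_cx)^2)
  phase <- stats::runif(1, 0, 2 * pi)

  frames <- array(0, dim = c(S, S, TT))
  for (t in seq_len(TT)) {
    # 0.25 fractional radius excursion ~ typical LV fractional shortening
    r_t <- r0 * (1 + 0.25 * sin(2 * pi * (t - 1) / P + phase))
    img <- matrix(0, S, S)
    img[fan] <- 60
    in_ring <- fan & (abs(rring - r_t) <= wall_t / 2)
    img[in_ring] <- 170
    if (config$speckle > 0) {
      sp <- matrix(stats::rgamma(S * S, shape = 4, rate = 4), S, S)
      sp <- 1 + config$speckle * (sp - 1)
      img <- img * sp
    }
    img[edge] <- 250
    img[!fan] <- 0
    frames[, , t] <- pmin(pmax(round(img), 0), 255)
  }
  structure(list(study_id = study_id, video_id = video_id,
                 frames = frames, fps = config$fps, view = "PLAX"),
            class = "echo_video")
}

#' Study-level anatomical parameters
#'
#' Derives the study-specific anatomy (cavity radius multiplier, wall
#' thickness multiplier, ring center offsets) deterministically from the
#' study id and cohort seed, so every video of a study shares one heart
#' while hearts vary continuously across studies.
#'
#' @param study_id Study identifier.
#' @param seed Cohort seed.
#' @return List: `r0_mult`, `wall_mult` (both in \[0.85, 1.15\]), `cx_off`,
#'   `cy_off` (fractions of the frame size in \[-0.03, 0.03\]).
#' @export
study_anatomy <- function(study_id, seed = 1L) {
  h <- as.double(seed %% 1e6)
  for (b in as.integer(charToRaw(study_id))) h <- (h * 131 + b) %% 2147483647
  u <- function() {
    h <<- (h * 48271) %% 2147483647  # Lehmer stream keyed by (study_id, seed)
    h / 2147483647
  }
  list(r0_mult = 0.85 + 0.3 * u(), wall_mult = 0.85 + 0.3 * u(),
       cx_off = 0.06 * (u() - 0.5), cy_off = 0.06 * (u() - 0.5))
}

#' Sex-specific LVH labeling from the left ventricular mass index
#'
#' A study is labeled positive for left ventricular hypertrophy when LVMI
#' strictly exceeds 95 g/m2 in women or 115 g/m2 in men.
#'
#' @param lvmi Left ventricular mass index in g/m2 (>= 0), or NA.
#' @param sex `"female"` or `"male"`, or NA.
#' @return 1L or 0L, or NA_integer_ when `lvmi` or `sex` is missing (the
#'   study is dropped from the LVH task but kept for pretraining).
#' @export
assign_lvh_label <- function(lvmi, sex) {
  if (length(lvmi) != 1L || length(sex) != 1L) stop("assign_lvh_label is scalar")
  if (is.na(lvmi) || is.na(sex)) return(NA_integer_)
  if (!sex %in% c("female", "male")) stop("sex must be 'female' or 'male'")
  if (lvmi < 0) stop("lvmi must be non-negative")
  thr <- if (sex == "female") 95 else 115
  as.integer(lvmi > thr)
}

#' Binarize an aortic-stenosis severity grade
#'
#' All AS designations other than "severe" are binned into the not-severe
#' category.
#'
#' @param as_grade One of `"none"`, `"mild"`, `"mild-to-moderate"`,
#'   `"moderate"`, `"moderate-to-severe"`, `"severe"`.
#' @return 1L iff the grade is `"severe"`, else 0L.
#' @export
binarize_as_grade <- function(as_grade) {
  known <- c("none", "mild", "mild-to-moderate", "moderate",
             "moderate-to-severe", "severe")
  if (length(as_grade) != 1L || is.na(as_grade) || !as_grade %in% known)
    stop("unknown AS grade: ", deparse(as_grade))
  as.integer(as_grade == "severe")
}

#' @rdname fixture_config
#' @param out_dir Directory for AVI files; created if missing. `NULL` keeps
#'   videos in memory only.
#' @details `generate_cohort()` generates a full cohort: exactly
#'   `round(prevalence * n_studies)` diseased studies, each study with a
#'   number of videos drawn from `videos_per_study`. LVMI values are sampled
#'   on the correct side of the sex-specific threshold so that the LVH label
#'   equals the planted disease state; the AS grade is `"severe"` for
#'   diseased studies and a non-severe grade otherwise.
#' @return `generate_cohort()` returns a list with `manifest` (a
#'   `cohort_manifest` data frame: study_id, video_ids
#'   (semicolon-separated), lvmi, sex, as_grade, lvh_label, severe_as_label,
#'   diseased, exclusion_flags), `videos` (named list of `echo_video`, by
#'   video_id), and `paths` (named AVI paths when `out_dir` is given).
#' @export
generate_cohort <- function(config, out_dir = NULL) {
  if (!inherits(config, "fixture_config")) stop("config must be a fixture_config")
  set.seed(config$seed)
  n <- config$n_studies
  n_pos <- round(config$prevalence * n)
  diseased <- c(rep(TRUE, n_pos), rep(FALSE, n - n_pos))[sample.int(n)]

  study_ids <- sprintf("study%04d", seq_len(n))
  sex <- sample(c("female", "male"), n, replace = TRUE)
  thr <- ifelse(sex == "female", 95, 115)
  lvmi <- ifelse(diseased,
                 thr + stats::runif(n, 5, 60),
                 thr - stats::runif(n, 5, 45))
  lvmi[stats::runif(n) < config$missing_label_rate] <- NA_real_
  not_severe <- c("none", "mild", "mild-to-moderate", "moderate", "moderate-to-severe")
  as_grade <- ifelse(diseased, "severe", sample(not_severe, n, replace = TRUE))
  flags <- ifelse(stats::runif(n) < config$exclusion_rate, "llg_as", "")

  vrange <- seq(config$videos_per_study[1L], config$videos_per_study[2L])
  n_vids <- if (length(vrange) == 1L) rep(vrange, n) else sample(vrange, n, replace = TRUE)
  videos <- list()
  paths <- character(0)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  video_ids_col <- character(n)
  for (i in seq_len(n)) {
    vids <- sprintf("%s_v%d", study_ids[i], seq_len(n_vids[i]))
    video_ids_col[i] <- paste(vids, collapse = ";")
    for (v in vids) {
      vid <- generate_video(config, study_id = study_ids[i], video_id = v,
                            diseased = diseased[i])
      videos[[v]] <- vid
      if (!is.null(out_dir)) {
        p <- file.path(out_dir, paste0(v, ".avi"))
        write_avi(vid$frames, p, fps = config$fps)
        paths[v] <- p
      }
    }
  }

  lvh <- mapply(function(m, s) assign_lvh_label(m, s), lvmi, sex)
  sev <- vapply(as_grade, binarize_as_grade, integer(1), USE.NAMES = FALSE)
  manifest <- data.frame(study_id = study_ids, video_ids = video_ids_col,
                         lvmi = lvmi, sex = sex, as_grade = as_grade,
                         lvh_label = as.integer(lvh), severe_as_label = sev,
                         diseased = as.integer(diseased),
                         exclusion_flags = flags, stringsAsFactors = FALSE)
  class(manifest) <- c("cohort_manifest", "data.frame")
  if (!is.null(out_dir)) {
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
    jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(manifest = manifest, videos = videos,
       paths = if (is.null(out_dir)) NULL else paths)
}

#' Read a cohort manifest written by [generate_cohort()]
#' @param path Path to `manifest.csv`.
#' @return A `cohort_manifest` data frame.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(study_id = "character",
                                      video_ids = "character",
                                      exclusion_flags = "character"))
  m$exclusion_flags[is.na(m$exclusion_flags)] <- ""
  class(m) <- c("cohort_manifest", "data.frame")
  m
}

#' Split a manifest's semicolon-packed video id column into a named list
#' @param manifest A `cohort_manifest`.
#' @return Named list (by study_id) of character vectors of video ids.
#' @export
manifest_video_ids <- function(manifest) {
  out <- strsplit(manifest$video_ids, ";", fixed = TRUE)
  names(out) <- manifest$study_id
  out
}
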