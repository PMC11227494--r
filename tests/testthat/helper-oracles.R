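# Shared fixtures and independent brute-force oracles for the test suite.

# Small cohort builder used across test files.
tiny_cohort <- function(n_studies = 12, frame_size = 32, frames = 12,
                        effect = 1, prevalence = 0.5, seed = 7, ...) {
  cfg <- fixture_config(n_studies = n_studies, frame_size = frame_size,
                        frames_per_video = frames, motion_period = 8,
                        videos_per_study = c(2, 2), prevalence = prevalence,
                        effect_size = effect, seed = seed, ...)
  generate_cohort(cfg)
}

# Brute-force wall-thickness score: fraction of in-fan pixels in the
# wall-intensity band, averaged over the first two frames. Serves as the
# planted-signal oracle classifier (threshold on this score).
oracle_wall_score <- function(video, lo = 120, hi = 230) {
  f <- video$frames[, , 1:2, drop = FALSE]
  fan <- f > 0
  if (sum(fan) == 0) return(0)
  sum(f >= lo & f <= hi) / sum(fan)
}

oracle_cohort_auroc <- function(cohort, videos = NULL) {
  videos <- videos %||% cohort$videos
  m <- cohort$manifest
  vids <- manifest_video_ids(m)
  scores <- vapply(m$study_id, function(sid) {
    mean(vapply(vids[[sid]], function(v) oracle_wall_score(videos[[v]]), numeric(1)))
  }, numeric(1))
  auroc(m$diseased, scores)
}

# O(n^2) pair-counting AUROC oracle (ties count one half).
oracle_auroc_pairs <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Brute-force point-in-convex-polygon test by triangle decomposition signs,
# independent of the implementation's half-plane intersection.
oracle_point_in_hull <- function(px, py, hull) {
  k <- nrow(hull)
  sgn <- function(ax, ay, bx, by, cx, cy) (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  vapply(seq_along(px), function(i) {
    s <- numeric(k)
    for (e in seq_len(k)) {
      j <- if (e == k) 1 else e + 1
      s[e] <- sgn(hull[e, 1], hull[e, 2], hull[j, 1], hull[j, 2], px[i], py[i])
    }
    all(s >= -1e-9) || all(s <= 1e-9)
  }, logical(1))
}

# Direct naive 3D convolution (valid padding handled explicitly).
oracle_conv3d <- function(x, w, stride, pad) {
  d <- dim(x)  # H W T N C
  kd <- dim(w) # kh kw kt Cin Cout
  oh <- (d[1] + 2 * pad[1] - kd[1]) %/% stride[1] + 1
  ow <- (d[2] + 2 * pad[2] - kd[2]) %/% stride[2] + 1
  ot <- (d[3] + 2 * pad[3] - kd[3]) %/% stride[3] + 1
  xp <- array(0, dim = c(d[1] + 2 * pad[1], d[2] + 2 * pad[2], d[3] + 2 * pad[3], d[4], d[5]))
  xp[pad[1] + seq_len(d[1]), pad[2] + seq_len(d[2]), pad[3] + seq_len(d[3]), , ] <- x
  y <- array(0, dim = c(oh, ow, ot, d[4], kd[5]))
  for (n in seq_len(d[4])) for (co in seq_len(kd[5]))
    for (i in seq_len(oh)) for (j in seq_len(ow)) for (t in seq_len(ot)) {
      acc <- 0
      for (ci in seq_len(d[5])) for (a in seq_len(kd[1])) for (b in seq_len(kd[2])) for (cc in seq_len(kd[3]))
        acc <- acc + xp[(i - 1) * stride[1] + a, (j - 1) * stride[2] + b,
                        (t - 1) * stride[3] + cc, n, ci] * w[a, b, cc, ci, co]
      y[i, j, t, n, co] <- acc
    }
  y
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A deterministic frame classifier factory for classify_view tests.
const_classifier <- function(probs) {
  force(probs)
  function(frame) probs
}
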