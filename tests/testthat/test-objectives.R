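test_that("cosine similarity matrix matches its definition", {
  z <- diag(4)
  expect_equal(cosine_similarity_matrix(z), diag(4))
  z2 <- rbind(c(1, 2), c(1, 2), c(3, -1))
  s <- cosine_similarity_matrix(z2)
  expect_equal(s[1, 2], 1)
  expect_equal(diag(s), rep(1, 3))
  expect_equal(s, t(s))

  set.seed(8)
  zr <- matrix(rnorm(6 * 128), 6, 128)
  sr <- cosine_similarity_matrix(zr)
  for (i in 1:6) for (k in 1:6) {
    manual <- sum(zr[i, ] * zr[k, ]) /
      (sqrt(sum(zr[i, ]^2)) * sqrt(sum(zr[k, ]^2)))
    expect_equal(sr[i, k], manual, tolerance = 1e-6)
  }
  expect_error(cosine_similarity_matrix(rbind(c(0, 0), c(1, 1))), "zero-norm")
})

test_that("NT-Xent reproduces its closed-form values", {
  # all 2N embeddings identical, N = 2: loss collapses to ln(2N-1) = ln 3
  z <- matrix(rep(c(0.3, -1, 2), each = 4), nrow = 4)
  expect_equal(as.numeric(nt_xent_loss(embedding_batch(z, tau = 0.5))),
               log(3), tolerance = 1e-5)
  # identical positives, orthogonal negatives, N = 2, tau = 0.5
  z2 <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  expect_equal(as.numeric(nt_xent_loss(embedding_batch(z2, tau = 0.5))),
               -log(exp(2) / (exp(2) + 2)), tolerance = 1e-6)
  expect_error(nt_xent_loss(embedding_batch(z2[1:2, , drop = FALSE])), "2 positive pairs")
})

test_that("NT-Xent is pair-order invariant, scale invariant and non-negative", {
  set.seed(5)
  z <- matrix(rnorm(8 * 16), 8, 16)
  l0 <- as.numeric(nt_xent_loss(embedding_batch(z)))
  perm <- c(5, 6, 1, 2, 7, 8, 3, 4)  # permute whole pairs
  expect_equal(as.numeric(nt_xent_loss(embedding_batch(z[perm, ]))), l0,
               tolerance = 1e-12)
  expect_equal(as.numeric(nt_xent_loss(embedding_batch(3.7 * z))), l0,
               tolerance = 1e-12)
  expect_gte(l0, 0)
})

test_that("NT-Xent decreases as positive similarity rises, fixed negatives", {
  mk <- function(a) {
    u <- c(cos(a), sin(a))
    rbind(c(1, 0), u, c(0, 1), c(0, 1))
  }
  losses <- vapply(seq(pi / 2, 0, length.out = 8), function(a)
    as.numeric(nt_xent_loss(embedding_batch(mk(a)))), numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("NT-Xent approaches ln(2N-1) for random embeddings at large tau", {
  set.seed(11)
  z <- matrix(rnorm(16 * 32), 16, 32)
  z <- z / sqrt(rowSums(z^2))
  expect_equal(as.numeric(nt_xent_loss(embedding_batch(z, tau = 1e6))),
               log(15), tolerance = 0.05)
})

test_that("NT-Xent analytic gradient matches finite differences", {
  set.seed(13)
  z <- matrix(rnorm(6 * 10), 6, 10)
  l <- nt_xent_loss(embedding_batch(z, tau = 0.7), grad = TRUE)
  g <- attr(l, "grad")
  eps <- 1e-6
  for (i in sample(length(z), 8)) {
    z0 <- z[i]
    z[i] <- z0 + eps
    lp <- as.numeric(nt_xent_loss(embedding_batch(z, tau = 0.7)))
    z[i] <- z0 - eps
    lm <- as.numeric(nt_xent_loss(embedding_batch(z, tau = 0.7)))
    z[i] <- z0
    expect_equal(g[i], (lp - lm) / (2 * eps), tolerance = 1e-5)
  }
})

test_that("reorder cross-entropy matches closed forms and a softmax oracle", {
  expect_equal(reorder_cross_entropy(matrix(0, 5, 24), c(0, 3, 7, 11, 23)),
               log(24), tolerance = 1e-6)
  sat <- matrix(0, 2, 24)
  sat[1, 3] <- 1000; sat[2, 18] <- 1000
  expect_lt(reorder_cross_entropy(sat, c(2, 17)), 1e-6)

  set.seed(19)
  lg <- matrix(rnorm(8 * 24), 8, 24)
  tg <- sample(0:23, 8, replace = TRUE)
  manual <- mean(vapply(1:8, function(i) {
    p <- exp(lg[i, ]) / sum(exp(lg[i, ]))
    -log(p[tg[i] + 1])
  }, numeric(1)))
  expect_equal(reorder_cross_entropy(lg, tg), manual, tolerance = 1e-6)
  expect_error(reorder_cross_entropy(lg, rep(24, 8)), "range")
})

test_that("the combined loss is the unweighted sum with an exact ablation", {
  set.seed(23)
  z <- matrix(rnorm(8 * 16), 8, 16)
  lg <- matrix(rnorm(8 * 24), 8, 24)
  tg <- sample(0:23, 8, replace = TRUE)
  b <- embedding_batch(z)
  full <- echoclr_loss(b, lg, tg)
  expect_equal(full$total, full$nt_xent + full$reorder)
  expect_equal(full$nt_xent, as.numeric(nt_xent_loss(b)))
  abl <- echoclr_loss(b)
  expect_equal(abl$total, as.numeric(nt_xent_loss(b)))
  expect_true(is.na(abl$reorder))
})

test_that("gradient of the summed loss equals the sum of component gradients", {
  set.seed(29)
  z <- matrix(rnorm(6 * 8), 6, 8)
  lg <- matrix(rnorm(6 * 24), 6, 24)
  tg <- sample(0:23, 6, replace = TRUE)
  gz <- attr(nt_xent_loss(embedding_batch(z), grad = TRUE), "grad")
  gl <- attr(reorder_cross_entropy(lg, tg, grad = TRUE), "grad")
  eps <- 1e-6
  total <- function() {
    echoclr_loss(embedding_batch(z), lg, tg)$total
  }
  for (i in sample(length(z), 4)) {
    z0 <- z[i]; z[i] <- z0 + eps; lp <- total(); z[i] <- z0 - eps; lm <- total(); z[i] <- z0
    expect_equal(gz[i], (lp - lm) / (2 * eps), tolerance = 1e-5)
  }
  for (i in sample(length(lg), 4)) {
    l0 <- lg[i]; lg[i] <- l0 + eps; lp <- total(); lg[i] <- l0 - eps; lm <- total(); lg[i] <- l0
    expect_equal(gl[i], (lp - lm) / (2 * eps), tolerance = 1e-5)
  }
})

test_that("encoder, projector and reorder head honor their dimension contracts", {
  enc <- encoder_tiny(seed = 1)
  x <- array(runif(16 * 16 * 4 * 2 * 3), c(16, 16, 4, 2, 3))
  h <- encoder_forward(enc, x)
  expect_equal(dim(h), c(2L, 512L))
  pj <- projector_mlp(seed = 2)
  z <- echoclr:::nn_seq_forward(pj$layers, h)
  expect_equal(dim(z), c(2L, 128L))
  rh <- reorder_head(k = 4, seed = 3)
  lg <- echoclr:::nn_seq_forward(rh$layers, h)
  expect_equal(dim(lg), c(2L, 24L))
  # deterministic in eval mode
  expect_identical(encoder_forward(enc, x), encoder_forward(enc, x))
})
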