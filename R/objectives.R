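#' Cosine similarity matrix
#'
#' Entry (i, k) is `z_i . z_k / (||z_i|| ||z_k||)`; the matrix is symmetric
#' with unit diagonal.
#'
#' @param z Numeric matrix of embeddings, one row per clip (2N x 128 during
#'   pretraining).
#' @return 2N x 2N similarity matrix.
#' @export
cosine_similarity_matrix <- function(z) {
  nrm <- sqrt(rowSums(z * z))
  if (any(nrm == 0)) stop("degenerate embedding: zero-norm row")
  u <- z / nrm
  tcrossprod(u)
}

#' Embedding batch for the contrastive objective
#'
#' Rows `2k-1` and `2k` (1-based) of `z` form positive pair k; `tau` is the
#' softmax temperature.
#'
#' @param z 2N x d embedding matrix with adjacent-row positive pairs.
#' @param tau Temperature > 0 (default 0.5).
#' @return List of class `embedding_batch` with `z`, `tau`, `n_pairs`.
#' @export
embedding_batch <- function(z, tau = 0.5) {
  stopifnot(is.matrix(z), nrow(z) %% 2L == 0L, tau > 0)
  structure(list(z = z, tau = tau, n_pairs = nrow(z) %/% 2L),
            class = "embedding_batch")
}

#' NT-Xent contrastive loss
#'
#' The temperature-normalized cross-entropy loss over a batch of 2N
#' embeddings with adjacent-row positive pairs:
#' \deqn{\ell_{i,j} = -\log \frac{\exp(sim(z_i, z_j)/\tau)}
#'   {\sum_{k=1}^{2N} 1[i \ne k] \exp(sim(z_i, z_k)/\tau)}}
#' The returned loss is the mean of \eqn{\ell_{i,j}} over both orderings of
#' every positive pair (2N terms). With `grad = TRUE` the analytic gradient
#' with respect to `z` is attached as attribute `"grad"`.
#'
#' @param batch An `embedding_batch` with at least 2 pairs.
#' @param grad Logical; also compute the gradient (used during pretraining).
#' @return Scalar loss (with optional `"grad"` attribute).
#' @export
nt_xent_loss <- function(batch, grad = FALSE) {
  stopifnot(inherits(batch, "embedding_batch"))
  n2 <- nrow(batch$z)
  if (batch$n_pairs < 2L) stop("NT-Xent needs at least 2 positive pairs")
  tau <- batch$tau
  nrm <- sqrt(rowSums(batch$z * batch$z))
  if (any(nrm == 0)) stop("degenerate embedding: zero-norm row")
  u <- batch$z / nrm
  s <- tcrossprod(u)
  partner <- as.integer(seq_len(n2) + c(1L, -1L))  # 1<->2, 3<->4, ...
  e <- exp(s / tau)
  diag(e) <- 0
  denom <- rowSums(e)
  pos <- s[cbind(seq_len(n2), partner)]
  losses <- -pos / tau + log(denom)
  loss <- mean(losses)
  if (grad) {
    p <- e / denom                       # softmax over k != i, rows i
    g_s <- p
    g_s[cbind(seq_len(n2), partner)] <- g_s[cbind(seq_len(n2), partner)] - 1
    g_s <- g_s / (tau * n2)              # dL/dS, zero diagonal already
    gu <- (g_s + t(g_s)) %*% u           # dL/du_i
    gz <- (gu - u * rowSums(gu * u)) / nrm
    attr(loss, "grad") <- gz
  }
  loss
}

#' Frame-reorder cross-entropy
#'
#' Mean over the batch of `-log softmax(logits)[class_index]`, the K!-way
#' classification loss of the frame-reorder pretext task. Chance level is
#' exactly `log(factorial(K))`.
#'
#' @param logits N x K! matrix of reorder logits.
#' @param targets Integer vector (length N) of 0-based permutation class
#'   indices, or a list of labels as returned by [shuffle_clip()].
#' @param grad Logical; attach the gradient with respect to `logits`.
#' @return Scalar loss (with optional `"grad"` attribute).
#' @export
reorder_cross_entropy <- function(logits, targets, grad = FALSE) {
  stopifnot(is.matrix(logits))
  if (is.list(targets))
    targets <- vapply(targets, function(t) t$class_index, numeric(1))
  targets <- as.integer(targets)
  n <- nrow(logits)
  stopifnot(length(targets) == n)
  if (any(targets < 0L | targets >= ncol(logits)))
    stop("class_index out of range [0, K!)")
  m <- apply(logits, 1L, max)
  ex <- exp(logits - m)
  logz <- m + log(rowSums(ex))
  picked <- logits[cbind(seq_len(n), targets + 1L)]
  loss <- mean(logz - picked)
  if (grad) {
    p <- ex / rowSums(ex)
    p[cbind(seq_len(n), targets + 1L)] <- p[cbind(seq_len(n), targets + 1L)] - 1
    attr(loss, "grad") <- p / n
  }
  loss
}

#' Combined pretraining loss
#'
#' The unweighted sum of the contrastive NT-Xent objective and the
#' frame-reorder cross-entropy. With the reorder term disabled the loss
#' reduces exactly to NT-Xent (the multi-instance-contrastive-only ablation).
#'
#' @param batch An `embedding_batch`.
#' @param logits Optional N x K! reorder logits (`NULL` disables the reorder
#'   term).
#' @param targets Reorder targets (see [reorder_cross_entropy()]).
#' @return List: `total`, `nt_xent`, `reorder` (NA when disabled).
#' @export
echoclr_loss <- function(batch, logits = NULL, targets = NULL) {
  l_con <- as.numeric(nt_xent_loss(batch))
  if (is.null(logits)) {
    list(total = l_con, nt_xent = l_con, reorder = NA_real_)
  } else {
    l_re <- as.numeric(reorder_cross_entropy(logits, targets))
    list(total = l_con + l_re, nt_xent = l_con, reorder = l_re)
  }
}

## Binary cross-entropy on pre-sigmoid logits, with gradient.
bce_with_logits <- function(logits, y, grad = FALSE) {
  p <- 1 / (1 + exp(-logits))
  eps <- 1e-12
  loss <- -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
  if (grad) attr(loss, "grad") <- matrix((p - y) / length(y), ncol = 1L)
  loss
}
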