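# Attention fusion block (AFB): merges the k channel-attended head maps by
# an element-wise mean, regresses the BDI-II score from the pooled fused
# map, and scores the joint objective L_sum = L_att + L_mse. The partition
# loss L_att = mean log(1 + k / (sigma^2 + eps)) penalises low variance of
# the globally pooled per-channel activations across heads, so minimising
# it drives the heads apart ("partitioning" the face among them).

#' Fuse cross-attention head outputs
#'
#' Element-wise mean of the `k` channel-attended maps produced by the
#' cross-attention heads.
#'
#' @param heads A non-empty list of equally shaped numeric arrays.
#' @return A numeric array of the common shape.
#' @examples
#' fuse_heads(list(array(1, c(2, 2, 1, 1)), array(3, c(2, 2, 1, 1))))
#' @export
fuse_heads <- function(heads) {
  if (length(heads) == 0) abort("fuse_heads: need at least one head output")
  dims <- lapply(heads, dim)
  if (!all(vapply(dims, identical, TRUE, dims[[1]])))
    abort("fuse_heads: head outputs must share one shape")
  Reduce(`+`, heads) / length(heads)
}

# pool a list of (H, W, C, N) maps to an (N, C, k) array of channel means
pool_heads <- function(heads) {
  pooled <- lapply(heads, function(h) {
    if (is.matrix(h)) h else gap_forward(h)
  })
  k <- length(pooled)
  d <- dim(pooled[[1]])
  arr <- array(0, c(d[1], d[2], k))
  for (i in seq_len(k)) arr[, , i] <- pooled[[i]]
  arr
}

#' Partition loss over attention heads
#'
#' For every sample and channel, the activations of the `k` heads (global
#' average of each channel-attended map) are summarised by their population
#' variance `sigma^2`; the loss is the mean of `log(1 + k / (sigma^2 +
#' eps))`. It is strictly decreasing in every variance, so minimising it
#' maximises the spread among the attention heads. For `k = 1` the loss is
#' defined as 0.
#'
#' @param heads List of `k` head outputs: either `(H, W, C, N)` arrays or
#'   already pooled `N x C` matrices.
#' @param eps Variance floor guarding `k / 0` (default `1e-6`).
#' @return Scalar loss (>= 0), with attributes `sigma_sq` (`N x C` matrix of
#'   across-head variances) and `k`.
#' @examples
#' partition_loss(list(matrix(0, 1, 1), matrix(2, 1, 1)))  # log(3)
#' @export
partition_loss <- function(heads, eps = 1e-6) {
  k <- length(heads)
  if (k < 1) abort("partition_loss: need at least one head")
  if (k == 1) return(structure(0, sigma_sq = NULL, k = 1L))
  pooled <- pool_heads(heads)                    # N x C x k
  if (any(!is.finite(pooled))) abort("partition_loss: non-finite head values")
  mu <- rowMeans(pooled, dims = 2)
  sig2 <- pmax(rowMeans(pooled^2, dims = 2) - mu^2, 0)
  l <- mean(log(1 + k / (sig2 + eps)))
  structure(l, sigma_sq = sig2, k = as.integer(k))
}

# gradient of the partition loss on the pooled (N, C, k) array
partition_loss_grad <- function(pooled, eps = 1e-6) {
  d <- dim(pooled)
  k <- d[3]
  mu <- rowMeans(pooled, dims = 2)
  sig2 <- pmax(rowMeans(pooled^2, dims = 2) - mu^2, 0)
  u <- sig2 + eps
  dl_dsig2 <- -(1 / (d[1] * d[2])) * k / (u * (u + k))
  grad <- array(0, d)
  for (i in seq_len(k)) grad[, , i] <- dl_dsig2 * 2 * (pooled[, , i] - mu) / k
  grad
}

#' Joint training loss
#'
#' Combines the mean-squared regression error on the predicted BDI-II
#' scores with the partition loss over the cross-attention heads:
#' `L_sum = L_att + L_mse`.
#'
#' @param pred,truth Numeric vectors of equal length (predicted and true
#'   scores).
#' @param heads List of head outputs as in [partition_loss()]; `NULL` drops
#'   the attention term (`L_att = 0`).
#' @param eps Variance floor for the partition loss.
#' @return A list of class `hmhn_loss_bundle` with `l_mse`, `l_att`,
#'   `l_sum`, `n`, and the across-head variance matrix `sigma_sq`.
#' @examples
#' total_loss(c(1), c(3), list(matrix(0, 1, 1), matrix(2, 1, 1)))
#' @export
total_loss <- function(pred, truth, heads = NULL, eps = 1e-6) {
  if (length(pred) != length(truth))
    abort("total_loss: pred and truth must have equal length")
  if (length(pred) < 1) abort("total_loss: empty batch")
  l_mse <- mean((pred - truth)^2)
  if (is.null(heads) || length(heads) < 2) {
    l_att <- 0; sig2 <- NULL; k <- length(heads %||% list())
  } else {
    pl <- partition_loss(heads, eps)
    l_att <- as.numeric(pl); sig2 <- attr(pl, "sigma_sq"); k <- attr(pl, "k")
  }
  structure(list(l_mse = l_mse, l_att = l_att, l_sum = l_att + l_mse,
                 n = length(pred), sigma_sq = sig2, k = k, eps = eps),
            class = "hmhn_loss_bundle")
}

#' @export
print.hmhn_loss_bundle <- function(x, ...) {
  cat(sprintf("<loss> L_sum = %.4f (L_mse = %.4f, L_att = %.4f), n = %d\n",
              x$l_sum, x$l_mse, x$l_att, x$n))
  invisible(x)
}

# ---- regression head --------------------------------------------------------

afb_module <- function(cin = 512L, dropout = 0.2) {
  structure(list(drop = nn_dropout(dropout), fc = nn_linear(cin, 1L),
                 cache = new.env(parent = emptyenv())),
            class = "hmhn_afb")
}

# fused (H, W, C, N) -> numeric N-vector of scores
afb_forward <- function(mod, fused, train = TRUE) {
  v <- gap_forward(fused)                        # N x C
  vd <- layer_forward(mod$drop, v, train)
  y <- layer_forward(mod$fc, vd, train)
  mod$cache$fdim <- dim(fused)
  as.numeric(y)
}

afb_backward <- function(mod, dpred) {
  dy <- matrix(dpred, ncol = 1)
  dv <- layer_backward(mod$fc, dy)
  dv <- layer_backward(mod$drop, dv)
  gap_backward(dv, mod$cache$fdim)
}

afb_layers <- function(mod) list(mod$fc)
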