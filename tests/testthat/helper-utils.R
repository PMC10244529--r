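rel_diff <- function(a, b) {
  max(abs(a - b)) / max(1e-12, max(abs(b)))
}

# mean pairwise cosine similarity among the pooled head vectors of a
# fitted model, averaged over the samples of x
mean_head_cosine <- function(model, x) {
  fwd <- hmhn:::model_forward(model, x, train = FALSE)
  pooled <- lapply(fwd$c_maps, hmhn:::gap_forward)   # list of N x C
  k <- length(pooled)
  n <- nrow(pooled[[1]])
  sims <- c()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    a <- pooled[[i]]; b <- pooled[[j]]
    num <- rowSums(a * b)
    den <- sqrt(rowSums(a^2)) * sqrt(rowSums(b^2))
    sims <- c(sims, num / pmax(den, 1e-12))
  }
  mean(sims)
}
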