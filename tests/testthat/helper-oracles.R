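# Independent oracles, coded as literal textbook transcriptions so they
# stay independent of the package internals they cross-check.

# Potential scale reduction factor: m chains of length n, per column j.
psrf_oracle <- function(chain_list) {
  m <- length(chain_list)
  n <- nrow(chain_list[[1]])
  k <- ncol(chain_list[[1]])
  out <- numeric(k)
  for (j in seq_len(k)) {
    xs <- sapply(chain_list, function(ch) ch[, j])      # n x m
    chain_means <- colMeans(xs)
    grand_mean <- mean(chain_means)
    B <- n / (m - 1) * sum((chain_means - grand_mean)^2)
    W <- mean(sapply(seq_len(m), function(i)
      sum((xs[, i] - chain_means[i])^2) / (n - 1)))
    var_hat <- (n - 1) / n * W + B / n
    out[j] <- sqrt(var_hat / W)
  }
  out
}

# Pearson chi-squared statistic by direct summation over the table.
chisq_oracle <- function(m) {
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - E)^2 / E)
}

# Two-sided permutation p-value for the rank-sum statistic of sample a.
perm_ranksum_p <- function(a, b, n_perm = 1e5, seed = 1) {
  pooled <- c(a, b)
  na <- length(a)
  obs <- sum(rank(pooled)[seq_len(na)])
  center <- na * (length(pooled) + 1) / 2
  withr::with_seed(seed, {
    perm <- replicate(n_perm, {
      idx <- sample.int(length(pooled), na)
      sum(rank(pooled)[idx])
    })
  })
  mean(abs(perm - center) >= abs(obs - center))
}

# Small deterministic viability fixture on the model curve plus fixed
# residuals, used by the likelihood tests.
viability_toy <- function(params, residuals) {
  grid <- expand.grid(c_im_uM = c(0, 5, 10, 20),
                      c_il12_ng_ml = c(0, 40, 100, 200))
  grid <- grid[seq_along(residuals), ]
  pred <- predict_viability(params, grid$c_im_uM, grid$c_il12_ng_ml)
  data.frame(c_im_uM = grid$c_im_uM, c_il12_ng_ml = grid$c_il12_ng_ml,
             live_pct = pred + residuals, assay = "flow")
}
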