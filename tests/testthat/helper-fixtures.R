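# Small-scale study configuration: 12 trials -> 132 volumes, default grid.
# Dots override any default (including the group sizes).
small_config <- function(seed = 1, ...) {
  args <- list(n_mdd = 4, n_ctrl = 3, n_trials = 12,
               n_reappraise_neg = 4, n_attend_neg = 3,
               n_always_press = 0, p_missing = 0, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synthetic_config, args)
}

# Vectorized sampler from a multinomial-logit truth: one severity draw per
# row of `features`.
sample_softmax <- function(features, coefs, seed) {
  categories <- attr(coefs, "categories")
  eta <- matrix(0, nrow(features), length(categories),
                dimnames = list(NULL, categories))
  eta[, rownames(coefs)] <- cbind(1, features) %*% t(coefs)
  p <- exp(eta - apply(eta, 1, max))
  p <- p / rowSums(p)
  cum <- t(apply(p, 1, cumsum))
  u <- withr::with_seed(seed, runif(nrow(features)))
  as.integer(categories[rowSums(u > cum) + 1L])
}

# Tiny hand-built BOLD dataset on an isotropic grid with a known affine.
tiny_bold <- function(grid = c(5, 5, 5), n_t = 40, voxel = 3,
                      origin = c(0, 0, 0), seed = 1) {
  affine <- diag(c(rep(voxel, 3), 1))
  affine[1:3, 4] <- origin
  withr::with_seed(seed, {
    bold_dataset(array(rnorm(prod(grid) * n_t), c(grid, n_t)), affine, 2)
  })
}

# Deterministic sample with exact mean and SD (for summary-statistic tests).
sample_with_moments <- function(n, mean, sd) {
  x <- seq_len(n)
  as.numeric(mean + sd * scale(x))
}

# Exact two-sided rank-sum p-value by full enumeration of group labelings.
enumerate_ranksum_p <- function(a, b) {
  n_a <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  combos <- utils::combn(length(pooled), n_a)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - n_a * (n_a + 1) / 2)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}
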