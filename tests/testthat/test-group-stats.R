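test_that("rank-sum p-values match full enumeration for small groups", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$statistic, 0)
  expect_equal(w$p, 0.1)
  expect_equal(w$p, enumerate_ranksum_p(c(1, 2, 3), c(4, 5, 6)))
  withr::with_seed(21, for (i in 1:10) {
    a <- rnorm(sample(4:8, 1)); b <- rnorm(sample(4:8, 1))
    expect_equal(wilcoxon_rank_sum(a, b)$p, enumerate_ranksum_p(a, b),
                 tolerance = 1e-12)
  })
})

test_that("rank-sum handles identity and degenerate inputs", {
  a <- c(1, 2, 3, 4)
  w <- wilcoxon_rank_sum(a, a)
  expect_equal(w$p, 1)
  all_tied <- wilcoxon_rank_sum(rep(2, 5), rep(2, 6))
  expect_equal(all_tied$p, 1)
  expect_equal(all_tied$effect_r, 0)
  expect_error(wilcoxon_rank_sum(1, c(2, 3)), "at least 2")
})

test_that("rank-sum detects a 2-SD shift at the study group sizes", {
  rej <- withr::with_seed(31, vapply(1:1000, function(i) {
    wilcoxon_rank_sum(rnorm(17), rnorm(14, 2))$p < 0.05
  }, logical(1)))
  expect_gt(mean(rej), 0.95)
})

test_that("signed-rank test is exact for all-positive differences", {
  b <- as.numeric(1:8)
  a <- b + (1:8) / 10  # all differences positive and distinct
  w <- wilcoxon_signed_rank(a, b)
  expect_equal(w$p, 2 / 2^8)
  expect_equal(wilcoxon_signed_rank(a, a)$p, 1)
  expect_error(wilcoxon_signed_rank(1:3, 1:4), "equal length")
})

test_that("signed-rank test holds its size under a symmetric null", {
  rej <- withr::with_seed(41, vapply(1:1000, function(i) {
    d <- rnorm(20)
    wilcoxon_signed_rank(d, numeric(20))$p < 0.05
  }, logical(1)))
  expect_lte(mean(rej), 0.06)
})

test_that("Holm adjustment is the step-down correction with monotonicity", {
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(0.037), 0.037)
  # hand step-down: sorted (0.01,0.03,0.04) * (3,2,1) -> (0.03,0.06,0.04),
  # running max -> (0.03,0.06,0.06), back in input order:
  expect_equal(holm_adjust(c(0.03, 0.01, 0.04)), c(0.06, 0.03, 0.06))
  expect_error(holm_adjust(c(0.2, 1.4)), "\\[0, 1\\]")
  withr::with_seed(51, for (i in 1:20) {
    p <- runif(7)
    adj <- holm_adjust(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))
  })
})

test_that("ANCOVA adjusted means reduce to raw means with an orthogonal covariate", {
  withr::with_seed(61, {
    grp <- rep(c("a", "b"), each = 10)
    val <- rnorm(20) + (grp == "b")
    cov_orth <- rnorm(20)
  })
  # force a zero covariate effect: residualize the covariate then add no signal
  fit0 <- ancova_group_effect(val, grp, cov_orth)
  raw_means <- tapply(val, grp, mean)
  # with the covariate coefficient forced to zero the adjusted means are the
  # raw means; with a fitted coefficient they differ only through the
  # group-wise covariate imbalance
  imbalance <- diff(tapply(cov_orth, grp, mean))
  slope <- coef(fit0$model)["covariate"]
  expect_equal(unname(fit0$adjusted_means["b"] - fit0$adjusted_means["a"]),
               unname(diff(raw_means) - slope * imbalance), tolerance = 1e-8)
  expect_warning(ancova_group_effect(val, grp, rep(1, 20)), "constant")
})

test_that("ANCOVA recovers a known group effect and holds its size", {
  covr <- withr::with_seed(71, {
    reps <- vapply(1:1000, function(i) {
      grp <- rep(c("a", "b"), each = 15)
      cv <- rnorm(30)
      val <- 2 * (grp == "b") + 0.5 * cv + rnorm(30)
      fit <- lm(val ~ factor(grp) + cv)
      ci <- stats::confint(fit)[2, ]
      c(ci[1] <= 2 && 2 <= ci[2],
        summary(fit)$coefficients[2, 4] < 0.05)
    }, logical(2))
    rowMeans(reps)
  })
  expect_gte(covr[1], 0.93)
  null_rej <- withr::with_seed(81, mean(vapply(1:1000, function(i) {
    grp <- rep(c("a", "b"), each = 15)
    cv <- rnorm(30)
    val <- 0.5 * cv + rnorm(30)
    ancova_group_effect(val, grp, cv)$p < 0.05
  }, logical(1))))
  expect_gt(null_rej, 0.03)
  expect_lt(null_rej, 0.07)
})

test_that("Welch t on the published HAMD moments is highly significant", {
  a <- sample_with_moments(17, 12.35, 3.87)
  b <- sample_with_moments(14, 1.46, 1.89)
  expect_equal(mean(a), 12.35)
  expect_equal(sd(a), 3.87)
  w <- welch_t(a, b)
  expect_lt(w$p, 0.001)
  # closed-form Welch t from the summary statistics
  t_closed <- (12.35 - 1.46) / sqrt(3.87^2 / 17 + 1.89^2 / 14)
  expect_equal(w$t, t_closed, tolerance = 1e-10)
  expect_equal(welch_t(a, a)$p, 1)
  expect_error(welch_t(rep(1, 5), rep(2, 5)), "zero variance")
})

test_that("pFDR flags a strongly separated parcel and nothing when groups coincide", {
  n_parcel <- 360
  hits <- withr::with_seed(91, vapply(1:20, function(s) {
    a <- matrix(rnorm(17 * n_parcel), 17)
    b <- matrix(rnorm(14 * n_parcel), 14)
    b[, 1] <- b[, 1] + 5
    res <- pfdr_parcelwise(a, b, n_resamples = 100, fdr = 0.05, seed = s)
    res$significant[1]
  }, logical(1)))
  expect_gte(mean(hits), 0.95)
  # identical groups: observed p = 1 everywhere, nothing significant
  x <- withr::with_seed(92, matrix(rnorm(6 * 50), 6))
  res0 <- pfdr_parcelwise(x, x, n_resamples = 50, seed = 1)
  expect_true(all(res0$observed_p == 1))
  expect_false(any(res0$significant))
  expect_error(pfdr_parcelwise(x, x, n_resamples = 10), ">= 20")
})

test_that("vectorized rank-sum p-values agree with the scalar test", {
  withr::with_seed(93, {
    x <- matrix(rnorm(31 * 20), 31)
    x[5, 3] <- x[6, 3]  # inject a tie
  })
  p_vec <- gstopo:::ranksum_p_cols(x, 1:17)
  for (j in c(1, 3, 7, 20)) {
    w <- wilcoxon_rank_sum(x[1:17, j], x[18:31, j])
    expect_equal(p_vec[j], w$p, tolerance = 1e-12)
  }
})

test_that("layer comparison tables carry Holm-adjusted p and ANCOVA means", {
  withr::with_seed(94, {
    gt <- expand.grid(subject = sprintf("s%02d", 1:20),
                      layer = c("interoceptive", "exteroceptive", "mental"),
                      stringsAsFactors = FALSE)
    gt$group <- ifelse(as.integer(sub("s", "", gt$subject)) <= 10,
                       "mdd", "ctrl")
    gt$z <- rnorm(nrow(gt)) +
      0.8 * (gt$group == "mdd" & gt$layer != "interoceptive")
    hamd <- setNames(c(runif(10, 7, 17), runif(10, 0, 5)),
                     sprintf("s%02d", 1:20))
  })
  tab <- layer_group_comparison(tibble::as_tibble(gt), covariate = hamd)
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$p_adjusted >= tab$p))
  expect_true(all(c("adj_mean_mdd", "adj_mean_ctrl", "ancova_p") %in%
                    names(tab)))
  within <- within_group_layer_comparison(tibble::as_tibble(gt), "mdd")
  expect_equal(nrow(within), 3)
})
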