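# Normal-approximation two-sided rank-sum p with tie correction and
# continuity correction; also returns the standardized statistic used for
# the effect size r = |z| / sqrt(N).
ranksum_normal <- function(r, n_a) {
  n <- length(r)
  n_b <- n - n_a
  u <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  mu <- n_a * n_b / 2
  tie <- sum(vapply(split(r, r), function(g) length(g)^3 - length(g),
                    numeric(1)))
  sig2 <- n_a * n_b / 12 * ((n + 1) - tie / (n * (n - 1)))
  if (sig2 <= 0) return(list(u = u, z = 0, p = 1))
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sig2)
  list(u = u, z = z, p = min(1, 2 * pnorm(-abs(z))))
}

#' Two-group Wilcoxon rank-sum comparison
#'
#' Two-sided Mann-Whitney test with the small-sample convention used for the
#' group comparisons: exact p-value when the combined sample size is at most
#' 25 and there are no ties, tie-corrected normal approximation (with
#' continuity correction) otherwise. The effect size is the common Wilcoxon
#' `r = |z| / sqrt(N)`, with `z` the standardized rank-sum statistic.
#'
#' @param a,b Numeric vectors (>= 2 observations each).
#' @return List with `statistic` (Mann-Whitney U of `a`), `p`, `effect_r`
#'   and `method`.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 observations")
  r <- rank(c(a, b))
  app <- ranksum_normal(r, length(a))
  ties <- anyDuplicated(c(a, b)) > 0
  if (!ties && length(a) + length(b) <= 25) {
    p <- suppressWarnings(wilcox.test(a, b, exact = TRUE)$p.value)
    method <- "exact"
  } else {
    p <- app$p
    method <- "normal approximation, tie-corrected"
  }
  list(statistic = app$u, p = p,
       effect_r = abs(app$z) / sqrt(length(a) + length(b)),
       method = method)
}

#' Paired Wilcoxon signed-rank comparison
#'
#' Two-sided signed-rank test on the paired differences; zero differences are
#' dropped (and `p = 1` when all differences are zero). Exact for small
#' samples without ties, normal approximation otherwise; effect size is
#' `|z| / sqrt(n)` over the non-zero pairs.
#'
#' @param paired_a,paired_b Numeric vectors of equal length (>= 2).
#' @return List with `statistic` (V), `p`, `effect_r` and `n_nonzero`.
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b) {
  if (length(paired_a) != length(paired_b))
    stop("paired vectors must have equal length")
  if (length(paired_a) < 2) stop("need at least 2 pairs")
  d <- paired_a - paired_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = 0, p = 1, effect_r = 0, n_nonzero = 0L))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  tie <- sum(vapply(split(r, r), function(g) length(g)^3 - length(g),
                    numeric(1)))
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - tie / 48
  z <- if (sig2 > 0) (v - mu - sign(v - mu) * 0.5) / sqrt(sig2) else 0
  p <- suppressWarnings(wilcox.test(paired_a, paired_b, paired = TRUE,
                                    exact = NULL)$p.value)
  if (is.na(p)) p <- 1
  list(statistic = v, p = p, effect_r = abs(z) / sqrt(n), n_nonzero = n)
}

#' Holm step-down adjustment of p-values
#'
#' Step-down Bonferroni-Holm correction with enforced monotonicity, capped
#' at 1.
#'
#' @param pvals Numeric vector of probabilities.
#' @return Adjusted probabilities in the original order.
#' @export
holm_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "holm")
}

#' ANCOVA group effect with a single covariate
#'
#' Linear model `value ~ group + covariate`; the group p-value is the partial
#' t-test of the group term and the adjusted group means are model
#' predictions at the grand covariate mean. A constant covariate reduces to
#' the plain two-group linear model with a warning.
#'
#' @param values Numeric response.
#' @param group Two-level factor (or coercible).
#' @param covariate Numeric covariate (e.g. HAMD score).
#' @return List with `adjusted_means` (named by group level), `p` (group
#'   effect), and the fitted `model`.
#' @export
ancova_group_effect <- function(values, group, covariate) {
  group <- factor(group)
  if (nlevels(group) != 2) stop("`group` must have exactly two levels")
  if (any(table(group) < 3)) stop("need >= 3 observations per group")
  if (sd(covariate) == 0) {
    warning("constant covariate; fitting the plain two-group model")
    fit <- lm(values ~ group)
    means <- predict(fit, data.frame(group = levels(group)))
  } else {
    fit <- lm(values ~ group + covariate)
    means <- predict(fit, data.frame(group = levels(group),
                                     covariate = mean(covariate)))
  }
  names(means) <- levels(group)
  list(adjusted_means = means,
       p = summary(fit)$coefficients[2, 4],
       model = fit)
}

#' Welch two-sample t-test
#'
#' Two-sided t-test with Welch's degrees of freedom, as used for demographic
#' comparisons.
#'
#' @param a,b Numeric vectors (>= 2 each).
#' @return List with `t`, `df` and `p`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 observations")
  if (sd(a) == 0 && sd(b) == 0)
    stop("zero variance in both groups; t undefined")
  ht <- t.test(a, b)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

# Column-wise tie-corrected normal-approximation rank-sum p-values for a
# stacked subjects-by-parcels matrix; `a_idx` indexes group A rows.
ranksum_p_cols <- function(x, a_idx) {
  n <- nrow(x)
  n_a <- length(a_idx)
  n_b <- n - n_a
  r <- apply(x, 2L, rank)
  u <- colSums(r[a_idx, , drop = FALSE]) - n_a * (n_a + 1) / 2
  mu <- n_a * n_b / 2
  tie <- apply(r, 2L, function(col) {
    t <- tabulate(match(col, unique(col)))
    sum(t^3 - t)
  })
  sig2 <- n_a * n_b / 12 * ((n + 1) - tie / (n * (n - 1)))
  z <- ifelse(sig2 > 0, (u - mu - sign(u - mu) * 0.5) / sqrt(sig2), 0)
  p <- pmin(1, 2 * pnorm(-abs(z)))
  p[sig2 <= 0] <- 1
  p
}

#' Parcelwise group comparison with resampling positive FDR
#'
#' The whole-brain topography comparison: (1) an observed Wilcoxon p-value
#' per parcel; (2) `n_resamples` random group-label permutations of the
#' subjects, recomputing every parcel's p-value to form that parcel's null
#' distribution; (3) a parcel is significant when the fraction of its null
#' p-values at or below its observed p is smaller than the expected false
#' discovery rate.
#'
#' @param group_a_maps,group_b_maps Subjects-by-parcels matrices of GSCORR
#'   values (same parcel set, >= 2 subjects each).
#' @param n_resamples Number of label permutations (>= 20).
#' @param fdr Expected false discovery rate (default 0.05).
#' @param seed Integer seed for the permutations.
#' @return A tibble with one row per parcel: `parcel`, `observed_p`,
#'   `null_exceedance_fraction`, `significant`; attributes `n_resamples` and
#'   `fdr_threshold`.
#' @export
pfdr_parcelwise <- function(group_a_maps, group_b_maps, n_resamples = 100L,
                            fdr = 0.05, seed = 1L) {
  group_a_maps <- as.matrix(group_a_maps)
  group_b_maps <- as.matrix(group_b_maps)
  if (ncol(group_a_maps) != ncol(group_b_maps))
    stop("groups must share the same parcel set")
  if (nrow(group_a_maps) < 2 || nrow(group_b_maps) < 2)
    stop("need >= 2 subjects per group")
  if (n_resamples < 20)
    stop("`n_resamples` must be >= 20; the null would be too coarse")
  x <- rbind(group_a_maps, group_b_maps)
  n_a <- nrow(group_a_maps)
  n <- nrow(x)
  p_obs <- ranksum_p_cols(x, seq_len(n_a))
  null_p <- withr::with_seed(seed, {
    vapply(seq_len(n_resamples), function(r) {
      ranksum_p_cols(x, sample.int(n, n_a))
    }, numeric(ncol(x)))
  })
  if (is.null(dim(null_p))) null_p <- matrix(null_p, nrow = ncol(x))
  frac <- rowMeans(null_p <= p_obs)
  parcel <- colnames(x)
  if (is.null(parcel)) parcel <- as.character(seq_len(ncol(x)))
  out <- tibble::tibble(parcel = parcel, observed_p = p_obs,
                        null_exceedance_fraction = frac,
                        significant = frac < fdr)
  attr(out, "n_resamples") <- as.integer(n_resamples)
  attr(out, "fdr_threshold") <- fdr
  out
}

#' Between-group layer comparison with Holm correction
#'
#' Runs [wilcoxon_rank_sum()] per layer (MDD vs control), Holm-adjusts the
#' p-values across layers, and attaches ANCOVA-adjusted means using a
#' covariate (typically HAMD).
#'
#' @param gscorr Tibble with columns `subject`, `group`, `layer`, `z` (one
#'   row per subject and layer).
#' @param covariate Optional named numeric vector (names = subject ids) used
#'   as ANCOVA covariate.
#' @return A tibble with one row per layer: Wilcoxon statistic, `p`,
#'   `p_adjusted`, `effect_r`, and (with a covariate) adjusted means and
#'   ANCOVA p.
#' @export
layer_group_comparison <- function(gscorr, covariate = NULL) {
  layers <- unique(gscorr$layer)
  rows <- lapply(layers, function(ly) {
    d <- gscorr[gscorr$layer == ly, ]
    a <- d$z[d$group == "mdd"]
    b <- d$z[d$group == "ctrl"]
    w <- wilcoxon_rank_sum(a, b)
    row <- tibble::tibble(layer = ly, statistic = w$statistic, p = w$p,
                          effect_r = w$effect_r,
                          median_mdd = median(a), median_ctrl = median(b))
    if (!is.null(covariate)) {
      av <- ancova_group_effect(d$z, d$group, covariate[d$subject])
      row$ancova_p <- av$p
      row$adj_mean_mdd <- unname(av$adjusted_means["mdd"])
      row$adj_mean_ctrl <- unname(av$adjusted_means["ctrl"])
    }
    row
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- holm_adjust(out$p)
  out
}

#' Within-group pairwise layer comparison
#'
#' Paired signed-rank comparisons between the three layers within one group
#' (the same subjects contribute all layers), Holm-corrected.
#'
#' @param gscorr Tibble with columns `subject`, `group`, `layer`, `z`.
#' @param group Group to compare within (`"mdd"` or `"ctrl"`).
#' @return A tibble with one row per layer pair.
#' @export
within_group_layer_comparison <- function(gscorr, group) {
  d <- gscorr[gscorr$group == group, ]
  layers <- unique(d$layer)
  pairs <- utils::combn(layers, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    a <- d$z[d$layer == pr[1]][order(d$subject[d$layer == pr[1]])]
    b <- d$z[d$layer == pr[2]][order(d$subject[d$layer == pr[2]])]
    w <- wilcoxon_signed_rank(a, b)
    tibble::tibble(group = group, layer_a = pr[1], layer_b = pr[2],
                   statistic = w$statistic, p = w$p, effect_r = w$effect_r,
                   median_diff = median(a - b))
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- holm_adjust(out$p)
  out
}
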