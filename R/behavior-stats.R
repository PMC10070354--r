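#' Clean trial-level severity responses
#'
#' Applies the behavioural cleaning rules: keep only the first button press
#' per rating window (lowest `response_rank` within a subject-trial), drop
#' trials without any response, and exclude every subject who pressed in all
#' four 2-s rating windows on every trial (the always-press rule).
#'
#' @param raw Tibble of trial records with columns `subject`, `trial`,
#'   `valence`, `instruction`, `response` (1-4 or `NA`) and optionally
#'   `response_rank` (press order within the trial's rating period).
#' @return Cleaned tibble, one row per retained trial. Excluded subjects are
#'   reported via a message; an empty result raises a warning.
#' @export
clean_responses <- function(raw) {
  needed <- c("subject", "trial", "valence", "instruction", "response")
  if (!all(needed %in% names(raw)))
    stop("missing columns: ", paste(setdiff(needed, names(raw)), collapse = ", "))
  if (!"response_rank" %in% names(raw))
    raw$response_rank <- ave(seq_len(nrow(raw)),
                             paste(raw$subject, raw$trial),
                             FUN = seq_along)
  # always-press rule: every trial of the subject has presses in all 4 windows
  key <- paste(raw$subject, raw$trial)
  pressed <- !is.na(raw$response)
  windows <- tapply(ifelse(pressed, raw$response, NA_integer_), key,
                    function(v) length(unique(v[!is.na(v)])))
  trial_subject <- tapply(raw$subject, key, `[`, 1L)
  all4 <- tapply(windows == 4L, trial_subject[names(windows)],
                 function(v) all(v))
  excluded <- names(all4)[all4]
  if (length(excluded))
    message("excluding always-press subject(s): ",
            paste(excluded, collapse = ", "))
  out <- raw[!(raw$subject %in% excluded) & !is.na(raw$response), , drop = FALSE]
  # first answer per trial
  ord <- order(out$subject, out$trial, out$response_rank)
  out <- out[ord, , drop = FALSE]
  first <- !duplicated(paste(out$subject, out$trial))
  out <- out[first, , drop = FALSE]
  if (!nrow(out)) warning("no trials remain after cleaning")
  tibble::as_tibble(out)
}

#' Group-by-severity contingency table for one condition
#'
#' Counts responses in a 2 (group) x 4 (severity) table restricted to one
#' valence/instruction condition.
#'
#' @param records Cleaned trial records with columns `group`, `valence`,
#'   `instruction`, `response`.
#' @param valence `"negative"` or `"neutral"`.
#' @param instruction `"attend"` or `"reappraise"`.
#' @return Integer matrix with rows `mdd`, `ctrl` and columns `1`..`4`.
#' @export
contingency_table <- function(records, valence, instruction) {
  d <- records[records$valence == valence &
                 records$instruction == instruction, , drop = FALSE]
  if (!nrow(d)) stop("no records for condition ", valence, "/", instruction)
  tab <- table(factor(d$group, levels = c("mdd", "ctrl")),
               factor(d$response, levels = 1:4))
  tab <- unclass(tab)
  if (any(rowSums(tab) == 0))
    warning("group '", rownames(tab)[rowSums(tab) == 0],
            "' has no responses in this condition")
  tab
}

#' Pearson chi-square test of a group-by-severity table
#'
#' Plain Pearson chi-square (no continuity correction) with expected counts
#' from the margins; for a 2 x k table the degrees of freedom are k - 1.
#'
#' @param tab 2 x k count matrix.
#' @return List with `chi2`, `df`, `n`, `p`, `expected` and
#'   `std_residuals` (see [standardized_residuals()]).
#' @export
chi_square_test <- function(tab) {
  tab <- as.matrix(tab)
  if (sum(tab) == 0) stop("empty table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero row or column margin; chi-square undefined")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       n = sum(tab), p = ct$p.value, expected = ct$expected,
       std_residuals = standardized_residuals(tab))
}

#' Standardized (adjusted) Pearson residuals
#'
#' `r_ij = (O_ij - E_ij) / sqrt(E_ij (1 - rowprop_i)(1 - colprop_j))`, the
#' z-normalized residuals whose two-sided normal cutoffs 1.96 / 3.29 / 3.89
#' mark p = 0.05 / 0.001 / 0.0001. Cells with zero expected count are
#' returned as `NA`.
#'
#' @param tab Count matrix.
#' @return Matrix of standardized residuals with attribute `cutoffs`.
#' @export
standardized_residuals <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  rp <- rowSums(tab) / n
  cp <- colSums(tab) / n
  expected <- outer(rowSums(tab), colSums(tab)) / n
  denom <- sqrt(expected * outer(1 - rp, 1 - cp))
  res <- (tab - expected) / denom
  res[expected == 0] <- NA_real_
  attr(res, "cutoffs") <- c(p0.05 = qnorm(0.975), p0.001 = qnorm(0.9995),
                            p0.0001 = qnorm(0.99995))
  res
}
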