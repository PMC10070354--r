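#' Fit a multinomial logistic regression by Newton's method
#'
#' Maximum-likelihood softmax regression of a categorical outcome on a
#' feature matrix, with a user-chosen reference category (whose coefficient
#' row is implicitly zero). Full Newton steps with step-halving guarantee a
#' non-decreasing log-likelihood; convergence is declared when the
#' log-likelihood improves by less than `tol` (default 1e-8) within
#' `max_iter` (200) iterations. Outcome categories absent from the data are
#' dropped with a warning; complete separation is flagged as
#' `converged = FALSE` with a warning, not penalized away.
#'
#' @param features Numeric trial-by-predictor matrix (no intercept column;
#'   one is added internally).
#' @param outcomes Severity labels (factor or coercible).
#' @param reference Reference category (must be present in the data).
#' @param max_iter,tol Newton iteration cap and log-likelihood tolerance.
#' @return An object of class `mlr_model`: coefficient matrix
#'   ((K-1) x (P+1)), `reference`, `categories`, `log_likelihood`,
#'   `converged`, `n_iter`, `dropped_categories`.
#' @export
fit_multinomial <- function(features, outcomes, reference,
                            max_iter = 200L, tol = 1e-8) {
  features <- as.matrix(features)
  if (any(!is.finite(features))) stop("features must be finite")
  if (!is.factor(outcomes)) outcomes <- factor(outcomes)
  declared <- levels(outcomes)
  present <- declared[tabulate(outcomes, length(declared)) > 0]
  if (length(present) < length(declared)) {
    warning("dropping outcome categor(ies) absent from data: ",
            paste(setdiff(declared, present), collapse = ", "))
    outcomes <- factor(outcomes, levels = present)
  }
  if (length(present) < 2) stop("need >= 2 outcome categories present")
  reference <- as.character(reference)
  if (!reference %in% present) stop("reference category '", reference,
                                    "' not present in the data")
  x <- cbind("(Intercept)" = 1, features)
  if (is.null(colnames(features)))
    colnames(x) <- c("(Intercept)", paste0("x", seq_len(ncol(features))))
  if (qr(x)$rank < ncol(x)) stop("singular design matrix")
  cats <- c(reference, setdiff(present, reference))
  y <- match(as.character(outcomes), cats)       # 1 = reference
  n <- nrow(x); p <- ncol(x); k1 <- length(cats) - 1L
  ymat <- matrix(0, n, k1)
  for (k in seq_len(k1)) ymat[, k] <- as.numeric(y == k + 1L)

  loglik <- function(b) {
    eta <- x %*% b                               # n x k1
    mx <- pmax(apply(eta, 1, max), 0)
    lse <- mx + log(exp(-mx) + rowSums(exp(eta - mx)))
    sum(eta[cbind(seq_len(n), pmax(y - 1L, 1L))][y > 1L]) - sum(lse)
  }
  probs_nonref <- function(b) {
    eta <- x %*% b
    mx <- pmax(apply(eta, 1, max), 0)
    e <- exp(eta - mx)
    e / (exp(-mx) + rowSums(e))
  }

  b <- matrix(0, p, k1)
  ll <- loglik(b)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    pr <- probs_nonref(b)
    grad <- as.vector(crossprod(x, ymat - pr))
    hess <- matrix(0, p * k1, p * k1)
    for (k in seq_len(k1)) {
      for (l in seq_len(k)) {
        w <- if (k == l) pr[, k] * (1 - pr[, k]) else -pr[, k] * pr[, l]
        blk <- crossprod(x, x * w)
        ri <- (k - 1L) * p + seq_len(p)
        ci <- (l - 1L) * p + seq_len(p)
        hess[ri, ci] <- blk
        hess[ci, ri] <- t(blk)
      }
    }
    delta <- tryCatch(solve(hess, grad),
                      error = function(e)
                        solve(hess + diag(1e-10, nrow(hess)), grad))
    step <- 1
    repeat {
      b_new <- b + step * matrix(delta, p, k1)
      ll_new <- loglik(b_new)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      step <- step / 2
      if (step < 1e-10) { b_new <- b; ll_new <- ll; break }
    }
    improved <- ll_new - ll
    b <- b_new; ll <- ll_new
    if (improved < tol && improved >= 0) { converged <- TRUE; break }
  }
  separated <- ll > -1e-4 * n || max(abs(b)) > 30
  if (converged && separated) {
    # a log-likelihood at (numerical) zero means every trial is fitted with
    # probability one: the likelihood has no interior maximum and the
    # coefficients are diverging (complete separation)
    converged <- FALSE
    warning("complete separation: fitted probabilities reached 0/1; ",
            "fit flagged as not converged")
  } else if (!converged) {
    warning("multinomial fit did not converge in ", max_iter,
            " iterations; coefficients reported as-is")
  }
  coefs <- t(b)
  rownames(coefs) <- cats[-1]
  colnames(coefs) <- colnames(x)
  structure(list(coefficients = coefs, reference = reference,
                 categories = cats, log_likelihood = ll,
                 converged = converged, n_iter = iter,
                 dropped_categories = setdiff(declared, present)),
            class = "mlr_model")
}

#' @export
print.mlr_model <- function(x, ...) {
  cat(sprintf("<mlr_model> %d categories (reference '%s'), logLik %.3f, %s\n",
              length(x$categories), x$reference, x$log_likelihood,
              if (x$converged) "converged" else "NOT converged"))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Relative risk ratios
#'
#' Elementwise exponential of a multinomial-logit coefficient matrix: the
#' multiplicative change in the odds of each response category versus the
#' reference for a one-unit predictor increase.
#'
#' @param model An `mlr_model` or a plain coefficient matrix/vector.
#' @return Matrix (or vector) of RRRs.
#' @export
relative_risk_ratios <- function(model) {
  if (inherits(model, "mlr_model")) return(exp(model$coefficients))
  exp(model)
}

#' Predicted category probabilities
#'
#' Softmax of the linear predictors, including the reference category; rows
#' sum to one.
#'
#' @param model An `mlr_model`.
#' @param features Numeric matrix with the same predictors as at fit time.
#' @return Trial-by-category probability matrix (columns in the model's
#'   category order, reference first).
#' @export
predict_probabilities <- function(model, features) {
  features <- as.matrix(features)
  x <- cbind(1, features)
  if (ncol(x) != ncol(model$coefficients))
    stop("feature dimension (", ncol(features), ") does not match model (",
         ncol(model$coefficients) - 1L, ")")
  eta <- cbind(0, x %*% t(model$coefficients))   # reference first
  mx <- apply(eta, 1, max)
  e <- exp(eta - mx)
  p <- e / rowSums(e)
  colnames(p) <- model$categories
  p
}

predict_category <- function(model, features) {
  p <- predict_probabilities(model, features)
  model$categories[max.col(p, ties.method = "first")]
}

#' One-sided binomial test of classification accuracy
#'
#' Exact binomial tail probability that `n_correct` or more successes out of
#' `n` arise at the no-information rate, i.e. a test of accuracy above the
#' largest-class baseline.
#'
#' @param n_correct Correct predictions.
#' @param n Total predictions.
#' @param nir No-information rate in (0, 1).
#' @return The one-sided p-value.
#' @export
accuracy_binomial_test <- function(n_correct, n, nir) {
  if (n_correct < 0 || n_correct > n) stop("`n_correct` must be in [0, n]")
  if (nir <= 0 || nir >= 1) stop("`nir` must be in (0, 1)")
  binom.test(n_correct, n, p = nir, alternative = "greater")$p.value
}

stratified_folds <- function(outcomes, k) {
  fold <- integer(length(outcomes))
  for (lev in unique(outcomes)) {
    idx <- sample(which(outcomes == lev))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Repeated stratified k-fold cross-validation of the multinomial model
#'
#' Stratified (by outcome category) k-fold cross-validation, repeated with
#' reshuffled folds; reports per-fold held-out accuracy and its mean. The
#' confusion matrix and the accuracy binomial test come from whole-data
#' predictions of a final whole-data fit (mirroring training the model and
#' then predicting the responses using the whole data). A fold whose
#' training split misses a category is fitted without it (that category is
#' then never predicted in the fold) with a warning.
#'
#' @param features Trial-by-predictor matrix.
#' @param outcomes Severity labels.
#' @param reference Reference category.
#' @param k Number of folds (default 10).
#' @param repeats Number of repeats (default 5).
#' @param seed Integer seed controlling fold assignment.
#' @return List with `fold_accuracies`, `mean_accuracy`,
#'   `whole_data_accuracy`, `no_information_rate`, `binomial_p`, `confusion`
#'   (true x predicted counts), and the final `model`.
#' @export
cross_validate <- function(features, outcomes, reference, k = 10L,
                           repeats = 5L, seed = 1L) {
  features <- as.matrix(features)
  outcomes <- factor(outcomes)
  n <- length(outcomes)
  if (k < 2) stop("`k` must be >= 2")
  if (n < k) stop("fewer observations than folds")
  acc <- numeric(0)
  withr::with_seed(seed, {
    for (rep_i in seq_len(repeats)) {
      fold <- stratified_folds(outcomes, k)
      for (f in seq_len(k)) {
        test <- fold == f
        if (!any(test) || length(unique(outcomes[!test])) < 2) next
        train_out <- droplevels(outcomes[!test])
        ref_f <- if (reference %in% levels(train_out)) reference else
          names(which.max(table(train_out)))
        fit <- suppressWarnings(
          fit_multinomial(features[!test, , drop = FALSE], train_out, ref_f))
        pred <- predict_category(fit, features[test, , drop = FALSE])
        acc <- c(acc, mean(pred == as.character(outcomes[test])))
      }
    }
  })
  final <- suppressWarnings(fit_multinomial(features, outcomes, reference))
  pred_all <- predict_category(final, features)
  levs <- levels(outcomes)
  confusion <- table(true = factor(as.character(outcomes), levels = levs),
                     predicted = factor(pred_all, levels = levs))
  n_correct <- sum(diag(confusion))
  nir <- max(table(outcomes)) / n
  list(fold_accuracies = acc,
       mean_accuracy = mean(acc),
       whole_data_accuracy = n_correct / n,
       no_information_rate = nir,
       binomial_p = accuracy_binomial_test(n_correct, n, nir),
       confusion = unclass(confusion),
       model = final)
}
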