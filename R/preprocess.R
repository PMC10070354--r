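#' Temporal filter specification
#'
#' Defines the infra-slow band-pass (0.01-0.1 Hz by default) or the
#' high-pass-only control variant. Cutoffs must respect the Nyquist frequency
#' `1/(2*tr)`.
#'
#' @param low_cut Lower cutoff in Hz, or `NULL` for no high-pass.
#' @param high_cut Upper cutoff in Hz, or `NULL` for no low-pass.
#' @param tr Sampling interval (repetition time) in seconds.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(low_cut = 0.01, high_cut = 0.1, tr = 2) {
  if (is.null(low_cut) && is.null(high_cut))
    stop("at least one of `low_cut`, `high_cut` must be set")
  nyq <- 1 / (2 * tr)
  for (f in c(low_cut, high_cut)) {
    if (!is.finite(f) || f <= 0 || f >= nyq)
      stop("cutoff ", f, " Hz violates 0 < f < Nyquist (", nyq, " Hz)")
  }
  if (!is.null(low_cut) && !is.null(high_cut) && low_cut >= high_cut)
    stop("`low_cut` must be below `high_cut`")
  structure(list(low_cut = low_cut, high_cut = high_cut, tr = tr),
            class = "filter_spec")
}

butter_filter <- function(spec) {
  nyq <- 1 / (2 * spec$tr)
  if (!is.null(spec$low_cut) && !is.null(spec$high_cut)) {
    signal::butter(2, c(spec$low_cut, spec$high_cut) / nyq, type = "pass")
  } else if (is.null(spec$high_cut)) {
    signal::butter(2, spec$low_cut / nyq, type = "high")
  } else {
    signal::butter(2, spec$high_cut / nyq, type = "low")
  }
}

filtfilt_padded <- function(bf, x, pad = 100L) {
  n <- length(x)
  p <- min(as.integer(pad), n - 1L)
  xp <- c(rev(x[2:(p + 1)]), x, rev(x[(n - p):(n - 1)]))
  y <- signal::filtfilt(bf, xp)
  y[(p + 1):(p + n)]
}

#' Zero-phase temporal filtering
#'
#' Forward-backward (zero-phase) Butterworth filter, order 2 per pass, with
#' reflect padding of up to 100 samples to suppress edge transients. Pass-band
#' amplitude is preserved within 5% and one octave beyond the cutoff the
#' amplitude is attenuated by more than 90%.
#'
#' @param x Numeric vector (one time series), a time-by-series matrix, or a
#'   [bold_dataset()] (filtered voxelwise).
#' @param spec A [filter_spec()].
#' @return Filtered object of the same shape/class as `x`.
#' @export
temporal_filter <- function(x, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  bf <- butter_filter(spec)
  filt1 <- function(v) {
    if (length(v) < 16L)
      stop("series too short to filter (length ", length(v), " < 16)")
    filtfilt_padded(bf, v)
  }
  if (inherits(x, "bold_dataset")) {
    m <- voxel_matrix(x)
    out <- t(apply(m, 1L, filt1))
    return(bold_dataset(array(out, dim(x$data)), x$affine, x$tr, x$mask))
  }
  if (is.matrix(x)) return(apply(x, 2L, filt1))
  filt1(as.numeric(x))
}

#' Regress nuisance signals out of a time series
#'
#' Least-squares residual of the series after projecting out the regressor
#' columns plus an intercept. Collinear (rank-deficient) regressor columns are
#' dropped with a warning. The residual is orthogonal to every retained
#' regressor column.
#'
#' @param series Numeric vector.
#' @param regressors Numeric matrix, one column per regressor, rows matching
#'   `series`.
#' @return Residual series (numeric vector).
#' @export
nuisance_regress <- function(series, regressors) {
  regressors <- as.matrix(regressors)
  if (nrow(regressors) != length(series))
    stop("regressor rows (", nrow(regressors), ") do not match series length (",
         length(series), ")")
  X <- cbind(intercept = 1, regressors)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    warning("dropping ", ncol(X) - qx$rank,
            " collinear regressor column(s) before projection")
  as.numeric(qr.resid(qx, series))
}

#' Global signal regression (GSR)
#'
#' Replaces every voxel series by its residual after regressing out the global
#' signal (plus an intercept). Used as a control: on GSR-processed data every
#' region's GSCORR against the regressed signal drops to zero (exact OLS
#' orthogonality), so any surviving group difference cannot be carried by the
#' global component.
#'
#' @param bold A [bold_dataset()].
#' @param gs Global signal, length `n_volumes(bold)`.
#' @return A [bold_dataset()] of residuals.
#' @export
global_signal_regression <- function(bold, gs) {
  if (length(gs) != n_volumes(bold))
    stop("`gs` length (", length(gs), ") does not match number of volumes (",
         n_volumes(bold), ")")
  if (sd(gs) == 0) stop("global signal is constant; cannot regress")
  Q <- qr.Q(qr(cbind(1, gs)))
  M <- voxel_matrix(bold)
  R <- M - (M %*% Q) %*% t(Q)
  bold_dataset(array(R, dim(bold$data)), bold$affine, bold$tr, bold$mask)
}

#' Discard initial volumes
#'
#' Drops the first `n` volumes (magnetisation-equilibration scans); affine,
#' TR and mask are unchanged.
#'
#' @param bold A [bold_dataset()].
#' @param n Number of volumes to discard (default 2).
#' @return A [bold_dataset()] with `n_volumes(bold) - n` volumes.
#' @export
discard_initial_volumes <- function(bold, n = 2L) {
  n <- as.integer(n)
  if (n < 0L) stop("`n` must be non-negative")
  tt <- n_volumes(bold)
  if (n >= tt)
    stop("cannot discard ", n, " volumes from a ", tt, "-volume dataset")
  if (n == 0L) return(bold)
  bold_dataset(bold$data[, , , (n + 1L):tt, drop = FALSE],
               bold$affine, bold$tr, bold$mask)
}
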