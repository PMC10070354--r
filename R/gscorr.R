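#' Extract the global signal
#'
#' The global signal (GS) is the per-volume mean BOLD signal over gray-matter
#' voxels.
#'
#' @param bold A [bold_dataset()].
#' @param gm_mask Optional 3D logical array; defaults to the dataset's mask.
#' @return Numeric vector of length `n_volumes(bold)`.
#' @export
extract_global_signal <- function(bold, gm_mask = NULL) {
  if (is.null(gm_mask)) gm_mask <- bold$mask
  if (!all(dim(gm_mask) == dim(bold$data)[1:3]))
    stop("`gm_mask` grid does not match the BOLD grid")
  sel <- as.vector(gm_mask)
  if (!any(sel)) stop("gray-matter mask is empty")
  colMeans(voxel_matrix(bold)[sel, , drop = FALSE])
}

#' Fisher-z global signal correlation (GSCORR)
#'
#' Pearson correlation between a region's time series and the global signal,
#' followed by the Fisher z-transform `z = atanh(rho)`. `rho` is clipped to
#' `+/-(1 - 1e-12)` before the transform so that perfectly correlated series
#' yield a large finite value instead of infinity.
#'
#' @param x Region (or voxel) time series.
#' @param gs Global signal of the same length.
#' @return List with elements `rho` and `z`.
#' @export
compute_gscorr <- function(x, gs) {
  if (length(x) != length(gs))
    stop("series lengths differ (", length(x), " vs ", length(gs), ")")
  if (length(x) < 3L) stop("series must have length >= 3")
  if (sd(x) == 0 || sd(gs) == 0)
    stop("constant series; correlation undefined")
  rho <- cor(x, gs)
  clipped <- max(min(rho, 1 - 1e-12), -(1 - 1e-12))
  list(rho = rho, z = atanh(clipped))
}

#' Layer GSCORR table for one subject
#'
#' Computes GSCORR for each compound self layer against the global signal.
#'
#' @param bold A [bold_dataset()] (already temporally preprocessed).
#' @param layers List of [layer_definition()]s; defaults to
#'   [default_self_layers()]. Pairwise disjointness is enforced.
#' @param gs Optional global signal; extracted from `bold` when `NULL`.
#' @return A tibble with columns `layer`, `n_voxels`, `rho`, `z`.
#' @export
layer_gscorr <- function(bold, layers = default_self_layers(), gs = NULL) {
  gd <- dim(bold$data)[1:3]
  masks <- assert_disjoint_layers(layers, gd, bold$affine)
  if (is.null(gs)) gs <- extract_global_signal(bold)
  M <- voxel_matrix(bold)
  rows <- lapply(names(masks), function(nm) {
    ts <- colMeans(M[as.vector(masks[[nm]]), , drop = FALSE])
    g <- compute_gscorr(ts, gs)
    tibble::tibble(layer = nm, n_voxels = sum(masks[[nm]]),
                   rho = g$rho, z = g$z)
  })
  do.call(rbind, rows)
}

#' Parcelwise GSCORR map
#'
#' For every nonzero label in a parcellation volume, averages the BOLD signal
#' over the parcel's voxels and computes GSCORR against the global signal.
#'
#' @param bold A [bold_dataset()].
#' @param labels 3D integer array on the same grid (0 = background).
#' @param gs Optional global signal; extracted from `bold` when `NULL`.
#' @param expected_labels Optional integer vector; labels in this set that are
#'   absent from the volume are reported with a warning and skipped.
#' @return A tibble with columns `region`, `n_voxels`, `rho`, `z`.
#' @export
parcel_gscorr_map <- function(bold, labels, gs = NULL, expected_labels = NULL) {
  if (!all(dim(labels) == dim(bold$data)[1:3]))
    stop("`labels` grid does not match the BOLD grid")
  lab <- as.vector(labels)
  present <- sort(unique(lab[lab != 0]))
  if (!length(present)) stop("label volume contains no nonzero labels")
  if (!is.null(expected_labels)) {
    absent <- setdiff(expected_labels, present)
    if (length(absent))
      warning("label(s) absent from volume, skipped: ",
              paste(absent, collapse = ", "))
  }
  M <- voxel_matrix(bold)
  if (is.null(gs)) gs <- extract_global_signal(bold)
  sel <- lab != 0
  sums <- rowsum(M[sel, , drop = FALSE], group = lab[sel])
  counts <- as.integer(table(lab[sel]))
  means <- sums / counts
  rows <- lapply(seq_along(present), function(i) {
    g <- compute_gscorr(means[i, ], gs)
    tibble::tibble(region = present[i], n_voxels = counts[i],
                   rho = g$rho, z = g$z)
  })
  do.call(rbind, rows)
}
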