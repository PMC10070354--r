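#' Spherical ROI specification
#'
#' @param name Region label.
#' @param center MNI mm coordinates (length-3 numeric).
#' @param radius Sphere radius in mm (default 8).
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(name, center, radius = 8) {
  center <- as.numeric(center)
  if (length(center) != 3L || any(!is.finite(center)))
    stop("`center` must be three finite MNI mm coordinates")
  if (!is.numeric(radius) || radius <= 0) stop("`radius` must be > 0")
  structure(list(name = name, center = center, radius = radius),
            class = "roi_spec")
}

#' Self-layer definition
#'
#' A named layer of the three-layer topography of self, given as a set of
#' spherical ROIs that are merged into one compound region.
#'
#' @param layer Layer name (`"interoceptive"`, `"exteroceptive"` or
#'   `"mental"`; other labels are allowed for custom systems).
#' @param rois List of [roi_spec()] objects.
#' @return An object of class `layer_definition`.
#' @export
layer_definition <- function(layer, rois) {
  if (!length(rois) || !all(vapply(rois, inherits, logical(1), "roi_spec")))
    stop("`rois` must be a non-empty list of roi_spec objects")
  structure(list(layer = layer, rois = rois), class = "layer_definition")
}

#' Default three-layer topography of self
#'
#' The six meta-analytic self-processing coordinates used throughout the
#' package: bilateral insula (interoceptive), right TPJ and MPFC
#' (exteroceptive), PCC and pACC (mental), each an 8 mm sphere. At this radius
#' the compiled layers are pairwise disjoint on common grids, which
#' [assert_disjoint_layers()] verifies.
#'
#' @param radius Sphere radius in mm.
#' @return Named list of three [layer_definition()] objects.
#' @export
default_self_layers <- function(radius = 8) {
  list(
    interoceptive = layer_definition("interoceptive", list(
      roi_spec("R_Insula", c(34, 14, 12), radius),
      roi_spec("L_Insula", c(-40, -2, 2), radius)
    )),
    exteroceptive = layer_definition("exteroceptive", list(
      roi_spec("R_TPJ", c(-48, -38, 36), radius),
      roi_spec("MPFC", c(-6, 60, 22), radius)
    )),
    mental = layer_definition("mental", list(
      roi_spec("PCC", c(-4, -54, 28), radius),
      roi_spec("pACC", c(-6, 48, 0), radius)
    ))
  )
}

#' Compile a spherical ROI to a voxel mask
#'
#' A voxel belongs to the sphere when the Euclidean MNI distance from its
#' centre to the ROI centre is at most the radius (boundary inclusive).
#'
#' @param roi A [roi_spec()].
#' @param grid_dim Integer vector of 3 voxel counts.
#' @param affine 4x4 voxel-to-mm matrix.
#' @return 3D logical array.
#' @export
sphere_mask <- function(roi, grid_dim, affine) {
  xyz <- voxel_coordinates(grid_dim, affine)
  d2 <- (xyz[, 1] - roi$center[1])^2 + (xyz[, 2] - roi$center[2])^2 +
    (xyz[, 3] - roi$center[3])^2
  m <- array(d2 <= roi$radius^2, grid_dim)
  if (!any(m))
    stop("ROI '", roi$name, "' compiles to an empty mask on this grid; ",
         "the grid does not cover its centre/radius")
  m
}

#' Compile a layer (union of its sphere masks) to a voxel mask
#'
#' @inheritParams sphere_mask
#' @param layer A [layer_definition()].
#' @return 3D logical array.
#' @export
layer_mask <- function(layer, grid_dim, affine) {
  masks <- lapply(layer$rois, sphere_mask, grid_dim = grid_dim, affine = affine)
  Reduce(`|`, masks)
}

#' Assert that compiled layers are pairwise disjoint
#'
#' The three-layer topography requires non-overlapping regions across layers;
#' overlap raises an error naming the offending pair.
#'
#' @param layers List of [layer_definition()] objects.
#' @inheritParams sphere_mask
#' @return Invisibly, the list of compiled masks (named by layer).
#' @export
assert_disjoint_layers <- function(layers, grid_dim, affine) {
  masks <- lapply(layers, layer_mask, grid_dim = grid_dim, affine = affine)
  names(masks) <- vapply(layers, `[[`, character(1), "layer")
  nm <- names(masks)
  if (length(masks) > 1) {
    for (i in seq_len(length(masks) - 1)) {
      for (j in seq((i + 1), length(masks))) {
        if (any(masks[[i]] & masks[[j]]))
          stop("layers '", nm[i], "' and '", nm[j],
               "' overlap on this grid; layers must be disjoint")
      }
    }
  }
  invisible(masks)
}

#' Mean time series of a compound layer ROI
#'
#' Unions the layer's sphere masks and averages the BOLD signal over the
#' resulting voxels, volume by volume.
#'
#' @param bold A [bold_dataset()].
#' @param layer A [layer_definition()].
#' @param other_layers Optional list of other [layer_definition()]s; when
#'   given, disjointness with `layer` is enforced before averaging.
#' @return Numeric vector of length `n_volumes(bold)`.
#' @export
layer_timeseries <- function(bold, layer, other_layers = NULL) {
  gd <- dim(bold$data)[1:3]
  if (!is.null(other_layers))
    assert_disjoint_layers(c(list(layer), other_layers), gd, bold$affine)
  m <- layer_mask(layer, gd, bold$affine)
  colMeans(voxel_matrix(bold)[as.vector(m), , drop = FALSE])
}
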