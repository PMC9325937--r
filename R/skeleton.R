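#' Skeletonize a binary mask
#'
#' Thins the bone mask to a one-voxel-thin, topology-preserving skeleton by
#' sequential directional thinning (26-connected foreground, 6-connected
#' background). Rod-like structures reduce to curves and plate-like
#' structures to one-voxel-thin sheets (a medial-surface-class skeleton);
#' curve endpoints are preserved, the volume faces are treated as background,
#' and branches may touch the faces. Deterministic: a fixed subiteration and
#' scan order. The number of 26-connected components is conserved exactly,
#' and the operation is idempotent.
#'
#' @param mask a non-empty [binary_mask()].
#' @return An object of class `skeleton3d` with fields `data` (logical
#'   array), `spacing` and `parent` (the input mask).
#' @export
skeletonize <- function(mask) {
  stopifnot(is_binary_mask(mask))
  if (!any(mask$data)) stop("cannot skeletonize an empty mask")
  skel <- .thin_skeleton_cpp(as.vector(mask$data), dim(mask$data))
  structure(
    list(data = array(skel, dim = dim(mask$data)), spacing = mask$spacing,
         origin = mask$origin, parent = mask),
    class = "skeleton3d"
  )
}

#' @rdname skeletonize
#' @param x object to test.
#' @export
is_skeleton3d <- function(x) inherits(x, "skeleton3d")

#' @export
print.skeleton3d <- function(x, ...) {
  cat(sprintf("<skeleton3d> %s voxels, %d skeleton voxels, %d node voxels\n",
              paste(dim(x$data), collapse = " x "), sum(x$data),
              count_node_voxels(x)))
  invisible(x)
}

#' Wrap an existing thin structure as a skeleton
#'
#' For fixtures and external skeletons; no thinning is applied.
#' @param data logical 3D array.
#' @param spacing voxel spacing in micrometres.
#' @param parent optional parent [binary_mask()].
#' @return A `skeleton3d`.
#' @export
as_skeleton3d <- function(data, spacing, parent = NULL) {
  storage.mode(data) <- "logical"
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = c(0, 0, 0), parent = parent),
            class = "skeleton3d")
}

#' Count node voxels (trabecular intersections) in a skeleton
#'
#' A skeleton voxel is classified as a node when the skeleton voxels in its
#' 26-neighbourhood split into at least three branches, where branches are
#' connected components of the neighbours under 6-adjacency (two branches
#' that merely touch diagonally are still distinct branches). Under this rule
#' a straight or diagonal line has no nodes, a "+" cross of two lines has
#' exactly one (its centre), an axis-aligned "Y" has one, and the interior of
#' a one-voxel sheet has none. Adjacent node voxels are not merged: the count
#' is the number of voxels classified as nodes.
#'
#' @param skel a `skeleton3d` (or [binary_mask()] already one voxel thin).
#' @return Integer node-voxel count (0 for an empty skeleton).
#' @export
count_node_voxels <- function(skel) {
  d <- skeleton_data(skel)
  sum(.node_mask_cpp(as.vector(d), dim(d)))
}

#' @rdname count_node_voxels
#' @return `node_voxel_mask()` returns the logical array of node voxels.
#' @export
node_voxel_mask <- function(skel) {
  d <- skeleton_data(skel)
  array(.node_mask_cpp(as.vector(d), dim(d)), dim = dim(d))
}

skeleton_data <- function(skel) {
  if (is_skeleton3d(skel) || is_binary_mask(skel)) skel$data
  else if (is.array(skel) && is.logical(skel)) skel
  else stop("expected a skeleton3d, binary_mask or logical array")
}

#' Invert a skeleton within its domain
#'
#' The boolean complement of the skeleton over the analysed volume, the
#' input for midline-spacing (Tb.Sc) computation.
#'
#' @param skel a `skeleton3d`.
#' @return A [binary_mask()] that is `TRUE` off the skeleton.
#' @export
invert_skeleton <- function(skel) {
  stopifnot(is_skeleton3d(skel))
  binary_mask(!skel$data, skel$spacing, skel$origin)
}

#' Label 26-connected components
#'
#' @param mask a [binary_mask()] or logical array.
#' @return Integer array of component labels (0 = background) with attribute
#'   `n_components`.
#' @export
label_components <- function(mask) {
  d <- skeleton_data(mask)
  lab <- .label_components_26_cpp(as.vector(d), dim(d))
  out <- array(as.integer(lab), dim = dim(d))
  attr(out, "n_components") <- attr(lab, "n_components")
  out
}

#' @rdname label_components
#' @export
count_components <- function(mask) {
  attr(label_components(mask), "n_components")
}
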