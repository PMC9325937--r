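#' Bone volume fraction (BVTV)
#'
#' The fraction of voxels in the analysed volume segmented as bone; the
#' full volume of interest is the denominator.
#'
#' @param mask a [binary_mask()].
#' @return Numeric fraction in \[0, 1\].
#' @export
bvtv <- function(mask) {
  stopifnot(is_binary_mask(mask))
  sum(mask$data) / length(mask$data)
}

#' 3D local thickness map by sphere fitting
#'
#' For every foreground voxel, the diameter (mm) of the largest sphere fully
#' contained in the foreground that covers the voxel. Implemented as an exact
#' Euclidean distance transform followed by sphere marking in order of
#' decreasing radius: a sphere centred at q has radius equal to the distance
#' from q to the nearest background voxel centre, coverage of p is decided at
#' voxel centres (`||p - q|| < r(q)`), and the local value is the largest
#' covering diameter `2 r(q)`. This is the standard sphere-fitting local
#' thickness; a two-voxel plate maps to two voxel widths.
#'
#' The volume faces are treated as background, consistently with the
#' skeletonization border policy: the distance transform is capped by the
#' distance to the first voxel layer outside the grid, so face-touching
#' structures read as cropped rather than as extending past the face.
#'
#' Requires isotropic voxels (resample first with [resample_isotropic()]).
#'
#' @param mask a non-empty [binary_mask()] with isotropic spacing.
#' @return A `local_map`: list with `values` (3D array, mm; `NA` off support),
#'   `support` (logical array) and `spacing`.
#' @export
local_thickness <- function(mask) {
  stopifnot(is_binary_mask(mask))
  sp <- mask$spacing
  if (diff(range(sp)) > 1e-9 * max(sp))
    stop("local thickness requires isotropic voxels; resample the volume ",
         "with resample_isotropic() first")
  if (!any(mask$data)) stop("empty mask has no thickness map")
  dims <- dim(mask$data)
  # squared EDT in voxel units (isotropic): spacing 1, scaled to mm afterwards
  edt2 <- .edt_sq_cpp(as.vector(mask$data), dims, c(1, 1, 1))
  edt2 <- pmin(edt2, as.vector(face_distance_vox(dims))^2)
  th_vox <- .local_thickness_vox_cpp(edt2, dims)
  h_mm <- sp[1] / 1000
  values <- array(ifelse(th_vox > 0, th_vox * h_mm, NA_real_), dim = dims)
  structure(
    list(values = values, support = mask$data, spacing = sp),
    class = "local_map"
  )
}

# distance (voxel units) from each voxel centre to the nearest voxel centre
# outside the grid; the faces count as background
face_distance_vox <- function(dims) {
  ax <- function(n) pmin(seq_len(n), n + 1L - seq_len(n))
  dx <- ax(dims[1]); dy <- ax(dims[2]); dz <- ax(dims[3])
  outer(outer(dx, dy, pmin), dz, pmin)
}

#' @export
print.local_map <- function(x, ...) {
  v <- x$values[x$support]
  cat(sprintf("<local_map> %d support voxels, mean %.4f mm, sd %.4f mm\n",
              sum(x$support), mean(v), stats::sd(v)))
  invisible(x)
}

#' Mean and dispersion of a local map
#'
#' The volume mean and the intra-volume dispersion of a 3D local map,
#' computed over the support voxels only. The dispersion `s(.)` is the
#' population standard deviation of the local map, reported alongside the
#' mean in the parameter tables.
#'
#' @param map a `local_map` from [local_thickness()], [tb_sp()] or [tb_sc()].
#' @return Named numeric vector `c(mean = ..., sd = ...)` in mm.
#' @export
tb_th_stats <- function(map) {
  stopifnot(inherits(map, "local_map"))
  v <- map$values[map$support]
  if (length(v) == 0L) stop("local map has empty support")
  m <- mean(v)
  c(mean = m, sd = sqrt(mean((v - m)^2)))
}

#' Trabecular separation (Tb.Sp)
#'
#' The minimum edge-to-edge distance between neighbouring trabeculae:
#' the local thickness of the inverted segmentation mask, with statistics
#' over the background voxels.
#'
#' @param mask the bone [binary_mask()].
#' @return A list with `map` (the background `local_map`), `mean` and `sd`
#'   (mm).
#' @export
tb_sp <- function(mask) {
  stopifnot(is_binary_mask(mask))
  if (all(mask$data)) stop("full mask: no background to measure separation on")
  inv <- binary_mask(!mask$data, mask$spacing, mask$origin)
  map <- local_thickness(inv)
  st <- tb_th_stats(map)
  list(map = map, mean = unname(st["mean"]), sd = unname(st["sd"]))
}

#' Trabecular spacing (Tb.Sc)
#'
#' The minimum midline-to-midline distance between neighbouring trabeculae:
#' the local thickness of the complement of the bone skeleton (the centres of
#' the bone structures), with statistics over that complement. Unlike the
#' more common trabecular number Tb.N (its reciprocal), Tb.Sc shares its unit
#' (mm) with Tb.Th and Tb.Sp. When the skeleton is a single structure with no
#' intersections there is no neighbouring midline and the value is governed
#' by the domain size; a warning flags that case.
#'
#' @param mask the bone [binary_mask()].
#' @param skel the `skeleton3d` derived from `mask` (computed if `NULL`).
#' @return A list with `map`, `mean` and `sd` (mm).
#' @export
tb_sc <- function(mask, skel = NULL) {
  stopifnot(is_binary_mask(mask))
  if (is.null(skel)) skel <- skeletonize(mask)
  stopifnot(is_skeleton3d(skel))
  if (!any(skel$data)) stop("empty skeleton")
  if (count_components(skel$data) == 1L && count_node_voxels(skel) == 0L)
    warning("skeleton is a single structure with no intersections; ",
            "Tb.Sc is governed by the domain size")
  inv <- invert_skeleton(skel)
  map <- local_thickness(inv)
  st <- tb_th_stats(map)
  list(map = map, mean = unname(st["mean"]), sd = unname(st["sd"]))
}

#' Trabecular node density (Tb.Nd)
#'
#' The number of skeleton voxels classified as nodes (intersections of the
#' trabecular network, see [count_node_voxels()]) divided by the analysed
#' volume in cubic millimetres.
#'
#' @param skel a `skeleton3d`.
#' @param domain_volume_mm3 analysed volume in mm^3; defaults to the full
#'   grid volume.
#' @return Nodes per mm^3.
#' @export
tb_nd <- function(skel, domain_volume_mm3 = NULL) {
  stopifnot(is_skeleton3d(skel))
  if (is.null(domain_volume_mm3))
    domain_volume_mm3 <- prod(dim(skel$data)) * prod(skel$spacing / 1000)
  if (domain_volume_mm3 <= 0) stop("domain volume must be positive")
  count_node_voxels(skel) / domain_volume_mm3
}

#' Contrast-to-noise ratio (CNR)
#'
#' The difference in mean intensity between foreground and background divided
#' by the standard deviation of the background, with the skeletonised bone as
#' the foreground signal and the skeletonised water (background) as the
#' background signal. Measuring on the skeletons keeps both samples away from
#' partial-volume voxels at the bone-water interface.
#'
#' @param vol the grayscale [image_volume()].
#' @param bone_skel `skeleton3d` of the bone mask.
#' @param water_skel `skeleton3d` of the background (complement) mask.
#' @return Unitless CNR.
#' @export
cnr <- function(vol, bone_skel, water_skel) {
  stopifnot(is_image_volume(vol), is_skeleton3d(bone_skel),
            is_skeleton3d(water_skel))
  if (!identical(dim(vol$data), dim(bone_skel$data)) ||
      !identical(dim(vol$data), dim(water_skel$data)))
    stop("volume and skeleton grids differ")
  if (!any(bone_skel$data) || !any(water_skel$data))
    stop("both skeletons must be non-empty")
  fgv <- vol$data[bone_skel$data]
  bgv <- vol$data[water_skel$data]
  s <- stats::sd(bgv)
  if (!is.finite(s) || s == 0) stop("background skeleton has zero intensity SD")
  (mean(fgv) - mean(bgv)) / s
}

#' Full structure-parameter set for one volume
#'
#' Computes the eight structure parameters and CNR from the binary segmented
#' data of a single volume: BVTV, Tb.Th and s(Tb.Th), Tb.Sp and s(Tb.Sp),
#' Tb.Sc and s(Tb.Sc), Tb.Nd, and CNR. Each field equals the output of the
#' corresponding standalone operation on the same inputs. A warning (not an
#' error) is emitted when Tb.Sc < Tb.Th, which is not expected for physical
#' specimens.
#'
#' @param vol the grayscale [image_volume()] (used for CNR; may be `NULL`, in
#'   which case CNR is `NA`).
#' @param mask the segmented [binary_mask()].
#' @param skel optional precomputed bone `skeleton3d`.
#' @return A one-row data frame of class `morphometry_result` with columns
#'   `bvtv`, `tb_th`, `s_tb_th`, `tb_sp`, `s_tb_sp`, `tb_sc`, `s_tb_sc`,
#'   `tb_nd`, `cnr`.
#' @export
measure_volume <- function(vol, mask, skel = NULL) {
  stopifnot(is_binary_mask(mask))
  if (!any(mask$data)) stop("empty bone mask: no structure to measure")
  if (is.null(skel)) skel <- skeletonize(mask)

  th_map <- local_thickness(mask)
  th <- tb_th_stats(th_map)
  sp <- tb_sp(mask)
  sc <- tb_sc(mask, skel)
  nd <- tb_nd(skel)

  cnr_val <- NA_real_
  if (!is.null(vol)) {
    stopifnot(is_image_volume(vol))
    water_skel <- skeletonize(binary_mask(!mask$data, mask$spacing, mask$origin))
    cnr_val <- cnr(vol, skel, water_skel)
  }

  res <- data.frame(
    bvtv = bvtv(mask),
    tb_th = unname(th["mean"]), s_tb_th = unname(th["sd"]),
    tb_sp = sp$mean, s_tb_sp = sp$sd,
    tb_sc = sc$mean, s_tb_sc = sc$sd,
    tb_nd = nd,
    cnr = cnr_val
  )
  if (res$tb_sc < res$tb_th)
    warning("Tb.Sc < Tb.Th; unexpected for a physical trabecular structure")
  class(res) <- c("morphometry_result", "data.frame")
  res
}

#' Colour-grade a local map for display
#'
#' Maps local values over \[min, max\] of the map to a blue-green-red ramp:
#' the minimum is pure blue, the midpoint pure green and the maximum pure
#' red. Off-support voxels get `NA`.
#'
#' @param map a `local_map`.
#' @return A 4D numeric array `dim x 3` with RGB channels in \[0, 1\].
#' @export
render_local_map <- function(map) {
  stopifnot(inherits(map, "local_map"))
  v <- map$values
  rng <- range(v[map$support])
  if (rng[1] == rng[2]) {
    warning("constant local map: rendering all green")
    t <- array(0.5, dim = dim(v))
  } else {
    t <- (v - rng[1]) / (rng[2] - rng[1])
  }
  # blue (0) -> green (0.5) -> red (1)
  r <- pmax(0, 2 * t - 1)
  g <- 1 - abs(2 * t - 1)
  b <- pmax(0, 1 - 2 * t)
  out <- array(NA_real_, dim = c(dim(v), 3L))
  out[, , , 1] <- ifelse(map$support, r, NA_real_)
  out[, , , 2] <- ifelse(map$support, g, NA_real_)
  out[, , , 3] <- ifelse(map$support, b, NA_real_)
  out
}

#' Segment and measure one scan end to end
#'
#' Convenience pipeline for a single acquired volume: resample to isotropic
#' voxels if needed (cubic interpolation to the coarsest spacing component by
#' default), segment (Otsu for reference-quality data, automated region
#' growing for clinical data), skeletonize, and compute the full parameter
#' set.
#'
#' @param vol an [image_volume()].
#' @param method `"otsu"` or `"arg"`.
#' @param target_spacing isotropic spacing in micrometres for resampling;
#'   default `max(vol$spacing)`.
#' @param config an [arg_config()] for `method = "arg"`.
#' @return A list with `result` (a `morphometry_result`), `mask`, `skeleton`
#'   and `report`.
#' @export
analyze_scan <- function(vol, method = c("arg", "otsu"), target_spacing = NULL,
                         config = arg_config()) {
  method <- match.arg(method)
  stopifnot(is_image_volume(vol))
  if (diff(range(vol$spacing)) > 1e-9 * max(vol$spacing)) {
    if (is.null(target_spacing)) target_spacing <- max(vol$spacing)
    vol <- resample_isotropic(vol, target_spacing)
  } else if (!is.null(target_spacing) &&
             abs(target_spacing - vol$spacing[1]) > 1e-9) {
    vol <- resample_isotropic(vol, target_spacing)
  }
  seg <- if (method == "otsu") otsu_segment(vol) else arg_segment(vol, config)
  skel <- skeletonize(seg$mask)
  res <- measure_volume(vol, seg$mask, skel)
  list(result = res, mask = seg$mask, skeleton = skel, report = seg$report)
}
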