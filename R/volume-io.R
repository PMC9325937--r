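#' 3D image volume with voxel spacing
#'
#' The unit all pipeline stages consume: a 3D scalar grid with anisotropic
#' voxel spacing and an origin, both in micrometres. Voxel indices are
#' 0-based in physical arithmetic; a voxel centre sits at
#' `origin + index * spacing` (voxel-centre convention).
#'
#' @param data numeric 3D array of intensities (arbitrary units).
#' @param spacing numeric length-3, voxel spacing (dx, dy, dz) in micrometres;
#'   all components must be positive.
#' @param origin numeric length-3, physical position of voxel (0,0,0) in
#'   micrometres.
#' @return An object of class `image_volume` with fields `data`, `spacing`,
#'   `origin`.
#' @export
image_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive values (micrometres)")
  if (any(dim(data) < 1L)) stop("all grid dimensions must be >= 1")
  structure(
    list(data = data, spacing = spacing, origin = as.numeric(origin)),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf(
    "<image_volume> %s voxels, spacing (%.6g, %.6g, %.6g) um\n",
    paste(dim(x$data), collapse = " x "),
    x$spacing[1], x$spacing[2], x$spacing[3]
  ))
  invisible(x)
}

#' @rdname image_volume
#' @param x object to test.
#' @export
is_image_volume <- function(x) inherits(x, "image_volume")

#' Binary mask over a volume grid
#'
#' @param data logical 3D array; `TRUE` marks bone (foreground).
#' @param spacing voxel spacing in micrometres, inherited from the source
#'   volume.
#' @param origin physical origin in micrometres.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, spacing, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  storage.mode(data) <- "logical"
  if (anyNA(data)) stop("mask may not contain NA")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive values (micrometres)")
  structure(
    list(data = data, spacing = spacing, origin = as.numeric(origin)),
    class = "binary_mask"
  )
}

#' @rdname binary_mask
#' @param x object to test.
#' @export
is_binary_mask <- function(x) inherits(x, "binary_mask")

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf(
    "<binary_mask> %s voxels, %d foreground (%.3f), spacing (%g, %g, %g) um\n",
    paste(dim(x$data), collapse = " x "), sum(x$data),
    mean(x$data), x$spacing[1], x$spacing[2], x$spacing[3]
  ))
  invisible(x)
}

#' Rigid transform (rotation + translation)
#'
#' Represents an externally supplied rigid registration between two scanner
#' coordinate frames, mapping source physical coordinates to reference
#' physical coordinates as `x_ref = R x_src + t`.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1 (checked to
#'   1e-9).
#' @param translation_um numeric length-3 translation in micrometres.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation_um = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be orthonormal with determinant +1")
  structure(
    list(rotation = rotation, translation_um = as.numeric(translation_um)),
    class = "rigid_transform"
  )
}

#' Read a rigid transform from JSON
#'
#' The file holds `rotation` (9 numbers, row-major) and `translation_um`
#' (3 numbers).
#'
#' @param path JSON file path.
#' @return A [rigid_transform()].
#' @export
read_transform <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(matrix(j$rotation, 3, 3, byrow = TRUE), j$translation_um)
}

#' @rdname read_transform
#' @param transform a [rigid_transform()].
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(
    list(rotation = as.vector(t(transform$rotation)),
         translation_um = transform$translation_um),
    path, auto_unbox = FALSE, digits = NA
  )
  invisible(path)
}

guess_format <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) return("nifti")
  if (grepl("\\.mhd$", lp)) return("mhd")
  if (grepl("\\.(tif|tiff)$", lp)) return("tiff_stack")
  stop("cannot guess volume format from path: ", path)
}

#' Read a CT volume with spacing metadata
#'
#' Supported formats: NIfTI (`.nii`/`.nii.gz`, spacing from pixdim, stored in
#' micrometres), MetaImage (`.mhd` text header + `.raw`), and multi-page TIFF
#' stacks with a YAML sidecar (same path with extension `.yaml`) holding
#' `spacing_um: [dx, dy, dz]`. Intensities are returned unmodified; volumes
#' are normalized to the internal x-fastest / z-slowest layout.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"nifti"`, `"mhd"`, `"tiff_stack"`.
#' @param spacing optional numeric length-3 spacing override in micrometres
#'   (required for TIFF stacks without a sidecar).
#' @return An [image_volume()].
#' @export
read_volume <- function(path, format = c("auto", "nifti", "mhd", "tiff_stack"),
                        spacing = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "auto") format <- guess_format(path)
  switch(format,
    nifti = read_nifti_volume(path, spacing),
    mhd = read_mhd_volume(path, spacing),
    tiff_stack = read_tiff_volume(path, spacing)
  )
}

#' Write a CT volume
#'
#' The on-disk spacing round-trips bit-exactly for all formats: NIfTI stores
#' spacing in micrometres in pixdim (units declared as "um"), MetaImage in
#' ElementSpacing, TIFF stacks in the YAML sidecar. NIfTI and MetaImage store
#' doubles, so grid values round-trip exactly; TIFF pages hold 32-bit floats
#' scaled to \[0, 1\] (offset and range recorded in the sidecar), so values
#' round-trip to single precision (~1e-7 relative).
#'
#' @param vol an [image_volume()].
#' @param path destination path; format guessed from the extension unless
#'   given.
#' @param format one of `"auto"`, `"nifti"`, `"mhd"`, `"tiff_stack"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path,
                         format = c("auto", "nifti", "mhd", "tiff_stack")) {
  stopifnot(is_image_volume(vol) || is_binary_mask(vol))
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  data <- vol$data
  storage.mode(data) <- "double"
  switch(format,
    nifti = {
      img <- RNifti::asNifti(data)
      RNifti::pixdim(img) <- vol$spacing
      RNifti::pixunits(img) <- c("um", "s")
      RNifti::writeNifti(img, path)
    },
    mhd = write_mhd_volume(data, vol$spacing, vol$origin, path),
    tiff_stack = {
      # TIFF pages hold 32-bit floats in [0,1]; the affine map back to the
      # original intensity range lives in the sidecar
      lo <- min(data)
      rng <- max(data) - lo
      scaled <- if (rng > 0) (data - lo) / rng else data * 0
      slices <- lapply(seq_len(dim(data)[3]), function(k) scaled[, , k])
      tiff::writeTIFF(slices, path, bits.per.sample = 32L, reduce = FALSE)
      yaml::write_yaml(
        list(spacing_um = as.numeric(vol$spacing),
             origin_um = as.numeric(vol$origin),
             intensity_offset = lo, intensity_range = rng),
        sidecar_path(path)
      )
    }
  )
  invisible(path)
}

sidecar_path <- function(path) paste0(sub("\\.(tif|tiff)$", "", path, ignore.case = TRUE), ".yaml")

read_nifti_volume <- function(path, spacing = NULL) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected a 3D NIfTI volume: ", path)
  data <- array(as.double(img), dim = dim(img))
  sp <- if (is.null(spacing)) RNifti::pixdim(img) else spacing
  if (any(sp <= 0))
    stop("non-positive spacing in NIfTI header of ", path,
         " and no override supplied")
  image_volume(data, sp)
}

read_tiff_volume <- function(path, spacing = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  data <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) data[, , k] <- pages[[k]]
  origin <- c(0, 0, 0)
  sc <- sidecar_path(path)
  y <- if (file.exists(sc)) yaml::read_yaml(sc) else NULL
  if (is.null(spacing)) {
    if (is.null(y))
      stop("TIFF stack ", path, " has no spacing: supply `spacing` or a ",
           "sidecar YAML at ", sc)
    spacing <- as.numeric(y$spacing_um)
  }
  if (!is.null(y$origin_um)) origin <- as.numeric(y$origin_um)
  if (!is.null(y$intensity_range))
    data <- data * y$intensity_range + y$intensity_offset
  image_volume(data, spacing, origin)
}

# --- MetaImage (MHD + RAW): trivial key = value text header ----------------

mhd_types <- c(
  MET_DOUBLE = "double", MET_FLOAT = "double", MET_SHORT = "integer",
  MET_USHORT = "integer", MET_UCHAR = "integer", MET_CHAR = "integer",
  MET_INT = "integer", MET_UINT = "integer"
)
mhd_sizes <- c(
  MET_DOUBLE = 8L, MET_FLOAT = 4L, MET_SHORT = 2L, MET_USHORT = 2L,
  MET_UCHAR = 1L, MET_CHAR = 1L, MET_INT = 4L, MET_UINT = 4L
)

read_mhd_volume <- function(path, spacing = NULL) {
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines, "=", fixed = TRUE)
  kv <- kv[lengths(kv) == 2]
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  h <- stats::setNames(as.list(vals), keys)
  need <- function(k) {
    if (is.null(h[[k]])) stop("MHD header ", path, " is missing ", k)
    h[[k]]
  }
  if (as.integer(need("NDims")) != 3L) stop("expected NDims = 3 in ", path)
  dims <- as.integer(strsplit(need("DimSize"), "\\s+")[[1]])
  type <- need("ElementType")
  if (!type %in% names(mhd_types))
    stop("unsupported ElementType ", type, " in ", path)
  if (is.null(spacing)) {
    if (is.null(h$ElementSpacing))
      stop("MHD header ", path, " has no ElementSpacing and no override given")
    spacing <- as.numeric(strsplit(h$ElementSpacing, "\\s+")[[1]])
  }
  if (any(spacing <= 0)) stop("non-positive ElementSpacing in ", path)
  origin <- if (!is.null(h$Offset))
    as.numeric(strsplit(h$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  datafile <- need("ElementDataFile")
  if (identical(datafile, "LOCAL")) stop("inline MHD data not supported")
  rawpath <- file.path(dirname(path), datafile)
  if (!file.exists(rawpath)) stop("raw data file missing: ", rawpath)
  n <- prod(dims)
  signed <- !type %in% c("MET_UCHAR", "MET_USHORT", "MET_UINT")
  con <- file(rawpath, "rb")
  on.exit(close(con))
  vals <- readBin(
    con,
    what = if (mhd_types[[type]] == "double") "double" else "integer",
    n = n, size = mhd_sizes[[type]], signed = signed, endian = "little"
  )
  if (length(vals) != n) stop("raw file ", rawpath, " is truncated")
  image_volume(array(as.double(vals), dim = dims), spacing, origin)
}

write_mhd_volume <- function(data, spacing, origin, path) {
  rawname <- paste0(sub("\\.mhd$", "", basename(path)), ".raw")
  header <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    sprintf("DimSize = %s", paste(dim(data), collapse = " ")),
    sprintf("ElementSpacing = %s", paste(format(spacing, digits = 17), collapse = " ")),
    sprintf("Offset = %s", paste(format(origin, digits = 17), collapse = " ")),
    "ElementType = MET_DOUBLE",
    sprintf("ElementDataFile = %s", rawname)
  )
  writeLines(header, path)
  con <- file(file.path(dirname(path), rawname), "wb")
  on.exit(close(con))
  writeBin(as.vector(data), con, size = 8L, endian = "little")
  invisible(path)
}

#' Resample a volume to an isotropic grid
#'
#' Clinical volumes with overlapping thick slices are resampled to isotropic
#' voxels (the study workflow downsamples to the slice increment) before
#' sphere-fitting morphometry, using separable cubic interpolation by
#' default. The output grid covers the same physical extent (within one
#' target voxel), with cell-aligned voxel centres and mirror boundary
#' handling. Cubic overshoot is left unclipped, since downstream segmentation
#' is threshold-based and clipping would bias the background noise
#' distribution used for CNR.
#'
#' @param vol an [image_volume()].
#' @param target_spacing isotropic output voxel size in micrometres.
#' @param order interpolation order: 0 (nearest), 1 (trilinear) or 3 (cubic,
#'   default).
#' @return An [image_volume()] with spacing `(t, t, t)`.
#' @export
resample_isotropic <- function(vol, target_spacing, order = 3L) {
  stopifnot(is_image_volume(vol))
  if (!is.numeric(target_spacing) || length(target_spacing) != 1L ||
      target_spacing <= 0)
    stop("`target_spacing` must be a single positive value (micrometres)")
  order <- check_order(order)
  din <- dim(vol$data)
  extent <- din * vol$spacing
  dout <- pmax(1L, as.integer(round(extent / target_spacing)))
  if (any(extent < target_spacing / 2))
    stop("target spacing is coarser than the whole volume")
  # cell-space map: centre of output voxel j lies at (j + 0.5) * t in units of
  # the shared corner-anchored physical axis
  A <- diag(target_spacing / vol$spacing)
  b <- 0.5 * target_spacing / vol$spacing - 0.5
  res <- .sample_affine_cpp(as.double(vol$data), din, A, b, dout, order)
  image_volume(array(res, dim = dout),
               rep(target_spacing, 3),
               vol$origin + 0.5 * (target_spacing - vol$spacing))
}

check_order <- function(order) {
  order <- as.integer(order)
  if (!order %in% c(0L, 1L, 3L))
    stop("interpolation `order` must be 0, 1 or 3")
  order
}

#' Resample a volume through a rigid transform onto a reference grid
#'
#' Applies an externally supplied rigid registration (e.g. from a manual
#' landmark alignment done elsewhere) so that the same volume of interest can
#' be compared across modalities. The output is sampled on the reference
#' grid; for each reference voxel centre `x_ref` the source is sampled at
#' `R^T (x_ref - t)`.
#'
#' @param vol the moving [image_volume()].
#' @param transform a [rigid_transform()] mapping `vol` coordinates into
#'   reference coordinates.
#' @param reference an [image_volume()] defining the output grid and spacing.
#' @param order interpolation order (0, 1 or 3).
#' @return An [image_volume()] on the reference grid.
#' @export
apply_rigid_transform <- function(vol, transform, reference, order = 1L) {
  stopifnot(is_image_volume(vol), is_image_volume(reference))
  if (!inherits(transform, "rigid_transform"))
    transform <- do.call(rigid_transform, transform)
  order <- check_order(order)
  R <- transform$rotation
  t_um <- transform$translation_um
  # source voxel index u for reference index i:
  #   x_ref = O_ref + S_ref i ; x_src = R^T (x_ref - t) ; u = S_src^-1 (x_src - O_src)
  Sref <- diag(reference$spacing)
  Sinv <- diag(1 / vol$spacing)
  A <- Sinv %*% t(R) %*% Sref
  b <- as.vector(Sinv %*% (t(R) %*% (reference$origin - t_um) - vol$origin))
  res <- .sample_affine_cpp(as.double(vol$data), dim(vol$data), A, b,
                            dim(reference$data), order)
  image_volume(array(res, dim = dim(reference$data)), reference$spacing,
               reference$origin)
}
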