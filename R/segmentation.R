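#' Otsu threshold segmentation
#'
#' Segments a grayscale volume into bone and background by maximizing the
#' between-class variance over a fixed-width histogram; the reference
#' (micro-CT-like) modality is segmented this way. Bone is the high-intensity
#' class: the mask keeps voxels with intensity >= threshold. Ties in the
#' objective are broken toward the lower threshold so results are
#' reproducible, and the 256 equal-width bins over \[min, max\] make the
#' segmentation invariant under strictly increasing affine intensity
#' transforms.
#'
#' @param vol an [image_volume()] with at least two distinct intensities.
#' @param n_bins number of histogram bins (default 256).
#' @return A list with `mask` (a [binary_mask()]) and `report` (a
#'   `segmentation_report`: threshold, method, foreground fraction, stacked
#'   class histogram).
#' @export
otsu_segment <- function(vol, n_bins = 256L) {
  stopifnot(is_image_volume(vol))
  x <- as.vector(vol$data)
  rng <- range(x)
  if (rng[1] == rng[2])
    stop("constant volume: no Otsu threshold exists")
  thr <- otsu_threshold(x, n_bins)
  mask_arr <- array(vol$data >= thr, dim = dim(vol$data))
  mask <- binary_mask(mask_arr, vol$spacing, vol$origin)
  list(mask = mask,
       report = segmentation_report(vol, mask, thr, "otsu", n_bins))
}

# exhaustive maximization of between-class variance over bin boundaries
otsu_threshold <- function(x, n_bins = 256L) {
  n_bins <- as.integer(n_bins)
  rng <- range(x)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- as.numeric(bin_counts(x, breaks))
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  n <- length(x)
  w0 <- cumsum(counts)[-n_bins]           # background: bins 1..k
  s0 <- cumsum(counts * centers)[-n_bins]
  w1 <- n - w0
  stot <- sum(counts * centers)
  valid <- w0 > 0 & w1 > 0
  m0 <- s0 / w0
  m1 <- (stot - s0) / w1
  between <- ifelse(valid, w0 * w1 * (m0 - m1)^2, -Inf)
  k <- which.max(between)                  # first max: lower threshold on ties
  breaks[k + 1L]
}

# fixed-rule histogram: right-open bins, last bin closed
bin_counts <- function(x, breaks) {
  idx <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  tabulate(idx, nbins = length(breaks) - 1L)
}

segmentation_report <- function(vol, mask, threshold, method, n_bins) {
  structure(
    list(
      threshold = threshold,
      method = method,
      foreground_fraction = sum(mask$data) / length(mask$data),
      histogram = stacked_histogram(vol, mask, n_bins)
    ),
    class = "segmentation_report"
  )
}

#' @export
print.segmentation_report <- function(x, ...) {
  cat(sprintf("<segmentation_report> method %s, threshold %.6g, foreground fraction %.4f\n",
              x$method, x$threshold, x$foreground_fraction))
  invisible(x)
}

#' Parameters for the automated region-growing segmentation
#'
#' @param seed_quantile intensity quantile above which voxels seed the growth
#'   (default 0.999: the brightest 0.1 percent, safely inside bone).
#' @param n_levels number of descending candidate thresholds swept between the
#'   seed level and the volume minimum.
#' @param smooth_sigma_vox Gaussian pre-smoothing sigma in voxels applied to
#'   the working copy used for growth and gradients (0 disables).
#' @param flood_fraction sweep levels whose grown region covers at least this
#'   fraction of the volume are considered flooded and are excluded from
#'   threshold selection.
#' @param shell_fraction growth is accepted while the mean boundary gradient
#'   stays at least this fraction of the sweep maximum; the accepted
#'   threshold is the lowest level still on that high-gradient shell.
#' @return A list of class `arg_config`.
#' @export
arg_config <- function(seed_quantile = 0.999, n_levels = 48L,
                       smooth_sigma_vox = 0, flood_fraction = 0.9,
                       shell_fraction = 0.9) {
  stopifnot(seed_quantile > 0, seed_quantile < 1, n_levels >= 4,
            smooth_sigma_vox >= 0, flood_fraction > 0, flood_fraction <= 1,
            shell_fraction > 0, shell_fraction <= 1)
  structure(list(seed_quantile = seed_quantile, n_levels = as.integer(n_levels),
                 smooth_sigma_vox = smooth_sigma_vox,
                 flood_fraction = flood_fraction,
                 shell_fraction = shell_fraction),
            class = "arg_config")
}

#' Automated region-growing (ARG) segmentation
#'
#' Fully automatic bone segmentation for the clinical (multislice CT)
#' modalities; no manual interaction, deterministic for a fixed input and
#' configuration. Seeds are the brightest voxels (above `seed_quantile`); the
#' region is grown from them with 26-connectivity over a descending sweep of
#' candidate thresholds, scored by the mean intensity-gradient magnitude over
#' the region surface. Growth is accepted while the boundary still sits on
#' the high-gradient shell at the bone-water interface: the accepted
#' threshold is the lowest sweep level whose boundary gradient remains at
#' least `shell_fraction` (default 90 percent) of the sweep maximum, i.e.
#' growth stops where the surface gradient falls off the shell into flat
#' background. Flooded levels (region covering most of the volume, or with
#' an empty interior boundary) never participate in the selection.
#'
#' @param vol an [image_volume()] containing both high- and low-intensity
#'   material.
#' @param config an [arg_config()].
#' @return A list with `mask` and `report` as for [otsu_segment()]; the
#'   report's `threshold` is the accepted growth threshold.
#' @export
arg_segment <- function(vol, config = arg_config()) {
  stopifnot(is_image_volume(vol))
  if (!inherits(config, "arg_config")) config <- do.call(arg_config, config)
  dims <- dim(vol$data)
  x <- as.double(vol$data)
  if (min(x) == max(x)) stop("constant volume: region growing cannot segment it")
  w <- if (config$smooth_sigma_vox > 0)
    .gauss_blur_cpp(x, dims, rep(config$smooth_sigma_vox, 3)) else x
  grad <- .gradient_mag_cpp(w, dims, vol$spacing)

  t_seed <- as.numeric(stats::quantile(w, config$seed_quantile, names = FALSE))
  seeds <- which(w >= t_seed) - 1L
  levels <- seq(t_seed, min(w), length.out = config$n_levels)
  n <- length(w)

  frac <- numeric(config$n_levels)
  gmean <- rep(NA_real_, config$n_levels)
  regions <- vector("list", config$n_levels)
  for (i in seq_along(levels)) {
    reg <- .region_grow_cpp(w, dims, seeds, levels[i])
    regions[[i]] <- reg
    frac[i] <- sum(reg) / n
    bnd <- boundary_voxels_6(reg, dims)
    gmean[i] <- if (any(bnd)) mean(grad[bnd]) else NA_real_
  }
  valid <- frac > 0 & frac < config$flood_fraction & !is.na(gmean)
  if (!any(valid))
    stop("region growing found no non-trivial segmentation ",
         "(no candidate threshold yields a usable bone mask)")
  # the boundary-gradient profile peaks while the region surface rides the
  # bone-water edge; accept the deepest level still on that shell
  score <- ifelse(valid, gmean, -Inf)
  accept <- max(which(valid & gmean >= config$shell_fraction * max(score)))
  best_t <- levels[accept]
  mask_arr <- array(regions[[accept]], dim = dims)
  if (!any(mask_arr) || all(mask_arr))
    stop("region growing produced a trivial mask")
  mask <- binary_mask(mask_arr, vol$spacing, vol$origin)
  list(mask = mask,
       report = segmentation_report(vol, mask, best_t, "arg", 256L))
}

# region voxels with at least one 6-neighbour (inside the domain) off-region
boundary_voxels_6 <- function(region, dims) {
  r <- array(region, dim = dims)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  bnd <- array(FALSE, dim = dims)
  if (nx > 1) {
    bnd[-nx, , ] <- bnd[-nx, , ] | (r[-nx, , ] & !r[-1, , ])
    bnd[-1, , ] <- bnd[-1, , ] | (r[-1, , ] & !r[-nx, , ])
  }
  if (ny > 1) {
    bnd[, -ny, ] <- bnd[, -ny, ] | (r[, -ny, ] & !r[, -1, ])
    bnd[, -1, ] <- bnd[, -1, ] | (r[, -1, ] & !r[, -ny, ])
  }
  if (nz > 1) {
    bnd[, , -nz] <- bnd[, , -nz] | (r[, , -nz] & !r[, , -1])
    bnd[, , -1] <- bnd[, , -1] | (r[, , -1] & !r[, , -nz])
  }
  as.vector(bnd)
}

#' Normalize intensities against the segmented background
#'
#' Applies one affine intensity map `a*x + b` to the whole volume such that
#' the background region (the complement of the bone mask within the analysed
#' volume, i.e. the water) ends up with mean 0 and standard deviation 500.
#' The map is determined on the background and applied everywhere, so bone
#' intensities move consistently. Idempotent. The SD is the population
#' standard deviation.
#'
#' @param vol an [image_volume()].
#' @param background a [binary_mask()] marking background voxels (`TRUE`
#'   where water), or a bone mask with `invert = TRUE`.
#' @param invert set `TRUE` when `background` is the bone mask.
#' @param target_sd target background standard deviation (default 500).
#' @return An [image_volume()] with rescaled intensities.
#' @export
normalize_background <- function(vol, background, invert = FALSE,
                                 target_sd = 500) {
  stopifnot(is_image_volume(vol), is_binary_mask(background))
  if (!identical(dim(vol$data), dim(background$data)))
    stop("volume and background mask grids differ")
  sel <- if (invert) !background$data else background$data
  if (sum(sel) < 2L) stop("background region must have at least 2 voxels")
  bgvals <- vol$data[sel]
  m <- mean(bgvals)
  s <- sqrt(mean((bgvals - m)^2))
  if (s == 0) stop("constant background: cannot normalize")
  a <- target_sd / s
  image_volume(a * (vol$data - m), vol$spacing, vol$origin)
}

#' Stacked bone/background intensity histogram
#'
#' Per-bin voxel counts of the segmented bone and background classes over a
#' common bin grid, the decomposition shown in stacked-histogram quality
#' checks of a segmentation. The two class counts sum to the total histogram
#' exactly.
#'
#' @param vol an [image_volume()].
#' @param mask the bone [binary_mask()] on the same grid.
#' @param n_bins number of bins.
#' @return A data frame with columns `bin_left`, `bin_right`, `count_bone`,
#'   `count_background`.
#' @export
stacked_histogram <- function(vol, mask, n_bins = 256L) {
  stopifnot(is_image_volume(vol), is_binary_mask(mask))
  if (!identical(dim(vol$data), dim(mask$data)))
    stop("volume and mask grids differ")
  x <- as.vector(vol$data)
  rng <- range(x)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  sel <- as.vector(mask$data)
  data.frame(
    bin_left = breaks[-length(breaks)],
    bin_right = breaks[-1],
    count_bone = if (any(sel)) bin_counts(x[sel], breaks) else integer(n_bins),
    count_background = if (any(!sel)) bin_counts(x[!sel], breaks) else integer(n_bins)
  )
}
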