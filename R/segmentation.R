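#' Segmentation configuration
#'
#' Parameters of the mitochondrial voxel identification procedure:
#' per-slice 2D Gaussian smoothing, Laplacian sharpening, fixed-threshold
#' binarization, 3D 26-connected component labeling and size filtering.
#'
#' The size bounds are exclusive-survival / inclusive-removal: a
#' component survives iff `min_size_excl < size < max_size_excl`, i.e.
#' with the defaults components of 125 voxels or fewer and of 100,000
#' voxels or more are removed.
#'
#' @param gaussian_sigma Gaussian smoothing radius in pixels, applied to
#'   each z slice independently (never across z). Default 2.0.
#' @param laplacian_weight weight of the subtracted Laplacian in the
#'   sharpening step `smoothed - w * laplacian(smoothed)`. The Laplacian
#'   operator is the per-slice 3x3 kernel `[[0,1,0],[1,-4,1],[0,1,0]]`.
#'   Default 1.0.
#' @param threshold intensity threshold; voxels are kept iff strictly
#'   above it. Default 750 (suited to a 12-bit-like intensity scale).
#' @param min_size_excl,max_size_excl exclusive size bounds in voxels;
#'   defaults 125 and 100,000.
#' @param border border policy for the smoothing/sharpening convolutions:
#'   `"reflect"` (default, mirrors the image at its edges) or
#'   `"replicate"` (repeats the edge pixel).
#' @param smooth logical; apply the smoothing/sharpening preprocessing at
#'   all. Disable for noise-free synthetic data, where blurring only
#'   moves object boundaries (see the methods vignette). Default `TRUE`.
#' @return an object of class `segmentation_config`.
#' @export
segmentation_config <- function(gaussian_sigma = 2.0, laplacian_weight = 1.0,
                                threshold = 750, min_size_excl = 125,
                                max_size_excl = 100000,
                                border = c("reflect", "replicate"),
                                smooth = TRUE) {
  stop_if_not_scalar_num(gaussian_sigma, "gaussian_sigma", 0, strict_min = TRUE)
  stop_if_not_scalar_num(laplacian_weight, "laplacian_weight")
  stop_if_not_scalar_num(threshold, "threshold", 0)
  stop_if_not_scalar_num(min_size_excl, "min_size_excl", 0)
  stop_if_not_scalar_num(max_size_excl, "max_size_excl", 0)
  if (min_size_excl >= max_size_excl) {
    stop("min_size_excl must be < max_size_excl", call. = FALSE)
  }
  structure(list(gaussian_sigma = gaussian_sigma,
                 laplacian_weight = laplacian_weight,
                 threshold = threshold,
                 min_size_excl = min_size_excl,
                 max_size_excl = max_size_excl,
                 border = match.arg(border),
                 smooth = isTRUE(smooth)),
            class = "segmentation_config")
}

# Pad a matrix by `r` pixels on every side under the given border policy.
.pad2d <- function(m, r, border) {
  nr <- nrow(m); nc <- ncol(m)
  ridx <- switch(border,
                 reflect   = c(rev(seq_len(min(r, nr))), seq_len(nr),
                               nr + 1 - seq_len(min(r, nr))),
                 replicate = c(rep(1L, r), seq_len(nr), rep(nr, r)))
  cidx <- switch(border,
                 reflect   = c(rev(seq_len(min(r, nc))), seq_len(nc),
                               nc + 1 - seq_len(min(r, nc))),
                 replicate = c(rep(1L, r), seq_len(nc), rep(nc, r)))
  m[ridx, cidx, drop = FALSE]
}

# Separable 2D Gaussian convolution, kernel radius ceil(3*sigma).
.gauss2d <- function(m, sigma, border) {
  r <- as.integer(ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  p <- .pad2d(m, r, border)
  nr <- nrow(m); nc <- ncol(m)
  tmp <- matrix(0, nr, nc + 2L * r)
  for (i in seq_along(k)) tmp <- tmp + k[i] * p[(i - 1L) + seq_len(nr), ]
  out <- matrix(0, nr, nc)
  for (i in seq_along(k)) out <- out + k[i] * tmp[, (i - 1L) + seq_len(nc)]
  out
}

# 3x3 discrete Laplacian [[0,1,0],[1,-4,1],[0,1,0]].
.laplacian2d <- function(m, border) {
  p <- .pad2d(m, 1L, border)
  nr <- nrow(m); nc <- ncol(m)
  ri <- 1L + seq_len(nr); ci <- 1L + seq_len(nc)
  p[ri - 1L, ci] + p[ri + 1L, ci] + p[ri, ci - 1L] + p[ri, ci + 1L] - 4 * m
}

#' Preprocess a z-stack: per-slice Gaussian smoothing + Laplacian sharpening
#'
#' Each z slice is smoothed with a 2D Gaussian (smoothing never crosses
#' slices), then sharpened by subtracting the weighted discrete Laplacian
#' of the smoothed slice; the result is clipped at 0.  Constant images
#' pass through unchanged.
#'
#' @param stack an [image_stack] or 3D array.
#' @param cfg a [segmentation_config].
#' @return an object of the same kind as `stack`, same shape.
#' @export
preprocess_stack <- function(stack, cfg = segmentation_config()) {
  arr <- as_stack_array(stack)
  if (length(arr) == 0L) stop("empty stack", call. = FALSE)
  out <- array(0, dim = dim(arr))
  for (z in seq_len(dim(arr)[1])) {
    sl <- .gauss2d(arr[z, , ], cfg$gaussian_sigma, cfg$border)
    sl <- sl - cfg$laplacian_weight * .laplacian2d(sl, cfg$border)
    out[z, , ] <- pmax(sl, 0)
  }
  if (inherits(stack, "image_stack")) image_stack(out, stack$voxel_size) else out
}

#' Threshold a stack into a binary mask
#'
#' A voxel enters the mask iff its intensity is strictly above the
#' threshold (a voxel exactly at the threshold is excluded).
#'
#' @param stack an [image_stack] or 3D array.
#' @param threshold nonnegative intensity cutoff.
#' @return a logical 3D array of the stack's shape.
#' @export
binarize_stack <- function(stack, threshold = 750) {
  stop_if_not_scalar_num(threshold, "threshold", 0)
  as_stack_array(stack) > threshold
}

#' Label 26-connected components of a 3D binary mask
#'
#' Two mask voxels belong to the same component iff they are linked by a
#' chain of 26-neighbor steps (face, edge, or corner adjacency in 3D).
#'
#' @param mask logical 3D array.
#' @return an object of class `component_set`: a list with `components`
#'   (a list of integer matrices of voxel coordinates, columns `z,y,x`),
#'   `shape`, and `config` (filled in by [segment_stack]).
#' @export
label_components_3d <- function(mask) {
  if (!is.array(mask) || length(dim(mask)) != 3L) {
    stop("'mask' must be a logical 3D array", call. = FALSE)
  }
  labels <- cpp_label_components_26(as.logical(mask), dim(mask))
  component_set_from_labels(labels, dim(mask))
}

component_set_from_labels <- function(labels, shape) {
  idx <- which(labels > 0L)
  comps <- if (length(idx)) {
    coords <- arrayInd(idx, shape)
    colnames(coords) <- c("z", "y", "x")
    lab <- labels[idx]
    lapply(split(seq_along(idx), lab), function(i) coords[i, , drop = FALSE])
  } else list()
  names(comps) <- NULL
  structure(list(components = comps, shape = shape, config = NULL),
            class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  sizes <- component_sizes(x)
  cat(sprintf("component_set: %d components in a %s stack\n",
              length(x$components), paste(x$shape, collapse = "x")))
  if (length(sizes)) {
    cat(sprintf("  sizes: min %d, median %g, max %d voxels\n",
                min(sizes), stats::median(sizes), max(sizes)))
  }
  invisible(x)
}

#' Component sizes in voxels
#' @param cs a `component_set`.
#' @return integer vector of component sizes.
#' @export
component_sizes <- function(cs) {
  vapply(cs$components, nrow, integer(1))
}

#' Filter components by size
#'
#' Keeps components whose voxel count is strictly between the bounds:
#' with the defaults, components of 125 voxels or fewer, or 100,000
#' voxels or more, are removed.  Component order is preserved.
#'
#' @param cs a `component_set`.
#' @param min_size_excl,max_size_excl exclusive size bounds.
#' @return a filtered `component_set`.
#' @export
filter_components <- function(cs, min_size_excl = 125, max_size_excl = 100000) {
  if (min_size_excl >= max_size_excl) {
    stop("min_size_excl must be < max_size_excl", call. = FALSE)
  }
  sizes <- component_sizes(cs)
  keep <- sizes > min_size_excl & sizes < max_size_excl
  cs$components <- cs$components[keep]
  cs
}

#' Per-cell mitochondrial count and mean size
#'
#' The mitochondrial count of a cell is the number of surviving
#' connected components; the mean size is the arithmetic mean of their
#' voxel counts (`NA`, not 0, when there are no components).
#'
#' @param cs a `component_set`.
#' @return a list with `n_components` and `mean_component_size`.
#' @export
component_stats <- function(cs) {
  sizes <- component_sizes(cs)
  list(n_components = length(sizes),
       mean_component_size = if (length(sizes)) mean(sizes) else NA_real_)
}

#' Segment mitochondria in a z-stack
#'
#' Runs the full identification chain: preprocessing (unless
#' `cfg$smooth` is `FALSE`), strict thresholding, 26-connected 3D
#' component labeling, and size filtering.
#'
#' @param stack an [image_stack] or 3D array.
#' @param cfg a [segmentation_config].
#' @return a `component_set` with `config` set to `cfg`.
#' @export
segment_stack <- function(stack, cfg = segmentation_config()) {
  pre <- if (cfg$smooth) preprocess_stack(stack, cfg) else stack
  mask <- binarize_stack(pre, cfg$threshold)
  cs <- label_components_3d(mask)
  cs <- filter_components(cs, cfg$min_size_excl, cfg$max_size_excl)
  cs$config <- cfg
  cs
}

#' Write a component label map as a 16-bit TIFF
#'
#' Voxels of the i-th component get value i, background 0.
#'
#' @param cs a `component_set`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_label_tiff <- function(cs, path) {
  labels <- array(0L, dim = cs$shape)
  for (i in seq_along(cs$components)) {
    labels[cs$components[[i]]] <- i
  }
  write_stack_tiff(labels, path)
}
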