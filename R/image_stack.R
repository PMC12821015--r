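#' Image stack container
#'
#' A 3D voxel grid of nonnegative fluorescence intensities together with
#' its physical voxel dimensions.  The array is indexed `[z, y, x]` with
#' `dim = c(nz, ny, nx)`; `voxel_size` holds the physical extent of one
#' voxel along each axis in micrometers, named `c(z=, y=, x=)`.
#'
#' @param data numeric 3D array, `dim = c(nz, ny, nx)`, values `>= 0`.
#' @param voxel_size named numeric vector `c(z=, y=, x=)` in micrometers;
#'   defaults to the acquisition geometry used throughout the package
#'   (0.2 um z-step, 0.0542 um lateral pixels).
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(data, voxel_size = c(z = 0.2, y = 0.0542, x = 0.0542)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("'data' must be a 3D array with dim = c(nz, ny, nx)", call. = FALSE)
  }
  if (any(data < 0, na.rm = TRUE)) stop("intensities must be >= 0", call. = FALSE)
  vs <- as.numeric(voxel_size)
  if (length(vs) != 3L || any(!is.finite(vs)) || any(vs <= 0)) {
    stop("'voxel_size' must be 3 positive numbers c(z, y, x)", call. = FALSE)
  }
  structure(list(data = data, voxel_size = setNames(vs, c("z", "y", "x"))),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_stack: %d x %d x %d voxels (z,y,x), voxel %.4f x %.4f x %.4f um\n",
              d[1], d[2], d[3], x$voxel_size["z"], x$voxel_size["y"], x$voxel_size["x"]))
  cat(sprintf("  intensity range [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$data)

as_stack_array <- function(stack) {
  if (inherits(stack, "image_stack")) stack$data
  else if (is.array(stack) && length(dim(stack)) == 3L) stack
  else stop("expected an image_stack or a 3D array", call. = FALSE)
}
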