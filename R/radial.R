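#' Per-voxel Euclidean distances to the nucleus center
#'
#' One distance per mitochondrial voxel across all components.  With
#' `units = "physical"` (default) each axis offset is scaled by its
#' voxel dimension before the Euclidean norm, so anisotropic stacks
#' (e.g. 0.2 um z-step vs 0.0542 um pixels) are measured in
#' micrometers; `units = "voxel"` uses raw index offsets.
#'
#' @param cs a `component_set` (see [segment_stack]).
#' @param nucleus_center voxel coordinates `(z, y, x)` of the nucleus
#'   center, fractional allowed; must lie within the stack bounds
#'   unless `allow_outside = TRUE` (which only warns).
#' @param voxel_size named numeric `c(z=, y=, x=)` in micrometers.
#' @param units `"physical"` (micrometers) or `"voxel"` (index units).
#' @param allow_outside tolerate a center outside the stack bounds.
#' @return numeric vector of distances, one per mitochondrial voxel.
#' @export
compute_pixel_distances <- function(cs, nucleus_center,
                                    voxel_size = c(z = 0.2, y = 0.0542, x = 0.0542),
                                    units = c("physical", "voxel"),
                                    allow_outside = FALSE) {
  units <- match.arg(units)
  ctr <- as.numeric(nucleus_center)
  if (length(ctr) != 3L || any(!is.finite(ctr))) {
    stop("'nucleus_center' must be 3 finite voxel coordinates (z, y, x)",
         call. = FALSE)
  }
  if (any(ctr < 1) || any(ctr > cs$shape)) {
    msg <- "nucleus center lies outside the stack bounds"
    if (allow_outside) warning(msg, call. = FALSE) else stop(msg, call. = FALSE)
  }
  scale <- if (units == "physical") {
    vs <- as.numeric(voxel_size)
    if (length(vs) != 3L || any(vs <= 0)) {
      stop("'voxel_size' must be 3 positive numbers c(z, y, x)", call. = FALSE)
    }
    vs
  } else c(1, 1, 1)
  vox <- do.call(rbind, cs$components)
  if (is.null(vox) || nrow(vox) == 0L) return(numeric(0))
  unname(sqrt(((vox[, 1] - ctr[1]) * scale[1])^2 +
                ((vox[, 2] - ctr[2]) * scale[2])^2 +
                ((vox[, 3] - ctr[3]) * scale[3])^2))
}

#' Normalize distances by the per-cell maximum
#'
#' Divides every distance by the cell's maximum mitochondrial-voxel
#' distance, so values lie in `[0, 1]` with the maximum exactly 1; the
#' result is invariant to rescaling the physical distances.
#'
#' @param distances nonempty numeric vector of nonnegative distances
#'   with a positive maximum.
#' @param cell_id optional identifier carried along.
#' @return an object of class `normalized_distances`: list with
#'   `cell_id` and `values`.
#' @export
normalize_distances <- function(distances, cell_id = NA_character_) {
  if (length(distances) == 0L) {
    stop("no mitochondrial pixels: cannot normalize an empty distance set",
         call. = FALSE)
  }
  if (any(!is.finite(distances)) || any(distances < 0)) {
    stop("distances must be finite and nonnegative", call. = FALSE)
  }
  m <- max(distances)
  if (m <= 0) {
    stop("degenerate cell: all mitochondrial pixels coincide with the nucleus center",
         call. = FALSE)
  }
  structure(list(cell_id = cell_id, values = distances / m),
            class = "normalized_distances")
}

#' Pool normalized distances across the cells of a condition
#'
#' Pixel-weighted pooling: the per-cell value vectors are concatenated,
#' so each cell contributes in proportion to its mitochondrial pixel
#' count.
#'
#' @param cells nonempty list of `normalized_distances`.
#' @return numeric vector of pooled normalized distances.
#' @export
pool_condition <- function(cells) {
  if (length(cells) == 0L) stop("no cells to pool", call. = FALSE)
  if (!all(vapply(cells, inherits, logical(1), "normalized_distances"))) {
    stop("'cells' must be a list of normalized_distances objects", call. = FALSE)
  }
  unlist(lapply(cells, `[[`, "values"), use.names = FALSE)
}

#' Peripheral subset of a pooled distribution
#'
#' The `ceiling(fraction * n)` largest pooled values; ties at the cutoff
#' are all included, so the subset is deterministic and independent of
#' input order.
#'
#' @param pooled nonempty numeric vector of pooled normalized distances.
#' @param fraction fraction in `(0, 1]`; default 0.30 (the "30% most
#'   distant pixels").
#' @return numeric vector, the peripheral subset.
#' @export
peripheral_subset <- function(pooled, fraction = 0.30) {
  if (length(pooled) == 0L) stop("empty pooled distribution", call. = FALSE)
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("'fraction' must be in (0, 1]", call. = FALSE)
  }
  k <- ceiling(fraction * length(pooled))
  cutoff <- sort(pooled, decreasing = TRUE)[k]
  pooled[pooled >= cutoff]
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' `D` is the supremum distance between the two empirical CDFs.  The
#' p-value is the exact two-sided permutation value (computed with the
#' tie-aware Smirnov distribution) whenever `n1 * n2 <= 1e4`, and the
#' asymptotic Kolmogorov series `2 * sum (-1)^(k-1) exp(-2 k^2 lambda^2)`
#' with `lambda = sqrt(n1 n2 / (n1 + n2)) * D` otherwise.  Symmetric in
#' its arguments.
#'
#' @param a,b nonempty numeric samples.
#' @param exact_max product `n1 * n2` up to which the exact p-value is
#'   used (default 1e4).
#' @return an object of class `ks_result`: list with `D`, `p_value`,
#'   `n1`, `n2`, `method`.
#' @export
ks_two_sample <- function(a, b, exact_max = 1e4) {
  if (length(a) == 0L || length(b) == 0L) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  n1 <- length(a); n2 <- length(b)
  u <- sort(unique(c(a, b)))
  ca <- cumsum(tabulate(findInterval(a, u), nbins = length(u))) / n1
  cb <- cumsum(tabulate(findInterval(b, u), nbins = length(u))) / n2
  D <- max(abs(ca - cb))
  if (n1 * n2 <= exact_max) {
    method <- "exact"
    p <- stats::psmirnov(D, sizes = c(n1, n2), z = c(a, b),
                         two.sided = TRUE, exact = TRUE, lower.tail = FALSE)
  } else {
    method <- "asymptotic"
    lambda <- sqrt(n1 * n2 / (n1 + n2)) * D
    k <- 1:100
    p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
    p <- min(max(p, 0), 1)
  }
  if (D == 0) p <- 1
  structure(list(D = D, p_value = p, n1 = n1, n2 = n2, method = method),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("two-sample KS: D = %.4f, p = %.4g (%s; n1 = %d, n2 = %d)\n",
              x$D, x$p_value, x$method, x$n1, x$n2))
  invisible(x)
}

#' Density histogram of normalized radial distances
#'
#' Equal-width density-normalized histogram over `[0, 1]`; bins are
#' right-closed (a value exactly at an internal edge falls in the lower
#' bin) and both endpoints are included.  Densities integrate to 1.
#'
#' @param values numeric vector with all values in `[0, 1]`.
#' @param n_bins number of bins, `>= 2` (default 50); ignored when
#'   `bin_edges` is given.
#' @param bin_edges optional explicit increasing edge vector over
#'   `[0, 1]`.
#' @return an object of class `radial_histogram`: list with
#'   `bin_edges`, `density`, `counts`, `n`.
#' @export
radial_histogram <- function(values, n_bins = 50, bin_edges = NULL) {
  if (is.null(bin_edges)) {
    stop_if_not_scalar_num(n_bins, "n_bins", 2)
    bin_edges <- seq(0, 1, length.out = n_bins + 1)
  }
  if (any(values < bin_edges[1]) || any(values > bin_edges[length(bin_edges)])) {
    stop("values outside the histogram range", call. = FALSE)
  }
  h <- graphics::hist(values, breaks = bin_edges, right = TRUE,
                      include.lowest = TRUE, plot = FALSE)
  structure(list(bin_edges = bin_edges, density = h$density,
                 counts = h$counts, n = length(values)),
            class = "radial_histogram")
}

#' @export
print.radial_histogram <- function(x, ...) {
  cat(sprintf("radial_histogram: %d bins over [%g, %g], n = %d\n",
              length(x$density), x$bin_edges[1],
              x$bin_edges[length(x$bin_edges)], x$n))
  invisible(x)
}

#' Write a radial histogram as CSV (`bin_left,bin_right,density`)
#' @param h a `radial_histogram`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_histogram_csv <- function(h, path) {
  ne <- length(h$bin_edges)
  write.csv(data.frame(bin_left = h$bin_edges[-ne], bin_right = h$bin_edges[-1],
                       density = h$density),
            path, row.names = FALSE)
  invisible(path)
}
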