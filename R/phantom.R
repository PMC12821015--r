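#' Radial placement density families
#'
#' Families for the in-plane radial placement of rendered mitochondria,
#' parameterized on the unit disk:
#'
#' * `"uniform-disk"`: uniform over disk area, i.e. `CDF(r) = r^2`;
#' * `"peripheral-shifted"`: `CDF(r) = r^(2 + strength)` with
#'   `strength > 0`, which shifts mass outward (mean radius
#'   `(2+s)/(3+s)`, strictly increasing in `s`; `s = 0` recovers the
#'   uniform family).
#'
#' @param family family name.
#' @param strength outward-shift strength for `"peripheral-shifted"`.
#' @return an object of class `radial_density`.
#' @export
radial_density <- function(family = c("uniform-disk", "peripheral-shifted"),
                           strength = 1) {
  family <- match.arg(family)
  if (family == "peripheral-shifted") {
    stop_if_not_scalar_num(strength, "strength", 0)
  }
  structure(list(family = family,
                 strength = if (family == "peripheral-shifted") strength else 0),
            class = "radial_density")
}

.as_radial_density <- function(x) {
  if (inherits(x, "radial_density")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (!x %in% c("uniform-disk", "peripheral-shifted")) {
      stop("unknown radial density family: ", x, call. = FALSE)
    }
    return(radial_density(x))
  }
  if (is.list(x) && !is.null(x$family)) {
    return(radial_density(x$family, x$strength %||% 1))
  }
  stop("unknown radial density family: ", deparse(x), call. = FALSE)
}

.sample_radial_r <- function(density, n) {
  u <- runif(n)
  switch(density$family,
         "uniform-disk" = sqrt(u),
         "peripheral-shifted" = u^(1 / (2 + density$strength)))
}

#' Sample positions in the unit disk from a radial placement family
#'
#' @param family a [radial_density], or its family name as a string.
#' @param n number of positions, `>= 0`.
#' @param seed optional integer seed; when `NULL` the current RNG stream
#'   is consumed.
#' @return an `n x 2` matrix of `(x, y)` positions with `x^2 + y^2 <= 1`.
#' @export
sample_radial_positions <- function(family, n, seed = NULL) {
  density <- .as_radial_density(family)
  stop_if_not_scalar_num(n, "n", 0)
  draw <- function() {
    r <- .sample_radial_r(density, n)
    th <- runif(n, 0, 2 * pi)
    cbind(x = r * cos(th), y = r * sin(th))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw)
}

#' Specification of a synthetic ("phantom") cell image stack
#'
#' Describes a stylized adherent cell: a flat slab of `stack_shape[1]` z
#' slices, a dark nucleus sphere at `nucleus_center`, and `n_mito`
#' bright capsule-shaped (cylinder + hemispherical caps) mitochondria
#' with in-plane random orientations, placed with an in-plane radial
#' density from `radial_density` and kept disjoint from each other, the
#' nucleus, and the cell boundary (a cylinder of radius `cell_radius`
#' around the nucleus axis).
#'
#' Intensities follow a 12-bit-like scale on which a fixed threshold of
#' ~750 separates signal (`signal_level`, default 2000) from background
#' (`background_level`, default 100); the nucleus is rendered darker
#' than background.  Geometry defaults: 21 slices of 512 x 512 pixels at
#' 0.0542 um laterally and a 0.2 um z-step.
#'
#' @param stack_shape integer `(nz, ny, nx)` voxel counts.
#' @param voxel_size named numeric `c(z=, y=, x=)` in micrometers.
#' @param cell_radius cell radius in micrometers (the value is a
#'   stylized placeholder; MIN6-like cells are not calibrated here).
#' @param nucleus_radius nucleus radius in micrometers, `< cell_radius`,
#'   and small enough relative to the slab half-thickness that
#'   mitochondria can clear the nucleus in z at any planar radius.
#' @param nucleus_center voxel coordinates `(z, y, x)` of the nucleus
#'   center (fractional allowed); default: the stack center.
#' @param n_mito number of mitochondria, `>= 0`.
#' @param mito_length_range capsule axis length range in micrometers.
#' @param mito_radius capsule radius in micrometers.
#' @param radial_density a [radial_density] (or family name) for the
#'   in-plane placement of mitochondrion centers.
#' @param background_level,signal_level,nucleus_level intensity counts;
#'   `signal_level > background_level >= nucleus_level >= 0`.
#'   `nucleus_level` defaults to half the background.
#' @param noise_model `"none"`, `"poisson"` (shot noise with the clean
#'   image as the rate), or `list(type = "gaussian", sd = ...)`.
#' @param seed integer seed; rendering is bit-deterministic given the
#'   spec and seed.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(stack_shape = c(21L, 512L, 512L),
                         voxel_size = c(z = 0.2, y = 0.0542, x = 0.0542),
                         cell_radius = 8, nucleus_radius = 1.2,
                         nucleus_center = NULL, n_mito = 40,
                         mito_length_range = c(0.8, 2.5), mito_radius = 0.25,
                         radial_density = "uniform-disk",
                         background_level = 100, signal_level = 2000,
                         nucleus_level = NULL,
                         noise_model = "none", seed = 1L) {
  stack_shape <- as.integer(stack_shape)
  if (length(stack_shape) != 3L || any(stack_shape < 1L)) {
    stop("'stack_shape' must be 3 positive voxel counts (nz, ny, nx)", call. = FALSE)
  }
  vs <- setNames(as.numeric(voxel_size), c("z", "y", "x"))
  stop_if_not_scalar_num(cell_radius, "cell_radius", 0, strict_min = TRUE)
  stop_if_not_scalar_num(nucleus_radius, "nucleus_radius", 0)
  if (nucleus_radius >= cell_radius) {
    stop("degenerate geometry: nucleus_radius must be < cell_radius", call. = FALSE)
  }
  stop_if_not_scalar_num(n_mito, "n_mito", 0)
  stop_if_not_scalar_num(mito_radius, "mito_radius", 0, strict_min = TRUE)
  if (length(mito_length_range) != 2L || any(mito_length_range < 0) ||
      mito_length_range[1] > mito_length_range[2]) {
    stop("'mito_length_range' must be an increasing pair of lengths", call. = FALSE)
  }
  stop_if_not_scalar_num(background_level, "background_level", 0)
  stop_if_not_scalar_num(signal_level, "signal_level", 0)
  if (signal_level <= background_level) {
    stop("'signal_level' must exceed 'background_level'", call. = FALSE)
  }
  nucleus_level <- nucleus_level %||% floor(background_level / 2)
  stop_if_not_scalar_num(nucleus_level, "nucleus_level", 0)
  if (is.null(nucleus_center)) nucleus_center <- (stack_shape + 1) / 2
  nucleus_center <- setNames(as.numeric(nucleus_center), c("z", "y", "x"))
  if (is.character(noise_model)) noise_model <- list(type = noise_model)
  if (!noise_model$type %in% c("none", "poisson", "gaussian")) {
    stop("unknown noise model: ", noise_model$type, call. = FALSE)
  }
  if (noise_model$type == "gaussian") {
    stop_if_not_scalar_num(noise_model$sd %||% stop("gaussian noise needs 'sd'",
                                                    call. = FALSE),
                           "noise sd", 0)
  }
  structure(list(stack_shape = stack_shape, voxel_size = vs,
                 cell_radius = cell_radius, nucleus_radius = nucleus_radius,
                 nucleus_center = nucleus_center, n_mito = as.integer(n_mito),
                 mito_length_range = as.numeric(mito_length_range),
                 mito_radius = mito_radius,
                 radial_density = .as_radial_density(radial_density),
                 background_level = background_level,
                 signal_level = signal_level, nucleus_level = nucleus_level,
                 noise_model = noise_model, seed = as.integer(seed)),
            class = "phantom_spec")
}

# 2D distance from points (px, py) to segment (a, b); vectorized in points.
.dist_point_seg2 <- function(px, py, a, b) {
  vx <- b[1] - a[1]; vy <- b[2] - a[2]
  l2 <- vx * vx + vy * vy
  if (l2 == 0) return(sqrt((px - a[1])^2 + (py - a[2])^2))
  t <- pmin(pmax(((px - a[1]) * vx + (py - a[2]) * vy) / l2, 0), 1)
  sqrt((px - (a[1] + t * vx))^2 + (py - (a[2] + t * vy))^2)
}

# 2D segment-segment distance (both segments as 2-point matrices).
.dist_seg_seg2 <- function(p, q) {
  min(.dist_point_seg2(p[1, 1], p[1, 2], q[1, ], q[2, ]),
      .dist_point_seg2(p[2, 1], p[2, 2], q[1, ], q[2, ]),
      .dist_point_seg2(q[1, 1], q[1, 2], p[1, ], p[2, ]),
      .dist_point_seg2(q[2, 1], q[2, 2], p[1, ], p[2, ]))
}

#' Render a phantom cell stack with ground truth
#'
#' Produces the synthetic image stack described by `spec` together with
#' the exact voxel-level ground truth.  With `noise_model = "none"`
#' every mitochondrial voxel has intensity `signal_level` and every
#' other voxel at most `background_level`, so a threshold between the
#' two recovers the ground-truth voxel union exactly.
#'
#' Mitochondria are placed so that (i) their in-plane center radius
#' follows `spec$radial_density` exactly (collisions are resolved by
#' resampling orientation and z first, which leaves the planar radial
#' law intact), (ii) every rendered voxel lies inside the cell boundary
#' and outside the nucleus, and (iii) distinct mitochondria are
#' separated by more than a voxel diagonal, so they can never merge
#' under 26-connectivity.
#'
#' @param spec a [phantom_spec].
#' @return a list with `stack` (an [image_stack]) and `truth`, a ground
#'   truth list: `mito_centers` (physical um, columns `z,y,x`),
#'   `mito_voxels` (list of voxel coordinate matrices `z,y,x`),
#'   `voxel_union` (their row-bound union), `norm_distances` (true
#'   normalized radial distance of every mitochondrial voxel, max 1),
#'   `nucleus_center`, `nucleus_radius`, `cell_radius`.
#' @export
make_phantom_cell <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, function() .render_phantom(spec))
}

.render_phantom <- function(spec) {
  d <- spec$stack_shape
  vz <- spec$voxel_size["z"]; vy <- spec$voxel_size["y"]; vx <- spec$voxel_size["x"]
  nc_phys <- (spec$nucleus_center - 1) * spec$voxel_size  # physical (z,y,x)
  mr <- spec$mito_radius
  pad <- 0.02
  sep_gap <- 1.5 * sqrt(sum(spec$voxel_size^2))
  z_hi_phys <- (d[1] - 1) * vz
  z_range <- c(mr + pad, z_hi_phys - mr - pad)
  if (z_range[1] >= z_range[2] && spec$n_mito > 0) {
    stop("stack too thin for the requested mitochondrion radius", call. = FALSE)
  }
  r_place <- spec$cell_radius - (max(spec$mito_length_range) / 2 + mr + pad)
  if (r_place <= 0 && spec$n_mito > 0) {
    stop("cell_radius too small for the requested mitochondrion size", call. = FALSE)
  }

  segs <- list()   # per mito: list(a, b (xy phys), zc, center (z,y,x phys))
  if (spec$n_mito > 0) {
    for (i in seq_len(spec$n_mito)) {
      placed <- FALSE
      for (outer_try in 1:50) {
        r_c <- .sample_radial_r(spec$radial_density, 1) * r_place
        th_c <- runif(1, 0, 2 * pi)
        cx <- nc_phys["x"] + r_c * cos(th_c)
        cy <- nc_phys["y"] + r_c * sin(th_c)
        len <- runif(1, spec$mito_length_range[1], spec$mito_length_range[2])
        for (inner_try in 1:60) {
          phi <- runif(1, 0, 2 * pi)
          ax <- (len / 2) * cos(phi); ay <- (len / 2) * sin(phi)
          a <- c(cx - ax, cy - ay); b <- c(cx + ax, cy + ay)
          # capsule must fit the cell cylinder
          end_r <- sqrt((c(a[1], b[1]) - nc_phys["x"])^2 +
                          (c(a[2], b[2]) - nc_phys["y"])^2)
          if (max(end_r) + mr + pad > spec$cell_radius) next
          # z placement clearing the nucleus sphere
          dxy <- .dist_point_seg2(nc_phys["x"], nc_phys["y"],
                                  cbind(a[1], a[2]), cbind(b[1], b[2]))
          c_req <- spec$nucleus_radius + mr + pad
          h <- sqrt(max(c_req^2 - dxy^2, 0))
          lo <- c(z_range[1], nc_phys["z"] + h)
          hi <- c(nc_phys["z"] - h, z_range[2])
          lens <- pmax(hi - lo, 0)
          if (sum(lens) <= 0) next
          pick <- runif(1, 0, sum(lens))
          seg_i <- if (pick <= lens[1]) 1L else 2L
          zc <- lo[seg_i] + (if (seg_i == 1L) pick else pick - lens[1])
          # separation from already placed capsules (3D, both in-plane)
          p <- rbind(a, b)
          ok <- TRUE
          for (s in segs) {
            dz <- zc - s$zc
            d2 <- .dist_seg_seg2(p, rbind(s$a, s$b))
            if (sqrt(d2^2 + dz^2) <= 2 * mr + sep_gap) { ok <- FALSE; break }
          }
          if (!ok) next
          segs[[i]] <- list(a = a, b = b, zc = zc,
                            center = c(z = zc, y = cy, x = cx))
          placed <- TRUE
          break
        }
        if (placed) break
      }
      if (!placed) {
        stop("could not place mitochondrion ", i,
             " without collisions; reduce n_mito or mito size", call. = FALSE)
      }
    }
  }

  arr <- array(spec$background_level, dim = d)

  # nucleus: dark sphere (anisotropic voxel grid, physical distances)
  zc_i <- seq_len(d[1]); yc_i <- seq_len(d[2]); xc_i <- seq_len(d[3])
  dz2 <- ((zc_i - spec$nucleus_center["z"]) * vz)^2
  dy2 <- ((yc_i - spec$nucleus_center["y"]) * vy)^2
  dx2 <- ((xc_i - spec$nucleus_center["x"]) * vx)^2
  nr2 <- spec$nucleus_radius^2
  for (iz in zc_i) {
    rem <- nr2 - dz2[iz]
    if (rem <= 0) next
    sl <- outer(dy2, dx2, `+`) <= rem
    if (any(sl)) {
      slice <- arr[iz, , ]
      slice[sl] <- spec$nucleus_level
      arr[iz, , ] <- slice
    }
  }

  mito_voxels <- vector("list", length(segs))
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    x_lo <- min(s$a[1], s$b[1]) - mr; x_hi <- max(s$a[1], s$b[1]) + mr
    y_lo <- min(s$a[2], s$b[2]) - mr; y_hi <- max(s$a[2], s$b[2]) + mr
    ix <- max(1L, floor(x_lo / vx)):min(d[3], ceiling(x_hi / vx) + 1L)
    iy <- max(1L, floor(y_lo / vy)):min(d[2], ceiling(y_hi / vy) + 1L)
    iz <- max(1L, floor((s$zc - mr) / vz)):min(d[1], ceiling((s$zc + mr) / vz) + 1L)
    px <- (ix - 1) * vx; py <- (iy - 1) * vy
    g <- expand.grid(y = py, x = px)
    d2xy <- .dist_point_seg2(g$x, g$y, s$a, s$b)^2
    vox <- NULL
    for (z in iz) {
      dzz <- ((z - 1) * vz - s$zc)^2
      hit <- which(d2xy + dzz <= mr^2)
      if (length(hit)) {
        gy <- iy[(hit - 1L) %% length(iy) + 1L]
        gx <- ix[(hit - 1L) %/% length(iy) + 1L]
        vox <- rbind(vox, cbind(z = z, y = gy, x = gx))
        arr[cbind(z, gy, gx)] <- spec$signal_level
      }
    }
    if (is.null(vox)) {
      stop("mitochondrion ", i, " rendered no voxels; enlarge mito_radius",
           call. = FALSE)
    }
    mito_voxels[[i]] <- vox
  }

  if (spec$noise_model$type == "poisson") {
    arr <- array(rpois(length(arr), lambda = arr), dim = d)
  } else if (spec$noise_model$type == "gaussian") {
    arr <- pmax(arr + array(rnorm(length(arr), 0, spec$noise_model$sd), dim = d), 0)
  }

  union <- if (length(mito_voxels)) do.call(rbind, mito_voxels) else
    matrix(integer(0), 0, 3, dimnames = list(NULL, c("z", "y", "x")))
  norm_d <- if (nrow(union)) {
    dd <- sqrt(((union[, "z"] - spec$nucleus_center["z"]) * vz)^2 +
                 ((union[, "y"] - spec$nucleus_center["y"]) * vy)^2 +
                 ((union[, "x"] - spec$nucleus_center["x"]) * vx)^2)
    dd / max(dd)
  } else numeric(0)

  list(stack = image_stack(arr, spec$voxel_size),
       truth = list(
         mito_centers = if (length(segs))
           do.call(rbind, lapply(segs, `[[`, "center")) else
             matrix(numeric(0), 0, 3),
         mito_voxels = mito_voxels,
         voxel_union = union,
         norm_distances = norm_d,
         nucleus_center = spec$nucleus_center,
         nucleus_radius = spec$nucleus_radius,
         cell_radius = spec$cell_radius))
}

#' Generate a condition's worth of phantom cells
#'
#' Renders `n_cells` phantom stacks from a common [phantom_spec], with
#' per-cell seeds derived as `seed + cell_index` so cells are
#' reproducible yet distinct, and a small per-cell jitter applied to the
#' mitochondrion count and the nucleus position to emulate biological
#' variability.
#'
#' @param spec a [phantom_spec] shared by all cells.
#' @param n_cells number of cells, `>= 1`.
#' @param per_cell_jitter relative jitter fraction: `n_mito` is scaled
#'   by `1 + U(-j, j)` and the nucleus center is displaced in-plane by
#'   up to `j * cell_radius`. Default 0.1.
#' @param seed master seed; default `spec$seed`.
#' @param dir optional output directory: when given, each cell's stack
#'   is written as a multi-page TIFF, its ground truth as JSON, and the
#'   annotation table as `annotations.csv` with columns
#'   `cell_id,stack_path,nucleus_z,nucleus_y,nucleus_x`.
#' @return an object of class `condition_dataset`: list with `cells`
#'   (each `list(stack, truth, spec)`), `annotations` (data.frame),
#'   `seed`, `dir`.
#' @export
make_condition_dataset <- function(spec, n_cells, per_cell_jitter = 0.1,
                                   seed = spec$seed, dir = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  stop_if_not_scalar_num(n_cells, "n_cells", 1)
  stop_if_not_scalar_num(per_cell_jitter, "per_cell_jitter", 0)
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)

  cells <- vector("list", n_cells)
  ann <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    cell_seed <- as.integer(seed) + i
    spec_i <- spec
    spec_i$seed <- cell_seed
    if (per_cell_jitter > 0) {
      jit <- with_seed(derive_seed(seed, "jitter", i), function() {
        list(f = runif(1, -per_cell_jitter, per_cell_jitter),
             off = runif(2, -per_cell_jitter, per_cell_jitter) * spec$cell_radius)
      })
      spec_i$n_mito <- max(1L, as.integer(round(spec$n_mito * (1 + jit$f))))
      spec_i$nucleus_center["y"] <- spec$nucleus_center["y"] +
        jit$off[1] / spec$voxel_size["y"]
      spec_i$nucleus_center["x"] <- spec$nucleus_center["x"] +
        jit$off[2] / spec$voxel_size["x"]
    }
    cell <- make_phantom_cell(spec_i)
    cell_id <- sprintf("cell_%03d", i)
    stack_path <- NA_character_
    if (!is.null(dir)) {
      stack_path <- file.path(dir, paste0(cell_id, ".tif"))
      write_stack_tiff(cell$stack, stack_path)
      jsonlite::write_json(
        list(nucleus_center = unname(spec_i$nucleus_center),
             nucleus_radius = spec_i$nucleus_radius,
             cell_radius = spec_i$cell_radius,
             n_mito = length(cell$truth$mito_voxels),
             voxel_union = unname(cell$truth$voxel_union),
             norm_distances = cell$truth$norm_distances),
        file.path(dir, paste0(cell_id, "_truth.json")),
        auto_unbox = TRUE, digits = NA)
    }
    cells[[i]] <- list(stack = cell$stack, truth = cell$truth, spec = spec_i)
    ann[[i]] <- data.frame(cell_id = cell_id, stack_path = stack_path,
                           nucleus_z = spec_i$nucleus_center["z"],
                           nucleus_y = spec_i$nucleus_center["y"],
                           nucleus_x = spec_i$nucleus_center["x"],
                           row.names = NULL)
  }
  annotations <- do.call(rbind, ann)
  rownames(annotations) <- NULL
  if (!is.null(dir)) {
    write.csv(annotations, file.path(dir, "annotations.csv"), row.names = FALSE)
  }
  structure(list(cells = cells, annotations = annotations,
                 seed = as.integer(seed), dir = dir),
            class = "condition_dataset")
}
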