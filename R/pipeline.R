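#' End-to-end run configuration
#'
#' Describes a full analysis run: one or more named conditions (each
#' either a synthetic phantom condition or a directory of TIFF stacks
#' with an annotation table), the segmentation configuration, and the
#' radial-analysis options.
#'
#' Each element of `conditions` is a list with either
#' * `spec` (a [phantom_spec]) and `n_cells` (and optionally
#'   `per_cell_jitter`), for synthetic input; or
#' * `annotation`, the path of a CSV with columns
#'   `cell_id,stack_path,nucleus_z,nucleus_y,nucleus_x` (stack paths
#'   are resolved relative to the CSV), for TIFF input.
#'
#' @param conditions named list of condition definitions (at least one).
#' @param seg a [segmentation_config].
#' @param fraction peripheral-subset fraction (default 0.30).
#' @param n_bins histogram bin count (default 50).
#' @param distance_units `"physical"` or `"voxel"` (see
#'   [compute_pixel_distances]).
#' @param ks_scope compare conditions on the `"peripheral"` subsets
#'   (default; the distributions the KS tests are reported on) or the
#'   `"full"` pooled distributions.
#' @param voxel_size physical voxel dimensions used for TIFF input.
#' @param out_dir optional output directory for artifacts.
#' @param seed master seed; all per-stage randomness derives from it.
#' @return an object of class `run_config`.
#' @export
run_config <- function(conditions, seg = segmentation_config(),
                       fraction = 0.30, n_bins = 50,
                       distance_units = c("physical", "voxel"),
                       ks_scope = c("peripheral", "full"),
                       voxel_size = c(z = 0.2, y = 0.0542, x = 0.0542),
                       out_dir = NULL, seed = 1L) {
  if (!is.list(conditions) || length(conditions) < 1L ||
      is.null(names(conditions)) || any(names(conditions) == "")) {
    stop("'conditions' must be a nonempty named list", call. = FALSE)
  }
  for (nm in names(conditions)) {
    cond <- conditions[[nm]]
    if (!is.null(cond$spec)) {
      stopifnot(inherits(cond$spec, "phantom_spec"))
      if (is.null(cond$n_cells)) stop("condition '", nm, "' needs n_cells",
                                      call. = FALSE)
    } else if (!is.null(cond$annotation)) {
      if (!file.exists(cond$annotation)) {
        stop("annotation file not found: ", cond$annotation, call. = FALSE)
      }
    } else {
      stop("condition '", nm, "' must provide either 'spec' or 'annotation'",
           call. = FALSE)
    }
  }
  stopifnot(inherits(seg, "segmentation_config"))
  structure(list(conditions = conditions, seg = seg, fraction = fraction,
                 n_bins = n_bins, distance_units = match.arg(distance_units),
                 ks_scope = match.arg(ks_scope),
                 voxel_size = setNames(as.numeric(voxel_size), c("z", "y", "x")),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

# Materialize a condition into (annotation row, stack) pairs.
.load_condition_cells <- function(cfg, name) {
  cond <- cfg$conditions[[name]]
  if (!is.null(cond$spec)) {
    ds <- make_condition_dataset(cond$spec, cond$n_cells,
                                 per_cell_jitter = cond$per_cell_jitter %||% 0.1,
                                 seed = derive_seed(cfg$seed, "phantom", name))
    lapply(seq_along(ds$cells), function(i) {
      list(cell_id = ds$annotations$cell_id[i],
           stack = ds$cells[[i]]$stack,
           nucleus_center = c(ds$annotations$nucleus_z[i],
                              ds$annotations$nucleus_y[i],
                              ds$annotations$nucleus_x[i]))
    })
  } else {
    ann <- read.csv(cond$annotation, stringsAsFactors = FALSE)
    base <- dirname(cond$annotation)
    lapply(seq_len(nrow(ann)), function(i) {
      p <- ann$stack_path[i]
      if (!file.exists(p)) p <- file.path(base, p)
      list(cell_id = ann$cell_id[i],
           stack = read_stack_tiff(p, voxel_size = cfg$voxel_size),
           nucleus_center = c(ann$nucleus_z[i], ann$nucleus_y[i], ann$nucleus_x[i]))
    })
  }
}

# Segment + measure one loaded cell; NULL distances if nothing survives.
.analyze_cell <- function(cell, seg, units) {
  cs <- segment_stack(cell$stack, seg)
  st <- component_stats(cs)
  if (st$n_components == 0L) {
    return(list(stats = data.frame(cell_id = cell$cell_id, n_components = 0L,
                                   mean_size_voxels = NA_real_, n_pixels = 0L),
                nd = NULL))
  }
  d <- compute_pixel_distances(cs, cell$nucleus_center,
                               voxel_size = cell$stack$voxel_size, units = units)
  nd <- normalize_distances(d, cell_id = cell$cell_id)
  list(stats = data.frame(cell_id = cell$cell_id,
                          n_components = st$n_components,
                          mean_size_voxels = st$mean_component_size,
                          n_pixels = length(nd$values)),
       nd = nd)
}

#' Run the full analysis pipeline
#'
#' Generates or loads every condition's stacks, segments them, builds
#' per-cell normalized radial distance distributions, pools them by
#' condition, and compares all condition pairs with two-sample KS tests
#' on the configured scope.  Cells with zero surviving components are
#' excluded from pooling and listed in the report.  Deterministic given
#' the configuration and master seed.
#'
#' @param cfg a [run_config].
#' @return an object of class `pipeline_report`: list with `conditions`
#'   (per condition: `cell_stats` data.frame, `pooled`, `histogram`,
#'   `peripheral`, `excluded_cells`), `comparisons` (data.frame of all
#'   pairwise KS results), `config`, `seed`.  When `cfg$out_dir` is set,
#'   per-cell stats and distance CSVs, histogram CSVs, and a JSON report
#'   are written there with stable filenames.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  cond_results <- list()
  for (name in names(cfg$conditions)) {
    cells <- .load_condition_cells(cfg, name)
    analyzed <- lapply(cells, .analyze_cell, seg = cfg$seg,
                       units = cfg$distance_units)
    stats_tab <- do.call(rbind, lapply(analyzed, `[[`, "stats"))
    nds <- Filter(Negate(is.null), lapply(analyzed, `[[`, "nd"))
    excluded <- stats_tab$cell_id[stats_tab$n_components == 0L]
    if (length(excluded)) {
      warning("condition '", name, "': ", length(excluded),
              " cell(s) with no surviving components excluded from pooling",
              call. = FALSE)
    }
    if (length(nds) == 0L) {
      stop("condition '", name, "' has no cells with mitochondrial pixels",
           call. = FALSE)
    }
    pooled <- pool_condition(nds)
    cond_results[[name]] <- list(
      cell_stats = stats_tab,
      distances = nds,
      pooled = pooled,
      histogram = radial_histogram(pooled, n_bins = cfg$n_bins),
      peripheral = peripheral_subset(pooled, cfg$fraction),
      excluded_cells = as.character(excluded))
  }

  nm <- names(cond_results)
  comparisons <- NULL
  if (length(nm) >= 2L) {
    pairs <- utils::combn(nm, 2)
    comparisons <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1, j]; b <- pairs[2, j]
      sa <- if (cfg$ks_scope == "peripheral") cond_results[[a]]$peripheral else
        cond_results[[a]]$pooled
      sb <- if (cfg$ks_scope == "peripheral") cond_results[[b]]$peripheral else
        cond_results[[b]]$pooled
      ks <- ks_two_sample(sa, sb)
      data.frame(condition_a = a, condition_b = b,
                 n_cells_a = nrow(cond_results[[a]]$cell_stats) -
                   length(cond_results[[a]]$excluded_cells),
                 n_cells_b = nrow(cond_results[[b]]$cell_stats) -
                   length(cond_results[[b]]$excluded_cells),
                 n1 = ks$n1, n2 = ks$n2, D = ks$D, p_value = ks$p_value,
                 fraction = cfg$fraction, scope = cfg$ks_scope,
                 method = ks$method)
    }))
  }

  report <- structure(list(conditions = cond_results, comparisons = comparisons,
                           config = cfg, seed = cfg$seed),
                      class = "pipeline_report")
  if (!is.null(cfg$out_dir)) write_pipeline_report(report, cfg$out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report\n")
  for (nm in names(x$conditions)) {
    co <- x$conditions[[nm]]
    cat(sprintf("  %s: %d cells (%d excluded), %d pixels, mean norm. distance %.4f\n",
                nm, nrow(co$cell_stats), length(co$excluded_cells),
                length(co$pooled), mean(co$pooled)))
  }
  if (!is.null(x$comparisons)) {
    for (j in seq_len(nrow(x$comparisons))) {
      cm <- x$comparisons[j, ]
      cat(sprintf("  %s vs %s (%s): D = %.4f, p = %.3g\n",
                  cm$condition_a, cm$condition_b, cm$scope, cm$D, cm$p_value))
    }
  }
  invisible(x)
}

#' Write pipeline artifacts to a directory
#'
#' Writes, per condition, `<name>_cell_stats.csv`,
#' `<name>_distances.csv` (`cell_id,normalized_distance`, one row per
#' pixel) and `<name>_histogram.csv`, plus a `report.json` with the
#' pooled summaries and pairwise comparisons.
#'
#' @param report a `pipeline_report`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_pipeline_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(report$conditions)) {
    co <- report$conditions[[nm]]
    write.csv(co$cell_stats, file.path(dir, paste0(nm, "_cell_stats.csv")),
              row.names = FALSE)
    dist_tab <- do.call(rbind, lapply(co$distances, function(nd) {
      data.frame(cell_id = nd$cell_id, normalized_distance = nd$values)
    }))
    write.csv(dist_tab, file.path(dir, paste0(nm, "_distances.csv")),
              row.names = FALSE)
    write_histogram_csv(co$histogram, file.path(dir, paste0(nm, "_histogram.csv")))
  }
  summary <- list(
    seed = report$seed,
    conditions = lapply(report$conditions, function(co) {
      list(n_cells = nrow(co$cell_stats),
           excluded_cells = co$excluded_cells,
           n_pixels = length(co$pooled),
           mean_normalized_distance = mean(co$pooled),
           mean_peripheral_distance = mean(co$peripheral))
    }),
    comparisons = report$comparisons)
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Robustness sweep over preprocessing parameters
#'
#' Repeats the full condition comparison for every combination of
#' Gaussian smoothing sigma and binarization threshold, reporting the
#' first condition pair's KS statistic and p-value together with each
#' condition's pooled mean normalized distance.  Stacks are generated
#' (or read) once and re-segmented per combination.  Combinations under
#' which a cell yields zero segmented pixels are flagged via
#' `n_excluded`; a combination where every cell of a condition is empty
#' yields `NA` results rather than an error.
#'
#' @param cfg a [run_config] with at least two conditions.
#' @param sigma_values,threshold_values nonempty numeric grids.
#' @return a data.frame with one row per `(sigma, threshold)` pair:
#'   `gaussian_sigma`, `threshold`, `D`, `p_value`, `significant`
#'   (p < 0.05), per-condition mean pooled distances, `n_excluded`.
#' @export
sensitivity_sweep <- function(cfg, sigma_values, threshold_values) {
  stopifnot(inherits(cfg, "run_config"))
  if (!length(sigma_values) || !length(threshold_values)) {
    stop("parameter grids must be nonempty", call. = FALSE)
  }
  if (length(cfg$conditions) < 2L) {
    stop("sensitivity_sweep needs at least two conditions", call. = FALSE)
  }
  loaded <- lapply(names(cfg$conditions), function(nm) .load_condition_cells(cfg, nm))
  names(loaded) <- names(cfg$conditions)

  grid <- expand.grid(gaussian_sigma = sigma_values, threshold = threshold_values,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    seg <- cfg$seg
    seg$gaussian_sigma <- grid$gaussian_sigma[g]
    seg$threshold <- grid$threshold[g]
    scope <- list()
    means <- list()
    n_excluded <- 0L
    for (nm in names(loaded)) {
      analyzed <- lapply(loaded[[nm]], .analyze_cell, seg = seg,
                         units = cfg$distance_units)
      nds <- Filter(Negate(is.null), lapply(analyzed, `[[`, "nd"))
      n_excluded <- n_excluded + sum(vapply(analyzed, function(a) is.null(a$nd),
                                            logical(1)))
      if (length(nds) == 0L) { scope[[nm]] <- NULL; means[[nm]] <- NA_real_; next }
      pooled <- pool_condition(nds)
      means[[nm]] <- mean(pooled)
      scope[[nm]] <- if (cfg$ks_scope == "peripheral") {
        peripheral_subset(pooled, cfg$fraction)
      } else pooled
    }
    ab <- names(loaded)[1:2]
    out <- data.frame(gaussian_sigma = grid$gaussian_sigma[g],
                      threshold = grid$threshold[g],
                      D = NA_real_, p_value = NA_real_, significant = NA,
                      n_excluded = n_excluded)
    if (!is.null(scope[[ab[1]]]) && !is.null(scope[[ab[2]]])) {
      ks <- ks_two_sample(scope[[ab[1]]], scope[[ab[2]]])
      out$D <- ks$D
      out$p_value <- ks$p_value
      out$significant <- ks$p_value < 0.05
    }
    for (nm in names(loaded)) out[[paste0("mean_", nm)]] <- means[[nm]]
    out
  })
  do.call(rbind, rows)
}

#' Read a run configuration from a YAML document
#'
#' The document mirrors [run_config]: a `conditions` mapping (each entry
#' with either `annotation:` or a `spec:` mapping of [phantom_spec]
#' arguments plus `n_cells:`), optional `segmentation:`, `analysis:`
#' (`fraction`, `n_bins`, `distance_units`, `ks_scope`), `out_dir:` and
#' `seed:` keys.
#'
#' @param path YAML file path.
#' @return a [run_config].
#' @export
read_run_config <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$conditions)) stop("config needs a 'conditions' mapping",
                                    call. = FALSE)
  conditions <- lapply(doc$conditions, function(cond) {
    if (!is.null(cond$spec)) {
      sp <- cond$spec
      if (!is.null(sp$radial_density) && is.list(sp$radial_density)) {
        sp$radial_density <- radial_density(sp$radial_density$family,
                                            sp$radial_density$strength %||% 1)
      }
      if (!is.null(sp$stack_shape)) sp$stack_shape <- unlist(sp$stack_shape)
      if (!is.null(sp$voxel_size)) sp$voxel_size <- unlist(sp$voxel_size)
      if (!is.null(sp$mito_length_range)) {
        sp$mito_length_range <- unlist(sp$mito_length_range)
      }
      list(spec = do.call(phantom_spec, sp), n_cells = cond$n_cells,
           per_cell_jitter = cond$per_cell_jitter)
    } else {
      cond
    }
  })
  seg <- do.call(segmentation_config, doc$segmentation %||% list())
  an <- doc$analysis %||% list()
  run_config(conditions = conditions, seg = seg,
             fraction = an$fraction %||% 0.30,
             n_bins = an$n_bins %||% 50,
             distance_units = an$distance_units %||% "physical",
             ks_scope = an$ks_scope %||% "peripheral",
             out_dir = doc$out_dir, seed = doc$seed %||% 1L)
}
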