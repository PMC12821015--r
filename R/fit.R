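#' Parameter grid for least-squares model fitting
#'
#' Cartesian grid over the transport-model parameters that matter for
#' the shape of the steady-state radial distribution: the PKA signal,
#' the binding rate, the anterograde speed, and a multiplier on the
#' free-state diffusion step size (`step_scale` multiplies the Gaussian
#' step standard deviation, i.e. scales the diffusion coefficient by
#' `step_scale^2`).
#'
#' @param pka_signal,k_bind,v_plus,step_scale nonempty numeric value
#'   lists.
#' @param base a [sim_params] supplying every other parameter.
#' @return an object of class `fit_grid`.
#' @export
fit_grid <- function(pka_signal = c(0.2, 0.5, 0.7, 1, 1.5, 2.5),
                     k_bind = 0.025, v_plus = 0.4, step_scale = 1,
                     base = sim_params()) {
  for (nm in c("pka_signal", "k_bind", "v_plus", "step_scale")) {
    v <- get(nm)
    if (!length(v) || any(!is.finite(v)) || any(v < 0)) {
      stop(sprintf("'%s' must be a nonempty vector of nonnegative values", nm),
           call. = FALSE)
    }
  }
  stopifnot(inherits(base, "sim_params"))
  structure(list(pka_signal = pka_signal, k_bind = k_bind, v_plus = v_plus,
                 step_scale = step_scale, base = base),
            class = "fit_grid")
}

#' Sum of squared differences between two density histograms
#'
#' @param h1,h2 `radial_histogram` objects on identical bin edges.
#' @return `sum((density1 - density2)^2)`; 0 iff the histograms are
#'   identical. Symmetric.
#' @export
histogram_sse <- function(h1, h2) {
  if (length(h1$bin_edges) != length(h2$bin_edges) ||
      any(abs(h1$bin_edges - h2$bin_edges) > 1e-12)) {
    stop("histograms must share identical bin edges", call. = FALSE)
  }
  sum((h1$density - h2$density)^2)
}

#' Fit the transport model to an observed radial histogram
#'
#' Grid-search least squares: for every grid point a steady-state
#' simulation is run with a common seed (common random numbers keep the
#' objective surface smooth), its final radial distances are histogrammed
#' on the observed bin edges, and the sum of squared density differences
#' is scored.  Grid points whose simulation fails to reach steady state
#' are excluded with a warning.
#'
#' @param observed a `radial_histogram` of observed normalized radial
#'   distances.
#' @param grid a [fit_grid].
#' @param seed seed reused for every grid point (default: the grid's
#'   base params seed).
#' @return an object of class `fit_result`: list with `best` (named list
#'   of the argmin parameter combination), `objective`, `surface` (long
#'   data.frame `pka_signal,k_bind,v_plus,step_scale,sse,converged`),
#'   and `seed`.
#' @export
fit_distribution <- function(observed, grid, seed = NULL) {
  stopifnot(inherits(observed, "radial_histogram"), inherits(grid, "fit_grid"))
  seed <- as.integer(seed %||% grid$base$seed)
  combos <- expand.grid(pka_signal = grid$pka_signal, k_bind = grid$k_bind,
                        v_plus = grid$v_plus, step_scale = grid$step_scale,
                        KEEP.OUT.ATTRS = FALSE)
  sse <- numeric(nrow(combos))
  conv <- logical(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    p <- grid$base
    p$pka_signal <- combos$pka_signal[i]
    p$k_bind <- combos$k_bind[i]
    p$v_plus <- combos$v_plus[i]
    p$diffusion <- p$diffusion * combos$step_scale[i]^2
    p$seed <- seed
    res <- withCallingHandlers(run_simulation(p),
                               warning = function(w) invokeRestart("muffleWarning"))
    conv[i] <- res$converged
    sse[i] <- if (res$converged) {
      histogram_sse(observed, radial_histogram(res$r, bin_edges = observed$bin_edges))
    } else NA_real_
  }
  if (any(!conv)) {
    warning(sum(!conv), " grid point(s) did not reach steady state and were excluded",
            call. = FALSE)
  }
  if (all(is.na(sse))) stop("no grid point reached steady state", call. = FALSE)
  best_i <- which.min(sse)
  surface <- cbind(combos, sse = sse, converged = conv)
  structure(list(best = as.list(combos[best_i, , drop = FALSE]),
                 objective = sse[best_i], surface = surface, seed = seed),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "fit_result: best pka_signal = %g, k_bind = %g, v_plus = %g, step_scale = %g (SSE = %.4g)\n",
    x$best$pka_signal, x$best$k_bind, x$best$v_plus, x$best$step_scale, x$objective))
  invisible(x)
}

#' Classify the mode location of a radial histogram
#'
#' Labels the histogram by the center of its maximum-density bin:
#' `"inner"` if the mode center is below 1/3, `"mid"` if in
#' `[1/3, 2/3]`, `"peripheral"` if above 2/3.  Ties (including flat
#' histograms) are broken toward the outermost maximal bin and flagged
#' via the `"tie"` attribute.
#'
#' @param h a `radial_histogram`.
#' @return a character label with attribute `tie`.
#' @export
classify_peak_location <- function(h) {
  stopifnot(inherits(h, "radial_histogram"))
  dmax <- max(h$density)
  maximal <- which(h$density == dmax)
  mode_bin <- maximal[length(maximal)]
  tie <- length(maximal) > 1L
  center <- (h$bin_edges[mode_bin] + h$bin_edges[mode_bin + 1]) / 2
  label <- if (center < 1 / 3) "inner" else if (center <= 2 / 3) "mid" else "peripheral"
  structure(label, tie = tie)
}
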