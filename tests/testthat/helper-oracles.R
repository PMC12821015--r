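# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the flood fill is plain-R queue-based BFS, the
# KS oracle enumerates label assignments exhaustively, and the walker step
# re-implements the documented RNG draw order with R-level draws.

# Brute-force 26-connectivity flood fill on a logical 3D array.
oracle_flood_fill_26 <- function(mask) {
  d <- dim(mask)
  labels <- array(0L, d)
  nb <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  nxt <- 0L
  for (i in which(mask)) {
    if (labels[i] != 0L) next
    nxt <- nxt + 1L
    queue <- matrix(arrayInd(i, d), ncol = 3)
    labels[i] <- nxt
    while (nrow(queue) > 0) {
      v <- queue[1, ]
      queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(nrow(nb))) {
        w <- v + nb[k, ]
        if (any(w < 1) || any(w > d)) next
        wi <- matrix(w, ncol = 3)
        if (mask[wi] && labels[wi] == 0L) {
          labels[wi] <- nxt
          queue <- rbind(queue, w)
        }
      }
    }
  }
  labels
}

# Partition signature invariant to label numbering: sorted list of sorted
# linear-index sets.
partition_signature <- function(labels) {
  idx <- which(labels > 0L)
  if (!length(idx)) return(list())
  sets <- split(idx, labels[idx])
  sets <- lapply(sets, sort)
  sets[order(vapply(sets, `[`, numeric(1), 1))]
}

component_set_signature <- function(cs) {
  sets <- lapply(cs$components, function(m) {
    as.integer(sort(m[, 1] + (m[, 2] - 1) * cs$shape[1] +
                      (m[, 3] - 1) * cs$shape[1] * cs$shape[2]))
  })
  sets[order(vapply(sets, `[`, numeric(1), 1))]
}

ks_D_stat <- function(a, b) {
  u <- sort(unique(c(a, b)))
  max(abs(cumsum(tabulate(findInterval(a, u), length(u))) / length(a) -
            cumsum(tabulate(findInterval(b, u), length(u))) / length(b)))
}

# Exact two-sample KS p-value by exhaustive enumeration of all C(n+m, n)
# label assignments of the pooled sample (feasible for small n, m).
oracle_ks_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  d_obs <- ks_D_stat(a, b)
  picks <- utils::combn(length(pooled), n)
  hits <- 0L
  for (j in seq_len(ncol(picks))) {
    aa <- pooled[picks[, j]]
    bb <- pooled[-picks[, j]]
    if (ks_D_stat(aa, bb) >= d_obs - 1e-12) hits <- hits + 1L
  }
  hits / ncol(picks)
}

# Plain-R single walker step following the documented draw order: one
# uniform (switch), then two normals iff unbound after the switch.
oracle_advance_step <- function(state, params) {
  v_drift <- drift_velocity(params$pka_signal, params$v_plus, params$v_minus)
  sd_step <- sqrt(2 * params$diffusion * params$dt)
  for (i in seq_along(state$x)) {
    u <- runif(1)
    if (state$bound[i]) {
      if (u < params$k_unbind * params$dt) state$bound[i] <- FALSE
    } else {
      if (u < params$k_bind * params$dt) state$bound[i] <- TRUE
    }
    if (!state$bound[i]) {
      xx <- state$x[i] + sd_step * rnorm(1)
      yy <- state$y[i] + sd_step * rnorm(1)
      r <- sqrt(xx^2 + yy^2)
      if (r > 1) {
        rr <- r
        for (g in 1:8) { if (rr <= 1) break; rr <- abs(2 - rr) }
        rr <- min(rr, 1)
        xx <- xx * rr / r
        yy <- yy * rr / r
        r2 <- xx^2 + yy^2
        if (r2 > 1) { xx <- xx / sqrt(r2); yy <- yy / sqrt(r2) }
      }
      state$x[i] <- xx
      state$y[i] <- yy
    } else {
      r <- sqrt(state$x[i]^2 + state$y[i]^2)
      rn <- min(r + v_drift * params$dt, 1)
      if (r > 0) {
        f <- rn / r
        state$x[i] <- state$x[i] * f
        state$y[i] <- state$y[i] * f
        r2 <- state$x[i]^2 + state$y[i]^2
        if (r2 > 1) {
          state$x[i] <- state$x[i] / sqrt(r2)
          state$y[i] <- state$y[i] / sqrt(r2)
        }
      } else {
        state$x[i] <- abs(rn)
        state$y[i] <- 0
      }
    }
  }
  state
}

mask_from_components <- function(cs) {
  m <- array(FALSE, cs$shape)
  for (co in cs$components) m[co] <- TRUE
  m
}

mask_from_voxels <- function(vox, shape) {
  m <- array(FALSE, shape)
  if (nrow(vox)) m[vox] <- TRUE
  m
}
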