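`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_num <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  bad <- if (strict_min) x <= min else x < min
  if (bad) {
    stop(sprintf("'%s' must be %s %s", name, if (strict_min) ">" else ">=", min),
         call. = FALSE)
  }
  invisible(x)
}

#' Derive a reproducible child seed from a master seed and string labels
#'
#' All pipeline randomness flows from one master seed; stage- and
#' cell-level seeds are derived by a stable string hash so that adding or
#' reordering stages does not perturb unrelated stages.  The hash is a
#' 31-multiplier polynomial over the UTF-8 bytes of
#' `paste(master, labels..., sep = "/")`, reduced mod 2^31 - 1 (safe in
#' doubles, and a valid R integer seed).
#'
#' @param master integer master seed.
#' @param ... character or numeric labels (stage name, cell id, ...).
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  key <- paste(c(master, ...), collapse = "/")
  bytes <- utf8ToInt(key)
  h <- 0
  m <- 2147483647
  for (b in bytes) h <- (h * 31 + b) %% m
  as.integer(h)
}

# Run fn with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  fn()
}
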