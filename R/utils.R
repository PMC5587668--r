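# Internal helpers: error signalling, seed management, small validators.

abort <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "tilscreen_error")))
}

#' @noRd
is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort(sprintf("`%s` must be a single finite number", name),
          "tilscreen_validation_error")
  if (positive && x <= 0)
    abort(sprintf("`%s` must be > 0 (got %g)", name, x),
          "tilscreen_validation_error")
  invisible(x)
}

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so simulators do not perturb the global stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    abort("`seed` must be a single finite integer", "tilscreen_validation_error")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% (.Machine$integer.max - 1L)) + 1L)
  force(expr)
}

#' Derive deterministic per-stage seeds from one root seed
#'
#' All randomness in a pipeline run flows from a single root seed; each stage
#' draws its own substream seed from this function so that adding or removing
#' a stage does not shift the randomness of the others.
#'
#' @param seed root seed (single integer).
#' @param n number of substream seeds to derive.
#' @return integer vector of `n` seeds, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot_scalar_number(seed, "seed")
  stopifnot_scalar_number(n, "n", positive = TRUE)
  with_seed(seed, sample.int(.Machine$integer.max - 1L, as.integer(n)))
}

# jsonlite writer with the conventions used throughout: scalars unboxed,
# full double precision.
write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}
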