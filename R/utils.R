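# Internal helpers shared across modules.

# Run `expr` under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic k-fold assignment keyed to sample ids: permuting rows (together
# with their ids) never changes which fold a sample lands in.
fold_ids <- function(ids, k, seed = 1L) {
  ids <- as.character(ids)
  uid <- sort(unique(ids))
  perm <- with_seed(seed, sample.int(length(uid)))
  fold_of_uid <- (perm - 1L) %% k + 1L
  fold_of_uid[match(ids, uid)]
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
}
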