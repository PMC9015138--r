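# internal helpers

# run code with a local RNG state so library internals don't perturb the
# caller's random stream
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# linear index (1-based) <-> voxel coordinate helpers for a dim-3 array
idx_to_coord <- function(idx, dm) {
  idx0 <- idx - 1L
  x <- idx0 %% dm[1]
  y <- (idx0 %/% dm[1]) %% dm[2]
  z <- idx0 %/% (dm[1] * dm[2])
  cbind(x = x + 1L, y = y + 1L, z = z + 1L)
}

coord_to_idx <- function(xyz, dm) {
  (xyz[, 1] - 1L) + dm[1] * ((xyz[, 2] - 1L) + dm[2] * (xyz[, 3] - 1L)) + 1L
}
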