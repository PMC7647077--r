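## internal helpers shared across modules

# Run code with a temporarily seeded RNG, restoring global state afterwards.
# All generator functions route their randomness through this so no call
# mutates the caller's RNG.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic number formatting used by every writer (exact round trip)
fmt_num <- function(x) sprintf("%.17g", x)

# coerce list-of-matrices / 3D array / network_tensor into a 3D array
as_tensor_array <- function(tensors) {
  if (inherits(tensors, "network_tensor")) return(tensors$coefficients)
  if (is.array(tensors) && length(dim(tensors)) == 3L) return(tensors)
  if (is.list(tensors)) {
    d <- dim(tensors[[1L]])
    if (is.null(d)) stop_invalid("tensor slices must be matrices")
    bad <- vapply(tensors, function(x) !identical(dim(x), d), logical(1))
    if (any(bad)) stop_invalid("tensor slices have inconsistent dimensions")
    return(array(unlist(tensors, use.names = FALSE), dim = c(d, length(tensors))))
  }
  stop_invalid("`tensors` must be a 3D array, a list of matrices, or a network_tensor")
}
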