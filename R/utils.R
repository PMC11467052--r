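# shared helpers

assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

is_binary <- function(x) all(x %in% c(0, 1, FALSE, TRUE))

as_mask <- function(x) {
  m <- matrix(as.integer(x != 0), nrow = nrow(x))
  m
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a stream of child seeds from one parent seed; values stay < 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 30269 + 1013) %%
               2147483629)
}

# pixel coordinates (row, col) of TRUE/1 entries of a matrix
which_pixels <- function(mask) {
  which(mask != 0, arr.ind = TRUE)
}
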