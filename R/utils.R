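# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_image <- function(x) is.matrix(x) && is.numeric(x)

assert_image <- function(x, what = "image") {
  if (!is_image(x)) stopf("%s must be a numeric matrix", what)
  if (anyNA(x)) stopf("%s contains missing values", what)
  invisible(x)
}

# binary disk mask of the given radius (used by tests and rasterizers)
disk_mask <- function(radius) {
  d <- -radius:radius
  outer(d^2, d^2, `+`) <= radius^2
}

# run `expr` under a private RNG stream seeded with `seed`; the caller's
# RNG state is untouched
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# linear (column-major, 1-based) indices of mask TRUE entries
mask_to_idx <- function(mask) which(mask)

idx_to_rc <- function(idx, nr) {
  cbind(row = ((idx - 1L) %% nr) + 1L, col = ((idx - 1L) %/% nr) + 1L)
}

rc_to_idx <- function(r, c, nr) (c - 1L) * nr + r

# intersection size of two sorted-or-unsorted integer index vectors
n_intersect <- function(a, b) {
  if (length(a) > length(b)) { tmp <- a; a <- b; b <- tmp }
  sum(!is.na(match(a, b)))
}
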