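#' @useDynLib emalign, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd var quantile median
NULL

#' Slice stack container
#'
#' An ordered sequence of same-shape 2D grayscale slices, the unit every
#' pipeline stage consumes and produces. Pixel values are stored as doubles in
#' \[0, 1\]; conversion to/from integer bit depths happens only at the I/O
#' boundary. Axis order is (z, row, col); pixel coordinates are 0-based with
#' pixel centers at integer positions.
#'
#' @param slices list of numeric matrices, all with identical dimensions.
#' @param bit_depth original bit depth (8 or 16), kept for write-back.
#' @return An object of class `slice_stack` with elements `slices`, `height`,
#'   `width`, `n`, `bit_depth`.
#' @export
slice_stack <- function(slices, bit_depth = 8L) {
  if (!is.list(slices) || length(slices) == 0L)
    stop("empty input: a slice stack needs at least one slice")
  dims <- vapply(slices, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("shape mismatch: all slices must share one shape")
  if (!all(vapply(slices, function(s) all(is.finite(s)), logical(1))))
    stop("slice values must be finite")
  structure(
    list(slices = slices, height = dims[1, 1], width = dims[2, 1],
         n = length(slices), bit_depth = as.integer(bit_depth)),
    class = "slice_stack")
}

#' @export
print.slice_stack <- function(x, ...) {
  cat(sprintf("<slice_stack> %d slices of %d x %d (bit depth %d)\n",
              x$n, x$height, x$width, x$bit_depth))
  invisible(x)
}

#' @export
length.slice_stack <- function(x) x$n

#' Extract one slice as a matrix
#' @param stack a `slice_stack`.
#' @param i slice index (1-based).
#' @return numeric matrix.
#' @export
get_slice <- function(stack, i) stack$slices[[i]]

# map over slices, keeping metadata
map_stack <- function(stack, f, ...) {
  out <- stack
  out$slices <- lapply(stack$slices, f, ...)
  out
}

# 0-based row/col coordinate grids for an h x w image
coord_grids <- function(h, w) {
  list(r = matrix(0:(h - 1), h, w),
       c = matrix(0:(w - 1), h, w, byrow = TRUE))
}

# deterministic local RNG scope: run f() under set.seed(seed) and restore
# the caller's RNG state afterwards
with_seed <- function(seed, f) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  f()
}

# normalized symmetric Gaussian taps for spatial filtering, radius = ceil(4*sigma)
gaussian_taps <- function(sigma, radius = ceiling(4 * sigma)) {
  k <- exp(-((-radius):radius)^2 / (2 * sigma^2))
  k / sum(k)
}

# replicate-boundary Gaussian blur of a matrix
blur2d <- function(img, sigma) {
  if (sigma <= 0) return(img)
  cpp_sepconv(img, gaussian_taps(sigma))
}

clip01 <- function(x) pmin(pmax(x, 0), 1)
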