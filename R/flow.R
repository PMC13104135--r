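#' Displacement field constructor
#'
#' A per-pixel backward-warp field between two slices: `field[, , 1]` holds
#' row displacements and `field[, , 2]` column displacements, in pixels.
#' Backward convention throughout: `warp(img, field)(p) = img(p + field(p))`.
#'
#' @param drow,dcol numeric matrices of row/column displacements (px).
#' @return array of dim `c(h, w, 2)` with class `displacement_field`.
#' @export
displacement_field <- function(drow, dcol) {
  if (!identical(dim(drow), dim(dcol)))
    stop("shape mismatch between displacement channels")
  if (!all(is.finite(drow)) || !all(is.finite(dcol)))
    stop("displacement values must be finite")
  f <- array(0, dim = c(nrow(drow), ncol(drow), 2))
  f[, , 1] <- drow
  f[, , 2] <- dcol
  class(f) <- "displacement_field"
  f
}

#' Spatially constant displacement field
#' @param h,w field dimensions.
#' @param u length-2 displacement (row, col) in px.
#' @return `displacement_field`.
#' @export
constant_field <- function(h, w, u) {
  displacement_field(matrix(u[1], h, w), matrix(u[2], h, w))
}

#' Zero displacement field
#' @param h,w field dimensions.
#' @export
zero_field <- function(h, w) constant_field(h, w, c(0, 0))

field_drow <- function(f) matrix(f[, , 1], dim(f)[1], dim(f)[2])
field_dcol <- function(f) matrix(f[, , 2], dim(f)[1], dim(f)[2])

is_constant_field <- function(f, tol = 1e-12) {
  (max(f[, , 1]) - min(f[, , 1]) <= tol) &&
    (max(f[, , 2]) - min(f[, , 2]) <= tol)
}

#' Scale a displacement field
#' @param field a `displacement_field`.
#' @param c scalar multiplier.
#' @export
scale_field <- function(field, c) {
  displacement_field(c * field_drow(field), c * field_dcol(field))
}

#' Weighted elementwise combination of displacement fields
#'
#' Computes `sum_k weights[k] * fields[[k]]` channelwise. This is the raw
#' weighted-sum algebra the axial Gaussian integration uses (not diffeomorphic
#' composition).
#'
#' @param fields list of same-shape `displacement_field`s.
#' @param weights numeric vector, one weight per field.
#' @export
combine_fields <- function(fields, weights) {
  stopifnot(length(fields) == length(weights), length(fields) >= 1)
  d <- dim(fields[[1]])
  for (f in fields) if (!identical(dim(f), d)) stop("shape mismatch among fields")
  if (!all(is.finite(weights))) stop("weights must be finite")
  dr <- matrix(0, d[1], d[2]); dc <- matrix(0, d[1], d[2])
  for (k in seq_along(fields)) {
    dr <- dr + weights[k] * field_drow(fields[[k]])
    dc <- dc + weights[k] * field_dcol(fields[[k]])
  }
  displacement_field(dr, dc)
}

#' Backward-warp an image by a displacement field
#'
#' `out(p) = img(p + field(p))`, bilinear interpolation, out-of-bounds samples
#' edge-clamped. If the image carries a `true_shift` attribute (translation
#' fixtures produced by [tag_shift()]) and the field is spatially constant,
#' the attribute is propagated (`true_shift - c`), so oracle-flow tests can
#' track content positions exactly through the pipeline.
#'
#' @param img numeric matrix.
#' @param field `displacement_field` with matching shape.
#' @return warped matrix.
#' @export
warp <- function(img, field) {
  if (!identical(dim(img), dim(field)[1:2]))
    stop("shape mismatch between image and field")
  g <- coord_grids(nrow(img), ncol(img))
  out <- cpp_bilinear_sample(img, g$r + field_drow(field), g$c + field_dcol(field))
  ts <- attr(img, "true_shift")
  if (!is.null(ts) && is_constant_field(field))
    attr(out, "true_shift") <- ts - c(field[1, 1, 1], field[1, 1, 2])
  out
}

#' Tag a translation-fixture image with its known content shift
#'
#' Test instrumentation for pure-translation stacks: records the true content
#' shift (row, col) as an attribute that [warp()] propagates through constant
#' fields and [translation_oracle_flow()] reads back.
#'
#' @param img numeric matrix.
#' @param shift length-2 numeric content shift (px).
#' @export
tag_shift <- function(img, shift) {
  attr(img, "true_shift") <- as.numeric(shift)
  img
}

#' Exact flow for tagged translation fixtures
#'
#' A flow estimator test double: for images tagged with [tag_shift()], the
#' exact backward field registering `moving` onto `fixed` is the constant
#' `shift(moving) - shift(fixed)`. Lets the axial Gaussian filtering algebra
#' be verified to machine precision, independent of estimator error.
#'
#' @param fixed,moving tagged numeric matrices.
#' @return constant `displacement_field`.
#' @export
translation_oracle_flow <- function(fixed, moving) {
  sf <- attr(fixed, "true_shift"); sm <- attr(moving, "true_shift")
  if (is.null(sf) || is.null(sm))
    stop("translation_oracle_flow needs images tagged with tag_shift()")
  constant_field(nrow(fixed), ncol(fixed), sm - sf)
}

#' Flow estimator parameters
#'
#' @param levels pyramid levels; `NULL` picks the number of levels so the
#'   coarsest level is at least `min_size` px on its short side.
#' @param outer_iters warp-and-relinearize iterations per level.
#' @param inner_iters Jacobi iterations of the linearized solve.
#' @param lambda quadratic smoothness weight of the displacement increment
#'   (larger = smoother fields).
#' @param min_size minimum image side at the coarsest pyramid level (px).
#' @param global_init initialize the coarsest level with an integer global
#'   translation from phase correlation (captures the slowly converging
#'   global mode; the relaxation solve then only handles local structure).
#' @return list of class `flow_params`.
#' @export
flow_params <- function(levels = NULL, outer_iters = 3L, inner_iters = 100L,
                        lambda = 0.15, min_size = 32L, global_init = TRUE) {
  if (!is.null(levels) && levels < 1) stop("levels must be >= 1")
  if (outer_iters < 1) stop("outer_iters must be >= 1")
  if (lambda <= 0) stop("lambda must be > 0")
  structure(list(levels = levels, outer_iters = as.integer(outer_iters),
                 inner_iters = as.integer(inner_iters), lambda = lambda,
                 min_size = as.integer(min_size),
                 global_init = isTRUE(global_init)),
            class = "flow_params")
}

#' Integer global translation by phase correlation
#'
#' Cross-correlation peak (FFT-based, mean-removed) between two same-shape
#' images; returns the integer (row, col) content shift of `moving` relative
#' to `fixed`, i.e. the constant backward field registering `moving` onto
#' `fixed`. Exact for integer circular shifts; used as coarse initialization
#' and as an independent translation oracle in tests.
#'
#' @param fixed,moving same-shape numeric matrices.
#' @return length-2 integer vector (row, col).
#' @export
phase_shift <- function(fixed, moving) {
  f <- fixed - mean(fixed); m <- moving - mean(moving)
  r <- Re(stats::fft(Conj(stats::fft(f)) * stats::fft(m), inverse = TRUE))
  idx <- which.max(r)
  h <- nrow(f); w <- ncol(f)
  dr <- (idx - 1) %% h
  dc <- (idx - 1) %/% h
  if (dr > h / 2) dr <- dr - h
  if (dc > w / 2) dc <- dc - w
  c(dr, dc)
}

# bilinear resize of a matrix to (h, w)
resize_bilinear <- function(img, h, w) {
  sr <- (nrow(img) - 1) / max(h - 1, 1)
  sc <- (ncol(img) - 1) / max(w - 1, 1)
  qr <- matrix((0:(h - 1)) * sr, h, w)
  qc <- matrix((0:(w - 1)) * sc, h, w, byrow = TRUE)
  cpp_bilinear_sample(img, qr, qc)
}

# antialiased half resolution
downsample2 <- function(img) {
  b <- blur2d(img, 1)
  resize_bilinear(b, max(2L, ceiling(nrow(img) / 2)), max(2L, ceiling(ncol(img) / 2)))
}

central_grad <- function(img) {
  h <- nrow(img); w <- ncol(img)
  up <- img[c(1, 1:(h - 1)), , drop = FALSE]
  dn <- img[c(2:h, h), , drop = FALSE]
  lf <- img[, c(1, 1:(w - 1)), drop = FALSE]
  rt <- img[, c(2:w, w), drop = FALSE]
  list(gr = (dn - up) / 2, gc = (rt - lf) / 2)
}

#' Estimate the dense displacement field between two slices
#'
#' Classical coarse-to-fine estimator: Gaussian pyramid, per-level linearized
#' brightness-constancy solve with quadratic smoothness (Horn-Schunck
#' increments), bilinear field upsampling with displacement rescaling, and
#' `outer_iters` warp-and-relinearize passes per level. Fulfills the same
#' contract as a learned pyramidal flow network and is pluggable wherever a
#' flow function is accepted: `warp(moving, field) ~ fixed`. Fully
#' deterministic given inputs and parameters.
#'
#' @param fixed,moving same-shape numeric matrices in \[0, 1\].
#' @param params a [flow_params()] list.
#' @return `displacement_field` (backward convention).
#' @export
estimate_flow <- function(fixed, moving, params = flow_params()) {
  if (!identical(dim(fixed), dim(moving))) stop("shape mismatch")
  h <- nrow(fixed); w <- ncol(fixed)
  if (min(h, w) < params$min_size)
    stop(sprintf("images smaller than the minimum pyramid level (%d px)", params$min_size))
  nlev <- params$levels
  if (is.null(nlev))
    nlev <- max(1L, floor(log2(min(h, w) / params$min_size)) + 1L)
  pyr_f <- vector("list", nlev); pyr_m <- vector("list", nlev)
  pyr_f[[1]] <- fixed; pyr_m[[1]] <- moving
  if (nlev > 1) for (l in 2:nlev) {
    pyr_f[[l]] <- downsample2(pyr_f[[l - 1]])
    pyr_m[[l]] <- downsample2(pyr_m[[l - 1]])
  }
  u <- NULL; v <- NULL
  if (isTRUE(params$global_init)) {
    s <- phase_shift(pyr_f[[nlev]], pyr_m[[nlev]])
    u <- matrix(s[1], nrow(pyr_f[[nlev]]), ncol(pyr_f[[nlev]]))
    v <- matrix(s[2], nrow(pyr_f[[nlev]]), ncol(pyr_f[[nlev]]))
  }
  for (l in nlev:1) {
    fl <- pyr_f[[l]]; ml <- pyr_m[[l]]
    hl <- nrow(fl); wl <- ncol(fl)
    if (is.null(u)) {
      u <- matrix(0, hl, wl); v <- matrix(0, hl, wl)
    } else {
      su <- hl / nrow(u)
      u <- resize_bilinear(u, hl, wl) * su
      v <- resize_bilinear(v, hl, wl) * su
    }
    for (t in seq_len(params$outer_iters)) {
      mw <- warp(ml, displacement_field(u, v))
      g <- central_grad((mw + fl) / 2)
      it <- mw - fl
      d <- cpp_hs_solve(g$gr, g$gc, it, params$lambda, params$inner_iters)
      u <- u + d$du
      v <- v + d$dv
    }
  }
  displacement_field(u, v)
}
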