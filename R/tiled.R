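#' Overlapping patch partition of an image plane
#'
#' Patch origins advance at stride `patch - overlap`; the last row/column of
#' patches is clamped so patches stay in bounds, giving full coverage. Each
#' patch carries a separable raised-cosine feather window over its overlap
#' margins (flat at image borders); the windows are normalized at fusion
#' time to a partition of unity.
#'
#' @param height,width image dimensions (px).
#' @param patch patch side length (px); images smaller than `patch` get a
#'   single patch covering the image.
#' @param overlap overlap between adjacent patches (px, `0 <= overlap < patch`).
#' @return list of class `patch_grid`: `patch` (possibly clamped), `overlap`,
#'   `origins` (n x 2 matrix, 0-based row/col), `height`, `width`, `windows`
#'   (list of weight matrices).
#' @export
partition_patches <- function(height, width, patch = 1024L, overlap = 128L) {
  if (overlap < 0 || patch <= overlap) stop("need patch > overlap >= 0")
  ph <- min(patch, height); pw <- min(patch, width)
  origins_axis <- function(size, p, ov) {
    if (size <= p) return(0L)
    stride <- p - ov
    o <- seq(0L, size - p, by = stride)
    if (o[length(o)] + p < size) o <- c(o, size - p)
    as.integer(o)
  }
  or <- origins_axis(height, ph, min(overlap, ph - 1L))
  oc <- origins_axis(width, pw, min(overlap, pw - 1L))
  origins <- as.matrix(expand.grid(row = or, col = oc))[, 1:2, drop = FALSE]
  windows <- lapply(seq_len(nrow(origins)), function(k) {
    wr <- feather_profile(ph, origins[k, 1], height, overlap)
    wc <- feather_profile(pw, origins[k, 2], width, overlap)
    outer(wr, wc)
  })
  structure(list(patch = c(ph, pw), overlap = as.integer(overlap),
                 origins = origins, height = as.integer(height),
                 width = as.integer(width), windows = windows),
            class = "patch_grid")
}

# raised-cosine ramp of length `overlap` at patch edges that have a neighbor;
# edges flush with the image border stay flat
feather_profile <- function(p, origin, size, overlap) {
  w <- rep(1, p)
  if (overlap > 0 && p > overlap) {
    ramp <- 0.5 - 0.5 * cos(pi * (seq_len(overlap) - 0.5) / overlap)
    if (origin > 0) w[seq_len(overlap)] <- ramp
    if (origin + p < size) w[p - seq_len(overlap) + 1L] <- ramp
  }
  w
}

#' Fuse per-patch displacement fields into one global field
#'
#' Weighted sum of patch fields under the grid's feather windows, normalized
#' pixelwise to a partition of unity; constant fields fuse to themselves and
#' the fused field is continuous across patch seams.
#'
#' @param grid a [partition_patches()] grid.
#' @param patch_fields list of patch-shaped [displacement_field()]s, one per
#'   patch, in grid order.
#' @return global [displacement_field()].
#' @export
fuse_fields <- function(grid, patch_fields) {
  n <- nrow(grid$origins)
  if (length(patch_fields) != n) stop("need one field per patch")
  if (n == 1L && grid$patch[1] == grid$height && grid$patch[2] == grid$width)
    return(patch_fields[[1]])  # single-patch reduction: exact
  acc_r <- matrix(0, grid$height, grid$width)
  acc_c <- matrix(0, grid$height, grid$width)
  wsum <- matrix(0, grid$height, grid$width)
  for (k in seq_len(n)) {
    f <- patch_fields[[k]]
    if (!identical(dim(f)[1:2], as.integer(grid$patch)))
      stop("patch field has wrong shape")
    ri <- grid$origins[k, 1] + seq_len(grid$patch[1])
    ci <- grid$origins[k, 2] + seq_len(grid$patch[2])
    wk <- grid$windows[[k]]
    acc_r[ri, ci] <- acc_r[ri, ci] + wk * field_drow(f)
    acc_c[ri, ci] <- acc_c[ri, ci] + wk * field_dcol(f)
    wsum[ri, ci] <- wsum[ri, ci] + wk
  }
  displacement_field(acc_r / wsum, acc_c / wsum)
}

#' Tiled elastic registration for large slices
#'
#' Hierarchical variant of [register_stack_elastic()] for slices too large to
#' process whole: each slice plane is partitioned into overlapping patches
#' with identical footprints across the z-neighborhood, [elastic_step()] runs
#' independently per patch group, the per-patch fields are fused into one
#' global field per slice, and the original full-resolution slice is warped
#' once. With a single patch the result is bit-identical to the whole-image
#' pipeline.
#'
#' @param stack a [slice_stack()] with `n >= 3`.
#' @param patch,overlap see [partition_patches()].
#' @param kernel radius-1 [gaussian_kernel_1d()].
#' @param flow_params a [flow_params()] list.
#' @param sweeps passes over the stack.
#' @param flow_fn optional flow function override.
#' @return list of class `elastic_result`: `stack`, `fields`.
#' @export
register_large_stack <- function(stack, patch = 1024L, overlap = 128L,
                                 kernel = gaussian_kernel_1d(1, 1),
                                 flow_params = emalign::flow_params(),
                                 sweeps = 1L, flow_fn = NULL) {
  if (stack$n < 3L) stop("need at least 3 slices")
  if (is.null(flow_fn))
    flow_fn <- function(fixed, moving) estimate_flow(fixed, moving, flow_params)
  grid <- partition_patches(stack$height, stack$width, patch, overlap)
  crop <- function(img, k) {
    if (is.null(img)) return(NULL)
    out <- img[grid$origins[k, 1] + seq_len(grid$patch[1]),
               grid$origins[k, 2] + seq_len(grid$patch[2]), drop = FALSE]
    ts <- attr(img, "true_shift")  # translation fixtures keep their tag
    if (!is.null(ts)) attr(out, "true_shift") <- ts
    out
  }
  cur <- stack$slices
  fields <- NULL
  npatch <- nrow(grid$origins)
  for (s in seq_len(sweeps)) {
    # per-patch fields for every slice; pairwise flows shared within a group
    patch_fields <- lapply(seq_len(stack$n), function(i) vector("list", npatch))
    for (k in seq_len(npatch)) {
      crops <- lapply(cur, crop, k)
      pairwise <- lapply(seq_len(stack$n - 1L), function(i)
        flow_fn(crops[[i]], crops[[i + 1L]]))
      for (i in seq_len(stack$n)) {
        st <- elastic_step(if (i > 1L) crops[[i - 1L]] else NULL,
                           crops[[i]],
                           if (i < stack$n) crops[[i + 1L]] else NULL,
                           kernel, flow_fn,
                           phi_i_im1 = if (i > 1L) pairwise[[i - 1L]] else NULL,
                           phi_ip1_i = if (i < stack$n) pairwise[[i]] else NULL)
        patch_fields[[i]][[k]] <- st$field
      }
    }
    nxt <- vector("list", stack$n)
    fields <- vector("list", stack$n)
    for (i in seq_len(stack$n)) {
      fields[[i]] <- fuse_fields(grid, patch_fields[[i]])
      nxt[[i]] <- warp(cur[[i]], fields[[i]])
    }
    cur <- nxt
    log_msg("debug", "tiled elastic sweep %d done (%d patches)", s, npatch)
  }
  structure(list(stack = slice_stack(cur, stack$bit_depth), fields = fields),
            class = "elastic_result")
}
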