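#' Symmetric normalized 1D Gaussian kernel
#'
#' Axial kernel `g_k` proportional to `exp(-k^2 / 2 sigma^2)` for
#' `k = -radius..radius`, normalized to sum 1. The radius-1 case drives the
#' axial integration of displacement fields.
#'
#' @param radius kernel radius (>= 1).
#' @param sigma kernel width (> 0).
#' @return list of class `gaussian_kernel_1d` with `radius`, `sigma`,
#'   `weights` (length `2*radius+1`, center at index `radius+1`).
#' @export
gaussian_kernel_1d <- function(radius = 1L, sigma = 1.0) {
  if (radius < 1L) stop("radius must be >= 1")
  if (sigma <= 0) stop("sigma must be > 0")
  k <- (-radius):radius
  wts <- exp(-k^2 / (2 * sigma^2))
  wts <- wts / sum(wts)
  structure(list(radius = as.integer(radius), sigma = sigma, weights = wts),
            class = "gaussian_kernel_1d")
}

kernel_g <- function(kernel, k) kernel$weights[k + kernel$radius + 1L]

#' Difference-reorganized 1D Gaussian filtering (radius 1)
#'
#' Rewrites the radius-1 Gaussian filter
#' `s^_i = g_-1 s_(i-1) + g_0 s_i + g_1 s_(i+1)` in terms of pairwise
#' differences `d_(i,j) = s_j - s_i`:
#' `s^_i = g_-1 d_(i,i-1) + g_0 d_(i+1,i) + g_-1 s_i + (g_0 + g_1) s_(i+1)`.
#' The two forms are algebraically identical at interior points; the
#' difference form is the one that generalizes to image stacks, where the
#' differences become displacement fields. Boundaries use replicated end
#' values.
#'
#' @param signal numeric vector, length >= 3.
#' @param kernel a radius-1 [gaussian_kernel_1d()].
#' @return filtered signal (same length).
#' @export
filter_1d_reorganized <- function(signal, kernel = gaussian_kernel_1d(1, 1)) {
  n <- length(signal)
  if (n < 3L) stop("signal must have length >= 3")
  if (kernel$radius != 1L) stop("reorganized form is defined for radius 1")
  gm1 <- kernel_g(kernel, -1L); g0 <- kernel_g(kernel, 0L); g1 <- kernel_g(kernel, 1L)
  s <- c(signal[1], signal, signal[n])  # replicate boundary
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- i + 1L  # index into padded signal
    d_im1 <- s[j - 1L] - s[j]       # d_{i,i-1} = s_{i-1} - s_i
    d_ip1 <- s[j] - s[j + 1L]       # d_{i+1,i} = s_i - s_{i+1}
    out[i] <- gm1 * d_im1 + g0 * d_ip1 + gm1 * s[j] + (g0 + g1) * s[j + 1L]
  }
  out
}

#' One axial Gaussian-filter registration step for a slice triple
#'
#' The frequency-decoupling core. With a radius-1 kernel `g` and a flow
#' function, the step executes exactly:
#' \enumerate{
#'   \item pairwise fields `phi_(i,i-1) = flow(I_prev, I_i)` and
#'     `phi_(i+1,i) = flow(I_i, I_next)`;
#'   \item intermediate images `I_i^tmp = warp(I_i, g_-1 phi_(i,i-1))` and
#'     `I_(i+1)^tmp = warp(I_next, g_0 phi_(i+1,i))`;
#'   \item re-estimated fields `phi_(i,i)^tmp = flow(I_i^tmp, I_i)` and
#'     `phi_(i,i+1)^tmp = flow(I_(i+1)^tmp, I_i)`;
#'   \item normalized weights `g0~ = (g_-1+g_0) / ((g_-1+g_0)+(g_0+g_1))`,
#'     `g1~ = (g_0+g_1) / ((g_-1+g_0)+(g_0+g_1))`;
#'   \item combined field `phi_i = g0~ phi_(i,i)^tmp + g1~ phi_(i,i+1)^tmp`
#'     and registered slice `I^_i = warp(I_i, phi_i)`.
#' }
#' A missing neighbor (`NULL`) contributes a zero pairwise field and the
#' weights are renormalized over the available re-estimated terms, which
#' preserves the identity property at stack boundaries.
#'
#' @param I_prev,I_i,I_next same-shape matrices (`I_prev`/`I_next` may be
#'   `NULL` at stack boundaries).
#' @param kernel radius-1 [gaussian_kernel_1d()].
#' @param flow_fn function `(fixed, moving) -> displacement_field`.
#' @param phi_i_im1,phi_ip1_i optionally precomputed pairwise fields
#'   (`flow_fn(I_prev, I_i)` and `flow_fn(I_i, I_next)`); sweep drivers pass
#'   them so each adjacent pair is estimated once, not twice.
#' @return list: `image` (registered slice), `field` (`phi_i`), and audit
#'   fields `phi_i_im1`, `phi_ip1_i`, `phi_tmp0`, `phi_tmp1`, `weights`.
#' @export
elastic_step <- function(I_prev, I_i, I_next, kernel = gaussian_kernel_1d(1, 1),
                         flow_fn = estimate_flow, phi_i_im1 = NULL,
                         phi_ip1_i = NULL) {
  if (kernel$radius != 1L) stop("elastic_step supports radius-1 kernels")
  h <- nrow(I_i); w <- ncol(I_i)
  for (nb in list(I_prev, I_next))
    if (!is.null(nb) && !identical(dim(nb), dim(I_i))) stop("shape mismatch")
  gm1 <- kernel_g(kernel, -1L); g0 <- kernel_g(kernel, 0L); g1 <- kernel_g(kernel, 1L)
  if (is.null(phi_i_im1))
    phi_i_im1 <- if (is.null(I_prev)) zero_field(h, w) else flow_fn(I_prev, I_i)
  if (is.null(phi_ip1_i) && !is.null(I_next)) phi_ip1_i <- flow_fn(I_i, I_next)

  I_i_tmp <- warp(I_i, scale_field(phi_i_im1, gm1))
  # identical inputs short-circuit to the estimator's exact identity answer
  phi_tmp0 <- if (identical(I_i_tmp, I_i)) zero_field(h, w)
              else flow_fn(I_i_tmp, I_i)
  w0 <- gm1 + g0
  if (!is.null(I_next)) {
    I_ip1_tmp <- warp(I_next, scale_field(phi_ip1_i, g0))
    phi_tmp1 <- flow_fn(I_ip1_tmp, I_i)
    w1 <- g0 + g1
  } else {
    phi_tmp1 <- NULL
    w1 <- 0
  }
  wsum <- w0 + w1
  weights <- c(w0 / wsum, 1 - w0 / wsum)  # sums to 1 exactly
  phi <- if (is.null(phi_tmp1)) scale_field(phi_tmp0, weights[1])
         else combine_fields(list(phi_tmp0, phi_tmp1), weights)
  list(image = warp(I_i, phi), field = phi,
       phi_i_im1 = phi_i_im1, phi_ip1_i = phi_ip1_i,
       phi_tmp0 = phi_tmp0, phi_tmp1 = phi_tmp1, weights = weights)
}

#' Elastic registration of a stack by axial Gaussian filtering
#'
#' Applies [elastic_step()] to every slice of the stack. Within one sweep
#' every step reads neighbors from the sweep's frozen input stack
#' (Jacobi-style), so the output is independent of slice processing order;
#' `sweeps` repeats the pass on the previous output. High-frequency (along z)
#' nonlinear distortion is attenuated while low-frequency natural deformation
#' — including any constant misalignment-free configuration — is a fixed
#' point.
#'
#' @param stack a [slice_stack()] with `n >= 3`.
#' @param kernel radius-1 [gaussian_kernel_1d()].
#' @param flow_params a [flow_params()] list for the default estimator.
#' @param sweeps number of passes (>= 1).
#' @param flow_fn optional flow function override (e.g.
#'   [translation_oracle_flow()]); default uses [estimate_flow()] with
#'   `flow_params`.
#' @return list of class `elastic_result`: `stack` (registered), `fields`
#'   (per-slice combined field, last sweep), `steps` (per-slice audit output
#'   of the last sweep).
#' @export
register_stack_elastic <- function(stack, kernel = gaussian_kernel_1d(1, 1),
                                   flow_params = emalign::flow_params(),
                                   sweeps = 1L, flow_fn = NULL) {
  if (stack$n < 3L) stop("need at least 3 slices to smooth along z")
  if (is.null(flow_fn))
    flow_fn <- function(fixed, moving) estimate_flow(fixed, moving, flow_params)
  cur <- stack$slices
  fields <- NULL; steps <- NULL
  for (s in seq_len(sweeps)) {
    # each adjacent pairwise field is estimated once per sweep
    pairwise <- lapply(seq_len(stack$n - 1L), function(i)
      flow_fn(cur[[i]], cur[[i + 1L]]))
    nxt <- vector("list", stack$n)
    fields <- vector("list", stack$n)
    steps <- vector("list", stack$n)
    for (i in seq_len(stack$n)) {
      st <- elastic_step(if (i > 1L) cur[[i - 1L]] else NULL,
                         cur[[i]],
                         if (i < stack$n) cur[[i + 1L]] else NULL,
                         kernel, flow_fn,
                         phi_i_im1 = if (i > 1L) pairwise[[i - 1L]] else NULL,
                         phi_ip1_i = if (i < stack$n) pairwise[[i]] else NULL)
      nxt[[i]] <- st$image
      fields[[i]] <- st$field
      steps[[i]] <- st
    }
    cur <- nxt
    log_msg("debug", "elastic sweep %d done", s)
  }
  structure(list(stack = slice_stack(cur, stack$bit_depth),
                 fields = fields, steps = steps),
            class = "elastic_result")
}
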