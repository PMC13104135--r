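#' Generate a phantom volume with cell-like structures
#'
#' Procedural stand-in for a high-resolution EM reference volume: smooth
#' ellipsoidal cell bodies with darker membrane boundaries, mild smooth
#' intracellular texture, all continuous along z (adjacent-plane NCC >= 0.9
#' at default settings). Values in \[0, 1\]; deterministic given the seed.
#'
#' @param shape integer (z, y, x), each axis at least (16, 64, 64).
#' @param n_structures number of cell bodies; 0 gives a smooth background
#'   volume.
#' @param seed RNG seed.
#' @return list of class `phantom_volume`: `planes` (list of z matrices),
#'   `shape`.
#' @export
generate_phantom <- function(shape = c(24L, 256L, 256L), n_structures = 24L,
                             seed = 1L) {
  if (length(shape) != 3L || shape[1] < 16L || shape[2] < 64L || shape[3] < 64L)
    stop("shape too small: need at least (16, 64, 64)")
  nz <- shape[1]; h <- shape[2]; w <- shape[3]
  if (n_structures == 0)  # degenerate case: constant background volume
    return(structure(list(planes = rep(list(matrix(0.55, h, w)), nz),
                          shape = as.integer(shape)),
                     class = "phantom_volume"))
  with_seed(seed, function() {
    g <- coord_grids(h, w)
    # smooth low-frequency background, fixed across z (blurred at reduced
    # resolution: kernels this wide are pure low-pass)
    bg <- 0.55 + 0.08 * blur_wide(matrix(rnorm(h * w), h, w), min(h, w) / 8)
    # blob parameters
    if (n_structures > 0) {
      cz <- runif(n_structures, 0, nz - 1)
      cy <- runif(n_structures, 0, h - 1)
      cx <- runif(n_structures, 0, w - 1)
      ry <- runif(n_structures, 0.04, 0.12) * min(h, w)
      rx <- runif(n_structures, 0.04, 0.12) * min(h, w)
      rz <- runif(n_structures, 1.0, 2.0) * nz   # elongated in z: axial continuity
      lum <- runif(n_structures, 0.65, 0.85)
    }
    # smooth 3D texture, two spatial scales (coarse organelle shading plus
    # fine cytoplasmic granularity), blended along z between keyframes and
    # normalized to unit standard deviation
    ntex <- max(3L, ceiling(nz / 10))
    tex_keys <- lapply(seq_len(ntex + 1), function(i) {
      t2 <- blur2d(matrix(rnorm(h * w), h, w), 6) +
            0.6 * blur2d(matrix(rnorm(h * w), h, w), 2.5)
      t2 / sd(t2)
    })
    planes <- vector("list", nz)
    for (z in seq_len(nz)) {
      img <- bg
      if (n_structures > 0) {
        for (b in seq_len(n_structures)) {
          dz2 <- ((z - 1 - cz[b]) / rz[b])^2
          if (dz2 > 1.44) next
          # only touch the blob's bounding box
          ri <- max(1, floor(cy[b] - 1.3 * ry[b])):min(h, ceiling(cy[b] + 1.3 * ry[b]))
          ci <- max(1, floor(cx[b] - 1.3 * rx[b])):min(w, ceiling(cx[b] + 1.3 * rx[b]))
          q <- sqrt(((g$r[ri, ci] - cy[b]) / ry[b])^2 +
                    ((g$c[ri, ci] - cx[b]) / rx[b])^2 + dz2)
          # interior plateau, dark membrane band around q = 1, smooth falloff
          interior <- smoothstep(1 - q, 0, 0.12)
          membrane <- exp(-((q - 1) / 0.06)^2)
          sub <- img[ri, ci]
          sub <- sub * (1 - interior) + lum[b] * interior
          img[ri, ci] <- sub * (1 - 0.75 * membrane) + 0.12 * 0.75 * membrane
        }
      }
      zf <- (z - 1) / max(nz - 1, 1) * ntex
      k0 <- floor(zf); fz <- zf - k0
      tex <- (1 - fz) * tex_keys[[k0 + 1]] + fz * tex_keys[[min(k0 + 2, ntex + 1)]]
      img <- img + 0.07 * tex
      planes[[z]] <- clip01(img)
    }
    structure(list(planes = planes, shape = as.integer(shape)),
              class = "phantom_volume")
  })
}

# wide Gaussian blur computed at reduced resolution (factor sigma/8), then
# upsampled; indistinguishable from direct convolution for pure low-pass use
blur_wide <- function(img, sigma) {
  if (sigma <= 16) return(blur2d(img, sigma))
  f <- sigma / 8
  hs <- max(2L, round(nrow(img) / f)); ws <- max(2L, round(ncol(img) / f))
  small <- resize_bilinear(blur2d(img, f), hs, ws)
  resize_bilinear(blur2d(small, 8), nrow(img), ncol(img))
}

# stationary smooth Gaussian random field: white noise convolved circularly
# (FFT) with a periodic Gaussian kernel, so the variance is spatially uniform
smooth_noise_periodic <- function(h, w, sigma) {
  kh <- exp(-pmin(0:(h - 1), h - 0:(h - 1))^2 / (2 * sigma^2))
  kw <- exp(-pmin(0:(w - 1), w - 0:(w - 1))^2 / (2 * sigma^2))
  K <- outer(kh / sum(kh), kw / sum(kw))
  n <- matrix(rnorm(h * w), h, w)
  Re(stats::fft(stats::fft(n) * stats::fft(K), inverse = TRUE)) / (h * w)
}

smoothstep <- function(x, e0, e1) {
  t <- pmin(pmax((x - e0) / (e1 - e0), 0), 1)
  t * t * (3 - 2 * t)
}

#' Extract every k-th plane of a phantom volume as a slice stack
#'
#' Larger intervals emulate stronger natural inter-slice change (thicker
#' sections), the knob used to probe robustness against genuine deformation.
#'
#' @param vol a [generate_phantom()] result.
#' @param interval section interval k (>= 1, < number of planes).
#' @return a [slice_stack()] with `floor((z-1)/k)+1` slices.
#' @export
slice_volume <- function(vol, interval = 1L) {
  k <- as.integer(interval)
  nz <- vol$shape[1]
  if (k < 1L) stop("interval must be >= 1")
  if (k >= nz) stop("interval must be smaller than the number of planes")
  slice_stack(vol$planes[seq(1L, nz, by = k)])
}

#' Apply random per-slice rigid jitter
#'
#' Slice 1 is untouched; every later slice is resampled once (bilinear, edge
#' clamp) under an independently drawn rigid transform about the image
#' center, with translations drawn uniformly from `[0, t_max]` per axis and
#' rotations from `[-theta_max, theta_max]` degrees — the standard synthetic
#' misalignment protocol (full scale: t_max = 100 px, theta_max = 35 deg on
#' 1024x1024 crops).
#'
#' @param stack a [slice_stack()].
#' @param t_max maximum per-axis translation (px), >= 0.
#' @param theta_max maximum absolute rotation (degrees), >= 0.
#' @param seed RNG seed.
#' @return list: `stack` (jittered), `gt` (list with per-slice applied
#'   `transforms`; recovery should invert them).
#' @export
apply_rigid_jitter <- function(stack, t_max = 100, theta_max = 35, seed = 1L) {
  if (t_max < 0 || theta_max < 0) stop("ranges must be non-negative")
  center <- c((stack$height - 1) / 2, (stack$width - 1) / 2)
  with_seed(seed, function() {
    out <- stack$slices
    trs <- vector("list", stack$n)
    trs[[1]] <- rigid_transform(0, c(0, 0), center)
    for (i in seq_len(stack$n)[-1]) {
      tr <- rigid_transform(runif(1, -theta_max, theta_max),
                            c(runif(1, 0, t_max), runif(1, 0, t_max)), center)
      out[[i]] <- if (t_max == 0 && theta_max == 0) stack$slices[[i]]
                  else apply_rigid(stack$slices[[i]], tr)
      trs[[i]] <- tr
    }
    list(stack = slice_stack(out, stack$bit_depth), gt = list(transforms = trs))
  })
}

#' Apply random smooth elastic distortion
#'
#' Each slice after the first is backward-warped by an independent random
#' field: white-noise 2-vector images smoothed spatially by a Gaussian of
#' `sigma_d` px and rescaled so the maximum displacement magnitude equals
#' `alpha * amp0` px. Per-slice independence makes the distortion
#' high-frequency along z — exactly what the axial Gaussian filtering is
#' meant to remove. `alpha = 0` is the identity.
#'
#' @param stack a [slice_stack()].
#' @param alpha deformation level (>= 0).
#' @param sigma_d spatial smoothing of the random field (px, > 0).
#' @param amp0 base amplitude (px) multiplied by `alpha`.
#' @param seed RNG seed.
#' @return list: `stack` (distorted), `gt` (list with per-slice `fields`;
#'   warping a distorted slice by the negated field approximately restores
#'   the original).
#' @export
apply_elastic_distortion <- function(stack, alpha = 1.0, sigma_d = 24,
                                     amp0 = 8, seed = 1L) {
  if (alpha < 0) stop("alpha must be >= 0")
  if (sigma_d <= 0) stop("sigma_d must be > 0")
  h <- stack$height; w <- stack$width
  with_seed(seed, function() {
    out <- stack$slices
    fields <- vector("list", stack$n)
    fields[[1]] <- zero_field(h, w)
    for (i in seq_len(stack$n)[-1]) {
      dr <- smooth_noise_periodic(h, w, sigma_d)
      dc <- smooth_noise_periodic(h, w, sigma_d)
      mag <- sqrt(dr^2 + dc^2)
      s <- if (max(mag) > 0) alpha * amp0 / max(mag) else 0
      f <- displacement_field(dr * s, dc * s)
      fields[[i]] <- f
      if (alpha > 0) out[[i]] <- warp(stack$slices[[i]], f)
    }
    list(stack = slice_stack(out, stack$bit_depth), gt = list(fields = fields))
  })
}

#' Add i.i.d. Gaussian noise
#'
#' Additive Gaussian noise in gray-value units on the \[0, 1\] scale, clipped
#' back to \[0, 1\]; applied after any geometric degradation.
#'
#' @param stack a [slice_stack()].
#' @param sigma noise standard deviation (>= 0).
#' @param seed RNG seed.
#' @export
add_gaussian_noise <- function(stack, sigma, seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(stack)
  h <- stack$height; w <- stack$width
  with_seed(seed, function() {
    map_stack(stack, function(s) clip01(s + matrix(rnorm(h * w, 0, sigma), h, w)))
  })
}

#' Build a pure-translation stack from a template
#'
#' Slice i is the template backward-warped by the constant field `-u_i`
#' (content shifted by `u_i`), edge-clamped, and tagged with its true shift
#' ([tag_shift()]) so the translation oracle flow applies. This is the
#' fixture for verifying the frequency-decoupling algebra in closed form.
#'
#' @param template numeric matrix.
#' @param shifts list (or n x 2 matrix) of per-slice (row, col) shifts.
#' @return a [slice_stack()] of tagged slices.
#' @export
make_translation_stack <- function(template, shifts) {
  if (is.matrix(shifts)) shifts <- lapply(seq_len(nrow(shifts)), function(i) shifts[i, ])
  slices <- lapply(shifts, function(u) {
    if (!all(is.finite(u))) stop("shifts must be finite")
    s <- if (all(u == 0)) template
         else warp(template, constant_field(nrow(template), ncol(template), -u))
    tag_shift(s, u)
  })
  slice_stack(slices)
}
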