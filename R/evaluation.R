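#' Signed difference image between adjacent slices
#' @param a,b same-shape matrices; returns `b - a`.
#' @export
difference_image <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  b - a
}

#' Discrete 4-neighbor Laplacian
#'
#' Kernel `[[0,1,0],[1,-4,1],[0,1,0]]` with replicated borders; makes the
#' residual noise in a difference image more pronounced before the noise and
#' texture statistics are computed.
#'
#' @param d numeric matrix.
#' @export
laplacian_filter <- function(d) {
  h <- nrow(d); w <- ncol(d)
  up <- d[c(1, 1:(h - 1)), , drop = FALSE]
  dn <- d[c(2:h, h), , drop = FALSE]
  lf <- d[, c(1, 1:(w - 1)), drop = FALSE]
  rt <- d[, c(2:w, w), drop = FALSE]
  up + dn + lf + rt - 4 * d
}

# linear min-max rescale to integer levels 0..(levels-1); constant -> all 0
quantize_levels <- function(x, levels = 256L) {
  rng <- range(x)
  if (rng[2] - rng[1] <= 0) return(matrix(0L, nrow(x), ncol(x)))
  q <- round((x - rng[1]) / (rng[2] - rng[1]) * (levels - 1L))
  matrix(as.integer(q), nrow(x), ncol(x))
}

#' Shannon entropy of an image over a 256-bin histogram
#'
#' `H = -sum p_i log2 p_i` over the 256 gray levels after linear min-max
#' quantization; empty bins contribute zero. Units: bits.
#'
#' @param img numeric matrix (any range; quantized internally).
#' @param levels number of gray levels.
#' @export
img_entropy <- function(img, levels = 256L) {
  q <- quantize_levels(img, levels)
  p <- tabulate(as.integer(q) + 1L, nbins = levels) / length(q)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Bilateral-split signal-to-noise ratio
#'
#' Splits the Laplacian-filtered difference image into a structural component
#' `I_f` (bilateral filter: spatial sigma `sigma_s`, range sigma `sigma_r` on
#' the \[0, 1\]-rescaled image, square window `window`) and a noise component
#' `I_n = input - I_f` (conservation exact by construction), and reports
#' `Var(I_f) / Var(I_n)`; `Inf` when the noise component has zero variance.
#'
#' @param lap numeric matrix (Laplacian-filtered difference image).
#' @param window window side length (odd).
#' @param sigma_s spatial standard deviation (px).
#' @param sigma_r range standard deviation on the rescaled \[0, 1\] scale.
#' @param components return `I_f`/`I_n` as well.
#' @export
snr_bilateral <- function(lap, window = 7L, sigma_s = 2, sigma_r = 0.1,
                          components = FALSE) {
  if (!all(is.finite(lap))) stop("input must be finite")
  rng <- range(lap)
  guide <- if (rng[2] - rng[1] > 0) (lap - rng[1]) / (rng[2] - rng[1])
           else matrix(0, nrow(lap), ncol(lap))
  If <- cpp_bilateral(lap, guide, as.integer(window) %/% 2L, sigma_s, sigma_r)
  In <- lap - If
  vn <- var(as.numeric(In))
  ratio <- if (vn <= 0) Inf else var(as.numeric(If)) / vn
  if (components) list(snr = ratio, If = If, In = In) else ratio
}

#' Difference-of-Gaussian pyramid
#'
#' Four full-resolution layers `DoG_i = img * G_i - img * G_(i+1)` from five
#' increasing Gaussian scales (defaults: half-octave ladder `2^(i/2)`). The
#' layers telescope: their sum equals `img * G_0 - img * G_4`.
#'
#' @param img numeric matrix.
#' @param sigmas five strictly increasing Gaussian sigmas.
#' @return list of 4 matrices.
#' @export
dog_pyramid <- function(img, sigmas = 2^((0:4) / 2)) {
  if (length(sigmas) != 5L || any(diff(sigmas) <= 0))
    stop("need 5 strictly increasing sigmas")
  blurred <- lapply(sigmas, function(s) blur2d(img, s))
  lapply(1:4, function(i) blurred[[i]] - blurred[[i + 1]])
}

#' Gray-level co-occurrence contrast
#'
#' Quantizes the image to `levels` gray levels, accumulates a symmetric
#' normalized co-occurrence matrix for each offset, computes
#' `Con = sum (k - j)^2 P(k, j)` per offset and averages. Default offsets are
#' the four unit directions (0, 45, 90, 135 degrees).
#'
#' @param img numeric matrix.
#' @param levels number of gray levels.
#' @param offsets list of (drow, dcol) integer offsets.
#' @export
glcm_contrast <- function(img, levels = 256L,
                          offsets = list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L),
                                         c(-1L, -1L))) {
  q <- quantize_levels(img, levels)
  h <- nrow(q); w <- ncol(q)
  cons <- vapply(offsets, function(off) {
    dr <- off[1]; dc <- off[2]
    r0 <- max(1L, 1L - dr):min(h, h - dr)
    c0 <- max(1L, 1L - dc):min(w, w - dc)
    a <- q[r0, c0, drop = FALSE]
    b <- q[r0 + dr, c0 + dc, drop = FALSE]
    # contrast of the symmetric normalized GLCM = mean squared level difference
    mean((as.numeric(a) - as.numeric(b))^2)
  }, numeric(1))
  mean(cons)
}

#' Full co-occurrence matrix (symmetric, normalized) for one offset
#'
#' Exposed for inspection and testing; [glcm_contrast()] uses the equivalent
#' direct accumulation.
#'
#' @param img numeric matrix.
#' @param levels number of gray levels.
#' @param offset (drow, dcol) integer offset.
#' @return `levels` x `levels` matrix summing to 1 (all-zero if no pairs).
#' @export
glcm_matrix <- function(img, levels = 256L, offset = c(0L, 1L)) {
  q <- quantize_levels(img, levels)
  h <- nrow(q); w <- ncol(q)
  dr <- offset[1]; dc <- offset[2]
  r0 <- max(1L, 1L - dr):min(h, h - dr)
  c0 <- max(1L, 1L - dc):min(w, w - dc)
  a <- as.integer(q[r0, c0]); b <- as.integer(q[r0 + dr, c0 + dc])
  counts <- tabulate(a * levels + b + 1L, nbins = levels * levels) +
            tabulate(b * levels + a + 1L, nbins = levels * levels)
  m <- matrix(counts, levels, levels, byrow = TRUE)
  if (sum(m) > 0) m / sum(m) else m
}

#' Ground-truth-free stack quality report
#'
#' For every adjacent slice pair: difference image -> Laplacian -> entropy H
#' (bits), bilateral-split SNR, and GLCM contrast of each DoG-pyramid layer
#' (`Con_0..Con_3`). Well-registered stacks show lower H, higher SNR and
#' higher multi-scale contrast than misaligned ones.
#'
#' @param stack a [slice_stack()] with `n >= 2`.
#' @param dog_sigmas five increasing sigmas for [dog_pyramid()].
#' @param glcm_levels gray levels for [glcm_contrast()].
#' @param bilateral_window,bilateral_sigma_s,bilateral_sigma_r see
#'   [snr_bilateral()].
#' @return list of class `evaluation_report`: `pairs` (data.frame with one
#'   row per adjacent pair), `summary` (means), `entropy_histogram`.
#' @export
evaluate_stack <- function(stack, dog_sigmas = 2^((0:4) / 2),
                           glcm_levels = 256L, bilateral_window = 7L,
                           bilateral_sigma_s = 2, bilateral_sigma_r = 0.1) {
  if (stack$n < 2L) stop("need at least 2 slices")
  rows <- vector("list", stack$n - 1L)
  for (i in seq_len(stack$n - 1L)) {
    lap <- laplacian_filter(difference_image(stack$slices[[i]],
                                             stack$slices[[i + 1L]]))
    H <- img_entropy(lap)
    snr <- snr_bilateral(lap, bilateral_window, bilateral_sigma_s,
                         bilateral_sigma_r)
    cons <- vapply(dog_pyramid(lap, dog_sigmas), glcm_contrast,
                   numeric(1), levels = glcm_levels)
    rows[[i]] <- data.frame(pair = i, H = H, SNR = snr,
                            Con0 = cons[1], Con1 = cons[2],
                            Con2 = cons[3], Con3 = cons[4])
  }
  pairs <- do.call(rbind, rows)
  fin <- is.finite(pairs$SNR)
  structure(list(
    pairs = pairs,
    summary = list(mean_H = mean(pairs$H),
                   mean_SNR = if (any(fin)) mean(pairs$SNR[fin]) else Inf,
                   mean_Con = mean(colMeans(pairs[, c("Con0", "Con1", "Con2", "Con3")]))),
    entropy_histogram = graphics::hist(pairs$H, breaks = "Sturges", plot = FALSE)
  ), class = "evaluation_report")
}

#' Structural similarity index (SSIM)
#'
#' Uniform 7x7 local window, `K1 = 0.01`, `K2 = 0.03`, data range 1 (images
#' in \[0, 1\]); mean taken over the window-valid interior.
#'
#' @param a,b same-shape matrices in \[0, 1\].
#' @param window window side length (odd).
#' @export
ssim <- function(a, b, window = 7L) {
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  k <- rep(1 / window, window)
  mu_a <- cpp_sepconv(a, k); mu_b <- cpp_sepconv(b, k)
  va <- cpp_sepconv(a * a, k) - mu_a^2
  vb <- cpp_sepconv(b * b, k) - mu_b^2
  cab <- cpp_sepconv(a * b, k) - mu_a * mu_b
  C1 <- 0.01^2; C2 <- 0.03^2
  s <- ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
       ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  m <- window %/% 2L
  mean(s[(m + 1):(nrow(s) - m), (m + 1):(ncol(s) - m)])
}

# SSIM over the interior, ignoring a clamped margin
interior_ssim <- function(a, b, margin) {
  ri <- (margin + 1):(nrow(a) - margin)
  ci <- (margin + 1):(ncol(a) - margin)
  ssim(a[ri, ci], b[ri, ci])
}

#' Normalized cross-correlation (zero-mean, unit-variance)
#' @param a,b same-shape matrices.
#' @export
ncc <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  stats::cor(as.numeric(a), as.numeric(b))
}

#' Mutual information over a 256-bin joint histogram
#'
#' Reported in nats. Images are quantized to 256 levels on the \[0, 1\] range
#' (values clipped).
#'
#' @param a,b same-shape matrices in \[0, 1\].
#' @param levels histogram bins per axis.
#' @export
mutual_information <- function(a, b, levels = 256L) {
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  qa <- as.integer(round(clip01(a) * (levels - 1L)))
  qb <- as.integer(round(clip01(b) * (levels - 1L)))
  joint <- tabulate(qa * levels + qb + 1L, nbins = levels * levels)
  p <- joint / sum(joint)
  pa <- tabulate(qa + 1L, nbins = levels) / length(qa)
  pb <- tabulate(qb + 1L, nbins = levels) / length(qb)
  nz <- p > 0
  idx <- which(nz) - 1L
  ka <- idx %/% levels + 1L
  kb <- idx %% levels + 1L
  sum(p[nz] * log(p[nz] / (pa[ka] * pb[kb])))
}

#' Dice coefficient between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty, 0 when
#' exactly one is.
#'
#' @param a,b logical (or 0/1) matrices.
#' @export
dice <- function(a, b) {
  a <- a > 0; b <- b > 0
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Symmetric Hausdorff distance between two binary masks (px)
#'
#' Maximum over both directed distances between the mask boundary pixel sets;
#' `NA` sentinel when either mask is empty.
#'
#' @param a,b logical (or 0/1) matrices.
#' @export
hausdorff_distance <- function(a, b) {
  a <- a > 0; b <- b > 0
  if (sum(a) == 0 || sum(b) == 0) return(NA_real_)
  pa <- mask_boundary_points(a)
  pb <- mask_boundary_points(b)
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * tcrossprod(pa, pb)
  d2[d2 < 0] <- 0
  max(sqrt(max(apply(d2, 1, min))), sqrt(max(apply(d2, 2, min))))
}

mask_boundary_points <- function(m) {
  h <- nrow(m); w <- ncol(m)
  pad <- function(i, lim) pmin(pmax(i, 1), lim)
  er <- m & m[pad(1:h - 1, h), ] & m[pad(1:h + 1, h), ] &
        m[, pad(1:w - 1, w)] & m[, pad(1:w + 1, w)]
  b <- m & !er
  if (!any(b)) b <- m  # mask with no interior: every pixel is boundary
  which(b, arr.ind = TRUE) * 1.0
}

#' Full-reference metrics against a ground-truth stack
#'
#' Per-slice SSIM, NCC and MI between a result stack and its ground truth,
#' plus Dice and Hausdorff distance when label stacks are supplied.
#'
#' @param result,gt [slice_stack()]s of equal shape.
#' @param result_labels,gt_labels optional lists of binary/integer label
#'   matrices.
#' @return data.frame with one row per slice.
#' @export
reference_metrics <- function(result, gt, result_labels = NULL, gt_labels = NULL) {
  if (result$n != gt$n || result$height != gt$height || result$width != gt$width)
    stop("shape mismatch between result and ground truth")
  out <- data.frame(
    slice = seq_len(result$n),
    SSIM = vapply(seq_len(result$n), function(i)
      ssim(result$slices[[i]], gt$slices[[i]]), numeric(1)),
    NCC = vapply(seq_len(result$n), function(i)
      ncc(result$slices[[i]], gt$slices[[i]]), numeric(1)),
    MI = vapply(seq_len(result$n), function(i)
      mutual_information(result$slices[[i]], gt$slices[[i]]), numeric(1)))
  if (!is.null(result_labels) && !is.null(gt_labels)) {
    out$Dice <- vapply(seq_len(result$n), function(i)
      dice(result_labels[[i]], gt_labels[[i]]), numeric(1))
    out$Hausdorff <- vapply(seq_len(result$n), function(i)
      hausdorff_distance(result_labels[[i]], gt_labels[[i]]), numeric(1))
  }
  out
}
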