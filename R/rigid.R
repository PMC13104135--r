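#' Rigid transform (2D rotation + translation)
#'
#' Canonical absolute-affine form `x' = R x + b` on 0-based (row, col)
#' coordinates, constructed from an angle, a translation and a rotation pivot:
#' `x' = R (x - center) + center + t`. Rotation is counterclockwise in the
#' (row, col) frame for positive `theta_deg`.
#'
#' @param theta_deg rotation angle in degrees.
#' @param t length-2 translation (row, col) in px, applied about `center`.
#' @param center rotation pivot (row, col); defaults to the origin.
#' @return object of class `rigid_transform` with fields `theta_deg`, `R`,
#'   `b`, `t`, `center`.
#' @export
rigid_transform <- function(theta_deg = 0, t = c(0, 0), center = c(0, 0)) {
  th <- theta_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  center <- as.numeric(center); t <- as.numeric(t)
  b <- center + t - R %*% center
  structure(list(theta_deg = theta_deg, R = R, b = as.numeric(b), t = t,
                 center = center),
            class = "rigid_transform")
}

# transform from explicit R (must be a proper rotation) and absolute offset b
rigid_from_Rb <- function(R, b, center = c(0, 0)) {
  stopifnot(max(abs(crossprod(R) - diag(2))) < 1e-6, det(R) > 0)
  theta <- atan2(R[2, 1], R[1, 1]) * 180 / pi
  t <- as.numeric(b) - center + as.numeric(R %*% center)
  tr <- rigid_transform(theta, t, center)
  tr$R <- R
  tr$b <- as.numeric(b)
  tr
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> theta = %.4f deg, t = (%.3f, %.3f) about (%.1f, %.1f)\n",
              x$theta_deg, x$t[1], x$t[2], x$center[1], x$center[2]))
  invisible(x)
}

# translation of the transform expressed about its stored center
transform_translation <- function(tr) tr$t

#' Compose rigid transforms
#' @param a,b `rigid_transform`s; returns the transform applying `b` first,
#'   then `a` (`x -> a(b(x))`), expressed about `a`'s center.
#' @export
compose_rigid <- function(a, b) {
  rigid_from_Rb(a$R %*% b$R, as.numeric(a$R %*% b$b) + a$b, a$center)
}

#' Invert a rigid transform
#' @param tr a `rigid_transform`.
#' @export
invert_rigid <- function(tr) {
  Ri <- t(tr$R)
  rigid_from_Rb(Ri, as.numeric(-Ri %*% tr$b), tr$center)
}

# point mapping: pts is 2 x n (row; col)
apply_rigid_points <- function(tr, pts) tr$R %*% pts + tr$b

#' Resample an image under a rigid transform
#'
#' Inverse coordinate mapping with bilinear interpolation and edge clamp:
#' `out(p) = img(R^T (p - b))`, i.e. the image content is moved by the
#' transform, sampled exactly once.
#'
#' @param img numeric matrix.
#' @param tr a [rigid_transform()].
#' @export
apply_rigid <- function(img, tr) {
  g <- coord_grids(nrow(img), ncol(img))
  Ri <- t(tr$R)
  qr <- Ri[1, 1] * (g$r - tr$b[1]) + Ri[1, 2] * (g$c - tr$b[2])
  qc <- Ri[2, 1] * (g$r - tr$b[1]) + Ri[2, 2] * (g$c - tr$b[2])
  cpp_bilinear_sample(img, qr, qc)
}

#' Detect keypoints with a multi-scale corner detector
#'
#' Default classical detector behind the pluggable keypoint+descriptor
#' contract: Harris corner response maximized over three smoothing scales,
#' greedy non-maximum suppression, subpixel refinement by quadratic fit, and
#' an orientation-normalized intensity-patch descriptor — the patch is
#' sampled (spacing `desc_spacing` px) from a Gaussian-smoothed copy
#' (`desc_sigma`), rotated to the keypoint's dominant gradient orientation,
#' mean-subtracted and unit-normalized, which makes matching robust to the
#' section-to-section rotations and independent noise realizations of serial
#' sections. A learned detector honoring the same contract can be
#' substituted via the `detector` argument of [align_stack_rigid()].
#'
#' @param img numeric matrix (>= 32x32) in \[0, 1\].
#' @param max_n maximum number of keypoints, strongest first.
#' @param nms_radius non-maximum suppression radius (px).
#' @param patch descriptor patch side length (px).
#' @param scales Gaussian integration scales for the corner response.
#' @param desc_sigma smoothing of the descriptor source image (px).
#' @param desc_spacing sample spacing of the descriptor grid (px).
#' @return data.frame with columns `row`, `col` (0-based, subpixel), `score`,
#'   `orientation` (radians), plus a `descriptors` attribute (matrix, one
#'   unit-norm row per keypoint).
#' @export
detect_keypoints <- function(img, max_n = 500L, nms_radius = 8, patch = 16L,
                             scales = c(1, 2, 4), desc_sigma = 2,
                             desc_spacing = 1.25) {
  if (nrow(img) < 32L || ncol(img) < 32L)
    stop("image too small for keypoint detection (need >= 32x32)")
  g <- central_grad(img)
  resp <- matrix(-Inf, nrow(img), ncol(img))
  for (s in scales) {
    a11 <- blur2d(g$gr * g$gr, s)
    a22 <- blur2d(g$gc * g$gc, s)
    a12 <- blur2d(g$gr * g$gc, s)
    r <- (a11 * a22 - a12^2) - 0.04 * (a11 + a22)^2
    resp <- pmax(resp, r)
  }
  m <- patch %/% 2L + 2L  # keep descriptor/orientation support inside the image
  resp[c(seq_len(m), (nrow(resp) - m + 1):nrow(resp)), ] <- -Inf
  resp[, c(seq_len(m), (ncol(resp) - m + 1):ncol(resp))] <- -Inf
  thr <- 1e-9
  idx <- which(resp > thr)
  empty <- data.frame(row = numeric(0), col = numeric(0), score = numeric(0),
                      orientation = numeric(0))
  if (length(idx) == 0L) {
    attr(empty, "descriptors") <- matrix(0, 0, patch * patch)
    return(empty)
  }
  rr <- (idx - 1) %% nrow(resp) + 1
  cc <- (idx - 1) %/% nrow(resp) + 1
  # local maxima over the 4-neighborhood only (NMS handles the rest)
  sel <- resp[idx] >= resp[cbind(rr - 1, cc)] & resp[idx] >= resp[cbind(rr + 1, cc)] &
         resp[idx] >= resp[cbind(rr, cc - 1)] & resp[idx] >= resp[cbind(rr, cc + 1)]
  rr <- rr[sel]; cc <- cc[sel]; sc <- resp[idx][sel]
  if (length(rr) == 0L) {
    attr(empty, "descriptors") <- matrix(0, 0, patch * patch)
    return(empty)
  }
  o <- order(sc, decreasing = TRUE)
  rr <- rr[o]; cc <- cc[o]; sc <- sc[o]
  keep <- cpp_nms(rr, cc, nms_radius, max_n)
  rr <- rr[keep]; cc <- cc[keep]; sc <- sc[keep]
  # subpixel: 1D quadratic fit along each axis on the response
  sub_r <- sub_c <- numeric(length(rr))
  for (k in seq_along(rr)) {
    i <- rr[k]; j <- cc[k]
    dr <- quad_peak(resp[i - 1, j], resp[i, j], resp[i + 1, j])
    dc <- quad_peak(resp[i, j - 1], resp[i, j], resp[i, j + 1])
    sub_r[k] <- i - 1 + dr
    sub_c[k] <- j - 1 + dc
  }
  # orientation-normalized descriptors from the smoothed image
  bl <- blur2d(img, desc_sigma)
  gb <- central_grad(bl)
  orad <- 8L  # orientation support half-width
  ow <- outer(exp(-(-orad:orad)^2 / 32), exp(-(-orad:orad)^2 / 32))
  half <- (patch - 1) / 2
  grid_d <- expand.grid(dr = seq(-half, half), dc = seq(-half, half)) * desc_spacing
  desc <- matrix(0, length(rr), patch * patch)
  ori <- numeric(length(rr))
  ok <- rep(TRUE, length(rr))
  h <- nrow(img); w <- ncol(img)
  for (k in seq_along(rr)) {
    i <- rr[k]; j <- cc[k]
    if (i <= orad || j <= orad || i > h - orad || j > w - orad) { ok[k] <- FALSE; next }
    gr <- gb$gr[(i - orad):(i + orad), (j - orad):(j + orad)]
    gc_ <- gb$gc[(i - orad):(i + orad), (j - orad):(j + orad)]
    mag <- sqrt(gr^2 + gc_^2) * ow
    # dominant orientation: peak of a 36-bin weighted gradient histogram
    bin <- floor((atan2(gr, gc_) + pi) / (2 * pi) * 36) %% 36
    hst <- numeric(36)
    agg <- rowsum(as.numeric(mag), as.integer(bin))
    hst[as.integer(rownames(agg)) + 1L] <- agg
    th <- (which.max(hst) - 0.5) / 36 * 2 * pi - pi
    co <- cos(th); si <- sin(th)
    qr <- matrix(sub_r[k] + co * grid_d$dr + si * grid_d$dc, patch, patch)
    qc <- matrix(sub_c[k] - si * grid_d$dr + co * grid_d$dc, patch, patch)
    p <- as.numeric(cpp_bilinear_sample(bl, qr, qc))
    p <- p - mean(p)
    nm <- sqrt(sum(p^2))
    if (nm < 1e-12) { ok[k] <- FALSE; next }
    desc[k, ] <- p / nm
    ori[k] <- th
  }
  out <- data.frame(row = sub_r[ok], col = sub_c[ok], score = sc[ok],
                    orientation = ori[ok])
  attr(out, "descriptors") <- desc[ok, , drop = FALSE]
  out
}

quad_peak <- function(lo, mid, hi) {
  den <- lo - 2 * mid + hi
  if (!is.finite(den) || den >= -1e-12) return(0)
  d <- 0.5 * (lo - hi) / den
  max(-0.5, min(0.5, d))
}

#' Edge mask by hysteresis-thresholded gradient magnitude
#'
#' Gradient-magnitude edges with hysteresis thresholds at `low`/`high` times
#' the maximum gradient magnitude, dilated by a disk of radius `dilate_r`.
#' Keypoints restricted to this mask sit on membrane boundaries, where
#' natural slice-to-slice deformation is smallest.
#'
#' @param img numeric matrix.
#' @param low,high hysteresis thresholds as fractions of the max gradient
#'   magnitude (`0 <= low < high`).
#' @param dilate_r dilation radius (px); 0 returns the raw edge set.
#' @return logical matrix.
#' @export
edge_mask <- function(img, low = 0.1, high = 0.2, dilate_r = 2L) {
  if (low < 0 || low >= high) stop("need 0 <= low < high")
  g <- central_grad(blur2d(img, 1))
  mag <- sqrt(g$gr^2 + g$gc^2)
  mx <- max(mag)
  if (mx <= 0) return(matrix(FALSE, nrow(img), ncol(img)))
  strong <- mag >= high * mx
  weak <- mag >= low * mx
  cpp_dilate_disk(cpp_hysteresis(strong, weak), as.integer(dilate_r))
}

#' Keep keypoints lying on an edge mask
#' @param kps keypoint data.frame from [detect_keypoints()].
#' @param mask logical matrix (image-shaped).
#' @export
filter_edge_keypoints <- function(kps, mask) {
  if (nrow(kps) == 0L) return(kps)
  ri <- pmin(pmax(round(kps$row) + 1, 1), nrow(mask))
  ci <- pmin(pmax(round(kps$col) + 1, 1), ncol(mask))
  keep <- mask[cbind(ri, ci)]
  out <- kps[keep, , drop = FALSE]
  attr(out, "descriptors") <- attr(kps, "descriptors")[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bidirectional (mutual) nearest-neighbor descriptor matching
#'
#' A putative pair (i, j) is accepted iff j is the Euclidean nearest neighbor
#' of i among the target descriptors AND i is the nearest neighbor of j among
#' the source descriptors; all other pairs are discarded. Exact distance ties
#' break to the smallest index. Accepted pairs form a partial one-to-one
#' mapping.
#'
#' @param src_kps,tgt_kps keypoint data.frames with `descriptors` attributes.
#' @param max_ratio optional Lowe ratio test: additionally require the best
#'   descriptor distance to be below `max_ratio` times the second best on the
#'   source side (`NULL` disables; mutual NN alone then decides).
#' @return data.frame of class `match_set` with columns `src`, `tgt`, `dist`.
#' @export
match_bidirectional <- function(src_kps, tgt_kps, max_ratio = NULL) {
  ds <- attr(src_kps, "descriptors"); dt <- attr(tgt_kps, "descriptors")
  if (is.null(ds) || is.null(dt) || nrow(ds) == 0L || nrow(dt) == 0L) {
    warning("empty keypoint set: no matches")
    return(structure(data.frame(src = integer(0), tgt = integer(0),
                                dist = numeric(0)), class = c("match_set", "data.frame")))
  }
  d2 <- outer(rowSums(ds^2), rowSums(dt^2), "+") - 2 * tcrossprod(ds, dt)
  nn_st <- max.col(-d2, ties.method = "first")          # per source row
  nn_ts <- max.col(-t(d2), ties.method = "first")       # per target col
  src <- which(nn_ts[nn_st] == seq_len(nrow(ds)))
  tgt <- nn_st[src]
  if (!is.null(max_ratio) && length(src) > 0L && ncol(d2) > 1L) {
    keep <- vapply(seq_along(src), function(i) {
      row <- d2[src[i], ]
      best <- row[tgt[i]]
      row[tgt[i]] <- Inf
      sqrt(max(best, 0)) < max_ratio * sqrt(max(min(row), 0))
    }, logical(1))
    src <- src[keep]; tgt <- tgt[keep]
  }
  structure(data.frame(src = src, tgt = tgt,
                       dist = sqrt(pmax(d2[cbind(src, tgt)], 0))),
            class = c("match_set", "data.frame"))
}

#' Locality-preserving match filtering
#'
#' Keeps matches whose local neighborhood structure is preserved: for each
#' match, the fraction of its `K` nearest matched neighbors (by source
#' position) whose counterparts remain among the `K` nearest matched
#' neighbors of its own counterpart (by target position) must reach `tau`.
#' Repeated for `passes` rounds, recomputing neighborhoods on survivors.
#'
#' @param src_kps,tgt_kps keypoint data.frames.
#' @param matches a `match_set` from [match_bidirectional()].
#' @param K neighborhood size.
#' @param tau minimum preserved fraction in \[0, 1\].
#' @param passes filtering rounds.
#' @export
lpm_filter <- function(src_kps, tgt_kps, matches, K = 6L, tau = 0.5, passes = 2L) {
  if (nrow(matches) <= K) {
    warning("too few matches for locality filtering; returning unchanged")
    return(matches)
  }
  cur <- matches
  for (p in seq_len(passes)) {
    n <- nrow(cur)
    if (n <= K) break
    sp <- cbind(src_kps$row[cur$src], src_kps$col[cur$src])
    tp <- cbind(tgt_kps$row[cur$tgt], tgt_kps$col[cur$tgt])
    ds <- as.matrix(stats::dist(sp)); diag(ds) <- Inf
    dt <- as.matrix(stats::dist(tp)); diag(dt) <- Inf
    frac <- numeric(n)
    for (i in seq_len(n)) {
      ns <- order(ds[i, ])[seq_len(K)]
      nt <- order(dt[i, ])[seq_len(K)]
      frac[i] <- length(intersect(ns, nt)) / K
    }
    keep <- frac >= tau
    if (all(keep)) break
    cur <- cur[keep, , drop = FALSE]
    rownames(cur) <- NULL
  }
  cur
}

#' Closed-form rigid fit between matched point sets (Kabsch/SVD)
#'
#' Least-squares rotation+translation mapping `Y` onto `X`: with centroids
#' `u`, `v` and centered sets, the cross-covariance `S = X̃ Ỹᵀ` is decomposed
#' by SVD and the rotation reflection-corrected via a determinant guard;
#' `t = u - R v`. Exact at machine precision on noise-free correspondences.
#'
#' @param X,Y n x 2 matrices of (row, col) points; `Y` is mapped onto `X`.
#' @return a [rigid_transform()] (absolute form, center at origin) with a
#'   `residual_rms` field.
#' @export
estimate_rigid <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) < 2L || nrow(X) != nrow(Y))
    stop("degenerate input: need >= 2 point pairs")
  u <- colMeans(X); v <- colMeans(Y)
  Xc <- sweep(X, 2, u); Yc <- sweep(Y, 2, v)
  if (max(abs(Xc)) < 1e-12 || max(abs(Yc)) < 1e-12)
    stop("degenerate input: zero-variance point set")
  S <- t(Xc) %*% Yc            # 2x2 cross-covariance (X̃ Ỹᵀ in column form)
  sv <- svd(S)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, d)) %*% t(sv$v)
  tt <- u - as.numeric(R %*% v)
  tr <- rigid_from_Rb(R, tt)
  pred <- t(apply_rigid_points(tr, t(Y)))
  tr$residual_rms <- sqrt(mean(rowSums((pred - X)^2)))
  tr
}

#' Sequential rigid alignment of a stack
#'
#' Slice 1 is the fixed reference. For each subsequent slice the full pairwise
#' sub-pipeline runs against the already-aligned previous slice (detect ->
#' edge filter -> mutual NN -> locality filter -> SVD fit); because the
#' reference already sits in the global frame, the fitted transform is the
#' cumulative transform, and the original slice is resampled exactly once
#' under it. Pairs with fewer than `min_matches` surviving correspondences
#' fall back to the previous cumulative transform (identity pairwise) with a
#' warning. When `passes > 1`, additional refinement passes fit a rigid
#' model to the dense residual displacement field between consecutive
#' *aligned* slices (trimmed least squares over an interior pixel grid) and
#' compose it in: both images have then been resampled exactly once, so the
#' sharp-versus-interpolated localization asymmetry of the first pass
#' cancels, and the dense consensus suppresses the keypoint-level drift that
#' otherwise accumulates along the stack; slices are still resampled from
#' the originals, once, after each pass.
#'
#' @param stack a [slice_stack()] with `n >= 2`.
#' @param max_keypoints,nms_radius,patch detector settings ([detect_keypoints()]).
#' @param edge_low,edge_high,edge_dilate edge-mask settings ([edge_mask()]).
#' @param lpm_k,lpm_tau,lpm_passes locality-filter settings ([lpm_filter()]).
#' @param min_matches minimum surviving matches before falling back.
#' @param match_ratio Lowe ratio passed to [match_bidirectional()].
#' @param border_margin fraction of the shorter image side (or px if >= 1)
#'   excluded at each border when collecting keypoints: border regions of the
#'   resampled reference hold edge-clamped (invalid) content and are where
#'   misaligned slices lose overlap.
#' @param refine_iters trimmed re-fit rounds after the locality filter: fit,
#'   drop pairs with residual above `refine_trim` times the median residual
#'   (never below 1 px), refit. Suppresses residual mismatches that survive
#'   the neighborhood filter.
#' @param refine_trim trim multiplier for the refinement rounds.
#' @param passes alignment passes: 1 = sequential only, 2 (default) adds one
#'   flow-based aligned-to-aligned drift-correction pass.
#' @param refine_flow_params [flow_params()] for the drift-correction pass.
#' @param detector pluggable keypoint function with the signature of
#'   [detect_keypoints()] (image, max_n, nms_radius, patch).
#' @return list with `stack` (aligned) and `transforms` (cumulative
#'   [rigid_transform()] per slice, identity for slice 1).
#' @export
align_stack_rigid <- function(stack, max_keypoints = 1000L, nms_radius = 5,
                              patch = 16L, edge_low = 0.1, edge_high = 0.2,
                              edge_dilate = 2L, lpm_k = 6L, lpm_tau = 0.5,
                              lpm_passes = 2L, min_matches = 8L,
                              match_ratio = 0.9, refine_iters = 3L,
                              refine_trim = 3.0, border_margin = 0.12,
                              passes = 2L,
                              refine_flow_params = flow_params(inner_iters = 60L),
                              detector = detect_keypoints) {
  if (stack$n < 2L) stop("need at least 2 slices")
  center <- c((stack$height - 1) / 2, (stack$width - 1) / 2)
  aligned <- vector("list", stack$n)
  transforms <- vector("list", stack$n)
  aligned[[1]] <- stack$slices[[1]]
  transforms[[1]] <- rigid_transform(0, c(0, 0), center)
  marg <- if (border_margin < 1) border_margin * min(stack$height, stack$width)
          else border_margin
  kp_of <- function(img) {
    kp <- detector(img, max_keypoints, nms_radius, patch)
    kp <- filter_edge_keypoints(kp, edge_mask(img, edge_low, edge_high, edge_dilate))
    keep <- kp$row > marg & kp$row < stack$height - 1 - marg &
            kp$col > marg & kp$col < stack$width - 1 - marg
    out <- kp[keep, , drop = FALSE]
    attr(out, "descriptors") <- attr(kp, "descriptors")[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  # trimmed pairwise fit between two keypoint sets; NULL if underdetermined
  fit_pair <- function(kpA, kpB) {
    if (nrow(kpA) == 0L || nrow(kpB) == 0L) return(NULL)
    m <- match_bidirectional(kpA, kpB, max_ratio = match_ratio)
    if (nrow(m) > lpm_k)
      m <- lpm_filter(kpA, kpB, m, lpm_k, lpm_tau, lpm_passes)
    if (nrow(m) < min_matches) return(NULL)
    X <- cbind(kpA$row[m$src], kpA$col[m$src])
    Y <- cbind(kpB$row[m$tgt], kpB$col[m$tgt])
    tr <- estimate_rigid(X, Y)
    for (it in seq_len(refine_iters)) {
      pred <- t(apply_rigid_points(tr, t(Y)))
      res <- sqrt(rowSums((pred - X)^2))
      keep <- res < max(refine_trim * median(res), 1.0)
      if (sum(keep) < max(min_matches, 3L) || all(keep)) break
      X <- X[keep, , drop = FALSE]; Y <- Y[keep, , drop = FALSE]
      tr <- estimate_rigid(X, Y)
    }
    tr$n_matches <- nrow(X)
    tr
  }
  recenter <- function(tr) {
    tr$center <- center
    tr$t <- as.numeric(tr$b) - center + as.numeric(tr$R %*% center)
    tr
  }
  kp_prev <- kp_of(aligned[[1]])
  for (t in 2:stack$n) {
    tr <- fit_pair(kp_prev, kp_of(stack$slices[[t]]))
    if (is.null(tr)) {
      log_msg("warn", "slice %d: insufficient matches, keeping previous transform", t)
      tr <- transforms[[t - 1]]
    } else {
      tr <- recenter(tr)
      log_msg("debug", "slice %d: %d matches, residual %.3f px",
              t, tr$n_matches, tr$residual_rms)
    }
    transforms[[t]] <- tr
    aligned[[t]] <- apply_rigid(stack$slices[[t]], tr)
    kp_prev <- kp_of(aligned[[t]])
  }
  if (passes > 1L) {
    g <- coord_grids(stack$height, stack$width)
    step <- max(2L, round(min(stack$height, stack$width) / 128))
    sel <- which(g$r >= marg & g$r <= stack$height - 1 - marg &
                 g$c >= marg & g$c <= stack$width - 1 - marg &
                 (g$r %% step == 0) & (g$c %% step == 0))
    for (p in seq_len(passes - 1L)) {
      for (t in 2:stack$n) {
        f <- estimate_flow(aligned[[t - 1L]], aligned[[t]], refine_flow_params)
        X <- cbind(g$r[sel], g$c[sel])
        Y <- cbind(g$r[sel] + f[, , 1][sel], g$c[sel] + f[, , 2][sel])
        fit <- estimate_rigid(X, Y)
        for (it in 1:2) {  # trim pixels that follow elastic, not rigid, motion
          pred <- t(apply_rigid_points(fit, t(Y)))
          rs <- sqrt(rowSums((pred - X)^2))
          keep <- rs < max(refine_trim * median(rs), 0.5)
          if (all(keep)) break
          X <- X[keep, , drop = FALSE]; Y <- Y[keep, , drop = FALSE]
          fit <- estimate_rigid(X, Y)
        }
        transforms[[t]] <- recenter(compose_rigid(fit, transforms[[t]]))
        aligned[[t]] <- apply_rigid(stack$slices[[t]], transforms[[t]])
        log_msg("debug", "refine pass %d slice %d: residual %.3f px",
                p, t, fit$residual_rms)
      }
    }
  }
  list(stack = slice_stack(aligned, stack$bit_depth), transforms = transforms)
}
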