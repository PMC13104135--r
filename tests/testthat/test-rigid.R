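test_that("keypoint detection is deterministic and respects its contracts", {
  img <- textured_slice()
  kp1 <- detect_keypoints(img)
  kp2 <- detect_keypoints(img)
  expect_identical(kp1, kp2)
  expect_gte(nrow(kp1), 50)
  expect_lte(nrow(kp1), 500)
  expect_true(all(kp1$row >= 0 & kp1$row <= nrow(img) - 1))
  d <- attr(kp1, "descriptors")
  expect_equal(unname(rowSums(d^2)), rep(1, nrow(kp1)), tolerance = 1e-6)
  expect_equal(nrow(detect_keypoints(matrix(0.5, 64, 64))), 0L)
  expect_error(detect_keypoints(matrix(0.5, 16, 16)), "small")
  # strongest-first ordering
  expect_true(all(diff(kp1$score) <= 0))
})

test_that("edge masks localize a step edge and obey dilation", {
  expect_false(any(edge_mask(matrix(0.3, 64, 64))))
  step <- cbind(matrix(0.2, 64, 32), matrix(0.8, 64, 32))
  m <- edge_mask(step, dilate_r = 2)
  on_cols <- which(apply(m, 2, any))
  expect_true(all(abs(on_cols - 32.5) <= 2 + 2.5))  # within dilate_r of the step
  expect_false(any(m[, c(1:20, 45:64)]))
  raw <- edge_mask(step, dilate_r = 0)
  expect_lte(sum(raw), sum(m))
})

test_that("edge keypoint filtering matches direct per-point lookup", {
  img <- textured_slice()
  kp <- detect_keypoints(img)
  mask <- edge_mask(img)
  kept <- filter_edge_keypoints(kp, mask)
  manual <- vapply(seq_len(nrow(kp)), function(i)
    mask[round(kp$row[i]) + 1, round(kp$col[i]) + 1], logical(1))
  expect_equal(nrow(kept), sum(manual))
  expect_equal(kept$row, kp$row[manual])
  expect_identical(filter_edge_keypoints(kp, matrix(TRUE, 256, 256))$row, kp$row)
  expect_equal(nrow(filter_edge_keypoints(kp, matrix(FALSE, 256, 256))), 0L)
})

test_that("mutual nearest-neighbor matching is exact against brute force", {
  mk <- function(desc, pos = NULL) {
    n <- nrow(desc)
    kp <- data.frame(row = if (is.null(pos)) seq_len(n) else pos[, 1],
                     col = if (is.null(pos)) seq_len(n) else pos[, 2],
                     score = rep(1, n))
    attr(kp, "descriptors") <- desc / sqrt(rowSums(desc^2))
    kp
  }
  set.seed(1)
  d <- matrix(rnorm(5 * 8), 5, 8)
  m <- match_bidirectional(mk(d), mk(d))
  expect_equal(m$src, 1:5)
  expect_equal(m$tgt, 1:5)
  expect_equal(m$dist, rep(0, 5), tolerance = 1e-7)

  # 3-vs-3 case where a1's NN is b2 but b2's NN is a3: (a1, b2) must be rejected
  A <- rbind(c(1, 0.30), c(0, 1), c(1, 0.1))
  B <- rbind(c(0, 1.05), c(1, 0), c(-1, 0))
  mab <- match_bidirectional(mk(A), mk(B))
  dn <- function(x, y) sqrt(sum((x / sqrt(sum(x^2)) - y / sqrt(sum(y^2)))^2))
  d2 <- outer(1:3, 1:3, Vectorize(function(i, j) dn(A[i, ], B[j, ])))
  expect_equal(which.min(d2[1, ]), 2L)       # a1 -> b2
  expect_false(which.min(d2[, 2]) == 1L)     # b2 -> a3, not a1
  expect_false(any(mab$src == 1 & mab$tgt == 2))
  # brute-force mutual set
  brute <- which(outer(1:3, 1:3, Vectorize(function(i, j)
    which.min(d2[i, ]) == j && which.min(d2[, j]) == i)), arr.ind = TRUE)
  expect_equal(nrow(mab), nrow(brute))
  # one-to-one partial mapping
  expect_false(any(duplicated(mab$src)))
  expect_false(any(duplicated(mab$tgt)))
  # symmetry: swapping sides transposes the accepted set
  mba <- match_bidirectional(mk(B), mk(A))
  expect_setequal(paste(mab$src, mab$tgt), paste(mba$tgt, mba$src))
})

test_that("locality-preserving filtering removes the displaced outlier only", {
  g <- expand.grid(row = seq(0, 90, by = 10), col = seq(0, 90, by = 10))
  n <- nrow(g)
  mk <- function(pos) {
    kp <- data.frame(row = pos[, 1], col = pos[, 2], score = rep(1, n))
    attr(kp, "descriptors") <- diag(n)
    kp
  }
  src <- as.matrix(g)
  tr <- rigid_transform(20, c(4, -7), c(45, 45))
  tgt <- t(apply_rigid_points(tr, t(src)))
  matches <- structure(data.frame(src = 1:n, tgt = 1:n, dist = 0),
                       class = c("match_set", "data.frame"))
  kept <- lpm_filter(mk(src), mk(tgt), matches, K = 6, tau = 0.5, passes = 2)
  expect_equal(nrow(kept), n)  # global rigid motion preserves neighborhoods
  tgt_bad <- tgt
  tgt_bad[37, ] <- tgt_bad[37, ] + c(300, 300)
  kept2 <- lpm_filter(mk(src), mk(tgt_bad), matches, K = 6, tau = 0.5, passes = 2)
  expect_false(37 %in% kept2$src)
  expect_gte(nrow(kept2), n - 3)
  kept3 <- lpm_filter(mk(src), mk(tgt_bad), matches, K = 6, tau = 0, passes = 2)
  expect_equal(nrow(kept3), n)  # tau = 0 removes nothing
  expect_warning(lpm_filter(mk(src), mk(tgt), matches[1:4, ], K = 6),
                 "few matches")
})

test_that("the SVD rigid fit is exact, reflection-guarded and equivariant", {
  X <- rbind(c(0, 0), c(10, 0), c(3, 8), c(-4, 5))
  fit0 <- estimate_rigid(X, X)
  expect_equal(fit0$theta_deg, 0, tolerance = 1e-12)
  expect_equal(fit0$b, c(0, 0), tolerance = 1e-12)
  expect_equal(fit0$residual_rms, 0, tolerance = 1e-12)

  tr <- rigid_transform(30, c(5, -3), c(2, 7))
  Y <- t(t(tr$R) %*% (t(X) - tr$b))         # inverse-map X so that fit(Y) = X
  fit <- estimate_rigid(X, Y)
  expect_equal(fit$theta_deg, 30, tolerance = 1e-9)
  expect_equal(fit$b, tr$b, tolerance = 1e-9)
  expect_lt(fit$residual_rms, 1e-9)
  # orthonormality and determinant invariants
  expect_equal(crossprod(fit$R), diag(2), tolerance = 1e-9)
  expect_equal(det(fit$R), 1, tolerance = 1e-9)

  # mirrored points: no reflection may be emitted
  Ym <- cbind(X[, 1], -X[, 2])
  fitm <- estimate_rigid(X, Ym)
  expect_equal(det(fitm$R), 1, tolerance = 1e-9)
  expect_gt(fitm$residual_rms, 0.1)

  # equivariance: pre-rotating both sets by Q conjugates the fit
  Q <- rigid_transform(57, c(0, 0))$R
  fitq <- estimate_rigid(t(Q %*% t(X)), t(Q %*% t(Y)))
  expect_equal(fitq$R, Q %*% fit$R %*% t(Q), tolerance = 1e-9)

  expect_error(estimate_rigid(X[1, , drop = FALSE], X[1, , drop = FALSE]),
               "degenerate")
  Z <- matrix(5, 4, 2)
  expect_error(estimate_rigid(Z, Z), "degenerate")
})

test_that("rigid resampling moves content as the transform dictates", {
  img <- textured_slice()
  ident <- apply_rigid(img, rigid_transform(0, c(0, 0)))
  expect_identical(ident, img)
  delta <- matrix(0, 64, 64); delta[11, 21] <- 1
  moved <- apply_rigid(delta, rigid_transform(0, c(5, 0)))
  peak <- which(moved == max(moved), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(16, 21))
  tr <- rigid_transform(9, c(4, -6), c(127.5, 127.5))
  back <- apply_rigid(apply_rigid(img, tr), invert_rigid(tr))
  expect_gt(interior_ssim_of(back, img, 32), 0.98)
})

test_that("transform composition and inversion are consistent", {
  a <- rigid_transform(17, c(3, -2), c(10, 10))
  b <- rigid_transform(-5, c(0.5, 4), c(10, 10))
  p <- rbind(c(1, 2), c(30, 40), c(-3, 12))
  via_compose <- t(apply_rigid_points(compose_rigid(a, b), t(p)))
  direct <- t(apply_rigid_points(a, apply_rigid_points(b, t(p))))
  expect_equal(via_compose, direct, tolerance = 1e-12)
  ident <- compose_rigid(a, invert_rigid(a))
  expect_equal(ident$R, diag(2), tolerance = 1e-12)
  expect_equal(ident$b, c(0, 0), tolerance = 1e-12)
})

test_that("an already-aligned stack stays put under sequential alignment", {
  vol <- phantom_mid()
  st <- slice_volume(vol, 1)
  res <- align_stack_rigid(st)
  for (tr in res$transforms) {
    expect_lt(abs(tr$theta_deg), 0.2)
    expect_lt(sqrt(sum(tr$t^2)), 0.5)
  }
})

test_that("sequential alignment recovers moderate jitter on a small stack", {
  vol <- generate_phantom(c(16, 512, 512), 60, seed = 42)
  st <- slice_volume(vol, 1)   # 16 slices, 512^2
  jit <- apply_rigid_jitter(st, t_max = 20, theta_max = 8, seed = 31)
  noisy <- add_gaussian_noise(jit$stack, 0.02, seed = 32)
  res <- align_stack_rigid(noisy)
  center <- c((st$height - 1) / 2, (st$width - 1) / 2)
  errs <- t(vapply(seq_len(st$n), function(i)
    transform_errors(res$transforms[[i]], jit$gt$transforms[[i]], center),
    numeric(2)))
  expect_lt(max(errs[, "translation"]), 1)
  expect_lt(max(errs[, "rotation"]), 0.5)
  # single-resample propagation beats repeated resampling at the same
  # cumulative transform (noise-free slice, so blur cannot masquerade as
  # denoising)
  post <- mean(vapply(2:st$n, function(i)
    ssim(get_slice(res$stack, i), get_slice(st, i)), numeric(1)))
  Tc <- res$transforms[[5]]
  T1 <- rigid_transform(Tc$theta_deg / 2, Tc$t / 2, center)
  T2 <- compose_rigid(Tc, invert_rigid(T1))
  double <- apply_rigid(apply_rigid(get_slice(jit$stack, 5), T1), T2)
  once <- apply_rigid(get_slice(jit$stack, 5), Tc)
  expect_gte(ssim(once, get_slice(st, 5)), ssim(double, get_slice(st, 5)))
  # alignment strictly improves similarity to the undistorted reference
  pre <- mean(vapply(2:st$n, function(i)
    ssim(get_slice(noisy, i), get_slice(st, i)), numeric(1)))
  expect_gt(post, pre)
})
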