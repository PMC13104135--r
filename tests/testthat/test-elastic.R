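test_that("the axial Gaussian kernel is normalized, symmetric and correct", {
  k <- gaussian_kernel_1d(1, 1)
  # exp(-k^2/2)/Z evaluated analytically
  z <- 1 + 2 * exp(-0.5)
  expect_equal(k$weights, c(exp(-0.5), 1, exp(-0.5)) / z, tolerance = 1e-12)
  expect_equal(k$weights, c(0.274069, 0.451863, 0.274069), tolerance = 1e-6)
  for (r in 1:3) for (s in c(0.3, 1, 2.7)) {
    kk <- gaussian_kernel_1d(r, s)
    expect_equal(sum(kk$weights), 1, tolerance = 1e-12)
    expect_equal(kk$weights, rev(kk$weights), tolerance = 1e-15)
    expect_true(all(kk$weights > 0))
  }
  expect_gt(gaussian_kernel_1d(1, 0.1)$weights[2], 0.999)
  expect_error(gaussian_kernel_1d(1, 0), "sigma")
  expect_error(gaussian_kernel_1d(0, 1), "radius")
})

test_that("difference-reorganized filtering equals direct convolution", {
  k <- gaussian_kernel_1d(1, 1)
  expect_equal(filter_1d_reorganized(rep(3.7, 10), k), rep(3.7, 10),
               tolerance = 1e-14)
  ramp <- seq(0, 6.3, length.out = 20)
  expect_equal(filter_1d_reorganized(ramp, k)[2:19], ramp[2:19],
               tolerance = 1e-13)
  set.seed(9)
  worst <- 0
  for (i in 1:100) {
    s <- rnorm(64)
    worst <- max(worst, max(abs(filter_1d_reorganized(s, k)[2:63] -
                                conv1d_direct(s, k)[2:63])))
  }
  expect_lte(worst, 1e-12)
  expect_error(filter_1d_reorganized(c(1, 2), k), "length")
})

test_that("elastic_step is the identity on identical slices", {
  img <- textured_slice()
  st <- elastic_step(img, img, img, flow_fn = function(a, b) zero_field(256, 256))
  expect_true(all(st$field == 0))
  expect_identical(st$image, img)
  expect_equal(sum(st$weights), 1, tolerance = 1e-15)
})

test_that("elastic_step matches the symbolic closed form on translations", {
  k <- gaussian_kernel_1d(1, 1)
  tmpl <- phantom_small()$planes[[8]]
  cases <- list(list(c(2, -1), c(0, 3), c(-4, 2)),
                list(c(0, 0), c(5, 5), c(0, 0)),
                list(c(1, 1), c(1, 1), c(1, 1)))
  for (sh in cases) {
    st <- make_translation_stack(tmpl, sh)
    out <- elastic_step(get_slice(st, 1), get_slice(st, 2), get_slice(st, 3),
                        k, translation_oracle_flow)
    pred <- elastic_step_shift_oracle(sh[[1]], sh[[2]], sh[[3]], k)
    expect_lt(max(abs(out$field[, , 1] - pred[1])), 1e-6)
    expect_lt(max(abs(out$field[, , 2] - pred[2])), 1e-6)
  }
  # constant-shift triples are exact fixed points
  stc <- make_translation_stack(tmpl, list(c(3, 2), c(3, 2), c(3, 2)))
  outc <- elastic_step(get_slice(stc, 1), get_slice(stc, 2), get_slice(stc, 3),
                       k, translation_oracle_flow)
  expect_true(all(outc$field == 0))
  # normalized weights sum to one exactly
  expect_identical(sum(outc$weights), 1)
})

test_that("a sweep is Jacobi-style and preserves already-smooth stacks", {
  # identity preservation with zero flow, including boundary slices
  img <- textured_slice()
  st <- slice_stack(rep(list(img), 4))
  res <- register_stack_elastic(st, flow_fn = function(a, b) zero_field(256, 256))
  expect_identical(res$stack$slices, st$slices)
  expect_true(all(vapply(res$fields, function(f) all(f == 0), logical(1))))
  # low-frequency (z-linear) smooth deformation is preserved: the combined
  # fields stay near identity. Closed-form systematic part for per-step
  # increment b: (g1/2) b in the interior, g1 b at the one-sided boundaries
  # (= 0.21 px for b = 0.75 px); the rest is estimator noise.
  P <- phantom_mid()$planes[[8]]
  g <- emalign:::coord_grids(256, 256)
  f0 <- displacement_field(3 * sin(2 * pi * g$c / 256),
                           3 * cos(2 * pi * g$r / 256))
  cs <- seq(-0.5, 0.5, by = 0.25)
  smooth_st <- slice_stack(lapply(cs, function(c_) warp(P, scale_field(f0, c_))))
  r2 <- register_stack_elastic(smooth_st)
  expect_lt(max(vapply(r2$fields, function(f) max(abs(f)), numeric(1))), 0.35)
  expect_error(register_stack_elastic(slice_stack(rep(list(img), 2))), "3 slices")
})

test_that("one sweep attenuates alternating jitter by the closed-form factor", {
  k <- gaussian_kernel_1d(1, 1)
  tmpl <- phantom_small()$planes[[8]]
  shifts <- lapply(1:8, function(i) c(4 * (-1)^i, 0))
  st <- make_translation_stack(tmpl, shifts)
  res <- register_stack_elastic(st, k, flow_fn = translation_oracle_flow)
  got <- vapply(1:8, function(i)
    shifts[[i]][1] - res$fields[[i]][1, 1, 1], numeric(1))
  pred <- vapply(elastic_sweep_shift_oracle(shifts, k), `[`, numeric(1), 1)
  expect_equal(got, pred, tolerance = 1e-6)
  # interior variance reduced by at least half; mean preserved
  expect_lt(var(got[2:7]), 0.5 * var(vapply(shifts[2:7], `[`, numeric(1), 1)))
  expect_equal(mean(got[2:7]), 0, tolerance = 1e-6)
  # constant sequences are fixed points of the sweep
  stc <- make_translation_stack(tmpl, rep(list(c(2, -3)), 5))
  resc <- register_stack_elastic(stc, k, flow_fn = translation_oracle_flow)
  expect_true(all(vapply(resc$fields, function(f) max(abs(f)), numeric(1)) == 0))
})

test_that("elastic registration improves distorted stacks against ground truth", {
  vol <- phantom_mid()
  clean <- slice_stack(vol$planes[4:11])
  dist <- apply_elastic_distortion(clean, alpha = 1, seed = 77)
  reg <- register_stack_elastic(dist$stack)
  pre <- vapply(1:8, function(i)
    ssim(get_slice(dist$stack, i), get_slice(clean, i)), numeric(1))
  post <- vapply(1:8, function(i)
    ssim(get_slice(reg$stack, i), get_slice(clean, i)), numeric(1))
  expect_gt(mean(post) - mean(pre), 0.05)
  expect_gte(mean(post[2:7] >= pre[2:7]), 0.9)
})
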