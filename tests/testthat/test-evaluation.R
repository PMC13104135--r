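test_that("difference images are exact signed subtractions", {
  a <- textured_slice(); b <- phantom_mid()$planes[[9]]
  expect_true(all(difference_image(a, a) == 0))
  expect_equal(difference_image(a, b), -difference_image(b, a), tolerance = 1e-15)
  expect_equal(difference_image(a, b), b - a, tolerance = 1e-15)
  expect_error(difference_image(a, matrix(0, 4, 4)), "shape")
})

test_that("the Laplacian kernel acts as expected on canonical inputs", {
  expect_true(all(laplacian_filter(matrix(2.2, 16, 16)) == 0))
  imp <- matrix(0, 9, 9); imp[5, 5] <- 1
  li <- laplacian_filter(imp)
  expect_equal(li[5, 5], -4)
  expect_equal(li[4, 5], 1); expect_equal(li[6, 5], 1)
  expect_equal(li[5, 4], 1); expect_equal(li[5, 6], 1)
  expect_equal(sum(abs(li)), 8)
  ramp <- outer(1:16, 1:16, function(i, j) 0.3 * i + 0.1 * j)
  expect_true(all(abs(laplacian_filter(ramp)[2:15, 2:15]) < 1e-12))
})

test_that("entropy matches closed forms and a brute-force histogram oracle", {
  expect_equal(img_entropy(matrix(0.7, 32, 32)), 0)
  half <- rbind(matrix(0, 16, 32), matrix(1, 16, 32))
  expect_equal(img_entropy(half), 1)
  uniform <- matrix(rep(0:255 / 255, each = 256), 256, 256)
  expect_equal(img_entropy(uniform), 8, tolerance = 1e-12)
  set.seed(4)
  x <- matrix(runif(40 * 40, -3, 5), 40)
  # independent oracle: quantize by hand, tabulate, Shannon formula
  q <- round((x - min(x)) / diff(range(x)) * 255)
  p <- as.numeric(table(q)) / length(q)
  expect_equal(img_entropy(x), -sum(p * log2(p)), tolerance = 1e-12)
  expect_lte(img_entropy(x), 8)  # bounded by log2(levels)
})

test_that("the bilateral split conserves its input and ranks structure above noise", {
  set.seed(5)
  noise <- matrix(rnorm(64 * 64), 64)
  sp <- snr_bilateral(noise, components = TRUE)
  expect_equal(sp$If + sp$In, noise, tolerance = 1e-12)
  g <- coord_grids(64, 64)
  smooth <- sin(2 * pi * g$r / 64) + cos(2 * pi * g$c / 64)
  smooth <- smooth * sd(noise) / sd(smooth)  # equalize variance
  expect_gt(snr_bilateral(smooth), snr_bilateral(noise))
  expect_identical(snr_bilateral(matrix(0, 16, 16)), Inf)
})

test_that("the DoG pyramid telescopes and reproduces analytic impulse responses", {
  set.seed(6)
  x <- matrix(rnorm(96 * 96), 96)
  layers <- dog_pyramid(x)
  total <- Reduce(`+`, layers)
  direct <- emalign:::blur2d(x, 1) - emalign:::blur2d(x, 4)
  expect_lt(max(abs(total - direct)), 1e-10)
  expect_length(layers, 4)
  expect_lt(max(abs(dog_pyramid(matrix(1, 32, 32))[[1]])), 1e-12)
  # unit impulse: layer values match sampled Gaussian differences
  imp <- matrix(0, 65, 65); imp[33, 33] <- 1
  sig <- 2^((0:4) / 2)
  li <- dog_pyramid(imp, sig)
  gauss2d <- function(s, d) exp(-d^2 / (2 * s^2)) / (2 * pi * s^2)
  for (l in 1:4) {
    for (d in 0:3) {
      got <- li[[l]][33, 33 + d]
      want <- gauss2d(sig[l], d) - gauss2d(sig[l + 1], d)
      expect_lt(abs(got - want), 1e-3)
    }
  }
  expect_error(dog_pyramid(x, c(1, 2, 2, 3, 4)), "increasing")
})

test_that("co-occurrence contrast equals brute-force pair enumeration", {
  expect_equal(glcm_contrast(matrix(0.5, 16, 16)), 0)
  stripes <- matrix(rep(c(0, 1), 8), 8, 16, byrow = TRUE)  # vertical stripes
  expect_equal(glcm_contrast(stripes, levels = 2, offsets = list(c(0L, 1L))), 1)
  set.seed(7)
  x <- matrix(runif(64), 8, 8)
  lv <- 8L
  q <- emalign:::quantize_levels(x, lv)
  for (off in list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L))) {
    # brute force: enumerate all pixel pairs at the offset
    cnt <- matrix(0, lv, lv)
    for (i in 1:8) for (j in 1:8) {
      ii <- i + off[1]; jj <- j + off[2]
      if (ii >= 1 && ii <= 8 && jj >= 1 && jj <= 8) {
        a <- q[i, j] + 1; b <- q[ii, jj] + 1
        cnt[a, b] <- cnt[a, b] + 1
        cnt[b, a] <- cnt[b, a] + 1
      }
    }
    P <- cnt / sum(cnt)
    want <- sum(outer(0:(lv - 1), 0:(lv - 1), function(k, j) (k - j)^2) * P)
    expect_equal(glcm_contrast(x, lv, list(off)), want, tolerance = 1e-12)
    expect_equal(glcm_matrix(x, lv, off), P, tolerance = 1e-12)
  }
  expect_equal(sum(glcm_matrix(x, lv)), 1, tolerance = 1e-12)
})

test_that("stack evaluation reports one row per adjacent pair with sane zeros", {
  img <- textured_slice()
  st <- slice_stack(rep(list(img), 5))
  rep_ <- evaluate_stack(st)
  expect_equal(nrow(rep_$pairs), 4)
  expect_true(all(rep_$pairs$H == 0))
  expect_true(all(rep_$pairs[, c("Con0", "Con1", "Con2", "Con3")] == 0))
  expect_error(evaluate_stack(slice_stack(list(img))), "2 slices")
  # report writers produce readable CSV/JSON
  jf <- withr::local_tempfile(fileext = ".json")
  cf <- withr::local_tempfile(fileext = ".csv")
  write_report(rep_, jf, cf)
  expect_equal(nrow(utils::read.csv(cf)), 4)
  expect_true(jsonlite::validate(paste(readLines(jf), collapse = "")))
})

test_that("reference metrics hit their closed-form anchor values", {
  img <- textured_slice()
  st <- slice_stack(list(img, img))
  m <- reference_metrics(st, st)
  expect_equal(m$SSIM, c(1, 1), tolerance = 1e-12)
  expect_equal(m$NCC, c(1, 1), tolerance = 1e-12)
  expect_equal(ncc(img, 1 - img), -1, tolerance = 1e-12)
  # MI of an image with itself = marginal entropy (in nats)
  q <- round(pmin(pmax(img, 0), 1) * 255)
  p <- as.numeric(table(q)) / length(q)
  expect_equal(mutual_information(img, img), -sum(p * log(p)), tolerance = 1e-10)

  a <- matrix(FALSE, 4, 4); a[1:3, 1] <- TRUE           # |A| = 3
  b <- matrix(FALSE, 4, 4); b[2:4, 1] <- TRUE           # |B| = 3, overlap 2
  expect_equal(dice(a, b), 2 * 2 / 6, tolerance = 1e-12)
  expect_equal(dice(matrix(FALSE, 4, 4), matrix(FALSE, 4, 4)), 1)
  expect_equal(dice(a, matrix(FALSE, 4, 4)), 0)
  expect_true(is.na(hausdorff_distance(a, matrix(FALSE, 4, 4))))
  expect_equal(hausdorff_distance(a, a), 0)
  c2 <- matrix(FALSE, 8, 8); c2[1, 1] <- TRUE
  d2 <- matrix(FALSE, 8, 8); d2[4, 5] <- TRUE
  expect_equal(hausdorff_distance(c2, d2), 5)  # 3-4-5 triangle
  labs_a <- list(a, c2); labs_b <- list(b, d2)
  rm_ <- reference_metrics(st, st, labs_a, labs_b)
  expect_equal(rm_$Dice[1], 2 / 3, tolerance = 1e-12)
  expect_equal(rm_$Hausdorff[2], 5)
})
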