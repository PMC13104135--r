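# shared fixtures and independent oracles for the test suite

# small phantom volumes, generated once per test run
phantom_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_phantom(c(16, 128, 128), 12, seed = 42)
    cache
  }
})

phantom_mid <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_phantom(c(16, 256, 256), 24, seed = 42)
    cache
  }
})

textured_slice <- function() phantom_mid()$planes[[8]]

# scalar mirror of the five elastic_step stages for pure-translation stacks:
# the independent closed-form oracle for the frequency-decoupling algebra
elastic_step_shift_oracle <- function(u_prev, u_i, u_next, kernel) {
  gm1 <- kernel$weights[1]; g0 <- kernel$weights[2]; g1 <- kernel$weights[3]
  phi_i_im1 <- if (is.null(u_prev)) c(0, 0) else u_i - u_prev
  s_tmp0 <- u_i - gm1 * phi_i_im1            # content shift of I_i^tmp
  phi_tmp0 <- u_i - s_tmp0
  if (!is.null(u_next)) {
    phi_ip1_i <- u_next - u_i
    s_tmp1 <- u_next - g0 * phi_ip1_i        # content shift of I_{i+1}^tmp
    phi_tmp1 <- u_i - s_tmp1
    w <- c(gm1 + g0, g0 + g1); w <- w / sum(w)
    w[1] * phi_tmp0 + w[2] * phi_tmp1
  } else phi_tmp0
}

# effective per-slice output shifts of a translation stack passed through one
# elastic sweep, from the scalar oracle
elastic_sweep_shift_oracle <- function(shifts, kernel) {
  n <- length(shifts)
  lapply(seq_len(n), function(i) {
    phi <- elastic_step_shift_oracle(if (i > 1) shifts[[i - 1]] else NULL,
                                     shifts[[i]],
                                     if (i < n) shifts[[i + 1]] else NULL,
                                     kernel)
    shifts[[i]] - phi
  })
}

# error of a recovered cumulative transform against the inverse of an applied
# ground-truth transform, measured at the image center
transform_errors <- function(recovered, applied_gt, center) {
  inv <- invert_rigid(applied_gt)
  p1 <- inv$R %*% center + inv$b
  p2 <- recovered$R %*% center + recovered$b
  c(translation = sqrt(sum((p1 - p2)^2)),
    rotation = abs(((recovered$theta_deg - inv$theta_deg + 180) %% 360) - 180))
}

# SSIM on the interior, ignoring a clamped margin
interior_ssim_of <- function(a, b, margin) {
  ri <- (margin + 1):(nrow(a) - margin)
  ci <- (margin + 1):(ncol(a) - margin)
  ssim(a[ri, ci], b[ri, ci])
}

# direct dense Gaussian convolution of a 1D signal, replicate boundary:
# independent oracle for the reorganized filtering identity
conv1d_direct <- function(signal, kernel) {
  r <- kernel$radius
  n <- length(signal)
  padded <- c(rep(signal[1], r), signal, rep(signal[n], r))
  vapply(seq_len(n), function(i)
    sum(kernel$weights * padded[i:(i + 2 * r)]), numeric(1))
}
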