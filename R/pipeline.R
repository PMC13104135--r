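#' Full synthetic degradation protocol
#'
#' Fixed composition order — section the volume, then rigid jitter, then
#' elastic distortion, then noise — i.e. an ideal stack degraded the way a
#' physical sectioning/imaging chain would degrade it. All ground truth is
#' recorded.
#'
#' @param vol a [generate_phantom()] volume.
#' @param interval section interval ([slice_volume()]).
#' @param t_max,theta_max rigid jitter ranges ([apply_rigid_jitter()]).
#' @param alpha,sigma_d,amp0 elastic distortion ([apply_elastic_distortion()]).
#' @param noise_sigma additive noise level ([add_gaussian_noise()]).
#' @param seed RNG seed (stages draw from derived seeds).
#' @return list: `clean` (undegraded stack), `stack` (degraded),
#'   `gt` (list with `transforms`, `fields`, `noise_sigma`, `interval`,
#'   `alpha`).
#' @export
simulate_stack <- function(vol, interval = 1L, t_max = 100, theta_max = 35,
                           alpha = 1.0, sigma_d = 24, amp0 = 8,
                           noise_sigma = 0, seed = 1L) {
  clean <- slice_volume(vol, interval)
  jit <- apply_rigid_jitter(clean, t_max, theta_max, seed = seed + 1L)
  ela <- apply_elastic_distortion(jit$stack, alpha, sigma_d, amp0,
                                  seed = seed + 2L)
  noisy <- add_gaussian_noise(ela$stack, noise_sigma, seed = seed + 3L)
  list(clean = clean, stack = noisy,
       gt = list(transforms = jit$gt$transforms, fields = ela$gt$fields,
                 noise_sigma = noise_sigma, interval = as.integer(interval),
                 alpha = alpha))
}

#' Run the full alignment pipeline (rigid then elastic)
#'
#' @param stack a [slice_stack()].
#' @param config a [default_config()]-style configuration list.
#' @return list: `stack` (aligned), `transforms` (cumulative rigid),
#'   `fields` (elastic displacement fields).
#' @export
align_stack <- function(stack, config = default_config()) {
  rg <- align_stack_rigid(
    stack,
    max_keypoints = config$rigid.max_keypoints,
    nms_radius = config$rigid.nms_radius, patch = config$rigid.patch,
    edge_low = config$rigid.edge_low, edge_high = config$rigid.edge_high,
    edge_dilate = config$rigid.edge_dilate, lpm_k = config$rigid.lpm_k,
    lpm_tau = config$rigid.lpm_tau, lpm_passes = config$rigid.lpm_passes,
    min_matches = config$rigid.min_matches)
  fp <- flow_params(
    levels = if (is.na(config$flow.levels)) NULL else config$flow.levels,
    outer_iters = config$flow.outer_iters,
    inner_iters = config$flow.inner_iters,
    lambda = config$flow.lambda, min_size = config$flow.min_size)
  el <- register_stack_elastic(
    rg$stack, gaussian_kernel_1d(config$elastic.radius, config$elastic.sigma_z),
    flow_params = fp, sweeps = config$elastic.sweeps)
  list(stack = el$stack, transforms = rg$transforms, fields = el$fields)
}
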