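# Analytic rendering -----------------------------------------------------
#
# Every structure is an ideal shape with Gaussian edge softness; convolution
# with the Gaussian PSF is carried out in closed form, so the noiseless
# image is exact (no raster convolution):
#   * box (length 2a x thickness 2b, rotated): amplitude *
#       [Phi((u+a)/s_u) - Phi((u-a)/s_u)] * [Phi((v+b)/s_v) - Phi((v-b)/s_v)]
#     with s^2 = softness^2 + sigma_psf^2 in the box frame (u along axis).
#   * Gaussian cloud sigma_c: amplitude * sigma_c^2/(sigma_c^2 + sigma_p^2) *
#       exp(-r^2 / (2 (sigma_c^2 + sigma_p^2))).
#   * disk radius R (somata): amplitude * Phi((R - r)/s), the 1-D edge
#     profile, accurate for R >> s.

EDGE_SOFTNESS_NM <- 10

edge_box <- function(t, half, s) {
  stats::pnorm((t + half) / s) - stats::pnorm((t - half) / s)
}

# evaluate one structure into `img` (in place, returned), physical nm coords
add_structure <- function(img, pixel_size_nm, st, sigma_psf) {
  nr <- nrow(img); nc <- ncol(img)
  if (st$amplitude <= 0) return(img)
  extent <- switch(st$type,
    box = sqrt(st$half_u^2 + st$half_v^2) +
      5 * sqrt(EDGE_SOFTNESS_NM^2 + sigma_psf^2),
    gauss = 5 * sqrt(st$sigma^2 + sigma_psf^2),
    disk = st$radius + 5 * sqrt(EDGE_SOFTNESS_NM^2 + sigma_psf^2),
    annulus = st$radius_outer + 5 * sqrt(EDGE_SOFTNESS_NM^2 + sigma_psf^2))
  c0 <- max(1L, floor((st$center[1] - extent) / pixel_size_nm + 0.5))
  c1 <- min(nc, ceiling((st$center[1] + extent) / pixel_size_nm + 0.5))
  r0 <- max(1L, floor((st$center[2] - extent) / pixel_size_nm + 0.5))
  r1 <- min(nr, ceiling((st$center[2] + extent) / pixel_size_nm + 0.5))
  if (c0 > c1 || r0 > r1) return(img)
  xs <- ((c0:c1) - 0.5) * pixel_size_nm - st$center[1]
  ys <- ((r0:r1) - 0.5) * pixel_size_nm - st$center[2]
  dx <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  dy <- matrix(ys, nrow = length(ys), ncol = length(xs))
  val <- switch(st$type,
    box = {
      u <- dx * cos(st$angle) + dy * sin(st$angle)
      v <- -dx * sin(st$angle) + dy * cos(st$angle)
      s <- sqrt(EDGE_SOFTNESS_NM^2 + sigma_psf^2)
      st$amplitude * edge_box(u, st$half_u, s) * edge_box(v, st$half_v, s)
    },
    gauss = {
      s2 <- st$sigma^2 + sigma_psf^2
      st$amplitude * (st$sigma^2 / s2) * exp(-(dx^2 + dy^2) / (2 * s2))
    },
    disk = {
      r <- sqrt(dx^2 + dy^2)
      s <- sqrt(EDGE_SOFTNESS_NM^2 + sigma_psf^2)
      st$amplitude * stats::pnorm((st$radius - r) / s)
    },
    annulus = {
      r <- sqrt(dx^2 + dy^2)
      s <- sqrt(EDGE_SOFTNESS_NM^2 + sigma_psf^2)
      st$amplitude * (stats::pnorm((st$radius_outer - r) / s) -
                        stats::pnorm((st$radius_inner - r) / s))
    })
  img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + val
  img
}

# trans-synaptic unit normal of a synapse; negative multiples lie on the
# presynaptic (vesicle cloud) side
synapse_normal <- function(s) c(-sin(s$axis_angle_rad), cos(s$axis_angle_rad))

# structures contributed by one synapse, per channel role
synapse_structures <- function(s) {
  n <- synapse_normal(s)
  list(
    psd95 = list(type = "box", center = s$center_nm,
                 angle = s$axis_angle_rad,
                 half_u = s$psd_length_nm / 2,
                 half_v = s$psd_thickness_nm / 2,
                 amplitude = s$psd_amplitude),
    channel_of_interest = list(type = "box",
                               center = s$center_nm + s$channel_offset_nm * n,
                               angle = s$axis_angle_rad,
                               half_u = s$channel_length_nm / 2,
                               half_v = s$channel_thickness_nm / 2,
                               amplitude = s$channel_amplitude),
    synapsin = list(type = "gauss",
                    center = s$center_nm - s$vesicle_cloud_offset_nm * n,
                    sigma = s$vesicle_cloud_radius_nm,
                    amplitude = s$synapsin_amplitude)
  )
}

soma_structures <- function(cell) {
  ctr <- c(cell$center_x_nm, cell$center_y_nm)
  list(
    neun = list(type = "disk", center = ctr, radius = cell$soma_radius_nm,
                amplitude = cell$neun_amplitude),
    nucleus = list(type = "disk", center = ctr,
                   radius = cell$nucleus_radius_nm,
                   amplitude = cell$nucleus_amplitude),
    channel_of_interest = list(type = "annulus", center = ctr,
                               radius_outer = cell$soma_radius_nm,
                               radius_inner = cell$nucleus_radius_nm,
                               amplitude = cell$ha_amplitude)
  )
}

#' Render a synthetic scene into a multi-channel image stack
#'
#' Each channel is the configured background plus the sum of the scene's
#' structure kernels convolved (analytically) with that channel's Gaussian
#' PSF, optionally followed by per-pixel Poisson sampling: counts are drawn
#' as `Poisson(photon_scale * expectation)` and divided back by
#' `photon_scale`, so the noiseless render is the expectation of the noisy
#' one. Sampling is seeded per channel, so a fixed seed reproduces pixels
#' bit for bit.
#'
#' @param scene A `scene_truth` from [build_scene()] or a `soma_scene` from
#'   [build_soma_scene()].
#' @param noise `"none"` or `"poisson"`.
#' @param seed Seed for the Poisson draw; defaults to the scene seed.
#' @return An [image_stack()].
#' @examples
#' sc <- build_scene(optics_spec(field_px = c(256, 256)), 1, seed = 1)
#' stk <- render_stack(sc, noise = "none")
#' @export
render_stack <- function(scene, noise = c("none", "poisson"), seed = NULL) {
  noise <- match.arg(noise)
  optics <- scene$optics
  seed <- seed %||% scene$seed

  structures <- if (inherits(scene, "scene_truth")) {
    purrr::map(scene$synapses, synapse_structures)
  } else if (inherits(scene, "soma_scene")) {
    purrr::map(seq_len(nrow(scene$cells)),
               function(i) soma_structures(scene$cells[i, ]))
  } else {
    abort("`scene` must be a scene_truth or soma_scene.")
  }

  roles <- names(optics$channels)
  pixels <- lapply(seq_along(roles), function(k) {
    role <- roles[k]
    modality <- optics$channels[[role]]
    sigma_psf <- fwhm_to_sigma(optics$psf_fwhm_nm[[modality]])
    img <- matrix(optics$background_counts,
                  optics$field_px[1], optics$field_px[2])
    for (sts in structures) {
      if (!is.null(sts[[role]]))
        img <- add_structure(img, optics$pixel_size_nm, sts[[role]], sigma_psf)
    }
    if (noise == "poisson") {
      set.seed(child_seed(seed, k, salt = 77L))
      lambda <- optics$photon_scale * img
      img <- matrix(stats::rpois(length(img), lambda) / optics$photon_scale,
                    nrow(img), ncol(img))
    }
    img
  })
  names(pixels) <- roles
  image_stack(pixels, optics$channels, optics$pixel_size_nm)
}
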