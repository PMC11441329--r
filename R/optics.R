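#' Imaging optics for the synthetic microscope
#'
#' Describes the sampling and point-spread properties used to render
#' synthetic fields: pixel size, field size, the Gaussian PSF full width at
#' half maximum per modality, the modality of each channel, a uniform
#' background, and a photon scale converting image units to expected photon
#' counts for Poisson noise.
#'
#' Defaults reproduce the synapse-imaging regime used throughout: a
#' 58.14 x 58.14 um^2 field at 4096 x 4096 px (14.194 nm pixels), STED
#' acquisition of the channel of interest and PSD-95, confocal acquisition
#' of synapsin.
#'
#' @param pixel_size_nm Pixel side length in nanometers.
#' @param field_px Integer vector `c(height, width)` in pixels.
#' @param channels Named character vector mapping channel roles to
#'   modalities (`"sted"` or `"confocal"`). Roles must be unique and drawn
#'   from `channel_of_interest`, `psd95`, `synapsin`, `neun`, `nucleus`.
#' @param psf_fwhm_nm Named numeric vector of PSF FWHM (nm) per modality.
#'   The STED FWHM must not exceed the confocal FWHM.
#' @param background_counts Expected background photon count per pixel
#'   (at `photon_scale = 1`). Non-negative.
#' @param photon_scale Multiplier from image units to expected photons.
#'
#' @return An object of class `optics_spec`.
#' @examples
#' optics_spec(field_px = c(512, 512))
#' @export
optics_spec <- function(pixel_size_nm = 14.194,
                        field_px = c(4096L, 4096L),
                        channels = c(channel_of_interest = "sted",
                                     psd95 = "sted",
                                     synapsin = "confocal"),
                        psf_fwhm_nm = c(confocal = 250, sted = 60),
                        background_counts = 5,
                        photon_scale = 1) {
  stopifnot_scalar_number(pixel_size_nm, "pixel_size_nm", positive = TRUE)
  stopifnot_scalar_number(background_counts, "background_counts")
  stopifnot_scalar_number(photon_scale, "photon_scale", positive = TRUE)
  if (background_counts < 0) abort("`background_counts` must be >= 0.")
  if (length(field_px) != 2L || any(field_px < 1))
    abort("`field_px` must be two positive integers (height, width).")
  known <- c("channel_of_interest", "psd95", "synapsin", "neun", "nucleus")
  if (is.null(names(channels)) || anyDuplicated(names(channels)) ||
      !all(names(channels) %in% known))
    abort("`channels` must map unique known roles to modalities.")
  if (!all(channels %in% c("confocal", "sted")))
    abort("channel modalities must be 'confocal' or 'sted'.")
  if (!all(channels %in% names(psf_fwhm_nm)))
    abort("every modality in `channels` needs an entry in `psf_fwhm_nm`.")
  if (any(psf_fwhm_nm <= 0)) abort("all PSF FWHM must be > 0.")
  if (all(c("sted", "confocal") %in% names(psf_fwhm_nm)) &&
      psf_fwhm_nm[["sted"]] > psf_fwhm_nm[["confocal"]])
    abort("STED PSF FWHM must not exceed the confocal PSF FWHM.")
  structure(
    list(pixel_size_nm = pixel_size_nm,
         field_px = as.integer(field_px),
         channels = channels,
         psf_fwhm_nm = psf_fwhm_nm,
         background_counts = background_counts,
         photon_scale = photon_scale),
    class = "optics_spec"
  )
}

#' @export
print.optics_spec <- function(x, ...) {
  cat(sprintf("<optics_spec> %d x %d px, %.3f nm/px\n",
              x$field_px[1], x$field_px[2], x$pixel_size_nm))
  for (role in names(x$channels)) {
    cat(sprintf("  %s: %s (PSF FWHM %.0f nm)\n", role, x$channels[[role]],
                x$psf_fwhm_nm[[x$channels[[role]]]]))
  }
  cat(sprintf("  background %.2f counts, photon scale %.2f\n",
              x$background_counts, x$photon_scale))
  invisible(x)
}

# field extent in nm, (height, width)
field_nm <- function(optics) optics$field_px * optics$pixel_size_nm

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Derive the pixel size from the acquired field extent
#'
#' Imaging metadata often records the physical field of view and the pixel
#' grid rather than the pixel pitch; the pitch follows as extent / pixels.
#' A 58.14 um field sampled at 4096 px gives 14.194 nm pixels.
#'
#' @param field_um Field extent along one axis, in micrometers.
#' @param field_px Number of pixels along the same axis.
#' @return Pixel side length in nanometers.
#' @examples
#' pixel_size_from_field(58.14, 4096)
#' @export
pixel_size_from_field <- function(field_um, field_px) {
  stopifnot_scalar_number(field_um, "field_um", positive = TRUE)
  stopifnot_scalar_number(field_px, "field_px", positive = TRUE)
  field_um * 1000 / field_px
}
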