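#' Multi-channel image stack
#'
#' A light container for co-registered 2-D channels: a named list of
#' matrices (role -> pixels), per-channel modality, and the pixel size in
#' nanometers. Pixel `[i, j]` has its center at physical coordinates
#' `((j - 0.5) * pixel_size_nm, (i - 0.5) * pixel_size_nm)` with x rightward
#' and y downward.
#'
#' @param pixels Named list of numeric matrices of identical dimensions;
#'   names are channel roles (unique, from `channel_of_interest`, `psd95`,
#'   `synapsin`, `neun`, `nucleus`).
#' @param channel_modalities Named character vector role -> `"confocal"` or
#'   `"sted"`.
#' @param pixel_size_nm Pixel side (nm), > 0.
#' @return An `image_stack` object.
#' @export
image_stack <- function(pixels, channel_modalities, pixel_size_nm) {
  if (!is.list(pixels) || length(pixels) == 0L || is.null(names(pixels)))
    abort("`pixels` must be a non-empty named list of matrices.")
  known <- c("channel_of_interest", "psd95", "synapsin", "neun", "nucleus")
  if (anyDuplicated(names(pixels)) || !all(names(pixels) %in% known))
    abort("channel roles must be unique and known.")
  dims <- vapply(pixels, dim, integer(2))
  if (!all(dims == dims[, 1]))
    abort("all channels must have identical dimensions.")
  if (any(vapply(pixels, function(m) any(!is.finite(m)) || any(m < 0),
                 logical(1))))
    abort("pixel values must be finite and non-negative.")
  stopifnot_scalar_number(pixel_size_nm, "pixel_size_nm", positive = TRUE)
  if (!all(names(pixels) %in% names(channel_modalities)))
    abort("every channel needs a modality.")
  if (!all(channel_modalities %in% c("confocal", "sted")))
    abort("modalities must be 'confocal' or 'sted'.")
  structure(
    list(pixels = pixels,
         channel_modalities = channel_modalities[names(pixels)],
         pixel_size_nm = pixel_size_nm),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pixels[[1]])
  cat(sprintf("<image_stack> %d x %d px, %.3f nm/px, channels: %s\n",
              d[1], d[2], x$pixel_size_nm,
              paste(names(x$pixels), collapse = ", ")))
  invisible(x)
}

#' @rdname image_stack
#' @param stack An `image_stack`.
#' @param role Channel role to extract.
#' @return `get_channel()` returns the pixel matrix for one role.
#' @export
get_channel <- function(stack, role) {
  stopifnot(inherits(stack, "image_stack"))
  if (!role %in% names(stack$pixels))
    abort(sprintf("channel role '%s' not present (have: %s).",
                  role, paste(names(stack$pixels), collapse = ", ")))
  stack$pixels[[role]]
}

#' @rdname image_stack
#' @export
channel_roles <- function(stack) names(stack$pixels)
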