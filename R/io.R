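# Image, annotation and table I/O ----------------------------------------

#' Write an image stack as multi-page TIFF plus sidecar JSON
#'
#' One TIFF page per channel. TIFF samples are stored normalized to `[0, 1]`
#' with the scale factor recorded in the sidecar JSON (`<path>.json`)
#' together with the pixel size, channel roles and modalities. Integer data
#' with maximum below 65536 is stored as 16-bit and round-trips exactly;
#' other data is stored as 32-bit float.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  if (length(stack$pixels) == 0L) abort("stack has no channels.")
  vals <- unlist(stack$pixels, use.names = FALSE)
  vmax <- max(vals, 1)
  integral <- all(vals == round(vals)) && vmax <= 65535
  scale <- if (integral) 65535 else vmax
  bps <- if (integral) 16L else 32L
  pages <- lapply(stack$pixels, function(m) m / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = bps, compression = "none")
  sidecar <- list(
    pixel_size_nm = stack$pixel_size_nm,
    channel_roles = as.list(names(stack$pixels)),
    channel_modalities = as.list(unname(stack$channel_modalities)),
    intensity_scale = scale,
    bits_per_sample = bps
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# resolve pixel size with precedence sidecar > TIFF tags > config override;
# a sidecar/tag conflict is an error, silence is an error
resolve_pixel_size <- function(sidecar, tiff_attr, pixel_size_nm) {
  from_sidecar <- sidecar$pixel_size_nm
  if (is.null(from_sidecar) && !is.null(sidecar$field_um) &&
      !is.null(sidecar$field_px)) {
    from_sidecar <- pixel_size_from_field(sidecar$field_um,
                                          sidecar$field_px)
  }
  from_tags <- NULL
  if (!is.null(tiff_attr$x.resolution) && tiff_attr$x.resolution > 0) {
    unit_nm <- switch(tiff_attr$resolution.unit %||% "inch",
                      inch = 25.4e6, cm = 1e7, NULL)
    if (!is.null(unit_nm)) from_tags <- unit_nm / tiff_attr$x.resolution
  }
  if (!is.null(from_sidecar) && !is.null(from_tags) &&
      abs(from_sidecar - from_tags) > 1e-6 * from_sidecar)
    abort("pixel size conflict between sidecar JSON and TIFF tags.")
  out <- from_sidecar %||% from_tags %||% pixel_size_nm
  if (is.null(out))
    abort(paste("pixel size not found in sidecar or TIFF tags and no",
                "`pixel_size_nm` override given."))
  out
}

#' Read an image stack written by [write_stack()]
#'
#' Pixel size is resolved in the order sidecar JSON > TIFF resolution tags >
#' `pixel_size_nm` override; a conflict between sidecar and tags, or no
#' source at all, is an error — the pixel pitch calibrates every nanometer
#' quantity downstream and is never guessed. The sidecar may state the pixel
#' size directly or as the acquired field extent (`field_um`, `field_px`),
#' from which the pitch is derived.
#'
#' @param path TIFF path; sidecar `<path>.json` is read if present.
#' @param channel_roles,channel_modalities Overrides when no sidecar exists.
#' @param pixel_size_nm Override used only if neither sidecar nor TIFF tags
#'   carry a pixel size.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, channel_roles = NULL, channel_modalities = NULL,
                       pixel_size_nm = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  sidecar_path <- paste0(path, ".json")
  sidecar <- if (file.exists(sidecar_path)) {
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  } else list()
  roles <- channel_roles %||% unlist(sidecar$channel_roles)
  if (is.null(roles)) abort("channel roles not found in sidecar or call.")
  if (length(roles) != length(pages))
    abort(sprintf("file has %d channels but %d roles declared.",
                  length(pages), length(roles)))
  modalities <- channel_modalities %||% unlist(sidecar$channel_modalities)
  if (is.null(modalities)) abort("channel modalities not found.")
  psz <- resolve_pixel_size(sidecar, attributes(pages[[1]]), pixel_size_nm)
  scale <- sidecar$intensity_scale %||% 1
  pixels <- lapply(pages, function(p) {
    m <- p * scale
    if (isTRUE((sidecar$bits_per_sample %||% 0) == 16)) m <- round(m)
    attributes(m) <- list(dim = dim(p))
    m
  })
  names(pixels) <- roles
  names(modalities) <- roles
  image_stack(pixels, modalities, psz)
}

#' Read and write side-view synapse annotations
#'
#' Annotations record manually (or automatically) selected side-view
#' synapses: an anchor point on the PSD structure, the orientation of the
#' PSD elongation axis, and an accepted flag. CSV and JSON are supported
#' (chosen by file extension); unknown columns are preserved.
#'
#' @param annotations A data frame with columns `synapse_id`, `anchor_x_nm`,
#'   `anchor_y_nm`, `axis_angle_rad`, `accepted`.
#' @param path File path ending in `.csv` or `.json`.
#' @return `read_annotations()` returns a tibble (possibly empty);
#'   `write_annotations()` returns `path` invisibly.
#' @export
write_annotations <- function(annotations, path) {
  annotations <- validate_annotations(annotations)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(annotations, path, digits = NA)
  } else {
    readr::write_csv(annotations, path)
  }
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  required <- c("synapse_id", "anchor_x_nm", "anchor_y_nm",
                "axis_angle_rad", "accepted")
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  if (nrow(df) == 0L && length(setdiff(required, names(df))) > 0) {
    return(tibble(synapse_id = integer(), anchor_x_nm = double(),
                  anchor_y_nm = double(), axis_angle_rad = double(),
                  accepted = logical()))
  }
  validate_annotations(df)
}

validate_annotations <- function(df) {
  required <- c("synapse_id", "anchor_x_nm", "anchor_y_nm",
                "axis_angle_rad", "accepted")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    abort(sprintf("annotation table lacks required column(s): %s",
                  paste(missing, collapse = ", ")))
  if (nrow(df) > 0 &&
      (any(df$axis_angle_rad < 0) || any(df$axis_angle_rad >= pi)))
    abort("`axis_angle_rad` must lie in [0, pi).")
  as_tibble(df)
}

#' Write / read a scene's ground-truth table
#'
#' @param truth A tibble from [truth_table()].
#' @param path CSV path.
#' @return The table (read) or `path` invisibly (write).
#' @export
write_truth_table <- function(truth, path) {
  readr::write_csv(truth, path)
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    synapse_id = readr::col_integer(),
                    view = readr::col_character(),
                    .default = readr::col_double()))
}

# results CSV with the run's config hash on a comment line
write_result_csv <- function(df, path, config_hash = NULL) {
  if (!is.null(config_hash)) {
    con <- file(path, "wb")
    writeLines(sprintf("# config_hash: %s", config_hash), con)
    close(con)
    readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_csv(df, path)
  }
  invisible(path)
}

#' Read a results CSV written by [run_experiment()]
#'
#' @param path CSV path (a leading `# config_hash:` comment line is skipped).
#' @return A tibble.
#' @export
read_result_csv <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}
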