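# Somatic donut-ROI quantification ---------------------------------------

#' Rasterize a polygon onto the pixel grid
#'
#' A pixel belongs to the polygon when its center lies inside under the
#' even-odd rule (standard ray-crossing test).
#'
#' @param poly_nm Two-column matrix of vertices `(x, y)` in nm (closed
#'   implicitly).
#' @param shape Integer `c(nrow, ncol)` of the target mask.
#' @param pixel_size_nm Pixel side (nm).
#' @return Logical matrix.
#' @export
rasterize_polygon <- function(poly_nm, shape, pixel_size_nm) {
  poly_nm <- as.matrix(poly_nm)
  if (ncol(poly_nm) != 2L || nrow(poly_nm) < 3L)
    abort("`poly_nm` must be an (n >= 3) x 2 matrix of vertices.")
  nr <- shape[1]; nc <- shape[2]
  mask <- matrix(FALSE, nr, nc)
  # restrict to the polygon's bounding box
  c0 <- max(1L, floor(min(poly_nm[, 1]) / pixel_size_nm + 0.5))
  c1 <- min(nc, ceiling(max(poly_nm[, 1]) / pixel_size_nm + 0.5))
  r0 <- max(1L, floor(min(poly_nm[, 2]) / pixel_size_nm + 0.5))
  r1 <- min(nr, ceiling(max(poly_nm[, 2]) / pixel_size_nm + 0.5))
  if (c0 > c1 || r0 > r1) return(mask)
  xs <- ((c0:c1) - 0.5) * pixel_size_nm
  ys <- ((r0:r1) - 0.5) * pixel_size_nm
  px <- poly_nm[, 1]; py <- poly_nm[, 2]
  nv <- nrow(poly_nm)
  jx <- px[c(nv, seq_len(nv - 1L))]; jy <- py[c(nv, seq_len(nv - 1L))]
  inside <- matrix(FALSE, length(ys), length(xs))
  X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  Y <- matrix(ys, length(ys), length(xs))
  for (v in seq_len(nv)) {
    crosses <- (py[v] > Y) != (jy[v] > Y)
    xint <- (jx[v] - px[v]) * (Y - py[v]) / (jy[v] - py[v]) + px[v]
    inside <- xor(inside, crosses & (X < xint))
  }
  mask[r0:r1, c0:c1] <- inside
  mask
}

as_region_mask <- function(region, shape, pixel_size_nm) {
  if (is.matrix(region) && (is.logical(region) ||
                            all(region %in% c(0, 1)))) {
    m <- matrix(as.logical(region), nrow(region), ncol(region))
    if (!all(dim(m) == shape)) abort("region mask shape mismatch.")
    return(m)
  }
  rasterize_polygon(region, shape, pixel_size_nm)
}

#' Build a somatic donut mask
#'
#' The somatic ROI is the soma region (outer edge of the NeuN profile,
#' neurites excluded) minus the nucleus region (EGFP), with the nucleus
#' clipped to the soma — so donut + (soma AND nucleus) = soma, exactly.
#'
#' @param soma,nucleus Polygons (n x 2 matrices, nm) or logical masks.
#' @param shape Mask dimensions `c(nrow, ncol)`.
#' @param pixel_size_nm Pixel side (nm).
#' @return Logical donut mask; an empty donut (nucleus covering the whole
#'   soma) is a degenerate-ROI error.
#' @export
build_donut_mask <- function(soma, nucleus, shape, pixel_size_nm) {
  soma_m <- as_region_mask(soma, shape, pixel_size_nm)
  nuc_m <- as_region_mask(nucleus, shape, pixel_size_nm)
  donut <- soma_m & !(soma_m & nuc_m)
  if (!any(donut))
    abort("degenerate somatic ROI: donut is empty.",
          class = "synquant_degenerate_roi")
  donut
}

#' Measure mean somatic intensity within donut ROIs
#'
#' @param stack An [image_stack()].
#' @param donuts A single logical mask, or a named list of masks (one per
#'   cell).
#' @param channel Channel to measure (default `"channel_of_interest"`, the
#'   HA channel).
#' @return Tibble `(cell_id, n_pixels, mean_intensity)` — one row per cell,
#'   the unit of analysis for somatic statistics.
#' @export
measure_soma <- function(stack, donuts, channel = "channel_of_interest") {
  img <- get_channel(stack, channel)
  if (is.matrix(donuts)) donuts <- list(cell_1 = donuts)
  if (is.null(names(donuts)))
    names(donuts) <- paste0("cell_", seq_along(donuts))
  purrr::imap(donuts, function(mask, id) {
    if (!all(dim(mask) == dim(img))) abort("donut mask shape mismatch.")
    tibble(cell_id = id, n_pixels = sum(mask),
           mean_intensity = mean(img[mask]))
  }) |> purrr::list_rbind()
}

#' Automatically delineate somatic donuts on a synthetic field
#'
#' Surrogate for manual donut drawing, for testing against synthetic ground
#' truth: the NeuN channel is Otsu-segmented and hole-filled to give soma
#' candidates; within each soma the nucleus channel is Otsu-segmented, and
#' the donut is soma minus nucleus.
#'
#' @param stack An [image_stack()] with `neun` and `nucleus` channels.
#' @param min_area_um2 Minimum soma area (default 20 um^2).
#' @return Named list of donut masks, in label order.
#' @export
detect_soma_donuts <- function(stack, min_area_um2 = 20) {
  neun <- segment_channel(stack, "neun")
  filled <- EBImage::fillHull(matrix(as.numeric(neun), nrow(neun))) > 0
  labels <- label_components(structure(
    filled, pixel_size_nm = stack$pixel_size_nm), connectivity = 8)
  somata <- filter_min_area(labels, min_area_um2 = min_area_um2,
                            pixel_size_nm = stack$pixel_size_nm)
  if (nrow(somata) == 0L) return(list())
  nuc_img <- get_channel(stack, "nucleus")
  nuc_mask <- nuc_img > otsu_threshold(nuc_img)
  lab <- attr(somata, "labels")
  out <- lapply(somata$label, function(lb) {
    soma_m <- lab == lb
    build_donut_mask(soma_m, nuc_mask & soma_m, dim(soma_m),
                     stack$pixel_size_nm)
  })
  names(out) <- paste0("cell_", seq_along(out))
  out
}

#' Read somatic annotations (polygons) from JSON
#'
#' Expected structure: an array of objects with `cell_id`, `soma` and
#' `nucleus`, each polygon an array of `[x, y]` vertices in nm.
#'
#' @param path JSON path.
#' @return Named list of `list(soma =, nucleus =)` vertex matrices.
#' @export
read_soma_annotations <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(raw) == 0L) return(list())
  cells <- purrr::map(seq_len(nrow(raw)), function(i) {
    list(soma = as.matrix(raw$soma[[i]]),
         nucleus = as.matrix(raw$nucleus[[i]]))
  })
  names(cells) <- raw$cell_id
  cells
}

#' @rdname read_soma_annotations
#' @param cells Named list of `list(soma =, nucleus =)` vertex matrices.
#' @export
write_soma_annotations <- function(cells, path) {
  objs <- purrr::imap(cells, function(cl, id) {
    list(cell_id = id,
         soma = unname(as.matrix(cl$soma)),
         nucleus = unname(as.matrix(cl$nucleus)))
  })
  jsonlite::write_json(unname(objs), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
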