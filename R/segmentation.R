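# Otsu segmentation, connected components, ROI measurement ---------------

#' Otsu threshold of an image
#'
#' Builds a 256-bin histogram spanning `[min, max]` of the data and returns
#' the bin edge maximizing the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2`, computed from exact per-bin intensity sums.
#' Pixels strictly above the threshold are foreground. Ties are broken
#' toward the smallest threshold.
#'
#' @param x Numeric matrix or vector with at least two distinct values.
#' @param n_bins Number of histogram bins (default 256).
#' @return The threshold (scalar), with attribute `"n_bins"`.
#' @examples
#' otsu_threshold(c(rep(10, 50), rep(200, 50)))
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  if (length(v) == 0L) abort("no finite pixel values.")
  lo <- min(v); hi <- max(v)
  if (lo == hi) abort("degenerate image: all pixel values identical.")
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  bin <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
  cnt <- tabulate(bin, nbins = n_bins)
  sums <- unname(rowsum(v, bin))
  s_full <- numeric(n_bins); s_full[sort(unique(bin))] <- sums
  w0 <- cumsum(cnt)[-n_bins]
  s0 <- cumsum(s_full)[-n_bins]
  n <- length(v); stot <- sum(v)
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, n_bins - 1L)
  mu0 <- s0[valid] / w0[valid]
  mu1 <- (stot - s0[valid]) / w1[valid]
  bcv[valid] <- (w0[valid] / n) * (w1[valid] / n) * (mu0 - mu1)^2
  k <- which.max(bcv)  # first maximum -> smallest threshold
  structure(edges[k + 1L], n_bins = n_bins)
}

# Otsu re-applied to the foreground until it occupies at most
# `max_foreground` of the image. Plain Otsu splits the background when the
# true foreground is a tiny fraction of the pixels (sparse PSD-95 bars in a
# large field); iterating climbs out of the background mode. Used by the
# automated side-view detector; ROI segmentation keeps the single pass.
otsu_threshold_iterated <- function(x, max_foreground = 0.05,
                                    max_iter = 20L) {
  thr <- otsu_threshold(x)
  it <- 1L
  while (mean(x > thr) > max_foreground && it < max_iter) {
    sub <- x[x > thr]
    if (length(unique(sub)) < 2L) break
    thr <- otsu_threshold(sub)
    it <- it + 1L
  }
  thr
}

#' Segment one channel of a stack by Otsu thresholding
#'
#' @param stack An [image_stack()].
#' @param role Channel role to segment (default `"synapsin"`, the
#'   presynaptic marker used to define synaptic ROIs).
#' @return A `segmentation_mask`: logical matrix with attributes
#'   `threshold`, `role` and `pixel_size_nm`.
#' @export
segment_channel <- function(stack, role = "synapsin") {
  img <- get_channel(stack, role)
  thr <- otsu_threshold(img)
  structure(img > thr,
            threshold = as.numeric(thr), role = role,
            pixel_size_nm = stack$pixel_size_nm,
            class = c("segmentation_mask", "matrix"))
}

#' Label connected components of a binary mask
#'
#' Maximal connected foreground sets under 4- or 8-connectivity. Labels are
#' assigned deterministically in column-major scan order of each component's
#' first pixel.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param connectivity 4 or 8 (default 8: diagonal pixels are contiguous).
#' @return Integer matrix of labels (0 = background) with attribute
#'   `pixel_size_nm` when the input carried one.
#' @export
label_components <- function(mask, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) abort("`connectivity` must be 4 or 8.")
  m <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  idx <- which(m)
  if (length(idx) > 0L) {
    vid <- integer(nr * nc)
    vid[idx] <- seq_along(idx)
    shifts <- list(c(1L, 0L), c(0L, 1L))
    if (connectivity == 8) shifts <- c(shifts, list(c(1L, 1L), c(-1L, 1L)))
    edges <- lapply(shifts, function(s) {
      r <- ((idx - 1L) %% nr) + 1L
      c <- ((idx - 1L) %/% nr) + 1L
      r2 <- r + s[1]; c2 <- c + s[2]
      ok <- r2 >= 1L & r2 <= nr & c2 <= nc
      j <- (c2[ok] - 1L) * nr + r2[ok]
      ok2 <- m[j]
      cbind(vid[idx[ok][ok2]], vid[j[ok2]])
    })
    edges <- do.call(rbind, edges)
    g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
    if (!is.null(edges) && nrow(edges) > 0)
      g <- igraph::add_edges(g, t(edges))
    comp <- igraph::components(g)$membership
    # relabel by first appearance in column-major order
    relab <- integer(max(comp))
    first <- !duplicated(comp)
    relab[comp[first]] <- seq_len(sum(first))
    lab[idx] <- relab[comp]
  }
  structure(lab, pixel_size_nm = attr(mask, "pixel_size_nm"))
}

#' Filter labeled components by minimum area
#'
#' Retains components whose area `pixel_count * (pixel_size_nm / 1000)^2`
#' is at least `min_area_um2` (boundary inclusive: exactly 0.05 um^2 is
#' kept). At the 14.194 nm pixel pitch the default floor corresponds to a
#' minimum of 249 pixels.
#'
#' @param labels Integer label matrix from [label_components()].
#' @param min_area_um2 Minimum ROI area (default 0.05).
#' @param pixel_size_nm Pixel side (nm); taken from the label matrix
#'   attribute when omitted.
#' @return A `roi_table` tibble (`label`, `pixel_count`, `area_um2`) whose
#'   `"labels"` attribute holds the label matrix restricted to retained ROIs.
#' @export
filter_min_area <- function(labels, min_area_um2 = 0.05,
                            pixel_size_nm = attr(labels, "pixel_size_nm")) {
  if (is.null(pixel_size_nm)) abort("`pixel_size_nm` is required.")
  stopifnot_scalar_number(pixel_size_nm, "pixel_size_nm", positive = TRUE)
  if (min_area_um2 < 0) abort("`min_area_um2` must be >= 0.")
  px_area_um2 <- (pixel_size_nm / 1000)^2
  counts <- tabulate(labels[labels > 0L])
  tbl <- tibble(label = seq_along(counts), pixel_count = counts,
                area_um2 = counts * px_area_um2) |>
    filter(.data$pixel_count > 0, .data$area_um2 >= min_area_um2)
  kept <- matrix(ifelse(labels %in% tbl$label, labels, 0L),
                 nrow(labels), ncol(labels))
  structure(tbl,
            labels = structure(kept, pixel_size_nm = pixel_size_nm),
            pixel_size_nm = pixel_size_nm,
            class = c("roi_table", class(tbl)))
}

#' Measure per-ROI mean intensities
#'
#' Adds, for each requested channel, the mean raw intensity over exactly the
#' ROI's pixels (no background subtraction).
#'
#' @param rois A `roi_table` from [filter_min_area()].
#' @param stack The [image_stack()] the mask was derived from.
#' @param channels Channel roles to measure.
#' @return The `roi_table` with one `mean_<role>` column per channel.
#' @export
measure_rois <- function(rois, stack, channels = "channel_of_interest") {
  stopifnot(inherits(rois, "roi_table"))
  labels <- attr(rois, "labels")
  out <- rois
  for (role in channels) {
    img <- get_channel(stack, role)  # errors if missing
    if (nrow(out) == 0L) {
      out[[paste0("mean_", role)]] <- double()
      next
    }
    fg <- labels > 0L
    means <- tapply(img[fg], labels[fg], mean)
    out[[paste0("mean_", role)]] <-
      as.numeric(means[as.character(out$label)])
  }
  structure(out, labels = labels,
            pixel_size_nm = attr(rois, "pixel_size_nm"),
            class = class(rois))
}

#' Per-image summary of ROI measurements
#'
#' The unit of analysis for confocal ROI quantification is the image: the
#' unweighted mean over ROI means (not pixel-weighted) plus the ROI count.
#'
#' @param rois A measured `roi_table`.
#' @return One-row tibble: `n_rois` and `mean_<role>` per measured channel.
#'   With zero ROIs the means are `NA` and a warning is raised.
#' @export
image_summary <- function(rois) {
  mcols <- grep("^mean_", names(rois), value = TRUE)
  if (length(mcols) == 0L) abort("`rois` has no measured channels.")
  if (nrow(rois) == 0L) {
    warn("image has no ROIs; summary undefined.")
    out <- tibble(n_rois = 0L)
    for (mc in mcols) out[[mc]] <- NA_real_
    return(out)
  }
  out <- tibble(n_rois = nrow(rois))
  for (mc in mcols) out[[mc]] <- mean(rois[[mc]])
  out
}
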