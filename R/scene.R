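#' Ground truth for one simulated synapse
#'
#' A side-view synapse is modeled as an elongated PSD-95 bar, a presynaptic
#' channel band displaced from the PSD center along the trans-synaptic axis,
#' and an isotropic synapsin (vesicle cloud) Gaussian on the presynaptic
#' side. Geometry is continuous, in nanometers, with the image origin at the
#' top-left corner, x rightward and y downward. The trans-synaptic axis is
#' the unit normal of the PSD elongation axis; negative offsets lie on the
#' presynaptic (vesicle cloud) side.
#'
#' @param center_nm Numeric `c(x, y)` of the PSD center, in nm.
#' @param axis_angle_rad Orientation of the PSD elongation axis, in `[0, pi)`.
#' @param psd_length_nm,psd_thickness_nm PSD bar dimensions (nm).
#' @param channel_offset_nm Signed distance of the channel band from the PSD
#'   center along the trans-synaptic axis; negative = presynaptic side.
#' @param channel_length_nm,channel_thickness_nm Channel band dimensions (nm).
#' @param channel_amplitude Peak channel intensity (0 = not expressed /
#'   not targeted).
#' @param vesicle_cloud_radius_nm Gaussian sigma of the vesicle cloud (nm).
#' @param vesicle_cloud_offset_nm Distance of the cloud center from the PSD
#'   center, placed on the presynaptic side (nm, positive).
#' @param psd_amplitude,synapsin_amplitude Peak intensities of the PSD bar
#'   and vesicle cloud.
#' @param view `"side"` (PSD elongated in-plane) or `"face"` (PSD seen
#'   end-on, rendered as a round blob: length = thickness).
#' @return A `synapse_truth` object (named list).
#' @export
synapse_truth <- function(center_nm,
                          axis_angle_rad = 0,
                          psd_length_nm = 400,
                          psd_thickness_nm = 80,
                          channel_offset_nm = -50,
                          channel_length_nm = 400,
                          channel_thickness_nm = 60,
                          channel_amplitude = 80,
                          vesicle_cloud_radius_nm = 300,
                          vesicle_cloud_offset_nm = 250,
                          psd_amplitude = 100,
                          synapsin_amplitude = 60,
                          view = c("side", "face")) {
  view <- match.arg(view)
  if (length(center_nm) != 2L || !all(is.finite(center_nm)))
    abort("`center_nm` must be finite (x, y).")
  if (axis_angle_rad < 0 || axis_angle_rad >= pi)
    abort("`axis_angle_rad` must lie in [0, pi).")
  amps <- c(channel_amplitude, psd_amplitude, synapsin_amplitude)
  if (any(amps < 0)) abort("amplitudes must be >= 0.")
  if (any(c(psd_length_nm, psd_thickness_nm, channel_length_nm,
            channel_thickness_nm, vesicle_cloud_radius_nm,
            vesicle_cloud_offset_nm) <= 0))
    abort("geometry dimensions must be > 0.")
  if (view == "side" && psd_length_nm <= psd_thickness_nm)
    abort("a side-view PSD must be elongated (length > thickness).")
  if (view == "face") psd_length_nm <- psd_thickness_nm
  structure(
    list(center_nm = as.numeric(center_nm),
         axis_angle_rad = axis_angle_rad,
         psd_length_nm = psd_length_nm,
         psd_thickness_nm = psd_thickness_nm,
         channel_offset_nm = channel_offset_nm,
         channel_length_nm = channel_length_nm,
         channel_thickness_nm = channel_thickness_nm,
         channel_amplitude = channel_amplitude,
         vesicle_cloud_radius_nm = vesicle_cloud_radius_nm,
         vesicle_cloud_offset_nm = vesicle_cloud_offset_nm,
         psd_amplitude = psd_amplitude,
         synapsin_amplitude = synapsin_amplitude,
         view = view),
    class = "synapse_truth"
  )
}

#' Build a synthetic scene of synapses with known ground truth
#'
#' Places `n_synapses` side-view synapses on a jittered grid so that centers
#' are at least `min_spacing_nm` apart and the full line-profile rectangle
#' stays inside the field. Per-synapse parameters (orientation, channel
#' offset, jitter) are drawn from child seeds derived from `seed`, so adding
#' synapses never perturbs earlier ones and a fixed seed reproduces the
#' scene exactly.
#'
#' @param optics An [optics_spec()].
#' @param n_synapses Number of synapses (>= 0).
#' @param amplitude_regime `"targeted"` (full channel amplitude),
#'   `"reduced"` (30% amplitude) or `"absent"` (amplitude 0).
#' @param offset_mean_nm,offset_sd_nm Normal distribution of the channel
#'   band offset along the trans-synaptic axis (nm; negative = presynaptic).
#'   The default, -50 +/- 15 nm, puts targeted channels within tens of
#'   nanometers of the PSD-95 peak on the presynaptic side.
#' @param seed Integer seed.
#' @param min_spacing_nm Minimum distance between synapse centers.
#' @param margin_nm Keep-out border so extraction rectangles fit.
#' @param view Synapse orientation passed to [synapse_truth()].
#' @param truth_args Named list of further [synapse_truth()] overrides
#'   applied to every synapse (e.g. `list(channel_amplitude = 40)`).
#' @return A `scene_truth` object: `optics`, list of `synapse_truth`, `seed`.
#' @examples
#' sc <- build_scene(optics_spec(field_px = c(512, 512)), n_synapses = 4, seed = 1)
#' truth_table(sc)
#' @export
build_scene <- function(optics,
                        n_synapses,
                        amplitude_regime = c("targeted", "absent", "reduced"),
                        offset_mean_nm = -50,
                        offset_sd_nm = 15,
                        seed = 1L,
                        min_spacing_nm = 1500,
                        margin_nm = 800,
                        view = "side",
                        truth_args = list()) {
  stopifnot(inherits(optics, "optics_spec"))
  amplitude_regime <- match.arg(amplitude_regime)
  if (n_synapses < 0) abort("`n_synapses` must be >= 0.")

  ext <- field_nm(optics)             # (height, width) nm
  usable <- ext - 2 * margin_nm
  synapses <- list()
  if (n_synapses > 0) {
    if (any(usable < min_spacing_nm))
      abort("field too small for the requested margin and spacing.")
    ncol_cells <- floor(usable[2] / min_spacing_nm)
    nrow_cells <- floor(usable[1] / min_spacing_nm)
    if (ncol_cells * nrow_cells < n_synapses)
      abort(sprintf(
        "field holds at most %d synapses at %.0f nm spacing; %d requested.",
        ncol_cells * nrow_cells, min_spacing_nm, n_synapses))
    cell_w <- usable[2] / ncol_cells
    cell_h <- usable[1] / nrow_cells
    jit_x <- (cell_w - min_spacing_nm) / 2
    jit_y <- (cell_h - min_spacing_nm) / 2

    amp_factor <- switch(amplitude_regime,
                         targeted = 1, reduced = 0.3, absent = 0)
    base_amp <- truth_args$channel_amplitude %||%
      formals(synapse_truth)$channel_amplitude

    synapses <- lapply(seq_len(n_synapses), function(i) {
      set.seed(child_seed(seed, i, salt = 1L))
      cell <- i - 1L
      cx <- margin_nm + (cell %% ncol_cells + 0.5) * cell_w +
        stats::runif(1, -jit_x, jit_x)
      cy <- margin_nm + (cell %/% ncol_cells + 0.5) * cell_h +
        stats::runif(1, -jit_y, jit_y)
      angle <- stats::runif(1, 0, pi)
      offset <- stats::rnorm(1, offset_mean_nm, offset_sd_nm)
      args <- utils::modifyList(
        list(center_nm = c(cx, cy),
             axis_angle_rad = angle,
             channel_offset_nm = offset,
             view = view),
        truth_args)
      args$channel_amplitude <- base_amp * amp_factor
      do.call(synapse_truth, args)
    })
  }
  structure(list(optics = optics, synapses = synapses, seed = as.integer(seed)),
            class = "scene_truth")
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("<scene_truth> %d synapses, seed %d\n",
              length(x$synapses), x$seed))
  invisible(x)
}

#' Tabulate the ground truth of a scene
#'
#' @param scene A `scene_truth` from [build_scene()].
#' @return A tibble with one row per synapse: id, center, axis angle,
#'   channel offset, geometry, amplitudes and view. Round-trips losslessly
#'   through [write_truth_table()] / [read_truth_table()].
#' @export
truth_table <- function(scene) {
  stopifnot(inherits(scene, "scene_truth"))
  if (length(scene$synapses) == 0L) {
    return(tibble(
      synapse_id = integer(), center_x_nm = double(), center_y_nm = double(),
      axis_angle_rad = double(), channel_offset_nm = double(),
      psd_length_nm = double(), psd_thickness_nm = double(),
      channel_length_nm = double(), channel_thickness_nm = double(),
      channel_amplitude = double(), vesicle_cloud_radius_nm = double(),
      vesicle_cloud_offset_nm = double(), psd_amplitude = double(),
      synapsin_amplitude = double(), view = character()))
  }
  purrr::imap(scene$synapses, function(s, i) {
    tibble(
      synapse_id = as.integer(i),
      center_x_nm = s$center_nm[1], center_y_nm = s$center_nm[2],
      axis_angle_rad = s$axis_angle_rad,
      channel_offset_nm = s$channel_offset_nm,
      psd_length_nm = s$psd_length_nm, psd_thickness_nm = s$psd_thickness_nm,
      channel_length_nm = s$channel_length_nm,
      channel_thickness_nm = s$channel_thickness_nm,
      channel_amplitude = s$channel_amplitude,
      vesicle_cloud_radius_nm = s$vesicle_cloud_radius_nm,
      vesicle_cloud_offset_nm = s$vesicle_cloud_offset_nm,
      psd_amplitude = s$psd_amplitude,
      synapsin_amplitude = s$synapsin_amplitude,
      view = s$view)
  }) |> purrr::list_rbind()
}

#' Build a synthetic field of neuronal somata
#'
#' Emulates single-section confocal somatic imaging (default: a
#' 92.65 x 92.65 um^2 field at 1024 x 1024 px, 90.2 nm pixels) with, per
#' cell, a NeuN-filled soma disk, an EGFP nucleus disk, and a cytoplasmic
#' channel-of-interest (HA) annulus between nucleus and soma edge.
#'
#' @param optics An [optics_spec()]; defaults to the somatic regime.
#' @param n_cells Number of cells.
#' @param soma_radius_nm,nucleus_radius_nm Disk radii (nm).
#' @param ha_amplitude,neun_amplitude,nucleus_amplitude Peak intensities.
#' @param seed Integer seed.
#' @return A `soma_scene` object: `optics`, per-cell truth tibble, `seed`.
#' @export
build_soma_scene <- function(optics = optics_spec(
                               pixel_size_nm = 90.2,
                               field_px = c(1024L, 1024L),
                               channels = c(channel_of_interest = "confocal",
                                            neun = "confocal",
                                            nucleus = "confocal")),
                             n_cells = 4,
                             soma_radius_nm = 8000,
                             nucleus_radius_nm = 4500,
                             ha_amplitude = 40,
                             neun_amplitude = 60,
                             nucleus_amplitude = 80,
                             seed = 1L) {
  stopifnot(inherits(optics, "optics_spec"))
  if (nucleus_radius_nm >= soma_radius_nm)
    abort("nucleus radius must be smaller than the soma radius.")
  ext <- field_nm(optics)
  margin <- soma_radius_nm * 1.3
  usable <- ext - 2 * margin
  spacing <- 2.4 * soma_radius_nm
  ncol_cells <- floor(usable[2] / spacing)
  nrow_cells <- floor(usable[1] / spacing)
  if (n_cells > 0 && ncol_cells * nrow_cells < n_cells)
    abort("field too small for the requested number of somata.")
  cells <- purrr::map(seq_len(n_cells), function(i) {
    set.seed(child_seed(seed, i, salt = 3L))
    cell <- i - 1L
    cx <- margin + (cell %% ncol_cells + 0.5) * usable[2] / ncol_cells +
      stats::runif(1, -0.1, 0.1) * soma_radius_nm
    cy <- margin + (cell %/% ncol_cells + 0.5) * usable[1] / nrow_cells +
      stats::runif(1, -0.1, 0.1) * soma_radius_nm
    tibble(cell_id = as.integer(i), center_x_nm = cx, center_y_nm = cy,
           soma_radius_nm = soma_radius_nm,
           nucleus_radius_nm = nucleus_radius_nm,
           ha_amplitude = ha_amplitude, neun_amplitude = neun_amplitude,
           nucleus_amplitude = nucleus_amplitude)
  }) |> purrr::list_rbind()
  structure(list(optics = optics, cells = cells, seed = as.integer(seed)),
            class = "soma_scene")
}
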