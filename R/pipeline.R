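# Seeded end-to-end workflow: simulate -> quantify -> stats -> report ----

RUN_REGIMES <- c("targeted", "absent", "reduced")

#' Configure a simulated experiment
#'
#' A run compares named conditions, each a synthetic scene regime (channel
#' amplitude x offset distribution), through the full pipeline: rendering
#' with Poisson noise, side-view selection, line profiles aligned to the
#' PSD-95 peak, in-window peak levels, synapsin-ROI confocal
#' quantification, and Kruskal-Wallis + Dunn statistics on the peak levels.
#'
#' @param conditions Named list; each element a list with `regime`
#'   (`"targeted"`, `"absent"`, `"reduced"`), and optional `n_synapses`,
#'   `offset_mean_nm`, `offset_sd_nm` overriding the defaults.
#' @param reference Condition label Dunn's comparisons are made against
#'   (default: first condition).
#' @param optics An [optics_spec()]; the default field is sized down from
#'   the acquisition regime for speed (pixel pitch is unchanged).
#' @param n_synapses Default synapses per condition.
#' @param mode Synapse selection: `"auto"` (Otsu-based detection) or
#'   `"truth"` (ground-truth anchors, mirroring annotated manual selection).
#' @param length_nm,width_nm,window_nm,smooth_px Profile parameters.
#' @param min_area_um2,connectivity ROI parameters.
#' @param alpha Significance level.
#' @param blind Replace condition labels by codes until the stats stage.
#' @param seed Integer seed for the whole run.
#' @return A validated `run_config` list.
#' @export
run_config <- function(conditions,
                       reference = names(conditions)[1],
                       optics = optics_spec(field_px = c(1024L, 1024L)),
                       n_synapses = 24,
                       mode = c("auto", "truth"),
                       length_nm = 1000, width_nm = 200, window_nm = 200,
                       smooth_px = 5L, min_area_um2 = 0.05,
                       connectivity = 8, alpha = 0.05, blind = TRUE,
                       seed = 1L, ...) {
  extra <- list(...)
  if (length(extra) > 0)
    abort(sprintf("unknown run_config parameter(s): %s",
                  paste(names(extra), collapse = ", ")))
  mode <- match.arg(mode)
  if (!is.list(conditions) || length(conditions) < 1 ||
      is.null(names(conditions)) || any(names(conditions) == ""))
    abort("`conditions` must be a non-empty named list.")
  for (nm in names(conditions)) {
    cond <- conditions[[nm]]
    if (!is.list(cond) || is.null(cond$regime) ||
        !cond$regime %in% RUN_REGIMES)
      abort(sprintf("condition '%s' needs a regime in {%s}.",
                    nm, paste(RUN_REGIMES, collapse = ", ")))
    unknown <- setdiff(names(cond),
                       c("regime", "n_synapses", "offset_mean_nm",
                         "offset_sd_nm"))
    if (length(unknown) > 0)
      abort(sprintf("condition '%s' has unknown parameter(s): %s",
                    nm, paste(unknown, collapse = ", ")))
  }
  if (!reference %in% names(conditions))
    abort("`reference` must name one of the conditions.")
  stopifnot(inherits(optics, "optics_spec"))
  if (smooth_px %% 2 == 0) abort("`smooth_px` must be odd.")
  if (window_nm <= 0 || window_nm > length_nm)
    abort("`window_nm` must lie in (0, length_nm].")
  if (!connectivity %in% c(4, 8)) abort("`connectivity` must be 4 or 8.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  structure(
    list(conditions = conditions, reference = reference, optics = optics,
         n_synapses = n_synapses, mode = mode, length_nm = length_nm,
         width_nm = width_nm, window_nm = window_nm, smooth_px = smooth_px,
         min_area_um2 = min_area_um2, connectivity = connectivity,
         alpha = alpha, blind = blind, seed = as.integer(seed)),
    class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with the [run_config()] fields (conditions as a
#'   named map; optics fields under an `optics` map).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$optics)) {
    oargs <- y$optics
    if (!is.null(oargs$channels)) oargs$channels <- unlist(oargs$channels)
    if (!is.null(oargs$psf_fwhm_nm))
      oargs$psf_fwhm_nm <- unlist(oargs$psf_fwhm_nm)
    y$optics <- do.call(optics_spec, oargs)
  }
  do.call(run_config, y)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[order(names(config))]), tmp)
  unname(tools::md5sum(tmp))
}

# seeded blinding codes; labels recoverable only through the key
blind_key <- function(labels, seed) {
  set.seed(child_seed(seed, 0L, salt = 13L))
  codes <- sprintf("cond_%02d", sample(seq_along(labels)))
  tibble(condition = labels, code = codes)
}

#' Run a configured simulated experiment end to end
#'
#' Deterministic given the config seed. Per condition: build a scene, render
#' with Poisson noise, select side-view synapses (automatically or from
#' ground truth), extract perpendicular profiles, align to the PSD-95 peak,
#' measure in-window peak levels, and quantify synapsin ROIs; then compare
#' conditions with a Kruskal-Wallis test and Dunn's post hoc against the
#' reference. When blinding is on, condition labels are replaced by codes
#' during quantification and restored (via the key) only at the stats stage.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, tidy CSVs (aligned
#'   profiles, peaks, ROI summaries, statistics, blinding key, log) are
#'   written, each carrying the config hash on a leading comment line.
#' @return A `synq_run` bundle: `aligned` (per-condition summaries),
#'   `peaks`, `roi_summary`, `omnibus`, `posthoc`, `blinding_key`,
#'   `config_hash`, `figures` (ggplot objects), `log`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(config)
  labels <- names(config$conditions)
  key <- blind_key(labels, config$seed)
  work_labels <- if (config$blind) key$code else key$condition
  log <- c(sprintf("config_hash: %s", hash),
           sprintf("seed: %d", config$seed),
           sprintf("mode: %s", config$mode),
           sprintf("blind: %s", config$blind))

  per_cond <- purrr::map(seq_along(labels), function(i) {
    cond <- config$conditions[[i]]
    scene <- build_scene(
      config$optics,
      n_synapses = cond$n_synapses %||% config$n_synapses,
      amplitude_regime = cond$regime,
      offset_mean_nm = cond$offset_mean_nm %||% -50,
      offset_sd_nm = cond$offset_sd_nm %||% 15,
      seed = child_seed(config$seed, i, salt = 29L))
    stack <- render_stack(scene, noise = "poisson")
    synapses <- if (config$mode == "auto") {
      detect_side_view_synapses(stack)
    } else {
      truth_table(scene)
    }
    profiles <- extract_profiles(stack, synapses,
                                 length_nm = config$length_nm,
                                 width_nm = config$width_nm)
    aligned <- align_profiles(profiles, smooth_px = config$smooth_px)
    peaks <- peak_in_window(aligned, window_nm = config$window_nm)
    rois <- segment_channel(stack, "synapsin") |>
      label_components(connectivity = config$connectivity) |>
      filter_min_area(min_area_um2 = config$min_area_um2) |>
      measure_rois(stack, channels = "channel_of_interest")
    list(aligned = aligned$summary, peaks = peaks,
         roi = image_summary(rois), n_synapses = aligned$n_synapses)
  })
  names(per_cond) <- work_labels

  aligned_tbl <- purrr::imap(per_cond, function(x, nm) {
    mutate(x$aligned, condition = nm, .before = 1)
  }) |> purrr::list_rbind()
  peaks_tbl <- summarize_peaks(purrr::map(per_cond, "peaks"))
  roi_tbl <- purrr::imap(per_cond, function(x, nm) {
    mutate(x$roi, condition = nm, .before = 1)
  }) |> purrr::list_rbind()
  log <- c(log, sprintf("synapses analyzed per condition: %s",
                        paste(purrr::map_int(per_cond, "n_synapses"),
                              collapse = ", ")))

  # stats stage: unblind through the key
  unblind <- function(df) {
    if (!config$blind) return(df)
    df$condition <- key$condition[match(df$condition, key$code)]
    df
  }
  aligned_tbl <- unblind(aligned_tbl)
  peaks_tbl <- unblind(peaks_tbl)
  roi_tbl <- unblind(roi_tbl)

  peak_data <- peaks_tbl |> mutate(unit = "synapse")
  omnibus <- kruskal_wallis(peak_data, "peak_value", "condition")
  posthoc <- dunn_posthoc(peak_data, "peak_value", "condition",
                          reference = config$reference,
                          alpha = config$alpha)

  figures <- list(
    profiles = plot_aligned_profiles(aligned_tbl),
    peaks = plot_peak_levels(peaks_tbl))

  bundle <- structure(
    list(aligned = aligned_tbl, peaks = peaks_tbl, roi_summary = roi_tbl,
         omnibus = omnibus, posthoc = posthoc, blinding_key = key,
         config = config, config_hash = hash, figures = figures, log = log),
    class = "synq_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_result_csv(aligned_tbl, file.path(out_dir, "profiles_aligned.csv"),
                     hash)
    write_result_csv(peaks_tbl, file.path(out_dir, "peaks.csv"), hash)
    write_result_csv(roi_tbl, file.path(out_dir, "roi_summary.csv"), hash)
    write_result_csv(
      bind_rows(glance(omnibus) |> mutate(group1 = NA, group2 = NA),
                posthoc |>
                  mutate(method = "Dunn post hoc", statistic = .data$z,
                         n = NA) |>
                  select("method", "statistic", p_value = "p_adjusted",
                         "group1", "group2")),
      file.path(out_dir, "stats.csv"), hash)
    write_result_csv(key, file.path(out_dir, "blinding_key.csv"), hash)
    writeLines(log, file.path(out_dir, "run_log.txt"))
  }
  bundle
}

#' @export
print.synq_run <- function(x, ...) {
  cat(sprintf("<synq_run> %d conditions, config %s\n",
              length(x$config$conditions), substr(x$config_hash, 1, 8)))
  print(x$omnibus)
  invisible(x)
}
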