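#' Pipeline run configuration
#'
#' Bundles every tunable of the analysis pipeline. Defaults follow the
#' standard protocol: intensity threshold 60 for particle, junction, marker
#' and IgG channels, 100 for the permeabilization comparison; 8-connectivity
#' for particles; 8 spatially stratified cells for polarization; shifts
#' -20..+20 px for the cross-correlation curve. Configurations round-trip
#' losslessly through YAML via [write_config()] / [read_config()].
#'
#' @param pixel_size Pixel size in µm.
#' @param threshold_particle,threshold_junction,threshold_marker,threshold_igg
#'   Channel thresholds (0-255).
#' @param threshold_permeabilization Threshold for permeabilization pairs.
#' @param connectivity Particle connectivity, 4 or 8.
#' @param k_cells Number of sampled cells for polarization.
#' @param min_cell_area Minimum segmented-cell area (px).
#' @param max_shift Maximum CCF shift (px).
#' @param band_length,band_width Band geometry for [band_profile()] (px).
#' @param subdivide_large Use the four-level size binning throughout?
#' @param seed Seed recorded with the run.
#' @return A list of class `run_config`.
#' @export
run_config <- function(pixel_size = 0.124,
                       threshold_particle = 60, threshold_junction = 60,
                       threshold_marker = 60, threshold_igg = 60,
                       threshold_permeabilization = 100,
                       connectivity = 8, k_cells = 8, min_cell_area = 200,
                       max_shift = 20, band_length = 1500, band_width = 250,
                       subdivide_large = FALSE, seed = 1) {
  cfg <- list(pixel_size = pixel_size,
              threshold_particle = threshold_particle,
              threshold_junction = threshold_junction,
              threshold_marker = threshold_marker,
              threshold_igg = threshold_igg,
              threshold_permeabilization = threshold_permeabilization,
              connectivity = connectivity, k_cells = k_cells,
              min_cell_area = min_cell_area, max_shift = max_shift,
              band_length = band_length, band_width = band_width,
              subdivide_large = subdivide_large, seed = seed)
  thr <- unlist(cfg[grep("^threshold_", names(cfg))])
  if (any(thr < 0 | thr > 255)) stop("all thresholds must be in [0, 255]")
  structure(cfg, class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   the reconstructed `run_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full analysis pipeline over a set of images
#'
#' For each input stack the pipeline segments cells from the junction
#' channel, detects and classifies particles, and computes area densities,
#' particles per cell, per-class downstream polarization over the sampled
#' cells, the fraction of cells with large particles, the two binary
#' colocalization fractions between particle and junction masks, and the
#' van Steensel peak shift. When a marker channel is present its area
#' density and junctional fraction are added; when an IgG channel is present
#' the leakage densities (overall and stratified by marker) are added.
#' Results are returned tidy: one row per (image, metric, channel).
#'
#' @param stacks A list of [channel_stack()] objects (or a single one), or a
#'   `synthetic_sheet` / list of them (their `$stack` is used). Must be
#'   non-empty.
#' @param config A [run_config()].
#' @param channels Named list mapping roles to channel names; defaults to
#'   `list(particle = "veptp", junction = "vecad", marker = "marker",
#'   igg = "igg")`. Roles whose channel is absent from a stack are skipped.
#' @return A data frame with columns `image`, `metric`, `channel`, `value`.
#' @export
run_pipeline <- function(stacks, config = run_config(),
                         channels = list(particle = "veptp",
                                         junction = "vecad",
                                         marker = "marker", igg = "igg")) {
  stopifnot(inherits(config, "run_config"))
  if (inherits(stacks, "channel_stack") || inherits(stacks, "synthetic_sheet"))
    stacks <- list(stacks)
  if (!is.list(stacks) || length(stacks) == 0L)
    stop("config error: empty input set")
  stacks <- lapply(stacks, function(s)
    if (inherits(s, "synthetic_sheet")) s$stack else s)
  cal <- calibration(config$pixel_size)
  rows <- list()
  emit <- function(image, metric, channel, value)
    rows[[length(rows) + 1L]] <<- data.frame(image = image, metric = metric,
                                             channel = channel,
                                             value = as.numeric(value))
  for (i in seq_along(stacks)) {
    stack <- stacks[[i]]
    stopifnot(inherits(stack, "channel_stack"))
    img <- if (!is.null(names(stacks)) && nzchar(names(stacks)[i]))
      names(stacks)[i] else sprintf("image_%03d", i)

    pch <- get_channel(stack, channels$particle)
    jch <- get_channel(stack, channels$junction)
    pmask <- binarize(pch, config$threshold_particle)
    jmask <- binarize(jch, config$threshold_junction)
    cells <- segment_cells(jmask, min_area = config$min_cell_area)
    particles <- label_particles(pmask, connectivity = config$connectivity,
                                 calibration = cal,
                                 subdivide_large = config$subdivide_large)
    particles <- assign_particles(particles, cells)

    emit(img, "cell_count", channels$junction, nrow(cells$cells))
    emit(img, "area_density_pct", channels$particle, area_density(pmask))
    emit(img, "area_density_pct", channels$junction, area_density(jmask))
    emit(img, "particles_per_cell", channels$particle,
         particles_per_cell(particles, cells))
    cc <- classify_and_count(particles, config$subdivide_large)
    for (k in seq_len(nrow(cc)))
      emit(img, paste0("count_", cc$size_class[k]), channels$particle,
           cc$count[k])
    sampled <- sample_cells(cells, k = min(config$k_cells,
                                           sum(!cells$cells$border)))
    pol <- polarization(particles, cells, sampled, config$subdivide_large)
    for (k in seq_len(nrow(pol)))
      emit(img, paste0("downstream_pct_", pol$size_class[k]),
           channels$particle, pol$downstream_pct[k])
    emit(img, "pct_cells_with_large", channels$particle,
         percent_cells_with_large(particles, cells))
    cf <- coloc_fraction(pmask, jmask)
    emit(img, "pct_particle_in_junction", channels$particle, cf$pct_a_in_b)
    emit(img, "pct_junction_in_particle", channels$junction, cf$pct_b_in_a)
    ccf <- van_steensel_ccf(pch, jch, max_shift = config$max_shift,
                            calibration = cal)
    emit(img, "ccf_peak_px", channels$particle, attr(ccf, "peak_px"))
    emit(img, "ccf_peak_um", channels$particle, attr(ccf, "peak_um"))

    if (!is.null(channels$marker) && channels$marker %in% names(stack)) {
      mmask <- binarize(get_channel(stack, channels$marker),
                        config$threshold_marker)
      emit(img, "area_density_pct", channels$marker, area_density(mmask))
      emit(img, "junctional_fraction_pct", channels$marker,
           junctional_fraction(mmask, jmask))
    }
    if (!is.null(channels$igg) && channels$igg %in% names(stack)) {
      imask <- binarize(get_channel(stack, channels$igg), config$threshold_igg)
      emit(img, "igg_density_pct", channels$igg, igg_density(imask))
      if (!is.null(channels$marker) && channels$marker %in% names(stack)) {
        lr <- density_by_marker(imask, binarize(
          get_channel(stack, channels$marker), config$threshold_marker))
        emit(img, "igg_with_marker_pct", channels$igg, lr$with_marker_pct)
        emit(img, "igg_without_marker_pct", channels$igg,
             lr$without_marker_pct)
      }
    }
  }
  do.call(rbind, rows)
}
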