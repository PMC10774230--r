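#' Specification of a synthetic endothelial sheet
#'
#' Geometry and rendering parameters for the synthetic image generator. The
#' generator emulates an en-face endothelial monolayer: an anisotropic
#' tessellation of cells elongated along the flow axis (aortic endothelium is
#' far more elongated than vena-cava endothelium), junction lines with a
#' bright stain, and additive Gaussian noise. Vessel presets fix the
#' elongation: `"aorta"` 3.0, `"vena_cava"` 1.2.
#'
#' @param width,height Image size in pixels.
#' @param n_cells Target cell count; the label map contains exactly this many
#'   cells.
#' @param pixel_size Pixel size in µm (default 0.124, the x100 objective).
#' @param vessel `"aorta"` (default) or `"vena_cava"`; sets `elongation`
#'   unless given explicitly.
#' @param elongation Cell elongation factor along the flow axis (>= 1).
#' @param junction_width Junction line width in pixels (>= 2).
#' @param junction_intensity Intensity of junction lines (0-255).
#' @param background Background intensity (must stay below thresholds after
#'   noise).
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @return A list of class `sheet_spec`.
#' @export
sheet_spec <- function(width = 768, height = 768, n_cells = 200,
                       pixel_size = 0.124, vessel = c("aorta", "vena_cava"),
                       elongation = NULL, junction_width = 2,
                       junction_intensity = 150, background = 20,
                       noise_sd = 6) {
  vessel <- match.arg(vessel)
  if (is.null(elongation))
    elongation <- switch(vessel, aorta = 3.0, vena_cava = 1.2)
  if (elongation < 1) stop("elongation must be >= 1")
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (junction_width < 2) stop("junction_width must be >= 2")
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_cells = as.integer(n_cells), pixel_size = pixel_size,
                 vessel = vessel, elongation = elongation,
                 junction_width = as.integer(junction_width),
                 junction_intensity = junction_intensity,
                 background = background, noise_sd = noise_sd),
            class = "sheet_spec")
}

#' Particle model for the synthetic generator
#'
#' Statistical model of punctate particle staining. Per cell, small and
#' medium particle counts are Poisson with the given means; each medium
#' particle falls in the downstream half of its cell with probability
#' `q_medium`; each cell independently carries one large particle at its
#' downstream tip with probability `pi_large` (0.54 emulates aortic
#' endothelium, 0.88 vena cava). Radii are drawn uniformly from discrete
#' sets whose rasterized disks fall inside the intended pixel-count bins
#' (small 1-10 px, medium 11-100 px, large > 100 px, with large radii
#' spanning the 101-200 and > 200 px sub-bins). For permeabilization pairs,
#' each particle is membrane-resident with the per-bin probability in
#' `membrane_fraction`; a "non-permeabilized" render draws only the
#' membrane-resident particles.
#'
#' @param mean_small,mean_medium Mean particles per cell for the small and
#'   medium classes.
#' @param q_medium Probability that a medium particle lies downstream.
#' @param pi_large Per-cell probability of one large tip particle.
#' @param radii_small,radii_medium,radii_large Candidate disk radii (px).
#' @param intensity Rendered particle intensity (must exceed the analysis
#'   threshold even at threshold 100).
#' @param membrane_fraction Named numeric: membrane probability per size bin
#'   (`small`, `medium`, `large_101_200`, `large_gt200`).
#' @return A list of class `particle_model`.
#' @export
particle_model <- function(mean_small = 15, mean_medium = 6, q_medium = 0.8,
                           pi_large = 0.54,
                           radii_small = c(0.5, 1, 1.5),
                           radii_medium = c(2, 3, 4, 5),
                           radii_large = c(6, 7, 8, 9),
                           intensity = 180,
                           membrane_fraction = c(small = 0.36, medium = 0.27,
                                                 large_101_200 = 0.37,
                                                 large_gt200 = 0.90)) {
  stopifnot(q_medium >= 0, q_medium <= 1, pi_large >= 0, pi_large <= 1,
            all(membrane_fraction >= 0), all(membrane_fraction <= 1))
  structure(list(mean_small = mean_small, mean_medium = mean_medium,
                 q_medium = q_medium, pi_large = pi_large,
                 radii_small = radii_small, radii_medium = radii_medium,
                 radii_large = radii_large, intensity = intensity,
                 membrane_fraction = membrane_fraction),
            class = "particle_model")
}

disk_offsets <- function(radius) {
  r <- ceiling(radius)
  dr <- rep(-r:r, times = 2 * r + 1)
  dc <- rep(-r:r, each = 2 * r + 1)
  keep <- dr^2 + dc^2 <= radius^2
  cbind(dr = dr[keep], dc = dc[keep])
}

add_noise_8bit <- function(channel, noise_sd) {
  if (noise_sd > 0)
    channel <- channel + rnorm(length(channel), sd = noise_sd)
  matrix(as.integer(pmin(pmax(round(channel), 0), 255)),
         nrow(channel), ncol(channel))
}

#' Generate a tessellated cell mosaic with a stained junction channel
#'
#' Seeds a jittered grid of exactly `n_cells` points (grid spacing stretched
#' along the flow axis by the elongation factor), assigns every pixel to its
#' nearest seed under the anisotropic metric, marks label boundaries as
#' junction lines of the requested width, and renders the junction intensity
#' channel with background and noise. Fully deterministic for a given seed.
#'
#' @param spec A [sheet_spec()].
#' @param seed Integer seed; determines the output bit-for-bit.
#' @return A list of class `cell_mosaic`: `labels` (true cell label map,
#'   1..n_cells), `junction_mask` (binary), `junction_channel` (0-255
#'   intensities), `seeds` (seed-point coordinates), `spec`, `seed`.
#' @export
generate_mosaic <- function(spec, seed) {
  stopifnot(inherits(spec, "sheet_spec"))
  set.seed(seed)
  W <- spec$width; H <- spec$height; n <- spec$n_cells; e <- spec$elongation
  nx <- max(1L, round(sqrt(n * W / (e * H))))
  ny <- ceiling(n / nx)
  total <- nx * ny
  cw <- W / nx; chh <- H / ny
  centres <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  keep <- if (total > n) sort(sample(total, n)) else seq_len(total)
  centres <- centres[keep, , drop = FALSE]
  sx <- (centres$ix - 0.5) * cw + runif(n, -0.35, 0.35) * cw
  sy <- (centres$iy - 0.5) * chh + runif(n, -0.35, 0.35) * chh
  sx <- pmin(pmax(sx, 1), W); sy <- pmin(pmax(sy, 1), H)
  # nearest seed under metric (dx/e)^2 + dy^2 (stretch along flow axis)
  px <- rep(seq_len(W), each = H); py <- rep(seq_len(H), times = W)
  nn <- class::knn1(train = cbind(sx / e, sy),
                    test = cbind(px / e, py),
                    cl = seq_len(n))
  labels <- matrix(as.integer(nn), H, W)
  vd <- labels[, -1, drop = FALSE] != labels[, -ncol(labels), drop = FALSE]
  hd <- labels[-1, , drop = FALSE] != labels[-nrow(labels), , drop = FALSE]
  jmask <- matrix(FALSE, H, W)
  jmask[, -1][vd] <- TRUE; jmask[, -W][vd] <- TRUE
  jmask[-1, ][hd] <- TRUE; jmask[-H, ][hd] <- TRUE
  if (spec$junction_width > 2) {
    extra <- spec$junction_width - 2L
    brush <- EBImage::makeBrush(2L * ceiling(extra / 2) + 1L, "disc")
    jmask <- EBImage::dilate(jmask * 1L, brush) > 0
  }
  jmask <- matrix(as.integer(jmask), H, W)
  jch <- spec$background + jmask * (spec$junction_intensity - spec$background)
  jch <- add_noise_8bit(jch, spec$noise_sd)
  structure(list(labels = labels, junction_mask = jmask,
                 junction_channel = jch,
                 seeds = data.frame(x = sx, y = sy),
                 spec = spec, seed = seed),
            class = "cell_mosaic")
}

#' @export
print.cell_mosaic <- function(x, ...) {
  cat(sprintf("<cell_mosaic> %d cells, %d x %d px (%s, elongation %.1f)\n",
              x$spec$n_cells, x$spec$height, x$spec$width,
              x$spec$vessel, x$spec$elongation))
  invisible(x)
}

# Columnwise split coordinate of every true cell (area-centroid column).
true_split_cols <- function(labels) {
  fg <- which(labels > 0L)
  l <- labels[fg]
  cols <- ((fg - 1L) %/% nrow(labels)) + 1L
  as.numeric(rowsum(as.numeric(cols), l)[, 1] / tabulate(l))
}

#' Render punctate particles into a cell mosaic
#'
#' Draws particles according to a [particle_model()]: small particles uniform
#' within cells, medium particles in the downstream half with probability
#' `q_medium`, and large particles abutting the downstream cell tip with
#' per-cell probability `pi_large`. The tip centre is the most-downstream
#' cell pixel that is at least 2 px from any neighbouring cell (so the disk
#' partially overlaps the junction line while its centroid stays within the
#' cell, within ~3 px of the most-downstream boundary pixel). Disks are
#' placed with rejection sampling so they do not touch (50 retries; a forced
#' placement sets the `collision` flag) and are kept clear of the image
#' border so rasterized pixel counts are exact. At the default densities the
#' generator operates in its no-forced-merge regime (`collision = FALSE`).
#'
#' @param mosaic A [generate_mosaic()] result.
#' @param model A [particle_model()].
#' @param seed Integer seed.
#' @param membrane_only Render only membrane-resident particles (emulates a
#'   non-permeabilized specimen)? All particles remain in the manifest with
#'   their `rendered` flag.
#' @return List of class `particle_render`: `channel` (0-255 intensity
#'   matrix) and `manifest` (data frame: `id`, `cell`, `class`
#'   (four-level bin), `radius`, `n_pixels`, `center_row`, `center_col`,
#'   `downstream`, `tip`, `membrane`, `rendered`), plus `split_cols`,
#'   `collision`, `model`, `seed`.
#' @export
render_particles <- function(mosaic, model, seed, membrane_only = FALSE) {
  stopifnot(inherits(mosaic, "cell_mosaic"), inherits(model, "particle_model"))
  set.seed(seed)
  labels <- mosaic$labels
  spec <- mosaic$spec
  H <- nrow(labels); W <- ncol(labels)
  n_cells <- max(labels)
  split_cols <- true_split_cols(labels)
  fg <- which(labels > 0L)
  pix_by_cell <- split(fg, labels[fg])
  all_radii <- sort(unique(c(model$radii_small, model$radii_medium,
                             model$radii_large)))
  offs <- lapply(all_radii, disk_offsets)
  names(offs) <- as.character(all_radii)
  npx <- vapply(offs, nrow, integer(1))
  max_r <- ceiling(max(all_radii))

  placed_r <- placed_c <- placed_rad <- numeric(0)
  rec <- list()
  n_forced <- 0L
  # cell "core": pixels with no junction pixel among their 8 neighbours, i.e.
  # at least 2 px from any neighbouring cell; tip centres are anchored here so
  # their centroids always fall on a segmented-cell pixel
  core <- EBImage::erode(1L - mosaic$junction_mask,
                         EBImage::makeBrush(3L, "box")) > 0

  ok_margin <- function(idx, rad) {
    r <- ((idx - 1L) %% H) + 1L
    c_ <- ((idx - 1L) %/% H) + 1L
    m <- ceiling(rad)
    idx[r > m & r <= H - m & c_ > m & c_ <= W - m]
  }
  try_place <- function(cand_idx, rad) {
    if (length(cand_idx) == 0L) return(NULL)
    # fast path: uniform rejection sampling against placed disks
    for (i in seq_len(50L)) {
      idx <- cand_idx[sample.int(length(cand_idx), 1L)]
      r0 <- ((idx - 1L) %% H) + 1L
      c0 <- ((idx - 1L) %/% H) + 1L
      if (length(placed_r) == 0L ||
          all((placed_r - r0)^2 + (placed_c - c0)^2 >
              (placed_rad + rad + 1.5)^2))
        return(c(r0, c0, FALSE))
    }
    # slow path: sample uniformly from the exact free subset of candidates
    cr <- ((cand_idx - 1L) %% H) + 1L
    cc_ <- ((cand_idx - 1L) %/% H) + 1L
    reach <- max(placed_rad) + rad + 1.5
    near <- which(placed_r >= min(cr) - reach & placed_r <= max(cr) + reach &
                    placed_c >= min(cc_) - reach & placed_c <= max(cc_) + reach)
    ok <- rep(TRUE, length(cand_idx))
    for (j in near)
      ok <- ok & ((cr - placed_r[j])^2 + (cc_ - placed_c[j])^2 >
                    (placed_rad[j] + rad + 1.5)^2)
    if (any(ok)) {
      pick <- which(ok)[sample.int(sum(ok), 1L)]
      return(c(cr[pick], cc_[pick], FALSE))
    }
    # candidate region truly packed: forced overlapping placement (flagged),
    # still inside the requested region so half assignments stay honest
    pick <- sample.int(length(cand_idx), 1L)
    c(cr[pick], cc_[pick], TRUE)
  }
  register <- function(cell, rad, r0, c0, downstream, tip) {
    placed_r <<- c(placed_r, r0); placed_c <<- c(placed_c, c0)
    placed_rad <<- c(placed_rad, rad)
    rec[[length(rec) + 1L]] <<- data.frame(
      cell = cell, radius = rad, n_pixels = npx[[as.character(rad)]],
      center_row = r0, center_col = c0, downstream = downstream, tip = tip)
  }

  for (cell in seq_len(n_cells)) {
    pix <- pix_by_cell[[as.character(cell)]]
    if (is.null(pix)) next
    # particle centres are drawn from the cell core (>= 2 px from neighbouring
    # cells) so every rendered particle unambiguously belongs to one cell
    pcore <- pix[core[pix]]
    if (length(pcore) == 0L) pcore <- pix
    ccore <- ((pcore - 1L) %/% H) + 1L
    s_c <- split_cols[cell]
    # large tip particle first: most-downstream core pixel of the cell,
    # kept clear of every disk already placed (including neighbouring cells'
    # particles) so tip components never merge
    if (runif(1) < model$pi_large) {
      rad <- model$radii_large[sample.int(length(model$radii_large), 1L)]
      m <- ceiling(rad)
      cand <- ok_margin(pcore, rad)
      if (length(cand) && length(placed_r)) {
        cr <- ((cand - 1L) %% H) + 1L
        cc_ <- ((cand - 1L) %/% H) + 1L
        reach <- max(placed_rad) + rad + 1.5
        near <- which(placed_r >= min(cr) - reach & placed_r <= max(cr) + reach &
                        placed_c >= min(cc_) - reach & placed_c <= max(cc_) + reach)
        ok <- rep(TRUE, length(cand))
        for (j in near)
          ok <- ok & ((cr - placed_r[j])^2 + (cc_ - placed_c[j])^2 >
                        (placed_rad[j] + rad + 1.5)^2)
        if (any(ok)) cand <- cand[ok] else n_forced <- n_forced + 1L
      }
      if (length(cand) == 0L) {
        cand <- ok_margin(pix, rad)
        n_forced <- n_forced + 1L
      }
      if (length(cand) == 0L) next
      ccol <- ((cand - 1L) %/% H) + 1L
      tipcol <- max(ccol)
      tp <- cand[ccol == tipcol]
      rows_t <- sort(((tp - 1L) %% H) + 1L)
      r0 <- rows_t[ceiling(length(rows_t) / 2)]
      c0 <- tipcol
      register(cell, rad, r0, c0, downstream = c0 >= s_c, tip = TRUE)
    }
    # medium particles: downstream with probability q_medium
    n_m <- rpois(1, model$mean_medium)
    if (n_m > 0) {
      down_flags <- runif(n_m) < model$q_medium
      for (dflag in down_flags) {
        rad <- model$radii_medium[sample.int(length(model$radii_medium), 1L)]
        half <- if (dflag) pcore[ccore >= s_c] else pcore[ccore < s_c]
        cand <- ok_margin(half, rad)
        if (length(cand) == 0L) cand <- ok_margin(pcore, rad)
        hit <- try_place(cand, rad)
        if (is.null(hit)) next
        if (hit[3]) n_forced <- n_forced + 1L
        register(cell, rad, hit[1], hit[2], downstream = hit[2] >= s_c,
                 tip = FALSE)
      }
    }
    # small particles: uniform within the cell
    n_s <- rpois(1, model$mean_small)
    for (k in seq_len(n_s)) {
      rad <- model$radii_small[sample.int(length(model$radii_small), 1L)]
      cand <- ok_margin(pcore, rad)
      hit <- try_place(cand, rad)
      if (is.null(hit)) next
      if (hit[3]) n_forced <- n_forced + 1L
      register(cell, rad, hit[1], hit[2], downstream = hit[2] >= s_c,
               tip = FALSE)
    }
  }

  manifest <- if (length(rec)) do.call(rbind, rec) else
    data.frame(cell = integer(), radius = numeric(), n_pixels = integer(),
               center_row = integer(), center_col = integer(),
               downstream = logical(), tip = logical())
  if (nrow(manifest)) {
    manifest <- cbind(id = seq_len(nrow(manifest)), manifest)
    manifest$class <- size_class(manifest$n_pixels, subdivide_large = TRUE)
    mf <- model$membrane_fraction[as.character(manifest$class)]
    manifest$membrane <- runif(nrow(manifest)) < mf
    manifest$rendered <- if (membrane_only) manifest$membrane else TRUE
  } else {
    manifest$id <- integer(); manifest$class <- size_class(1, TRUE)[0]
    manifest$membrane <- logical(); manifest$rendered <- logical()
  }

  channel <- matrix(spec$background, H, W)
  for (i in which(manifest$rendered)) {
    o <- offs[[as.character(manifest$radius[i])]]
    idx <- (manifest$center_col[i] + o[, "dc"] - 1L) * H +
      manifest$center_row[i] + o[, "dr"]
    channel[idx] <- model$intensity
  }
  channel <- add_noise_8bit(channel, spec$noise_sd)
  structure(list(channel = channel, manifest = manifest,
                 split_cols = split_cols, collision = n_forced > 0L,
                 n_forced = n_forced,
                 model = model, seed = seed),
            class = "particle_render")
}

#' Render a mosaic (patchy per-cell) marker channel
#'
#' Marks a target fraction of cells positive using seeded cluster growth on
#' the cell adjacency graph: with probability `contiguity` the next positive
#' cell is drawn from neighbours of the current positive set, otherwise a
#' fresh random cell seeds a new cluster. Positive cells receive either
#' cytoplasmic staining (whole cell) or junction-localized staining (cell
#' pixels within a halo of the junction lines).
#'
#' @param mosaic A [generate_mosaic()] result.
#' @param fraction Target fraction of positive cells in \[0, 1\] (hit within
#'   rounding to a whole cell).
#' @param contiguity Probability of growing an existing cluster (default
#'   0.8); 0 reproduces independent assignment.
#' @param localization `"cytoplasm"` (default) or `"junction"`.
#' @param intensity Stain intensity (0-255).
#' @param seed Integer seed.
#' @param halo Junction halo width in pixels for junction localization.
#' @return List of class `marker_render`: `channel`, `positive_cells`,
#'   `mask` (binary stained-pixel mask before noise), `fraction_target`,
#'   `seed`.
#' @export
render_marker_mosaic <- function(mosaic, fraction, contiguity = 0.8,
                                 localization = c("cytoplasm", "junction"),
                                 intensity = 150, seed, halo = 2) {
  stopifnot(inherits(mosaic, "cell_mosaic"), fraction >= 0, fraction <= 1)
  localization <- match.arg(localization)
  set.seed(seed)
  labels <- mosaic$labels
  spec <- mosaic$spec
  n <- max(labels)
  m <- round(fraction * n)
  positive <- integer(0)
  if (m > 0) {
    vd <- cbind(as.vector(labels[, -1]), as.vector(labels[, -ncol(labels)]))
    hd <- cbind(as.vector(labels[-1, ]), as.vector(labels[-nrow(labels), ]))
    ee <- rbind(vd, hd)
    ee <- ee[ee[, 1] != ee[, 2] & ee[, 1] > 0 & ee[, 2] > 0, , drop = FALSE]
    ee <- cbind(pmin(ee[, 1], ee[, 2]), pmax(ee[, 1], ee[, 2]))
    ee <- ee[!duplicated(ee), , drop = FALSE]
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    if (nrow(ee)) g <- igraph::add_edges(g, t(ee))
    positive <- sample.int(n, 1L)
    while (length(positive) < m) {
      frontier <- setdiff(unique(unlist(
        igraph::adjacent_vertices(g, positive))), positive)
      grow <- runif(1) < contiguity && length(frontier) > 0
      pool <- if (grow) frontier else setdiff(seq_len(n), positive)
      positive <- c(positive, pool[sample.int(length(pool), 1L)])
    }
    positive <- sort(positive)
  }
  posmask <- matrix(as.integer(labels %in% positive &
                                 labels > 0L), nrow(labels), ncol(labels))
  if (localization == "junction" && sum(posmask) > 0) {
    brush <- EBImage::makeBrush(2L * halo + 1L, "disc")
    near_j <- EBImage::dilate(mosaic$junction_mask, brush) > 0
    posmask <- posmask * matrix(as.integer(near_j), nrow(labels), ncol(labels))
  }
  channel <- spec$background + posmask * (intensity - spec$background)
  channel <- add_noise_8bit(channel, spec$noise_sd)
  structure(list(channel = channel, positive_cells = positive, mask = posmask,
                 fraction_target = fraction, seed = seed),
            class = "marker_render")
}

#' Render a column-shifted phantom channel for cross-correlation tests
#'
#' Produces a second channel equal to the base translated downstream
#' (content moved right) by `offset` columns, padded with background and
#' given optional Gaussian noise. By construction the van Steensel curve of
#' (base, phantom) peaks at `+offset` on noiseless input.
#'
#' @param base Intensity matrix.
#' @param offset Integer column shift; `|offset|` must not exceed a quarter
#'   of the image width.
#' @param noise_sd Gaussian noise SD (default 0).
#' @param background Fill value for vacated columns.
#' @param seed Optional seed for the noise.
#' @return Intensity matrix of the same shape.
#' @export
render_ccf_phantom <- function(base, offset, noise_sd = 0, background = 20,
                               seed = NULL) {
  stopifnot(is.matrix(base))
  if (abs(offset) > ncol(base) / 4) stop("|offset| must be <= width / 4")
  if (!is.null(seed)) set.seed(seed)
  W <- ncol(base)
  out <- matrix(background, nrow(base), W)
  if (offset >= 0) {
    if (offset < W) out[, (offset + 1):W] <- base[, 1:(W - offset)]
  } else {
    out[, 1:(W + offset)] <- base[, (1 - offset):W]
  }
  add_noise_8bit(out, noise_sd)
}

#' Render a patchy extravasated-tracer (IgG) channel
#'
#' Thresholds a smoothed Gaussian random field at the quantile matching the
#' target area fraction, which yields spatially correlated patches covering
#' the requested fraction of the image to within one pixel in 10^4. The
#' field can be made anti-correlated with a marker mask (leakage avoiding
#' marker-positive regions) or left independent of it.
#'
#' @param mosaic A [generate_mosaic()] result (provides geometry, background
#'   and noise level).
#' @param fraction Target area fraction of tracer patches in \[0, 1\].
#' @param patch_scale Gaussian smoothing sigma in pixels; larger values give
#'   fewer, larger patches (default 15).
#' @param intensity Tracer intensity (0-255).
#' @param marker_mask Optional binary marker mask for `dependence = "anti"`.
#' @param dependence `"independent"` (default) or `"anti"`.
#' @param seed Integer seed.
#' @return List of class `igg_render`: `channel`, `mask`, `fraction_target`,
#'   `fraction_realized`, `seed`.
#' @export
render_igg <- function(mosaic, fraction, patch_scale = 15, intensity = 160,
                       marker_mask = NULL,
                       dependence = c("independent", "anti"), seed) {
  stopifnot(inherits(mosaic, "cell_mosaic"), fraction >= 0, fraction <= 1)
  dependence <- match.arg(dependence)
  set.seed(seed)
  spec <- mosaic$spec
  H <- spec$height; W <- spec$width
  if (fraction == 0) mask <- matrix(0L, H, W)
  else if (fraction == 1) mask <- matrix(1L, H, W)
  else {
    field <- EBImage::gblur(matrix(rnorm(H * W), H, W), sigma = patch_scale)
    field <- (field - mean(field)) / sd(field)
    if (dependence == "anti") {
      if (is.null(marker_mask)) stop("anti-correlation requires marker_mask")
      mk <- EBImage::gblur(as_mask_matrix(marker_mask) + 0, sigma = patch_scale)
      if (sd(mk) > 0) field <- field - 1.5 * (mk - mean(mk)) / sd(mk)
    }
    mask <- matrix(as.integer(field > quantile(field, 1 - fraction)), H, W)
  }
  channel <- spec$background + mask * (intensity - spec$background)
  channel <- add_noise_8bit(channel, spec$noise_sd)
  structure(list(channel = channel, mask = mask, fraction_target = fraction,
                 fraction_realized = mean(mask), seed = seed),
            class = "igg_render")
}

#' Simulate a complete synthetic endothelial sheet
#'
#' Convenience wrapper assembling a [channel_stack()] with a particle channel
#' (`veptp`), a junction channel (`vecad`) and, optionally, a mosaic marker
#' channel (`marker`) and a leakage channel (`igg`), together with the full
#' ground-truth manifest. Sub-seeds are derived from `seed` by fixed small
#' offsets, so a single integer reproduces the whole sheet bit-for-bit.
#'
#' @param spec A [sheet_spec()].
#' @param model A [particle_model()].
#' @param seed Integer master seed.
#' @param marker_fraction Optional fraction of marker-positive cells.
#' @param marker_localization Passed to [render_marker_mosaic()].
#' @param igg_fraction Optional tracer area fraction.
#' @param igg_dependence Passed to [render_igg()].
#' @param membrane_only Render only membrane particles (non-permeabilized
#'   specimen)?
#' @return List of class `synthetic_sheet` with elements `stack`
#'   (a [channel_stack()]) and `truth` (list: `labels`, `split_cols`,
#'   `particles` manifest, `marker`, `igg`, `spec`, `model`, `seed`).
#' @export
simulate_sheet <- function(spec, model = particle_model(), seed = 1,
                           marker_fraction = NULL,
                           marker_localization = "cytoplasm",
                           igg_fraction = NULL,
                           igg_dependence = "independent",
                           membrane_only = FALSE) {
  mosaic <- generate_mosaic(spec, seed)
  pr <- render_particles(mosaic, model, seed + 1L, membrane_only = membrane_only)
  channels <- list(veptp = pr$channel, vecad = mosaic$junction_channel)
  marker <- igg <- NULL
  if (!is.null(marker_fraction)) {
    marker <- render_marker_mosaic(mosaic, marker_fraction,
                                   localization = marker_localization,
                                   seed = seed + 2L)
    channels$marker <- marker$channel
  }
  if (!is.null(igg_fraction)) {
    igg <- render_igg(mosaic, igg_fraction,
                      marker_mask = if (is.null(marker)) NULL else marker$mask,
                      dependence = igg_dependence, seed = seed + 3L)
    channels$igg <- igg$channel
  }
  structure(list(
    stack = channel_stack(channels, calibration(spec$pixel_size, "synthetic")),
    truth = list(labels = mosaic$labels, split_cols = pr$split_cols,
                 particles = pr$manifest, collision = pr$collision,
                 marker = marker, igg = igg,
                 spec = spec, model = model, seed = seed)),
    class = "synthetic_sheet")
}

#' Simulate a permeabilized / non-permeabilized specimen pair
#'
#' Two independent sheets sharing one particle model: the permeabilized
#' specimen renders every particle, the non-permeabilized specimen only the
#' membrane-resident ones (per-bin membrane probabilities from the model).
#' The pair feeds [compartment_fractions()].
#'
#' @inheritParams simulate_sheet
#' @return List with `perm` and `nonperm`, each a `synthetic_sheet`.
#' @export
simulate_permeabilization_pair <- function(spec, model = particle_model(),
                                           seed = 1) {
  list(perm = simulate_sheet(spec, model, seed, membrane_only = FALSE),
       nonperm = simulate_sheet(spec, model, seed + 101L, membrane_only = TRUE))
}
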