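#' Count particles per size class
#'
#' Tabulates a particle table into per-class counts. The class counts always
#' sum to the total number of particles.
#'
#' @param particles A particle table from [label_particles()].
#' @param subdivide_large Use the four-level binning (large split at 200 px)?
#'   Requires the particle table to carry pixel counts (always true).
#' @return Data frame with columns `size_class` and `count`, one row per
#'   class (zero counts included).
#' @export
classify_and_count <- function(particles, subdivide_large = FALSE) {
  lv <- size_class_levels(subdivide_large)
  if (nrow(particles) == 0L) {
    return(data.frame(size_class = factor(lv, levels = lv),
                      count = integer(length(lv))))
  }
  cls <- size_class(particles$pixel_count, subdivide_large)
  data.frame(size_class = factor(lv, levels = lv),
             count = as.integer(table(cls)[lv]))
}

#' Assign particles to cells and cell halves by centroid
#'
#' Each particle is assigned to the cell whose label its centroid pixel
#' carries (centroid rounded to the nearest pixel; particles whose centroid
#' lands on junction/background get `cell = NA`). Within a cell the particle
#' is upstream if its centroid column is strictly below the cell's split
#' column, downstream otherwise — a centroid exactly on the split column
#' counts as downstream.
#'
#' @param particles Particle table from [label_particles()].
#' @param cells A `cell_map` from [segment_cells()].
#' @return The particle table with `cell` filled in and a `half` column
#'   (`"upstream"`/`"downstream"`, NA outside cells).
#' @export
assign_particles <- function(particles, cells) {
  stopifnot(inherits(cells, "cell_map"))
  if (nrow(particles) == 0L) {
    particles$half <- character(0)
    return(particles)
  }
  lab <- cells$labels
  r <- pmin(pmax(floor(particles$centroid_row + 0.5), 1L), nrow(lab))
  c_ <- pmin(pmax(floor(particles$centroid_col + 0.5), 1L), ncol(lab))
  cid <- lab[cbind(r, c_)]
  cid[cid == 0L] <- NA_integer_
  particles$cell <- cid
  split <- cells$cells$split_col[match(cid, cells$cells$id)]
  particles$half <- ifelse(is.na(cid), NA_character_,
                           ifelse(particles$centroid_col < split,
                                  "upstream", "downstream"))
  particles
}

#' Downstream-polarization percentage per size class
#'
#' Pools upstream/downstream particle counts over the sampled cells and
#' expresses, for each size class, the percentage of particles in the
#' downstream half. Counts are pooled before forming the percentage (no
#' per-cell averaging), so sparse classes never produce undefined per-cell
#' ratios; a class with no particles in the sampled cells is reported as
#' missing, not 0.
#'
#' @param particles Particle table with `cell` and `half` columns (see
#'   [assign_particles()]); assignment is performed on the fly if absent.
#' @param cells A `cell_map`.
#' @param cell_ids Cells to pool over, e.g. from [sample_cells()]. Default:
#'   all non-border cells.
#' @param subdivide_large Four-level binning?
#' @return Data frame with one row per size class: `size_class`, `n_up`,
#'   `n_down`, `downstream_pct` (NA when the class is empty) and `n_cells`.
#' @export
polarization <- function(particles, cells, cell_ids = NULL,
                         subdivide_large = FALSE) {
  stopifnot(inherits(cells, "cell_map"))
  if (is.null(particles$half)) particles <- assign_particles(particles, cells)
  if (is.null(cell_ids)) cell_ids <- cells$cells$id[!cells$cells$border]
  lv <- size_class_levels(subdivide_large)
  p <- particles[!is.na(particles$cell) & particles$cell %in% cell_ids, , drop = FALSE]
  cls <- size_class(p$pixel_count, subdivide_large)
  n_up <- n_down <- integer(length(lv))
  for (i in seq_along(lv)) {
    sel <- cls == lv[i]
    n_up[i] <- sum(p$half[sel] == "upstream")
    n_down[i] <- sum(p$half[sel] == "downstream")
  }
  tot <- n_up + n_down
  data.frame(size_class = factor(lv, levels = lv),
             n_up = n_up, n_down = n_down,
             downstream_pct = ifelse(tot > 0, 100 * n_down / tot, NA_real_),
             n_cells = length(cell_ids))
}

#' Percentage of cells containing at least one large particle
#'
#' The proportion of segmented cells that contain (by particle centroid) at
#' least one particle of the large size class (> 100 px).
#'
#' @inheritParams polarization
#' @param min_class Size class that qualifies (default `"large"`).
#' @return Percentage in \[0, 100\].
#' @export
percent_cells_with_large <- function(particles, cells, min_class = "large") {
  stopifnot(inherits(cells, "cell_map"))
  n_cells <- nrow(cells$cells)
  if (n_cells == 0L) stop("cell map contains no cells")
  if (is.null(particles$half)) particles <- assign_particles(particles, cells)
  sel <- !is.na(particles$cell) &
    as.character(size_class(particles$pixel_count)) == min_class
  100 * length(unique(particles$cell[sel])) / n_cells
}

#' Particles per endothelial cell
#'
#' Total particle count divided by the number of segmented cells (all
#' counted cells, not only the sampled subset).
#'
#' @inheritParams polarization
#' @return Numeric scalar.
#' @export
particles_per_cell <- function(particles, cells) {
  stopifnot(inherits(cells, "cell_map"))
  n_cells <- nrow(cells$cells)
  if (n_cells == 0L) stop("cell map contains no cells")
  nrow(particles) / n_cells
}

#' Membrane fraction per size bin from a permeabilization pair
#'
#' Compares particle counts from a permeabilized specimen (all particles
#' stained) with a non-permeabilized specimen (only plasma-membrane particles
#' stained) to estimate, per size bin, the percentage of particles residing
#' in the plasma membrane: `100 * nonperm / perm`. The comparison pairs
#' different specimens, so it operates on per-image aggregate counts — never
#' on matched particles. Fractions can exceed 100 under sampling noise and
#' are then reported as-is with `flagged = TRUE`.
#'
#' @param perm Counts from the permeabilized image: output of
#'   [classify_and_count()] with `subdivide_large = TRUE` (both inputs must
#'   use the same threshold — 100 for this assay — and the same bins).
#' @param nonperm Same for the non-permeabilized image.
#' @return Data frame per bin: `size_class`, `n_perm`, `n_nonperm`,
#'   `membrane_pct` (NA when the permeabilized count is 0), `flagged`.
#' @export
compartment_fractions <- function(perm, nonperm) {
  if (!identical(as.character(perm$size_class), as.character(nonperm$size_class)))
    stop("perm and nonperm must use identical size bins")
  frac <- ifelse(perm$count > 0, 100 * nonperm$count / perm$count, NA_real_)
  data.frame(size_class = perm$size_class,
             n_perm = perm$count, n_nonperm = nonperm$count,
             membrane_pct = frac,
             flagged = !is.na(frac) & frac > 100)
}
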