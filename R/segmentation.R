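#' Binarize an intensity channel
#'
#' Thresholds a channel with a strict `>` comparison: a pixel enters the mask
#' iff its intensity is strictly above `threshold` (an intensity "above" the
#' threshold). The default threshold of 60 on the 0-255 scale is the standard
#' setting for particle, junction and leakage channels; the permeabilization
#' comparison uses 100.
#'
#' @param x An intensity matrix, or a [channel_stack()] together with
#'   `channel`.
#' @param threshold Integer threshold in \[0, 255\].
#' @param channel Channel name, required when `x` is a `channel_stack`.
#' @return A `binary_mask`: an integer 0/1 matrix with attributes
#'   `threshold` and `source`.
#' @examples
#' m <- matrix(c(60, 61), 1)
#' binarize(m, 60) # only the 61-pixel survives
#' @export
binarize <- function(x, threshold = 60, channel = NULL) {
  if (inherits(x, "channel_stack")) {
    if (is.null(channel)) stop("supply `channel` when binarizing a channel_stack")
    src <- channel
    x <- get_channel(x, channel)
  } else src <- NA_character_
  stopifnot(is.matrix(x))
  if (threshold < 0 || threshold > 255) stop("threshold must be in [0, 255]")
  mask <- matrix(as.integer(x > threshold), nrow(x), ncol(x))
  structure(mask, threshold = threshold, source = src,
            class = c("binary_mask", class(mask)))
}

as_mask_matrix <- function(mask) {
  stopifnot(is.matrix(mask))
  if (any(mask != 0 & mask != 1)) stop("mask must be binary (0/1)")
  mask
}

#' Area density of a mask within a region of interest
#'
#' The field's standard "area density (%)": the percentage of ROI pixels
#' that are set in the mask.
#'
#' @param mask A binary 0/1 matrix (e.g. from [binarize()]).
#' @param roi Optional binary ROI matrix of the same shape; defaults to the
#'   whole image.
#' @return Percentage in \[0, 100\].
#' @export
area_density <- function(mask, roi = NULL) {
  mask <- as_mask_matrix(mask)
  if (is.null(roi)) return(100 * sum(mask) / length(mask))
  roi <- as_mask_matrix(roi)
  if (!identical(dim(mask), dim(roi))) stop("mask and roi dimensions differ")
  n_roi <- sum(roi)
  if (n_roi == 0) stop("ROI is empty")
  100 * sum(mask * roi) / n_roi
}

# Connected-component labeling. 4-connectivity delegates to EBImage::bwlabel;
# 8-connectivity builds the pixel adjacency graph (orthogonal + diagonal
# neighbour pairs) and labels components with igraph.
label_components <- function(mask, connectivity = 8) {
  mask <- as_mask_matrix(mask)
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  if (connectivity == 4) {
    lab <- EBImage::bwlabel(mask)
    return(matrix(as.integer(lab), nrow(mask), ncol(mask)))
  }
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask == 1L)
  lab <- matrix(0L, nr, nc)
  if (length(fg) == 0L) return(lab)
  id <- integer(nr * nc)
  id[fg] <- seq_along(fg)
  logi <- mask == 1L
  edge_pairs <- function(from_sel, to_off) {
    a <- which(from_sel)
    cbind(id[a], id[a + to_off])
  }
  # neighbour offsets: down (+1), right (+nr), down-right (+nr+1), up-right (+nr-1)
  down  <- logi; down[nr, ] <- FALSE
  down  <- down & rbind(logi[-1, , drop = FALSE], FALSE)
  right <- logi; right[, nc] <- FALSE
  right <- right & cbind(logi[, -1, drop = FALSE], FALSE)
  dr <- logi; dr[nr, ] <- FALSE; dr[, nc] <- FALSE
  dr <- dr & rbind(cbind(logi[-1, -1, drop = FALSE], FALSE), FALSE)
  ur <- logi; ur[1, ] <- FALSE; ur[, nc] <- FALSE
  ur <- ur & rbind(FALSE, cbind(logi[-nr, -1, drop = FALSE], FALSE))
  ee <- rbind(edge_pairs(down, 1L), edge_pairs(right, nr),
              edge_pairs(dr, nr + 1L), edge_pairs(ur, nr - 1L))
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (nrow(ee) > 0L) g <- igraph::add_edges(g, t(ee))
  memb <- igraph::components(g)$membership
  lab[fg] <- as.integer(memb)
  lab
}

#' Detect particles as connected components of a binary mask
#'
#' Labels connected components (default 8-connectivity, the common
#' particle-analysis convention) and returns one record per particle with
#' pixel count, centroid (arithmetic mean of member pixel coordinates,
#' 1-based), size class and, when a calibration is given, the equivalent
#' circular diameter in µm.
#'
#' @param mask A binary 0/1 matrix (e.g. from [binarize()]).
#' @param connectivity 8 (default) or 4.
#' @param calibration Optional [calibration()] for diameters.
#' @param subdivide_large Split the large size class at 200 px?
#' @return A data frame with columns `id`, `pixel_count`, `centroid_row`,
#'   `centroid_col`, `size_class`, `diameter_um` (NA without calibration)
#'   and `cell` (NA until assigned with [assign_particles()]); the label
#'   matrix is attached as attribute `labels`.
#' @export
label_particles <- function(mask, connectivity = 8, calibration = NULL,
                            subdivide_large = FALSE) {
  lab <- label_components(mask, connectivity)
  n <- max(lab)
  if (n == 0L) {
    out <- data.frame(id = integer(), pixel_count = integer(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      size_class = size_class(1, subdivide_large)[0],
                      diameter_um = numeric(), cell = integer())
    attr(out, "labels") <- lab
    return(out)
  }
  fg <- which(lab > 0L)
  l <- lab[fg]
  cnt <- tabulate(l, nbins = n)
  rows <- ((fg - 1L) %% nrow(lab)) + 1L
  cols <- ((fg - 1L) %/% nrow(lab)) + 1L
  cr <- rowsum(as.numeric(rows), l)[, 1] / cnt
  cc <- rowsum(as.numeric(cols), l)[, 1] / cnt
  out <- data.frame(id = seq_len(n), pixel_count = cnt,
                    centroid_row = as.numeric(cr), centroid_col = as.numeric(cc),
                    size_class = size_class(cnt, subdivide_large),
                    diameter_um = if (is.null(calibration)) NA_real_
                                  else equivalent_diameter(cnt, calibration),
                    cell = NA_integer_)
  attr(out, "labels") <- lab
  out
}

#' Segment endothelial cells from a junction mask
#'
#' Cells are the connected components (4-connectivity, so single-pixel
#' diagonal junction lines still separate neighbours) of the complement of
#' the junction mask. Components smaller than `min_area` — speckle "cells"
#' and small holes inside junction lines — are merged back into the
#' background. Components touching the image border are flagged and, if
#' `exclude_border = TRUE`, removed. Each retained cell gets an
#' upstream/downstream split coordinate at its area-centroid column.
#'
#' @param junction_mask Binary junction mask (e.g. [binarize()] of a
#'   VE-cadherin channel at threshold 60-100).
#' @param min_area Minimum cell area in pixels (default 200 px, ~3 µm² at
#'   0.124 µm/px).
#' @param exclude_border Drop border-touching components from the label map?
#' @return A `cell_map`: list with `labels` (matrix, 0 = junction/background,
#'   k >= 1 = cell k) and `cells` (data frame: `id`, `area`, `centroid_row`,
#'   `centroid_col`, `col_min`, `col_max`, `split_col`, `border`), plus
#'   bookkeeping counts `junction_px` and `discarded_px` for pixel-conservation
#'   checks.
#' @export
segment_cells <- function(junction_mask, min_area = 200, exclude_border = FALSE) {
  junction_mask <- as_mask_matrix(junction_mask)
  comp <- 1L - junction_mask
  lab <- label_components(comp, connectivity = 4)
  n <- max(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  if (n == 0L) {
    return(structure(list(labels = lab, cells = empty_cell_table(),
                          junction_px = sum(junction_mask), discarded_px = 0L),
                     class = "cell_map"))
  }
  fg <- which(lab > 0L)
  l <- lab[fg]
  area <- tabulate(l, nbins = n)
  border_ids <- unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc]))
  border <- seq_len(n) %in% border_ids[border_ids > 0L]
  keep <- area >= min_area & !(exclude_border & border)
  # relabel kept cells 1..K in original label order
  new_id <- integer(n)
  new_id[keep] <- seq_len(sum(keep))
  lab2 <- lab
  lab2[fg] <- new_id[l]
  discarded <- sum(area[!keep])
  if (!any(keep)) {
    return(structure(list(labels = lab2, cells = empty_cell_table(),
                          junction_px = sum(junction_mask),
                          discarded_px = discarded),
                     class = "cell_map"))
  }
  fg2 <- fg[new_id[l] > 0L]
  l2 <- lab2[fg2]
  k <- max(l2)
  cnt <- tabulate(l2, nbins = k)
  rows <- ((fg2 - 1L) %% nr) + 1L
  cols <- ((fg2 - 1L) %/% nr) + 1L
  cr <- rowsum(as.numeric(rows), l2)[, 1] / cnt
  cc <- rowsum(as.numeric(cols), l2)[, 1] / cnt
  col_min <- tapply(cols, l2, min)
  col_max <- tapply(cols, l2, max)
  cells <- data.frame(id = seq_len(k), area = cnt,
                      centroid_row = as.numeric(cr), centroid_col = as.numeric(cc),
                      col_min = as.integer(col_min), col_max = as.integer(col_max),
                      split_col = as.numeric(cc),
                      border = border[keep])
  structure(list(labels = lab2, cells = cells,
                 junction_px = sum(junction_mask), discarded_px = discarded),
            class = "cell_map")
}

empty_cell_table <- function() {
  data.frame(id = integer(), area = integer(), centroid_row = numeric(),
             centroid_col = numeric(), col_min = integer(), col_max = integer(),
             split_col = numeric(), border = logical())
}

#' @export
print.cell_map <- function(x, ...) {
  cat(sprintf("<cell_map> %d cell(s), %d x %d px\n",
              nrow(x$cells), nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Select spatially stratified cells for per-cell statistics
#'
#' Emulates choosing "uniformly distributed" cells across the field: the
#' image is divided into a tile grid (2 x 4 for the default k = 8), tiles are
#' visited in row-major order, and each tile takes the eligible
#' (non-border) cell whose centroid is nearest the tile centre among cells
#' not yet chosen; ties go to the lower cell id. The rule is fully
#' deterministic; `seed` is accepted for interface symmetry with the
#' stochastic generators and ignored.
#'
#' @param cells A `cell_map` from [segment_cells()].
#' @param k Number of cells to select (default 8).
#' @param seed Ignored (the rule is deterministic); kept for API symmetry.
#' @param grid Tile grid as `c(rows, cols)`; defaults to 2 x 4 for k = 8,
#'   otherwise a near-square grid with at least k tiles.
#' @return Integer vector of k cell ids.
#' @export
sample_cells <- function(cells, k = 8, seed = NULL, grid = NULL) {
  stopifnot(inherits(cells, "cell_map"))
  tab <- cells$cells
  eligible <- tab[!tab$border, , drop = FALSE]
  if (nrow(eligible) < k)
    stop(sprintf("only %d eligible (non-border) cells for k = %d", nrow(eligible), k))
  if (is.null(grid)) {
    if (k == 8) grid <- c(2L, 4L)
    else {
      r <- max(1L, floor(sqrt(k)))
      grid <- c(r, ceiling(k / r))
    }
  }
  nr <- nrow(cells$labels); nc <- ncol(cells$labels)
  tile_centres <- expand.grid(
    row = (seq_len(grid[1]) - 0.5) * nr / grid[1],
    col = (seq_len(grid[2]) - 0.5) * nc / grid[2]
  )
  # row-major visiting order (expand.grid varies rows fastest -> reorder)
  tile_centres <- tile_centres[order(rep(seq_len(grid[1]), grid[2])), , drop = FALSE]
  row_edges <- nr / grid[1]; col_edges <- nc / grid[2]
  chosen <- integer(0)
  for (t in seq_len(min(k, nrow(tile_centres)))) {
    avail <- eligible[!eligible$id %in% chosen, , drop = FALSE]
    # prefer centroids lying inside the tile; fall back to the global nearest
    inside <- ceiling(avail$centroid_row / row_edges) ==
      ceiling(tile_centres$row[t] / row_edges) &
      ceiling(avail$centroid_col / col_edges) ==
      ceiling(tile_centres$col[t] / col_edges)
    pool <- if (any(inside)) avail[inside, , drop = FALSE] else avail
    d2 <- (pool$centroid_row - tile_centres$row[t])^2 +
          (pool$centroid_col - tile_centres$col[t])^2
    chosen <- c(chosen, pool$id[order(d2, pool$id)][1])
  }
  chosen
}

#' Split a cell into upstream and downstream halves
#'
#' Splits a cell mask at its area-centroid column: pixels with column index
#' strictly below the (fractional) split coordinate are upstream, the rest
#' downstream. The halves partition the cell exactly.
#'
#' @param cell_mask Binary 0/1 matrix of one cell (e.g.
#'   `cells$labels == id`).
#' @return List with binary matrices `upstream` and `downstream` and the
#'   numeric `split_col`.
#' @export
split_cell <- function(cell_mask) {
  m <- as_mask_matrix(cell_mask * 1L)
  if (sum(m) == 0) stop("cell mask is empty")
  cols <- col(m)
  s <- sum(cols * m) / sum(m)
  up <- m * (cols < s)
  down <- m * (cols >= s)
  list(upstream = up, downstream = down, split_col = s)
}
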