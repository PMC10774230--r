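make_particles <- function(sizes) {
  n <- length(sizes)
  data.frame(id = seq_len(n), pixel_count = sizes,
             centroid_row = rep(1, n), centroid_col = rep(1, n),
             size_class = if (n) size_class(sizes) else size_class(1)[0],
             diameter_um = rep(NA_real_, n), cell = rep(NA_integer_, n))
}

test_that("class counting respects bin boundaries and sums to the total", {
  cc <- classify_and_count(make_particles(c(3, 10, 11, 100, 101)))
  expect_equal(cc$count, c(2L, 2L, 1L))
  expect_equal(sum(cc$count), 5L)
  cc0 <- classify_and_count(make_particles(integer(0)))
  expect_equal(cc0$count, c(0L, 0L, 0L))
  cc4 <- classify_and_count(make_particles(c(150, 201, 250)),
                            subdivide_large = TRUE)
  expect_equal(cc4$count, c(0L, 0L, 1L, 2L))
})

test_that("polarization pools counts over sampled cells, 100% when all downstream", {
  # two rectangular cells separated by a junction column
  jm <- matrix(0L, 20, 41); jm[, 21] <- 1L
  cm <- segment_cells(jm, min_area = 10)
  expect_equal(nrow(cm$cells), 2)
  # all particles right of each cell's centroid column
  p <- data.frame(id = 1:4, pixel_count = c(5, 50, 5, 120),
                  centroid_row = c(5, 10, 6, 11),
                  centroid_col = c(18, 19, 38, 39),
                  size_class = size_class(c(5, 50, 5, 120)),
                  diameter_um = NA_real_, cell = NA_integer_)
  pol <- polarization(p, cm, cell_ids = cm$cells$id)
  expect_equal(pol$downstream_pct, c(100, 100, 100))
  # a class with no particles is missing, not zero
  p2 <- p[p$pixel_count < 100, ]
  pol2 <- polarization(p2, cm, cell_ids = cm$cells$id)
  expect_true(is.na(pol2$downstream_pct[3]))
  expect_equal(pol2$n_up + pol2$n_down, c(2L, 1L, 0L))
})

test_that("a centroid exactly on the split column counts as downstream", {
  jm <- matrix(0L, 10, 21)           # one cell spanning all columns
  cm <- segment_cells(jm, min_area = 10)
  s <- cm$cells$split_col[1]
  p <- make_particles(c(5, 5))
  p$centroid_row <- c(5, 5)
  p$centroid_col <- c(s, s - 0.6)
  p <- assign_particles(p, cm)
  expect_equal(p$half, c("downstream", "upstream"))
})

test_that("pooled polarization equals a brute-force recount over half masks", {
  sp <- tiny_sheet_spec()
  sh <- simulate_sheet(sp, particle_model(mean_small = 6, mean_medium = 3),
                       seed = 31)
  cm <- segment_cells(binarize(sh$stack$vecad, 60))
  pt <- assign_particles(label_particles(binarize(sh$stack$veptp, 60)), cm)
  ids <- sample_cells(cm, k = 8)
  pol <- polarization(pt, cm, ids)
  # brute force: recount per cell from the half masks
  for (cls in c("small", "medium", "large")) {
    up <- down <- 0L
    for (k in ids) {
      halves <- split_cell(cm$labels == k)
      sel <- !is.na(pt$cell) & pt$cell == k &
        as.character(pt$size_class) == cls
      for (i in which(sel)) {
        if (pt$centroid_col[i] < halves$split_col) up <- up + 1L
        else down <- down + 1L
      }
    }
    row <- pol[pol$size_class == cls, ]
    expect_equal(row$n_up, up)
    expect_equal(row$n_down, down)
    if (up + down > 0)
      expect_equal(row$downstream_pct, 100 * down / (up + down))
  }
  # upstream + downstream = total in-cell count per class
  in_cells <- pt[!is.na(pt$cell) & pt$cell %in% ids, ]
  expect_equal(sum(pol$n_up + pol$n_down), nrow(in_cells))
})

test_that("percent of cells with large particles covers the edge cases", {
  jm <- matrix(0L, 20, 41); jm[, 21] <- 1L
  cm <- segment_cells(jm, min_area = 10)
  p <- make_particles(c(150, 200))
  p$centroid_row <- c(10, 10); p$centroid_col <- c(10, 30)
  expect_equal(percent_cells_with_large(p, cm), 100)
  p_small <- make_particles(c(5, 9))
  p_small$centroid_row <- c(10, 10); p_small$centroid_col <- c(10, 30)
  expect_equal(percent_cells_with_large(p_small, cm), 0)
})

test_that("compartment fractions are ratios per bin with scale invariance", {
  lv <- c("small", "medium", "large_101_200", "large_gt200")
  counts <- function(v) data.frame(size_class = factor(lv, levels = lv),
                                   count = as.integer(v))
  same <- compartment_fractions(counts(c(40, 30, 20, 10)),
                                counts(c(40, 30, 20, 10)))
  expect_equal(same$membrane_pct, rep(100, 4))
  zero <- compartment_fractions(counts(c(40, 30, 20, 10)), counts(c(0, 0, 0, 0)))
  expect_equal(zero$membrane_pct, rep(0, 4))
  a <- compartment_fractions(counts(c(100, 80, 60, 40)), counts(c(36, 22, 22, 36)))
  b <- compartment_fractions(counts(2 * c(100, 80, 60, 40)),
                             counts(2 * c(36, 22, 22, 36)))
  expect_equal(a$membrane_pct, b$membrane_pct)
  # empty permeabilized bin is missing; >100% is flagged, not clipped
  odd <- compartment_fractions(counts(c(0, 10, 10, 10)), counts(c(5, 12, 10, 9)))
  expect_true(is.na(odd$membrane_pct[1]))
  expect_equal(odd$membrane_pct[2], 120)
  expect_true(odd$flagged[2])
})

test_that("membrane fractions are recovered from a permeabilization pair", {
  sp <- sheet_spec(width = 640, height = 640, n_cells = 140,
                   vessel = "vena_cava")
  pair <- simulate_permeabilization_pair(sp, particle_model(pi_large = 0.7),
                                         seed = 17)
  cnt <- function(sheet) classify_and_count(
    label_particles(binarize(sheet$stack$veptp, 100)), subdivide_large = TRUE)
  cf <- compartment_fractions(cnt(pair$perm), cnt(pair$nonperm))
  mf <- pair$perm$truth$model$membrane_fraction
  for (i in seq_len(4)) {
    # the two specimens are independent renders, so the ratio carries both
    # Poisson count noise and binomial membrane-thinning noise (delta method)
    lam <- cf$n_perm[i]
    # family-wise 99% over the four bins (Bonferroni z = 3.02)
    band <- 302 * sqrt(mf[i]^2 * 2 / lam + mf[i] * (1 - mf[i]) / lam)
    expect_lt(abs(cf$membrane_pct[i] - 100 * mf[i]), band)
  }
  # the >200 px bin is predominantly membrane, the cytoplasmic bins are not
  expect_gt(cf$membrane_pct[4], cf$membrane_pct[2])
})
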