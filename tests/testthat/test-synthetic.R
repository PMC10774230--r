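test_that("the generator is bit-deterministic in its seed", {
  sp <- tiny_sheet_spec()
  a <- simulate_sheet(sp, particle_model(mean_small = 4, mean_medium = 2),
                      seed = 5, marker_fraction = 0.4, igg_fraction = 0.3)
  b <- simulate_sheet(sp, particle_model(mean_small = 4, mean_medium = 2),
                      seed = 5, marker_fraction = 0.4, igg_fraction = 0.3)
  expect_identical(a$stack$veptp, b$stack$veptp)
  expect_identical(a$stack$vecad, b$stack$vecad)
  expect_identical(a$stack$marker, b$stack$marker)
  expect_identical(a$stack$igg, b$stack$igg)
  expect_identical(a$truth$particles, b$truth$particles)
  c_ <- simulate_sheet(sp, particle_model(mean_small = 4, mean_medium = 2),
                       seed = 6)
  expect_false(identical(a$stack$veptp, c_$stack$veptp))
})

test_that("the label map hosts exactly the requested number of cells", {
  sp <- tiny_sheet_spec(n_cells = 50, width = 400, height = 400)
  mo <- generate_mosaic(sp, seed = 2)
  expect_equal(sort(unique(as.vector(mo$labels))), 1:50)
  expect_true(all(tabulate(mo$labels) > 0))
})

test_that("isotropic and elongated tessellations differ in cell aspect", {
  aspect <- function(mo) {
    mean(vapply(seq_len(max(mo$labels)), function(k) {
      ix <- which(mo$labels == k, arr.ind = TRUE)
      (diff(range(ix[, 2])) + 1) / (diff(range(ix[, 1])) + 1)
    }, numeric(1)))
  }
  iso <- generate_mosaic(sheet_spec(width = 420, height = 420, n_cells = 50,
                                    elongation = 1), seed = 3)
  expect_lt(abs(aspect(iso) - 1), 0.2)
  ao <- generate_mosaic(sheet_spec(width = 420, height = 420, n_cells = 50,
                                   vessel = "aorta"), seed = 3)
  expect_gt(aspect(ao), 2)
})

test_that("rendered intensities respect the 8-bit range and thresholds", {
  sp <- tiny_sheet_spec()
  sh <- simulate_sheet(sp, particle_model(mean_small = 4, mean_medium = 2),
                       seed = 12)
  for (ch in sh$stack) {
    expect_true(all(ch >= 0 & ch <= 255))
    expect_true(all(ch == round(ch)))
  }
  # particle disks stay above threshold 100, background below 60, post-noise
  tr <- sh$truth$particles
  centers <- cbind(tr$center_row, tr$center_col)
  expect_true(all(sh$stack$veptp[centers] > 100))
  expect_lt(area_density(binarize(sh$stack$veptp, 60)), 15)
})

test_that("q = 1 places every medium particle in the true downstream half", {
  sp <- tiny_sheet_spec()
  mo <- generate_mosaic(sp, seed = 13)
  pr <- render_particles(mo, particle_model(q_medium = 1, pi_large = 0),
                         seed = 14)
  med <- pr$manifest[pr$manifest$class == "medium", ]
  expect_gt(nrow(med), 50)
  expect_true(all(med$downstream))
  expect_true(all(med$center_col >= pr$split_cols[med$cell]))
})

test_that("a symmetric model measures 50% downstream within the binomial bound", {
  sp <- sheet_spec(width = 640, height = 640, n_cells = 140,
                   vessel = "vena_cava")
  sh <- simulate_sheet(sp, particle_model(q_medium = 0.5, pi_large = 0),
                       seed = 15)
  cm <- segment_cells(binarize(sh$stack$vecad, 60))
  pt <- assign_particles(label_particles(binarize(sh$stack$veptp, 60)), cm)
  pol <- polarization(pt, cm)
  for (i in 1:2) {  # small and medium classes both symmetric here
    n <- pol$n_up[i] + pol$n_down[i]
    expect_lt(abs(pol$downstream_pct[i] - 50), 300 * sqrt(0.25 / n))
  }
})

test_that("tip particles sit at the downstream cell tip against the junction", {
  sp <- tiny_sheet_spec()
  mo <- generate_mosaic(sp, seed = 16)
  # pi = 1: every cell carries exactly one downstream tip particle
  pr <- render_particles(mo, particle_model(pi_large = 1, mean_small = 0,
                                            mean_medium = 0), seed = 17)
  expect_equal(sort(unique(pr$manifest$cell)), 1:40)
  expect_true(all(pr$manifest$tip))
  expect_true(all(pr$manifest$downstream))
  # moderate pi: mutual-exclusion pushes are rare, so the geometry is clean
  pr2 <- render_particles(mo, particle_model(pi_large = 0.5, mean_small = 0,
                                             mean_medium = 0), seed = 18)
  tips <- pr2$manifest
  expect_gt(nrow(tips), 10)
  # image-border margins legitimately pull border-cell tips inward; the
  # geometry contract applies to interior cells
  dist_tip <- overlaps <- numeric(0)
  for (i in seq_len(nrow(tips))) {
    cellpix <- which(mo$labels == tips$cell[i], arr.ind = TRUE)
    interior <- min(cellpix) > 12 && max(cellpix[, 1]) < nrow(mo$labels) - 12 &&
      max(cellpix[, 2]) < ncol(mo$labels) - 12
    if (!interior) next
    dist_tip <- c(dist_tip, max(cellpix[, 2]) - tips$center_col[i])
    o <- endomosaic:::disk_offsets(tips$radius[i])
    overlaps <- c(overlaps,
                  sum(mo$junction_mask[cbind(tips$center_row[i] + o[, 1],
                                             tips$center_col[i] + o[, 2])]))
  }
  expect_gte(mean(dist_tip <= 4), 0.9)
  expect_true(all(overlaps > 0))
})

test_that("marker mosaics hit the target fraction and cluster when contiguous", {
  sp <- tiny_sheet_spec(n_cells = 50, width = 400, height = 400)
  mo <- generate_mosaic(sp, seed = 18)
  all_pos <- render_marker_mosaic(mo, 1, seed = 19)
  expect_equal(all_pos$positive_cells, 1:50)
  none <- render_marker_mosaic(mo, 0, seed = 19)
  expect_equal(length(none$positive_cells), 0)
  expect_equal(sum(none$mask), 0)
  half <- render_marker_mosaic(mo, 0.5, seed = 19)
  expect_equal(length(half$positive_cells), 25)
  # cluster growth produces fewer connected clusters than independent picks
  adj <- local({
    l <- mo$labels
    p <- rbind(cbind(as.vector(l[, -1]), as.vector(l[, -ncol(l)])),
               cbind(as.vector(l[-1, ]), as.vector(l[-nrow(l), ])))
    p <- p[p[, 1] != p[, 2], , drop = FALSE]
    unique(cbind(pmin(p[, 1], p[, 2]), pmax(p[, 1], p[, 2])))
  })
  g <- igraph::graph_from_edgelist(adj, directed = FALSE)
  n_clusters <- function(cells) {
    sub <- igraph::induced_subgraph(g, cells)
    igraph::components(sub)$no
  }
  wins <- 0
  for (s in 1:10) {
    contig <- render_marker_mosaic(mo, 0.5, contiguity = 1, seed = 100 + s)
    indep <- render_marker_mosaic(mo, 0.5, contiguity = 0, seed = 200 + s)
    if (n_clusters(contig$positive_cells) < n_clusters(indep$positive_cells))
      wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("junction-localized marker staining stays near the junction lines", {
  sp <- tiny_sheet_spec(n_cells = 30)
  mo <- generate_mosaic(sp, seed = 20)
  jm <- render_marker_mosaic(mo, 0.5, localization = "junction", seed = 21,
                             halo = 2)
  frac <- junctional_fraction(jm$mask, mo$junction_mask)
  expect_gt(frac, 30)  # much of the stain overlaps the lines themselves
  # and the complement of a generous junction halo holds none of it
  brush <- EBImage::makeBrush(5L, "disc")
  near <- matrix(as.integer(EBImage::dilate(mo$junction_mask, brush) > 0),
                 nrow(mo$labels), ncol(mo$labels))
  expect_equal(sum(jm$mask * (1L - near)), 0)
})

test_that("IgG patch fractions are realized to within rasterization error", {
  sp <- tiny_sheet_spec()
  mo <- generate_mosaic(sp, seed = 22)
  for (f in c(0.31, 0.92)) {
    ig <- render_igg(mo, f, seed = 23)
    expect_lt(abs(ig$fraction_realized - f), 0.001)
    measured <- area_density(binarize(ig$channel, 60))
    expect_lt(abs(measured - 100 * f), 2)
  }
  expect_equal(render_igg(mo, 0, seed = 23)$fraction_realized, 0)
  expect_equal(render_igg(mo, 1, seed = 23)$fraction_realized, 1)
  # anti-correlated leakage avoids the marker stratum
  mk <- render_marker_mosaic(mo, 0.5, seed = 24)
  anti <- render_igg(mo, 0.3, marker_mask = mk$mask, dependence = "anti",
                     seed = 25)
  lr <- density_by_marker(anti$mask, mk$mask)
  expect_lt(lr$with_marker_pct, lr$without_marker_pct)
})

test_that("permeabilization pairs thin each bin by its membrane fraction", {
  sp <- tiny_sheet_spec()
  pair <- simulate_permeabilization_pair(sp, particle_model(), seed = 26)
  man <- pair$nonperm$truth$particles
  expect_true(all(man$rendered == man$membrane))
  expect_true(all(pair$perm$truth$particles$rendered))
})
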