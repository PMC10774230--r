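test_that("heterogeneity summaries follow the sample-SD definitions", {
  h <- heterogeneity(c(1, 2, 3))
  expect_equal(h$mean, 2)
  expect_equal(h$sd, 1)
  expect_equal(h$cv_pct, 50)
  expect_equal(h$sem, 1 / sqrt(3))
  expect_equal(heterogeneity(rep(4.2, 6))$cv_pct, 0)
  expect_true(is.na(heterogeneity(c(-1, 1))$cv_pct))
  expect_error(heterogeneity(5), "at least 2")
})

test_that("a known coefficient of variation is recovered from noisy densities", {
  # gamma-distributed region densities with true CV 60% (shape = 1/0.36)
  set.seed(14)
  x <- rgamma(200, shape = 1 / 0.36, rate = 1)
  cv_hat <- heterogeneity(x)$cv_pct
  boots <- replicate(400, heterogeneity(sample(x, replace = TRUE))$cv_pct)
  ci <- quantile(boots, c(0.005, 0.995))
  expect_gte(60, ci[[1]])
  expect_lte(60, ci[[2]])
  expect_lt(abs(cv_hat - 60), 15)
})

test_that("simple regression is exact on a line and matches normal equations", {
  x <- c(1, 2, 3, 4, 5)
  fit <- ols_fit(x, 2 * x + 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)
  set.seed(15)
  x10 <- runif(10, 0, 50)
  y10 <- 3.2 * x10 + rnorm(10, sd = 8)
  fit10 <- ols_fit(x10, y10)
  oracle <- ols_normal_equations(x10, y10)
  expect_equal(fit10$slope, oracle$slope, tolerance = 1e-10)
  expect_equal(fit10$intercept, oracle$intercept, tolerance = 1e-10)
  expect_equal(fit10$r_squared, oracle$r_squared, tolerance = 1e-10)
  expect_equal(fit10$p_value, oracle$p_value, tolerance = 1e-10)
  # R^2 equals the squared Pearson correlation in simple regression
  expect_equal(fit10$r_squared, cor(x10, y10)^2, tolerance = 1e-12)
  expect_error(ols_fit(rep(1, 5), 1:5), "constant")
  expect_error(ols_fit(1:2, 1:2), "at least 3")
})

test_that("slope p-values are uniform when y is independent of x", {
  set.seed(16)
  p <- replicate(600, ols_fit(1:15, rnorm(15))$p_value)
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("KS statistic matches the brute-force sweep and its edge cases", {
  a <- c(1, 2, 2, 3.5, 7, 7, 9, 10)
  b <- c(0.5, 2, 4, 4, 6.5, 8, 9, 12)
  ks <- ks_two_sample(a, b)
  expect_equal(ks$D, ks_brute_D(a, b))
  expect_equal(ks_two_sample(a, a)$D, 0)
  expect_equal(ks_two_sample(1:4, 11:14)$D, 1)
  expect_error(ks_two_sample(numeric(0), 1:3), "non-empty")
})

test_that("KS matches exhaustive enumeration for all small samples over {0,1,2}", {
  multisets <- function(n) {
    grid <- expand.grid(rep(list(0:2), n))
    unique(t(apply(grid, 1, sort)))
  }
  sets <- lapply(1:4, multisets)
  for (na in 1:4) for (nb in 1:4) {
    A <- sets[[na]]; B <- sets[[nb]]
    for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
      a <- as.numeric(A[i, ]); b <- as.numeric(B[j, ])
      expect_equal(ks_two_sample(a, b)$D, ks_brute_D(a, b))
    }
  }
})

test_that("band profiles tile the panorama and preserve pooled density", {
  set.seed(17)
  pan <- matrix(30, 80, 1200)
  pan[sample(length(pan), 20000)] <- 150
  stack <- channel_stack(list(veptp = pan), calibration(0.132))
  bp <- band_profile(stack, "veptp", thresholds = 60, band_length = 300)
  expect_equal(nrow(bp), 4)
  pooled <- sum(bp$area_density_pct * attr(bp, "band_px")) /
    (4 * attr(bp, "band_px"))
  expect_equal(pooled, area_density(binarize(pan, 60)))
  # a constructed step lands in the right band
  step <- matrix(30, 60, 900); step[, 301:600] <- 200
  sstack <- channel_stack(list(cl5 = step), calibration(0.132))
  sb <- band_profile(sstack, "cl5", band_length = 300)
  expect_equal(sb$area_density_pct, c(0, 100, 0))
  # uniform panorama: flat profile
  flat <- band_profile(channel_stack(list(x = matrix(100, 50, 600)), 0.1),
                       "x", band_length = 200)
  expect_equal(sd(flat$area_density_pct), 0)
  expect_error(band_profile(sstack, "cl5", band_length = 5000), "exceeds")
})

test_that("co-varying band densities reproduce the regression association", {
  # two channels whose per-band densities follow the same sinusoid
  n_b <- 12; bl <- 100; H <- 60
  dens <- 0.25 + 0.2 * sin(seq_len(n_b))
  chan <- function(scale, seed) {
    set.seed(seed)
    m <- matrix(20, H, n_b * bl)
    for (b in seq_len(n_b)) {
      cols <- ((b - 1) * bl + 1):(b * bl)
      k <- round(scale * dens[b] * H * bl)
      m[cbind(sample(H, k, TRUE), sample(cols, k, TRUE))] <- 200
    }
    m
  }
  stack <- channel_stack(list(cl5 = chan(1, 18), veptp = chan(0.6, 19)), 0.132)
  bp <- band_profile(stack, c("cl5", "veptp"), band_length = bl)
  fit <- ols_fit(bp$area_density_pct[bp$channel == "cl5"],
                 bp$area_density_pct[bp$channel == "veptp"])
  expect_gt(fit$r_squared, 0.9)
  expect_gt(fit$slope, 0)
})

test_that("normalization to the mean is exact and idempotent", {
  expect_equal(normalize_to_mean(c(1, 3)), c(0.5, 1.5))
  expect_equal(normalize_to_mean(rep(7, 5)), rep(1, 5))
  v <- c(2, 5, 11, 0.4)
  expect_equal(mean(normalize_to_mean(v)), 1)
  expect_equal(normalize_to_mean(normalize_to_mean(v)), normalize_to_mean(v))
  expect_error(normalize_to_mean(c(-1, 1)), "positive")
  # proportional profiles coincide after normalization: KS finds no difference
  prof_a <- 10 + 5 * sin(1:30)
  prof_b <- 4 * prof_a  # power of two: normalization is bitwise identical
  ks <- ks_two_sample(normalize_to_mean(prof_a), normalize_to_mean(prof_b))
  expect_equal(ks$D, 0)
  expect_gt(ks$p_value, 0.5)
})
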