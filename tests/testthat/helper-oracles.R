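# Independent oracles used to cross-check the implementation. These stay
# deliberately naive: flood fill instead of graph labeling, normal equations
# instead of lm, explicit ECDF sweeps instead of ks.test.

# Stack-based flood fill connected-component labeling.
flood_fill_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  moves <- if (connectivity == 8)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (mask[i, j] == 1 && lab[i, j] == 0L) {
      nxt <- nxt + 1L
      stack <- list(c(i, j))
      lab[i, j] <- nxt
      while (length(stack)) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (k in seq_len(nrow(moves))) {
          r <- p[1] + moves[k, 1]; c_ <- p[2] + moves[k, 2]
          if (r >= 1 && r <= nr && c_ >= 1 && c_ <= nc &&
              mask[r, c_] == 1 && lab[r, c_] == 0L) {
            lab[r, c_] <- nxt
            stack[[length(stack) + 1L]] <- c(r, c_)
          }
        }
      }
    }
  }
  lab
}

# Partition signature of a labeling: set of pixel-index groups, order-free.
label_signature <- function(lab) {
  fg <- which(lab > 0)
  if (!length(fg)) return(character(0))
  sort(vapply(split(fg, lab[fg]), function(ix)
    paste(sort(ix), collapse = ","), character(1)), method = "radix")
}

# OLS by explicit normal equations, with R^2 and slope p-value.
ols_normal_equations <- function(x, y) {
  n <- length(x)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  se_slope <- sqrt(sse / (n - 2) / sum((x - mean(x))^2))
  tval <- beta[2] / se_slope
  list(slope = beta[2], intercept = beta[1], r_squared = 1 - sse / sst,
       p_value = 2 * stats::pt(-abs(tval), n - 2))
}

# Two-sample KS D by explicit ECDF sweep over the pooled support.
ks_brute_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  Fa <- vapply(pts, function(t) mean(a <= t), numeric(1))
  Fb <- vapply(pts, function(t) mean(b <= t), numeric(1))
  max(abs(Fa - Fb))
}

# Half-width of the 99% normal-approximation binomial interval, in percent.
binom99_halfwidth_pct <- function(p, n) 100 * 2.576 * sqrt(p * (1 - p) / n)

# Rasterized disk mask helper.
disk_mask <- function(nr, nc, r0, c0, radius) {
  m <- matrix(0L, nr, nc)
  rr <- row(m); cc <- col(m)
  m[(rr - r0)^2 + (cc - c0)^2 <= radius^2] <- 1L
  m
}

# Smoothly varying base image for cross-correlation phantoms: band-limited
# noise with per-column structure, intensities in [20, 220].
ccf_base <- function(nr = 120, nc = 300, seed = 1, sigma = 3) {
  set.seed(seed)
  f <- EBImage::gblur(matrix(rnorm(nr * nc), nr, nc), sigma = sigma)
  f <- (f - min(f)) / diff(range(f))
  matrix(round(20 + 200 * f), nr, nc)
}

# Small default sheet for unit tests (kept light; the acceptance suite uses
# the full 200-cell study conditions).
tiny_sheet_spec <- function(n_cells = 40, width = 320, height = 320, ...) {
  sheet_spec(width = width, height = height, n_cells = n_cells,
             vessel = "vena_cava", ...)
}
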