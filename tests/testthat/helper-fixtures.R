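# shared fixtures and independent oracles, all built in code

# binary disk mask of radius r with pad background pixels around it
make_disk_mask <- function(r, pad = 5, center = NULL, shape = NULL) {
  if (is.null(shape)) shape <- rep(2 * (r + pad) + 1, 2)
  if (is.null(center)) center <- (shape - 1) / 2
  dy <- (0:(shape[1] - 1)) - center[1]
  dx <- (0:(shape[2] - 1)) - center[2]
  outer(dy^2, dx^2, "+") <= r^2
}

# small test geometry (same shape as the real grids, ~1/5 scale)
small_geometry <- function(plane = "intermed", center = c(400, 400))
  aco_geometry(plane, center, radii = c(60, 130, 190, 270, 350))

# brute-force Huang threshold: exhaustive scan over all candidate bins,
# recomputing the fuzziness from its definition (independent of the
# package's vectorized implementation)
oracle_huang <- function(centers, counts) {
  L <- length(centers)
  C <- centers[L] - centers[1]
  best <- Inf; best_t <- NA
  for (t in 1:(L - 1)) {
    n0 <- sum(counts[1:t]); n1 <- sum(counts[(t + 1):L])
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(counts[1:t] * centers[1:t]) / n0
    mu1 <- sum(counts[(t + 1):L] * centers[(t + 1):L]) / n1
    s <- 0
    for (g in 1:L) {
      mu <- if (g <= t) 1 / (1 + abs(centers[g] - mu0) / C) else
        1 / (1 + abs(centers[g] - mu1) / C)
      h <- -mu * log(mu) - if (mu < 1) (1 - mu) * log(1 - mu) else 0
      s <- s + counts[g] * h
    }
    if (s < best) { best <- s; best_t <- t }
  }
  best_t
}

# step-up BH directly from the definitional formula:
# q_(i) = min(1, min_{j >= i} p_(j) * m / j) on the sorted vector
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- numeric(m)
  for (i in seq_len(m)) qs[i] <- min(1, min(ps[i:m] * m / (i:m)))
  q <- numeric(m)
  q[o] <- qs
  q
}

# Spearman rho by the no-ties rank formula 1 - 6*sum(d^2)/(n(n^2-1))
oracle_spearman_rho <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Pearson chi-square by the hand formula sum (O-E)^2 / E
oracle_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# fast sim config for statistical tests: one plane, moderate density
calib_config <- function(density = 3, effect_map = NULL)
  sim_config(planes = "intermed", nuclei_density = density,
             effect_map = effect_map)
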