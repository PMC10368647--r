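# Independent oracles and small fixture builders used across test files.

# Dense-matrix restricted log-likelihood for Y ~ N(X b, s2 * (h A + (1-h) I)),
# with s2 profiled out. Deliberately computed with generic solve()/determinant()
# rather than the package's eigendecomposition route.
dense_reml_ll <- function(h, a, y, x = matrix(1, length(y), 1)) {
  n <- length(y)
  p <- ncol(x)
  v <- h * a + (1 - h) * diag(n)
  vi <- solve(v)
  xtvx <- t(x) %*% vi %*% x
  b <- solve(xtvx, t(x) %*% vi %*% y)
  r <- y - x %*% b
  s2 <- as.numeric(t(r) %*% vi %*% r) / (n - p)
  -0.5 * ((n - p) * (log(s2) + 1 + log(2 * pi)) +
            determinant(v, logarithm = TRUE)$modulus[1] +
            determinant(xtvx, logarithm = TRUE)$modulus[1])
}

dense_reml_grid <- function(a, y, step = 1e-3) {
  grid <- seq(step, 1 - step, by = step)
  ll <- vapply(grid, dense_reml_ll, numeric(1), a = a, y = y)
  grid[which.max(ll)]
}

# Small founder cohort with phenotypes, for tests that need raw populations.
founder_pop <- function(n, m, seed, h2 = 0.25, n2 = 0, maf = c(0.1, 0.5)) {
  cfg <- sim_config(n_snps = m, n_fam_disc1 = 2, n_fam_disc2 = 2,
                    n_fam_pred = max(2L, n %/% 2L), h2 = h2, n2 = n2,
                    founder_maf_range = maf, seed = seed)
  set.seed(seed)
  eff <- draw_effects(cfg)
  pop <- draw_founders(n, cfg)
  list(pop = assign_phenotype(pop, eff, h2, n2), effects = eff, config = cfg)
}

# CR1 cluster-robust vcov for a fitted lm, computed from first principles.
cr1_vcov_lm <- function(fit, cluster) {
  x <- model.matrix(fit)
  u <- residuals(fit)
  bread <- solve(crossprod(x))
  g <- rowsum(x * u, cluster)
  ng <- nrow(g)
  n <- nrow(x)
  k <- ncol(x)
  ng / (ng - 1) * (n - 1) / (n - k) * (bread %*% crossprod(g) %*% bread)
}
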