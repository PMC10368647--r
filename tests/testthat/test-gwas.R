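test_that("per-SNP regression matches lm() slope and standard error", {
  set.seed(31)
  n <- 200
  g <- matrix(rbinom(n * 10, 2, 0.3), n, 10)
  storage.mode(g) <- "integer"
  y <- rnorm(n)
  ss <- run_gwas(g, y)
  for (j in c(1, 4, 10)) {
    fit <- summary(lm(y ~ g[, j]))$coefficients
    expect_equal(ss$beta[j], fit[2, 1], tolerance = 1e-10)
    expect_equal(ss$se[j], fit[2, 2], tolerance = 1e-10)
  }
  expect_true(all(ss$n == n))
  expect_equal(ss$eaf, colMeans(g) / 2)

  g[, 3] <- 1L # monomorphic
  ss2 <- run_gwas(g, y)
  expect_equal(ss2$beta[3], 0)
  expect_identical(ss2$se[3], Inf)
})

test_that("a single causal SNP is recovered within sampling error", {
  set.seed(32)
  n <- 50000
  g <- matrix(rbinom(n * 3, 2, 0.4), n, 3)
  storage.mode(g) <- "integer"
  b <- 0.08
  y <- b * g[, 2] + rnorm(n)
  ss <- run_gwas(g, y)
  expect_lt(abs(ss$beta[2] - b), 3 * ss$se[2])
  expect_lt(abs(ss$beta[1]), 3 * ss$se[1])
})

test_that("the per-SNP test has nominal type-I error under the null", {
  set.seed(33)
  m <- 5000
  g <- matrix(rbinom(500 * m, 2, runif(m, 0.1, 0.5)[rep(1:m, each = 500)]), 500, m)
  storage.mode(g) <- "integer"
  y <- rnorm(500) # independent of all genotypes
  ss <- run_gwas(g, y)
  rej <- mean(abs(ss$beta / ss$se) > 1.96)
  expect_lt(abs(rej - 0.05), 0.01)
})

test_that("meta-analysis weights inversely to variance", {
  ss <- function(beta, se, n = 100) {
    out <- data.frame(snp = paste0("snp", seq_along(beta)), eaf = 0.3,
                      beta = beta, se = se, n = n)
    class(out) <- c("gwas_sumstats", "data.frame")
    out
  }
  # equal SEs: simple average
  m <- meta_analyze(ss(c(0.2, -0.4), c(0.1, 0.1)), ss(c(0.4, 0), c(0.1, 0.1)))
  expect_equal(m$beta, c(0.3, -0.2), tolerance = 1e-12)
  expect_equal(m$n, c(200, 200))
  # infinite SE gets zero weight
  m2 <- meta_analyze(ss(0.2, Inf), ss(0.5, 0.1))
  expect_equal(m2$beta, 0.5)
  expect_equal(m2$se, 0.1)
  # inverse-variance weights
  m3 <- meta_analyze(ss(0, 0.1), ss(1, 0.2))
  expect_equal(m3$beta, (1 / 0.01 * 0 + 1 / 0.04 * 1) / (1 / 0.01 + 1 / 0.04))
  # mismatched SNP sets are refused with the offender named
  bad <- ss(0.1, 0.1)
  bad$snp <- "rs_other"
  expect_error(meta_analyze(ss(0.1, 0.1), bad), "rs_other")
})

test_that("PGI construction is the weighted allele-count sum", {
  set.seed(34)
  g <- matrix(rbinom(60, 2, 0.4), 20, 3)
  storage.mode(g) <- "integer"
  expect_equal(build_pgi(g, c(0, 0, 0)), rep(0, 20), ignore_attr = TRUE)
  w <- c(0.5, -1, 2)
  expect_equal(as.numeric(build_pgi(g, w)), as.numeric(g %*% w))
  expect_error(build_pgi(g, c(1, 2)), "length")
  expect_message(build_pgi(g, c(1, Inf, 0)), "non-finite")
})

test_that("PGI weighted by the true effects recovers the latent factor", {
  fp <- founder_pop(2000, 400, seed = 35)
  score <- build_pgi(fp$pop$geno, fp$effects$direct)
  expect_gt(cor(score, fp$pop$true_pgi), 0.999999)
})

test_that("standardization contract: mean 0, variance 1, idempotent", {
  set.seed(36)
  x <- rnorm(100, 5, 3)
  s <- standardize(x)
  expect_lt(abs(mean(s)), 1e-12)
  expect_lt(abs(var(s) - 1), 1e-12)
  expect_equal(standardize(s), s, tolerance = 1e-12)
  expect_error(standardize(rep(2, 10)), "zero variance")
})

test_that("ORIV scaling inflates variance by 1/rhat", {
  set.seed(37)
  z <- rnorm(4000)
  p1 <- standardize(z + rnorm(4000, sd = 0.75))
  p2 <- standardize(z + rnorm(4000, sd = 0.75))
  set <- scale_for_oriv(p1, p2)
  expect_equal(var(set$pgi1_plus), 1 / set$rhat, tolerance = 1e-10)
  expect_equal(var(set$pgi2_plus), 1 / set$rhat, tolerance = 1e-10)
  # rhat = 0.64 gives variance 1.5625 exactly
  q1 <- standardize(z)
  q2 <- standardize(0.64 * z + sqrt(1 - 0.64^2) * rnorm(4000))
  s2 <- scale_for_oriv(q1, q2)
  expect_equal(var(q1 / sqrt(0.64)), 1 / 0.64, tolerance = 1e-12)
  # identical PGIs: identity scaling
  s3 <- scale_for_oriv(q1, q1)
  expect_equal(s3$rhat, 1)
  expect_equal(s3$pgi1_plus, q1)
  expect_error(scale_for_oriv(q1, -q1), "not positive")
})
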