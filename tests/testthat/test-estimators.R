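test_that("expected R-squared follows the closed form", {
  expect_equal(expected_r2(0.25, 5000, 2000), 0.0625 / 2.75, tolerance = 1e-12)
  expect_equal(round(100 * expected_r2(0.25, 5000, 16000), 1), 11.1)
  # limit: R2 -> h2 as the GWAS grows
  expect_equal(expected_r2(0.25, 5000, 1e12), 0.25, tolerance = 1e-6)
  expect_error(expected_r2(1.2, 100, 100), "h2_snp")
  expect_error(expected_r2(0.25, 0, 100), ">= 1")
})

test_that("first-stage F equals the squared first-stage t-statistic", {
  expect_equal(first_stage_f(0, 100), 0)
  expect_equal(first_stage_f(0.5, 1002), 0.25 * 1000 / 0.75, tolerance = 1e-12)
  expect_error(first_stage_f(1, 100), "undefined")
  expect_error(first_stage_f(0.5, 2), "n > 2")
  set.seed(51)
  z <- rnorm(500)
  p1 <- standardize(z + rnorm(500))
  p2 <- standardize(z + rnorm(500))
  fs <- summary(lm(p1 ~ p2))
  expect_equal(first_stage_f(cor(p1, p2), 500),
               (fs$coefficients[2, 1] / fs$coefficients[2, 2])^2,
               tolerance = 1e-6)
})

test_that("OLS slope and clustered standard errors match lm + sandwich", {
  skip_if_not_installed("sandwich")
  set.seed(52)
  n <- 400
  fam <- rep(1:(n / 2), each = 2)
  x <- standardize(rnorm(n) + rnorm(n / 2)[fam])
  y <- standardize(0.4 * x + rnorm(n))
  fit <- ols_pgi(y, x, family_id = fam)
  ref <- lm(y ~ x)
  expect_equal(unname(coef(fit)), unname(coef(ref)[2]), tolerance = 1e-10)
  vref <- sandwich::vcovCL(ref, cluster = fam, type = "HC1")
  expect_equal(fit$se, sqrt(vref[2, 2]), tolerance = 1e-8)
  expect_equal(fit$implied_h2, fit$beta^2)
  # attenuation identity: slope^2 equals the regression R-squared
  expect_equal(fit$beta^2, summary(ref)$r.squared, tolerance = 1e-12)
})

test_that("within-family OLS equals the dummy-variable fixed-effects fit", {
  set.seed(53)
  n <- 120
  fam <- rep(1:(n / 2), each = 2)
  x <- rnorm(n)
  y <- 0.5 * x + rnorm(n / 2)[fam] + rnorm(n)
  fit <- ols_pgi(y, x, family_id = fam, within = TRUE)
  ref <- lm(y ~ x + factor(fam))
  expect_equal(unname(coef(fit)), unname(coef(ref)["x"]), tolerance = 1e-10)
  v <- cr1_vcov_lm(ref, fam)
  expect_equal(fit$se, sqrt(v["x", "x"]), tolerance = 1e-8)
  expect_error(ols_pgi(y, x, family_id = seq_len(n), within = TRUE), "singleton")
})

test_that("ORIV equals the average of the two directed 2SLS estimates", {
  set.seed(54)
  n <- 600
  z <- rnorm(n)
  y <- standardize(0.5 * z + rnorm(n))
  p1 <- standardize(z + rnorm(n))
  p2 <- standardize(z + rnorm(n))
  set <- scale_for_oriv(p1, p2)
  fit <- oriv(y, set)
  directed <- function(x, w) { # 2SLS slope of y on x instrumented by w
    xd <- x - mean(x); wd <- w - mean(w); yd <- y - mean(y)
    sum(wd * yd) / sum(wd * xd)
  }
  avg <- (directed(set$pgi1_plus, set$pgi2_plus) +
            directed(set$pgi2_plus, set$pgi1_plus)) / 2
  expect_equal(fit$beta, avg, tolerance = 1e-10)
  expect_equal(fit$first_stage_F, first_stage_f(set$rhat, n), tolerance = 1e-12)
  expect_equal(fit$n_obs, 2 * n)

  # identity instruments reduce ORIV to OLS on the common PGI
  set_id <- scale_for_oriv(p1, p1)
  fit_id <- oriv(y, set_id)
  ref <- ols_pgi(y, p1)
  expect_equal(fit_id$beta, ref$beta, tolerance = 1e-10)
})

test_that("within-family ORIV matches the family-dummy 2SLS on a small instance", {
  set.seed(55)
  nf <- 40
  fam <- rep(1:nf, each = 2)
  z <- rnorm(2 * nf)
  y <- standardize(0.5 * z + rnorm(nf)[fam] + rnorm(2 * nf))
  p1 <- standardize(z + rnorm(2 * nf))
  p2 <- standardize(z + rnorm(2 * nf))
  set <- scale_for_oriv(p1, p2)
  fit <- oriv(y, set, family_id = fam, within = TRUE)
  # explicit family-by-stack dummy IV fit
  ys <- c(y, y); x <- c(set$pgi1_plus, set$pgi2_plus)
  zi <- c(set$pgi2_plus, set$pgi1_plus)
  cell <- factor(paste0(rep(fam, 2), "_", rep(1:2, each = 2 * nf)))
  d <- model.matrix(~ cell - 1)
  xm <- cbind(x, d); zm <- cbind(zi, d)
  b <- solve(crossprod(zm, xm), crossprod(zm, ys))
  expect_equal(fit$beta, b[1], tolerance = 1e-8)
})

test_that("PGI repository correction rescales point estimate and both SEs", {
  rc <- pgi_rc(0.2, 0.05, h2_hat = 0.25, se_h2 = 0.02, r2_hat = 0.04)
  expect_equal(rc$default$beta, 0.5, tolerance = 1e-12)
  expect_equal(rc$default$se, sqrt(0.25 / 0.04) * 0.05, tolerance = 1e-12)
  expect_equal(rc$greml_unc$beta, 0.5, tolerance = 1e-12)
  # Delta-method SE: se(h2) / (2 sqrt(h2))
  rc2 <- pgi_rc(0.4, 0.05, h2_hat = 0.16, se_h2 = 0.020)
  expect_equal(rc2$greml_unc$se, 0.020 / (2 * 0.4), tolerance = 1e-12)
  # univariate identity: the corrected estimate IS sqrt(h2_hat)
  expect_equal(rc2$default$beta, sqrt(0.16), tolerance = 1e-12)
  # no correction when R2 already equals the heritability
  rc3 <- pgi_rc(0.3, 0.05, h2_hat = 0.09, se_h2 = 0.02, r2_hat = 0.09)
  expect_equal(rc3$default$beta, 0.3, tolerance = 1e-12)
  # degenerate-heritability flag for the harness drop rule
  rc4 <- pgi_rc(0.1, 0.05, h2_hat = 0.005, se_h2 = 0.02)
  expect_true("h2_below_0.01" %in% rc4$default$flags)
  expect_error(pgi_rc(0.2, 0.05, h2_hat = 0.2, se_h2 = 0.01, r2_hat = 0), "positive")
})

test_that("pgi_fit methods expose estimate, interval, and summary", {
  set.seed(56)
  x <- standardize(rnorm(100))
  y <- standardize(0.3 * x + rnorm(100))
  fit <- ols_pgi(y, x)
  expect_named(coef(fit), "beta")
  ci <- confint(fit)
  expect_lt(ci[1, "low"], ci[1, "high"])
  expect_equal(unname(ci[1, "high"] - ci[1, "low"]), 2 * qnorm(0.975) * fit$se,
               tolerance = 1e-10)
  expect_output(print(fit), "ols_meta")
  expect_output(summary(fit), "implied h2")
})
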