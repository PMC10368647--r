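#' Expected out-of-sample R-squared of a PGI
#'
#' Closed-form approximation of the variance a PGI explains out of sample
#' when all SNPs contribute equally:
#' `R2 = h2_snp * h2_snp / (h2_snp + M / N_gwas)`. It approaches the SNP
#' heritability as the GWAS discovery sample grows.
#'
#' @param h2_snp SNP-based heritability in `[0, 1]`.
#' @param m_snps Number of SNPs (>= 1).
#' @param n_gwas GWAS discovery sample size (>= 1).
#' @return Expected R-squared (proportion).
#' @examples
#' expected_r2(0.25, 5000, 2000)   # ~0.023
#' expected_r2(0.25, 5000, 32000)  # ~0.154
#' @export
expected_r2 <- function(h2_snp, m_snps, n_gwas) {
  if (h2_snp < 0 || h2_snp > 1) stop("expected_r2(): h2_snp must be in [0, 1]", call. = FALSE)
  if (m_snps < 1 || n_gwas < 1) stop("expected_r2(): m_snps and n_gwas must be >= 1", call. = FALSE)
  h2_snp * h2_snp / (h2_snp + m_snps / n_gwas)
}

#' First-stage F-statistic for two mutually instrumenting PGIs
#'
#' For standardized PGIs the first-stage coefficient equals their
#' correlation, so the F-statistic is the squared t-statistic
#' `F = r^2 (N - 2) / (1 - r^2)`.
#'
#' @param corr_pgi Sample correlation of the two standardized PGIs
#'   (`|corr| < 1`).
#' @param n Prediction sample size (> 2).
#' @return The F value.
#' @export
first_stage_f <- function(corr_pgi, n) {
  if (abs(corr_pgi) >= 1) stop("first_stage_f(): undefined at |corr| = 1", call. = FALSE)
  if (n <= 2) stop("first_stage_f(): need n > 2", call. = FALSE)
  corr_pgi^2 * (n - 2) / (1 - corr_pgi^2)
}

new_pgi_fit <- function(method, beta, se, within, n_obs, n_clusters = NA_integer_,
                        first_stage_coef = NA_real_, first_stage_F = NA_real_,
                        flags = character()) {
  structure(list(
    method = method, beta = beta, se = se,
    ci_low = beta - 1.96 * se, ci_high = beta + 1.96 * se,
    implied_h2 = beta^2, implied_h2_se = 2 * abs(beta) * se,
    first_stage_coef = first_stage_coef, first_stage_F = first_stage_F,
    within = within, n_obs = n_obs, n_clusters = n_clusters, flags = flags
  ), class = "pgi_fit")
}

# CR1 cluster-robust vcov for a (possibly IV) linear fit.
# bread_l = (Z'X)^{-1}; scores = Z * u (row-wise); cluster id per row.
cluster_vcov_cr1 <- function(bread_l, scores, cluster, n_par) {
  g <- rowsum(scores, group = cluster)
  ng <- nrow(g)
  n <- nrow(scores)
  adj <- ng / (ng - 1) * (n - 1) / (n - n_par)
  adj * (bread_l %*% crossprod(g) %*% t(bread_l))
}

#' OLS of a standardized outcome on a standardized PGI
#'
#' Between families: the simple-regression slope with (optionally
#' family-)cluster-robust CR1 standard errors. Within families: the
#' family-demeaned regression (numerically identical to family fixed
#' effects), with family-clustered CR1 standard errors; families with a
#' single member drop out.
#'
#' @param y Standardized outcome.
#' @param pgi_st Standardized PGI.
#' @param family_id Family identifier per individual; required for
#'   `within = TRUE` and used for clustering between families when supplied.
#' @param within Family fixed effects?
#' @param method Label stored on the result, e.g. `"ols_meta"`.
#' @return A `"pgi_fit"` object.
#' @export
ols_pgi <- function(y, pgi_st, family_id = NULL, within = FALSE,
                    method = "ols_meta") {
  n <- length(y)
  stopifnot(length(pgi_st) == n)
  if (within) {
    if (is.null(family_id)) stop("ols_pgi(): within = TRUE needs family_id", call. = FALSE)
    fam <- as.factor(family_id)
    multi <- ave(rep(1L, n), fam, FUN = length) >= 2L
    if (!any(multi)) stop("ols_pgi(): all families are singletons", call. = FALSE)
    yd <- y[multi] - ave(y[multi], fam[multi])
    xd <- pgi_st[multi] - ave(pgi_st[multi], fam[multi])
    famu <- droplevels(fam[multi])
    sxx <- sum(xd^2)
    b <- sum(xd * yd) / sxx
    u <- yd - xd * b
    n_par <- nlevels(famu) + 1L # absorbed fixed effects + slope
    v <- cluster_vcov_cr1(matrix(1 / sxx), matrix(xd * u, ncol = 1), famu,
                          n_par = min(n_par, length(yd) - 1L))
    return(new_pgi_fit(method, b, sqrt(v[1L, 1L]), within = TRUE,
                       n_obs = length(yd), n_clusters = nlevels(famu)))
  }
  x <- cbind(1, pgi_st)
  xtx_inv <- solve(crossprod(x))
  bhat <- xtx_inv %*% crossprod(x, y)
  u <- y - x %*% bhat
  if (is.null(family_id)) {
    s2 <- sum(u^2) / (n - 2L)
    v <- s2 * xtx_inv
    ncl <- NA_integer_
  } else {
    fam <- as.factor(family_id)
    v <- cluster_vcov_cr1(xtx_inv, x * as.numeric(u), fam, n_par = 2L)
    ncl <- nlevels(fam)
  }
  new_pgi_fit(method, bhat[2L], sqrt(v[2L, 2L]), within = FALSE,
              n_obs = n, n_clusters = ncl)
}

#' Obviously-related instrumental variables (stacked 2SLS)
#'
#' Duplicates the data into two stacks; in stack 1 the regressor is the first
#' scaled PGI instrumented by the second, in stack 2 the roles are reversed.
#' Stack-specific intercepts are included between families; within families
#' the model is demeaned within family-by-stack cells (family fixed effects
#' per stack). Standard errors are CR1 cluster-robust, clustered on the
#' individual between families and two-way on individual and family within
#' families (which, individuals being nested in families, equals family-level
#' clustering). The point estimate equals the average of the two directed
#' just-identified 2SLS estimates.
#'
#' @param y Standardized outcome.
#' @param pgi1_plus,pgi2_plus Scaled PGIs from [scale_for_oriv()] (or a
#'   `"pgi_set"` passed as `pgi1_plus`, in which case `pgi2_plus` is ignored).
#' @param family_id Family identifier; required for `within = TRUE`.
#' @param within Family fixed effects?
#' @param cluster `"individual"` (default between families) or `"twoway"`
#'   (default within families).
#' @return A `"pgi_fit"` with first-stage diagnostics.
#' @export
oriv <- function(y, pgi1_plus, pgi2_plus = NULL, family_id = NULL,
                 within = FALSE, cluster = NULL) {
  if (inherits(pgi1_plus, "pgi_set")) {
    set <- pgi1_plus
    pgi1_plus <- set$pgi1_plus
    pgi2_plus <- set$pgi2_plus
  }
  n <- length(y)
  stopifnot(length(pgi1_plus) == n, length(pgi2_plus) == n)
  rhat <- cor(pgi1_plus, pgi2_plus)
  if (!is.finite(rhat) || rhat <= 0) {
    stop("oriv(): non-positive PGI correlation; instruments unusable", call. = FALSE)
  }
  if (is.null(cluster)) cluster <- if (within) "twoway" else "individual"
  cluster <- match.arg(cluster, c("individual", "twoway"))
  fsF <- if (rhat >= 1 - 1e-12) Inf else first_stage_f(rhat, n)
  ys <- c(y, y)
  x <- c(pgi1_plus, pgi2_plus)
  z <- c(pgi2_plus, pgi1_plus)
  stack <- rep(1:2, each = n)
  indiv <- rep(seq_len(n), 2L)
  if (within) {
    if (is.null(family_id)) stop("oriv(): within = TRUE needs family_id", call. = FALSE)
    fam2 <- rep(as.integer(as.factor(family_id)), 2L)
    multi <- ave(rep(1L, 2L * n), fam2 * 2L + stack, FUN = length) >= 2L
    if (!any(multi)) stop("oriv(): all families are singletons", call. = FALSE)
    cell <- interaction(fam2, stack, drop = TRUE)
    yd <- ys - ave(ys, cell)
    xd <- x - ave(x, cell)
    zd <- z - ave(z, cell)
    keep <- multi
    yd <- yd[keep]; xd <- xd[keep]; zd <- zd[keep]
    fam_k <- fam2[keep]; ind_k <- indiv[keep]
    ztx <- sum(zd * xd)
    b <- sum(zd * yd) / ztx
    u <- yd - xd * b
    n_par <- length(unique(cell[keep])) + 1L
    bread_l <- matrix(1 / ztx)
    scores <- matrix(zd * u, ncol = 1)
    n_eff <- length(yd)
    vc <- function(cl, np) cluster_vcov_cr1(bread_l, scores, cl, min(np, n_eff - 1L))
    v <- if (cluster == "twoway") {
      vi <- vc(ind_k, n_par)
      vf <- vc(fam_k, n_par)
      vint <- vc(interaction(ind_k, fam_k, drop = TRUE), n_par)
      vi + vf - vint
    } else vc(ind_k, n_par)
    fit <- new_pgi_fit("oriv", b, sqrt(v[1L, 1L]), within = TRUE,
                       n_obs = n_eff, n_clusters = length(unique(fam_k)),
                       first_stage_coef = ztx / sum(zd^2),
                       first_stage_F = fsF)
    return(fit)
  }
  d1 <- as.numeric(stack == 1L)
  d2 <- as.numeric(stack == 2L)
  xm <- cbind(d1, d2, x)
  zm <- cbind(d1, d2, z)
  ztx_inv <- solve(crossprod(zm, xm))
  bhat <- ztx_inv %*% crossprod(zm, ys)
  u <- ys - xm %*% bhat
  cl <- if (cluster == "twoway" && !is.null(family_id)) {
    rep(as.integer(as.factor(family_id)), 2L)
  } else indiv
  v <- cluster_vcov_cr1(ztx_inv, zm * as.numeric(u), cl, n_par = 3L)
  # first stage: x on stack dummies + z
  fs <- lm.fit(zm, x)
  new_pgi_fit("oriv", bhat[3L], sqrt(v[3L, 3L]), within = FALSE,
              n_obs = 2L * n, n_clusters = length(unique(cl)),
              first_stage_coef = coef(fs)[["z"]],
              first_stage_F = fsF)
}

#' PGI repository correction
#'
#' Rescales the OLS coefficient of a standardized PGI by
#' `sqrt(h2_hat / r2_hat)` so the implied effect matches the SNP-based
#' heritability. Two standard errors are returned: the default, which scales
#' the OLS standard error by the same factor, and the GREML-uncertainty
#' variant `se(h2_hat) / (2 * sqrt(h2_hat))` (Delta method), which accounts
#' for the estimation error in the scaling factor. In the univariate case
#' `r2_hat = beta^2` and the point estimate is exactly `sqrt(h2_hat)`; the
#' function asserts this identity. Runs with `h2_hat < 0.01` are flagged so
#' scenario aggregation can exclude them.
#'
#' @param beta_st_hat OLS coefficient of the standardized PGI (e.g.
#'   `coef(ols_pgi(...))`).
#' @param se_beta Its standard error.
#' @param h2_hat Estimated SNP heritability (e.g. from [greml_h2()]).
#' @param se_h2 Standard error of `h2_hat`.
#' @param r2_hat The regression R-squared; defaults to `beta_st_hat^2`, the
#'   univariate identity.
#' @return List of class `"pgi_rc"` with components `default` and
#'   `greml_unc`, both `"pgi_fit"` objects.
#' @export
pgi_rc <- function(beta_st_hat, se_beta, h2_hat, se_h2,
                   r2_hat = beta_st_hat^2) {
  if (r2_hat <= 0) stop("pgi_rc(): r2_hat must be positive", call. = FALSE)
  if (h2_hat < 0) stop("pgi_rc(): h2_hat must be non-negative", call. = FALSE)
  factor <- sqrt(h2_hat / r2_hat)
  b <- beta_st_hat * factor
  if (isTRUE(all.equal(r2_hat, beta_st_hat^2)) && beta_st_hat >= 0) {
    stopifnot(abs(b - sqrt(h2_hat)) < 1e-10) # univariate identity
  }
  flags <- if (h2_hat < 0.01) "h2_below_0.01" else character()
  structure(list(
    default = new_pgi_fit("pgi_rc_default", b, factor * se_beta,
                          within = FALSE, n_obs = NA_integer_, flags = flags),
    greml_unc = new_pgi_fit("pgi_rc_greml_unc", b,
                            if (h2_hat > 0) se_h2 / (2 * sqrt(h2_hat)) else Inf,
                            within = FALSE, n_obs = NA_integer_, flags = flags)
  ), class = "pgi_rc")
}

#' @export
print.pgi_rc <- function(x, ...) {
  print(x$default)
  print(x$greml_unc)
  invisible(x)
}

#' @export
print.pgi_fit <- function(x, ...) {
  cat(sprintf("%-18s beta = %6.3f (SE %.3f), 95%% CI [%.3f, %.3f]%s\n",
              paste0(x$method, if (x$within) " (within)" else ""),
              x$beta, x$se, x$ci_low, x$ci_high,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' @export
summary.pgi_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  implied h2 = %.4f (SE %.4f); n = %s, clusters = %s\n",
              object$implied_h2, object$implied_h2_se,
              object$n_obs, object$n_clusters))
  if (is.finite(object$first_stage_F)) {
    cat(sprintf("  first stage: coef = %.4f, F = %.1f\n",
                object$first_stage_coef, object$first_stage_F))
  }
  invisible(object)
}

#' @export
coef.pgi_fit <- function(object, ...) c(beta = object$beta)

#' @export
confint.pgi_fit <- function(object, parm, level = 0.95, ...) {
  q <- qnorm(1 - (1 - level) / 2)
  matrix(c(object$beta - q * object$se, object$beta + q * object$se),
         nrow = 1, dimnames = list("beta", c("low", "high")))
}

#' @export
vcov.pgi_fit <- function(object, ...) matrix(object$se^2, dimnames = list("beta", "beta"))

#' @importFrom stats ave
NULL
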