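# Single-component GREML via one eigendecomposition of the GRM and
# one-dimensional profiled restricted likelihood over the heritability.

# Profiled restricted log-likelihood at heritability h, in the rotated basis.
# ev: eigenvalues of A; yr, xr: rotated phenotype and fixed-effect design.
greml_profile_ll <- function(h, ev, yr, xr) {
  n <- length(yr)
  p <- ncol(xr)
  w <- h * ev + (1 - h)
  if (any(w <= 0)) return(-Inf)
  iw <- 1 / w
  xtx <- crossprod(xr, xr * iw)
  xty <- crossprod(xr, yr * iw)
  bhat <- solve(xtx, xty)
  r <- yr - xr %*% bhat
  rss <- sum(r^2 * iw)
  s2 <- rss / (n - p)
  -0.5 * ((n - p) * (log(s2) + 1 + log(2 * pi)) + sum(log(w)) +
            determinant(xtx, logarithm = TRUE)$modulus[1L])
}

#' GREML estimate of SNP heritability
#'
#' Restricted maximum likelihood for the single-component model
#' `Y ~ N(mu 1, sigma_g^2 A + sigma_e^2 I)` with an intercept as the only
#' fixed effect. The GRM is eigendecomposed once, the data rotated, and the
#' restricted log-likelihood profiled over the heritability
#' `h2 = sigma_g^2 / (sigma_g^2 + sigma_e^2)` on `[0, 1]` (golden-section via
#' `optimize()` plus local refinement, tolerance 1e-6). The standard error
#' comes from the observed information (numeric curvature) of the profiled
#' restricted log-likelihood at the optimum. Boundary estimates are flagged.
#'
#' @param grm A `"grm"` object (typically pruned with [prune_related()]).
#' @param phenotype Standardized outcome for the same individuals/order.
#' @param keep Optional index vector (e.g. from [prune_related()]) selecting
#'   the individuals to use.
#' @param tol Convergence tolerance for the heritability, default 1e-6.
#' @return Object of class `"greml"`: `h2_hat`, `se_h2`, `sigma2` (total
#'   variance), `n_used`, `converged`, `boundary`, `loglik`.
#' @export
greml_h2 <- function(grm, phenotype, keep = NULL, tol = 1e-6) {
  a <- grm$A
  y <- as.numeric(phenotype)
  if (length(y) != nrow(a)) stop("greml_h2(): phenotype length mismatch", call. = FALSE)
  if (!is.null(keep)) {
    a <- a[keep, keep, drop = FALSE]
    y <- y[keep]
  }
  n <- length(y)
  eg <- eigen(a, symmetric = TRUE)
  yr <- crossprod(eg$vectors, y)
  xr <- crossprod(eg$vectors, matrix(1, n, 1))
  ll <- function(h) greml_profile_ll(h, eg$values, yr, xr)
  opt <- optimize(ll, interval = c(0, 1), maximum = TRUE, tol = tol)
  h <- opt$maximum
  # optimize() never returns the exact interval ends; probe them explicitly
  for (hb in c(0, 1)) if (ll(hb) > opt$objective) {
    h <- hb
    opt$objective <- ll(hb)
  }
  boundary <- h < 1e-4 || h > 1 - 1e-4
  step <- 1e-4
  h0 <- min(max(h, step), 1 - step)
  d2 <- (ll(h0 + step) - 2 * ll(h0) + ll(h0 - step)) / step^2
  se <- if (is.finite(d2) && d2 < 0) sqrt(-1 / d2) else NA_real_
  # total variance at the optimum, for completeness
  w <- h * eg$values + (1 - h)
  iw <- 1 / pmax(w, .Machine$double.eps)
  bhat <- sum(yr * iw * xr) / sum(xr^2 * iw)
  s2 <- sum((yr - xr * bhat)^2 * iw) / (n - 1)
  structure(list(h2_hat = h, se_h2 = se, sigma2 = s2, n_used = n,
                 converged = is.finite(opt$objective) && is.finite(h),
                 boundary = boundary, loglik = opt$objective),
            class = "greml")
}

#' @export
print.greml <- function(x, ...) {
  cat(sprintf("GREML: h2 = %.4f (SE %.4f), n = %d%s%s\n",
              x$h2_hat, x$se_h2, x$n_used,
              if (x$boundary) " [boundary]" else "",
              if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}

#' One-call GREML on a simulated prediction sample
#'
#' Computes the GRM of the prediction sample, prunes pairs above the
#' relatedness cutoff (default 0.05, which in a sibling cohort keeps one
#' sibling per family), and runs [greml_h2()]. Alternatively,
#' `method = "one_sib"` skips the GRM-based pruning and simply uses the first
#' sibling of every family.
#'
#' @param sim A `"pgi_sim"` object.
#' @param cutoff Relatedness cutoff for pruning.
#' @param method `"grm_cutoff"` (default) or `"one_sib"`.
#' @return A `"greml"` object.
#' @export
greml_prediction_sample <- function(sim, cutoff = 0.05,
                                    method = c("grm_cutoff", "one_sib")) {
  method <- match.arg(method)
  pop <- sim$pred
  if (method == "one_sib") {
    idx <- seq(1L, nrow(pop$geno), by = 2L)
    grm <- compute_grm(pop$geno[idx, , drop = FALSE])
    return(greml_h2(grm, pop$phenotype[idx]))
  }
  grm <- compute_grm(pop$geno)
  keep <- prune_related(grm, cutoff)
  greml_h2(grm, pop$phenotype, keep = keep)
}
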