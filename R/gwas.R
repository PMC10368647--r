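#' Between-family GWAS
#'
#' Per-SNP simple regression of a standardized phenotype on allele count,
#' vectorized in compiled code; returns the slope, its classical standard
#' error, the effect-allele frequency, and the sample size. Supply at most
#' one individual per family (the canonical between-family design); the
#' function does not enforce this because the family structure lives with the
#' caller, but [simulate_study()] provides ready-made one-sibling subsets.
#' Monomorphic SNPs get `beta = 0` and `se = Inf` and are excluded from PGI
#' weights downstream.
#'
#' @param genotypes Integer matrix, individuals x SNPs, entries 0/1/2.
#' @param phenotype Numeric outcome vector.
#' @param snp_ids Optional SNP identifiers (default `snp1..snpM`).
#' @return A `data.frame` of class `"gwas_sumstats"` with columns
#'   `snp`, `eaf`, `beta`, `se`, `n`.
#' @export
run_gwas <- function(genotypes, phenotype, snp_ids = NULL) {
  if (nrow(genotypes) != length(phenotype)) {
    stop("run_gwas(): genotype rows and phenotype length differ", call. = FALSE)
  }
  if (nrow(genotypes) < 3L) stop("run_gwas(): need n >= 3", call. = FALSE)
  res <- .gwas_cpp(genotypes, as.numeric(phenotype))
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(genotypes)))
  out <- data.frame(snp = snp_ids, eaf = res$eaf, beta = res$beta,
                    se = res$se, n = nrow(genotypes),
                    stringsAsFactors = FALSE)
  class(out) <- c("gwas_sumstats", "data.frame")
  out
}

#' Inverse-variance meta-analysis of two GWAS
#'
#' Fixed-effects inverse-variance weighting per SNP; a SNP with infinite
#' standard error in one input gets zero weight there, and the combined
#' sample size is the sum of the inputs'. With equal standard errors the
#' meta-analyzed effect is the simple average.
#'
#' @param ss1,ss2 `"gwas_sumstats"` objects over identical SNP sets in the
#'   same order and effect-allele orientation.
#' @return A `"gwas_sumstats"` data frame.
#' @export
meta_analyze <- function(ss1, ss2) {
  if (nrow(ss1) != nrow(ss2) || any(ss1$snp != ss2$snp)) {
    bad <- union(setdiff(ss1$snp, ss2$snp), setdiff(ss2$snp, ss1$snp))
    stop("meta_analyze(): SNP sets differ: ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) ", ..." else "", call. = FALSE)
  }
  w1 <- ifelse(is.finite(ss1$se), 1 / ss1$se^2, 0)
  w2 <- ifelse(is.finite(ss2$se), 1 / ss2$se^2, 0)
  wt <- w1 + w2
  beta <- ifelse(wt > 0, (w1 * ss1$beta + w2 * ss2$beta) / wt, 0)
  se <- ifelse(wt > 0, sqrt(1 / wt), Inf)
  eaf <- (ss1$n * ss1$eaf + ss2$n * ss2$eaf) / (ss1$n + ss2$n)
  out <- data.frame(snp = ss1$snp, eaf = eaf, beta = beta, se = se,
                    n = ss1$n + ss2$n, stringsAsFactors = FALSE)
  class(out) <- c("gwas_sumstats", "data.frame")
  out
}

#' Build a polygenic index
#'
#' The PGI is the allele-count sum weighted by per-SNP effects:
#' `score_i = sum_j w_j * genotype_ij`. SNPs with non-finite weights (e.g.
#' monomorphic SNPs flagged with `se = Inf` whose weight is passed as `NA` or
#' `Inf`) are dropped with a message; the count of dropped SNPs is attached
#' as attribute `"n_dropped"`.
#'
#' @param genotypes Integer matrix, individuals x SNPs.
#' @param weights Per-SNP weight vector aligned with the genotype columns,
#'   typically `beta` from a [run_gwas()] or [meta_analyze()] result.
#' @return Numeric score per individual.
#' @export
build_pgi <- function(genotypes, weights) {
  if (ncol(genotypes) != length(weights)) {
    stop("build_pgi(): weight length does not match SNP count", call. = FALSE)
  }
  bad <- !is.finite(weights)
  if (any(bad)) {
    message(sprintf("build_pgi(): dropping %d SNP(s) with non-finite weights",
                    sum(bad)))
    weights[bad] <- 0
  }
  out <- .geno_score_cpp(genotypes, as.numeric(weights))
  attr(out, "n_dropped") <- sum(bad)
  out
}

#' Standardize scores to mean 0, variance 1
#'
#' Sample standardization with the `N - 1` standard-deviation divisor.
#' Already-standardized input is returned unchanged up to floating point;
#' a constant vector is an error.
#'
#' @param scores Numeric vector.
#' @return Standardized vector.
#' @export
standardize <- function(scores) {
  s <- sd(scores)
  if (!is.finite(s) || s <= 0) {
    stop("standardize(): zero variance input", call. = FALSE)
  }
  (scores - mean(scores)) / s
}

#' Scale two standardized PGIs for ORIV
#'
#' Divides each standardized PGI by the square root of their sample
#' correlation, so that instrumenting the scaled PGIs by each other targets
#' the standardized effect of the true latent PGI directly. The scaled PGIs
#' have variance `1 / rhat`. When a within-family estimate is planned, the
#' correlation is still the between-family (plain sample) correlation.
#'
#' @param pgi1_st,pgi2_st Standardized PGIs over the same individuals.
#' @return List of class `"pgi_set"` with `pgi1_st`, `pgi2_st`, `pgi1_plus`,
#'   `pgi2_plus`, and `rhat`.
#' @export
scale_for_oriv <- function(pgi1_st, pgi2_st) {
  if (length(pgi1_st) != length(pgi2_st)) {
    stop("scale_for_oriv(): length mismatch", call. = FALSE)
  }
  rhat <- cor(pgi1_st, pgi2_st)
  if (!is.finite(rhat) || rhat <= 0) {
    stop(sprintf("scale_for_oriv(): PGI correlation %.4f is not positive; instruments unusable",
                 rhat), call. = FALSE)
  }
  structure(list(pgi1_st = pgi1_st, pgi2_st = pgi2_st,
                 pgi1_plus = pgi1_st / sqrt(rhat),
                 pgi2_plus = pgi2_st / sqrt(rhat),
                 rhat = rhat),
            class = "pgi_set")
}

#' Construct the three standardized PGIs of a simulated study
#'
#' Convenience wrapper running the full discovery pipeline on a
#' [simulate_study()] result: two between-family GWAS on the one-sibling
#' subsets, inverse-variance meta-analysis, PGI construction in the
#' prediction sample, and standardization there.
#'
#' @param sim A `"pgi_sim"` object.
#' @return List with `pgi1_st`, `pgi2_st`, `pgi_meta_st` (standardized in the
#'   prediction sample), the three `"gwas_sumstats"` objects, and `oriv_set`
#'   (the [scale_for_oriv()] result).
#' @export
build_study_pgis <- function(sim) {
  i1 <- sim$gwas_idx$disc1
  i2 <- sim$gwas_idx$disc2
  ss1 <- run_gwas(sim$disc1$geno[i1, , drop = FALSE], sim$disc1$phenotype[i1])
  ss2 <- run_gwas(sim$disc2$geno[i2, , drop = FALSE], sim$disc2$phenotype[i2])
  meta <- meta_analyze(ss1, ss2)
  usable <- function(ss) ifelse(is.finite(ss$se), ss$beta, 0)
  g <- sim$pred$geno
  pgi1 <- standardize(suppressMessages(build_pgi(g, usable(ss1))))
  pgi2 <- standardize(suppressMessages(build_pgi(g, usable(ss2))))
  pgim <- standardize(suppressMessages(build_pgi(g, usable(meta))))
  list(pgi1_st = pgi1, pgi2_st = pgi2, pgi_meta_st = pgim,
       ss1 = ss1, ss2 = ss2, ss_meta = meta,
       oriv_set = scale_for_oriv(pgi1, pgi2))
}
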