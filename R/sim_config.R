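#' Simulation configuration
#'
#' Bundles and validates all parameters of the forward family simulation:
#' genome size, family counts for the three samples (two GWAS discovery
#' samples and one prediction sample), the variance shares of direct genetic
#' effects (`h2`) and genetic nurture (`n2`), the strength of assortative
#' mating, cross-sample genetic correlations, the number of offspring
#' generations, founder allele frequencies, and the seed.
#'
#' The outcome's SNP heritability implied by the configuration is
#' `h2 + 0.5 * n2` (a child's genotype carries half of the parental
#' genotypes that mediate nurture), so that quantity must not exceed 1.
#' At most one of the two genetic-correlation parameters may be below 1:
#' either the two discovery samples deviate genetically from the prediction
#' sample together (`rg_disc_pred < 1`), or discovery sample 1 deviates from
#' discovery sample 2 and the prediction sample (`rg_disc_disc < 1`).
#'
#' @param n_snps Number of unlinked SNPs (M).
#' @param n_fam_disc1,n_fam_disc2,n_fam_pred Families in the final generation
#'   of each sample. Every family has two children; between-family GWAS uses
#'   one child per discovery family, so the GWAS sample size equals the
#'   discovery family count.
#' @param h2 Phenotypic variance share of direct genetic effects.
#' @param n2 Phenotypic variance share of genetic nurture.
#' @param am_rho Target phenotypic correlation between mates, in `[0, 1]`.
#' @param rg_disc_pred Genetic correlation between the discovery samples and
#'   the prediction sample, in `(0, 1]`.
#' @param rg_disc_disc Genetic correlation between discovery samples 1 and 2,
#'   in `(0, 1]`.
#' @param n_generations Offspring generations to simulate. Default: 1 when
#'   `am_rho == 0` and 10 otherwise, so that mating-induced correlations can
#'   approach equilibrium.
#' @param founder_maf_range Interval within `(0, 0.5]` from which per-SNP
#'   founder allele frequencies are drawn uniformly.
#' @param seed Integer seed; mandatory, drives every random draw.
#' @param standardize_each_generation If `TRUE` (default) the latent direct
#'   genetic factor is standardized to mean 0, variance 1 within every
#'   generation, keeping the contemporary heritability and the target
#'   coefficient fixed under assortative mating. If `FALSE`, offspring
#'   generations reuse the founder-generation scaling so genetic variance
#'   may drift.
#'
#' @return An object of class `"sim_config"` (a validated list).
#' @examples
#' cfg <- sim_config(n_snps = 100, n_fam_disc1 = 20, n_fam_disc2 = 20,
#'                   n_fam_pred = 40, seed = 1)
#' cfg
#' @export
sim_config <- function(n_snps,
                       n_fam_disc1, n_fam_disc2, n_fam_pred,
                       h2 = 0.25, n2 = 0,
                       am_rho = 0,
                       rg_disc_pred = 1, rg_disc_disc = 1,
                       n_generations = NULL,
                       founder_maf_range = c(0.1, 0.5),
                       seed,
                       standardize_each_generation = TRUE) {
  if (missing(seed)) stop("sim_config(): 'seed' is mandatory", call. = FALSE)
  cfg <- list(
    n_snps = as.integer(n_snps),
    n_fam_disc1 = as.integer(n_fam_disc1),
    n_fam_disc2 = as.integer(n_fam_disc2),
    n_fam_pred = as.integer(n_fam_pred),
    h2 = as.numeric(h2), n2 = as.numeric(n2),
    am_rho = as.numeric(am_rho),
    rg_disc_pred = as.numeric(rg_disc_pred),
    rg_disc_disc = as.numeric(rg_disc_disc),
    n_generations = if (is.null(n_generations)) {
      if (am_rho == 0) 1L else 10L
    } else as.integer(n_generations),
    founder_maf_range = as.numeric(founder_maf_range),
    seed = as.integer(seed),
    standardize_each_generation = isTRUE(standardize_each_generation)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  err <- function(field, msg) {
    stop(sprintf("sim_config: invalid '%s': %s", field, msg), call. = FALSE)
  }
  if (is.na(cfg$n_snps) || cfg$n_snps < 1L) err("n_snps", "need at least 1 SNP")
  for (f in c("n_fam_disc1", "n_fam_disc2", "n_fam_pred")) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L) err(f, "need at least 1 family")
  }
  if (cfg$h2 < 0 || cfg$n2 < 0) err("h2", "h2 and n2 must be non-negative")
  if (cfg$h2 + 0.5 * cfg$n2 > 1 + 1e-12) {
    err("h2", sprintf("h2 + 0.5*n2 = %.3f exceeds 1 (SNP heritability cannot exceed 1)",
                      cfg$h2 + 0.5 * cfg$n2))
  }
  if (cfg$h2 + cfg$n2 > 1 + 1e-12) {
    err("n2", "h2 + n2 exceeds 1; no variance left for the environment")
  }
  if (cfg$am_rho < 0 || cfg$am_rho > 1) err("am_rho", "must lie in [0, 1]")
  for (f in c("rg_disc_pred", "rg_disc_disc")) {
    if (cfg[[f]] <= 0 || cfg[[f]] > 1) err(f, "must lie in (0, 1]")
  }
  if (cfg$rg_disc_pred < 1 && cfg$rg_disc_disc < 1) {
    err("rg_disc_pred", "at most one of rg_disc_pred, rg_disc_disc may be < 1")
  }
  if (cfg$n_generations < 1L) err("n_generations", "need at least 1 offspring generation")
  r <- cfg$founder_maf_range
  if (length(r) != 2L || r[1] > r[2] || r[1] <= 0 || r[2] > 0.5) {
    err("founder_maf_range", "must be an interval within (0, 0.5]")
  }
  if (is.na(cfg$seed)) err("seed", "must be an integer")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  SNPs: %d, families (disc1/disc2/pred): %d/%d/%d\n",
              x$n_snps, x$n_fam_disc1, x$n_fam_disc2, x$n_fam_pred))
  cat(sprintf("  h2 = %.3f, n2 = %.3f (h2_SNP = %.3f), AM rho = %.2f\n",
              x$h2, x$n2, x$h2 + 0.5 * x$n2, x$am_rho))
  cat(sprintf("  rg(disc, pred) = %.2f, rg(disc1, disc2) = %.2f\n",
              x$rg_disc_pred, x$rg_disc_disc))
  cat(sprintf("  generations: %d, founder MAF ~ U(%.2f, %.2f), seed %d\n",
              x$n_generations, x$founder_maf_range[1], x$founder_maf_range[2],
              x$seed))
  invisible(x)
}
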