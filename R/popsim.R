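#' Draw per-SNP effect sizes
#'
#' Draws the direct-effect and genetic-nurture effect vectors, plus the three
#' sample-specific direct-effect variants that realize the configured genetic
#' correlations. Direct and nurture effects are independent i.i.d. standard
#' normal draws; their absolute scale is irrelevant because
#' [assign_phenotype()] standardizes the aggregate factors before applying the
#' `h2`/`n2` variance shares.
#'
#' At most one genetic correlation may be below 1 (see [sim_config()]), so the
#' correlated variants are built exactly: all samples share a base vector `u`,
#' and the deviating sample(s) use `rg * u + sqrt(1 - rg^2) * v` with an
#' independent vector `v`. When `rg_disc_pred < 1` the two discovery samples
#' deviate together from the prediction sample; when `rg_disc_disc < 1`
#' discovery sample 1 deviates from the other two.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `"effect_set"` with elements `direct` (the
#'   prediction-sample direct effects), `nurture`, and `variants`, an
#'   `n_snps x 3` matrix with columns `disc1`, `disc2`, `pred`.
#' @export
draw_effects <- function(config) {
  validate_sim_config(config)
  m <- config$n_snps
  u <- rnorm(m)
  v <- rnorm(m)
  nurture <- rnorm(m)
  rg_dp <- config$rg_disc_pred
  rg_dd <- config$rg_disc_disc
  if (rg_dp < 1) {
    disc <- rg_dp * u + sqrt(1 - rg_dp^2) * v
    variants <- cbind(disc1 = disc, disc2 = disc, pred = u)
  } else if (rg_dd < 1) {
    d1 <- rg_dd * u + sqrt(1 - rg_dd^2) * v
    variants <- cbind(disc1 = d1, disc2 = u, pred = u)
  } else {
    variants <- cbind(disc1 = u, disc2 = u, pred = u)
  }
  structure(list(direct = variants[, "pred"], nurture = nurture,
                 variants = variants),
            class = "effect_set")
}

#' Draw a founder population
#'
#' Founder genotypes are drawn per SNP as Binomial(2, p_j) with allele
#' frequencies p_j uniform on `config$founder_maf_range`. Founders have no
#' pedigree links and no nurture component; call [assign_phenotype()] to fill
#' in phenotypes.
#'
#' @param n_individuals Number of founders (must be even to allow mating).
#' @param config A [sim_config()] object.
#' @param freqs Optional vector of per-SNP allele frequencies; drawn from
#'   `founder_maf_range` when omitted. Used internally so the three samples
#'   share one frequency spectrum.
#' @return An object of class `"population"`: a list with `id`, `father`,
#'   `mother`, `family`, `generation`, integer genotype matrix `geno`
#'   (individuals x SNPs, entries 0/1/2), and phenotype slots (filled later).
#' @export
draw_founders <- function(n_individuals, config, freqs = NULL) {
  validate_sim_config(config)
  n <- as.integer(n_individuals)
  if (n < 2L) stop("draw_founders(): need at least 2 founders", call. = FALSE)
  r <- config$founder_maf_range
  if (is.null(freqs)) freqs <- stats::runif(config$n_snps, r[1], r[2])
  geno <- .founder_geno_cpp(n, freqs)
  structure(list(
    id = seq_len(n),
    father = rep(NA_integer_, n),
    mother = rep(NA_integer_, n),
    family = seq_len(n),          # founders are their own "family"
    generation = 0L,
    geno = geno,
    freqs = freqs,
    nurture_raw = NULL,
    true_pgi = NULL, true_nurture = NULL, phenotype = NULL,
    pgi_scale = NULL
  ), class = "population")
}

#' Pair mates with a target phenotypic correlation
#'
#' Assortative mating by Gaussian-coupling rank matching: the generation is
#' split at random into two equal pools; pool A is sorted by phenotype and
#' pool B by the noisy index `am_rho * Y + sqrt(1 - am_rho^2) * z` with `z`
#' standard normal, and mates are paired by rank. Because the noisy index has
#' the same marginal distribution as the phenotype, the realized mate
#' correlation converges to `am_rho` as the number of couples grows;
#' `am_rho = 0` reduces to uniform random pairing and `am_rho = 1` to exact
#' rank matching.
#'
#' @param population A `"population"` with phenotypes assigned.
#' @param am_rho Target mate phenotypic correlation in `[0, 1]`.
#' @return Integer matrix with one row per couple and columns `mate1`,
#'   `mate2` holding row indices into the population.
#' @export
mate <- function(population, am_rho) {
  if (am_rho < 0 || am_rho > 1) {
    stop("mate(): am_rho must lie in [0, 1]", call. = FALSE)
  }
  y <- population$phenotype
  if (is.null(y)) stop("mate(): phenotypes not assigned", call. = FALSE)
  n <- length(y)
  if (n %% 2L != 0L) stop("mate(): need an even number of individuals", call. = FALSE)
  perm <- sample.int(n)
  a <- perm[seq_len(n %/% 2L)]
  b <- perm[(n %/% 2L + 1L):n]
  if (am_rho == 0) {
    return(cbind(mate1 = a, mate2 = b))
  }
  sy <- sd(y)
  ys <- if (sy > 0) (y - mean(y)) / sy else y * 0
  idx_b <- am_rho * ys[b] + sqrt(1 - am_rho^2) * rnorm(length(b))
  cbind(mate1 = a[order(ys[a])], mate2 = b[order(idx_b)])
}

#' Produce the next generation
#'
#' Every couple has exactly two children. Per SNP, each child independently
#' receives one allele from each parent, drawn uniformly from that parent's
#' two alleles (no linkage). The children's parental-nurture raw score
#' `sum_j nurture_j * (geno_father_j + geno_mother_j)` is computed here while
#' the parents' genotypes are in hand.
#'
#' @param couples Couple matrix from [mate()].
#' @param population The parent `"population"`.
#' @param effects An `"effect_set"`; only the nurture vector is used.
#' @return The offspring `"population"`; `family` numbers couples, and two
#'   consecutive rows are siblings.
#' @export
reproduce <- function(couples, population, effects) {
  nf <- nrow(couples)
  geno <- .transmit_cpp(population$geno, couples[, 1L], couples[, 2L])
  fi <- rep(couples[, 1L], each = 2L)
  mi <- rep(couples[, 2L], each = 2L)
  gamma_score <- .geno_score_cpp(population$geno, effects$nurture)
  structure(list(
    id = max(population$id) + seq_len(2L * nf),
    father = population$id[fi],
    mother = population$id[mi],
    family = rep(seq_len(nf), each = 2L),
    generation = population$generation + 1L,
    geno = geno,
    freqs = population$freqs,
    nurture_raw = gamma_score[fi] + gamma_score[mi],
    true_pgi = NULL, true_nurture = NULL, phenotype = NULL,
    pgi_scale = population$pgi_scale
  ), class = "population")
}

#' Assign phenotypes
#'
#' Builds the outcome `Y = sqrt(h2) * G_st + sqrt(n2) * P_st + e`, where
#' `G_st` is the latent direct genetic factor (genotypes weighted by the
#' sample's direct-effect variant, standardized within the generation),
#' `P_st` is the standardized parental-nurture factor (zero for founders),
#' and `e` is independent Gaussian noise with variance `1 - h2 - n2`
#' (`1 - h2` for founders). The standardized direct factor is stored as
#' `true_pgi`. Under simultaneous assortative mating and genetic nurture a
#' positive covariance between `G_st` and `P_st` emerges over generations, so
#' the realized `Var(Y)` may exceed 1; it is reported via the returned
#' population, not forced back to 1.
#'
#' @param population A `"population"` with genotypes.
#' @param effects An `"effect_set"`.
#' @param h2,n2 Variance shares of direct genetic effects and genetic nurture.
#' @param variant Which direct-effect variant to use: `"pred"`, `"disc1"`, or
#'   `"disc2"`.
#' @param standardize If `TRUE` (default) standardize the latent factors
#'   within this generation; if `FALSE`, reuse the scaling stored from the
#'   founder generation.
#' @return The population with `phenotype`, `true_pgi`, `true_nurture` filled.
#' @export
assign_phenotype <- function(population, effects, h2, n2,
                             variant = c("pred", "disc1", "disc2"),
                             standardize = TRUE) {
  variant <- match.arg(variant)
  if (h2 < 0 || n2 < 0 || h2 + n2 > 1 + 1e-12) {
    stop(sprintf("assign_phenotype(): variance budget h2 + n2 = %.3f not in [0, 1]",
                 h2 + n2), call. = FALSE)
  }
  beta <- effects$variants[, variant]
  g_raw <- .geno_score_cpp(population$geno, beta)
  founder <- is.null(population$nurture_raw)
  if (standardize || is.null(population$pgi_scale)) {
    mu_g <- mean(g_raw); sd_g <- sd(g_raw)
    scale_rec <- list(mu_g = mu_g, sd_g = sd_g, mu_p = NA_real_, sd_p = NA_real_)
  } else {
    scale_rec <- population$pgi_scale
    mu_g <- scale_rec$mu_g; sd_g <- scale_rec$sd_g
  }
  if (!is.finite(sd_g) || sd_g <= 0) {
    stop("assign_phenotype(): latent genetic factor has zero variance", call. = FALSE)
  }
  g_st <- (g_raw - mu_g) / sd_g
  if (!founder && n2 > 0) {
    p_raw <- population$nurture_raw
    if (standardize || is.na(scale_rec$mu_p)) {
      mu_p <- mean(p_raw); sd_p <- sd(p_raw)
      scale_rec$mu_p <- mu_p; scale_rec$sd_p <- sd_p
    } else {
      mu_p <- scale_rec$mu_p; sd_p <- scale_rec$sd_p
    }
    p_st <- (p_raw - mu_p) / sd_p
    e_var <- 1 - h2 - n2
  } else {
    p_st <- numeric(length(g_st))
    e_var <- 1 - h2
  }
  y <- sqrt(h2) * g_st + sqrt(n2) * p_st + rnorm(length(g_st), sd = sqrt(e_var))
  population$true_pgi <- g_st
  population$true_nurture <- p_st
  population$phenotype <- y
  population$pgi_scale <- scale_rec
  population
}

simulate_partition <- function(config, effects, n_fam, variant, freqs) {
  pop <- draw_founders(2L * n_fam, config, freqs = freqs)
  pop <- assign_phenotype(pop, effects, config$h2, config$n2, variant = variant,
                          standardize = TRUE) # founder scaling is the anchor
  for (g in seq_len(config$n_generations)) {
    couples <- mate(pop, config$am_rho)
    pop <- reproduce(couples, pop, effects)
    pop <- assign_phenotype(pop, effects, config$h2, config$n2, variant = variant,
                            standardize = config$standardize_each_generation)
  }
  pop
}

#' Run the full family simulation
#'
#' Simulates the three samples (two GWAS discovery samples and a prediction
#' sample) as separate sub-populations sharing one founder allele-frequency
#' spectrum and the nurture effect vector, each using its own rg-correlated
#' direct-effect variant. Each sub-population runs
#' `draw_founders -> n_generations x (mate -> reproduce -> assign_phenotype)`.
#' In the final generation each discovery family contributes one randomly
#' chosen sibling to the GWAS subset; the prediction sample keeps both
#' siblings so within-family estimation is possible.
#'
#' @param config A [sim_config()] object.
#' @return Object of class `"pgi_sim"`: list with `config`, `effects`,
#'   populations `disc1`, `disc2`, `pred`, and `gwas_idx` (row indices of the
#'   one-sibling-per-family GWAS subsets of the two discovery samples).
#' @examples
#' sim <- simulate_study(sim_config(n_snps = 200, n_fam_disc1 = 50,
#'                                  n_fam_disc2 = 50, n_fam_pred = 100,
#'                                  seed = 7))
#' sim
#' @export
simulate_study <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  effects <- draw_effects(config)
  r <- config$founder_maf_range
  freqs <- stats::runif(config$n_snps, r[1], r[2])
  disc1 <- simulate_partition(config, effects, config$n_fam_disc1, "disc1", freqs)
  disc2 <- simulate_partition(config, effects, config$n_fam_disc2, "disc2", freqs)
  pred <- simulate_partition(config, effects, config$n_fam_pred, "pred", freqs)
  pick_one <- function(pop) {
    nf <- length(pop$family) %/% 2L
    2L * seq_len(nf) - 1L + (sample.int(2L, nf, replace = TRUE) - 1L)
  }
  structure(list(config = config, effects = effects,
                 disc1 = disc1, disc2 = disc2, pred = pred,
                 gwas_idx = list(disc1 = pick_one(disc1),
                                 disc2 = pick_one(disc2))),
            class = "pgi_sim")
}

#' @export
print.pgi_sim <- function(x, ...) {
  cat("Simulated family study\n")
  cat(sprintf("  discovery 1: %d individuals (%d in GWAS subset)\n",
              nrow(x$disc1$geno), length(x$gwas_idx$disc1)))
  cat(sprintf("  discovery 2: %d individuals (%d in GWAS subset)\n",
              nrow(x$disc2$geno), length(x$gwas_idx$disc2)))
  cat(sprintf("  prediction : %d individuals in %d sibling pairs\n",
              nrow(x$pred$geno), nrow(x$pred$geno) %/% 2L))
  print(x$config)
  invisible(x)
}

#' True target coefficient of a scenario
#'
#' The between-family target is the slope of the outcome on the standardized
#' latent additive SNP factor in the prediction sample. That factor is the
#' infinite-GWAS-limit PGI: genotypes weighted by the phenotype-scale
#' per-allele direct effects plus the per-allele nurture effects (the
#' projection of the parental nurture factor onto the child's own genotype).
#' Under random mating its expectation is `sqrt(h2 + 0.5 * n2)`; under
#' simultaneous assortative mating and genetic nurture the emergent
#' direct-nurture covariance drives it up. The within-family target is the
#' square root of the direct genetic effect, `sqrt(h2)`.
#'
#' @param sim A `"pgi_sim"` object.
#' @param scope `"between"` or `"within"`.
#' @return The target coefficient (scalar).
#' @export
true_target_coefficient <- function(sim, scope = c("between", "within")) {
  scope <- match.arg(scope)
  cfg <- sim$config
  if (scope == "within") return(sqrt(cfg$h2))
  pop <- sim$pred
  sc <- pop$pgi_scale
  b <- sqrt(cfg$h2) * sim$effects$direct / sc$sd_g
  w <- b
  if (cfg$n2 > 0 && !is.na(sc$sd_p)) {
    w <- w + sqrt(cfg$n2) * sim$effects$nurture / sc$sd_p
  }
  t_raw <- .geno_score_cpp(pop$geno, w)
  t_st <- (t_raw - mean(t_raw)) / sd(t_raw)
  unname(coef(lm.fit(cbind(1, t_st), pop$phenotype))[2L])
}

# lm.fit is used without attaching its full formula machinery
#' @importFrom stats lm.fit
NULL
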