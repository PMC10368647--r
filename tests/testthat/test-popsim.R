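test_that("configuration validation rejects out-of-range parameters", {
  ok <- function(...) sim_config(n_snps = 10, n_fam_disc1 = 2, n_fam_disc2 = 2,
                                 n_fam_pred = 4, seed = 1, ...)
  expect_s3_class(ok(), "sim_config")
  expect_error(ok(h2 = 0.8, n2 = 0.5), "0.5\\*n2|exceeds 1")
  expect_error(ok(am_rho = 1.5), "am_rho")
  expect_error(ok(rg_disc_pred = 0), "rg_disc_pred")
  expect_error(ok(rg_disc_pred = 0.5, rg_disc_disc = 0.5), "at most one")
  expect_error(ok(founder_maf_range = c(0, 0.6)), "founder_maf_range")
  expect_error(sim_config(n_snps = 10, n_fam_disc1 = 2, n_fam_disc2 = 2,
                          n_fam_pred = 4), "seed")
})

test_that("effect draws realize the configured genetic correlations", {
  m <- 5000
  tol <- 3 / sqrt(m)
  base <- function(...) sim_config(n_snps = m, n_fam_disc1 = 2, n_fam_disc2 = 2,
                                   n_fam_pred = 4, seed = 1, ...)
  set.seed(42)
  e0 <- draw_effects(base())
  expect_identical(e0$variants[, "disc1"], e0$variants[, "pred"])
  expect_identical(e0$variants[, "disc2"], e0$variants[, "pred"])
  expect_lt(abs(cor(e0$direct, e0$nurture)), tol)

  e1 <- draw_effects(base(rg_disc_disc = 0.5))
  expect_lt(abs(cor(e1$variants[, "disc1"], e1$variants[, "disc2"]) - 0.5), tol)
  expect_identical(e1$variants[, "disc2"], e1$variants[, "pred"])

  e2 <- draw_effects(base(rg_disc_pred = 0.7))
  expect_lt(abs(cor(e2$variants[, "disc1"], e2$variants[, "pred"]) - 0.7), tol)
  expect_identical(e2$variants[, "disc1"], e2$variants[, "disc2"])
})

test_that("founder genotypes follow Binomial(2, p)", {
  cfg <- sim_config(n_snps = 3, n_fam_disc1 = 2, n_fam_disc2 = 2,
                    n_fam_pred = 2, seed = 3,
                    founder_maf_range = c(0.5, 0.5))
  set.seed(3)
  tiny <- draw_founders(2, cfg)
  expect_identical(dim(tiny$geno), c(2L, 3L))
  expect_true(all(tiny$geno %in% 0:2))

  big <- draw_founders(20000, cfg)
  expect_true(all(abs(colMeans(big$geno) - 1) < 0.03)) # mean allele count 2p = 1
})

test_that("assortative mating achieves the target mate correlation", {
  fp <- founder_pop(20000, 10, seed = 11)
  for (rho in c(0, 0.5, 1)) {
    set.seed(100 + rho * 100)
    cpl <- mate(fp$pop, rho)
    r <- cor(fp$pop$phenotype[cpl[, 1]], fp$pop$phenotype[cpl[, 2]])
    if (rho == 1) expect_gt(r, 0.99) else expect_lt(abs(r - rho), 0.03)
  }
  expect_error(mate(fp$pop, 1.2), "am_rho")
})

test_that("transmission is Mendelian and siblings correlate at one half", {
  # enumerated transmission law for every parental genotype pair
  probs <- function(g) switch(g + 1L, c(1, 0), c(0.5, 0.5), c(0, 1)) # P(allele=0,1)
  set.seed(5)
  for (gf in 0:2) for (gm in 0:2) {
    parents <- matrix(c(gf, gm), 2, 1)
    kids <- pgicorrect:::.transmit_cpp(parents, rep(1L, 50000), rep(2L, 50000))
    pf <- probs(gf); pm <- probs(gm)
    expected <- c(pf[1] * pm[1], pf[1] * pm[2] + pf[2] * pm[1], pf[2] * pm[2])
    obs <- tabulate(kids + 1L, nbins = 3)
    keep <- expected > 0
    if (sum(keep) > 1) {
      p <- chisq.test(obs[keep], p = expected[keep])$p.value
      expect_gt(p, 0.001)
    } else {
      expect_true(all(kids == which(keep) - 1L))
    }
  }

  # sibling genotypic correlation under random mating
  fp <- founder_pop(10000, 50, seed = 6)
  set.seed(6)
  cpl <- mate(fp$pop, 0)
  kids <- reproduce(cpl, fp$pop, fp$effects)
  s1 <- kids$geno[seq(1, nrow(kids$geno), 2), ]
  s2 <- kids$geno[seq(2, nrow(kids$geno), 2), ]
  sib_cor <- vapply(seq_len(50), function(j) cor(s1[, j], s2[, j]), numeric(1))
  expect_lt(abs(mean(sib_cor) - 0.5), 0.02)
})

test_that("allele frequencies are conserved across a random-mating generation", {
  fp <- founder_pop(10000, 200, seed = 7)
  set.seed(7)
  kids <- reproduce(mate(fp$pop, 0), fp$pop, fp$effects)
  p0 <- colMeans(fp$pop$geno) / 2
  p1 <- colMeans(kids$geno) / 2
  se <- sqrt(p0 * (1 - p0) / (2 * nrow(kids$geno)))
  expect_true(all(abs(p1 - p0) <= 4 * se))
})

test_that("the latent direct factor is standardized within each generation", {
  cfg <- sim_config(n_snps = 300, n_fam_disc1 = 50, n_fam_disc2 = 50,
                    n_fam_pred = 100, h2 = 0.2, n2 = 0.1, am_rho = 0.5,
                    n_generations = 3, seed = 9)
  sim <- simulate_study(cfg)
  for (part in c("disc1", "disc2", "pred")) {
    expect_lt(abs(mean(sim[[part]]$true_pgi)), 1e-8)
    expect_lt(abs(var(sim[[part]]$true_pgi) - 1), 1e-8)
    expect_lt(abs(var(sim[[part]]$true_nurture) - 1), 1e-8)
  }
})

test_that("identical configurations give bit-identical simulations", {
  cfg <- sim_config(n_snps = 200, n_fam_disc1 = 30, n_fam_disc2 = 30,
                    n_fam_pred = 60, am_rho = 0.25, n_generations = 2, seed = 123)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$pred$geno, s2$pred$geno)
  expect_identical(s1$pred$phenotype, s2$pred$phenotype)
  expect_identical(s1$gwas_idx, s2$gwas_idx)
})

test_that("study bookkeeping: partition sizes and one GWAS sibling per family", {
  cfg <- sim_config(n_snps = 100, n_fam_disc1 = 40, n_fam_disc2 = 30,
                    n_fam_pred = 50, seed = 17)
  sim <- simulate_study(cfg)
  expect_equal(nrow(sim$disc1$geno), 80)
  expect_equal(nrow(sim$disc2$geno), 60)
  expect_equal(nrow(sim$pred$geno), 100)
  expect_equal(length(sim$gwas_idx$disc1), 40)
  fams <- sim$disc1$family[sim$gwas_idx$disc1]
  expect_false(any(duplicated(fams))) # at most one sibling per family
  # every non-founder has both parents from the previous generation
  expect_false(anyNA(sim$pred$father))
  expect_true(all(table(sim$pred$family) == 2))
})

test_that("the target coefficient reflects the SNP heritability", {
  cfg <- sim_config(n_snps = 1000, n_fam_disc1 = 5, n_fam_disc2 = 5,
                    n_fam_pred = 4000, seed = 21)
  sim <- simulate_study(cfg)
  expect_lt(abs(true_target_coefficient(sim, "between") - 0.5), 0.05)
  expect_equal(true_target_coefficient(sim, "within"), sqrt(0.25))

  cfg_gn <- sim_config(n_snps = 1000, n_fam_disc1 = 5, n_fam_disc2 = 5,
                       n_fam_pred = 4000, h2 = 0.2, n2 = 0.1, seed = 22)
  sim_gn <- simulate_study(cfg_gn)
  expect_lt(abs(true_target_coefficient(sim_gn, "between") - sqrt(0.25)), 0.05)
  expect_equal(true_target_coefficient(sim_gn, "within"), sqrt(0.2))
})
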