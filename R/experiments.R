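#' Baseline-style scenario configuration
#'
#' Builds a [sim_config()] for the canonical simulation design: `M = 5000`
#' SNPs, SNP heritability 0.25 (split as `h2 = 0.2`, `n2 = 0.1` when genetic
#' nurture is on), total GWAS discovery size split into two equal
#' non-overlapping GWAS, and a prediction sample of sibling pairs.
#'
#' @param n_gwas_total Total GWAS discovery sample size (individuals, one per
#'   family); split into two GWAS of `n_gwas_total / 2`.
#' @param n_pred Prediction sample size in individuals (`n_pred / 2` sibling
#'   pairs).
#' @param gn Genetic nurture on (`h2 = 0.2`, `n2 = 0.1`) or off
#'   (`h2 = 0.25`, `n2 = 0`)?
#' @param am_rho Assortative-mating strength.
#' @param rg_disc_pred,rg_disc_disc Genetic correlations, see [sim_config()].
#' @param n_snps Number of SNPs.
#' @param seed Seed.
#' @param ... Further arguments passed to [sim_config()].
#' @return A `"sim_config"`.
#' @export
scenario_config <- function(n_gwas_total, n_pred, gn = FALSE, am_rho = 0,
                            rg_disc_pred = 1, rg_disc_disc = 1,
                            n_snps = 5000, seed, ...) {
  sim_config(n_snps = n_snps,
             n_fam_disc1 = n_gwas_total %/% 2L,
             n_fam_disc2 = n_gwas_total %/% 2L,
             n_fam_pred = n_pred %/% 2L,
             h2 = if (gn) 0.2 else 0.25,
             n2 = if (gn) 0.1 else 0,
             am_rho = am_rho,
             rg_disc_pred = rg_disc_pred, rg_disc_disc = rg_disc_disc,
             seed = seed, ...)
}

run_one_replication <- function(config, within = FALSE, greml = TRUE,
                                greml_method = "grm_cutoff") {
  sim <- simulate_study(config)
  pgis <- build_study_pgis(sim)
  y <- standardize(sim$pred$phenotype)
  fam <- sim$pred$family
  target_b <- true_target_coefficient(sim, "between")
  target_w <- true_target_coefficient(sim, "within")
  fits <- list(
    ols_meta = ols_pgi(y, pgis$pgi_meta_st, fam, method = "ols_meta"),
    oriv = oriv(y, pgis$oriv_set, family_id = fam)
  )
  if (within) {
    fits$ols_meta_within <- ols_pgi(y, pgis$pgi_meta_st, fam, within = TRUE,
                                    method = "ols_meta")
    fits$oriv_within <- oriv(y, pgis$oriv_set, family_id = fam, within = TRUE)
  }
  h2_rec <- NULL
  if (greml) {
    h2_rec <- greml_prediction_sample(sim, method = greml_method)
    rc <- pgi_rc(fits$ols_meta$beta, fits$ols_meta$se,
                 h2_rec$h2_hat, h2_rec$se_h2)
    fits$pgi_rc_default <- rc$default
    fits$pgi_rc_greml_unc <- rc$greml_unc
  }
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(method = nm, within = f$within, estimate = f$beta, se = f$se,
               excluded = "h2_below_0.01" %in% f$flags,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$target <- ifelse(out$within, target_w, target_b)
  out$h2_hat <- if (is.null(h2_rec)) NA_real_ else h2_rec$h2_hat
  out$rhat <- pgis$oriv_set$rhat
  out
}

#' Run one scenario over replications
#'
#' Per replication: simulate the study, run the two GWAS and the
#' meta-analysis, build and scale the PGIs, run the estimators (meta-OLS and
#' ORIV between families; optionally within families; PGI-RC when GREML is
#' run), and record per-method estimates together with the replication's
#' true target coefficients. Replication `r` uses seed `base_seed + r`, so
#' grid points given distinct base seeds are independent and every record is
#' reproducible in isolation.
#'
#' @param config A `"sim_config"` (its `seed` is overridden per replication).
#' @param replications Number of runs.
#' @param base_seed Base seed.
#' @param within Also run the within-family estimators?
#' @param greml_reps Number of replications (from the first) in which GREML
#'   and hence PGI-RC are computed; defaults to all. GREML cost is cubic in
#'   the pruned prediction sample, so large-sample scenarios may reduce this.
#' @param greml_method Passed to [greml_prediction_sample()].
#' @return Data frame of class `"scenario_runs"` with one row per
#'   (replication, method).
#' @export
run_scenario <- function(config, replications, base_seed, within = FALSE,
                         greml_reps = replications,
                         greml_method = "grm_cutoff") {
  recs <- vector("list", replications)
  for (r in seq_len(replications)) {
    cfg <- config
    cfg$seed <- as.integer(base_seed + r)
    rec <- run_one_replication(cfg, within = within, greml = r <= greml_reps,
                               greml_method = greml_method)
    rec$replication <- r
    recs[[r]] <- rec
  }
  out <- do.call(rbind, recs)
  class(out) <- c("scenario_runs", "data.frame")
  out
}

#' Summarize a scenario
#'
#' Per method: mean estimate over included runs, the confidence interval
#' `mean estimate +/- 1.96 * mean SE`, the empirical SD of the estimates, and
#' the root-mean-squared error against the scenario's true target
#' coefficient (`RMSE^2 = bias^2 + variance`, with the variance computed with
#' denominator n so the identity is exact). PGI-RC aggregation excludes runs
#' flagged by the `h2 < 0.01` rule.
#'
#' @param runs A `"scenario_runs"` data frame.
#' @param target Optional scalar target overriding the per-run recorded
#'   target (whose mean is used by default).
#' @return Data frame with one row per method.
#' @export
summarize_scenario <- function(runs, target = NULL) {
  stopifnot(nrow(runs) > 0L)
  parts <- split(runs, runs$method)
  rows <- lapply(parts, function(d) {
    d <- d[!d$excluded, , drop = FALSE]
    if (nrow(d) == 0L) stop("summarize_scenario(): no included runs for a method", call. = FALSE)
    tgt <- if (is.null(target)) mean(d$target) else target
    m <- mean(d$estimate)
    vv <- mean((d$estimate - m)^2)
    data.frame(method = d$method[1L], within = d$within[1L],
               mean = m, mean_se = mean(d$se),
               ci_low = m - 1.96 * mean(d$se), ci_high = m + 1.96 * mean(d$se),
               sd = sqrt(vv), target = tgt,
               rmse = sqrt((m - tgt)^2 + vv),
               n_runs = nrow(d) + sum(runs$method == d$method[1L] & runs$excluded),
               n_included = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Baseline scenario table across GWAS and prediction sample sizes
#'
#' Runs the baseline design (no genetic nurture, no assortative mating) over
#' the grid of two GWAS discovery sizes (total 4000, "~EA2-like", and total
#' 32000, "~EA4-like") by prediction sample sizes, and reports mean
#' estimates with confidence intervals for the meta-analysis PGI, ORIV, and
#' both PGI-RC variants. The true coefficient is 0.5.
#'
#' @param replications Replications per cell.
#' @param base_seed Base seed; each cell gets a disjoint derived seed block.
#' @param n_pred Prediction sample sizes (individuals).
#' @param n_gwas_total Total GWAS discovery sizes.
#' @param greml_reps Per-cell cap on GREML-bearing replications (see
#'   [run_scenario()]); may be a single number.
#' @param n_snps Number of SNPs.
#' @return Data frame with one row per (GWAS size, prediction size, method).
#' @export
baseline_table <- function(replications = 100, base_seed = 20250101,
                           n_pred = c(1000, 4000, 16000),
                           n_gwas_total = c(4000, 32000),
                           greml_reps = replications,
                           n_snps = 5000) {
  cells <- expand.grid(n_gwas = n_gwas_total, n_pred = n_pred)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cfg <- scenario_config(cells$n_gwas[i], cells$n_pred[i], seed = 1,
                           n_snps = n_snps)
    runs <- run_scenario(cfg, replications,
                         base_seed = base_seed + (i - 1L) * 100000L,
                         greml_reps = min(greml_reps, replications))
    s <- summarize_scenario(runs, target = 0.5)
    s$n_gwas_total <- cells$n_gwas[i]
    s$n_pred <- cells$n_pred[i]
    out[[i]] <- s
  }
  do.call(rbind, out)
}
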