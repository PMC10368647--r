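#' Genetic relatedness matrix
#'
#' Column-standardizes the genotype matrix (per-SNP sample mean and SD) and
#' forms `A = Z Z' / M`. Monomorphic SNPs cannot be standardized and are
#' excluded with a message. The diagonal averages about 1 for standardized
#' genotypes and full siblings average about 0.5 off-diagonal.
#'
#' @param genotypes Integer matrix, individuals x SNPs.
#' @param ids Optional individual identifiers (default row number).
#' @return List of class `"grm"` with `A` (symmetric relatedness matrix),
#'   `n_snps` (SNPs used), and `ids`.
#' @export
compute_grm <- function(genotypes, ids = NULL) {
  n <- nrow(genotypes)
  if (n < 2L) stop("compute_grm(): need at least 2 individuals", call. = FALSE)
  if (is.null(ids)) ids <- seq_len(n)
  z <- scale(genotypes)
  keep <- is.finite(colSums(z)) & attr(z, "scaled:scale") > 0
  if (!all(keep)) {
    message(sprintf("compute_grm(): excluding %d monomorphic SNP(s)", sum(!keep)))
    z <- z[, keep, drop = FALSE]
  }
  m <- ncol(z)
  if (m < 1L) stop("compute_grm(): no polymorphic SNPs", call. = FALSE)
  structure(list(A = tcrossprod(z) / m, n_snps = m, ids = ids), class = "grm")
}

#' Greedy relatedness pruning
#'
#' Repeatedly drops the individual involved in the most remaining pairs with
#' relatedness above the cutoff (ties broken by lowest ID) until no pair
#' exceeds the cutoff. With a sibling-pair cohort and the conventional 0.05
#' cutoff this retains exactly one sibling per family.
#'
#' @param grm A `"grm"` object.
#' @param cutoff Relatedness threshold (> 0), default 0.05.
#' @return Integer vector of retained row indices (sorted).
#' @export
prune_related <- function(grm, cutoff = 0.05) {
  if (cutoff <= 0) stop("prune_related(): cutoff must be positive", call. = FALSE)
  a <- grm$A
  n <- nrow(a)
  hits <- which(a > cutoff & upper.tri(a), arr.ind = TRUE)
  if (nrow(hits) == 0L) return(seq_len(n))
  alive <- rep(TRUE, n)
  deg <- tabulate(c(hits[, 1L], hits[, 2L]), nbins = n)
  edge_alive <- rep(TRUE, nrow(hits))
  while (any(edge_alive)) {
    worst <- which(deg == max(deg))[1L] # indices ascend, so first = lowest ID
    alive[worst] <- FALSE
    touch <- edge_alive & (hits[, 1L] == worst | hits[, 2L] == worst)
    if (any(touch)) {
      others <- ifelse(hits[touch, 1L] == worst, hits[touch, 2L], hits[touch, 1L])
      deg[others] <- deg[others] - 1L
      edge_alive[touch] <- FALSE
    }
    deg[worst] <- 0L
  }
  which(alive)
}
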