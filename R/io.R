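# Plain-text interchange formats: PLINK-.raw-style genotypes, pedigree/
# phenotype tables, GWAS summary statistics, PGI tables, the GCTA text GRM
# layout, and JSON/YAML configs. TSV with header rows, '.' for missing,
# UTF-8, LF endings throughout.

tsv_write <- function(df, path) {
  df[] <- lapply(df, function(col) {
    if (is.numeric(col)) ifelse(is.na(col), ".", format(col, digits = 15, trim = TRUE))
    else ifelse(is.na(col), ".", as.character(col))
  })
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
}

tsv_read <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, na.strings = ".",
             stringsAsFactors = FALSE)
}

#' Write/read genotypes in a PLINK-.raw-style TSV
#'
#' Columns `FID`, `IID`, `PAT`, `MAT`, then one column per SNP holding the
#' allele count (0/1/2).
#'
#' @param population A `"population"` object.
#' @param path Output path.
#' @export
write_genotypes_raw <- function(population, path) {
  g <- as.data.frame(population$geno)
  names(g) <- paste0("snp", seq_len(ncol(g)))
  df <- cbind(data.frame(FID = population$family, IID = population$id,
                         PAT = population$father, MAT = population$mother),
              g)
  tsv_write(df, path)
}

#' @rdname write_genotypes_raw
#' @return `read_genotypes_raw()`: list with `geno` (integer matrix) and the
#'   identifier columns.
#' @export
read_genotypes_raw <- function(path) {
  df <- tsv_read(path)
  snp_cols <- setdiff(names(df), c("FID", "IID", "PAT", "MAT"))
  geno <- as.matrix(df[, snp_cols, drop = FALSE])
  storage.mode(geno) <- "integer"
  list(geno = geno, id = df$IID, family = df$FID,
       father = df$PAT, mother = df$MAT)
}

#' Write/read a pedigree + phenotype table
#'
#' Columns `IID`, `FID`, `PAT`, `MAT`, `GENERATION`, `Y`, `TRUE_PGI`.
#'
#' @param population A `"population"` with phenotypes assigned.
#' @param path Output path.
#' @export
write_pedigree <- function(population, path) {
  tsv_write(data.frame(IID = population$id, FID = population$family,
                       PAT = population$father, MAT = population$mother,
                       GENERATION = population$generation,
                       Y = population$phenotype,
                       TRUE_PGI = population$true_pgi), path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) tsv_read(path)

#' Write/read GWAS summary statistics
#'
#' Columns `SNP`, `EAF`, `BETA`, `SE`, `N`.
#'
#' @param sumstats A `"gwas_sumstats"` data frame.
#' @param path File path.
#' @export
write_sumstats <- function(sumstats, path) {
  tsv_write(data.frame(SNP = sumstats$snp, EAF = sumstats$eaf,
                       BETA = sumstats$beta, SE = sumstats$se,
                       N = sumstats$n), path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  df <- tsv_read(path)
  need <- c("SNP", "EAF", "BETA", "SE", "N")
  if (!all(need %in% names(df))) {
    stop("read_sumstats(): missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  out <- data.frame(snp = df$SNP, eaf = df$EAF, beta = df$BETA,
                    se = ifelse(is.na(df$SE), Inf, df$SE), n = df$N,
                    stringsAsFactors = FALSE)
  class(out) <- c("gwas_sumstats", "data.frame")
  out
}

#' Write a PGI table
#'
#' Columns `IID`, `FID`, `PGI1`, `PGI2`, `PGI_META` (standardized values,
#' 6 decimals).
#'
#' @param id,family Identifier vectors.
#' @param pgi1_st,pgi2_st,pgi_meta_st Standardized PGIs.
#' @param path File path.
#' @export
write_pgi_table <- function(id, family, pgi1_st, pgi2_st, pgi_meta_st, path) {
  df <- data.frame(IID = id, FID = family,
                   PGI1 = sprintf("%.6f", pgi1_st),
                   PGI2 = sprintf("%.6f", pgi2_st),
                   PGI_META = sprintf("%.6f", pgi_meta_st))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
}

#' @rdname write_pgi_table
#' @export
read_pgi_table <- function(path) tsv_read(path)

#' Write/read a GRM as lower-triangle text (GCTA layout)
#'
#' One row per pair (including the diagonal): `ID1`, `ID2`, `NSNPS`, `VALUE`.
#'
#' @param grm A `"grm"` object.
#' @param path File path.
#' @export
write_grm_text <- function(grm, path) {
  n <- nrow(grm$A)
  idx <- which(lower.tri(grm$A, diag = TRUE), arr.ind = TRUE)
  tsv_write(data.frame(ID1 = grm$ids[idx[, 1L]], ID2 = grm$ids[idx[, 2L]],
                       NSNPS = grm$n_snps, VALUE = grm$A[idx]), path)
}

#' @rdname write_grm_text
#' @export
read_grm_text <- function(path) {
  df <- tsv_read(path)
  ids <- unique(c(df$ID2, df$ID1))
  n <- length(ids)
  a <- matrix(0, n, n)
  i <- match(df$ID1, ids)
  j <- match(df$ID2, ids)
  a[cbind(i, j)] <- df$VALUE
  a[cbind(j, i)] <- df$VALUE
  structure(list(A = a, n_snps = df$NSNPS[1L], ids = ids), class = "grm")
}

#' Read/write a simulation config as JSON or YAML
#'
#' Field names mirror [sim_config()] exactly; `seed` is mandatory. The format
#' follows the file extension (`.json`, `.yaml`/`.yml`).
#'
#' @param path File path.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lst <- switch(ext,
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                yaml = , yml = yaml::read_yaml(path),
                stop("read_config(): unsupported extension '", ext, "'", call. = FALSE))
  known <- names(formals(sim_config))
  unknown <- setdiff(names(lst), known)
  if (length(unknown)) {
    stop("read_config(): unknown field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(lst$seed)) stop("read_config(): missing mandatory field 'seed'", call. = FALSE)
  do.call(sim_config, lst)
}

#' @rdname read_config
#' @param config A `"sim_config"` object.
#' @export
write_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  lst <- unclass(config)
  switch(ext,
         json = jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA),
         yaml = , yml = yaml::write_yaml(lst, path),
         stop("write_config(): unsupported extension '", ext, "'", call. = FALSE))
  invisible(path)
}

#' Write estimator results
#'
#' Columns `METHOD`, `SCOPE`, `BETA`, `SE`, `CI_LOW`, `CI_HIGH`,
#' `IMPLIED_H2`, `FIRST_STAGE_F`, `N`, `N_CLUSTERS`, `FLAGS`.
#'
#' @param fits A list of `"pgi_fit"` objects.
#' @param path File path.
#' @export
write_estimates <- function(fits, path) {
  rows <- lapply(fits, function(f) {
    data.frame(METHOD = f$method,
               SCOPE = if (f$within) "within" else "between",
               BETA = f$beta, SE = f$se, CI_LOW = f$ci_low, CI_HIGH = f$ci_high,
               IMPLIED_H2 = f$implied_h2,
               FIRST_STAGE_F = ifelse(is.finite(f$first_stage_F),
                                      f$first_stage_F, NA_real_),
               N = f$n_obs, N_CLUSTERS = f$n_clusters,
               FLAGS = if (length(f$flags)) paste(f$flags, collapse = ",") else NA_character_,
               stringsAsFactors = FALSE)
  })
  tsv_write(do.call(rbind, rows), path)
}

#' Write a run manifest
#'
#' Structured-text record of a command-line run: the config, seed, package
#' version, timestamp, and md5 digests of the files produced.
#'
#' @param config A `"sim_config"` (or NULL).
#' @param outputs Character vector of output file paths.
#' @param path Manifest path (JSON).
#' @export
write_manifest <- function(config, outputs, path) {
  man <- list(
    package = "pgicorrect",
    version = as.character(utils::packageVersion("pgicorrect")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = if (is.null(config)) NULL else unclass(config),
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(f) unname(tools::md5sum(f)))
  )
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
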