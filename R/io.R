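# File handling: delimited phenotype/covariate tables, genotype matrices,
# VCF dosages, and the per-SNP testing workflow.

read_delim_auto <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

#' Read a phenotype or covariate table
#'
#' Reads a delimited text file (TSV, or CSV by extension) with a header row.
#' The first column (or `id_col`) is taken as the individual identifier and
#' coerced to character; remaining columns must be numeric.
#'
#' @param path Path to the file.
#' @param id_col Name or position of the identifier column.
#' @return A tibble whose first column is `id`.
#' @export
read_phenotype_table <- function(path, id_col = 1L) {
  tab <- read_delim_auto(path)
  idx <- if (is.character(id_col)) match(id_col, names(tab)) else as.integer(id_col)
  if (is.na(idx)) abort(paste0("id column '", id_col, "' not found in ", path))
  ids <- as.character(tab[[idx]])
  out <- tab[, -idx, drop = FALSE]
  if (!all(vapply(out, is.numeric, logical(1)))) {
    abort(paste0("non-numeric data column in ", path))
  }
  bind_cols(tibble(id = ids), out)
}

#' Read a delimited 0/1/2 genotype matrix
#'
#' Expects a header row, an identifier column (first by default) and one
#' column per SNP holding minor-allele counts 0, 1 or 2 (missing values
#' allowed).
#'
#' @inheritParams read_phenotype_table
#' @return A tibble whose first column is `id`, other columns SNP dosages.
#' @export
read_genotype_matrix <- function(path, id_col = 1L) {
  tab <- read_phenotype_table(path, id_col = id_col)
  vals <- unlist(tab[, -1L], use.names = FALSE)
  vals <- vals[!is.na(vals)]
  if (length(vals) > 0 && (any(vals != round(vals)) || any(vals < 0) || any(vals > 2))) {
    abort(paste0("genotype matrix ", path, " must contain only 0/1/2 dosages"))
  }
  tab
}

#' Read per-SNP dosages from a VCF
#'
#' Extracts GT fields from a VCF and converts them to minor-allele counts.
#' For each biallelic SNP the ALT-allele dosage is computed from the genotype
#' calls; if the ALT allele is the major one in the sample (frequency above
#' 0.5) the coding is flipped to count the REF allele instead, so dosages
#' always count the observed minor allele (ties are kept on the ALT allele).
#' Multiallelic records are dropped with a warning. Missing calls become
#' `NA`.
#'
#' @param path Path to a VCF file.
#' @return A tibble whose first column is `id` (sample names), other columns
#'   per-SNP minor-allele dosages named by the VCF ID field (or
#'   `CHROM_POS` when the ID is missing).
#' @export
read_vcf_dosages <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcfR::getFIX(v)
  if (is.null(dim(fixm))) { # single record drops to a named vector
    fixm <- matrix(fixm, nrow = 1L, dimnames = list(NULL, names(fixm)))
  }
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT %||% "")
  if (any(multi)) {
    warn(paste0(sum(multi), " multiallelic record(s) dropped from ", path))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  snp_names <- ifelse(is.na(fix$ID) | fix$ID == ".",
                      paste0(fix$CHROM, "_", fix$POS), fix$ID)
  count_alt <- function(calls) {
    alleles <- strsplit(gsub("\\|", "/", calls), "/", fixed = FALSE)
    vapply(alleles, function(a) {
      if (length(a) == 0 || any(a == ".") || any(is.na(a))) return(NA_real_)
      sum(a == "1")
    }, numeric(1))
  }
  dos <- t(apply(gt, 1L, count_alt))
  if (ncol(gt) == 1L) dos <- matrix(dos, ncol = 1L) # guard 1-sample edge
  # orient to the minor allele: flip when ALT frequency exceeds 0.5
  for (j in seq_len(nrow(dos))) {
    af <- mean(dos[j, ], na.rm = TRUE) / 2
    if (!is.nan(af) && af > 0.5) dos[j, ] <- 2 - dos[j, ]
  }
  out <- as_tibble(t(dos), .name_repair = "minimal")
  names(out) <- snp_names
  bind_cols(tibble(id = colnames(gt)), out)
}

#' Write a simulated cohort to delimited files
#'
#' Convenience writer pairing [simulate_bivariate()] / [simulate_highdim()]
#' with the file-based testing workflow: phenotypes (id + Y columns) go to
#' one TSV, genotypes (id + one dosage column named `snp`) to another.
#'
#' @param data A simulated cohort tibble (columns `id`, `g`, `Y*`).
#' @param phenotype_file,genotype_file Output paths.
#' @param snp Column name for the variant in the genotype file.
#' @return Invisibly, the input `data`.
#' @export
write_cohort <- function(data, phenotype_file, genotype_file, snp = "snp1") {
  pheno <- select(data, "id", dplyr::starts_with("Y"))
  geno <- tibble(id = data$id, !!snp := data$g)
  readr::write_tsv(pheno, phenotype_file, progress = FALSE)
  readr::write_tsv(geno, genotype_file, progress = FALSE)
  invisible(data)
}

as_input_table <- function(x, reader, what) {
  if (is.character(x) && length(x) == 1L) return(reader(x))
  if (is.data.frame(x)) {
    x <- as_tibble(x)
    if (names(x)[1L] != "id") names(x)[1L] <- "id"
    x$id <- as.character(x$id)
    return(x)
  }
  abort(paste0(what, " must be a file path or a data frame"))
}

#' Per-SNP association testing
#'
#' Runs the chosen multi-phenotype association test for every SNP in a
#' genotype source against a common phenotype table. Individuals are aligned
#' by identifier; for each SNP, individuals with a missing dosage or any
#' missing phenotype/covariate are dropped (so `n_used` may vary across
#' SNPs), phenotypes are residualized on covariates, transformed according to
#' `method`, and tested. Monomorphic SNPs in the aligned sample are skipped
#' with a warning and recorded in the `skipped` attribute. The
#' `p.bonferroni` column multiplies p-values by the number of SNPs actually
#' tested.
#'
#' @param phenotypes Phenotype table: a data frame or path to a delimited
#'   file (first column = individual id).
#' @param genotypes Genotype source: a data frame or path. Paths ending in
#'   `.vcf`/`.vcf.gz` are parsed as VCF; anything else as a delimited 0/1/2
#'   matrix (first column = individual id, one column per SNP).
#' @param covariates Optional covariate table or path, residualized out of
#'   every phenotype before transformation.
#' @param method `"multiphen"`, `"atemp-rn"` or `"atemp-or"`; a single method
#'   applied to all phenotypes, or one method per phenotype column.
#' @param permutations If > 0, permutation p-values with this many
#'   permutations per SNP.
#' @param seed Optional seed (permutations only).
#' @param out_file Optional path; results are written there as TSV.
#'
#' @return A tibble with one row per tested SNP: `snp`, `maf`, `n`,
#'   `statistic`, `df`, `p.value`, optionally `p.permutation`, and
#'   `p.bonferroni`. Skipped SNPs are listed in `attr(, "skipped")`.
#' @export
test_snps <- function(phenotypes, genotypes, covariates = NULL,
                      method = c("multiphen", "atemp-rn", "atemp-or"),
                      permutations = 0, seed = NULL, out_file = NULL) {
  if (identical(method, c("multiphen", "atemp-rn", "atemp-or"))) {
    method <- "multiphen"
  }
  method <- vapply(method, match_method, character(1), USE.NAMES = FALSE)
  method_label <- paste(method, collapse = ",")
  pheno <- as_input_table(phenotypes, read_phenotype_table, "phenotypes")
  geno_reader <- function(p) {
    if (grepl("\\.vcf(\\.gz)?$", p, ignore.case = TRUE)) {
      read_vcf_dosages(p)
    } else {
      read_genotype_matrix(p)
    }
  }
  geno <- as_input_table(genotypes, geno_reader, "genotypes")
  covar <- if (is.null(covariates)) NULL else {
    as_input_table(covariates, read_phenotype_table, "covariates")
  }
  ids <- intersect(pheno$id, geno$id)
  if (!is.null(covar)) ids <- intersect(ids, covar$id)
  if (length(ids) == 0L) {
    abort("no overlapping individual ids between the input tables")
  }
  Yall <- as.matrix(pheno[match(ids, pheno$id), -1L, drop = FALSE])
  Xall <- if (is.null(covar)) NULL else {
    as.matrix(covar[match(ids, covar$id), -1L, drop = FALSE])
  }
  Gall <- geno[match(ids, geno$id), -1L, drop = FALSE]
  snps <- names(Gall)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  skipped <- character()
  for (s in snps) {
    g <- Gall[[s]]
    keep <- complete.cases(Yall) & !is.na(g)
    if (!is.null(Xall)) keep <- keep & complete.cases(Xall)
    gk <- g[keep]
    if (length(gk) < 2L || length(unique(gk)) < 2L) {
      warn(paste0("SNP '", s, "' skipped: monomorphic or too few complete observations"))
      skipped <- c(skipped, s)
      next
    }
    Y <- Yall[keep, , drop = FALSE]
    if (!is.null(Xall)) Y <- residualize(Y, Xall[keep, , drop = FALSE])
    Y <- apply_transform(Y, method)
    fit <- multiphen_score(Y, gk, permutations = permutations, snp = s)
    fit$method <- method_label
    maf <- mean(gk) / 2
    rows[[s]] <- mutate(tidy(fit), maf = min(maf, 1 - maf), .after = "snp")
  }
  if (length(rows) == 0L) {
    abort("all SNPs were skipped; nothing to test")
  }
  out <- bind_rows(rows)
  m <- nrow(out)
  out <- mutate(out, p.bonferroni = pmin(1, .data$p.value * m))
  attr(out, "skipped") <- skipped
  if (!is.null(out_file)) readr::write_tsv(out, out_file, progress = FALSE)
  out
}
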