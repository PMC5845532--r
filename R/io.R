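#' Write a data frame as TSV
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a twin cohort as TSV (one row per twin)
#' @param cohort Twin cohort data frame.
#' @param path File path.
#' @return `path` invisibly / the cohort data frame.
#' @export
write_cohort_tsv <- function(cohort, path) write_tsv(cohort, path)

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  co <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in intersect(c("gout", "sle"), names(co)))
    co[[col]] <- as.logical(co[[col]])
  validate_cohort(co)
  co
}

# ---- PLINK BED/BIM/FAM (binary, SNP-major, v1.00) ---------------------

#' Write genotypes as a PLINK BED/BIM/FAM file set
#'
#' SNP-major bed v1.00. A1 is the counted (alt/minor) allele, so the
#' stored 2-bit codes are: 00 = 2 copies, 10 = 1 copy, 11 = 0 copies,
#' 01 = missing.
#'
#' @param genotypes Individuals x SNPs matrix in \{0,1,2,NA\}, rows named
#'   `<family>_<member>`.
#' @param meta SNP metadata: `snp`, `chrom`, `pos`, `ref`, `alt`.
#' @param prefix Output path prefix (writes `prefix.bed/.bim/.fam`).
#' @param sex Optional per-individual sex codes ("M"/"F"), for the FAM.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(genotypes, meta, prefix, sex = NULL) {
  n <- nrow(genotypes); m <- ncol(genotypes)
  stopifnot(nrow(meta) == m)
  ids <- rownames(genotypes)
  if (is.null(ids)) ids <- paste0("ind", seq_len(n), "_1")
  fid <- sub("_[^_]*$", "", ids)
  fam <- data.frame(fid = fid, iid = ids, pid = 0, mid = 0,
                    sex = if (is.null(sex)) 0
                          else ifelse(sex == "M", 1L, 2L),
                    pheno = -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  bim <- data.frame(chrom = meta$chrom, snp = meta$snp, cm = 0,
                    pos = meta$pos, a1 = meta$alt, a2 = meta$ref)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  # genotype value -> 2-bit code (indexing by value + 1; NA -> 01)
  code <- c(`0` = 3L, `1` = 2L, `2` = 0L)
  bpr <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  idx <- rep(seq_len(bpr), each = 4)[seq_len(n)]
  shift <- rep(c(0L, 2L, 4L, 6L), length.out = n)
  for (j in seq_len(m)) {
    g <- genotypes[, j]
    cj <- ifelse(is.na(g), 1L, code[as.character(g)])
    bytes <- as.vector(rowsum(cj * 2L^shift, idx))
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}

#' Read a PLINK BED/BIM/FAM file set
#'
#' @param prefix Path prefix of the `.bed/.bim/.fam` files.
#' @return List with `genotypes` (individuals x SNPs, counts of the A1
#'   allele, NA for missing), `meta` (snp, chrom, pos, ref, alt) and
#'   `fam`.
#' @export
read_plink <- function(prefix) {
  fam <- utils::read.table(paste0(prefix, ".fam"),
                           col.names = c("fid", "iid", "pid", "mid",
                                         "sex", "pheno"),
                           stringsAsFactors = FALSE)
  bim <- utils::read.table(paste0(prefix, ".bim"),
                           col.names = c("chrom", "snp", "cm", "pos",
                                         "a1", "a2"),
                           stringsAsFactors = FALSE)
  n <- nrow(fam); m <- nrow(bim)
  bpr <- ceiling(n / 4)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3 + bpr * m)
  if (!identical(as.integer(raw[1:3]), c(0x6cL, 0x1bL, 0x01L)))
    stop("not a SNP-major PLINK bed v1.00 file")
  body <- as.integer(raw[-(1:3)])
  # decode 2-bit fields: 0 -> 2 copies, 1 -> NA, 2 -> 1 copy, 3 -> 0
  lut <- c(2L, NA_integer_, 1L, 0L)
  geno <- matrix(NA_integer_, n, m)
  shift <- rep(c(1L, 4L, 16L, 64L), length.out = 4)
  for (j in seq_len(m)) {
    bytes <- body[((j - 1) * bpr + 1):(j * bpr)]
    codes <- integer(bpr * 4)
    for (k in 0:3)
      codes[seq(k + 1, bpr * 4, by = 4)] <- (bytes %/% shift[k + 1]) %% 4
    geno[, j] <- lut[codes[seq_len(n)] + 1L]
  }
  rownames(geno) <- fam$iid
  colnames(geno) <- bim$snp
  list(genotypes = geno,
       meta = data.frame(snp = bim$snp, chrom = bim$chrom, pos = bim$pos,
                         ref = bim$a2, alt = bim$a1,
                         stringsAsFactors = FALSE),
       fam = fam)
}

# ---- VCF --------------------------------------------------------------

#' Write genotypes as a minimal VCF with GT fields
#'
#' @param genotypes Individuals x SNPs matrix of alt-allele counts.
#' @param meta SNP metadata: `snp`, `chrom`, `pos`, `ref`, `alt`.
#' @param path Output `.vcf` path (uncompressed).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, meta, path) {
  ids <- rownames(genotypes)
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(genotypes)))
  gt <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", ids),
                     collapse = "\t")), con)
  for (j in seq_len(ncol(genotypes))) {
    g <- genotypes[, j]
    calls <- ifelse(is.na(g), "./.", gt[as.character(g)])
    writeLines(paste(c(meta$chrom[j], meta$pos[j], meta$snp[j],
                       meta$ref[j], meta$alt[j], ".", "PASS", ".", "GT",
                       calls), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotypes (alt-allele counts) from a VCF
#'
#' @param path VCF path (anything `vcfR` reads).
#' @return List with `genotypes` (individuals x SNPs) and `meta`.
#' @export
read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count <- function(x) {
    x <- sub("\\|", "/", x)
    ifelse(is.na(x) | x %in% c("./.", "."), NA_integer_,
           vapply(strsplit(x, "/"),
                  function(a) sum(as.integer(a) > 0), integer(1)))
  }
  geno <- apply(gt, 1, count)               # individuals x SNPs
  if (is.null(dim(geno))) geno <- matrix(geno, ncol = nrow(gt))
  fix <- vcfR::getFIX(v)
  meta <- data.frame(snp = fix[, "ID"], chrom = fix[, "CHROM"],
                     pos = as.integer(fix[, "POS"]), ref = fix[, "REF"],
                     alt = fix[, "ALT"], stringsAsFactors = FALSE)
  colnames(geno) <- meta$snp
  list(genotypes = geno, meta = meta)
}

# ---- gene annotation and gene sets ------------------------------------

#' Read gene intervals from a BED-like TSV
#'
#' Expects tab-separated columns `chrom`, `start`, `stop`, `name`
#' (1-based inclusive coordinates), with a header line.
#'
#' @param path File path.
#' @return Data frame sorted by chromosome and start.
#' @export
read_gene_intervals <- function(path) {
  gi <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "stop", "name")
  if (!all(need %in% names(gi)))
    stop("gene interval file must have columns: ",
         paste(need, collapse = ", "))
  gi[order(gi$chrom, gi$start), ]
}

#' Read gene sets from a GMT file
#'
#' @param path GMT path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) fgsea::gmtPathways(path)

# ---- simulation config ------------------------------------------------

#' Write / read a YAML capture of simulation parameters
#'
#' Records the sex-limitation parameters, group sizes, covariate spec
#' and seed of a simulated cohort so it can be regenerated exactly.
#'
#' @param params,sizes,covariates,seed Simulation inputs.
#' @param path YAML path.
#' @return `path` invisibly / a list with the four components rebuilt.
#' @export
write_sim_config <- function(params, sizes, covariates, seed, path) {
  yaml::write_yaml(list(params = unclass(params), sizes = unclass(sizes),
                        covariates = unclass(covariates), seed = seed),
                   path, precision = 17L)   # exact double round-trip
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  list(params = do.call(sexlim_parameters, cfg$params),
       sizes = do.call(group_sizes, cfg$sizes),
       covariates = do.call(covariate_spec, cfg$covariates),
       seed = cfg$seed)
}

# ---- published reference tables ---------------------------------------

#' Published sex-limitation model-fit summary for SUA
#'
#' The -2 log-likelihood and degrees of freedom of the six sex-limitation
#' models as published for the 379-pair Chinese SUA twin cohort this
#' package emulates. These are inputs for the derived quantities (AIC,
#' likelihood-ratio tests, model choice); the raw data behind them are
#' not available.
#'
#' @return Data frame with `model`, `neg2ll`, `df`.
#' @export
published_model_fits <- function() {
  utils::read.delim(system.file("extdata", "sua_model_fits.tsv",
                                package = "twinsua"),
                    stringsAsFactors = FALSE)
}

#' Published gene-set overlap counts for the SUA gene list
#'
#' Gene-set sizes (K) and overlap counts (k) of the published
#' over-representation analysis of SUA-associated genes; inputs for the
#' k/K ratio bookkeeping.
#'
#' @return Data frame with `set`, `K`, `k`.
#' @export
published_gene_set_overlaps <- function() {
  utils::read.delim(system.file("extdata", "sua_gene_set_overlaps.tsv",
                                package = "twinsua"),
                    stringsAsFactors = FALSE)
}
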