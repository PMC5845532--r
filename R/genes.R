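#' Assign SNPs to gene intervals
#'
#' A SNP is assigned to every gene whose flanked interval
#' `[start - flank_bp, stop + flank_bp]` (1-based, closed) contains its
#' position on the same chromosome; multi-assignment is allowed and
#' unassigned SNPs are simply absent from the result.
#'
#' @param snp_meta Data frame with `snp`, `chrom`, `pos`.
#' @param gene_intervals Data frame with `chrom`, `start`, `stop`,
#'   `name` (1-based inclusive coordinates).
#' @param flank_bp Flank added to both gene ends, default 0.
#' @return Data frame with `gene` and `snp` columns, one row per
#'   assignment, in gene-interval order.
#' @export
map_snps_to_genes <- function(snp_meta, gene_intervals, flank_bp = 0) {
  snps <- GenomicRanges::GRanges(
    seqnames = as.character(snp_meta$chrom),
    ranges = IRanges::IRanges(start = snp_meta$pos, width = 1))
  genes <- GenomicRanges::GRanges(
    seqnames = as.character(gene_intervals$chrom),
    ranges = IRanges::IRanges(
      start = pmax(gene_intervals$start - flank_bp, 1),
      end = gene_intervals$stop + flank_bp))
  ov <- GenomicRanges::findOverlaps(genes, snps)
  data.frame(gene = gene_intervals$name[S4Vectors::queryHits(ov)],
             snp = snp_meta$snp[S4Vectors::subjectHits(ov)],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Gene-based association test by LD-corrected chi-square aggregation
#'
#' VEGAS-style statistic: the sum over member SNPs of the 1-df
#' chi-square quantiles of their p-values. Its null distribution is
#' simulated by drawing `z ~ MVN(0, R)` with `R` the local LD
#' correlation matrix and summing `z^2`; the empirical p-value is
#' `(1 + #\{null >= observed\}) / (n_sims + 1)`, never exactly 0. When
#' the first-stage p falls below `escalate_below`, the simulation is
#' repeated at `n_sims_max` draws (in memory-bounded chunks).
#'
#' @param member_pvalues P-values of the SNPs assigned to the gene.
#' @param ld_correlation SNP correlation matrix (positive semi-definite;
#'   a ridge of 1e-6 is added before factorization). Identity by default.
#' @param n_sims First-stage simulation count, default 1e4.
#' @param seed Integer seed.
#' @param escalate_below Escalation trigger on the first-stage p,
#'   default 1e-3; `NULL` disables escalation.
#' @param n_sims_max Second-stage simulation count, default 1e6.
#' @return List with `statistic`, `p` (empirical), `n_snps`, `n_sims`
#'   actually used, `top_p` (smallest member p).
#' @export
gene_based_test <- function(member_pvalues,
                            ld_correlation = diag(length(member_pvalues)),
                            n_sims = 1e4, seed = 1L,
                            escalate_below = 1e-3, n_sims_max = 1e6) {
  m <- length(member_pvalues)
  stopifnot(m >= 1, all(member_pvalues > 0 & member_pvalues <= 1))
  R <- as.matrix(ld_correlation)
  stopifnot(nrow(R) == m, ncol(R) == m)
  stat <- sum(stats::qchisq(member_pvalues, 1, lower.tail = FALSE))
  Rr <- R + diag(1e-6, m)
  L <- tryCatch(chol(Rr), error = function(e)
    stop("LD correlation matrix is not positive semi-definite ",
         "(after ridge 1e-6)"))
  set.seed(seed)
  count_exceed <- function(n_total) {
    chunk <- max(1L, min(n_total, floor(2e7 / m)))
    exceed <- 0
    left <- n_total
    while (left > 0) {
      b <- min(chunk, left)
      Z <- matrix(stats::rnorm(b * m), b, m) %*% L
      exceed <- exceed + sum(rowSums(Z^2) >= stat)
      left <- left - b
    }
    exceed
  }
  used <- n_sims
  p <- (1 + count_exceed(n_sims)) / (n_sims + 1)
  if (!is.null(escalate_below) && p < escalate_below &&
      n_sims_max > n_sims) {
    used <- n_sims_max
    p <- (1 + count_exceed(n_sims_max)) / (n_sims_max + 1)
  }
  list(statistic = stat, p = p, n_snps = m, n_sims = used,
       top_p = min(member_pvalues))
}

#' Run gene-based tests over an association scan
#'
#' Convenience wrapper: maps SNPs to genes, builds each gene's LD
#' correlation from sample genotypes (one individual per pair when
#' `pair_ids` is given), and runs [gene_based_test()] per gene.
#'
#' @param assoc Association data frame with `snp` and `p`.
#' @param snp_meta SNP metadata (`snp`, `chrom`, `pos`).
#' @param gene_intervals Gene interval table.
#' @param genotypes Genotype matrix for the LD estimate (columns named
#'   by SNP), or `NULL` for identity LD.
#' @param pair_ids Optional pair ids for one-per-pair LD estimation.
#' @param flank_bp Gene flank, default 0.
#' @param n_sims,seed Passed to [gene_based_test()].
#' @return Data frame mirroring the published gene-table columns: gene,
#'   chrom, start, stop, n_snps, statistic, p, top_snp, top_snp_p.
#' @export
gene_scan <- function(assoc, snp_meta, gene_intervals, genotypes = NULL,
                      pair_ids = NULL, flank_bp = 0, n_sims = 1e4,
                      seed = 1L) {
  amap <- map_snps_to_genes(snp_meta, gene_intervals, flank_bp)
  amap <- amap[amap$snp %in% assoc$snp, ]
  if (!nrow(amap)) return(NULL)
  if (!is.null(genotypes) && !is.null(pair_ids)) {
    set.seed(seed)
    one <- vapply(split(seq_len(nrow(genotypes)), pair_ids),
                  function(ix) ix[sample.int(length(ix), 1L)], integer(1))
    genotypes <- genotypes[one, , drop = FALSE]
  }
  p_of <- stats::setNames(assoc$p, assoc$snp)
  rows <- lapply(split(amap$snp, amap$gene), function(snps) snps)
  out <- lapply(names(rows), function(gname) {
    snps <- rows[[gname]]
    R <- if (is.null(genotypes)) diag(length(snps)) else {
      G <- genotypes[, snps, drop = FALSE]
      suppressWarnings(stats::cor(G, use = "pairwise.complete.obs"))
    }
    R[!is.finite(R)] <- 0; diag(R) <- 1
    gt <- gene_based_test(p_of[snps], R, n_sims = n_sims, seed = seed)
    gi <- gene_intervals[match(gname, gene_intervals$name), ]
    data.frame(gene = gname, chrom = gi$chrom, start = gi$start,
               stop = gi$stop, n_snps = gt$n_snps,
               statistic = gt$statistic, p = gt$p,
               top_snp = snps[which.min(p_of[snps])],
               top_snp_p = gt$top_p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res[order(res$p), ]
}

#' Per-gene Bonferroni threshold
#'
#' `0.05 / n_genes`; with the published count of 19,001 evaluated genes
#' this is 2.63e-6.
#'
#' @param n_genes Number of genes evaluated (>= 1).
#' @return Genome-wide significance threshold for gene tests.
#' @export
gene_bonferroni_threshold <- function(n_genes) {
  stopifnot(n_genes >= 1)
  0.05 / n_genes
}

#' Hypergeometric over-representation of a gene set
#'
#' `K` is the gene-set size within the universe, `k` the overlap with the
#' query; the p-value is the hypergeometric upper tail `P(X >= k)` with
#' population `|universe|`, `K` successes and `|query|` draws.
#'
#' @param query_genes Character vector of query genes (subset of the
#'   universe; genes outside it are dropped with a warning).
#' @param gene_set Character vector, the gene set.
#' @param universe Character vector, the background.
#' @param set_name Label carried into the result.
#' @return One-row data frame: set, K, k, ratio (k/K, 4 decimals), p.
#' @export
ora_enrichment <- function(query_genes, gene_set, universe,
                           set_name = NA_character_) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  query <- unique(query_genes)
  if (any(!(query %in% universe))) {
    warning("query genes outside the universe were dropped")
    query <- intersect(query, universe)
  }
  set_u <- intersect(unique(gene_set), universe)
  K <- length(set_u)
  k <- length(intersect(query, set_u))
  p <- if (K == 0) 1 else
    stats::phyper(k - 1, K, length(universe) - K, length(query),
                  lower.tail = FALSE)
  data.frame(set = set_name, K = K, k = k,
             ratio = if (K > 0) round(k / K, 4) else NA_real_,
             p = p, stringsAsFactors = FALSE)
}

#' Gene-set over-representation across a GMT collection
#'
#' @param query_genes Query gene list (e.g. genes with gene-based
#'   p < 0.05).
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe Background gene list.
#' @return Data frame of [ora_enrichment()] rows with a BH FDR `q`
#'   column, sorted by p.
#' @export
ora_scan <- function(query_genes, gene_sets, universe) {
  rows <- mapply(function(gs, nm)
    ora_enrichment(query_genes, gs, universe, nm),
    gene_sets, names(gene_sets), SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg FDR q-values
#'
#' Standard step-up procedure:
#' `q_i = min_{j: p_j >= p_i} (p_j * m / rank_j)`, capped at 1.
#'
#' @param pvalues Numeric p-values in \[0, 1\].
#' @return Q-values, same order as the input.
#' @export
bh_fdr <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  stats::p.adjust(pvalues, method = "BH")
}
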