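#' Log2 allelic ratio of one SNP
#'
#' @param a1,a2 allele read counts (non-negative)
#' @param pseudo pseudocount per allele
#' @return log2((a1 + pseudo) / (a2 + pseudo))
#' @export
snp_allelic_ratio <- function(a1, a2, pseudo = 1) {
  if (any(a1 < 0) || any(a2 < 0)) stop("allele counts must be >= 0")
  # difference of logs, so swapping the alleles negates the ratio exactly
  log2(a1 + pseudo) - log2(a2 + pseudo)
}

#' Allele-specific expression and chromatin-enrichment test for one gene
#'
#' The expression ratio is the mean per-SNP log2 allelic ratio across
#' input samples; the enrichment ratio is the mean per-SNP ratio in the
#' pulldown samples minus that in the inputs, which isolates
#' chromatin-enrichment skew from expression skew. Significance is a
#' two-sided Mann-Whitney test comparing the per-SNP allele-1 read
#' fractions of pulldown samples against input samples. Genes with fewer
#' than \code{min_snps} SNPs are reported with ratios but p = NA
#' (untestable).
#'
#' @param counts long allele-counts data.frame (see
#'   \code{\link{simulate_allele}} / \code{\link{read_allele}})
#' @param gene gene id to test
#' @param pulldown,input sample names of the two groups (default: by the
#'   \code{assay} column)
#' @param pseudo pseudocount for the ratios
#' @param min_snps minimum SNPs for a p-value
#' @return data.frame (one row): gene_id, expr_log2ratio,
#'   enrich_log2ratio, p_value, n_snps
#' @export
gene_allelic_test <- function(counts, gene, pulldown = NULL, input = NULL,
                              pseudo = 1, min_snps = 3) {
  sub <- counts[counts$gene_id == gene, , drop = FALSE]
  if (!nrow(sub)) stop("gene '", gene, "' absent from allele counts")
  if (is.null(pulldown)) {
    pulldown <- unique(sub$sample[sub$assay != "input"])
  }
  if (is.null(input)) input <- unique(sub$sample[sub$assay == "input"])
  pd <- sub[sub$sample %in% pulldown, ]
  ip <- sub[sub$sample %in% input, ]
  ratio_mean <- function(x) {
    mean(snp_allelic_ratio(x$allele1, x$allele2, pseudo))
  }
  expr <- ratio_mean(ip)
  enrich <- ratio_mean(pd) - expr
  n_snps <- length(unique(sub$pos))
  p <- NA_real_
  if (n_snps >= min_snps) {
    frac <- function(x) x$allele1 / pmax(x$allele1 + x$allele2, 1)
    p <- suppressWarnings(
      stats::wilcox.test(frac(pd), frac(ip))$p.value)
  }
  data.frame(gene_id = gene, expr_log2ratio = expr,
             enrich_log2ratio = enrich, p_value = p, n_snps = n_snps)
}

#' Allele-specific test over all genes
#'
#' @param counts long allele-counts data.frame
#' @param ... passed to \code{\link{gene_allelic_test}}
#' @return data.frame with one row per gene
#' @export
allelic_tests <- function(counts, ...) {
  do.call(rbind, lapply(unique(counts$gene_id), function(g) {
    gene_allelic_test(counts, g, ...)
  }))
}
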