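# shared in-code fixtures for the suite

# tiny two-exon gene: exons [0,100) and [200,300), intron [100,200)
toy_gene <- function(strand = "+") {
  gene_models(
    genes = data.frame(gene_id = "g1", biotype = "lncRNA",
                       chrom = "chr1", strand = strand),
    exons = data.frame(gene_id = "g1", start = c(0L, 200L),
                       end = c(100L, 300L)))
}

# constant-coverage pileup
flat_pileup <- function(L, value = 1, tx = "tx1") {
  pirch_pileup(tx, rep(value, L))
}

# null count matrix under the generator's default study conditions
null_counts <- function(n_genes = 2000, seed = 1) {
  cfg <- sim_config(n_genes = n_genes, n_per_state = 0, seed = seed)
  simulate_counts(cfg)$counts
}

# independent Spearman rho for the rank-concordance oracle
oracle_rho <- function(a, b) stats::cor(rank(-a), rank(-b),
                                        method = "spearman")
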