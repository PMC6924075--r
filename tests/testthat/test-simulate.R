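test_that("count simulation is deterministic and carries planted effects", {
  cfg <- sim_config(n_genes = 300, n_per_state = 5, seed = 42)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth$effects, b$truth$effects)

  # planted genes exist in the emitted matrix and have non-coding biotypes
  expect_true(all(a$truth$enriched$gene_id %in%
                    rownames(a$counts$counts)))
  bt <- a$counts$genes$biotype[match(a$truth$enriched$gene_id,
                                     a$counts$genes$gene_id)]
  expect_true(all(bt != "coding"))
})

test_that("expected counts respect the planted log2 effects", {
  # a gene with effect +2 on one mark has pulldown mean 4x its input mean,
  # up to the per-column depth scaling
  cfg <- sim_config(n_genes = 200, n_per_state = 2, noise_sd = 0,
                    seed = 3)
  sim <- simulate_counts(cfg)
  mu <- sim$truth$mu
  lib <- sim$truth$library_sizes
  meta <- sim$counts$samples
  g <- sim$truth$enriched$gene_id[1]
  mk <- names(which(sim$truth$effects[g, ] == 2))[1]
  skip_if(is.na(mk))
  pd_col <- which(meta$assay == mk)[1]
  in_col <- which(meta$assay == "input")[1]
  # depth-normalize the expected means, then the ratio is exactly 2^2
  # times the ratio of the column normalizing constants absorbed into mu;
  # comparing normalized columns removes them
  mu_pd <- mu[, pd_col] / sum(mu[, pd_col])
  mu_in <- mu[, in_col] / sum(mu[, in_col])
  base_ratio <- mu_pd / mu_in
  null_genes <- setdiff(rownames(mu), sim$truth$enriched$gene_id)
  rel <- (base_ratio[g]) / stats::median(base_ratio[null_genes])
  expect_equal(unname(rel), 4, tolerance = 1e-6)
})

test_that("null count marginals match negative-binomial moments", {
  cfg <- sim_config(n_genes = 2000, n_per_state = 0, seed = 1)
  sim <- simulate_counts(cfg)
  cts <- sim$counts$counts
  mu <- sim$truth$mu
  # moment check per sample: regress sample variance of (count - mu) on
  # the NB closed form mu + dispersion * mu^2 across genes, binned
  disp_hat <- vapply(seq_len(ncol(cts)), function(j) {
    x <- cts[, j]; m <- mu[, j]
    # method-of-moments estimate of dispersion from (x - m)^2
    sum((x - m)^2 - m) / sum(m^2)
  }, numeric(1))
  expect_equal(mean(disp_hat), cfg$dispersion, tolerance = 0.15)
  # and the mean is unbiased
  expect_equal(mean(rowMeans(cts) / rowMeans(mu)), 1, tolerance = 0.05)
})

test_that("pileup simulation conserves reads and rejects bad input", {
  sim <- simulate_pileup(1000, n_reads = 500, read_len = 40, seed = 9)
  expect_equal(sum(sim$pileup$coverage), 500 * 40)
  expect_error(simulate_pileup(30, 10, read_len = 50), "read_len")
  z <- simulate_pileup(100, 0, 10, seed = 1)
  expect_true(all(z$pileup$coverage == 0))
})

test_that("planted pileup peaks put the coverage maximum at the summit", {
  hits <- vapply(1:100, function(s) {
    pk <- data.frame(summit = 600, width = 50, amplitude = 20)
    sim <- simulate_pileup(2000, 400, 30, peaks = pk, seed = s)
    mx <- which.max(sim$pileup$coverage) - 1
    abs(mx - 600) <= 25
  }, logical(1))
  expect_true(all(hits))
})

test_that("shape tracks are elevated only where planted", {
  lens <- c(tx1 = 3000)
  truth <- data.frame(transcript_id = "tx1", summit = c(1000, 2000))
  flat <- simulate_shape(lens, truth, baseline_mean = 0.3,
                         elevation = 0, missing_frac = 0, seed = 2)
  m <- mean(flat$tx1)
  se <- stats::sd(flat$tx1) / sqrt(length(flat$tx1))
  expect_lt(abs(m - 0.3), 2 * se + 0.01)

  up <- simulate_shape(lens, truth, baseline_mean = 0.3,
                       elevation = 0.3, missing_frac = 0, seed = 2)
  win <- c(1000 + (-10:-5), 2000 + (-10:-5)) + 1
  expect_gt(mean(up$tx1[win]), mean(up$tx1[-win]) + 0.15)

  gone <- simulate_shape(lens, truth, missing_frac = 1, seed = 2)
  expect_true(all(is.na(gone$tx1)))
})

test_that("allele counts recover planted skews", {
  # balanced: pooled allele-1 fraction ~ 0.5 everywhere
  al <- simulate_allele(20, 10, expr_skew = 0, enrich_skew = 0,
                        depth = 100, seed = 5)
  frac <- with(al$counts, sum(allele1) / sum(allele1 + allele2))
  expect_equal(frac, 0.5, tolerance = 0.02)

  # binomial MLE of a log2 skew of 1 lands within 0.1 at depth 10000
  al <- simulate_allele(5, 20, expr_skew = 1, enrich_skew = 0,
                        depth = 10000, seed = 6)
  ip <- al$counts[al$counts$assay == "input", ]
  mle <- log2(sum(ip$allele1) / sum(ip$allele2))
  expect_lt(abs(mle - 1), 0.1)

  # pulldown exceeds input allele-1 fraction when enrichment skew opposes
  # expression skew (the Gas5 configuration)
  al <- simulate_allele(5, 20, expr_skew = -1.58, enrich_skew = 2,
                        depth = 500, seed = 7)
  f <- function(a) sum(a$allele1) / sum(a$allele1 + a$allele2)
  expect_gt(f(al$counts[al$counts$assay == "pulldown", ]),
            f(al$counts[al$counts$assay == "input", ]))
})

test_that("annotation simulation is valid, deterministic and sized", {
  m1 <- simulate_annotation(100, 3, 5e5, seed = 8)
  m2 <- simulate_annotation(100, 3, 5e5, seed = 8)
  expect_identical(m1$genes, m2$genes)
  expect_identical(m1$exons, m2$exons)
  # genes do not overlap
  g <- m1$genes[order(m1$genes$start), ]
  expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  # single-exon genes have no intronic bases
  s1 <- simulate_annotation(10, 1, 1e5, seed = 9)
  expect_equal(nrow(gene_introns(s1)), 0)
  expect_error(simulate_annotation(100, 3, 1000), "too small")
})
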