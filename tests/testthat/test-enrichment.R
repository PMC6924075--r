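test_that("depth normalization scales every sample to the target", {
  m <- cbind(s1 = c(10, 30, 60), s2 = c(5, 5, 0))
  norm <- depth_normalize(m)
  expect_equal(unname(colSums(norm)), c(1e7, 1e7))
  expect_equal(norm[, 1], c(s1 = 1e6, s2 = 3e6, s3 = 6e6),
               ignore_attr = TRUE)

  # a column already at target is untouched; equal proportions at
  # different depths coincide after normalization
  m2 <- cbind(a = c(2e6, 8e6), b = c(1, 4))
  norm2 <- depth_normalize(m2)
  expect_equal(norm2[, "a"], m2[, "a"])
  expect_equal(unname(norm2[, "a"]), unname(norm2[, "b"]))

  m3 <- cbind(ok = c(1, 2), empty = c(0, 0))
  expect_error(depth_normalize(m3), "empty")
})

test_that("expression filter applies the raw-count rule", {
  m <- rbind(zero = c(0, 0, 0, 0),
             kept = c(12, 11, 0, 0),
             weak = c(12, 0, 0, 0))
  out <- filter_expressed(m, min_count = 10, min_samples = 2)
  expect_equal(rownames(out), "kept")
  expect_equal(filter_expressed(m, min_count = 0, min_samples = 0), m)
  expect_error(filter_expressed(m, min_count = 100, min_samples = 4),
               "all genes")
})

test_that("moderated t matches the closed-form posterior-variance oracle", {
  # three genes, two pulldown vs two input samples, hand-chosen counts
  cts <- rbind(g1 = c(100, 120, 380, 400),
               g2 = c(50, 60, 45, 55),
               g3 = c(200, 210, 205, 190))
  grp <- c(0, 0, 1, 1)
  fit <- fit_moderated_test(cts, grp, weights = FALSE)

  # oracle: independent brute-force computation of every ingredient
  lib <- colSums(cts)
  y <- log2(t((t(cts) + 0.5) / (lib + 1)) * 1e6)
  beta <- rowMeans(y[, 3:4]) - rowMeans(y[, 1:2])
  s2 <- apply(y, 1, function(v) {
    sum((v[1:2] - mean(v[1:2]))^2 + (v[3:4] - mean(v[3:4]))^2) / 2
  })
  d <- 2
  cc <- 1 / 2 + 1 / 2
  d0 <- fit$d0; s02 <- fit$s02
  s2_post <- if (is.finite(d0)) (d0 * s02 + d * s2) / (d0 + d) else
    rep(s02, 3)
  t_oracle <- beta / sqrt(s2_post * cc)
  expect_equal(unname(fit$table$t), unname(t_oracle), tolerance = 1e-10)
  expect_equal(unname(fit$table$log2fc), unname(beta), tolerance = 1e-10)
  expect_equal(unname(fit$s2), unname(s2), tolerance = 1e-10)
  expect_equal(fit$df_total, d0 + d)
})

test_that("a gene identical across groups gets log2fc 0 and p 1", {
  # equal library sizes, so log2-CPM preserves the equality
  cts <- rbind(flat = c(100, 100, 100, 100),
               up = c(10, 20, 200, 150),
               dn = c(290, 280, 100, 150))
  fit <- fit_moderated_test(cts, c(0, 0, 1, 1), weights = FALSE)
  expect_equal(fit$table$log2fc[1], 0)
  expect_equal(fit$table$p_value[1], 1)
})

test_that("infinite prior df collapses every posterior variance to s0^2", {
  set.seed(21)
  # homogeneous gene-wise variances: log-variance spread below the
  # chi-square baseline, so the prior dominates completely
  cts <- matrix(rnbinom(200 * 4, mu = 100, size = 50), 200, 4)
  rownames(cts) <- paste0("g", 1:200)
  fit <- fit_moderated_test(cts, c(0, 0, 1, 1), weights = FALSE)
  if (is.finite(fit$d0)) skip("prior df finite for this draw")
  expect_true(all(fit$s2_post == fit$s02))
})

test_that("variance shrinkage and moderated t agree with limma", {
  skip_if_not_installed("limma")
  set.seed(31)
  s2 <- rchisq(400, 3) / 3 * exp(rnorm(400, 0, 0.6))
  mine <- squeeze_variances(s2, 3)
  ref <- limma::squeezeVar(s2, 3)
  expect_equal(mine$d0, ref$df.prior, tolerance = 1e-6)
  expect_equal(mine$s02, ref$var.prior, tolerance = 1e-6)
  expect_equal(mine$s2_post, ref$var.post, tolerance = 1e-6)

  # heterogeneous dispersions give a finite prior; unweighted moderated t
  # then matches lmFit + eBayes on the same log2-CPM matrix
  set.seed(32)
  sz <- exp(rnorm(300, log(10), 1))
  cts <- matrix(rnbinom(300 * 4, mu = 100, size = sz), 300, 4)
  rownames(cts) <- paste0("g", 1:300)
  fit <- fit_moderated_test(cts, c(0, 0, 1, 1), weights = FALSE)
  skip_if(!is.finite(fit$d0))
  y <- log2(t((t(cts) + 0.5) / (colSums(cts) + 1)) * 1e6)
  ref <- limma::eBayes(limma::lmFit(y, cbind(1, c(0, 0, 1, 1))))
  expect_equal(unname(fit$table$t), unname(ref$t[, 2]), tolerance = 1e-8)
  expect_equal(unname(fit$table$p_value), unname(ref$p.value[, 2]),
               tolerance = 1e-8)
})

test_that("welch fallback runs gene-wise t tests", {
  cts <- rbind(g1 = c(10, 20, 200, 150), g2 = c(100, 90, 95, 105))
  fit <- fit_moderated_test(cts, c(0, 0, 1, 1), welch = TRUE)
  expect_equal(fit$method, "welch")
  expect_true(all(fit$table$p_value >= 0 & fit$table$p_value <= 1))
  expect_error(fit_moderated_test(cts[, c(1, 3)], c(0, 1)),
               "welch")
})

test_that("enrichment score follows the log-ratio contract", {
  expect_equal(enrichment_score(100, 100), 0)
  expect_equal(enrichment_score(31, 7, pseudo = 1), 2)
  expect_equal(enrichment_score(0, 0), 0)
  expect_error(enrichment_score(5, -1), "non-negative")
  # replicate averaging happens before the ratio
  expect_equal(enrichment_score(cbind(c(30), c(32)), cbind(c(6), c(8))), 2)
})

test_that("enrichment score is antisymmetric under pulldown/input swap", {
  set.seed(41)
  for (i in 1:20) {
    p <- runif(1, 0, 500); q <- runif(1, 0, 500)
    expect_equal(enrichment_score(p, q), -enrichment_score(q, p))
  }
})

test_that("variation score is the sample SD across marks", {
  expect_equal(variation_score(c(3, 3, 3, 3)), 0)
  expect_equal(variation_score(c(1, 3)), sqrt(2))
  set.seed(42)
  v <- rnorm(6)
  expect_equal(variation_score(v),
               sqrt(sum((v - mean(v))^2) / 5))   # one-line oracle
  expect_error(variation_score(5), ">= 2 marks")
})

test_that("enrichment calls obey the alpha/log2fc rule on planted data", {
  cfg <- sim_config(n_genes = 800, n_per_state = 10, seed = 11)
  sim <- simulate_counts(cfg)
  filt <- filter_expressed(sim$counts)
  enr <- pirch_enrich(filt, marks = default_marks())
  expect_true(all(enr$enriched ==
                    (enr$p_value < 0.05 & enr$log2fc > 0)))
  # planted genes dominate the calls
  called <- unique(enr$gene_id[enr$enriched])
  recall <- mean(sim$truth$enriched$gene_id %in% called)
  expect_gt(recall, 0.8)
})

test_that("preranked GSEA matches a brute-force running sum", {
  scores <- c(a = 3, b = 2, c = 1, d = -1, e = -2)
  gs <- c("a", "b")
  res <- gsea_preranked(scores, gs, n_perm = 200, seed = 1)
  # hand enumeration: hits at ranks 1,2 weighted by |score|
  p_hit <- cumsum(c(3, 2, 0, 0, 0)) / 5
  p_miss <- cumsum(c(0, 0, 1, 1, 1)) / 3
  run <- p_hit - p_miss
  expect_equal(res$running, run)
  expect_equal(res$es, run[which.max(abs(run))])
  # set occupying the top ranks gives a positive ES
  expect_gt(res$es, 0)
  # p is a valid add-one permutation p
  expect_gte(res$p_value, 1 / 201)
  expect_lte(res$p_value, 1)
})

test_that("GSEA is stable under tie-break permutations of equal scores", {
  set.seed(5)
  scores <- stats::setNames(rep(1, 20), paste0("g", 1:20))
  gs <- paste0("g", 1:5)
  es1 <- gsea_preranked(scores, gs, n_perm = 100, seed = 1)$es
  es2 <- gsea_preranked(scores[sample(20)], gs, n_perm = 100, seed = 1)$es
  expect_equal(es1, es2, tolerance = 1e-12)
  expect_error(gsea_preranked(scores, character(0)), "empty")
})
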