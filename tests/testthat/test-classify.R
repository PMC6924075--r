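make_state_matrix <- function(n_per = 40, noise = 0.3, seed = 1) {
  tm <- state_templates()
  set.seed(seed)
  m <- tm[rep(1:6, each = n_per), ] +
    matrix(rnorm(6 * n_per * 6, 0, noise), 6 * n_per, 6)
  rownames(m) <- sprintf("nc%03d", seq_len(nrow(m)))
  m
}

test_that("silhouette selection recovers two well-separated blobs", {
  ok <- vapply(1:20, function(s) {
    set.seed(s)
    m <- rbind(matrix(rnorm(40 * 3, 0, 0.5), 40),
               matrix(rnorm(40 * 3, 5, 0.5), 40))
    rownames(m) <- paste0("g", 1:80)
    colnames(m) <- c("H3K4me1", "H3K4me3", "H3K27ac")
    as.integer(select_k(m, k_range = 2:6, seed = s)) == 2L
  }, logical(1))
  expect_true(all(ok))
})

test_that("silhouette selection is invariant to row permutation", {
  m <- make_state_matrix(seed = 2)
  k1 <- select_k(m, seed = 7)
  set.seed(99)
  k2 <- select_k(m[sample(nrow(m)), ], seed = 7)
  expect_equal(as.integer(k1), as.integer(k2))
})

test_that("pure-noise matrices fall back to the smallest K with a warning", {
  set.seed(3)
  m <- matrix(rnorm(120 * 6), 120, 6)
  rownames(m) <- paste0("g", 1:120)
  colnames(m) <- default_marks()
  expect_warning(k <- select_k(m, k_range = 2:6, seed = 1),
                 "low confidence")
  expect_equal(as.integer(k), 2L)
  expect_error(select_k(matrix(1, 30, 6, dimnames = list(paste0("g", 1:30),
                                                         default_marks()))),
               "degenerate")
})

test_that("cluster labeling follows cosine similarity to the templates", {
  m <- make_state_matrix(seed = 4)
  st <- cluster_states(m, 6, seed = 1)
  truth <- rep(rownames(state_templates()), each = 40)
  # strip any disambiguating suffix before comparing
  lab <- sub("\\.\\d+$", "", st$state)
  expect_gt(mean(lab == truth), 0.95)
  expect_true(all(table(st$gene_id) == 1))
  expect_true(all(c("dim1", "dim2") %in% names(st)))

  # labels are invariant to positive rescaling (cosine labeling)
  st2 <- cluster_states(m * 7, 6, seed = 1)
  expect_equal(st2$state, st$state)
})

test_that("centroids matching a single template get its label", {
  tm <- state_templates()
  set.seed(6)
  # two tight clusters exactly on the Active Promoter / Heterochromatin
  # templates
  m <- rbind(tm[rep("Active Promoter", 20), ],
             tm[rep("Heterochromatin", 20), ]) +
    matrix(rnorm(40 * 6, 0, 0.05), 40, 6)
  rownames(m) <- paste0("g", 1:40)
  st <- cluster_states(m, 2, seed = 1)
  expect_setequal(unique(st$state),
                  c("Active Promoter", "Heterochromatin"))
  expect_false(any(st$unassigned))
})

test_that("orthogonal centroids are flagged unassigned", {
  set.seed(7)
  # H3K9me3-only and H4K16ac-only clusters: neither is any template's
  # dominant pattern alone, and similarity stays below the threshold for
  # the orthogonal one
  m <- rbind(matrix(rep(c(0, 0, 0, 0, 4, 0), each = 25), 25),
             matrix(rep(c(0, 0, 0, 0, -4, 0), each = 25), 25)) +
    matrix(rnorm(50 * 6, 0, 0.05), 50, 6)
  colnames(m) <- default_marks()
  rownames(m) <- paste0("g", 1:50)
  st <- suppressWarnings(cluster_states(m, 2, seed = 1))
  expect_true(any(st$unassigned))
})

test_that("cross-type correlation recovers planted cell-type structure", {
  # identical profiles correlate at 1; a negated profile at -1
  set.seed(8)
  base <- rnorm(60)
  prof <- cbind(a = base, b = base, neg = -base)
  cc <- crosstype_correlation(prof)
  expect_equal(cc$r["a", "b"], 1)
  expect_equal(cc$r["a", "neg"], -1)

  # planted: within-type profiles share signal, across-type do not
  t1 <- rnorm(100); t2 <- rnorm(100)
  prof <- cbind(esc.K4 = t1 + rnorm(100, 0, 0.3),
                esc.K27 = t1 + rnorm(100, 0, 0.3),
                mef.K4 = t2 + rnorm(100, 0, 0.3),
                mef.K27 = t2 + rnorm(100, 0, 0.3))
  cc <- crosstype_correlation(prof)
  merged_first <- stats::cutree(cc$hclust, 2)
  expect_equal(merged_first[["esc.K4"]], merged_first[["esc.K27"]])
  expect_equal(merged_first[["mef.K4"]], merged_first[["mef.K27"]])
  expect_true(merged_first[["esc.K4"]] != merged_first[["mef.K4"]])

  # too few shared genes -> NA entry
  prof_na <- cbind(x = c(1, 2, NA, NA, NA), y = c(NA, NA, 1, 2, 3))
  expect_true(is.na(suppressWarnings(
    crosstype_correlation(prof_na))$r["x", "y"]))
})

test_that("bi/mono classification follows the valence definition", {
  expect_equal(bi_mono_classify(c("H3K4me1", "H3K27me3")), "bi")
  expect_equal(bi_mono_classify("H3K4me3"), "mono")
  expect_equal(bi_mono_classify(character(0)), "none")
  expect_equal(bi_mono_classify(c("H3K27me3", "H3K9me3")), "mono")
  expect_error(bi_mono_classify("H3K99ac"), "valence")
  expect_error(bi_mono_classify("H3K4me3", active_set = c("H3K4me3"),
                                repressive_set = c("H3K4me3")),
               "disjoint")

  # swapping the two classes maps bi->bi and mono->mono
  v <- mark_valence()
  sets <- list(c("H3K4me1", "H3K27me3"), "H3K4me3", c("H3K9me3"))
  orig <- vapply(sets, bi_mono_classify, character(1))
  swap <- vapply(sets, bi_mono_classify, character(1),
                 active_set = v$repressive, repressive_set = v$active)
  expect_equal(orig, swap)
})

test_that("bi:mono chi-square matches the contingency-table oracle", {
  res <- bi_mono_test(30, 33, 8, 32)
  # independent textbook computation
  tab <- matrix(c(30, 33, 8, 32), 2, byrow = TRUE)
  exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  x2 <- sum((tab - exp_tab)^2 / exp_tab)
  p_oracle <- stats::pchisq(x2, df = 1, lower.tail = FALSE)
  expect_equal(unname(res$statistic), x2, tolerance = 1e-10)
  expect_equal(res$p.value, p_oracle, tolerance = 1e-10)
})

test_that("nearby coding expression uses a closed +/- 100 kb boundary", {
  models <- gene_models(
    data.frame(gene_id = c("nc1", "cod_at_edge", "cod_far"),
               biotype = c("lncRNA", "coding", "coding"),
               chrom = "chr1", strand = "+"),
    data.frame(gene_id = c("nc1", "cod_at_edge", "cod_far"),
               start = c(0L, 100100L, 300000L),
               end = c(100L, 100200L, 300100L)))
  loci <- data.frame(gene_id = "nc1", chrom = "chr1", start = 0L,
                     end = 100L, group = "active")
  expr <- c(cod_at_edge = 10, cod_far = 99)
  res <- nearby_coding_expression(loci, models, expr, window = 1e5)
  expect_equal(res$by_group$active, c(cod_at_edge = 10))

  # no coding neighbors: empty group, no test
  loci2 <- data.frame(gene_id = "nc1", chrom = "chr2", start = 0L,
                      end = 100L, group = "lonely")
  res2 <- nearby_coding_expression(loci2, models, expr)
  expect_length(res2$by_group$lonely, 0)
  expect_null(res2$welch)
})

test_that("planted active-state ncRNAs show higher neighbor expression", {
  set.seed(16)
  n <- 40
  genes <- data.frame(
    gene_id = c(sprintf("nc%02d", 1:n), sprintf("cod%02d", 1:n)),
    biotype = rep(c("lncRNA", "coding"), each = n),
    chrom = "chr1", strand = "+")
  # each ncRNA i sits next to coding gene i
  pos <- (0:(n - 1)) * 250000L
  exons <- data.frame(
    gene_id = genes$gene_id,
    start = c(pos, pos + 5000L),
    end = c(pos + 1000L, pos + 6000L))
  models <- gene_models(genes, exons)
  grp <- rep(c("active", "repressed"), each = n / 2)
  expr <- stats::setNames(
    c(2^rnorm(n / 2, 6, 0.5), 2^rnorm(n / 2, 2, 0.5)),
    sprintf("cod%02d", 1:n))
  loci <- data.frame(gene_id = sprintf("nc%02d", 1:n), chrom = "chr1",
                     start = pos, end = pos + 1000L, group = grp)
  res <- nearby_coding_expression(loci, models, expr, window = 1e5)
  expect_lt(res$welch$p_value[1], 0.01)
  expect_gt(res$welch$mean1, res$welch$mean2)
})
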