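#' Normalize each sample to a common sequencing depth
#'
#' Scales every column so that its total equals \code{target} reads
#' (default 10 million), the convention used throughout the pipeline.
#'
#' @param x a \code{pirch_counts} or numeric matrix
#' @param target desired column total
#' @return same type as \code{x}, real-valued
#' @export
depth_normalize <- function(x, target = 1e7) {
  m <- if (inherits(x, "pirch_counts")) x$counts else x
  cs <- colSums(m)
  if (any(cs == 0)) {
    stop("sample '", colnames(m)[which(cs == 0)[1]],
         "' has zero total counts and cannot be depth-normalized")
  }
  m <- sweep(m, 2, target / cs, "*")
  if (inherits(x, "pirch_counts")) {
    x$counts <- m
    x
  } else m
}

#' Filter lowly expressed genes
#'
#' Keeps genes with raw count >= \code{min_count} in at least
#' \code{min_samples} samples. \code{min_samples} defaults to the smallest
#' assay-group size in the metadata (or 1 for a bare matrix).
#'
#' @param x a \code{pirch_counts} or numeric matrix of raw counts
#' @param min_count minimum raw count
#' @param min_samples minimum number of samples reaching it
#' @return filtered object of the same type
#' @export
filter_expressed <- function(x, min_count = 10, min_samples = NULL) {
  if (min_count < 0 || (!is.null(min_samples) && min_samples < 0)) {
    stop("thresholds must be >= 0")
  }
  m <- if (inherits(x, "pirch_counts")) x$counts else x
  if (is.null(min_samples)) {
    min_samples <- if (inherits(x, "pirch_counts")) {
      min(table(x$samples$assay))
    } else 1L
  }
  keep <- rowSums(m >= min_count) >= min_samples
  if (!any(keep)) stop("expression filter removed all genes")
  if (inherits(x, "pirch_counts")) x[keep, ] else m[keep, , drop = FALSE]
}

# Newton solve of trigamma(y) = x, vectorized; used to moment-match the
# prior degrees of freedom on the log-variance scale.
trigamma_inverse <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-12) break
  }
  y
}

#' Empirical-Bayes shrinkage of per-gene residual variances
#'
#' Moment-matches a scaled inverse-chi-square prior on the log scale:
#' with d residual df, log s2 - digamma(d/2) + log(d/2) has variance
#' trigamma(d/2) + trigamma(d0/2) under the prior, which is solved for the
#' prior df d0; the prior variance s0^2 comes from the mean. When the
#' empirical spread does not exceed the chi-square baseline the prior df is
#' infinite and every posterior variance equals s0^2.
#'
#' @param s2 per-gene residual variances
#' @param df residual degrees of freedom (scalar)
#' @return list with \code{d0}, \code{s02}, and \code{s2_post}
#' @export
squeeze_variances <- function(s2, df) {
  if (df <= 0) stop("no residual degrees of freedom to shrink")
  z <- log(pmax(s2, 1e-12))
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (!is.finite(evar) || evar <= 0) {
    # empirical spread below the chi-square baseline: the prior dominates
    d0 <- Inf
    s02 <- mean(s2)
    s2_post <- rep(s02, length(s2))
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    s2_post <- (d0 * s02 + df * s2) / (d0 + df)
  }
  list(d0 = d0, s02 = s02, s2_post = s2_post)
}

#' Moderated two-group test on log-scale counts
#'
#' The statistical core of enrichment calling: per gene, a two-group linear
#' model on log2 counts-per-million (offset 0.5) contrasting pulldown
#' against input, with mean-variance precision weights from a lowess trend
#' of sqrt(residual SD) against average log-count, and residual variances
#' shrunk toward a common prior by empirical Bayes
#' (\code{\link{squeeze_variances}}). The moderated t statistic is
#' logFC / sqrt(s2_post * c) with c the unscaled standard error, on
#' d0 + d degrees of freedom.
#'
#' @param counts raw count matrix (genes x samples)
#' @param group logical or 0/1 vector: TRUE/1 = pulldown, FALSE/0 = input
#' @param weights use mean-variance precision weights? Disabled
#'   automatically when 10 or fewer genes are available (the trend is not
#'   estimable), falling back to unit weights.
#' @param welch fall back to gene-wise Welch t tests (no moderation); use
#'   when there are no residual degrees of freedom for the pooled model
#' @return object of class \code{moderated_fit}: data.frame fields
#'   \code{table} (gene_id, log2fc, t, p_value) and fit internals
#'   (\code{s2}, \code{s2_post}, \code{d0}, \code{s02}, \code{df_residual},
#'   \code{df_total}, \code{c_unscaled})
#' @export
fit_moderated_test <- function(counts, group, weights = TRUE,
                               welch = FALSE) {
  counts <- as.matrix(counts)
  grp <- as.logical(group)
  if (length(grp) != ncol(counts)) stop("group length must match columns")
  n1 <- sum(grp); n0 <- sum(!grp)
  if (n1 < 1 || n0 < 1) stop("both groups need at least one sample")
  lib <- colSums(counts)
  y <- log2(t((t(counts) + 0.5) / (lib + 1)) * 1e6)

  if (welch) {
    res <- t(apply(y, 1, function(v) {
      tt <- stats::t.test(v[grp], v[!grp])
      c(mean(v[grp]) - mean(v[!grp]), tt$statistic, tt$p.value)
    }))
    out <- list(table = data.frame(gene_id = rownames(counts),
                                   log2fc = res[, 1], t = res[, 2],
                                   p_value = res[, 3]),
                method = "welch")
    class(out) <- "moderated_fit"
    return(out)
  }
  df <- n1 + n0 - 2
  if (df <= 0) {
    stop("zero residual degrees of freedom; rerun with welch = TRUE for ",
         "gene-wise Welch tests, or provide replicates")
  }

  fit_w <- function(w) {
    w1 <- rowSums(w[, grp, drop = FALSE])
    w0 <- rowSums(w[, !grp, drop = FALSE])
    m1 <- rowSums((y * w)[, grp, drop = FALSE]) / w1
    m0 <- rowSums((y * w)[, !grp, drop = FALSE]) / w0
    fitted <- matrix(m0, nrow(y), ncol(y))
    fitted[, grp] <- m1
    s2 <- rowSums(w * (y - fitted)^2) / df
    list(beta = m1 - m0, s2 = s2, c_unscaled = 1 / w1 + 1 / w0,
         fitted = fitted)
  }
  u <- fit_w(matrix(1, nrow(y), ncol(y)))
  used_weights <- FALSE
  if (weights && nrow(y) > 10) {
    xb <- rowMeans(y)
    lo <- suppressWarnings(stats::lowess(xb, sqrt(sqrt(u$s2)), f = 0.5))
    lf <- stats::approxfun(lo$x, lo$y, rule = 2, ties = mean)
    w <- matrix(1 / pmax(lf(u$fitted), 0.05)^4, nrow(y), ncol(y))
    u <- fit_w(w)
    used_weights <- TRUE
  }
  sq <- squeeze_variances(u$s2, df)
  df_total <- sq$d0 + df
  tt <- u$beta / sqrt(sq$s2_post * u$c_unscaled)
  p <- 2 * stats::pt(-abs(tt), df_total)
  out <- list(table = data.frame(gene_id = rownames(counts),
                                 log2fc = u$beta, t = tt, p_value = p),
              s2 = u$s2, s2_post = sq$s2_post, d0 = sq$d0, s02 = sq$s02,
              df_residual = df, df_total = df_total,
              c_unscaled = u$c_unscaled, weighted = used_weights,
              method = "moderated")
  class(out) <- "moderated_fit"
  out
}

#' @export
print.moderated_fit <- function(x, ...) {
  cat("moderated_fit (", x$method, "): ", nrow(x$table), " genes",
      sep = "")
  if (!is.null(x$d0)) {
    cat("; prior df ", signif(x$d0, 4), ", prior variance ",
        signif(x$s02, 4), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Enrichment score: log2 pulldown over input
#'
#' Computed on depth-normalized counts with a pseudocount; replicate
#' values are averaged before the ratio is taken.
#'
#' @param pulldown,input non-negative normalized counts (vectors or
#'   matrices with replicates in columns)
#' @param pseudo pseudocount added to both numerator and denominator
#' @return numeric vector of log2 scores
#' @export
enrichment_score <- function(pulldown, input, pseudo = 1) {
  p <- if (is.matrix(pulldown)) rowMeans(pulldown) else pulldown
  i <- if (is.matrix(input)) rowMeans(input) else input
  if (any(p < 0) || any(i < 0)) stop("counts must be non-negative")
  log2((p + pseudo) / (i + pseudo))
}

#' Variation score across histone marks
#'
#' Sample standard deviation (denominator n-1) of a gene's enrichment
#' scores across marks; genes varying strongly between marks associate
#' with chromatin mark-specifically.
#'
#' @param scores numeric vector (one gene) or matrix (genes x marks)
#' @return numeric scalar or per-gene vector
#' @export
variation_score <- function(scores) {
  if (is.matrix(scores)) {
    if (ncol(scores) < 2) stop("variation score needs >= 2 marks")
    return(apply(scores, 1, stats::sd))
  }
  if (length(scores) < 2) stop("variation score needs >= 2 marks")
  stats::sd(scores)
}

#' Per-mark enrichment calls for a pulldown/input experiment
#'
#' Runs the moderated test for every histone mark against the input
#' columns of the same object and assembles the tidy enrichment table. A
#' gene is called enriched for a mark when p < alpha and log2FC > 0 (raw
#' p, as is conventional for this assay; a BH-FDR column is included for
#' reference but not used for calls).
#'
#' @param x a \code{pirch_counts} of raw counts (already expression
#'   filtered)
#' @param marks assays to test; defaults to every non-input assay
#' @param alpha significance level for the enrichment call
#' @param ... passed to \code{\link{fit_moderated_test}}
#' @return data.frame: gene_id, biotype, mark, log2fc, p_value, fdr,
#'   enriched
#' @export
pirch_enrich <- function(x, marks = NULL, alpha = 0.05, ...) {
  stopifnot(inherits(x, "pirch_counts"))
  if (is.null(marks)) marks <- setdiff(unique(x$samples$assay), "input")
  inp <- x$samples$assay == "input"
  if (!any(inp)) stop("no input samples in metadata")
  bt <- if (!is.null(x$genes)) x$genes$biotype else NA
  out <- lapply(marks, function(mk) {
    sel <- x$samples$assay == mk
    if (!any(sel)) stop("unknown assay '", mk, "'")
    sub <- x$counts[, sel | inp, drop = FALSE]
    grp <- x$samples$assay[sel | inp] == mk
    fit <- fit_moderated_test(sub, grp, ...)
    data.frame(gene_id = fit$table$gene_id, biotype = bt, mark = mk,
               log2fc = fit$table$log2fc, p_value = fit$table$p_value,
               fdr = stats::p.adjust(fit$table$p_value, "BH"),
               enriched = fit$table$p_value < alpha & fit$table$log2fc > 0)
  })
  do.call(rbind, out)
}

#' Genes x marks enrichment-score matrix of the chromatin-associated ncRNAs
#'
#' Restricts to non-coding genes enriched in at least one histone mark and
#' returns their per-mark scores as the matrix that drives state
#' classification.
#'
#' @param enrich_table output of \code{\link{pirch_enrich}}
#' @param score which column provides the matrix entries
#' @param marks marks to keep as columns (default: all in the table except
#'   H3)
#' @return numeric matrix, enriched ncRNAs x marks
#' @export
enrichment_matrix <- function(enrich_table, score = "log2fc",
                              marks = NULL) {
  if (is.null(marks)) marks <- setdiff(unique(enrich_table$mark), "H3")
  tab <- enrich_table[enrich_table$mark %in% marks, ]
  nc <- is.na(tab$biotype) | tab$biotype != "coding"
  enr_genes <- unique(tab$gene_id[tab$enriched & nc])
  tab <- tab[tab$gene_id %in% enr_genes, ]
  m <- matrix(NA_real_, length(enr_genes), length(marks),
              dimnames = list(enr_genes, marks))
  m[cbind(match(tab$gene_id, enr_genes), match(tab$mark, marks))] <-
    tab[[score]]
  if (anyNA(m)) stop("enrichment table is missing gene x mark entries")
  m
}

#' Preranked gene set enrichment analysis
#'
#' Classic weighted Kolmogorov-Smirnov running-sum statistic: walking down
#' the ranked list, hits advance the sum proportionally to |score| and
#' misses retreat uniformly; the enrichment score (ES) is the largest
#' deviation from zero (signed). Significance is estimated by shuffling
#' gene labels and comparing |ES|.
#'
#' @param scores named numeric vector of ranking scores (e.g. enrichment
#'   scores); ranked in decreasing order internally
#' @param gene_set character vector of member genes (must all be scored)
#' @param n_perm number of label permutations (>= 100)
#' @param seed integer seed for the permutations
#' @return list with \code{es}, \code{p_value}, and \code{running} (the
#'   running-sum vector in rank order)
#' @export
gsea_preranked <- function(scores, gene_set, n_perm = 1000, seed = 1L) {
  if (!length(gene_set)) stop("empty gene set")
  if (!all(gene_set %in% names(scores))) {
    stop("gene set contains unscored genes")
  }
  if (n_perm < 100) stop("n_perm must be >= 100")
  # ties broken by gene name so the ranking is input-order invariant
  ord <- order(-scores, names(scores))
  s <- scores[ord]
  inset <- names(s) %in% gene_set
  es_of <- function(inset, s) {
    w <- abs(s) * inset
    denom <- sum(w)
    p_hit <- if (denom > 0) cumsum(w) / denom else cumsum(inset) / sum(inset)
    n_miss <- sum(!inset)
    p_miss <- if (n_miss > 0) cumsum(!inset) / n_miss else rep(0, length(s))
    run <- p_hit - p_miss
    run[which.max(abs(run))]
  }
  run_w <- abs(s) * inset
  denom <- sum(run_w)
  p_hit <- if (denom > 0) cumsum(run_w) / denom else
    cumsum(inset) / sum(inset)
  n_miss <- sum(!inset)
  p_miss <- if (n_miss > 0) cumsum(!inset) / n_miss else
    rep(0, length(s))
  running <- p_hit - p_miss
  es <- running[which.max(abs(running))]
  set.seed(seed)
  k <- sum(inset)
  null_es <- replicate(n_perm, {
    perm <- logical(length(s))
    perm[sample.int(length(s), k)] <- TRUE
    es_of(perm, s)
  })
  p <- (1 + sum(abs(null_es) >= abs(es))) / (n_perm + 1)
  list(es = unname(es), p_value = p, running = unname(running))
}
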