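#' Select the number of chromatin-association states by silhouette
#'
#' Fits K-means (Euclidean distance on the raw enrichment scores,
#' \code{n_init} restarts) for every K in \code{k_range} and returns the K
#' with the largest mean silhouette width; ties go to the smallest K. When
#' no K achieves a mean silhouette above \code{low_sil} the matrix has no
#' usable cluster structure: the smallest K is returned with a warning.
#'
#' @param m enrichment matrix (genes x marks)
#' @param k_range candidate K values
#' @param n_init K-means restarts
#' @param seed integer seed
#' @param low_sil silhouette floor below which selection is flagged; the
#'   default 0.25 is the conventional boundary under which a clustering
#'   shows no substantial structure
#' @return chosen K (integer), with the silhouette profile attached as
#'   attribute \code{"silhouette"}
#' @export
select_k <- function(m, k_range = 2:10, n_init = 25, seed = 1L,
                     low_sil = 0.25) {
  m <- as.matrix(m)
  if (nrow(m) < max(k_range) + 1) {
    stop("need at least max(k_range)+1 rows")
  }
  if (all(apply(m, 2, function(v) length(unique(v)) == 1))) {
    stop("degenerate matrix: all rows identical")
  }
  d <- stats::dist(m)
  set.seed(seed)
  sil <- vapply(k_range, function(k) {
    km <- stats::kmeans(m, centers = k, nstart = n_init)
    mean(cluster::silhouette(km$cluster, d)[, 3])
  }, numeric(1))
  if (max(sil) < low_sil) {
    warning("mean silhouette below ", low_sil,
            " for every K; returning smallest K (low confidence)")
    k <- min(k_range)
  } else {
    k <- k_range[which.max(sil)]   # which.max takes the first = smallest K
  }
  attr(k, "silhouette") <- stats::setNames(sil, k_range)
  k
}

# cosine similarity between rows of a and rows of b
.cosine <- function(a, b) {
  an <- sqrt(rowSums(a^2)); bn <- sqrt(rowSums(b^2))
  (a %*% t(b)) / outer(pmax(an, 1e-12), pmax(bn, 1e-12))
}

#' Cluster enriched ncRNAs and label functional chromatin states
#'
#' K-means on the enrichment matrix, then each cluster is named after the
#' state template with maximal cosine similarity to its centroid (a
#' transparent stand-in for emission-based chromatin-state labeling).
#' Clusters whose best similarity falls below \code{min_sim} keep the
#' best-matching label but are flagged unassigned; two clusters mapping to
#' the same template keep the label with disambiguating suffixes and a
#' warning. 2-D embedding coordinates (classical MDS) are attached for
#' plotting only.
#'
#' @param m enrichment matrix (genes x marks)
#' @param k number of clusters (>= 2)
#' @param seed integer seed
#' @param templates states x marks template matrix; columns are matched to
#'   \code{colnames(m)}
#' @param n_init K-means restarts
#' @param min_sim cosine similarity below which a cluster is flagged
#' @return data.frame: gene_id, cluster, state, similarity, unassigned,
#'   silhouette, dim1, dim2; K-means centers in attribute
#'   \code{"centers"}
#' @export
cluster_states <- function(m, k, seed = 1L,
                           templates = state_templates(colnames(m)),
                           n_init = 25, min_sim = 0.3) {
  m <- as.matrix(m)
  if (k < 2) stop("k must be >= 2")
  set.seed(seed)
  km <- stats::kmeans(m, centers = k, nstart = n_init)
  tm <- templates[, colnames(m), drop = FALSE]
  sim <- .cosine(km$centers, tm)
  lab <- rownames(tm)[apply(sim, 1, which.max)]
  best <- apply(sim, 1, max)
  dup <- duplicated(lab) | duplicated(lab, fromLast = TRUE)
  if (any(dup)) {
    warning("clusters share a template label: ",
            paste(unique(lab[dup]), collapse = ", "))
    lab <- stats::ave(lab, lab, FUN = function(v) {
      if (length(v) > 1) paste0(v, ".", seq_along(v)) else v
    })
  }
  sil <- cluster::silhouette(km$cluster, stats::dist(m))[, 3]
  emb <- stats::cmdscale(stats::dist(m), k = 2)
  out <- data.frame(gene_id = rownames(m), cluster = km$cluster,
                    state = lab[km$cluster],
                    similarity = best[km$cluster],
                    unassigned = best[km$cluster] < min_sim,
                    silhouette = sil, dim1 = emb[, 1], dim2 = emb[, 2])
  attr(out, "centers") <- km$centers
  out
}

#' Correlation structure of enrichment profiles across cell types
#'
#' Pairwise Pearson correlation between per-mark (or per-cell-type x mark)
#' enrichment score vectors on their shared genes, with average-linkage
#' clustering of 1 - r for the display order. Pairs sharing fewer than
#' three genes are set NA.
#'
#' @param profiles genes x profiles numeric matrix (NA for genes absent
#'   from a profile); columns typically named celltype.mark
#' @return list with \code{r} (correlation matrix), \code{order}
#'   (dendrogram leaf order), \code{hclust}
#' @export
crosstype_correlation <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (ncol(profiles) < 2) stop("need >= 2 profiles")
  np <- ncol(profiles)
  r <- matrix(NA_real_, np, np,
              dimnames = list(colnames(profiles), colnames(profiles)))
  for (i in seq_len(np)) {
    for (j in i:np) {
      ok <- stats::complete.cases(profiles[, c(i, j)])
      r[i, j] <- r[j, i] <- if (sum(ok) >= 3) {
        stats::cor(profiles[ok, i], profiles[ok, j])
      } else NA_real_
    }
  }
  d <- stats::as.dist(1 - ifelse(is.na(r), 0, r))
  hc <- stats::hclust(d, method = "average")
  list(r = r, order = hc$order, hclust = hc)
}

#' Default active/repressive valence of the histone marks
#' @return list with \code{active} and \code{repressive} mark sets
#' @export
mark_valence <- function() {
  list(active = c("H3K4me1", "H3K4me3", "H3K27ac", "H4K16ac"),
       repressive = c("H3K27me3", "H3K9me3"))
}

#' Classify genes as bi- or mono-chromatin enriched
#'
#' Bi-enriched genes are enriched on at least one active and one
#' repressive mark; mono-enriched on at least one mark of exactly one
#' valence class; all others are none.
#'
#' @param enriched_marks character vector of marks a gene is enriched in
#'   (single gene), or a named list per gene
#' @param active_set,repressive_set disjoint mark sets
#' @return "bi", "mono" or "none" (vector when a list is given)
#' @export
bi_mono_classify <- function(enriched_marks,
                             active_set = mark_valence()$active,
                             repressive_set = mark_valence()$repressive) {
  if (length(intersect(active_set, repressive_set))) {
    stop("active and repressive sets must be disjoint")
  }
  one <- function(mks) {
    unknown <- setdiff(mks, c(active_set, repressive_set))
    if (length(unknown)) {
      stop("mark(s) not in either valence class: ",
           paste(unknown, collapse = ", "))
    }
    a <- any(mks %in% active_set)
    r <- any(mks %in% repressive_set)
    if (a && r) "bi" else if (a || r) "mono" else "none"
  }
  if (is.list(enriched_marks)) {
    vapply(enriched_marks, one, character(1))
  } else one(enriched_marks)
}

#' Chi-square test of bi:mono proportions between two cell types
#'
#' Plain (uncorrected) contingency chi-square on the 2x2 table of bi- and
#' mono-enriched ncRNA counts.
#'
#' @param bi1,mono1 counts in the first cell type
#' @param bi2,mono2 counts in the second cell type
#' @return \code{htest} object from \code{chisq.test}
#' @export
bi_mono_test <- function(bi1, mono1, bi2, mono2) {
  stats::chisq.test(matrix(c(bi1, mono1, bi2, mono2), 2, byrow = TRUE),
                    correct = FALSE)
}

#' Nearby coding gene expression by ncRNA group
#'
#' Collects the expression of coding genes whose span lies within
#' \code{window} bases of each ncRNA locus (closed boundary: a gene
#' exactly at the window edge is included) and compares two groups with a
#' two-tailed Welch t test on log2 expression.
#'
#' @param loci data.frame of ncRNA loci: \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{group}
#' @param models a \code{gene_models} object supplying the coding genes
#' @param expression named numeric vector of expression per coding gene
#' @param window flank distance in bases (default 100 kb)
#' @return list with \code{by_group} (named list of expression vectors)
#'   and \code{welch} (data.frame of pairwise Welch tests on log2 values)
#' @export
nearby_coding_expression <- function(loci, models, expression,
                                     window = 1e5) {
  cod <- models$genes[models$genes$biotype == "coding", ]
  by_group <- list()
  for (grp in unique(loci$group)) {
    sub <- loci[loci$group == grp, ]
    vals <- numeric(0)
    for (i in seq_len(nrow(sub))) {
      hit <- cod$chrom == sub$chrom[i] &
        cod$start <= sub$end[i] + window &
        cod$end >= sub$start[i] - window
      vals <- c(vals, expression[cod$gene_id[hit]])
    }
    by_group[[grp]] <- vals[!is.na(vals)]
  }
  grps <- names(by_group)
  tests <- NULL
  if (length(grps) >= 2) {
    cmb <- utils::combn(grps, 2)
    tests <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
      a <- by_group[[cmb[1, j]]]; b <- by_group[[cmb[2, j]]]
      if (length(a) < 2 || length(b) < 2) return(NULL)
      tt <- stats::t.test(log2(a + 1), log2(b + 1))
      data.frame(group1 = cmb[1, j], group2 = cmb[2, j],
                 mean1 = mean(log2(a + 1)), mean2 = mean(log2(b + 1)),
                 p_value = tt$p.value)
    }))
  }
  list(by_group = by_group, welch = tests)
}
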