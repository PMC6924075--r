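#' Overlap ratio of RNA binding-site peaks with ChIP-seq peaks
#'
#' Fraction of RNA peaks intersecting (>= 1 bp) at least one ChIP peak,
#' optionally rescaled by the mark's ChIP peak count relative to a
#' reference count, so that marks with many more ChIP peaks do not win
#' the comparison by chance alone.
#'
#' @param rna_peaks,chip_peaks data.frames of 0-based half-open intervals
#'   (\code{chrom}, \code{start}, \code{end}) or \code{GRanges}
#' @param n_chip_total ChIP peak count used for scaling (default: number
#'   of chip_peaks rows)
#' @param n_chip_ref reference count the scaling is relative to (default
#'   equal to \code{n_chip_total}, i.e. no rescaling: the raw fraction)
#' @return overlap fraction divided by (n_chip_total / n_chip_ref)
#' @export
overlap_ratio <- function(rna_peaks, chip_peaks,
                          n_chip_total = NULL, n_chip_ref = NULL) {
  to_gr <- function(x) {
    if (inherits(x, "GRanges")) return(x)
    GenomicRanges::GRanges(x$chrom,
                           IRanges::IRanges(x$start + 1L, x$end))
  }
  rna <- to_gr(rna_peaks)
  chip <- to_gr(chip_peaks)
  if (!length(rna)) stop("empty RNA peak set")
  if (is.null(n_chip_total)) n_chip_total <- length(chip)
  if (is.null(n_chip_ref)) n_chip_ref <- n_chip_total
  frac <- mean(GenomicRanges::countOverlaps(rna, chip) > 0)
  frac / (n_chip_total / n_chip_ref)
}

#' Per-mark overlap matrix for a set of lncRNAs
#'
#' Applies \code{\link{overlap_ratio}} to every lncRNA x mark pair,
#' scaling each mark by its ChIP peak count relative to the mean count
#' across marks.
#'
#' @param rna_peak_sets named list (per lncRNA) of interval data.frames
#' @param chip_peak_sets named list (per mark) of interval data.frames
#' @return numeric matrix, lncRNAs x marks
#' @export
overlap_matrix <- function(rna_peak_sets, chip_peak_sets) {
  n_chip <- vapply(chip_peak_sets, nrow, 0L)
  ref <- mean(n_chip)
  out <- matrix(NA_real_, length(rna_peak_sets), length(chip_peak_sets),
                dimnames = list(names(rna_peak_sets),
                                names(chip_peak_sets)))
  for (i in seq_along(rna_peak_sets)) {
    for (j in seq_along(chip_peak_sets)) {
      out[i, j] <- overlap_ratio(rna_peak_sets[[i]], chip_peak_sets[[j]],
                                 n_chip_total = n_chip[j],
                                 n_chip_ref = ref)
    }
  }
  out
}

# all permutations of seq_len(n), one per row (n! rows)
.all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_perms(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    blk <- cbind(k, ifelse(sub >= k, sub + 1L, sub))
    out[r + seq_len(nrow(sub)), ] <- blk
    r <- r + nrow(sub)
  }
  out
}

#' Rank concordance between ChIP-overlap and pulldown-enrichment matrices
#'
#' Each lncRNA's marks are ranked 1..m in both matrices (rank 1 = most
#' enriched, ties averaged) and per-lncRNA Spearman correlation between
#' the two rank vectors is computed. The null distribution comes from
#' shuffling the column labels of the overlap matrix: exhaustively over
#' all m! permutations when feasible within \code{n_perm}, otherwise by
#' sampling. Per-lncRNA one-sided permutation p-values (concordance
#' direction) and a two-tailed Welch t test of observed versus permuted
#' correlations are returned. Constant rows have no defined ranking and
#' are skipped with a warning.
#'
#' @param overlap_m,enrich_m matrices with identical row/column labels
#'   (>= 3 columns)
#' @param n_perm permutation budget
#' @param seed integer seed (used only when sampling)
#' @return list with \code{rho} (per-lncRNA Spearman), \code{p}
#'   (per-lncRNA permutation p), \code{null_rho}, \code{welch_p},
#'   \code{exhaustive}
#' @export
rank_concordance <- function(overlap_m, enrich_m, n_perm = 10000,
                             seed = 1L) {
  stopifnot(identical(dim(overlap_m), dim(enrich_m)))
  m <- ncol(overlap_m)
  if (m < 3) stop("need >= 3 marks")
  const <- apply(overlap_m, 1, function(v) length(unique(v)) == 1) |
    apply(enrich_m, 1, function(v) length(unique(v)) == 1)
  if (any(const)) {
    warning(sum(const), " constant row(s) skipped (rank undefined)")
    overlap_m <- overlap_m[!const, , drop = FALSE]
    enrich_m <- enrich_m[!const, , drop = FALSE]
  }
  rk <- function(v) rank(-v)   # rank 1 = most enriched, ties averaged
  ro <- t(apply(overlap_m, 1, rk))
  re <- t(apply(enrich_m, 1, rk))
  rho_of <- function(a, b) stats::cor(a, b, method = "spearman")
  rho <- vapply(seq_len(nrow(ro)), function(i) rho_of(ro[i, ], re[i, ]),
                numeric(1))
  exhaustive <- factorial(m) <= n_perm
  if (exhaustive) {
    perms <- .all_perms(m)
  } else {
    set.seed(seed)
    perms <- t(replicate(n_perm, sample.int(m)))
  }
  null_rho <- numeric(0)
  p <- numeric(nrow(ro))
  for (i in seq_len(nrow(ro))) {
    nr <- vapply(seq_len(nrow(perms)), function(k) {
      rho_of(ro[i, perms[k, ]], re[i, ])
    }, numeric(1))
    p[i] <- if (exhaustive) mean(nr >= rho[i]) else
      (1 + sum(nr >= rho[i])) / (nrow(perms) + 1)
    null_rho <- c(null_rho, nr)
  }
  welch_p <- if (length(rho) >= 2) {
    stats::t.test(rho, null_rho)$p.value
  } else NA_real_
  list(rho = stats::setNames(rho, rownames(ro)),
       p = stats::setNames(p, rownames(ro)),
       null_rho = null_rho, welch_p = welch_p, exhaustive = exhaustive)
}
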