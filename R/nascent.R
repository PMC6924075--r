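#' Intron over exon read ratio for one gene
#'
#' Base-level overlap of reads with the gene's introns divided by the
#' overlap with its exons. Chromatin-associated mature RNAs give low
#' ratios; nascent-transcript contamination inflates intronic signal.
#'
#' @param reads data.frame of 0-based half-open read intervals
#'   (\code{start}, \code{end}) on the gene's chromosome
#' @param model a \code{gene_models} object containing exactly one gene,
#'   or a list with \code{exons} for one gene
#' @return intronic bases / exonic bases; \code{Inf} when no read base
#'   falls in an exon but some fall in introns; \code{NaN} if neither
#' @export
intron_exon_ratio <- function(reads, model) {
  ex <- if (inherits(model, "gene_models")) model$exons else model$exons
  if (is.null(ex) || !nrow(ex)) stop("gene model has no exons")
  if (length(unique(ex$gene_id)) > 1) {
    stop("intron_exon_ratio expects a single gene")
  }
  exr <- IRanges::reduce(IRanges::IRanges(ex$start + 1L, ex$end)) # 1-based
  inr <- IRanges::gaps(exr, start = min(IRanges::start(exr)),
                       end = max(IRanges::end(exr)))
  rd <- IRanges::IRanges(reads$start + 1L, reads$end)
  # each read contributes its base-level overlap to each class
  ov_bases <- function(target) {
    hits <- IRanges::findOverlaps(rd, target)
    if (!length(hits)) return(0L)
    pi <- IRanges::pintersect(rd[S4Vectors::queryHits(hits)],
                              target[S4Vectors::subjectHits(hits)])
    sum(IRanges::width(pi))
  }
  ex_bases <- ov_bases(exr)
  in_bases <- ov_bases(inr)
  if (ex_bases == 0 && in_bases > 0) return(Inf)
  in_bases / ex_bases
}

# Mean of a piecewise-constant coverage vector over the real interval
# [a, b) in 0-based coordinates, by linear interpolation of the cumulative
# sum. Exact for uniform coverage regardless of window width.
.interval_mean <- function(cum, a, b) {
  S <- function(x) {
    f <- floor(x)
    base <- cum[f + 1L]
    frac <- x - f
    base + frac * (cum[pmin(f + 2L, length(cum))] - cum[f + 1L])
  }
  (S(b) - S(a)) / (b - a)
}

# 100 equal fractional windows over coverage[start, end) (0-based).
.segment_windows <- function(cov_cum, start, end, n = 100L) {
  bounds <- start + (end - start) * (0:n) / n
  vapply(seq_len(n), function(k) {
    .interval_mean(cov_cum, bounds[k], bounds[k + 1])
  }, numeric(1))
}

#' Intron metagene profile over 300 scaled windows
#'
#' For every intron that has flanking exons on both sides, the region
#' (upstream exon + intron + downstream exon) is rescaled to 300 equal
#' windows (100 per segment), the mean coverage per window is taken and
#' log2(x+1)-transformed, and profiles are averaged across introns. Minus
#' strand genes are flipped so every profile runs 5' to 3'.
#'
#' @param coverage named list of per-chromosome coverage vectors (0-based
#'   positions), or a single numeric vector if all genes share one
#'   chromosome
#' @param models a \code{gene_models} object
#' @return object of class \code{intron_metagene}: list with
#'   \code{profile} (300 window means, log2 scale), \code{n_introns}, and
#'   \code{segments} (window index ranges of the three segments)
#' @export
intron_metagene <- function(coverage, models) {
  if (!is.list(coverage)) {
    coverage <- stats::setNames(list(coverage),
                                unique(models$genes$chrom)[1])
  }
  introns <- gene_introns(models)
  profs <- list()
  for (g in unique(introns$gene_id)) {
    gi <- models$genes[models$genes$gene_id == g, ]
    cov <- coverage[[gi$chrom]]
    if (is.null(cov)) next
    cum <- c(0, cumsum(cov))
    e <- models$exons[models$exons$gene_id == g, ]
    ii <- introns[introns$gene_id == g, ]
    for (k in seq_len(nrow(ii))) {
      up <- e[e$end == ii$start[k], ][1, ]    # flanking exon upstream (left)
      dn <- e[e$start == ii$end[k], ][1, ]
      if (is.na(up$start) || is.na(dn$start)) next
      win <- c(.segment_windows(cum, up$start, up$end),
               .segment_windows(cum, ii$start[k], ii$end[k]),
               .segment_windows(cum, dn$start, dn$end))
      if (gi$strand == "-") win <- rev(win)
      profs[[length(profs) + 1L]] <- log2(win + 1)
    }
  }
  if (!length(profs)) stop("no intron with flanking exons on both sides")
  profile <- Reduce(`+`, profs) / length(profs)
  structure(list(profile = profile, n_introns = length(profs),
                 segments = list(flank5 = 1:100, intron = 101:200,
                                 flank3 = 201:300)),
            class = "intron_metagene")
}

#' @export
print.intron_metagene <- function(x, ...) {
  cat("intron_metagene over", x$n_introns, "introns; flank/intron mean",
      signif(mean(x$profile[c(1:100, 201:300)]), 4), "/",
      signif(mean(x$profile[101:200]), 4), "(log2)\n")
  invisible(x)
}
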