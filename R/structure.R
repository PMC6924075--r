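#' Structure-score profile around peak summits
#'
#' Averages icSHAPE-like scores at every offset within \code{flank} bases
#' of each peak summit, against a background profile built around
#' positions drawn uniformly from the same transcripts (matched
#' composition). Per-offset significance is a two-tailed Welch t test of
#' peak-anchored versus background-anchored scores; missing bases are
#' skipped, and offsets running past a transcript end simply contribute
#' fewer observations.
#'
#' @param peaks peak data.frame with \code{transcript_id}, \code{summit}
#' @param shape named list of per-base score vectors (NA = missing)
#' @param flank half-width of the profile in bases
#' @param n_background number of background anchor positions (default:
#'   number of peaks)
#' @param seed integer seed for the background draw
#' @return object of class \code{flank_profile}: data.frame with
#'   \code{offset} (-flank..flank), \code{mean}, \code{n},
#'   \code{bg_mean}, \code{bg_n}, \code{p_value}
#' @export
shape_flank_profile <- function(peaks, shape, flank = 200,
                                n_background = NULL, seed = 1L) {
  peaks <- peaks[peaks$transcript_id %in% names(shape), , drop = FALSE]
  if (!nrow(peaks)) stop("no peak lies on a transcript with shape coverage")
  if (is.null(n_background)) n_background <- nrow(peaks)
  set.seed(seed)
  txs <- sample(peaks$transcript_id, n_background, replace = TRUE)
  bg_pos <- vapply(txs, function(tx) {
    sample.int(length(shape[[tx]]), 1) - 1L
  }, integer(1))
  offs <- -flank:flank
  gather <- function(tx_ids, anchors) {
    lapply(seq_along(offs), function(k) {
      pos <- anchors + offs[k]
      val <- numeric(0)
      for (i in seq_along(tx_ids)) {
        v <- shape[[tx_ids[i]]]
        p <- pos[i]
        if (p >= 0 && p < length(v) && !is.na(v[p + 1L])) {
          val <- c(val, v[p + 1L])
        }
      }
      val
    })
  }
  pv <- gather(peaks$transcript_id, peaks$summit)
  bv <- gather(txs, bg_pos)
  if (sum(lengths(pv)) == 0) {
    stop("no peak lies on a transcript with shape coverage")
  }
  p_of <- function(a, b) {
    if (length(a) < 2 || length(b) < 2) return(NA_real_)
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
    }
    stats::t.test(a, b)$p.value
  }
  out <- data.frame(
    offset = offs,
    mean = vapply(pv, function(v) if (length(v)) mean(v) else NA_real_,
                  numeric(1)),
    n = lengths(pv),
    bg_mean = vapply(bv, function(v) if (length(v)) mean(v) else NA_real_,
                     numeric(1)),
    bg_n = lengths(bv),
    p_value = mapply(p_of, pv, bv))
  class(out) <- c("flank_profile", "data.frame")
  out
}

#' Mean structure score per gene
#'
#' @param shape named list of per-base score vectors
#' @param min_bases minimum number of scored (non-missing) bases for a
#'   gene to be reported
#' @return named numeric vector of per-gene mean scores
#' @export
gene_mean_shape <- function(shape, min_bases = 50) {
  v <- vapply(shape, function(x) {
    if (sum(!is.na(x)) < min_bases) NA_real_ else mean(x, na.rm = TRUE)
  }, numeric(1))
  v[!is.na(v)]
}

#' Compare mean structure scores of enriched versus depleted genes
#'
#' Two-tailed Welch t test of per-gene mean icSHAPE-like scores between
#' chromatin-enriched and chromatin-depleted genes.
#'
#' @param mean_shape named numeric vector from
#'   \code{\link{gene_mean_shape}}
#' @param enriched character vector of enriched gene ids (the remainder
#'   of \code{mean_shape} is the depleted group), or a named logical
#' @return list with \code{mean_enriched}, \code{mean_depleted},
#'   \code{p_value}, group sizes
#' @export
shape_group_comparison <- function(mean_shape, enriched) {
  if (is.logical(enriched)) enriched <- names(enriched)[enriched]
  a <- mean_shape[names(mean_shape) %in% enriched]
  b <- mean_shape[!(names(mean_shape) %in% enriched)]
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 genes")
  }
  tt <- stats::t.test(a, b)
  list(mean_enriched = mean(a), mean_depleted = mean(b),
       n_enriched = length(a), n_depleted = length(b),
       p_value = tt$p.value)
}

#' Compare enrichment of the most single- vs most double-stranded RNAs
#'
#' Ranks genes by mean structure score, takes the top and bottom k, and
#' compares their chromatin enrichment scores by two-tailed Welch t test.
#'
#' @param mean_shape named per-gene mean structure scores
#' @param enrich_score named per-gene enrichment scores
#' @param k group size
#' @return list with the two group means and \code{p_value}
#' @export
top_k_comparison <- function(mean_shape, enrich_score, k = 100) {
  common <- intersect(names(mean_shape), names(enrich_score))
  if (k > floor(length(common) / 2)) {
    stop("k = ", k, " exceeds half the scored population (",
         length(common), ")")
  }
  ord <- common[order(mean_shape[common], decreasing = TRUE)]
  top <- enrich_score[ord[seq_len(k)]]
  bot <- enrich_score[ord[(length(ord) - k + 1):length(ord)]]
  tt <- stats::t.test(top, bot)
  list(mean_single = mean(top), mean_double = mean(bot),
       p_value = tt$p.value)
}

#' Overlap of peaks with m6A modification intervals
#'
#' Fraction of peak bases falling inside m6A intervals, compared with the
#' same statistic for random regions of identical lengths drawn from the
#' same transcripts; the permutation p-value is
#' (1 + #\{background fraction >= observed\}) / (n_background + 1).
#'
#' @param peaks peak data.frame with \code{transcript_id}, \code{start},
#'   \code{end} (0-based half-open, transcript coordinates)
#' @param m6a data.frame of m6A intervals: \code{transcript_id} (or
#'   \code{chrom}), \code{start}, \code{end}
#' @param lengths named vector of transcript lengths
#' @param n_background number of background draws
#' @param seed integer seed
#' @return list with \code{overlap}, \code{bg_overlap} (mean background
#'   fraction), \code{p_value}
#' @export
m6a_overlap <- function(peaks, m6a, lengths, n_background = 200,
                        seed = 1L) {
  if ("chrom" %in% names(m6a) && !("transcript_id" %in% names(m6a))) {
    m6a$transcript_id <- m6a$chrom
  }
  in_m6a <- function(tx, start, end) {
    # bases of [start,end) covered by the union of m6a intervals on tx
    mm <- m6a[m6a$transcript_id == tx, , drop = FALSE]
    if (!nrow(mm)) return(0L)
    r <- IRanges::reduce(IRanges::IRanges(mm$start + 1L, mm$end))
    q <- IRanges::IRanges(start + 1L, end)
    hits <- IRanges::findOverlaps(q, r)
    if (!length(hits)) return(0L)
    sum(IRanges::width(IRanges::pintersect(
      q[S4Vectors::queryHits(hits)], r[S4Vectors::subjectHits(hits)])))
  }
  frac_of <- function(tab) {
    tot <- sum(tab$end - tab$start)
    cov <- sum(vapply(seq_len(nrow(tab)), function(i) {
      in_m6a(tab$transcript_id[i], tab$start[i], tab$end[i])
    }, numeric(1)))
    cov / tot
  }
  obs <- frac_of(peaks)
  set.seed(seed)
  widths <- peaks$end - peaks$start
  bg <- vapply(seq_len(n_background), function(b) {
    st <- vapply(seq_len(nrow(peaks)), function(i) {
      L <- lengths[[peaks$transcript_id[i]]]
      sample.int(max(L - widths[i], 1L), 1) - 1L
    }, integer(1))
    frac_of(data.frame(transcript_id = peaks$transcript_id, start = st,
                       end = st + widths))
  }, numeric(1))
  list(overlap = obs, bg_overlap = mean(bg),
       p_value = (1 + sum(bg >= obs)) / (n_background + 1))
}
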