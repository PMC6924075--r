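#' Merge replicate pileups and smooth on a sliding-window grid
#'
#' Replicates are (optionally depth-rescaled and) summed, then smoothed
#' with a \code{window}-base sliding mean evaluated every \code{step}
#' bases, windows truncated at the transcript ends.
#'
#' @param pileups a \code{pirch_pileup} or list of replicate pileups of
#'   equal length
#' @param window odd window width in bases
#' @param step grid spacing in bases
#' @param lib_sizes optional per-replicate library sizes; when given each
#'   replicate is scaled to 10 million total depth before summing
#' @return object of class \code{smoothed_signal}: list with \code{grid}
#'   (0-based positions), \code{value}, \code{merged} (per-base merged
#'   coverage), \code{window}, \code{step}
#' @export
merge_and_smooth <- function(pileups, window = 5, step = 2,
                             lib_sizes = NULL) {
  if (inherits(pileups, "pirch_pileup")) pileups <- list(pileups)
  if (window %% 2 != 1) stop("window must be odd")
  L <- length(pileups[[1]]$coverage)
  if (!all(vapply(pileups, function(p) length(p$coverage), 0L) == L)) {
    stop("replicate pileups differ in length")
  }
  covs <- lapply(seq_along(pileups), function(i) {
    v <- pileups[[i]]$coverage
    if (!is.null(lib_sizes)) v <- v * 1e7 / lib_sizes[i]
    v
  })
  merged <- Reduce(`+`, covs)
  if (L < window) {
    return(structure(list(grid = 0L, value = mean(merged),
                          merged = merged, window = window, step = step,
                          transcript_id = pileups[[1]]$transcript_id),
                     class = "smoothed_signal"))
  }
  S <- c(0, cumsum(merged))
  grid <- seq(0L, L - 1L, by = step)
  h <- (window - 1L) %/% 2L
  a <- pmax(grid - h, 0L)
  b <- pmin(grid + h + 1L, L)
  structure(list(grid = grid, value = (S[b + 1L] - S[a + 1L]) / (b - a),
                 merged = merged, window = window, step = step,
                 transcript_id = pileups[[1]]$transcript_id),
            class = "smoothed_signal")
}

# median over positive-coverage bases; global mean when fewer than
# min_pos bases are covered (an all-zero median would make a relative
# threshold vacuous)
.transcript_baseline <- function(cov, min_pos = 20) {
  pos <- cov[cov > 0]
  if (length(pos) < min_pos) mean(cov) else stats::median(pos)
}

#' Call candidate peaks on a smoothed transcript signal
#'
#' Candidate summits are strict local maxima on the smoothing grid
#' (plateaus keep their leftmost point), retained when the smoothed height
#' reaches \code{fold} times the transcript baseline (median coverage over
#' positive bases). The peak extent is the maximal contiguous grid run
#' above threshold containing the summit, projected to base coordinates;
#' overlapping extents are merged keeping the higher summit.
#'
#' @param smoothed a \code{smoothed_signal} from
#'   \code{\link{merge_and_smooth}}
#' @param fold fold-over-baseline threshold (default 5)
#' @return data.frame of peaks: \code{transcript_id}, \code{summit},
#'   \code{start}, \code{end} (0-based half-open), \code{height},
#'   \code{fold_median}
#' @export
call_peaks <- function(smoothed, fold = 5) {
  v <- smoothed$value
  g <- smoothed$grid
  empty <- data.frame(transcript_id = character(), summit = integer(),
                      start = integer(), end = integer(),
                      height = numeric(), fold_median = numeric())
  if (all(smoothed$merged == 0) || length(v) < 2) return(empty)
  base <- .transcript_baseline(smoothed$merged)
  if (base <= 0) base <- mean(smoothed$merged)
  thr <- fold * base
  n <- length(v)
  # strict local maxima with leftmost-of-plateau policy
  is_max <- logical(n)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && v[j + 1L] == v[i]) j <- j + 1L
    left_ok <- i == 1L || v[i - 1L] < v[i]
    right_ok <- j == n || v[j + 1L] < v[i]
    if (left_ok && right_ok && v[i] > 0) is_max[i] <- TRUE
    i <- j + 1L
  }
  cand <- which(is_max & v >= thr)
  if (!length(cand)) return(empty)
  above <- v >= thr
  runs <- rle(above)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  pk <- do.call(rbind, lapply(cand, function(ci) {
    ri <- which(run_start <= ci & run_end >= ci & runs$values)
    a <- run_start[ri]; b <- run_end[ri]
    data.frame(summit = g[ci],
               start = g[a],
               end = g[b] + 1L,
               height = v[ci])
  }))
  # merge overlapping extents keeping the higher summit
  pk <- pk[order(pk$start, -pk$height), ]
  keep <- rep(TRUE, nrow(pk))
  last_end <- -1L; last_i <- 0L
  for (r in seq_len(nrow(pk))) {
    if (pk$start[r] < last_end) {
      if (pk$height[r] > pk$height[last_i]) {
        keep[last_i] <- FALSE; last_i <- r
        last_end <- max(last_end, pk$end[r])
      } else keep[r] <- FALSE
    } else {
      last_i <- r; last_end <- pk$end[r]
    }
  }
  pk <- pk[keep, ]
  data.frame(transcript_id = smoothed$transcript_id, summit = pk$summit,
             start = pk$start, end = pk$end, height = pk$height,
             fold_median = pk$height / base)
}

#' Bootstrap p-value for a peak height
#'
#' Re-places the transcript's reads uniformly at random \code{B} times
#' (read count and length preserved), smooths each null pileup with the
#' same window/step, and records the maximum grid value. The p-value is
#' (1 + #\{null max >= observed height\}) / (B + 1); the add-one keeps p
#' strictly positive.
#'
#' @param observed_height smoothed height of the peak being tested
#' @param transcript_len transcript length in bases
#' @param n_reads number of reads on the transcript
#' @param read_len read length in bases
#' @param window,step smoothing parameters (must match the observed
#'   signal)
#' @param B bootstrap resamples (>= 100)
#' @param seed integer seed
#' @param scale multiplicative factor applied to null coverage before
#'   comparison (use when the observed signal was depth-rescaled)
#' @return p-value in (0, 1]
#' @export
bootstrap_pvalue <- function(observed_height, transcript_len, n_reads,
                             read_len, window = 5, step = 2, B = 1000,
                             seed = 1L, scale = 1) {
  if (B < 100) stop("B must be >= 100")
  if (n_reads < 1) return(1)
  set.seed(seed)
  S <- transcript_len - read_len + 1L
  h <- (window - 1L) %/% 2L
  grid <- seq(0L, transcript_len - 1L, by = step)
  a <- pmax(grid - h, 0L)
  b <- pmin(grid + h + 1L, transcript_len)
  mx <- vapply(seq_len(B), function(i) {
    st <- sample.int(S, n_reads, replace = TRUE) - 1L
    cov <- coverage_from_starts(st, read_len, transcript_len) * scale
    cs <- c(0, cumsum(cov))
    max((cs[b + 1L] - cs[a + 1L]) / (b - a))
  }, numeric(1))
  (1 + sum(mx >= observed_height)) / (B + 1)
}

#' Fold change of a peak over the input control
#'
#' Mean pulldown coverage over the peak extent divided by mean input
#' coverage, each with a pseudocount.
#'
#' @param peak one-row peak data.frame with \code{start}, \code{end}
#' @param pulldown,input per-base coverage vectors covering the extent
#' @param pseudo pseudocount
#' @return numeric fold change
#' @export
fold_vs_input <- function(peak, pulldown, input, pseudo = 1) {
  idx <- (peak$start + 1L):peak$end
  (mean(pulldown[idx]) + pseudo) / (mean(input[idx]) + pseudo)
}

#' Full transcript peak calling with bootstrap significance
#'
#' Convenience wrapper: merge + smooth the pulldown replicates, call
#' candidate peaks at \code{fold} x baseline, attach bootstrap p-values
#' and fold over input, and filter (p < \code{alpha}, fold over input >
#' \code{min_fold_input}).
#'
#' @param pulldown_reps list of replicate \code{pirch_pileup}s
#' @param input_reps list of replicate input pileups (same transcript)
#' @param n_reads,read_len read count and length used for the bootstrap
#'   null; when \code{n_reads} is NULL it is estimated as
#'   total_coverage / read_len of the merged pulldown
#' @param fold fold-over-baseline threshold
#' @param window,step smoothing parameters
#' @param B bootstrap resamples
#' @param alpha significance threshold
#' @param min_fold_input input fold-change threshold
#' @param seed integer seed
#' @param filter apply the significance/fold filter? (FALSE returns all
#'   candidates with their statistics)
#' @return peak data.frame with \code{height}, \code{fold_median},
#'   \code{fold_input}, \code{p_value}
#' @export
transcript_peaks <- function(pulldown_reps, input_reps = NULL,
                             n_reads = NULL, read_len = 30, fold = 5,
                             window = 5, step = 2, B = 1000, alpha = 0.05,
                             min_fold_input = 1, seed = 1L,
                             filter = TRUE) {
  sm <- merge_and_smooth(pulldown_reps, window, step)
  pk <- call_peaks(sm, fold)
  if (!nrow(pk)) {
    pk$fold_input <- numeric(0)
    pk$p_value <- numeric(0)
    return(pk)
  }
  if (is.null(n_reads)) {
    n_reads <- max(1L, round(sum(sm$merged) / read_len))
  }
  L <- length(sm$merged)
  pk$p_value <- vapply(seq_len(nrow(pk)), function(i) {
    bootstrap_pvalue(pk$height[i], L, n_reads, read_len, window, step, B,
                     seed = seed + i)
  }, numeric(1))
  if (!is.null(input_reps)) {
    smi <- merge_and_smooth(input_reps, window, step)
    pk$fold_input <- vapply(seq_len(nrow(pk)), function(i) {
      fold_vs_input(pk[i, ], sm$merged, smi$merged)
    }, numeric(1))
  } else {
    pk$fold_input <- NA_real_
  }
  if (filter) {
    keep <- pk$p_value < alpha &
      (is.na(pk$fold_input) | pk$fold_input > min_fold_input)
    pk <- pk[keep, ]
  }
  pk
}
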