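#' Count matrix with sample metadata
#'
#' Lightweight container pairing a genes x samples matrix of read counts with
#' per-sample metadata, in the style of limma's \code{EList}/edgeR's
#' \code{DGEList}. Rows are genes, columns are sequencing samples (inputs and
#' histone-mark pulldowns).
#'
#' @param counts numeric matrix, genes x samples, non-negative. Raw counts
#'   must be integers; normalized matrices may be real-valued.
#' @param samples data.frame with one row per column of \code{counts} and at
#'   least the columns \code{sample}, \code{assay} (\code{"input"},
#'   \code{"H3"}, or a histone-mark name), \code{replicate} and
#'   \code{cell_type}.
#' @param genes optional data.frame of per-gene annotation (e.g.
#'   \code{biotype}), one row per row of \code{counts}.
#' @return an object of class \code{pirch_counts}: a list with elements
#'   \code{counts}, \code{samples}, \code{genes}.
#' @export
pirch_counts <- function(counts, samples, genes = NULL) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts) || any(counts < 0)) {
    stop("'counts' must be a non-negative numeric matrix")
  }
  samples <- as.data.frame(samples)
  if (nrow(samples) != ncol(counts)) {
    stop("metadata rows (", nrow(samples), ") must equal count columns (",
         ncol(counts), ")")
  }
  need <- c("sample", "assay", "replicate", "cell_type")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("sample metadata lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(colnames(counts))) colnames(counts) <- samples$sample
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("gene%05d", seq_len(nrow(counts)))
  }
  if (!is.null(genes)) {
    genes <- as.data.frame(genes)
    if (nrow(genes) != nrow(counts)) {
      stop("gene annotation rows must equal count rows")
    }
  }
  structure(list(counts = counts, samples = samples, genes = genes),
            class = "pirch_counts")
}

#' @export
print.pirch_counts <- function(x, ...) {
  cat("pirch_counts: ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples\n", sep = "")
  cat("assays: ", paste(unique(x$samples$assay), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
dim.pirch_counts <- function(x) dim(x$counts)

#' Subset a pirch_counts object
#'
#' @param x a \code{pirch_counts} object
#' @param i gene (row) index
#' @param j sample (column) index
#' @param ... ignored
#' @export
`[.pirch_counts` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  pirch_counts(x$counts[i, j, drop = FALSE],
               x$samples[j, , drop = FALSE],
               if (!is.null(x$genes)) x$genes[i, , drop = FALSE])
}

#' Per-base transcript pileup
#'
#' Coverage along a mature transcript (introns spliced out), 5' to 3',
#' 0-based positions.
#'
#' @param transcript_id transcript identifier
#' @param coverage non-negative numeric vector, one value per base
#' @param sample sample tag (e.g. \code{"H3K4me3_rep1"})
#' @return object of class \code{pirch_pileup}
#' @export
pirch_pileup <- function(transcript_id, coverage, sample = NA_character_) {
  coverage <- as.numeric(coverage)
  if (any(coverage < 0) || anyNA(coverage)) {
    stop("coverage must be non-negative and complete")
  }
  structure(list(transcript_id = transcript_id, coverage = coverage,
                 sample = sample),
            class = "pirch_pileup")
}

#' @export
length.pirch_pileup <- function(x) length(x$coverage)

#' @export
print.pirch_pileup <- function(x, ...) {
  cat("pirch_pileup: ", x$transcript_id, " (", length(x$coverage),
      " nt), total coverage ", signif(sum(x$coverage), 4), "\n", sep = "")
  invisible(x)
}

#' Gene model set
#'
#' Genes with exon structure on a common coordinate system. Intervals are
#' stored 0-based half-open; exons per gene are sorted and non-overlapping.
#' The TSS is the leftmost exon start on the + strand and the rightmost
#' exon end minus one on the - strand.
#'
#' @param genes data.frame with columns \code{gene_id}, \code{biotype},
#'   \code{chrom}, \code{strand}
#' @param exons data.frame with columns \code{gene_id}, \code{start},
#'   \code{end} (0-based half-open)
#' @return object of class \code{gene_models}; \code{genes} gains
#'   \code{start}, \code{end} (gene span) and \code{tss} columns.
#' @export
gene_models <- function(genes, exons) {
  genes <- as.data.frame(genes)
  exons <- as.data.frame(exons)
  if (!all(exons$gene_id %in% genes$gene_id)) {
    stop("exon table references unknown gene ids")
  }
  bad_bt <- !genes$biotype %in% gene_biotypes()
  if (any(bad_bt)) {
    warning("unknown biotype(s) ",
            paste(unique(genes$biotype[bad_bt]), collapse = ", "),
            " mapped to 'other-ncRNA'")
    genes$biotype[bad_bt] <- "other-ncRNA"
  }
  exons <- exons[order(exons$gene_id, exons$start), ]
  for (g in unique(exons$gene_id)) {
    e <- exons[exons$gene_id == g, ]
    if (any(e$end <= e$start)) stop("empty exon in gene ", g)
    if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)])) {
      stop("overlapping exons in gene ", g)
    }
  }
  span <- do.call(rbind, lapply(genes$gene_id, function(g) {
    e <- exons[exons$gene_id == g, ]
    data.frame(start = min(e$start), end = max(e$end))
  }))
  genes$start <- span$start
  genes$end <- span$end
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' Recognized gene biotypes
#' @return character vector of the biotype labels used throughout
#' @export
gene_biotypes <- function() {
  c("coding", "lncRNA", "pre-miRNA", "snoRNA", "other-ncRNA")
}

#' Non-coding biotype labels
#' @return character vector; every biotype except \code{"coding"}
#' @export
noncoding_biotypes <- function() setdiff(gene_biotypes(), "coding")

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models: ", nrow(x$genes), " genes, ", nrow(x$exons),
      " exons on ", length(unique(x$genes$chrom)), " chromosome(s)\n",
      sep = "")
  invisible(x)
}

#' Introns of a gene model set
#'
#' @param models a \code{gene_models} object
#' @return data.frame of 0-based half-open intron intervals with
#'   \code{gene_id}, \code{start}, \code{end}; genes with a single exon
#'   contribute no rows
#' @export
gene_introns <- function(models) {
  out <- lapply(unique(models$exons$gene_id), function(g) {
    e <- models$exons[models$exons$gene_id == g, ]
    if (nrow(e) < 2) return(NULL)
    data.frame(gene_id = g, start = e$end[-nrow(e)], end = e$start[-1])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), start = integer(),
                      end = integer())
  }
  out
}
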