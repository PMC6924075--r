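#' Read a GTF gene annotation
#'
#' Parses an Ensembl-dialect GTF via rtracklayer and returns gene models in
#' the package's internal convention (0-based half-open intervals). Exon
#' records are required; biotypes are taken from the \code{gene_biotype}
#' attribute, with unknown labels mapped to \code{"other-ncRNA"} (warning).
#'
#' @param path GTF file path
#' @return a \code{gene_models} object
#' @export
read_gtf <- function(path) {
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  for (i in which(body)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9) {
      stop("GTF parse error at line ", i, ": expected 9 tab-separated ",
           "fields, found ", length(f))
    }
    if (!grepl("gene_id\\s+\"[^\"]*\"", f[9])) {
      stop("GTF parse error at line ", i, ": attribute field lacks gene_id")
    }
  }
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  if (!length(ex)) stop("GTF contains no exon records")
  bt <- if ("gene_biotype" %in% names(S4Vectors::mcols(ex))) {
    ex$gene_biotype
  } else rep("other-ncRNA", length(ex))
  exdf <- data.frame(gene_id = ex$gene_id,
                     start = GenomicRanges::start(ex) - 1L,  # to 0-based
                     end = GenomicRanges::end(ex))
  first <- !duplicated(ex$gene_id)
  genes <- data.frame(gene_id = ex$gene_id[first],
                      biotype = bt[first],
                      chrom = as.character(GenomicRanges::seqnames(ex))[first],
                      strand = as.character(GenomicRanges::strand(ex))[first])
  gene_models(genes, exdf)
}

#' Write gene models as GTF
#'
#' Inverse of \code{\link{read_gtf}}: internal 0-based half-open exons are
#' written as 1-based closed GTF records (one \code{gene} and one
#' \code{exon} line per feature).
#'
#' @param models a \code{gene_models} object
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_gtf <- function(models, path) {
  g <- models$genes
  e <- models$exons
  gi <- match(e$gene_id, g$gene_id)
  attr_of <- function(id, bt) {
    sprintf("gene_id \"%s\"; gene_biotype \"%s\";", id, bt)
  }
  gene_ln <- sprintf("%s\tpirchkit\tgene\t%d\t%d\t.\t%s\t.\t%s",
                     g$chrom, g$start + 1L, g$end, g$strand,
                     attr_of(g$gene_id, g$biotype))
  exon_ln <- sprintf("%s\tpirchkit\texon\t%d\t%d\t.\t%s\t.\t%s",
                     g$chrom[gi], e$start + 1L, e$end, g$strand[gi],
                     attr_of(e$gene_id, g$biotype[gi]))
  writeLines(c(gene_ln, exon_ln), path)
  invisible(path)
}

#' Read a count table with sample metadata
#'
#' @param counts_path TSV with columns \code{gene_id}, \code{biotype}, then
#'   one integer column per sample
#' @param meta_path TSV with columns \code{sample}, \code{assay},
#'   \code{replicate}, \code{cell_type}
#' @return a \code{pirch_counts}
#' @export
read_counts <- function(counts_path, meta_path) {
  tab <- utils::read.delim(counts_path, check.names = FALSE)
  meta <- utils::read.delim(meta_path)
  cnt <- as.matrix(tab[, !(names(tab) %in% c("gene_id", "biotype")),
                       drop = FALSE])
  rownames(cnt) <- tab$gene_id
  neg <- which(cnt < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop("negative count at row ", neg[1, 1], " (gene ",
         tab$gene_id[neg[1, 1]], ")")
  }
  pirch_counts(cnt, meta,
               genes = data.frame(gene_id = tab$gene_id,
                                  biotype = tab$biotype))
}

#' Write a count table (+ metadata) to TSV
#' @param x a \code{pirch_counts}
#' @param counts_path,meta_path output paths
#' @return \code{counts_path}, invisibly
#' @export
write_counts <- function(x, counts_path, meta_path) {
  bt <- if (!is.null(x$genes)) x$genes$biotype else "other-ncRNA"
  tab <- data.frame(gene_id = rownames(x$counts), biotype = bt,
                    x$counts, check.names = FALSE)
  utils::write.table(tab, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$samples, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(counts_path)
}

#' Read a BED file of intervals (0-based half-open)
#'
#' Accepts BED3/BED6, plus the extra columns \code{height},
#' \code{fold_median}, \code{fold_input}, \code{p_value} written by
#' \code{\link{write_bed}} for peak sets.
#'
#' @param path BED path
#' @return data.frame with \code{chrom}, \code{start}, \code{end} and any
#'   further columns present
#' @export
read_bed <- function(path) {
  tab <- utils::read.delim(path, header = FALSE)
  base_cols <- c("chrom", "start", "end", "name", "score", "strand",
                 "height", "fold_median", "fold_input", "p_value")
  names(tab) <- base_cols[seq_len(ncol(tab))]
  if (any(tab$end <= tab$start)) {
    stop("empty interval at row ", which(tab$end <= tab$start)[1])
  }
  tab
}

#' Write intervals (or peaks) as BED6 + peak columns
#'
#' @param x data.frame with \code{chrom}, \code{start}, \code{end};
#'   optional \code{name}, \code{score}, \code{strand} and the peak columns
#'   \code{height}, \code{fold_median}, \code{fold_input}, \code{p_value}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_bed <- function(x, path) {
  out <- data.frame(chrom = x$chrom, start = x$start, end = x$end,
                    name = if ("name" %in% names(x)) x$name else ".",
                    score = if ("score" %in% names(x)) x$score else 0,
                    strand = if ("strand" %in% names(x)) x$strand else "+")
  for (cn in c("height", "fold_median", "fold_input", "p_value")) {
    if (cn %in% names(x)) out[[cn]] <- x[[cn]]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read icSHAPE-like structure score tracks
#'
#' TSV with columns \code{transcript_id}, \code{pos} (0-based),
#' \code{score} in \[0,1\] or NA. Positions absent from the file are
#' missing bases.
#'
#' @param path TSV path
#' @param lengths optional named vector of transcript lengths; defaults to
#'   max(pos)+1 per transcript
#' @return named list of numeric vectors with NAs at missing bases
#' @export
read_shape <- function(path, lengths = NULL) {
  tab <- utils::read.delim(path)
  bad <- which(!is.na(tab$score) & (tab$score < 0 | tab$score > 1))
  if (length(bad)) {
    stop("structure score outside [0,1] at row ", bad[1], " (",
         tab$score[bad[1]], ")")
  }
  txs <- unique(tab$transcript_id)
  out <- lapply(txs, function(tx) {
    sub <- tab[tab$transcript_id == tx, ]
    L <- if (!is.null(lengths)) lengths[[tx]] else max(sub$pos) + 1L
    v <- rep(NA_real_, L)
    v[sub$pos + 1L] <- sub$score
    v
  })
  names(out) <- txs
  out
}

#' Write structure score tracks to TSV
#' @param tracks named list of score vectors (NA = missing)
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_shape <- function(tracks, path) {
  tab <- do.call(rbind, lapply(names(tracks), function(tx) {
    data.frame(transcript_id = tx,
               pos = seq_along(tracks[[tx]]) - 1L,
               score = tracks[[tx]])
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read per-SNP biallelic counts
#'
#' TSV with columns \code{gene_id}, \code{pos}, \code{sample},
#' \code{assay}, \code{allele1}, \code{allele2}.
#'
#' @param path TSV path
#' @return data.frame in the long allele-counts layout
#' @export
read_allele <- function(path) {
  tab <- utils::read.delim(path)
  bad <- which(tab$allele1 < 0 | tab$allele2 < 0)
  if (length(bad)) stop("negative allele count at row ", bad[1])
  tab
}

#' Write per-SNP biallelic counts to TSV
#' @param counts long allele-counts data.frame
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_allele <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read transcript pileups from a bedGraph-like TSV
#'
#' Columns: \code{transcript_id}, \code{start}, \code{end} (0-based
#' half-open runs), \code{coverage}, \code{sample}.
#'
#' @param path TSV path
#' @param lengths optional named vector of transcript lengths
#' @return list of \code{pirch_pileup} objects, one per
#'   transcript x sample combination present
#' @export
read_pileup <- function(path, lengths = NULL) {
  tab <- utils::read.delim(path)
  if (any(tab$coverage < 0)) {
    stop("negative coverage at row ", which(tab$coverage < 0)[1])
  }
  keys <- unique(tab[, c("transcript_id", "sample")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- tab[tab$transcript_id == keys$transcript_id[i] &
                 tab$sample == keys$sample[i], ]
    L <- if (!is.null(lengths)) lengths[[keys$transcript_id[i]]]
         else max(sub$end)
    v <- numeric(L)
    for (r in seq_len(nrow(sub))) {
      v[(sub$start[r] + 1L):sub$end[r]] <- sub$coverage[r]
    }
    pirch_pileup(keys$transcript_id[i], v, keys$sample[i])
  })
  out
}

#' Write transcript pileups as run-length bedGraph-like TSV
#' @param pileups list of \code{pirch_pileup}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_pileup <- function(pileups, path) {
  tab <- do.call(rbind, lapply(pileups, function(p) {
    r <- rle(p$coverage)
    en <- cumsum(r$lengths)
    data.frame(transcript_id = p$transcript_id,
               start = c(0L, en[-length(en)]), end = en,
               coverage = r$values, sample = p$sample)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
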