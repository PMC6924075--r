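#' Default histone marks profiled by the pulldown panel
#'
#' Six histone modifications covering active promoter/enhancer methylation
#' (H3K4me1, H3K4me3), active acetylation (H3K27ac, H4K16ac) and repressive
#' methylation (H3K27me3, H3K9me3).
#' @return character vector of the six mark names
#' @export
default_marks <- function() {
  c("H3K4me1", "H3K4me3", "H3K27ac", "H3K27me3", "H3K9me3", "H4K16ac")
}

#' Chromatin-state templates for the six functional association states
#'
#' Per-mark mean log2 enrichment prototypes for the six functional states
#' used to classify chromatin-associated ncRNAs: active promoters carry
#' H3K4me3 + H3K27ac, heterochromatin carries H3K27me3 + H3K9me3, weak
#' promoters H3K4me3 alone, strong enhancers H3K4me1 + H3K27ac + H4K16ac,
#' bivalent genes both H3K4me3 and H3K27me3, and weak enhancers H3K4me1
#' alone. Marks present in a state get log2 effect \code{high}; all other
#' entries are 0. The qualitative patterns are fixed; the magnitude is a
#' generator parameter.
#'
#' @param marks mark names (columns)
#' @param high log2 enrichment assigned to a state's characteristic marks
#' @return numeric matrix, states x marks
#' @export
state_templates <- function(marks = default_marks(), high = 2) {
  pat <- list(
    "Active Promoter" = c("H3K4me3", "H3K27ac"),
    "Heterochromatin" = c("H3K27me3", "H3K9me3"),
    "Weak Promoter"   = "H3K4me3",
    "Strong Enhancer" = c("H3K4me1", "H3K27ac", "H4K16ac"),
    "Bivalent"        = c("H3K4me3", "H3K27me3"),
    "Weak Enhancer"   = "H3K4me1")
  tm <- matrix(0, length(pat), length(marks),
               dimnames = list(names(pat), marks))
  for (s in names(pat)) {
    hit <- intersect(pat[[s]], marks)
    tm[s, hit] <- high
  }
  tm
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults define the
#' study conditions emulated throughout the test-suite: 2000 expressed
#' genes of which 30% are non-coding, six histone marks in two replicates
#' plus an H3 pulldown and inputs, negative-binomial counts with
#' overdispersion 0.1 (variance = mean + dispersion * mean^2), library
#' sizes drawn uniformly between 0.8 and 1.2 million reads, and 40 enriched
#' ncRNAs planted per functional state (240 total, commensurate with the
#' few-hundred chromatin-enriched ncRNAs such experiments recover).
#'
#' @param n_genes number of genes
#' @param frac_ncrna fraction of genes given a non-coding biotype
#' @param marks histone-mark names (H3 and input are always added as assays)
#' @param n_replicates replicates per assay
#' @param library_size_range min/max total reads per sample
#' @param dispersion NB overdispersion (variance = mean + dispersion*mean^2)
#' @param templates states x marks matrix of planted mean log2 effects
#' @param noise_sd SD of per-gene Gaussian jitter added to template effects
#' @param n_per_state planted enriched ncRNAs per state
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of per-gene
#'   baseline expression
#' @param seed integer seed; the generator is bit-reproducible given it
#' @return object of class \code{sim_config}
#' @export
sim_config <- function(n_genes = 2000, frac_ncrna = 0.3,
                       marks = default_marks(), n_replicates = 2,
                       library_size_range = c(8e5, 1.2e6),
                       dispersion = 0.1,
                       templates = state_templates(marks),
                       noise_sd = 0.3, n_per_state = 40,
                       baseline_meanlog = log(100), baseline_sdlog = 1,
                       seed = 1L) {
  if (n_genes < 1 || n_replicates < 1) {
    stop("invalid config: n_genes and n_replicates must be positive")
  }
  if (frac_ncrna < 0 || frac_ncrna > 1) {
    stop("invalid config: frac_ncrna must lie in [0,1]")
  }
  if (dispersion <= 0) stop("invalid config: dispersion must be > 0")
  if (ncol(templates) != length(marks)) {
    stop("invalid config: template columns must match marks")
  }
  if (noise_sd < 0) stop("invalid config: noise_sd must be >= 0")
  structure(list(n_genes = n_genes, frac_ncrna = frac_ncrna, marks = marks,
                 n_replicates = n_replicates,
                 library_size_range = library_size_range,
                 dispersion = dispersion, templates = templates,
                 noise_sd = noise_sd, n_per_state = n_per_state,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a pulldown/input count matrix with planted enrichment
#'
#' Draws raw read counts for inputs, an H3 pulldown and one pulldown per
#' histone mark, \code{n_replicates} each. Planted chromatin-associated
#' ncRNAs receive their state template's per-mark log2 effects plus
#' Gaussian jitter; all other genes (and all input columns) have effect 0.
#' The H3 pulldown reflects overall chromatin association: planted genes
#' get the mean of their positive template entries. Counts are
#' NB(mean = baseline x column scale x 2^effect) with
#' variance = mean + dispersion * mean^2; each column is scaled so its
#' expected total equals the sampled library size.
#'
#' @param cfg a \code{sim_config}
#' @param cell_type label stored in the sample metadata
#' @return list with \code{counts} (a \code{pirch_counts}) and \code{truth}
#'   (list: \code{enriched} data.frame of gene_id/state, \code{effects}
#'   genes x marks matrix of true log2 effects, \code{mu} the expected-count
#'   matrix, \code{library_sizes})
#' @export
simulate_counts <- function(cfg, cell_type = "simESC") {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_genes
  gene_id <- sprintf("gene%05d", seq_len(n))
  n_nc <- round(cfg$frac_ncrna * n)
  biotype <- rep("coding", n)
  if (n_nc > 0) {
    nc_idx <- sample.int(n, n_nc)
    nc_split <- sample(c("lncRNA", "pre-miRNA", "snoRNA", "other-ncRNA"),
                       n_nc, replace = TRUE, prob = c(0.7, 0.1, 0.1, 0.1))
    biotype[nc_idx] <- nc_split
  }

  states <- rownames(cfg$templates)
  n_enr <- cfg$n_per_state * length(states)
  nc_all <- which(biotype != "coding")
  if (n_enr > length(nc_all)) {
    stop("not enough non-coding genes to plant ", n_enr, " enriched ncRNAs")
  }
  enr_idx <- sample(nc_all, n_enr)
  enr_state <- rep(states, each = cfg$n_per_state)

  effects <- matrix(0, n, length(cfg$marks),
                    dimnames = list(gene_id, cfg$marks))
  # H3 captures chromatin association regardless of mark identity
  h3_eff <- numeric(n)
  if (n_enr > 0) {
    effects[enr_idx, ] <- cfg$templates[enr_state, , drop = FALSE] +
      matrix(rnorm(n_enr * length(cfg$marks), 0, cfg$noise_sd), n_enr,
             length(cfg$marks))
    h3_eff[enr_idx] <- vapply(enr_state, function(s) {
      v <- cfg$templates[s, ]
      mean(v[v > 0])
    }, 0)
  }

  assays <- c("input", "H3", cfg$marks)
  meta <- data.frame(
    sample = paste(rep(assays, each = cfg$n_replicates),
                   rep(seq_len(cfg$n_replicates), length(assays)),
                   sep = "_rep"),
    assay = rep(assays, each = cfg$n_replicates),
    replicate = rep(seq_len(cfg$n_replicates), length(assays)),
    cell_type = cell_type)

  baseline <- exp(rnorm(n, cfg$baseline_meanlog, cfg$baseline_sdlog))
  lib <- runif(nrow(meta), cfg$library_size_range[1],
               cfg$library_size_range[2])
  mu <- matrix(0, n, nrow(meta), dimnames = list(gene_id, meta$sample))
  for (j in seq_len(nrow(meta))) {
    a <- meta$assay[j]
    eff <- if (a == "input") numeric(n)
           else if (a == "H3") h3_eff
           else effects[, a]
    m0 <- baseline * 2^eff
    mu[, j] <- m0 / sum(m0) * lib[j]
  }
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion),
                   n, ncol(mu), dimnames = dimnames(mu))

  obj <- pirch_counts(counts, meta,
                      genes = data.frame(gene_id = gene_id,
                                         biotype = biotype))
  truth <- list(enriched = data.frame(gene_id = gene_id[enr_idx],
                                      state = enr_state),
                effects = effects, h3_effect = h3_eff, mu = mu,
                library_sizes = lib)
  list(counts = obj, truth = truth)
}

#' Simulate a transcript pileup with planted peaks
#'
#' Background read starts are uniform along the transcript; each planted
#' peak adds reads centered within +/- width/2 of its summit so that local
#' coverage is about \code{amplitude} times the background density.
#'
#' @param length transcript length in bases
#' @param n_reads number of background reads
#' @param read_len read length in bases
#' @param peaks data.frame with columns \code{summit}, \code{width},
#'   \code{amplitude} (amplitude >= 1), or NULL for a null transcript
#' @param seed integer seed
#' @param transcript_id,sample identifiers stored on the pileup
#' @return list with \code{pileup} (a \code{pirch_pileup}), \code{truth}
#'   (the peak table), and \code{n_reads}/\code{read_len} actually used
#' @export
simulate_pileup <- function(length, n_reads, read_len, peaks = NULL,
                            seed = 1L, transcript_id = "tx1",
                            sample = NA_character_) {
  if (read_len > length) stop("read_len exceeds transcript length")
  set.seed(seed)
  if (!is.null(peaks) && nrow(peaks)) {
    if (any(peaks$summit < 0 | peaks$summit >= length)) {
      stop("peak summits must lie within [0, length)")
    }
    if (any(peaks$amplitude < 1)) stop("peak amplitude must be >= 1")
  }
  starts <- integer(0)
  if (n_reads > 0) {
    starts <- sample.int(length - read_len + 1L, n_reads,
                         replace = TRUE) - 1L
  }
  if (!is.null(peaks) && nrow(peaks) && n_reads > 0) {
    for (k in seq_len(nrow(peaks))) {
      p <- peaks[k, ]
      n_extra <- round((p$amplitude - 1) * n_reads * p$width / length)
      if (n_extra > 0) {
        ctr <- p$summit + sample.int(p$width + 1L, n_extra,
                                     replace = TRUE) -
          1L - floor(p$width / 2)
        st <- pmin(pmax(ctr - floor(read_len / 2), 0L),
                   length - read_len)
        starts <- c(starts, as.integer(st))
      }
    }
  }
  cov <- coverage_from_starts(starts, read_len, length)
  truth <- if (is.null(peaks)) {
    data.frame(summit = integer(), width = integer(), amplitude = numeric())
  } else peaks
  list(pileup = pirch_pileup(transcript_id, cov, sample), truth = truth,
       n_reads = length(starts), read_len = read_len)
}

#' Per-base coverage from read start positions
#'
#' @param starts 0-based read start positions
#' @param read_len read length
#' @param length transcript length
#' @return numeric coverage vector of \code{length} bases
#' @export
coverage_from_starts <- function(starts, read_len, length) {
  if (!base::length(starts)) return(numeric(length))
  up <- tabulate(starts + 1L, nbins = length)
  dn <- tabulate(pmin(starts + read_len, length) + 1L, nbins = length + 1L)
  cumsum(up - dn[seq_len(length)])
}

#' Simulate icSHAPE-like structure score tracks
#'
#' Per-base scores are Beta-distributed with mean \code{baseline_mean}
#' (concentration \code{conc}); bases 5-10 nt upstream (5' side) of each
#' true peak summit have their mean raised by \code{elevation}, emulating
#' the single-strandedness preference just upstream of chromatin-contact
#' sites. A fraction of bases is set missing (NA), as in real probing data.
#'
#' @param lengths named integer vector of transcript lengths
#' @param peak_truth data.frame with \code{transcript_id}, \code{summit}
#' @param baseline_mean background mean score, in (0,1)
#' @param elevation added to the mean inside upstream windows;
#'   \code{baseline_mean + elevation} must stay in (0,1)
#' @param missing_frac fraction of bases set to NA
#' @param conc Beta concentration (a+b); larger = less noisy scores
#' @param seed integer seed
#' @param window offsets (relative to the summit) whose mean is elevated
#' @return named list of numeric score vectors in \[0,1\] with NAs
#' @export
simulate_shape <- function(lengths, peak_truth = NULL, baseline_mean = 0.3,
                           elevation = 0, missing_frac = 0.1, conc = 10,
                           seed = 1L, window = -10:-5) {
  if (baseline_mean <= 0 || baseline_mean >= 1 ||
      baseline_mean + elevation <= 0 || baseline_mean + elevation >= 1) {
    stop("baseline_mean and baseline_mean + elevation must lie in (0,1)")
  }
  set.seed(seed)
  out <- lapply(names(lengths), function(tx) {
    L <- lengths[[tx]]
    mu <- rep(baseline_mean, L)
    if (!is.null(peak_truth)) {
      sm <- peak_truth$summit[peak_truth$transcript_id == tx]
      for (s in sm) {
        idx <- s + window + 1L
        idx <- idx[idx >= 1 & idx <= L]
        mu[idx] <- baseline_mean + elevation
      }
    }
    x <- rbeta(L, mu * conc, (1 - mu) * conc)
    if (missing_frac > 0) {
      x[runif(L) < missing_frac] <- NA_real_
    }
    x
  })
  names(out) <- names(lengths)
  out
}

#' Simulate per-SNP biallelic read counts
#'
#' Input samples draw their allele-1 read fraction from the expression skew
#' alone; pulldown samples from expression plus enrichment skew. SNPs are
#' spaced about one per hundred bases, as in an F1-hybrid transcriptome.
#'
#' @param n_genes number of genes
#' @param snps_per_gene SNPs per gene (>= 1)
#' @param expr_skew log2 allele1/allele2 expression ratio (scalar or one
#'   per gene)
#' @param enrich_skew log2 enrichment skew added in pulldown samples
#'   (scalar or per gene)
#' @param depth reads per SNP per sample
#' @param n_replicates samples per assay group
#' @param seed integer seed
#' @param alleles labels for the two alleles
#' @return list with \code{counts} (long data.frame: gene_id, pos, sample,
#'   assay, allele1, allele2) and \code{truth} (per-gene skews)
#' @export
simulate_allele <- function(n_genes, snps_per_gene, expr_skew = 0,
                            enrich_skew = 0, depth = 200,
                            n_replicates = 2, seed = 1L,
                            alleles = c("129S1", "CAST")) {
  if (snps_per_gene < 1) stop("snps_per_gene must be >= 1")
  if (depth <= 0) stop("depth must be > 0")
  set.seed(seed)
  expr_skew <- rep_len(expr_skew, n_genes)
  enrich_skew <- rep_len(enrich_skew, n_genes)
  gene_id <- sprintf("gene%05d", seq_len(n_genes))
  samples <- data.frame(
    sample = c(paste0("input_rep", seq_len(n_replicates)),
               paste0("pulldown_rep", seq_len(n_replicates))),
    assay = rep(c("input", "pulldown"), each = n_replicates))
  rows <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    pos <- seq_len(snps_per_gene) * 100L
    p_in <- 2^expr_skew[g] / (1 + 2^expr_skew[g])
    p_pd <- 2^(expr_skew[g] + enrich_skew[g]) /
      (1 + 2^(expr_skew[g] + enrich_skew[g]))
    tab <- expand.grid(pos = pos, sample = samples$sample,
                       stringsAsFactors = FALSE)
    tab$assay <- samples$assay[match(tab$sample, samples$sample)]
    p <- ifelse(tab$assay == "input", p_in, p_pd)
    tab$allele1 <- rbinom(nrow(tab), depth, p)
    tab$allele2 <- depth - tab$allele1
    tab$gene_id <- gene_id[g]
    rows[[g]] <- tab[, c("gene_id", "pos", "sample", "assay",
                         "allele1", "allele2")]
  }
  counts <- do.call(rbind, rows)
  attr(counts, "alleles") <- alleles
  list(counts = counts,
       truth = data.frame(gene_id = gene_id, expr_skew = expr_skew,
                          enrich_skew = enrich_skew))
}

#' Simulate a gene annotation with exon/intron structure
#'
#' Places non-overlapping genes along one chromosome, each with
#' \code{exons_per_gene} exons separated by introns. Deterministic for a
#' fixed seed; errors if the chromosome cannot hold the requested genes.
#'
#' @param n_genes number of genes
#' @param exons_per_gene exons per gene (>= 1)
#' @param chrom_len chromosome length in bases
#' @param seed integer seed
#' @param chrom chromosome name
#' @param frac_ncrna fraction of genes given biotype lncRNA
#' @param exon_len,intron_len mean exon and intron lengths
#' @return a \code{gene_models} object
#' @export
simulate_annotation <- function(n_genes, exons_per_gene, chrom_len,
                                seed = 1L, chrom = "chrSim",
                                frac_ncrna = 0.3, exon_len = 200,
                                intron_len = 500) {
  if (exons_per_gene < 1) stop("exons_per_gene must be >= 1")
  set.seed(seed)
  gid <- sprintf("gene%05d", seq_len(n_genes))
  glist <- vector("list", n_genes)
  span <- integer(n_genes)
  for (g in seq_len(n_genes)) {
    el <- pmax(20L, as.integer(round(rexp(exons_per_gene, 1 / exon_len))))
    il <- if (exons_per_gene > 1) {
      pmax(50L, as.integer(round(rexp(exons_per_gene - 1, 1 / intron_len))))
    } else integer(0)
    glist[[g]] <- list(el = el, il = il)
    span[g] <- sum(el) + sum(il)
  }
  gap <- 100L
  need <- sum(span) + gap * (n_genes + 1L)
  if (need > chrom_len) {
    stop("chrom_len ", chrom_len, " too small; need at least ", need)
  }
  slack <- chrom_len - need
  extra <- if (n_genes > 0) {
    as.integer(diff(sort(c(0, sample.int(slack + 1L, n_genes) - 1L))))
  } else integer(0)
  pos <- gap
  genes <- data.frame(gene_id = gid,
                      biotype = ifelse(runif(n_genes) < frac_ncrna,
                                       "lncRNA", "coding"),
                      chrom = chrom,
                      strand = sample(c("+", "-"), n_genes, replace = TRUE))
  ex <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    pos <- pos + extra[g]
    p <- pos
    st <- integer(0); en <- integer(0)
    for (k in seq_along(glist[[g]]$el)) {
      st <- c(st, p); en <- c(en, p + glist[[g]]$el[k])
      p <- p + glist[[g]]$el[k]
      if (k < length(glist[[g]]$el)) p <- p + glist[[g]]$il[k]
    }
    ex[[g]] <- data.frame(gene_id = gid[g], start = st, end = en)
    pos <- pos + span[g] + gap
  }
  gene_models(genes, do.call(rbind, ex))
}
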