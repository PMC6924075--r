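#' Default pipeline configuration
#'
#' Every analysis constant is surfaced as a named parameter with its
#' conventional default: 10 million target depth, alpha 0.05,
#' fivefold peak threshold with 5-base window and 2-base step, 1000
#' bootstrap resamples, +/- 200-base structure flank, +/- 100 kb
#' neighbor window, K range 2..10, top-k 100.
#'
#' @param seed single top-level seed; all stage seeds are derived from it
#' @param ... overrides for any default parameter
#' @return named list of parameters
#' @export
pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    target_depth = 1e7,
    alpha = 0.05,
    min_count = 10,
    peak_fold = 5,
    peak_window = 5,
    peak_step = 2,
    bootstrap_B = 1000,
    shape_flank = 200,
    neighbor_window = 1e5,
    k_range = 2:10,
    top_k = 100,
    marks = default_marks(),
    sim = list(n_genes = 2000, frac_ncrna = 0.3, n_replicates = 2,
               dispersion = 0.1, noise_sd = 0.3, n_per_state = 40))
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config parameter(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  if (!all(cfg$marks %in% c(default_marks(), "H3"))) {
    stop("unknown mark name(s): ",
         paste(setdiff(cfg$marks, c(default_marks(), "H3")),
               collapse = ", "))
  }
  cfg
}

# derived stage seeds: deterministic, well below 2^31
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 101L, enrich = 211L, classify = 307L,
               peaks = 401L, structure = 503L, allele = 601L,
               validate = 701L)
  (as.integer(seed) * 1009L + offsets[[stage]]) %% 1000003L
}

#' Run the simulate -> enrich -> classify -> allele pipeline
#'
#' Generates synthetic pulldown/input data, calls chromatin-enriched
#' ncRNAs per mark, classifies them into functional states, and runs the
#' allele-specific test, writing every table (plus a manifest recording
#' parameters, derived seeds and input hashes) into \code{out_dir}.
#' Rerunning with an identical config reproduces every file byte for
#' byte.
#'
#' @param config from \code{\link{pipeline_config}}
#' @param out_dir output directory (created if missing)
#' @return invisibly, a list of the in-memory stage results
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- vapply(c("simulate", "enrich", "classify", "allele"),
                  function(s) stage_seed(config$seed, s), numeric(1))

  cfg <- sim_config(n_genes = config$sim$n_genes,
                    frac_ncrna = config$sim$frac_ncrna,
                    marks = config$marks,
                    n_replicates = config$sim$n_replicates,
                    dispersion = config$sim$dispersion,
                    noise_sd = config$sim$noise_sd,
                    n_per_state = config$sim$n_per_state,
                    seed = seeds[["simulate"]])
  sim <- simulate_counts(cfg)
  counts_f <- file.path(out_dir, "counts.tsv")
  meta_f <- file.path(out_dir, "samples.tsv")
  write_counts(sim$counts, counts_f, meta_f)

  filtered <- filter_expressed(sim$counts, min_count = config$min_count)
  enrich <- pirch_enrich(filtered, marks = config$marks,
                         alpha = config$alpha)
  utils::write.table(enrich, file.path(out_dir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  mat <- enrichment_matrix(enrich)
  k <- select_k(mat, k_range = config$k_range,
                seed = seeds[["classify"]])
  states <- cluster_states(mat, k, seed = seeds[["classify"]])
  utils::write.table(states, file.path(out_dir, "states.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  al <- simulate_allele(50, 20, expr_skew = 0, enrich_skew = 0,
                        seed = seeds[["allele"]])
  allelic <- allelic_tests(al$counts)
  utils::write.table(allelic, file.path(out_dir, "allelic.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  files <- c("counts.tsv", "samples.tsv", "enrichment.tsv", "states.tsv",
             "allelic.tsv")
  manifest <- list(
    seed = config$seed,
    derived_seeds = as.list(seeds),
    parameters = config[setdiff(names(config), "seed")],
    selected_k = as.integer(k),
    files = as.list(tools::md5sum(file.path(out_dir, files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(sim = sim, enrich = enrich, matrix = mat, k = k,
                 states = states, allelic = allelic))
}
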