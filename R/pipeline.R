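#' Pipeline configuration
#'
#' One named list holding every analysis constant, with the study values
#' as defaults: the 100-read contact and gene thresholds, the +/-2.5 kb
#' extension, the 50% chromatin-state overlap rule, the effective genome
#' size and bait-chromosome exclusion used for RPKM normalization, the
#' 50-bp QC bin size, and the shuffle counts of the two resampling nulls
#' (10,000 for chromatin states, 100,000 for gene-list overlap).
#'
#' @param contact_read_threshold read threshold on intersected contacts.
#' @param gene_read_threshold read threshold for the contact-gene list.
#' @param extension_bp symmetric contact extension (assay resolution).
#' @param min_state_overlap_fraction chromatin-state assignment rule.
#' @param effective_genome_size mappable genome size (study value
#'   142,573,017; informational for synthetic genomes).
#' @param excluded_normalization_chroms chromosomes excluded from the RPKM
#'   library size (the bait-bearing chromosome).
#' @param bin_size_bp QC bin size.
#' @param n_shuffles_states shuffles for state enrichment.
#' @param n_shuffles_overlap shuffles for the gene-list overlap null.
#' @param rng_seed master seed; every stage derives its substream from it.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(contact_read_threshold = 100L,
                            gene_read_threshold = 100L,
                            extension_bp = 2500L,
                            min_state_overlap_fraction = 0.5,
                            effective_genome_size = 142573017,
                            excluded_normalization_chroms = "chrX",
                            bin_size_bp = 50L,
                            n_shuffles_states = 10000L,
                            n_shuffles_overlap = 100000L,
                            rng_seed = 1L) {
  stopifnot(contact_read_threshold > 0, gene_read_threshold > 0,
            extension_bp >= 0, min_state_overlap_fraction > 0,
            min_state_overlap_fraction <= 1, bin_size_bp > 0,
            n_shuffles_states > 0, n_shuffles_overlap > 0)
  structure(list(contact_read_threshold = contact_read_threshold,
                 gene_read_threshold = gene_read_threshold,
                 extension_bp = extension_bp,
                 min_state_overlap_fraction = min_state_overlap_fraction,
                 effective_genome_size = effective_genome_size,
                 excluded_normalization_chroms =
                   excluded_normalization_chroms,
                 bin_size_bp = bin_size_bp,
                 n_shuffles_states = n_shuffles_states,
                 n_shuffles_overlap = n_shuffles_overlap,
                 rng_seed = rng_seed),
            class = "pipeline_config")
}

#' Run the whole contact-analysis pipeline
#'
#' Composes every stage on one set of inputs: replicate intersection with
#' averaging, repeat filtering, read thresholding, extension and gene
#' assignment, contact-gene selection, differential contact and (when a
#' count matrix is supplied) differential expression analysis restricted
#' to the contact-gene list, genomic-feature and chromatin-state
#' annotation with a permutation enrichment null, the gene-list overlap
#' null, the viewpoint proximity check, and (when a signal track is
#' supplied) a metaprofile around the called contact sites. With
#' \code{simulate = TRUE} (the default when no inputs are given) the
#' synthetic study generator provides the inputs and the returned
#' manifest carries the truth for recovery checks.
#'
#' @param config a \code{pipeline_config}.
#' @param inputs list with tracks (named list of 4 contact tracks), genes,
#'   repeats, states, chrom_sizes, bait, and optionally counts/condition
#'   (expression) and signal; ignored when \code{simulate = TRUE}.
#' @param simulate generate inputs with
#'   \code{\link{simulate_4c_experiment}} seeded from the config.
#' @param out_dir optional directory; when given, stage outputs are
#'   written there as bedGraph/TSV.
#' @return list of class \code{pipeline_run}: stage outputs plus
#'   \code{manifest} (config snapshot, stage record counts, seeds and,
#'   for simulated runs, the truth manifest).
#' @export
run_pipeline <- function(config = pipeline_config(), inputs = NULL,
                         simulate = is.null(inputs), out_dir = NULL) {
  if (simulate) {
    sim <- simulate_4c_experiment(seed = config$rng_seed)
    inputs <- list(tracks = sim$tracks, genes = sim$genes,
                   repeats = sim$repeats, states = sim$states,
                   chrom_sizes = sim$spec$chromosomes,
                   bait = sim$spec$bait, counts = sim$counts,
                   condition = sim$condition, signal = sim$signal)
    truth <- sim$truth
  } else {
    if (is.null(inputs$tracks) || length(inputs$tracks) != 4L)
      stop("configuration error: inputs$tracks must hold 4 contact tracks")
    truth <- NULL
  }
  tr <- inputs$tracks
  cs <- inputs$chrom_sizes
  counts_log <- c()
  log_stage <- function(name, n) {
    counts_log[[name]] <<- n
  }
  # contact calling per condition: intersect -> repeat filter -> threshold
  called <- lapply(list(control = tr[c(1L, 2L)],
                        heat_shock = tr[c(3L, 4L)]),
                   function(pair)
                     call_contacts(pair[[1L]], pair[[2L]], inputs$repeats,
                                   config$contact_read_threshold))
  for (cond in names(called))
    for (st in names(called[[cond]]$stage_counts))
      log_stage(paste(cond, st, sep = "."),
                called[[cond]]$stage_counts[[st]])
  contacts <- called$control$thresholded
  # replicate QC on the control pair
  qc <- lapply(tr[c(1L, 2L)], binned_rpkm, chrom_sizes = cs,
               bin_size_bp = config$bin_size_bp,
               excluded_chroms = config$excluded_normalization_chroms)
  qc_cor <- c(pearson = replicate_correlation(qc[[1L]], qc[[2L]],
                                              "pearson"),
              spearman = replicate_correlation(qc[[1L]], qc[[2L]],
                                               "spearman"))
  # gene quantification on the intersected+filtered control contacts
  extended <- extend_contacts(contacts, config$extension_bp, cs)
  gene_counts <- assign_contacts_to_genes(extended, inputs$genes)
  contact_genes <- select_contact_genes(gene_counts,
                                        config$gene_read_threshold)
  log_stage("contact_genes", length(contact_genes))
  # differential contacts from the 4 per-replicate raw tracks
  cmat <- gene_contact_counts(tr, inputs$genes, cs, config$extension_bp)
  cond <- factor(c("control", "control", "heat_shock", "heat_shock"),
                 levels = c("control", "heat_shock"))
  diff_contact <- diff_counts(cmat, cond)
  # differential expression restricted to the contact-gene list
  diff_expr <- NULL
  if (!is.null(inputs$counts)) {
    keep <- intersect(contact_genes, rownames(inputs$counts))
    if (length(keep) >= 2L)
      diff_expr <- diff_counts(inputs$counts[keep, , drop = FALSE],
                               inputs$condition)
  }
  # annotation of the called contact sites
  feat_dist <- feature_distribution(contacts, inputs$genes, inputs$repeats)
  state_dist <- state_distribution(contacts, inputs$states,
                                   config$min_state_overlap_fraction)
  enrichment <- state_enrichment(contacts, inputs$states,
                                 scheme = "label_shuffle",
                                 n_shuffles = config$n_shuffles_states,
                                 min_overlap_fraction =
                                   config$min_state_overlap_fraction,
                                 seed = config$rng_seed + 11L)
  # gene-list overlap null over the annotated universe
  universe <- inputs$genes$genes$gene_id
  k <- max(length(contact_genes), 2L)
  onull <- overlap_null(universe,
                        reference = if (length(contact_genes) >= 2L)
                          contact_genes else universe[seq_len(k)],
                        k = k,
                        n_shuffles = config$n_shuffles_overlap,
                        seed = config$rng_seed + 12L)
  vp <- viewpoint_proximity(inputs$bait, inputs$genes, contact_genes)
  profile <- NULL
  if (!is.null(inputs$signal))
    profile <- metaprofile(inputs$signal, contacts, cs)
  run <- list(contacts = contacts, called = called,
              qc_correlation = qc_cor, gene_counts = gene_counts,
              contact_genes = contact_genes,
              contact_count_matrix = cmat,
              diff_contact = diff_contact, diff_expression = diff_expr,
              feature_distribution = feat_dist,
              state_distribution = state_dist,
              state_enrichment = enrichment,
              overlap_null = onull, viewpoint = vp, profile = profile,
              manifest = list(config = unclass(config),
                              stage_counts = unlist(counts_log),
                              seeds = c(master = config$rng_seed),
                              truth = truth))
  class(run) <- "pipeline_run"
  if (!is.null(out_dir)) .write_run(run, inputs, out_dir)
  run
}

# write the main stage outputs as plain-text files
.write_run <- function(run, inputs, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_bedgraph(run$contacts, file.path(out_dir, "contacts.bedGraph"),
                 name = "called_contacts")
  writeLines(run$contact_genes, file.path(out_dir, "contact_genes.txt"))
  utils::write.table(as.data.frame(run$diff_contact),
                     file.path(out_dir, "diff_contacts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(run$diff_expression))
    utils::write.table(as.data.frame(run$diff_expression),
                       file.path(out_dir, "diff_expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(run$state_distribution,
                     file.path(out_dir, "state_distribution.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(run$viewpoint,
                     file.path(out_dir, "viewpoint_proximity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("4C contact-analysis run\n")
  cat(sprintf("  called contacts: %d; contact genes: %d\n",
              nrow(x$contacts), length(x$contact_genes)))
  cat(sprintf("  replicate correlation (control): pearson %.3f, spearman %.3f\n",
              x$qc_correlation[["pearson"]],
              x$qc_correlation[["spearman"]]))
  cat(sprintf("  overlap null: %.5f +/- %.3f\n",
              x$overlap_null$mean, x$overlap_null$sd))
  invisible(x)
}
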