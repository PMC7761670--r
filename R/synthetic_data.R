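#' Miniature genome specification
#'
#' The default desk-size genome scales the fly setting: four 1-Mb arms
#' plus a 0.3-Mb bait-bearing chromosome whose distal end carries the
#' viewpoint (the rDNA cluster sits near the X-chromosome end in the real
#' genome). All pipeline thresholds (100 reads, +/-2.5 kb extension)
#' remain meaningful at this scale.
#'
#' @param chromosomes named vector of chromosome lengths (bp).
#' @param bait list with chrom, start, end for the viewpoint.
#' @param seed integer master seed.
#' @return list of class \code{genome_spec}.
#' @export
genome_spec <- function(chromosomes = c(chr2L = 1000000L, chr2R = 1000000L,
                                        chr3L = 1000000L, chr3R = 1000000L,
                                        chrX = 300000L),
                        bait = list(chrom = "chrX", start = 240000L,
                                    end = 300000L),
                        seed = 1L) {
  stopifnot(all(chromosomes > 0), bait$chrom %in% names(chromosomes),
            bait$start >= 0,
            bait$end <= chromosomes[[bait$chrom]],
            bait$end > bait$start)
  structure(list(chromosomes = chromosomes, bait = bait, seed = seed),
            class = "genome_spec")
}

# place n non-overlapping intervals of the given lengths uniformly in
# [lo, hi); broken-stick gap allocation keeps placement exchangeable
.place_disjoint <- function(n, lengths, lo, hi) {
  if (n == 0L) return(integer(0))
  slack <- (hi - lo) - sum(lengths)
  if (slack < 0) stop("capacity error: region too small for requested features")
  gaps <- c(stats::runif(n + 1L))
  gaps <- floor(gaps / sum(gaps) * slack)
  starts <- lo + cumsum(gaps[seq_len(n)]) +
    c(0L, cumsum(lengths[-n]))[seq_len(n)]
  as.integer(starts)
}

#' Simulate gene, repeat and chromatin-state annotation
#'
#' Generates non-overlapping gene bodies with strands, exons and UTRs,
#' repeat elements (placed independently, so some overlap genes), and a
#' 9-state segmentation tiling every chromosome without gaps, with segment
#' lengths drawn log-uniformly between 1 and 30 kb. On the bait
#' chromosome, genes are kept clear of the bait interval.
#'
#' @param spec a \code{genome_spec}.
#' @param n_genes,n_repeats numbers of genes and repeats.
#' @return list with \code{genes} (a \code{gene_set}), \code{repeats}
#'   (data.frame with family and repeat_class) and \code{states} (a
#'   \code{state_annotation}).
#' @export
simulate_annotation <- function(spec, n_genes = 200L, n_repeats = 150L) {
  stopifnot(n_genes >= 0L, n_repeats >= 0L)
  set.seed(spec$seed)
  chroms <- names(spec$chromosomes)
  lens <- as.numeric(spec$chromosomes)
  # usable span per chromosome (bait region excluded from gene placement)
  usable <- lens
  usable[chroms == spec$bait$chrom] <- spec$bait$start
  alloc <- floor(n_genes * usable / sum(usable))
  while (sum(alloc) < n_genes) {
    i <- which.max(usable / (alloc + 1))
    alloc[i] <- alloc[i] + 1L
  }
  genes_df <- NULL; feats <- NULL
  gi <- 0L
  for (ci in seq_along(chroms)) {
    ng <- alloc[ci]
    if (ng == 0L) next
    glen <- as.integer(round(stats::runif(ng, 2000, 8000)))
    starts <- .place_disjoint(ng, glen, 0L, as.integer(usable[ci]))
    strand <- sample(c("+", "-"), ng, replace = TRUE)
    ids <- sprintf("gene%04d", gi + seq_len(ng))
    gi <- gi + ng
    genes_df <- rbind(genes_df, data.frame(
      gene_id = ids, symbol = toupper(ids), chrom = chroms[ci],
      start = starts, end = starts + glen, strand = strand,
      stringsAsFactors = FALSE))
    for (k in seq_len(ng)) {
      nex <- sample(2:5, 1L)
      max_el <- max(150L, as.integer(floor(glen[k] * 0.6 / nex)))
      elen <- as.integer(round(stats::runif(nex, 150, min(600L, max_el))))
      es <- .place_disjoint(nex, elen, starts[k], starts[k] + glen[k])
      ex <- data.frame(gene_id = ids[k], type = "exon", chrom = chroms[ci],
                       start = es, end = es + elen,
                       stringsAsFactors = FALSE)
      # 5' UTR at the transcription start, 3' UTR at the end
      first <- if (strand[k] == "+") 1L else nex
      last <- if (strand[k] == "+") nex else 1L
      u5len <- min(100L, ex$end[first] - ex$start[first] - 1L)
      u3len <- min(100L, ex$end[last] - ex$start[last] - 1L)
      u5 <- if (strand[k] == "+")
        c(ex$start[first], ex$start[first] + u5len)
      else c(ex$end[first] - u5len, ex$end[first])
      u3 <- if (strand[k] == "+")
        c(ex$end[last] - u3len, ex$end[last])
      else c(ex$start[last], ex$start[last] + u3len)
      feats <- rbind(feats, ex,
                     data.frame(gene_id = ids[k],
                                type = c("utr5", "utr3"),
                                chrom = chroms[ci],
                                start = c(u5[1L], u3[1L]),
                                end = c(u5[2L], u3[2L]),
                                stringsAsFactors = FALSE))
    }
  }
  genes <- gene_set(if (is.null(genes_df))
    data.frame(gene_id = character(), symbol = character(),
               chrom = character(), start = integer(), end = integer(),
               strand = character(), stringsAsFactors = FALSE)
    else genes_df, feats)
  # repeats: uniform placement, may overlap genes and each other
  repeats <- NULL
  if (n_repeats > 0L) {
    rc <- sample(chroms, n_repeats, replace = TRUE,
                 prob = lens / sum(lens))
    rlen <- as.integer(round(exp(stats::runif(n_repeats, log(500),
                                              log(3000)))))
    rstart <- as.integer(floor(stats::runif(n_repeats) *
                                 (lens[match(rc, chroms)] - rlen)))
    fams <- c(roo = "LTR", copia = "LTR", gypsy = "LTR",
              jockey = "LINE", Doc = "LINE", F_element = "LINE",
              DNAREP1 = "SINE", low_comp = "low_complexity",
              INE1 = "other")
    fam <- sample(names(fams), n_repeats, replace = TRUE)
    repeats <- data.frame(chrom = rc, start = rstart, end = rstart + rlen,
                          family = fam, repeat_class = unname(fams[fam]),
                          stringsAsFactors = FALSE)
    repeats <- repeats[order(repeats$chrom, repeats$start), , drop = FALSE]
    rownames(repeats) <- NULL
  }
  # 9-state tiling, log-uniform segment lengths 1-30 kb, no gaps
  st <- NULL
  for (ci in seq_along(chroms)) {
    pos <- 0L; ss <- integer(0); se <- integer(0)
    while (pos < lens[ci]) {
      sl <- as.integer(round(exp(stats::runif(1L, log(1000), log(30000)))))
      ss <- c(ss, pos); se <- c(se, min(pos + sl, lens[ci]))
      pos <- pos + sl
    }
    st <- rbind(st, data.frame(chrom = chroms[ci], start = ss,
                               end = as.integer(se),
                               state = sample.int(9L, length(ss),
                                                  replace = TRUE),
                               stringsAsFactors = FALSE))
  }
  list(genes = genes, repeats = repeats, states = state_annotation(st))
}

#' Default contact-simulation parameters
#'
#' The study-condition defaults: numbers of planted contact genes per
#' category (retained / lost / gained under heat shock, plus genes with a
#' +/-2 log2 fold change in contact intensity), per-site negative-binomial
#' mean and dispersion, the lognormal latent factor inducing replicate
#' correlation, repeat-contained decoy sites, and genome-wide sub-threshold
#' background sites.
#'
#' @return named list of parameters.
#' @export
contact_sim_params <- function() {
  list(n_retained = 60L, n_lost = 20L, n_gained = 20L,
       n_up = 20L, n_down = 20L,
       site_mean = 200, dispersion = 0.02, latent_sdlog = 0.25,
       near_zero_mean = 2, de_log2fc = 2,
       n_repeat_decoys = 15L, decoy_mean = 300,
       n_background = 300L, background_mean = 10,
       site_width = 150L, max_sites_per_gene = 3L,
       planted_state = 1L, planted_state_fraction = 0.7)
}

# NB draw with variance mu + alpha * mu^2; alpha = 0 degenerates to Poisson
.rnb <- function(n, mu, alpha) {
  if (any(mu <= 0)) stop("parameter error: NB mean must be positive")
  if (any(alpha < 0)) stop("parameter error: NB dispersion must be >= 0")
  if (alpha == 0) stats::rpois(n, mu)
  else stats::rnbinom(n, size = 1 / alpha, mu = mu)
}

#' Simulate replicate-correlated 4C contact tracks
#'
#' Plants 1-3 contact sites (~150 bp) within +/-2.5 kb of each chosen
#' contact gene's body. Per site, a lognormal latent factor shared by all
#' four samples scales the negative-binomial mean (this induces the
#' replicate concordance seen in real 4C); per-sample read counts are then
#' drawn independently. Condition structure: "retained" genes keep the
#' same mean in both conditions, "gained" sites have near-zero control
#' means, "lost" sites near-zero heat-shock means, and "up"/"down" genes
#' change by +/- \code{de_log2fc} under heat shock. Decoy sites planted
#' wholly inside repeat elements and genome-wide sub-threshold background
#' sites are added and recorded in the truth manifest.
#'
#' @param spec a \code{genome_spec}.
#' @param genes a \code{gene_set}.
#' @param repeats repeat data.frame.
#' @param params list as from \code{\link{contact_sim_params}}.
#' @return list with \code{tracks} (named list control_rep1/2,
#'   heat_shock_rep1/2 of \code{contact_track}s) and \code{truth} (the
#'   manifest: contact_genes, sites, repeat_decoys, background, seeds).
#' @export
simulate_contact_tracks <- function(spec, genes, repeats,
                                    params = contact_sim_params()) {
  p <- utils::modifyList(contact_sim_params(), params)
  if (p$site_mean <= 0 || p$decoy_mean <= 0 || p$background_mean <= 0)
    stop("parameter error: NB mean must be positive")
  if (p$dispersion < 0)
    stop("parameter error: NB dispersion must be >= 0")
  set.seed(spec$seed + 1L)
  g <- genes$genes
  categories <- c(rep("retained", p$n_retained), rep("lost", p$n_lost),
                  rep("gained", p$n_gained), rep("up", p$n_up),
                  rep("down", p$n_down))
  n_contact <- length(categories)
  if (n_contact > nrow(g))
    stop("capacity error: more contact genes requested than genes available")
  pick <- sample.int(nrow(g), n_contact)
  lens <- spec$chromosomes
  taken <- NULL   # occupied site intervals, to keep tracks non-overlapping
  place_site <- function(chrom, lo, hi, width, forbid_repeats = TRUE) {
    for (try in 1:200) {
      s <- as.integer(floor(stats::runif(1L, lo, hi - width)))
      cand <- c(s, s + width)
      if (forbid_repeats && !is.null(repeats)) {
        rr <- repeats[repeats$chrom == chrom, , drop = FALSE]
        if (any(cand[1L] >= rr$start & cand[2L] <= rr$end)) next
      }
      tt <- if (is.null(taken)) NULL
            else taken[taken$chrom == chrom, , drop = FALSE]
      if (!is.null(tt) && nrow(tt) > 0L &&
          any(cand[1L] < tt$end & cand[2L] > tt$start)) next
      return(cand)
    }
    NULL
  }
  sites <- NULL
  for (i in seq_len(n_contact)) {
    gi <- pick[i]
    nsite <- sample.int(p$max_sites_per_gene, 1L)
    ch <- g$chrom[gi]
    lo <- max(0L, g$start[gi] - 2500L)
    hi <- min(as.integer(lens[[ch]]), g$end[gi] + 2500L)
    for (k in seq_len(nsite)) {
      pos <- place_site(ch, lo, hi, p$site_width)
      if (is.null(pos)) next
      m <- switch(categories[i],
                  retained = c(p$site_mean, p$site_mean),
                  lost = c(p$site_mean, p$near_zero_mean),
                  gained = c(p$near_zero_mean, p$site_mean),
                  up = c(p$site_mean, p$site_mean * 2^p$de_log2fc),
                  down = c(p$site_mean, p$site_mean * 2^(-p$de_log2fc)))
      row <- data.frame(chrom = ch, start = pos[1L], end = pos[2L],
                        gene_id = g$gene_id[gi], category = categories[i],
                        control_mean = m[1L], heat_shock_mean = m[2L],
                        stringsAsFactors = FALSE)
      sites <- rbind(sites, row)
      taken <- rbind(taken, row[, c("chrom", "start", "end")])
    }
  }
  # repeat-contained decoys: sites fully inside repeat elements
  decoys <- NULL
  big <- repeats[repeats$end - repeats$start >= p$site_width + 2L, ,
                 drop = FALSE]
  if (p$n_repeat_decoys > 0L && nrow(big)) {
    for (i in seq_len(p$n_repeat_decoys)) {
      r <- big[sample.int(nrow(big), 1L), ]
      pos <- place_site(r$chrom, r$start, r$end, p$site_width,
                        forbid_repeats = FALSE)
      if (is.null(pos) || pos[1L] < r$start || pos[2L] > r$end) next
      row <- data.frame(chrom = r$chrom, start = pos[1L], end = pos[2L],
                        gene_id = NA_character_, category = "repeat_decoy",
                        control_mean = p$decoy_mean,
                        heat_shock_mean = p$decoy_mean,
                        stringsAsFactors = FALSE)
      decoys <- rbind(decoys, row)
      taken <- rbind(taken, row[, c("chrom", "start", "end")])
    }
  }
  # genome-wide sub-threshold background
  background <- NULL
  chroms <- names(lens)
  for (i in seq_len(p$n_background)) {
    ch <- sample(chroms, 1L, prob = as.numeric(lens) / sum(lens))
    pos <- place_site(ch, 0L, as.integer(lens[[ch]]), p$site_width,
                      forbid_repeats = FALSE)
    if (is.null(pos)) next
    row <- data.frame(chrom = ch, start = pos[1L], end = pos[2L],
                      gene_id = NA_character_, category = "background",
                      control_mean = p$background_mean,
                      heat_shock_mean = p$background_mean,
                      stringsAsFactors = FALSE)
    background <- rbind(background, row)
    taken <- rbind(taken, row[, c("chrom", "start", "end")])
  }
  all_sites <- rbind(sites, decoys, background)
  ns <- nrow(all_sites)
  latent <- stats::rlnorm(ns, meanlog = -p$latent_sdlog^2 / 2,
                          sdlog = p$latent_sdlog)
  draw <- function(mu) vapply(seq_len(ns), function(i)
    as.numeric(.rnb(1L, max(mu[i], 1e-9), p$dispersion)), numeric(1))
  mk_track <- function(counts, sid, cond) {
    keep <- counts > 0
    contact_track(all_sites$chrom[keep], all_sites$start[keep],
                  all_sites$end[keep], counts[keep],
                  sample_id = sid, condition = cond)
  }
  mu_c <- all_sites$control_mean * latent
  mu_h <- all_sites$heat_shock_mean * latent
  tracks <- list(
    control_rep1 = mk_track(draw(mu_c), "control_rep1", "control"),
    control_rep2 = mk_track(draw(mu_c), "control_rep2", "control"),
    heat_shock_rep1 = mk_track(draw(mu_h), "heat_shock_rep1", "heat_shock"),
    heat_shock_rep2 = mk_track(draw(mu_h), "heat_shock_rep2", "heat_shock"))
  contact_genes <- unique(sites[, c("gene_id", "category")])
  truth <- list(contact_genes = contact_genes,
                sites = sites, repeat_decoys = decoys,
                background = background, params = p,
                seeds = c(annotation = spec$seed,
                          contacts = spec$seed + 1L))
  list(tracks = tracks, truth = truth)
}

#' Simulate an RNA-seq style expression count matrix
#'
#' Negative-binomial counts with gene-level base means, per-sample library
#' size factors, and planted condition effects for a subset of genes.
#'
#' @param genes a \code{gene_set}.
#' @param de_spec data.frame (gene_id, log2fc) of planted effects; other
#'   genes get log2fc 0.
#' @param n_reps replicates per condition (default 2).
#' @param library_sizes relative per-sample library sizes, length
#'   2 * n_reps (default all 1).
#' @param dispersion NB dispersion alpha (default 0.05).
#' @param base_mean_range log-uniform range of gene base means.
#' @param seed integer seed.
#' @return list with \code{counts} (genes x samples integer matrix),
#'   \code{condition} factor, and \code{truth} (gene_id, log2fc).
#' @export
simulate_expression_counts <- function(genes, de_spec = NULL, n_reps = 2L,
                                       library_sizes = NULL,
                                       dispersion = 0.05,
                                       base_mean_range = c(50, 2000),
                                       seed = 1L) {
  if (dispersion < 0) stop("parameter error: NB dispersion must be >= 0")
  set.seed(seed)
  g <- genes$genes
  ngene <- nrow(g)
  nsamp <- 2L * n_reps
  if (is.null(library_sizes)) library_sizes <- rep(1, nsamp)
  stopifnot(length(library_sizes) == nsamp, all(library_sizes > 0))
  condition <- factor(rep(c("control", "heat_shock"), each = n_reps),
                      levels = c("control", "heat_shock"))
  base <- exp(stats::runif(ngene, log(base_mean_range[1L]),
                           log(base_mean_range[2L])))
  lfc <- stats::setNames(rep(0, ngene), g$gene_id)
  if (!is.null(de_spec) && nrow(de_spec)) {
    if (!all(de_spec$gene_id %in% g$gene_id))
      stop("validation error: de_spec references unknown gene_id")
    lfc[de_spec$gene_id] <- de_spec$log2fc
  }
  counts <- matrix(0L, ngene, nsamp,
                   dimnames = list(g$gene_id,
                                   paste0(condition, "_rep",
                                          rep(seq_len(n_reps), 2L))))
  for (j in seq_len(nsamp)) {
    mu <- base * library_sizes[j] *
      (if (condition[j] == "heat_shock") 2^lfc else 1)
    counts[, j] <- .rnb(ngene, mu, dispersion)
  }
  storage.mode(counts) <- "integer"
  list(counts = counts, condition = condition,
       truth = data.frame(gene_id = g$gene_id, log2fc = unname(lfc),
                          base_mean = base, stringsAsFactors = FALSE))
}

#' Simulate a deterministic signal track
#'
#' Constant baseline over every chromosome plus a rectangular bump of the
#' stated width and height centred at each provided site midpoint;
#' overlapping bumps add.
#'
#' @param spec a \code{genome_spec}.
#' @param sites data.frame of site intervals (may be empty).
#' @param baseline,height,width bump shape parameters.
#' @return a signal \code{contact_track}.
#' @export
simulate_signal_track <- function(spec, sites = NULL, baseline = 1,
                                  height = 10, width = 500) {
  lens <- spec$chromosomes
  base_gr <- GenomicRanges::GRanges(names(lens),
                                    IRanges::IRanges(1L, as.integer(lens)))
  covs <- GenomicRanges::coverage(base_gr, weight = baseline)
  if (!is.null(sites) && nrow(sites)) {
    mid <- floor((sites$start + sites$end) / 2)
    s <- pmax(0L, as.integer(mid - floor(width / 2)))
    e <- pmin(as.integer(lens[sites$chrom]), as.integer(s + width))
    bump_gr <- GenomicRanges::GRanges(
      sites$chrom, IRanges::IRanges(s + 1L, e),
      seqlengths = stats::setNames(as.integer(lens), names(lens)))
    covs <- covs + GenomicRanges::coverage(bump_gr, weight = height)
  }
  recs <- NULL
  for (ch in names(covs)) {
    r <- covs[[ch]]
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- c(0L, ends[-length(ends)])
    recs <- rbind(recs, data.frame(chrom = ch, start = starts, end = ends,
                                   value = S4Vectors::runValue(r),
                                   stringsAsFactors = FALSE))
  }
  recs <- recs[recs$end > recs$start, , drop = FALSE]
  contact_track(recs$chrom, recs$start, recs$end, recs$value,
                allow_negative = TRUE)
}

#' Plant chromatin-state enrichment at contact sites
#'
#' Relabels the segmentation over each site's interval to a planted state:
#' a stated fraction of sites get the enriched state, the rest a state
#' drawn uniformly from the remaining labels. Segments are split at site
#' boundaries so the annotation keeps tiling the genome.
#'
#' @param states a \code{state_annotation}.
#' @param sites data.frame of site intervals.
#' @param state enriched state label (default 1).
#' @param fraction fraction of sites planted with \code{state}
#'   (default 0.7).
#' @param seed integer seed.
#' @return list with \code{states} (modified annotation) and
#'   \code{planted} (per-site planted state labels).
#' @export
plant_state_enrichment <- function(states, sites, state = 1L,
                                   fraction = 0.7, seed = 1L) {
  set.seed(seed)
  ns <- nrow(sites)
  planted <- integer(ns)
  n_enr <- round(fraction * ns)
  enr <- sample.int(ns, n_enr)
  planted[enr] <- state
  planted[-enr] <- sample(setdiff(1:9, state), ns - n_enr, replace = TRUE)
  df <- as.data.frame(states)
  for (i in seq_len(ns)) {
    ch <- sites$chrom[i]; s <- sites$start[i]; e <- sites$end[i]
    sel <- df$chrom == ch & df$end > s & df$start < e
    if (!any(sel)) next
    seg <- df[sel, , drop = FALSE]
    pre <- seg[seg$start < s, , drop = FALSE]
    if (nrow(pre)) pre$end <- pmin(pre$end, s)
    post <- seg[seg$end > e, , drop = FALSE]
    if (nrow(post)) post$start <- pmax(post$start, e)
    mids <- data.frame(chrom = ch, start = max(s, min(seg$start)),
                       end = min(e, max(seg$end)), state = planted[i],
                       stringsAsFactors = FALSE)
    df <- rbind(df[!sel, , drop = FALSE], pre, mids, post)
  }
  list(states = state_annotation(df), planted = planted)
}

#' Simulate the full study: annotation, 4C tracks, expression, signal
#'
#' One call generating everything the pipeline consumes under the default
#' study conditions, plus the truth manifest for recovery tests.
#'
#' @param seed integer master seed.
#' @param n_genes,n_repeats annotation sizes.
#' @param params contact-simulation parameter overrides (see
#'   \code{\link{contact_sim_params}}).
#' @param n_de_expression number of genes with planted expression changes
#'   (half up, half down, |log2fc| = 2), drawn from the contact genes.
#' @return list with spec, genes, repeats, states, tracks, counts,
#'   condition, signal and \code{truth} (the manifest).
#' @export
simulate_4c_experiment <- function(seed = 1L, n_genes = 200L,
                                   n_repeats = 150L, params = list(),
                                   n_de_expression = 20L) {
  spec <- genome_spec(seed = seed)
  ann <- simulate_annotation(spec, n_genes, n_repeats)
  sim <- simulate_contact_tracks(spec, ann$genes, ann$repeats, params)
  p <- sim$truth$params
  planted <- plant_state_enrichment(ann$states, sim$truth$sites,
                                    state = p$planted_state,
                                    fraction = p$planted_state_fraction,
                                    seed = seed + 2L)
  sim$truth$planted_states <- planted$planted
  sim$truth$enriched_states <- stats::setNames(
    p$planted_state_fraction, as.character(p$planted_state))
  # planted expression changes among contact genes
  cg <- sim$truth$contact_genes$gene_id
  n_de <- min(n_de_expression, length(cg))
  de_genes <- sample(cg, n_de)
  de_spec <- data.frame(gene_id = de_genes,
                        log2fc = rep(c(2, -2), length.out = n_de),
                        stringsAsFactors = FALSE)
  expr <- simulate_expression_counts(ann$genes, de_spec, n_reps = 2L,
                                     dispersion = 0.05,
                                     seed = seed + 3L)
  signal <- simulate_signal_track(spec, sim$truth$sites)
  list(spec = spec, genes = ann$genes, repeats = ann$repeats,
       states = planted$states, tracks = sim$tracks,
       counts = expr$counts, condition = expr$condition,
       signal = signal,
       truth = c(sim$truth, list(de_genes = de_spec,
                                 expression_truth = expr$truth)))
}
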