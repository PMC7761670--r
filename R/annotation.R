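#' Genomic feature class of contact sites
#'
#' Classifies each site by its midpoint with a fixed priority order:
#' promoter > TTS > utr5 > utr3 > exon > intron > repeat_LTR >
#' repeat_other > intergenic. Promoters are strand-aware windows
#' [TSS-1000, TSS+100) and TTS windows [TES-100, TES+1000) in the
#' direction of transcription. Exactly one class per site.
#'
#' @param sites data.frame of intervals (chrom, start, end).
#' @param genes a \code{gene_set}.
#' @param repeats repeat data.frame with chrom, start, end and a
#'   \code{repeat_class} column ("LTR" vs anything else), or NULL.
#' @param promoter_window,tts_window 2-vectors of offsets (bp) around the
#'   TSS / TES in transcription direction.
#' @return factor of feature classes, one per site.
#' @export
annotate_feature <- function(sites, genes, repeats = NULL,
                             promoter_window = c(-1000L, 100L),
                             tts_window = c(-100L, 1000L)) {
  classes <- c("promoter", "TTS", "utr5", "utr3", "exon", "intron",
               "repeat_LTR", "repeat_other", "intergenic")
  n <- nrow(sites)
  mid <- floor((sites$start + sites$end) / 2)
  midgr <- GenomicRanges::GRanges(sites$chrom,
                                  IRanges::IRanges(mid + 1L, mid + 1L))
  g <- genes$genes
  plus <- g$strand == "+"
  # strand-aware windows in genomic coordinates (0-based half-open)
  win <- function(anchor, w, plus) {
    s <- ifelse(plus, anchor + w[1L], anchor - w[2L])
    data.frame(chrom = g$chrom, start = pmax(0L, as.integer(s)),
               end = as.integer(s + (w[2L] - w[1L])))
  }
  tss <- ifelse(plus, g$start, g$end)
  tes <- ifelse(plus, g$end, g$start)
  prom <- win(tss, promoter_window, plus)
  tts <- win(tes, tts_window, plus)
  feat <- genes$features
  region_of <- function(df) {
    if (is.null(df) || nrow(df) == 0L) return(rep(FALSE, n))
    hits <- GenomicRanges::findOverlaps(midgr, .ivl_gr(df))
    seq_len(n) %in% S4Vectors::queryHits(hits)
  }
  in_prom <- region_of(prom)
  in_tts <- region_of(tts)
  in_u5 <- region_of(feat[feat$type == "utr5", , drop = FALSE])
  in_u3 <- region_of(feat[feat$type == "utr3", , drop = FALSE])
  in_exon <- region_of(feat[feat$type == "exon", , drop = FALSE])
  in_body <- region_of(g)
  has_class <- !is.null(repeats) && nrow(repeats) > 0 &&
    "repeat_class" %in% names(repeats)
  in_ltr <- if (has_class)
    region_of(repeats[repeats$repeat_class == "LTR", , drop = FALSE])
  else rep(FALSE, n)
  in_rep <- if (is.null(repeats)) rep(FALSE, n) else region_of(repeats)
  cls <- rep("intergenic", n)
  cls[in_rep] <- "repeat_other"
  cls[in_ltr] <- "repeat_LTR"
  cls[in_body] <- "intron"
  cls[in_exon] <- "exon"
  cls[in_u3] <- "utr3"
  cls[in_u5] <- "utr5"
  cls[in_tts] <- "TTS"
  cls[in_prom] <- "promoter"
  factor(cls, levels = classes)
}

#' Assign contact sites to chromatin states
#'
#' A site is assigned to a state iff at least \code{min_overlap_fraction}
#' of its length lies within segments of that state (overlap accumulates
#' across segments of the same state). When several states qualify
#' (possible only at fractions <= 0.5) the state with the larger overlap
#' wins, with ties going to the lower state label; otherwise the site is
#' unassigned (NA).
#'
#' @param sites data.frame of intervals.
#' @param states a \code{state_annotation}.
#' @param min_overlap_fraction required overlap fraction in (0, 1]
#'   (default 0.5, as with \code{bedtools intersect -f 0.5}).
#' @return integer vector of state labels (NA = unassigned).
#' @export
assign_chromatin_state <- function(sites, states,
                                   min_overlap_fraction = 0.5) {
  stopifnot(min_overlap_fraction > 0, min_overlap_fraction <= 1)
  n <- nrow(sites)
  if (n == 0L || nrow(states) == 0L) return(rep(NA_integer_, n))
  hits <- GenomicRanges::findOverlaps(.ivl_gr(sites), .ivl_gr(states))
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  ovl <- pmin(sites$end[q], states$end[s]) - pmax(sites$start[q],
                                                  states$start[s])
  .state_assign_core(q, states$state[s], ovl,
                     sites$end - sites$start, n, min_overlap_fraction)
}

# shared aggregation: per-site per-state overlap sums -> assignment.
# q: site index per overlap pair; lab: state label per pair; ovl: overlap
# width per pair; width: site widths; n: number of sites.
.state_assign_core <- function(q, lab, ovl, width, n,
                               min_overlap_fraction) {
  out <- rep(NA_integer_, n)
  if (length(q) == 0L) return(out)
  key <- q * 16L + lab   # states are 1..9 < 16
  agg <- rowsum(ovl, key, reorder = FALSE)
  k <- as.integer(rownames(agg))
  qa <- k %/% 16L; st <- k %% 16L; w <- as.numeric(agg)
  ok <- w >= min_overlap_fraction * width[qa]
  qa <- qa[ok]; st <- st[ok]; w <- w[ok]
  if (length(qa)) {
    o <- order(qa, -w, st)   # per site: max overlap, ties to lower label
    first <- !duplicated(qa[o])
    out[qa[o][first]] <- st[o][first]
  }
  out
}

#' Distribution of contact sites over chromatin states
#'
#' @param sites data.frame of intervals.
#' @param states a \code{state_annotation}.
#' @param min_overlap_fraction see \code{\link{assign_chromatin_state}}.
#' @return data.frame with state (1..9), count, proportion (over assigned
#'   sites); attr "n_sites" and "n_unassigned".
#' @export
state_distribution <- function(sites, states, min_overlap_fraction = 0.5) {
  st <- assign_chromatin_state(sites, states, min_overlap_fraction)
  counts <- vapply(1:9, function(k) sum(st == k, na.rm = TRUE), integer(1))
  total <- sum(counts)
  out <- data.frame(state = 1:9, count = counts,
                    proportion = if (total > 0) counts / total
                                 else rep(NA_real_, 9L))
  attr(out, "n_sites") <- length(st)
  attr(out, "n_unassigned") <- sum(is.na(st))
  out
}

#' Distribution of contact sites over genomic feature classes
#'
#' @inheritParams annotate_feature
#' @return data.frame with class, count, proportion.
#' @export
feature_distribution <- function(sites, genes, repeats = NULL, ...) {
  f <- annotate_feature(sites, genes, repeats, ...)
  tab <- table(f)
  data.frame(class = names(tab), count = as.integer(tab),
             proportion = if (length(f)) as.integer(tab) / length(f)
                          else NA_real_,
             stringsAsFactors = FALSE)
}

#' Per-chromosome counts of a gene list
#'
#' @param gene_list character vector of gene_ids.
#' @param genes a \code{gene_set}.
#' @return data.frame (chrom, count), all chromosomes of the gene set.
#' @export
per_chromosome_counts <- function(gene_list, genes) {
  g <- genes$genes
  chroms <- sort(unique(g$chrom))
  sel <- g$chrom[g$gene_id %in% gene_list]
  data.frame(chrom = chroms,
             count = vapply(chroms, function(ch) sum(sel == ch), integer(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
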