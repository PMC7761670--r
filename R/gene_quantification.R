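#' Assign contact reads to genes
#'
#' Each contact record contributes its full read value to every gene whose
#' body overlaps the (extended) record by at least one base — multi-overlap
#' counting, matching featureCounts with \code{-t gene -M} and symmetric
#' read extension. Records overlapping no gene contribute nothing.
#'
#' @param contacts data.frame of (possibly extended, possibly overlapping)
#'   contact intervals with a \code{value} column.
#' @param genes a \code{gene_set}.
#' @return named numeric vector of per-gene totals over all genes in the
#'   set (genes without contacts get 0).
#' @export
assign_contacts_to_genes <- function(contacts, genes) {
  g <- genes$genes
  totals <- stats::setNames(numeric(nrow(g)), g$gene_id)
  if (nrow(contacts) == 0L || nrow(g) == 0L) return(totals)
  hits <- GenomicRanges::findOverlaps(.ivl_gr(contacts), .ivl_gr(g))
  if (length(hits)) {
    s <- S4Vectors::subjectHits(hits)
    agg <- tapply(contacts$value[S4Vectors::queryHits(hits)], s, sum)
    totals[as.integer(names(agg))] <- as.numeric(agg)
  }
  totals
}

#' Build a gene x sample contact-count matrix
#'
#' Extends each sample's raw contact track to the assay resolution, assigns
#' reads to genes and rounds half-up to integers for count modelling.
#'
#' @param tracks named list of \code{contact_track}s (one per sample).
#' @param genes a \code{gene_set}.
#' @param chrom_sizes named chromosome lengths.
#' @param extension_bp symmetric extension applied before assignment
#'   (default 2500).
#' @return integer matrix, genes x samples.
#' @export
gene_contact_counts <- function(tracks, genes, chrom_sizes,
                                extension_bp = 2500) {
  cols <- lapply(tracks, function(tr)
    round_half_up(assign_contacts_to_genes(
      extend_contacts(tr, extension_bp, chrom_sizes), genes)))
  m <- do.call(cbind, cols)
  colnames(m) <- names(tracks)
  storage.mode(m) <- "integer"
  m
}

# round half away from zero (counts are non-negative here)
round_half_up <- function(x) floor(x + 0.5)

#' Select the contact-gene list
#'
#' Genes with total assigned reads at or above the threshold, sorted by
#' descending reads with ties broken lexicographically by gene_id.
#'
#' @param counts named numeric vector of per-gene totals.
#' @param gene_read_threshold positive threshold (default 100).
#' @return character vector of gene_ids.
#' @export
select_contact_genes <- function(counts, gene_read_threshold = 100) {
  stopifnot(gene_read_threshold > 0)
  keep <- counts[counts >= gene_read_threshold]
  names(keep)[order(-keep, names(keep))]
}

#' Venn partition of two or three gene lists
#'
#' @param lists named list of 2 or 3 character vectors of unique
#'   identifiers.
#' @return object of class \code{gene_list_comparison}: list with
#'   \code{counts} (named region counts) and \code{members} (region ->
#'   identifiers). Region names use the input list names joined by "&",
#'   e.g. "A&B" for elements in A and B but no other list.
#' @export
compare_gene_lists <- function(lists) {
  stopifnot(is.list(lists), length(lists) %in% c(2L, 3L),
            !is.null(names(lists)), all(nzchar(names(lists))))
  for (nm in names(lists))
    if (anyDuplicated(lists[[nm]]))
      stop("validation error: duplicate identifiers within list ", nm)
  universe <- unique(unlist(lists))
  member <- vapply(lists, function(l) universe %in% l,
                   logical(length(universe)))
  if (length(universe) == 0L)
    member <- matrix(logical(0), 0L, length(lists),
                     dimnames = list(NULL, names(lists)))
  region <- apply(member, 1L, function(r)
    paste(names(lists)[r], collapse = "&"))
  combos <- unlist(lapply(seq_along(lists), function(k)
    utils::combn(names(lists), k, paste, collapse = "&")))
  counts <- stats::setNames(integer(length(combos)), combos)
  tab <- table(region)
  counts[names(tab)] <- as.integer(tab)
  members <- lapply(combos, function(cb) universe[region == cb])
  names(members) <- combos
  structure(list(counts = counts, members = members,
                 union_size = length(universe)),
            class = "gene_list_comparison")
}

#' @export
print.gene_list_comparison <- function(x, ...) {
  cat("gene-list Venn partition (", x$union_size, " in union):\n", sep = "")
  for (nm in names(x$counts))
    cat(sprintf("  %-12s %d\n", nm, x$counts[[nm]]))
  invisible(x)
}

#' Distance from the viewpoint to each contact gene
#'
#' For contact genes on the bait chromosome, the distance is the gap
#' between the bait interval and the gene-body edge nearest the bait (0 if
#' they overlap); genes on other chromosomes are reported as unlinked
#' (trans contacts, NA distance). Used to check that near-bait cis
#' interactions do not dominate the contact list.
#'
#' @param bait list or data.frame row with chrom, start, end (0-based
#'   half-open) for the viewpoint (rDNA cluster).
#' @param genes a \code{gene_set}.
#' @param contact_gene_list character vector of gene_ids.
#' @return data.frame (gene_id, chrom, distance_bp, cis) sorted ascending
#'   by distance with trans genes last.
#' @export
viewpoint_proximity <- function(bait, genes, contact_gene_list) {
  g <- genes$genes[match(contact_gene_list, genes$genes$gene_id), ,
                   drop = FALSE]
  if (any(is.na(g$gene_id)))
    stop("validation error: contact gene absent from gene set")
  cis <- g$chrom == bait$chrom
  d <- rep(NA_real_, nrow(g))
  d[cis] <- pmax(0, pmax(bait$start - g$end[cis], g$start[cis] - bait$end))
  out <- data.frame(gene_id = g$gene_id, chrom = g$chrom,
                    distance_bp = d, cis = cis, stringsAsFactors = FALSE)
  out <- out[order(!out$cis, out$distance_bp, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
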