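#' Intersect two replicate contact tracks with value averaging
#'
#' Reads are treated as the same contact when the replicate records overlap
#' by at least one nucleotide. Each overlapping record pair contributes one
#' output record covering the overlap region, valued at the arithmetic mean
#' of the two replicate values; records present in only one replicate are
#' dropped. Abutting output records are merged only when their values are
#' equal, so no averaging cascade is invented.
#'
#' @param rep1,rep2 \code{contact_track}s for the two replicates.
#' @return a \code{contact_track} of intersected, averaged contacts.
#' @export
intersect_replicates <- function(rep1, rep2) {
  validate_track(rep1); validate_track(rep2)
  if (nrow(rep1) == 0L || nrow(rep2) == 0L)
    return(contact_track(character(), integer(), integer(), numeric()))
  g1 <- .track_gr(rep1); g2 <- .track_gr(rep2)
  hits <- GenomicRanges::findOverlaps(g1, g2)
  if (length(hits) == 0L)
    return(contact_track(character(), integer(), integer(), numeric()))
  i <- S4Vectors::queryHits(hits); j <- S4Vectors::subjectHits(hits)
  chrom <- rep1$chrom[i]
  start <- pmax(rep1$start[i], rep2$start[j])
  end <- pmin(rep1$end[i], rep2$end[j])
  value <- (rep1$value[i] + rep2$value[j]) / 2
  o <- order(chrom, start)
  chrom <- chrom[o]; start <- start[o]; end <- end[o]; value <- value[o]
  # merge abutting records with equal values
  if (length(start) > 1L) {
    grp <- cumsum(c(TRUE, !(chrom[-1L] == chrom[-length(chrom)] &
                              start[-1L] == end[-length(end)] &
                              value[-1L] == value[-length(value)])))
    chrom <- chrom[!duplicated(grp)]
    start <- start[!duplicated(grp)]
    end <- tapply(end, grp, max)
    value <- value[!duplicated(grp)]
  }
  contact_track(chrom, start, end, value)
}

#' Remove contacts fully contained in repeat elements
#'
#' A record is removed iff its interval lies entirely inside at least one
#' single repeat record (full-containment semantics, as with
#' \code{bedtools intersect -v -f 1.0}); partial overlaps are retained
#' unmodified.
#'
#' @param track a \code{contact_track}.
#' @param repeats data.frame of repeat intervals (chrom, start, end,
#'   0-based half-open; extra columns ignored).
#' @return the filtered \code{contact_track}.
#' @export
filter_repeats <- function(track, repeats) {
  validate_track(track)
  if (nrow(track) == 0L || is.null(repeats) || nrow(repeats) == 0L)
    return(track)
  hits <- GenomicRanges::findOverlaps(.track_gr(track), .ivl_gr(repeats),
                                      type = "within")
  drop <- unique(S4Vectors::queryHits(hits))
  out <- track[setdiff(seq_len(nrow(track)), drop), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(track)
  out
}

#' Threshold contacts by read value
#'
#' Retains exactly the records whose value is greater than or equal to the
#' threshold ("100 or more reads" is inclusive).
#'
#' @param track a \code{contact_track}.
#' @param threshold positive read threshold (default 100).
#' @return the thresholded \code{contact_track}.
#' @export
threshold_contacts <- function(track, threshold = 100) {
  stopifnot(threshold > 0)
  validate_track(track)
  out <- track[track$value >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(track)
  out
}

#' Extend contact records to the assay resolution
#'
#' With a six-cutter 4C design, contacts are resolved to about +/-2.5 kb,
#' so each record is widened by \code{extension_bp} on both sides (clamped
#' to the chromosome). The result may contain mutually overlapping
#' intervals and is returned as a plain data.frame, not a
#' \code{contact_track}.
#'
#' @param track a \code{contact_track}.
#' @param extension_bp non-negative extension in bp (default 2500).
#' @param chrom_sizes named vector of chromosome lengths covering every
#'   chromosome present in the track.
#' @return data.frame with chrom, start, end, value.
#' @export
extend_contacts <- function(track, extension_bp = 2500, chrom_sizes) {
  stopifnot(extension_bp >= 0)
  validate_track(track)
  missing_chr <- setdiff(unique(track$chrom), names(chrom_sizes))
  if (length(missing_chr))
    stop("lookup error: chromosome(s) absent from chrom_sizes: ",
         paste(missing_chr, collapse = ", "))
  out <- data.frame(chrom = track$chrom,
                    start = pmax(0L, track$start - as.integer(extension_bp)),
                    end = pmin(as.integer(chrom_sizes[track$chrom]),
                               track$end + as.integer(extension_bp)),
                    value = track$value,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Run the contact-calling stage
#'
#' Convenience composition: replicate intersection with averaging, repeat
#' containment filtering, read thresholding. Extension is left to the
#' quantification step so both raw and extended coordinates stay available.
#'
#' @param rep1,rep2 replicate \code{contact_track}s.
#' @param repeats repeat intervals, or NULL to skip repeat filtering.
#' @param threshold read threshold (default 100).
#' @return list with the \code{track} after each stage and a
#'   \code{stage_counts} vector of surviving record numbers.
#' @export
call_contacts <- function(rep1, rep2, repeats = NULL, threshold = 100) {
  inter <- intersect_replicates(rep1, rep2)
  nodfam <- if (is.null(repeats)) inter else filter_repeats(inter, repeats)
  thr <- threshold_contacts(nodfam, threshold)
  list(intersected = inter, repeat_filtered = nodfam, thresholded = thr,
       stage_counts = c(rep1 = nrow(rep1), rep2 = nrow(rep2),
                        intersected = nrow(inter),
                        repeat_filtered = nrow(nodfam),
                        thresholded = nrow(thr)))
}
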