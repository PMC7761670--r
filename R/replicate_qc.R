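#' Binned RPKM coverage
#'
#' Tiles every chromosome with fixed-size bins (the last bin may be short)
#' and apportions each record's read value to bins by overlap fraction.
#' Bin values are RPKM-normalized: reads per bin / (library size in
#' millions) / (bin size in kb), with the library size taken as the total
#' reads on non-excluded chromosomes only. Excluded chromosomes (by
#' default the bait-bearing one) still receive bins but do not contribute
#' to the library-size denominator, which removes the influence of
#' bait/anchor mapping on the normalization.
#'
#' @param track a \code{contact_track}.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param bin_size_bp bin width (default 50).
#' @param excluded_chroms chromosomes excluded from the library size
#'   (default "chrX").
#' @return object of class \code{binned_coverage}: list with
#'   \code{bin_size_bp} and \code{bins} (chrom, start, end, value).
#' @export
binned_rpkm <- function(track, chrom_sizes, bin_size_bp = 50,
                        excluded_chroms = "chrX") {
  stopifnot(bin_size_bp > 0)
  validate_track(track)
  lib <- sum(track$value[!(track$chrom %in% excluded_chroms)])
  if (lib <= 0)
    stop("normalization error: zero total reads on non-excluded chromosomes")
  bins <- do.call(rbind, lapply(names(chrom_sizes), function(ch) {
    len <- as.integer(chrom_sizes[[ch]])
    s <- seq.int(0L, len - 1L, by = bin_size_bp)
    data.frame(chrom = ch, start = s, end = pmin(s + as.integer(bin_size_bp),
                                                 len),
               stringsAsFactors = FALSE)
  }))
  bins$value <- 0
  tr <- track[track$chrom %in% names(chrom_sizes), , drop = FALSE]
  if (nrow(tr)) {
    hits <- GenomicRanges::findOverlaps(.ivl_gr(bins), .track_gr(tr))
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    ovl <- pmin(bins$end[q], tr$end[s]) - pmax(bins$start[q], tr$start[s])
    contrib <- tr$value[s] * ovl / (tr$end[s] - tr$start[s])
    agg <- tapply(contrib, q, sum)
    bins$value[as.integer(names(agg))] <- as.numeric(agg)
  }
  bins$value <- bins$value / (lib / 1e6) / (bin_size_bp / 1e3)
  structure(list(bin_size_bp = bin_size_bp, bins = bins,
                 excluded_chroms = excluded_chroms),
            class = "binned_coverage")
}

#' Correlation between two binned coverages
#'
#' Computes the Pearson or Spearman correlation over paired bins. When
#' \code{skip_zeros}, bins where both samples are zero are dropped; when
#' \code{remove_outliers}, bins where either value exceeds that sample's
#' median + 200 * MAD are dropped first. Coefficients are computed on the
#' untransformed values (any log1p is a plotting choice only).
#'
#' @param a,b \code{binned_coverage} objects over identical bins.
#' @param method "pearson" or "spearman".
#' @param skip_zeros drop bins that are zero in both samples.
#' @param remove_outliers drop bins exceeding median + 200 * MAD in either
#'   sample.
#' @param drop_excluded_bins also drop bins on the chromosomes excluded
#'   from normalization (default FALSE: they are kept in the correlation).
#' @return the correlation coefficient.
#' @export
replicate_correlation <- function(a, b, method = c("pearson", "spearman"),
                                  skip_zeros = TRUE, remove_outliers = TRUE,
                                  drop_excluded_bins = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(a, "binned_coverage"), inherits(b, "binned_coverage"))
  if (nrow(a$bins) != nrow(b$bins) ||
      !all(a$bins$chrom == b$bins$chrom & a$bins$start == b$bins$start))
    stop("validation error: inputs are not identically binned")
  x <- a$bins$value; y <- b$bins$value
  keep <- rep(TRUE, length(x))
  if (drop_excluded_bins)
    keep <- keep & !(a$bins$chrom %in% a$excluded_chroms)
  if (remove_outliers) {
    # sparse 4C coverage leaves most bins at zero, where median and MAD
    # collapse to 0; a zero MAD disables removal for that sample
    cut_of <- function(v) {
      m <- stats::mad(v)
      if (m == 0) Inf else stats::median(v) + 200 * m
    }
    keep <- keep & x <= cut_of(x) & y <= cut_of(y)
  }
  if (skip_zeros) keep <- keep & !(x == 0 & y == 0)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L)
    stop("insufficient-data error: fewer than 3 bins after filtering")
  stats::cor(x, y, method = method)
}
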