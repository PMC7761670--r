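#' Signal metaprofile around contact sites
#'
#' Averages a signal track within fixed-size bins of a window centred on
#' each site's anchor (midpoint by default). Bases without a signal record
#' and bins extending past chromosome ends are treated as missing, not
#' zero; the mean curve averages over sites ignoring missing entries.
#'
#' @param signal a signal track (contact_track, negative values allowed).
#' @param sites data.frame of site intervals.
#' @param chrom_sizes named chromosome lengths.
#' @param window_bp half-window in bp (default 2000); must be divisible by
#'   \code{bin_bp}.
#' @param bin_bp bin width in bp (default 50).
#' @param anchor "midpoint" or "start".
#' @return object of class \code{metaprofile}: list with \code{matrix}
#'   (sites x bins), \code{offsets} (bin start offsets relative to the
#'   anchor) and \code{mean} curve.
#' @export
metaprofile <- function(signal, sites, chrom_sizes, window_bp = 2000,
                        bin_bp = 50, anchor = c("midpoint", "start")) {
  anchor <- match.arg(anchor)
  if (nrow(sites) == 0L) stop("insufficient-data error: no sites")
  if (window_bp %% bin_bp != 0)
    stop("parameter error: window_bp must be divisible by bin_bp")
  a <- if (anchor == "midpoint") floor((sites$start + sites$end) / 2)
       else sites$start
  offsets <- seq.int(-window_bp, window_bp - bin_bp, by = bin_bp)
  nb <- length(offsets)
  ns <- nrow(sites)
  bin_start <- rep(a, each = nb) + rep(offsets, ns)
  bins <- data.frame(chrom = rep(sites$chrom, each = nb),
                     start = bin_start, end = bin_start + bin_bp,
                     site = rep(seq_len(ns), each = nb),
                     bin = rep(seq_len(nb), ns),
                     stringsAsFactors = FALSE)
  mat <- matrix(NA_real_, ns, nb)
  inside <- bins$start >= 0 &
    bins$end <= as.numeric(chrom_sizes[bins$chrom]) &
    !is.na(chrom_sizes[bins$chrom])
  bb <- bins[inside, , drop = FALSE]
  if (nrow(bb) && nrow(signal)) {
    qgr <- GenomicRanges::GRanges(bb$chrom,
                                  IRanges::IRanges(bb$start + 1L, bb$end))
    hits <- GenomicRanges::findOverlaps(qgr, .track_gr(signal))
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    if (length(hits)) {
      ovl <- pmin(bb$end[q], signal$end[s]) - pmax(bb$start[q],
                                                   signal$start[s])
      wsum <- tapply(ovl * signal$value[s], q, sum)
      bsum <- tapply(ovl, q, sum)
      idx <- as.integer(names(wsum))
      mat[cbind(bb$site[idx], bb$bin[idx])] <-
        as.numeric(wsum) / as.numeric(bsum)
    }
  }
  mean_curve <- colMeans(mat, na.rm = TRUE)
  mean_curve[is.nan(mean_curve)] <- NA_real_
  structure(list(matrix = mat, offsets = offsets, mean = mean_curve,
                 bin_bp = bin_bp, anchor = anchor),
            class = "metaprofile")
}

#' @export
print.metaprofile <- function(x, ...) {
  cat(sprintf("metaprofile: %d sites x %d bins (%d bp bins, %s anchor)\n",
              nrow(x$matrix), ncol(x$matrix), x$bin_bp, x$anchor))
  invisible(x)
}

#' Plot a metaprofile mean curve
#'
#' @param x a \code{metaprofile}.
#' @param ... passed to \code{plot}.
#' @method plot metaprofile
#' @export
plot.metaprofile <- function(x, ...) {
  graphics::plot(x$offsets + x$bin_bp / 2, x$mean, type = "l",
                 xlab = "offset from anchor (bp)", ylab = "mean signal",
                 ...)
  graphics::abline(v = 0, lty = 2, col = "grey50")
  invisible(x)
}
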