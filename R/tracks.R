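#' Construct a contact track
#'
#' A contact track is the pipeline's central currency: a set of genomic
#' intervals (0-based, half-open) each carrying a non-negative value (read
#' count for 4C coverage, arbitrary signal otherwise). Records are kept
#' sorted by (chrom, start) and, within a chromosome, must not overlap.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; 0-based half-open coordinates.
#' @param value numeric vector of non-negative values.
#' @param sample_id optional sample label.
#' @param condition optional condition label (e.g. "control", "heat_shock").
#' @param allow_negative permit negative values (signal tracks such as
#'   ChIP-chip M values); contact tracks keep the default \code{FALSE}.
#' @return A data.frame of class \code{contact_track} with columns
#'   \code{chrom}, \code{start}, \code{end}, \code{value}.
#' @export
contact_track <- function(chrom, start, end, value,
                          sample_id = NA_character_,
                          condition = NA_character_,
                          allow_negative = FALSE) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   value = as.numeric(value),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  validate_track(df, allow_negative = allow_negative)
  attr(df, "sample_id") <- sample_id
  attr(df, "condition") <- condition
  class(df) <- c("contact_track", "data.frame")
  df
}

#' Validate contact-track invariants
#'
#' Checks 0-based half-open interval sanity, non-negative values (unless
#' \code{allow_negative}) and, within each chromosome, sortedness and the
#' absence of overlapping records.
#'
#' @param df data.frame with chrom/start/end/value columns, sorted by
#'   (chrom, start).
#' @param allow_negative permit negative values.
#' @return Invisibly \code{TRUE}; stops with a validation error otherwise.
#' @export
validate_track <- function(df, allow_negative = FALSE) {
  stopifnot(is.data.frame(df),
            all(c("chrom", "start", "end", "value") %in% names(df)))
  if (nrow(df) == 0L) return(invisible(TRUE))
  if (any(is.na(df$start)) || any(is.na(df$end)) || any(is.na(df$value)))
    stop("track validation error: NA coordinates or values")
  if (any(!nzchar(df$chrom)))
    stop("track validation error: empty chromosome name")
  if (any(df$start < 0L))
    stop("track validation error: negative start coordinate")
  if (any(df$end <= df$start))
    stop("track validation error: end must exceed start (half-open)")
  if (!allow_negative && any(df$value < 0))
    stop("track validation error: negative value")
  same <- df$chrom[-1L] == df$chrom[-nrow(df)]
  if (any(same & df$start[-1L] < df$end[-nrow(df)]))
    stop("track validation error: overlapping records within a chromosome")
  invisible(TRUE)
}

# internal: contact track (0-based half-open) -> GRanges (1-based closed)
.track_gr <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1L, df$end),
                         value = df$value)
}

# internal: plain intervals df -> GRanges
.ivl_gr <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1L, df$end))
}

#' @method as.data.frame contact_track
#' @export
as.data.frame.contact_track <- function(x, ...) {
  out <- data.frame(chrom = x$chrom, start = x$start, end = x$end,
                    value = x$value, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @export
print.contact_track <- function(x, ...) {
  cat(sprintf("contact track: %d records on %d chromosome(s)",
              nrow(x), length(unique(x$chrom))))
  sid <- attr(x, "sample_id"); cond <- attr(x, "condition")
  if (!is.na(sid)) cat(sprintf("  [sample %s%s]", sid,
                               if (!is.na(cond)) paste0(", ", cond) else ""))
  cat("\n")
  if (nrow(x) > 0L) print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}
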