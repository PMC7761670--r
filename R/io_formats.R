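#' Read a bedGraph coverage file
#'
#' Parses a 4-column bedGraph (chrom, start, end, value; 0-based half-open)
#' into a \code{\link{contact_track}}. Track definition lines, comments and
#' blank lines are skipped. Records are sorted on read; overlapping records
#' within a chromosome or negative values are rejected.
#'
#' @param path file path.
#' @param sample_id,condition optional labels stored on the track.
#' @param allow_negative permit negative values (signal tracks).
#' @return a \code{contact_track}.
#' @export
read_bedgraph <- function(path, sample_id = NA_character_,
                          condition = NA_character_,
                          allow_negative = FALSE) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    return(contact_track(character(), integer(), integer(), numeric(),
                         sample_id = sample_id, condition = condition))
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 4L))
    stop(sprintf("parse error: line %d of %s: expected 4 columns, got %d",
                 lineno[which(nf != 4L)[1L]], path, nf[which(nf != 4L)[1L]]))
  m <- matrix(unlist(fields), ncol = 4L, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2L]))
  end <- suppressWarnings(as.integer(m[, 3L]))
  value <- suppressWarnings(as.numeric(m[, 4L]))
  bad <- which(is.na(start) | is.na(end) | is.na(value))
  if (length(bad))
    stop(sprintf("parse error: line %d of %s: non-numeric field",
                 lineno[bad[1L]], path))
  contact_track(m[, 1L], start, end, value,
                sample_id = sample_id, condition = condition,
                allow_negative = allow_negative)
}

#' Write a contact track as bedGraph
#'
#' Emits a track definition header followed by the records in sorted order.
#' \code{read_bedgraph(write_bedgraph(t))} reproduces the records exactly.
#'
#' @param track a \code{contact_track} (or data.frame with the same columns).
#' @param path output file path.
#' @param name track name for the header line.
#' @export
write_bedgraph <- function(track, path, name = "track") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=%s", name), con)
  if (nrow(track) > 0L)
    writeLines(sprintf("%s\t%d\t%d\t%s", track$chrom, track$start, track$end,
                       format(track$value, scientific = FALSE, trim = TRUE,
                              digits = 15L)), con)
  invisible(path)
}

#' Read gene models from GTF or GFF3
#'
#' External 1-based closed coordinates are converted to internal 0-based
#' half-open on read. Exon and UTR features are grouped under their gene by
#' the \code{gene_id} attribute.
#'
#' @param path file path.
#' @param dialect "gtf" (Ensembl) or "gff3".
#' @return a \code{gene_set}: list with \code{genes} (gene_id, symbol,
#'   chrom, start, end, strand) and \code{features} (gene_id, type in
#'   exon/utr5/utr3, chrom, start, end).
#' @export
read_gene_annotation <- function(path, dialect = c("gtf", "gff3")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  gr <- rtracklayer::import(path, format = dialect)
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  gid <- as.character(md$gene_id)
  is_gene <- type == "gene"
  if (any(is_gene & (is.na(gid) | !nzchar(gid))))
    stop("parse error: gene feature without gene_id attribute in ", path)
  g <- gr[is_gene]
  gids <- as.character(S4Vectors::mcols(g)$gene_id)
  if (anyDuplicated(gids))
    stop("validation error: duplicate gene_id in ", path)
  sym <- S4Vectors::mcols(g)$gene_name
  sym <- if (is.null(sym)) gids else ifelse(is.na(sym), gids, as.character(sym))
  genes <- data.frame(gene_id = gids, symbol = sym,
                      chrom = as.character(GenomicRanges::seqnames(g)),
                      start = GenomicRanges::start(g) - 1L,
                      end = GenomicRanges::end(g),
                      strand = as.character(GenomicRanges::strand(g)),
                      stringsAsFactors = FALSE)
  ftype_map <- c(exon = "exon",
                 five_prime_utr = "utr5", three_prime_utr = "utr3",
                 five_prime_UTR = "utr5", three_prime_UTR = "utr3")
  is_feat <- type %in% names(ftype_map)
  f <- gr[is_feat]
  features <- data.frame(gene_id = as.character(S4Vectors::mcols(f)$gene_id),
                         type = unname(ftype_map[type[is_feat]]),
                         chrom = as.character(GenomicRanges::seqnames(f)),
                         start = GenomicRanges::start(f) - 1L,
                         end = GenomicRanges::end(f),
                         stringsAsFactors = FALSE)
  gene_set(genes, features)
}

#' Construct a gene set
#'
#' @param genes data.frame with gene_id, symbol, chrom, start, end, strand
#'   (0-based half-open).
#' @param features data.frame with gene_id, type ("exon"/"utr5"/"utr3"),
#'   chrom, start, end; may be empty.
#' @return list of class \code{gene_set}.
#' @export
gene_set <- function(genes, features = NULL) {
  if (is.null(features))
    features <- data.frame(gene_id = character(), type = character(),
                           chrom = character(), start = integer(),
                           end = integer(), stringsAsFactors = FALSE)
  if (anyDuplicated(genes$gene_id))
    stop("validation error: duplicate gene_id in gene set")
  if (nrow(genes) && any(genes$end <= genes$start))
    stop("validation error: gene with end <= start")
  if (nrow(features) && !all(features$gene_id %in% genes$gene_id))
    stop("validation error: feature references unknown gene_id")
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  structure(list(genes = genes, features = features), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene set: %d genes, %d sub-features on %d chromosome(s)\n",
              nrow(x$genes), nrow(x$features), length(unique(x$genes$chrom))))
  invisible(x)
}

#' Write gene models as Ensembl-dialect GTF
#'
#' Internal 0-based half-open intervals are emitted 1-based closed.
#'
#' @param gs a \code{gene_set}.
#' @param path output path.
#' @export
write_gtf <- function(gs, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  attr_str <- function(gid, sym)
    sprintf('gene_id "%s"; gene_name "%s";', gid, sym)
  g <- gs$genes
  type_out <- c(exon = "exon", utr5 = "five_prime_utr",
                utr3 = "three_prime_utr")
  sym <- stats::setNames(g$symbol, g$gene_id)
  strand <- stats::setNames(g$strand, g$gene_id)
  lines <- character(0)
  for (i in seq_len(nrow(g))) {
    lines <- c(lines, sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\t%s",
                              g$chrom[i], g$start[i] + 1L, g$end[i],
                              g$strand[i], attr_str(g$gene_id[i], g$symbol[i])))
    f <- gs$features[gs$features$gene_id == g$gene_id[i], , drop = FALSE]
    if (nrow(f))
      lines <- c(lines, sprintf("%s\tsim\t%s\t%d\t%d\t.\t%s\t.\t%s",
                                f$chrom, type_out[f$type], f$start + 1L, f$end,
                                strand[f$gene_id],
                                attr_str(f$gene_id, sym[f$gene_id])))
  }
  writeLines(lines, con)
  invisible(path)
}

#' Read a BED file (3-6 columns)
#'
#' BED is 0-based half-open; coordinates are kept as-is.
#'
#' @param path file path.
#' @return data.frame with chrom, start, end and, when present, name,
#'   score, strand.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  if (length(lines) == 0L) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
    return(out)
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop(sprintf("parse error: line %d of %s: fewer than 3 columns",
                 lineno[which(nf < 3L)[1L]], path))
  n <- min(nf, 6L)
  out <- as.data.frame(do.call(rbind, lapply(fields, function(f)
    f[seq_len(n)])), stringsAsFactors = FALSE)
  names(out) <- cols[seq_len(n)]
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  if (any(is.na(out$start) | is.na(out$end)))
    stop("parse error: non-integer coordinates in ", path)
  if (any(out$end <= out$start))
    stop("validation error: end <= start in ", path)
  if ("score" %in% names(out))
    out$score <- suppressWarnings(as.numeric(out$score))
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Write intervals as BED
#'
#' @param df data.frame with chrom, start, end and optional name, score,
#'   strand columns (0-based half-open).
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(df))
  utils::write.table(df[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 9-state chromatin segmentation from GFF3
#'
#' Expects one feature per segment with a \code{state} attribute (integer
#' 1-9); 1-based closed GFF3 coordinates become 0-based half-open.
#'
#' @param path file path.
#' @return data.frame of class \code{state_annotation} with chrom, start,
#'   end, state.
#' @export
read_state_gff <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  st <- S4Vectors::mcols(gr)$state
  if (is.null(st))
    stop("parse error: no 'state' attribute in ", path)
  state_annotation(data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    state = as.integer(as.character(st)),
    stringsAsFactors = FALSE))
}

#' Construct a chromatin-state annotation
#'
#' @param df data.frame with chrom, start, end (0-based half-open) and
#'   integer state in 1..9.
#' @return the validated data.frame, classed \code{state_annotation},
#'   sorted by (chrom, start).
#' @export
state_annotation <- function(df) {
  stopifnot(all(c("chrom", "start", "end", "state") %in% names(df)))
  df$state <- as.integer(df$state)
  if (nrow(df) && (any(is.na(df$state)) || any(df$state < 1L | df$state > 9L)))
    stop("validation error: state labels must be integers in 1..9")
  if (nrow(df) && any(df$end <= df$start))
    stop("validation error: segment with end <= start")
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("state_annotation", "data.frame")
  df
}

#' Write a chromatin-state segmentation as GFF3
#'
#' @param states a \code{state_annotation}.
#' @param path output path.
#' @export
write_state_gff <- function(states, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(states))
    writeLines(sprintf(
      "%s\tsim\tchromatin_state\t%d\t%d\t.\t.\t.\tID=seg%06d;state=%d",
      states$chrom, states$start + 1L, states$end,
      seq_len(nrow(states)), states$state), con)
  invisible(path)
}

#' Read a wiggle signal track
#'
#' Supports fixedStep and variableStep dialects (span/step semantics);
#' 1-based wiggle coordinates become 0-based half-open records.
#'
#' @param path file path.
#' @return a \code{contact_track} with \code{allow_negative} values (signal).
#' @export
read_wiggle <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  gr <- rtracklayer::import(path, format = "wig")
  contact_track(as.character(GenomicRanges::seqnames(gr)),
                GenomicRanges::start(gr) - 1L,
                GenomicRanges::end(gr),
                S4Vectors::mcols(gr)$score,
                allow_negative = TRUE)
}

#' Write / read a counts matrix as TSV
#'
#' The TSV has a \code{gene_id} first column and one column per sample.
#'
#' @param counts integer matrix, genes x samples, with dimnames.
#' @param path file path.
#' @return \code{read_counts_tsv} returns the matrix.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "numeric"
  m
}
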