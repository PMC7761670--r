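# Fixture builders and brute-force per-base oracles used across the suite.
# Oracles work on dense per-base vectors and stay independent of the
# package's interval-algebra implementation.

# random sorted non-overlapping track on the given chromosomes
random_track <- function(chrom_sizes, n_records = 20, max_len = 500,
                         value_range = c(1, 300)) {
  recs <- NULL
  for (ch in names(chrom_sizes)) {
    len <- chrom_sizes[[ch]]
    k <- max(1L, rpois(1, n_records / length(chrom_sizes)))
    starts <- sort(sample.int(len - max_len, k))
    widths <- sample.int(max_len, k)
    ends <- pmin(starts + widths, len)
    # enforce non-overlap by trimming at the next start
    if (k > 1) ends[-k] <- pmin(ends[-k], starts[-1])
    keep <- ends > starts
    if (!any(keep)) next
    recs <- rbind(recs, data.frame(
      chrom = ch, start = starts[keep], end = ends[keep],
      value = round(runif(sum(keep), value_range[1], value_range[2]), 1),
      stringsAsFactors = FALSE))
  }
  contact_track(recs$chrom, recs$start, recs$end, recs$value)
}

# dense per-base representation: list chrom -> numeric vector (NA = no record)
base_values <- function(track, chrom_sizes) {
  out <- lapply(chrom_sizes, function(len) rep(NA_real_, len))
  for (i in seq_len(nrow(track))) {
    ch <- track$chrom[i]
    out[[ch]][(track$start[i] + 1):track$end[i]] <- track$value[i]
  }
  out
}

# collapse a per-base vector into maximal equal-valued runs (0-based)
runs_of <- function(v, chrom) {
  idx <- which(!is.na(v))
  if (!length(idx)) return(NULL)
  r <- rle(paste(is.na(v), v))
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)])
  keep <- !is.na(v)[ends]
  data.frame(chrom = chrom, start = starts[keep], end = ends[keep],
             value = v[ends[keep]], stringsAsFactors = FALSE)
}

# oracle for intersect_replicates: per-base mean where both covered
oracle_intersect <- function(a, b, chrom_sizes) {
  va <- base_values(a, chrom_sizes)
  vb <- base_values(b, chrom_sizes)
  out <- NULL
  for (ch in names(chrom_sizes)) {
    m <- (va[[ch]] + vb[[ch]]) / 2   # NA wherever either is NA
    out <- rbind(out, runs_of(m, ch))
  }
  out
}

# oracle for filter_repeats: drop records fully inside a single repeat
oracle_filter_repeats <- function(track, repeats) {
  keep <- vapply(seq_len(nrow(track)), function(i) {
    r <- repeats[repeats$chrom == track$chrom[i], , drop = FALSE]
    !any(track$start[i] >= r$start & track$end[i] <= r$end)
  }, logical(1))
  track[keep, , drop = FALSE]
}

# oracle for assign_contacts_to_genes: full value to every >=1 bp gene
oracle_assign_genes <- function(contacts, genes) {
  g <- genes$genes
  totals <- setNames(numeric(nrow(g)), g$gene_id)
  for (i in seq_len(nrow(contacts)))
    for (j in seq_len(nrow(g)))
      if (contacts$chrom[i] == g$chrom[j] &&
          contacts$start[i] < g$end[j] && contacts$end[i] > g$start[j])
        totals[j] <- totals[j] + contacts$value[i]
  totals
}

# oracle for assign_chromatin_state: per-base state tally + 50% rule
oracle_assign_state <- function(sites, states, frac = 0.5,
                                chrom_sizes) {
  lab <- lapply(chrom_sizes, function(len) rep(NA_integer_, len))
  for (i in seq_len(nrow(states)))
    lab[[states$chrom[i]]][(states$start[i] + 1):states$end[i]] <-
      states$state[i]
  vapply(seq_len(nrow(sites)), function(i) {
    v <- lab[[sites$chrom[i]]][(sites$start[i] + 1):sites$end[i]]
    w <- sites$end[i] - sites$start[i]
    tab <- table(factor(v, levels = 1:9))
    ok <- which(tab >= frac * w)
    if (!length(ok)) return(NA_integer_)
    best <- ok[order(-tab[ok], ok)]
    as.integer(best[1])
  }, integer(1))
}

# small deterministic gene set for annotation tests
tiny_gene_set <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB", "gC"),
    symbol = c("GA", "GB", "GC"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(10000L, 30000L, 5000L),
    end = c(16000L, 36000L, 11000L),
    strand = c("+", "-", "+"),
    stringsAsFactors = FALSE)
  feats <- data.frame(
    gene_id = c("gA", "gA", "gA", "gA", "gB", "gC"),
    type = c("exon", "exon", "utr5", "utr3", "exon", "exon"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr2"),
    start = c(10000L, 14000L, 10000L, 15800L, 30500L, 5000L),
    end = c(11000L, 16000L, 10200L, 16000L, 31500L, 6000L),
    stringsAsFactors = FALSE)
  gene_set(genes, feats)
}

# random tiling 9-state segmentation
random_states <- function(chrom_sizes, min_len = 1000, max_len = 20000) {
  st <- NULL
  for (ch in names(chrom_sizes)) {
    pos <- 0; ss <- c(); se <- c()
    while (pos < chrom_sizes[[ch]]) {
      sl <- round(exp(runif(1, log(min_len), log(max_len))))
      ss <- c(ss, pos)
      se <- c(se, min(pos + sl, chrom_sizes[[ch]]))
      pos <- pos + sl
    }
    st <- rbind(st, data.frame(chrom = ch, start = as.integer(ss),
                               end = as.integer(se),
                               state = sample.int(9L, length(ss), TRUE),
                               stringsAsFactors = FALSE))
  }
  state_annotation(st)
}

# brute-force BH step-up, for checking the adjustment path
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- rep(NA_real_, m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, m * p[o[i]] / i)
    adj[o[i]] <- prev
  }
  adj
}
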