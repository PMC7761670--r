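#' Random gene-list overlap null
#'
#' Estimates how strongly two same-universe gene lists overlap by chance.
#' At each of \code{n_shuffles} steps the universe is Fisher-Yates
#' shuffled, the first \code{k} elements form a random list, and the
#' fraction of them present in the reference list is recorded (drawing the
#' first k of an unbiased shuffle is equivalent to sampling k without
#' replacement, which is how it is computed). Mean, sd, min and max of the
#' overlap fraction are reported; with an observed list, the add-one
#' empirical p-value for enrichment is included.
#'
#' @param universe character vector of unique identifiers.
#' @param reference subset of the universe (the fixed reference list).
#' @param k list size drawn at each step (default: size of reference).
#' @param n_shuffles number of shuffles (default 100000).
#' @param seed integer RNG seed.
#' @param observed optional character vector: the actually observed list
#'   whose overlap with the reference is to be tested.
#' @return object of class \code{overlap_null}: list with n_shuffles, N,
#'   k, mean, sd, min, max, fractions, and optionally observed /
#'   empirical_p.
#' @export
overlap_null <- function(universe, reference, k = length(reference),
                         n_shuffles = 100000L, seed = 1L,
                         observed = NULL) {
  if (anyDuplicated(universe))
    stop("validation error: duplicate identifiers in universe")
  if (!all(reference %in% universe))
    stop("validation error: reference is not a subset of the universe")
  if (anyDuplicated(reference))
    stop("validation error: duplicate identifiers in reference")
  N <- length(universe)
  if (k > N) stop("parameter error: k exceeds universe size")
  set.seed(seed)
  ref <- universe %in% reference
  frac <- vapply(seq_len(n_shuffles), function(i)
    sum(ref[sample.int(N, k)]) / k, numeric(1))
  out <- list(n_shuffles = n_shuffles, N = N, k = k,
              mean = mean(frac), sd = stats::sd(frac),
              min = min(frac), max = max(frac), fractions = frac)
  if (!is.null(observed)) {
    obs <- sum(observed %in% reference) / k
    out$observed <- obs
    out$empirical_p <- (1 + sum(frac >= obs)) / (n_shuffles + 1)
  }
  structure(out, class = "overlap_null")
}

#' @export
print.overlap_null <- function(x, ...) {
  cat(sprintf(
    "overlap null (N=%d, k=%d, %d shuffles): %.5f +/- %.3f, min=%.5f, max=%.5f\n",
    x$N, x$k, x$n_shuffles, x$mean, x$sd, x$min, x$max))
  if (!is.null(x$observed))
    cat(sprintf("observed %.5f, empirical p = %.3g\n", x$observed,
                x$empirical_p))
  invisible(x)
}

#' Shuffle a chromatin-state segmentation
#'
#' Three null schemes that preserve the intrinsic structure of the
#' segmentation to different degrees:
#' \describe{
#'   \item{label_shuffle}{segment coordinates untouched; labels permuted
#'     uniformly genome-wide.}
#'   \item{segment_shuffle}{within each chromosome the sequence of
#'     (length, label) segments is uniformly reordered and coordinates
#'     rebuilt cumulatively from the chromosome start.}
#'   \item{coord_and_state_shuffle}{all (length, label) segments pooled
#'     genome-wide and reassigned by sequentially filling each
#'     chromosome's original total segment length; coordinates rebuilt
#'     cumulatively. The genome-wide (length, label) multiset is preserved
#'     exactly; a chromosome's final segment may overhang its original
#'     extent.}
#' }
#'
#' @param states a \code{state_annotation}.
#' @param scheme one of "label_shuffle", "segment_shuffle",
#'   "coord_and_state_shuffle".
#' @param seed optional integer seed (omit when calling inside an outer
#'   seeded loop).
#' @return a shuffled \code{state_annotation}.
#' @export
shuffle_states <- function(states,
                           scheme = c("label_shuffle", "segment_shuffle",
                                      "coord_and_state_shuffle"),
                           seed = NULL) {
  scheme <- match.arg(scheme)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(states)
  if (n == 0L) return(states)
  out <- as.data.frame(states)
  if (scheme == "label_shuffle") {
    out$state <- out$state[sample.int(n)]
  } else if (scheme == "segment_shuffle") {
    for (ch in unique(out$chrom)) {
      i <- which(out$chrom == ch)
      len <- out$end[i] - out$start[i]
      lab <- out$state[i]
      p <- sample.int(length(i))
      origin <- min(out$start[i])
      ends <- origin + cumsum(len[p])
      out$start[i] <- c(origin, ends[-length(ends)])
      out$end[i] <- ends
      out$state[i] <- lab[p]
    }
  } else {
    len <- out$end - out$start
    lab <- out$state
    p <- sample.int(n)
    len <- len[p]; lab <- lab[p]
    chroms <- unique(out$chrom)
    totals <- vapply(chroms, function(ch)
      sum(out$end[out$chrom == ch] - out$start[out$chrom == ch]), numeric(1))
    origins <- vapply(chroms, function(ch)
      min(out$start[out$chrom == ch]), numeric(1))
    res <- vector("list", length(chroms))
    pos <- 1L
    cum <- cumsum(len)
    base <- 0
    for (ci in seq_along(chroms)) {
      if (ci == length(chroms)) {
        take <- seq.int(pos, n)
      } else {
        # smallest prefix whose placed length reaches this chromosome's total
        last <- which(cum - base >= totals[ci])[1L]
        if (is.na(last)) last <- n
        take <- seq.int(pos, last)
      }
      l <- len[take]
      ends <- origins[ci] + cumsum(l)
      res[[ci]] <- data.frame(chrom = chroms[ci],
                              start = as.integer(c(origins[ci],
                                                   ends[-length(ends)])),
                              end = as.integer(ends),
                              state = lab[take],
                              stringsAsFactors = FALSE)
      base <- cum[take[length(take)]]
      pos <- take[length(take)] + 1L
      if (pos > n && ci < length(chroms)) {
        res <- res[seq_len(ci)]
        break
      }
    }
    out <- do.call(rbind, res)
  }
  state_annotation(out)
}

#' Permutation test of chromatin-state enrichment at contact sites
#'
#' Observed per-state site counts (50%-overlap assignment by default) are
#' compared with counts recomputed after repeatedly shuffling the
#' segmentation under the chosen scheme. Per state the add-one empirical
#' p-values for enrichment and depletion are reported together with a
#' two-proportion z test comparing the observed assignment proportion
#' against the pooled null proportion.
#'
#' @param sites data.frame of contact-site intervals.
#' @param states a \code{state_annotation}.
#' @param scheme shuffle scheme, see \code{\link{shuffle_states}}.
#' @param n_shuffles number of shuffles (default 10000).
#' @param min_overlap_fraction assignment rule (default 0.5).
#' @param seed integer RNG seed.
#' @return object of class \code{state_enrichment}: data.frame per state
#'   with observed count/proportion, null mean/sd proportion, empirical
#'   p (enrichment and depletion), z and two-sided normal p.
#' @export
state_enrichment <- function(sites, states, scheme = "label_shuffle",
                             n_shuffles = 10000L,
                             min_overlap_fraction = 0.5, seed = 1L) {
  n_sites <- nrow(sites)
  if (n_sites == 0L) stop("insufficient-data error: zero sites")
  obs <- assign_chromatin_state(sites, states, min_overlap_fraction)
  if (all(is.na(obs)))
    stop("insufficient-data error: zero assigned sites")
  count_of <- function(assign) vapply(1:9, function(k)
    sum(assign == k, na.rm = TRUE), integer(1))
  obs_counts <- count_of(obs)
  set.seed(seed)
  null_counts <- matrix(0L, n_shuffles, 9L)
  if (scheme == "label_shuffle") {
    # coordinates never change under label shuffling: compute the
    # site-segment overlap structure once, re-aggregate labels per shuffle
    hits <- GenomicRanges::findOverlaps(.ivl_gr(sites), .ivl_gr(states))
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    ovl <- pmin(sites$end[q], states$end[s]) - pmax(sites$start[q],
                                                    states$start[s])
    width <- sites$end - sites$start
    nseg <- nrow(states)
    for (i in seq_len(n_shuffles)) {
      lab <- states$state[sample.int(nseg)]
      null_counts[i, ] <- count_of(
        .state_assign_core(q, lab[s], ovl, width, n_sites,
                           min_overlap_fraction))
    }
  } else {
    for (i in seq_len(n_shuffles)) {
      sh <- shuffle_states(states, scheme)
      null_counts[i, ] <- count_of(
        assign_chromatin_state(sites, sh, min_overlap_fraction))
    }
  }
  p_enr <- (1 + colSums(null_counts >= rep(obs_counts, each = n_shuffles))) /
    (n_shuffles + 1)
  p_dep <- (1 + colSums(null_counts <= rep(obs_counts, each = n_shuffles))) /
    (n_shuffles + 1)
  p_obs <- obs_counts / n_sites
  p_null <- colSums(null_counts) / (n_shuffles * n_sites)
  n_null <- n_shuffles * n_sites
  pbar <- (obs_counts + colSums(null_counts)) / (n_sites + n_null)
  z <- (p_obs - p_null) /
    sqrt(pbar * (1 - pbar) * (1 / n_sites + 1 / n_null))
  z[!is.finite(z)] <- 0
  res <- data.frame(state = 1:9,
                    observed_count = obs_counts,
                    observed_proportion = p_obs,
                    null_mean_proportion = colMeans(null_counts) / n_sites,
                    null_sd_proportion = apply(null_counts, 2L,
                                               stats::sd) / n_sites,
                    empirical_p_enrichment = p_enr,
                    empirical_p_depletion = p_dep,
                    z = z,
                    p_proportions = 2 * stats::pnorm(-abs(z)))
  attr(res, "scheme") <- scheme
  attr(res, "n_shuffles") <- n_shuffles
  attr(res, "n_sites") <- n_sites
  class(res) <- c("state_enrichment", "data.frame")
  res
}

#' @export
print.state_enrichment <- function(x, ...) {
  cat(sprintf("chromatin-state enrichment (%s, %d shuffles, %d sites):\n",
              attr(x, "scheme"), attr(x, "n_shuffles"), attr(x, "n_sites")))
  print(as.data.frame(x), digits = 4)
  invisible(x)
}

#' Two-proportion z test
#'
#' Pooled-variance z statistic for the difference between two proportions,
#' with a two-sided normal p-value.
#'
#' @param x1,n1 successes and trials in group 1.
#' @param x2,n2 successes and trials in group 2.
#' @return list with z and p.
#' @export
proportions_z_test <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1; p2 <- x2 / n2
  pbar <- (x1 + x2) / (n1 + n2)
  z <- (p1 - p2) / sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}
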