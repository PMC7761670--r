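#' Median-of-ratios size factors
#'
#' Per-sample scaling constants: each sample's factor is the median, over
#' genes with an all-positive row, of that sample's count divided by the
#' gene's geometric mean across samples.
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @return positive numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("normalization error: no gene with all-positive counts")
  logg <- rowMeans(log(counts[pos, , drop = FALSE]))
  apply(counts[pos, , drop = FALSE], 2L,
        function(col) stats::median(exp(log(col) - logg)))
}

#' Method-of-moments negative-binomial dispersion
#'
#' Per gene, on size-factor-normalized counts pooled within each
#' condition: alpha_c = max(0, (s^2 - mean) / mean^2); the gene's
#' dispersion is the average of alpha_c over conditions with positive
#' mean. Genes with zero overall mean get alpha = 0 (they are untested
#' downstream). Variance is parameterized as mu + alpha * mu^2.
#'
#' @param counts genes x samples integer matrix.
#' @param sf per-sample size factors.
#' @param condition factor/character of length ncol(counts) with 2 levels.
#' @return per-gene dispersion vector (>= 0).
#' @export
estimate_dispersion <- function(counts, sf, condition) {
  norm <- sweep(as.matrix(counts), 2L, sf, "/")
  condition <- as.factor(condition)
  per_cond <- sapply(levels(condition), function(lv) {
    m <- norm[, condition == lv, drop = FALSE]
    mu <- rowMeans(m)
    v <- apply(m, 1L, stats::var)
    ifelse(mu > 0, pmax(0, (v - mu) / mu^2), NA_real_)
  })
  a <- rowMeans(as.matrix(per_cond), na.rm = TRUE)
  a[is.nan(a)] <- 0
  unname(a)
}

#' Negative-binomial Wald test for two-condition count tables
#'
#' The workhorse for differential 4C contact counts and for RNA-seq counts
#' restricted to a contact-gene list. Counts are normalized by
#' median-of-ratios size factors, per-gene dispersions are estimated by
#' method of moments, and for each gene a Wald statistic is formed for the
#' log2 fold change between the two conditions:
#' \deqn{log2FC = log2((\mu_2 + \epsilon) / (\mu_1 + \epsilon))}
#' with delta-method standard error
#' \deqn{se^2 = (1/\ln 2)^2 \sum_c (1/n_c) (1/(\mu_c+\epsilon) + \alpha)}
#' two-sided normal p-values and Benjamini-Hochberg adjustment over the
#' tested genes. All-zero genes are emitted untested with p = padj = 1 and
#' log2FC = 0.
#'
#' @param counts non-negative integer matrix, genes x samples (non-integer
#'   contact averages should be rounded half-up first, as
#'   \code{\link{gene_contact_counts}} does).
#' @param condition length-ncol factor with exactly 2 levels; the first
#'   level is the reference ("control").
#' @param pseudo pseudo-count epsilon for fold-change stability at zeros
#'   (default 0.5).
#' @param prior_df moderation strength for the dispersion: per-gene
#'   method-of-moments estimates are shrunk toward their across-gene mean
#'   with weight \code{df / (df + prior_df)} on the per-gene value, where
#'   df is the residual degrees of freedom. At the default 2v2 design the
#'   raw per-gene estimate has 2 df and is far too noisy for a calibrated
#'   Wald test; moderation keeps the type-I error near nominal. Set to 0
#'   for the raw per-gene estimates.
#' @return object of class \code{nb_diff}: a data.frame with gene_id,
#'   base_mean, log2fc, se, wald, p, padj, tested; ordered by padj.
#' @export
diff_counts <- function(counts, condition, pseudo = 0.5, prior_df = 10) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("validation error: counts must be non-negative integers")
  condition <- as.factor(condition)
  if (nlevels(condition) != 2L)
    stop("validation error: exactly 2 conditions required")
  if (any(table(condition) < 2L))
    stop("validation error: at least 2 replicates per condition required")
  sf <- size_factors(counts)
  alpha <- estimate_dispersion(counts, sf, condition)
  if (prior_df > 0) {
    df_resid <- ncol(counts) - 2L
    w <- df_resid / (df_resid + prior_df)
    alpha <- w * alpha + (1 - w) * mean(alpha)
  }
  norm <- sweep(counts, 2L, sf, "/")
  lv <- levels(condition)
  n1 <- sum(condition == lv[1L]); n2 <- sum(condition == lv[2L])
  mu1 <- rowMeans(norm[, condition == lv[1L], drop = FALSE])
  mu2 <- rowMeans(norm[, condition == lv[2L], drop = FALSE])
  base_mean <- rowMeans(norm)
  log2fc <- log2((mu2 + pseudo) / (mu1 + pseudo))
  se <- sqrt((1 / log(2))^2 *
               ((1 / n1) * (1 / (mu1 + pseudo) + alpha) +
                (1 / n2) * (1 / (mu2 + pseudo) + alpha)))
  wald <- log2fc / se
  p <- 2 * stats::pnorm(-abs(wald))
  tested <- base_mean > 0
  log2fc[!tested] <- 0; wald[!tested] <- 0; p[!tested] <- 1
  padj <- rep(1, length(p))
  padj[tested] <- stats::p.adjust(p[tested], method = "BH")
  res <- data.frame(gene_id = rownames(counts), base_mean = base_mean,
                    log2fc = log2fc, se = se, wald = wald, p = p,
                    padj = padj, tested = tested,
                    stringsAsFactors = FALSE)
  res <- res[order(res$padj, res$p, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "conditions") <- lv
  attr(res, "size_factors") <- sf
  attr(res, "pseudo") <- pseudo
  class(res) <- c("nb_diff", "data.frame")
  res
}

#' Classify differential records for a volcano plot
#'
#' @param records an \code{nb_diff} result (or compatible data.frame).
#' @param lfc_cut log2 fold-change cutoff (default 1).
#' @param padj_cut adjusted-p cutoff (default 0.05).
#' @return the table with an added \code{class} column ("up", "down",
#'   "ns"); per-class counts in \code{attr(, "class_counts")}.
#' @export
volcano_table <- function(records, lfc_cut = 1, padj_cut = 0.05) {
  cls <- ifelse(records$log2fc > lfc_cut & records$padj < padj_cut, "up",
                ifelse(records$log2fc < -lfc_cut & records$padj < padj_cut,
                       "down", "ns"))
  out <- as.data.frame(records)
  out$class <- cls
  attr(out, "class_counts") <- c(up = sum(cls == "up"),
                                 down = sum(cls == "down"),
                                 ns = sum(cls == "ns"))
  out
}

#' @export
print.nb_diff <- function(x, ...) {
  lv <- attr(x, "conditions")
  cat(sprintf("negative-binomial Wald test: %d genes (%d tested), %s vs %s\n",
              nrow(x), sum(x$tested), lv[2L], lv[1L]))
  print(utils::head(as.data.frame(x), 8L))
  invisible(x)
}

#' @method summary nb_diff
#' @export
summary.nb_diff <- function(object, lfc_cut = 1, padj_cut = 0.05, ...) {
  v <- volcano_table(object, lfc_cut, padj_cut)
  cc <- attr(v, "class_counts")
  cat(sprintf("tested genes: %d of %d\n", sum(object$tested), nrow(object)))
  cat(sprintf("at |log2FC| > %g and padj < %g: %d up, %d down\n",
              lfc_cut, padj_cut, cc[["up"]], cc[["down"]]))
  invisible(cc)
}

#' Volcano plot of a differential result
#'
#' @param x an \code{nb_diff} object.
#' @param lfc_cut,padj_cut significance cutoffs.
#' @param ... passed to \code{plot}.
#' @method plot nb_diff
#' @export
plot.nb_diff <- function(x, lfc_cut = 1, padj_cut = 0.05, ...) {
  v <- volcano_table(x, lfc_cut, padj_cut)
  col <- c(up = "firebrick", down = "steelblue", ns = "grey60")[v$class]
  graphics::plot(v$log2fc, -log10(pmax(v$padj, 1e-300)), col = col,
                 pch = 20, xlab = "log2 fold change",
                 ylab = "-log10 adjusted p", ...)
  graphics::abline(v = c(-lfc_cut, lfc_cut), h = -log10(padj_cut),
                   lty = 2, col = "grey40")
  invisible(v)
}
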