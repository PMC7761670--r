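test_that("median-of-ratios size factors match hand computation", {
  m <- matrix(c(100, 200, 10, 20, 50, 100), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  expect_equal(size_factors(m), c(s1 = 1 / sqrt(2), s2 = sqrt(2)),
               tolerance = 1e-10)
  one <- matrix(c(4, 1), 1, dimnames = list("g", c("a", "b")))
  expect_equal(size_factors(one), c(a = 2, b = 0.5))
  same <- matrix(rpois(40, 50) + 1, 10, 4)
  expect_equal(unname(size_factors(cbind(same[, 1], same[, 1]))), c(1, 1))
  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2, 2)),
               "normalization error")
})

test_that("method-of-moments dispersion recovers the truth in expectation", {
  cond <- factor(c("a", "a", "b", "b"))
  # zero variance -> zero dispersion
  const <- matrix(rep(c(5, 80, 200), each = 4), 3, 4, byrow = TRUE)
  expect_equal(estimate_dispersion(const, rep(1, 4), cond), c(0, 0, 0))
  set.seed(21)
  # Poisson counts: alpha near zero (the zero-floor keeps it positive)
  pois <- matrix(rpois(4000 * 4, 500), 4000, 4)
  a0 <- estimate_dispersion(pois, rep(1, 4), cond)
  expect_lt(mean(a0), 0.02)
  # NB alpha = 0.5
  nb <- matrix(rnbinom(1000 * 4, size = 2, mu = 500), 1000, 4)
  a5 <- estimate_dispersion(nb, rep(1, 4), cond)
  expect_gt(mean(a5), 0.3)
  expect_lt(mean(a5), 0.7)
  expect_gt(mean(a5), mean(a0))
})

test_that("Wald records behave at the null and under scaling", {
  cond <- factor(c("a", "a", "b", "b"))
  m <- matrix(rep(c(40L, 90L, 300L), each = 4), 3, 4, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:4)))
  d <- diff_counts(m, cond)
  expect_equal(d$log2fc, rep(0, 3))
  expect_equal(d$wald, rep(0, 3))
  expect_equal(d$p, rep(1, 3))
  # scaling one all-positive sample by c: the geometric-mean reference of
  # median-of-ratios absorbs c^(1/m), so the scaled sample's factor grows
  # by exactly c^((m-1)/m) and every sample's normalized counts scale by
  # the same c^(1/m), leaving fold changes essentially unchanged (the
  # pseudo-count introduces a sub-percent perturbation)
  set.seed(31)
  r <- matrix(rpois(200 * 4, 100) + 1L, 200, 4,
              dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:4)))
  d1 <- diff_counts(r, cond)
  r2 <- r; r2[, 2] <- r2[, 2] * 3L
  d2 <- diff_counts(r2, cond)
  expect_equal(attr(d2, "size_factors")[2] / attr(d1, "size_factors")[2],
               3^(3 / 4), tolerance = 1e-12, ignore_attr = TRUE)
  n1 <- sweep(r, 2, attr(d1, "size_factors"), "/")
  n2 <- sweep(r2, 2, attr(d2, "size_factors"), "/")
  expect_equal(n2, n1 * 3^(1 / 4), tolerance = 1e-12)
  expect_equal(d2$log2fc[order(d2$gene_id)], d1$log2fc[order(d1$gene_id)],
               tolerance = 0.01)
})

test_that("all-zero genes are emitted untested with p = padj = 1", {
  cond <- factor(c("a", "a", "b", "b"))
  m <- rbind(g0 = c(0L, 0L, 0L, 0L), g1 = c(10L, 12L, 50L, 60L),
             g2 = c(30L, 28L, 31L, 29L))
  colnames(m) <- paste0("s", 1:4)
  d <- diff_counts(m, cond)
  z <- d[d$gene_id == "g0", ]
  expect_false(z$tested)
  expect_equal(z$p, 1)
  expect_equal(z$padj, 1)
  expect_equal(z$log2fc, 0)
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  # hand-worked case: all adjusted values collapse to the largest
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(p.adjust(p, "BH"), rep(0.04, 4))
  expect_equal(bh_stepup(p), rep(0.04, 4))
  set.seed(77)
  for (i in 1:20) {
    pv <- runif(sample(5:60, 1))
    expect_equal(p.adjust(pv, "BH"), bh_stepup(pv))
  }
  # padj is never below p and is monotone in p-rank
  cond <- factor(c("a", "a", "b", "b"))
  m <- matrix(rnbinom(500 * 4, size = 8, mu = 150), 500, 4,
              dimnames = list(sprintf("g%03d", 1:500), paste0("s", 1:4)))
  d <- diff_counts(m, cond)
  expect_true(all(d$padj >= d$p - 1e-12))
  expect_true(all(diff(d$padj[order(d$p)]) >= -1e-12))
})

test_that("planted 4-fold changes are recovered at 2v2", {
  set.seed(55)
  nge <- 200   # planted genes
  nbg <- 800   # null background genes
  mu_bg <- exp(runif(nbg, log(50), log(2000)))
  mk <- function(mu) rnbinom(length(mu), size = 1 / 0.05, mu = mu)
  mu <- c(rep(500, nge), mu_bg)
  mu2 <- c(rep(2000, nge), mu_bg)
  counts <- cbind(mk(mu), mk(mu), mk(mu2), mk(mu2))
  rownames(counts) <- sprintf("g%04d", seq_len(nrow(counts)))
  colnames(counts) <- paste0("s", 1:4)
  d <- diff_counts(counts, factor(c("a", "a", "b", "b")))
  planted <- d[match(sprintf("g%04d", 1:nge), d$gene_id), ]
  expect_lt(abs(median(planted$log2fc) - 2), 0.3)
  expect_gt(mean(planted$padj < 0.05 & planted$log2fc > 0), 0.9)
})

test_that("volcano classification matches a direct filter", {
  set.seed(66)
  rec <- data.frame(gene_id = sprintf("g%03d", 1:300),
                    log2fc = rnorm(300, 0, 2),
                    padj = runif(300))
  v <- volcano_table(rec, lfc_cut = 1, padj_cut = 0.05)
  expect_equal(sum(v$class == "up"),
               sum(rec$log2fc > 1 & rec$padj < 0.05))
  expect_equal(sum(v$class == "down"),
               sum(rec$log2fc < -1 & rec$padj < 0.05))
  expect_equal(unname(attr(v, "class_counts")["ns"]),
               sum(!(abs(rec$log2fc) > 1 & rec$padj < 0.05)))
  allnull <- volcano_table(data.frame(gene_id = "g", log2fc = 5, padj = 1))
  expect_equal(unname(attr(allnull, "class_counts")[c("up", "down")]),
               c(0L, 0L))
})

test_that("counts must be non-negative integers with 2x2 design", {
  cond <- factor(c("a", "a", "b", "b"))
  expect_error(diff_counts(matrix(c(1.5, 2, 3, 4), 1), cond), "integer")
  expect_error(diff_counts(matrix(1:6, 2, 3),
                           factor(c("a", "a", "b"))), "2 replicates")
  expect_error(diff_counts(matrix(1:8, 2, 4),
                           factor(c("a", "b", "c", "a"))), "2 conditions")
})
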