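test_that("generators are deterministic under a fixed seed", {
  s1 <- simulate_annotation(genome_spec(seed = 9), 50, 30)
  s2 <- simulate_annotation(genome_spec(seed = 9), 50, 30)
  expect_identical(s1$genes$genes, s2$genes$genes)
  expect_identical(s1$repeats, s2$repeats)
  expect_identical(as.data.frame(s1$states), as.data.frame(s2$states))
  small <- list(n_retained = 10L, n_lost = 3L, n_gained = 3L,
                n_up = 3L, n_down = 3L)
  a <- simulate_contact_tracks(genome_spec(seed = 9), s1$genes, s1$repeats,
                               small)
  b <- simulate_contact_tracks(genome_spec(seed = 9), s2$genes, s2$repeats,
                               small)
  for (nm in names(a$tracks))
    expect_identical(as.data.frame(a$tracks[[nm]]),
                     as.data.frame(b$tracks[[nm]]))
})

test_that("simulated genes are pairwise disjoint and clear of the bait", {
  spec <- genome_spec(seed = 17)
  sim <- simulate_annotation(spec, n_genes = 200, n_repeats = 0)
  g <- sim$genes$genes
  expect_equal(nrow(g), 200L)
  for (ch in unique(g$chrom)) {
    gg <- g[g$chrom == ch, ]
    gg <- gg[order(gg$start), ]
    if (nrow(gg) > 1)
      expect_true(all(gg$start[-1] >= gg$end[-nrow(gg)]))
  }
  bait <- spec$bait
  on_bait <- g[g$chrom == bait$chrom, ]
  expect_true(all(on_bait$end <= bait$start))
  # exons and UTRs stay inside their gene body
  f <- sim$genes$features
  m <- match(f$gene_id, g$gene_id)
  expect_true(all(f$start >= g$start[m] & f$end <= g$end[m]))
})

test_that("state segmentation tiles every chromosome without gaps", {
  spec <- genome_spec(seed = 18)
  for (sim in list(simulate_annotation(spec, 50, 20),
                   simulate_annotation(spec, 0, 0))) {
    st <- sim$states
    for (ch in names(spec$chromosomes)) {
      seg <- st[st$chrom == ch, ]
      expect_equal(seg$start[1], 0L)
      expect_equal(seg$end[nrow(seg)],
                   as.integer(spec$chromosomes[[ch]]))
      if (nrow(seg) > 1)
        expect_equal(seg$start[-1], seg$end[-nrow(seg)])
    }
    expect_true(all(st$state %in% 1:9))
  }
  expect_equal(nrow(simulate_annotation(spec, 0, 0)$genes$genes), 0L)
})

test_that("an oversubscribed genome raises a capacity error", {
  tiny <- genome_spec(chromosomes = c(c1 = 30000L),
                      bait = list(chrom = "c1", start = 25000L,
                                  end = 30000L), seed = 1)
  expect_error(simulate_annotation(tiny, n_genes = 50, n_repeats = 0),
               "capacity error")
})

test_that("contact tracks respect track invariants and plant the manifest", {
  spec <- genome_spec(seed = 23)
  ann <- simulate_annotation(spec, 200, 150)
  sim <- simulate_contact_tracks(spec, ann$genes, ann$repeats)
  for (tr in sim$tracks) expect_true(validate_track(tr))
  truth <- sim$truth
  expect_true(all(truth$contact_genes$gene_id %in%
                    ann$genes$genes$gene_id))
  # decoys really are fully inside repeat records
  d <- truth$repeat_decoys
  for (i in seq_len(nrow(d))) {
    rr <- ann$repeats[ann$repeats$chrom == d$chrom[i], ]
    expect_true(any(d$start[i] >= rr$start & d$end[i] <= rr$end))
  }
  # planted sites sit within 2.5 kb of their gene body
  s <- truth$sites
  m <- match(s$gene_id, ann$genes$genes$gene_id)
  expect_true(all(s$start >= ann$genes$genes$start[m] - 2500 &
                    s$end <= ann$genes$genes$end[m] + 2500))
  expect_error(
    simulate_contact_tracks(spec, ann$genes, ann$repeats,
                            list(site_mean = -5)),
    "parameter error")
  expect_error(
    simulate_contact_tracks(spec, ann$genes, ann$repeats,
                            list(dispersion = -0.1)),
    "parameter error")
})

test_that("zero dispersion yields Poisson-like site counts", {
  spec <- genome_spec(seed = 29)
  ann <- simulate_annotation(spec, 200, 150)
  sim <- simulate_contact_tracks(spec, ann$genes, ann$repeats,
                                 list(dispersion = 0, latent_sdlog = 1e-9,
                                      n_background = 0,
                                      n_repeat_decoys = 0))
  tr <- sim$tracks$control_rep1
  v <- tr$value[tr$value > 50]   # the planted mean-200 sites
  # index of dispersion of Poisson(200) draws is ~1
  expect_lt(abs(var(v) / mean(v) - 1), 3 * sqrt(2 * 200 / length(v)) + 0.5)
})

test_that("expression counts carry the planted fold changes", {
  genes <- simulate_annotation(genome_spec(seed = 31), 300, 0)$genes
  # null: conditions exchangeable when no effect is planted
  e0 <- simulate_expression_counts(genes, NULL, n_reps = 2, seed = 5)
  expect_equal(dim(e0$counts), c(300L, 4L))
  m1 <- rowMeans(e0$counts[, 1:2]); m2 <- rowMeans(e0$counts[, 3:4])
  expect_lt(abs(mean(log2((m2 + 0.5) / (m1 + 0.5)))), 0.05)
  # planted log2FC = 2 at high mean: ratio of condition means near 4
  de <- data.frame(gene_id = genes$genes$gene_id[1:200], log2fc = 2)
  e2 <- simulate_expression_counts(genes, de, n_reps = 2,
                                   base_mean_range = c(500, 500), seed = 6)
  r <- rowMeans(e2$counts[1:200, 3:4]) / rowMeans(e2$counts[1:200, 1:2])
  expect_lt(abs(mean(r) - 4), 0.2)
  # library sizes scale a sample's counts
  e3 <- simulate_expression_counts(genes, NULL, n_reps = 2,
                                   library_sizes = c(1, 1, 1, 3), seed = 7)
  expect_gt(sum(e3$counts[, 4]) / sum(e3$counts[, 3]), 2)
  expect_error(simulate_expression_counts(genes, NULL, dispersion = -1),
               "parameter error")
})

test_that("NB moments match their specification at large n", {
  set.seed(37)
  for (alpha in c(0, 0.3)) {
    mu <- 50
    x <- if (alpha == 0) rpois(3000, mu) else
      rnbinom(3000, size = 1 / alpha, mu = mu)
    target_var <- mu + alpha * mu^2
    se_var <- sqrt(2 / 3000) * target_var * 1.8
    expect_lt(abs(mean(x) - mu), 3 * sqrt(target_var / 3000))
    expect_lt(abs(var(x) - target_var), 3 * se_var)
  }
})

test_that("signal tracks are baseline plus additive deterministic bumps", {
  spec <- genome_spec(chromosomes = c(c1 = 10000L),
                      bait = list(chrom = "c1", start = 9000L,
                                  end = 10000L), seed = 1)
  flat <- simulate_signal_track(spec, NULL, baseline = 2)
  expect_equal(unique(flat$value), 2)
  expect_equal(sum(flat$end - flat$start), 10000)
  one <- simulate_signal_track(spec,
                               data.frame(chrom = "c1", start = 4000L,
                                          end = 4150L),
                               baseline = 1, height = 10, width = 500)
  expect_equal(max(one$value), 11)
  # two overlapping bumps add on their shared span
  two <- simulate_signal_track(spec,
                               data.frame(chrom = "c1",
                                          start = c(4000L, 4200L),
                                          end = c(4150L, 4350L)),
                               baseline = 1, height = 10, width = 500)
  expect_equal(max(two$value), 21)
  # oracle: direct per-base summation
  base <- rep(1, 10000)
  for (mid in c(floor((4000 + 4150) / 2), floor((4200 + 4350) / 2))) {
    lo <- mid - 250; hi <- lo + 500
    base[(lo + 1):hi] <- base[(lo + 1):hi] + 10
  }
  dense <- rep(two$value, two$end - two$start)
  expect_equal(dense, base)
})

test_that("planted chromatin-state labels take over the site intervals", {
  spec <- genome_spec(seed = 41)
  ann <- simulate_annotation(spec, 100, 80)
  sim <- simulate_contact_tracks(spec, ann$genes, ann$repeats,
                                 list(n_retained = 30L, n_lost = 10L,
                                      n_gained = 10L, n_up = 10L,
                                      n_down = 10L))
  pl <- plant_state_enrichment(ann$states, sim$truth$sites, state = 1,
                               fraction = 0.7, seed = 3)
  st <- pl$states
  # tiling is preserved
  for (ch in names(spec$chromosomes)) {
    seg <- st[st$chrom == ch, ]
    expect_equal(seg$start[1], 0L)
    expect_equal(seg$end[nrow(seg)], as.integer(spec$chromosomes[[ch]]))
    if (nrow(seg) > 1) expect_equal(seg$start[-1], seg$end[-nrow(seg)])
  }
  got <- assign_chromatin_state(sim$truth$sites, st, 0.5)
  expect_equal(got, pl$planted)
  expect_equal(mean(pl$planted == 1), 0.7, tolerance = 0.02)
})
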