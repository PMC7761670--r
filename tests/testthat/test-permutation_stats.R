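test_that("overlap null degenerate and smoothing cases are exact", {
  u <- sprintf("id%03d", 1:40)
  ref <- u[1:10]
  # drawing the whole universe always overlaps the reference fully
  on <- overlap_null(u, ref, k = 40, n_shuffles = 50, seed = 1)
  expect_equal(on$mean, 10 / 40)
  expect_equal(on$sd, 0)
  # observed above every draw gets the add-one smoothed minimum p
  on2 <- overlap_null(u, ref, k = 5, n_shuffles = 100, seed = 2,
                      observed = ref[1:5])
  expect_equal(on2$observed, 1)
  expect_equal(on2$empirical_p, 1 / 101)
  expect_error(overlap_null(c("a", "a", "b"), "a", 1, 10), "duplicate")
  expect_error(overlap_null(u, ref, k = 41, n_shuffles = 10),
               "parameter error")
  expect_error(overlap_null(u, c(ref, "zzz"), 5, 10), "subset")
})

test_that("overlap null converges to the hypergeometric closed form", {
  set.seed(12)
  N <- 1000; K <- 60; k <- 50; n <- 4000
  u <- sprintf("id%04d", 1:N)
  ref <- sample(u, K)
  on <- overlap_null(u, ref, k = k, n_shuffles = n, seed = 13)
  hyper_mean <- k * K / N / k
  hyper_var <- k * (K / N) * (1 - K / N) * ((N - k) / (N - 1)) / k^2
  se_mean <- sqrt(hyper_var / n)
  expect_lt(abs(on$mean - hyper_mean), 3 * se_mean)
  se_sd <- sqrt(hyper_var) / sqrt(2 * (n - 1))
  expect_lt(abs(on$sd - sqrt(hyper_var)), 3 * se_sd)
})

test_that("label shuffling permutes labels over fixed coordinates", {
  set.seed(14)
  st <- random_states(c(c1 = 50000, c2 = 30000))
  sh <- shuffle_states(st, "label_shuffle", seed = 3)
  expect_equal(sh[, c("chrom", "start", "end")],
               as.data.frame(st)[, c("chrom", "start", "end")],
               ignore_attr = TRUE)
  expect_equal(sort(sh$state), sort(st$state))
})

test_that("segment shuffling reorders per-chromosome lengths", {
  two <- state_annotation(data.frame(
    chrom = "c1", start = c(0L, 10L), end = c(10L, 30L),
    state = c(1L, 2L)))
  seen <- character()
  for (s in 1:20) {
    sh <- shuffle_states(two, "segment_shuffle", seed = s)
    expect_equal(min(sh$start), 0L)
    expect_equal(max(sh$end), 30L)
    expect_setequal(paste(sh$end - sh$start, sh$state),
                    c("10 1", "20 2"))
    seen <- c(seen, paste(sh$state, collapse = ""))
  }
  # both orders occur across seeds
  expect_setequal(unique(seen), c("12", "21"))
})

test_that("each scheme preserves its stated structure", {
  set.seed(15)
  for (i in 1:10) {
    st <- random_states(c(c1 = 40000, c2 = 25000, c3 = 10000))
    key <- sort(paste(st$end - st$start, st$state))
    # (a) coordinates fixed, label multiset preserved
    sa <- shuffle_states(st, "label_shuffle")
    expect_equal(sa[, c("chrom", "start", "end")],
                 as.data.frame(st)[, c("chrom", "start", "end")],
                 ignore_attr = TRUE)
    expect_equal(sort(sa$state), sort(st$state))
    # (b) and (c) preserve the (length,label) multiset genome-wide,
    # hence also the total length per state
    for (scheme in c("segment_shuffle", "coord_and_state_shuffle")) {
      sh <- shuffle_states(st, scheme)
      expect_equal(sort(paste(sh$end - sh$start, sh$state)), key)
      for (k in unique(st$state))
        expect_equal(sum((sh$end - sh$start)[sh$state == k]),
                     sum((st$end - st$start)[st$state == k]))
    }
    # per-chromosome multiset under segment_shuffle
    sh2 <- shuffle_states(st, "segment_shuffle")
    for (ch in unique(st$chrom))
      expect_setequal(
        paste((sh2$end - sh2$start)[sh2$chrom == ch],
              sh2$state[sh2$chrom == ch]),
        paste((st$end - st$start)[st$chrom == ch],
              st$state[st$chrom == ch]))
  }
})

test_that("the two-proportion z statistic matches the direct formula", {
  out <- proportions_z_test(300, 1000, 2500, 10000)
  expect_equal(out$z, 3.461, tolerance = 1e-3)
  expect_equal(out$p, 2 * pnorm(-out$z))
})

test_that("enrichment p-values are add-one smoothed and never zero", {
  set.seed(16)
  st <- random_states(c(c1 = 60000))
  n <- 25
  s <- sort(sample.int(59000, n))
  sites <- data.frame(chrom = "c1", start = s, end = s + 150)
  enr <- state_enrichment(sites, st, "label_shuffle", n_shuffles = 99,
                          seed = 8)
  expect_true(all(enr$empirical_p_enrichment > 0))
  expect_true(all(enr$empirical_p_enrichment <= 1))
  expect_true(all(enr$empirical_p_enrichment >= 1 / 100))
  expect_equal(sum(enr$observed_count), sum(!is.na(
    assign_chromatin_state(sites, st, 0.5))))
  expect_error(state_enrichment(sites[0, ], st), "insufficient-data")
})

test_that("planted state enrichment is detected at the smoothed minimum p", {
  sim <- simulate_4c_experiment(seed = 1)
  enr <- state_enrichment(sim$truth$sites, sim$states, "label_shuffle",
                          n_shuffles = 500, seed = 2)
  expect_equal(enr$empirical_p_enrichment[1], 1 / 501)
  expect_gt(enr$observed_proportion[1], 0.5)
})
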