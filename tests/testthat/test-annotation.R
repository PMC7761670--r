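test_that("feature classification follows midpoint + priority rules", {
  gs <- tiny_gene_set()
  reps <- data.frame(chrom = "chr1", start = c(14100L, 50000L),
                     end = c(14600L, 51000L),
                     repeat_class = c("LTR", "other"),
                     stringsAsFactors = FALSE)
  site <- function(chrom, s, e) data.frame(chrom = chrom, start = s, end = e)
  cls <- function(df) as.character(annotate_feature(df, gs, reps))
  # 500 bp upstream of gA's + strand TSS (10000) is promoter territory
  expect_equal(cls(site("chr1", 9400, 9600)), "promoter")
  # gB is - strand: its TSS is the gene end (36000)
  expect_equal(cls(site("chr1", 36300, 36500)), "promoter")
  # and gB's TTS window sits at the gene start
  expect_equal(cls(site("chr1", 29400, 29600)), "TTS")
  # midpoint in an exon that also lies in an LTR: exon wins by priority
  expect_equal(cls(site("chr1", 14200, 14400)), "exon")
  # in the gene body but outside exons/UTRs
  expect_equal(cls(site("chr1", 12000, 12200)), "intron")
  expect_equal(cls(site("chr1", 10050, 10150)), "utr5")
  # inside gA's 3' UTR but upstream of the TTS window (which would win)
  expect_equal(cls(site("chr1", 15800, 15880)), "utr3")
  expect_equal(cls(site("chr1", 50200, 50400)), "repeat_other")
  expect_equal(cls(site("chr1", 70000, 70200)), "intergenic")
})

test_that("every site gets exactly one feature class", {
  set.seed(88)
  gs <- tiny_gene_set()
  reps <- data.frame(chrom = sample(c("chr1", "chr2"), 10, TRUE),
                     start = s <- sample.int(80000, 10),
                     end = s + 800,
                     repeat_class = sample(c("LTR", "LINE"), 10, TRUE))
  n <- 200
  st <- sample.int(90000, n)
  sites <- data.frame(chrom = sample(c("chr1", "chr2"), n, TRUE),
                      start = st, end = st + 150)
  f <- annotate_feature(sites, gs, reps)
  expect_equal(length(f), n)
  expect_false(any(is.na(f)))
})

test_that("state assignment applies the 50% rule with documented ties", {
  states <- state_annotation(data.frame(
    chrom = "chr1", start = c(0L, 40L), end = c(40L, 200L),
    state = c(7L, 3L)))
  site <- data.frame(chrom = "chr1", start = 0L, end = 100L)
  # 60 of 100 bases in state 3
  expect_equal(assign_chromatin_state(site, states, 0.5), 3L)
  half <- state_annotation(data.frame(
    chrom = "chr1", start = c(0L, 50L), end = c(50L, 100L),
    state = c(7L, 2L)))
  # exact 50/50 split: both qualify at 0.5, tie goes to the lower label
  expect_equal(assign_chromatin_state(site, half, 0.5), 2L)
  # at fraction 1.0 only fully contained sites are assigned
  expect_true(is.na(assign_chromatin_state(site, half, 1)))
  inside <- data.frame(chrom = "chr1", start = 55L, end = 95L)
  expect_equal(assign_chromatin_state(inside, half, 1), 2L)
})

test_that("overlap accumulates across segments of the same state", {
  states <- state_annotation(data.frame(
    chrom = "chr1", start = c(0L, 30L, 60L), end = c(30L, 60L, 100L),
    state = c(4L, 9L, 4L)))
  site <- data.frame(chrom = "chr1", start = 0L, end = 100L)
  # state 4 covers 30 + 40 = 70 bases
  expect_equal(assign_chromatin_state(site, states, 0.5), 4L)
})

test_that("state assignment matches the per-base oracle on random inputs", {
  set.seed(99)
  sizes <- c(chr1 = 30000, chr2 = 20000)
  for (i in 1:15) {
    states <- random_states(sizes, min_len = 300, max_len = 5000)
    n <- 40
    ch <- sample(names(sizes), n, TRUE)
    s <- floor(runif(n) * (unlist(sizes)[ch] - 200))
    sites <- data.frame(chrom = ch, start = as.integer(s),
                        end = as.integer(s + sample(50:200, n, TRUE)))
    for (frac in c(0.3, 0.5, 1)) {
      expect_equal(assign_chromatin_state(sites, states, frac),
                   oracle_assign_state(sites, states, frac, sizes))
    }
  }
})

test_that("state and feature distributions aggregate their classifiers", {
  states <- state_annotation(data.frame(
    chrom = "chr1", start = 0L, end = 10000L, state = 5L))
  sites <- data.frame(chrom = "chr1", start = c(100L, 500L, 900L),
                      end = c(250L, 650L, 1050L))
  sd <- state_distribution(sites, states)
  expect_equal(sd$proportion[sd$state == 5], 1)
  expect_equal(sum(sd$count), 3L)
  empty <- state_distribution(sites[0, ], states)
  expect_equal(sum(empty$count), 0L)
  expect_equal(attr(empty, "n_sites"), 0L)

  fd <- feature_distribution(sites, tiny_gene_set(), NULL)
  expect_equal(sum(fd$count), 3L)
  expect_equal(sum(fd$proportion), 1)
})

test_that("per-chromosome counts tally the selected genes", {
  gs <- tiny_gene_set()
  out <- per_chromosome_counts(c("gA", "gC"), gs)
  expect_equal(out$count[out$chrom == "chr1"], 1L)
  expect_equal(out$count[out$chrom == "chr2"], 1L)
})
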