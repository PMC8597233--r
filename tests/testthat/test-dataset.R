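test_that("promoter windows sit immediately upstream of the TSS on each strand", {
  g <- genome_sequence(setNames(strrep("A", 2000), "c1"))
  plus <- promoter_intervals(genomic_intervals("c1", 1000, 1001, "+"), g)
  expect_identical(plus$start, 960L)
  expect_identical(plus$end, 1000L)
  expect_identical(plus$strand, "+")
  minus <- promoter_intervals(genomic_intervals("c1", 1000, 1001, "-"), g)
  expect_identical(minus$start, 1001L)
  expect_identical(minus$end, 1041L)
  expect_identical(minus$strand, "-")
  expect_warning(
    dropped <- promoter_intervals(genomic_intervals("c1", 10, 11, "+"), g),
    "dropped")
  expect_identical(nrow(dropped), 0L)
})

test_that("extracted promoter sequences read 5'->3' toward the TSS", {
  # genome with a marker right before a plus TSS and after a minus TSS
  set.seed(9)
  body <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  g <- genome_sequence(setNames(body, "c"))
  tss <- genomic_intervals("c", c(100, 150), c(101, 151), c("+", "-"))
  pr <- promoter_intervals(tss, g)
  seqs <- fetch_sequence(g, pr)
  expect_identical(seqs[1], substr(body, 61, 100))
  expect_identical(seqs[2], reverse_complement(substr(body, 152, 191)))
  expect_identical(nchar(seqs), c(40L, 40L))
})

test_that("exact-duplicate intervals collapse to first occurrences in order", {
  a <- genomic_intervals("c1", 0, 10, "+")
  b <- genomic_intervals("c1", 5, 15, "-")
  both <- rbind(a, a, b, a)
  dd <- deduplicate_intervals(both)
  expect_identical(nrow(dd), 2L)
  expect_identical(dd$start, c(0L, 5L))
  empty <- a[0, ]
  expect_identical(nrow(deduplicate_intervals(empty)), 0L)
  set.seed(2)
  distinct <- genomic_intervals("c1", seq(0, 990, 10), seq(5, 995, 10), "+")
  expect_identical(deduplicate_intervals(distinct), distinct)
})

test_that("negative sampling avoids excluded intervals and is reproducible", {
  sim <- simulate_genome(length = 1e6, n_promoters = 100, seed = 13)
  neg <- sample_negative_intervals(sim$genome, 5000, exclude = sim$truth,
                                   seed = 31)
  expect_identical(nrow(neg), 5000L)
  expect_true(all(neg$end - neg$start == 40L))
  # all-pairs overlap oracle: no negative shares a base with any positive
  n_overlaps <- 0L
  for (j in seq_len(nrow(sim$truth))) {
    ov <- pmin(neg$end, sim$truth$end[j]) - pmax(neg$start, sim$truth$start[j])
    n_overlaps <- n_overlaps + sum(neg$chrom == sim$truth$chrom[j] & ov > 0)
  }
  expect_identical(n_overlaps, 0L)
  expect_identical(sample_negative_intervals(sim$genome, 50,
                                             exclude = sim$truth, seed = 31),
                   sample_negative_intervals(sim$genome, 50,
                                             exclude = sim$truth, seed = 31))
  none <- sample_negative_intervals(sim$genome, 0, seed = 1)
  expect_identical(nrow(none), 0L)
})

test_that("dataset assembly honours the declared class ratio exactly", {
  sim <- simulate_genome(length = 2e5, n_promoters = 100, seed = 17)
  ds <- build_dataset(sim$genome, sim$tss, neg_per_pos = 10, seed = 23)
  expect_identical(nrow(ds), 1100L)
  expect_identical(as.vector(table(ds$label)), c(1000L, 100L))
  expect_identical(attr(ds, "neg_per_pos"), 10L)
  expect_true(all(nchar(ds$sequence) == 40L))

  balanced <- build_dataset(sim$genome, sim$tss, neg_per_pos = 1, seed = 23)
  expect_identical(as.vector(table(balanced$label)), c(100L, 100L))

  # duplicated TSS rows collapse before sampling
  dup_tss <- rbind(sim$tss, sim$tss[1:20, ])
  ds2 <- build_dataset(sim$genome, dup_tss, neg_per_pos = 2, seed = 5)
  expect_identical(sum(ds2$label == 1L), 100L)
})

test_that("positive sequences equal strand-consistent re-extraction", {
  sim <- simulate_genome(length = 2e5, n_promoters = 60, seed = 29)
  ds <- build_dataset(sim$genome, sim$tss, neg_per_pos = 2, seed = 7)
  pos <- ds[ds$label == 1L, ]
  refetched <- fetch_sequence(sim$genome,
                              genomic_intervals(pos$chrom, pos$start,
                                                pos$end, pos$strand))
  expect_identical(pos$sequence, refetched)
})

test_that("train/test split is stratified, disjoint and reproducible", {
  sim <- simulate_genome(length = 2e5, n_promoters = 100, seed = 17)
  ds <- build_dataset(sim$genome, sim$tss, neg_per_pos = 10, seed = 23)
  sp <- split_train_test(ds, 0.25, seed = 41)
  expect_identical(sum(sp$test$label == 1L), 25L)
  expect_identical(sum(sp$test$label == 0L), 250L)
  expect_identical(nrow(sp$train) + nrow(sp$test), nrow(ds))
  key <- function(d) paste(d$chrom, d$start, d$strand, d$label)
  expect_length(intersect(key(sp$train), key(sp$test)), 0L)
  expect_setequal(c(key(sp$train), key(sp$test)), key(ds))
  sp2 <- split_train_test(ds, 0.25, seed = 41)
  expect_identical(sp, sp2)

  tiny <- data.frame(sequence = random_sequences(4), label = c(1L, 1L, 0L, 0L))
  sp3 <- split_train_test(tiny, 0.5, seed = 1)
  expect_identical(as.vector(table(sp3$test$label)), c(1L, 1L))
  expect_error(split_train_test(tiny[c(1, 3, 4), ], 0.5, seed = 1),
               "at least 2")
})

test_that("dataset TSV round-trips through write/read", {
  sim <- simulate_genome(length = 1e5, n_promoters = 20, seed = 3)
  ds <- build_dataset(sim$genome, sim$tss, neg_per_pos = 2, seed = 3)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_dataset(ds, tsv)
  back <- read_dataset(tsv)
  expect_identical(back$sequence, ds$sequence)
  expect_identical(back$label, ds$label)
})
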