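test_that("dereplication groups exact sequences and conserves reads", {
  reads <- read_df(c("ACGTACGT", "ACGTACGT", "ACGTACGT", "TTTTTTTT"),
                   samples = c("s1", "s1", "s2", "s2"))
  dr <- dereplicate(reads)
  expect_equal(dr$uniques$size, c(3L, 1L))
  expect_equal(dr$uniques$sequence[1], "ACGTACGT")
  expect_equal(sum(dr$uniques$size), nrow(reads))
  expect_equal(unname(rowSums(dr$counts)), dr$uniques$size)
  expect_equal(dr$counts[1, c("s1", "s2")], c(s1 = 2L, s2 = 1L))
})

test_that("dereplication orders by size with lexicographic ties", {
  reads <- read_df(c("TTTT", "AAAA", "CCCC", "CCCC"), samples = "s1")
  dr <- dereplicate(reads)
  expect_equal(dr$uniques$sequence, c("CCCC", "AAAA", "TTTT"))
})

test_that("two-parent concatenations are flagged as chimeras", {
  pa <- strrep("A", 100)
  pb <- strrep("C", 100)
  chim <- paste0(strrep("A", 50), strrep("C", 50))
  reads <- read_df(c(rep(pa, 20), rep(pb, 20), rep(chim, 2)), samples = "s1")
  dr <- dereplicate(reads)
  flags <- detect_chimeras(dr)
  expect_equal(flags, c(FALSE, FALSE, TRUE))
  cleaned <- drop_chimeras(dr, flags)
  expect_equal(attr(cleaned, "removed_reads"), 2L)
  expect_equal(nrow(cleaned$uniques), 2L)
})

test_that("parents and near-copies of parents are not flagged", {
  pa <- strrep("AG", 50)
  pb <- strrep("CT", 50)
  near_pa <- paste0("T", substr(pa, 2, 100))  # 1 mismatch to parent A
  reads <- read_df(c(rep(pa, 20), rep(pb, 20), rep(near_pa, 2)),
                   samples = "s1")
  flags <- detect_chimeras(dereplicate(reads))
  expect_false(any(flags[1:2]))
  expect_false(flags[3])   # single-parent model already near-perfect
})

test_that("greedy clustering joins by identity and conserves counts", {
  reads <- read_df(c(rep(strrep("ACGT", 25), 10),
                     rep(paste0("T", substr(strrep("ACGT", 25), 2, 100)), 3),
                     rep(strrep("GGCA", 25), 5)),
                   samples = c(rep("s1", 13), rep("s2", 5)))
  dr <- dereplicate(reads)
  mt <- greedy_cluster(dr, 95)
  expect_equal(nrow(mt$counts), 2L)       # 99%-similar variant joins its parent
  expect_equal(sum(mt$counts), nrow(reads))
  expect_equal(sort(unname(mt$motus$total), decreasing = TRUE), c(13L, 5L))
  mt97 <- greedy_cluster(dr, 100)
  expect_equal(nrow(mt97$counts), 3L)     # at 100% the variant founds its own
})

test_that("species ten percent apart stay separate at the 95% level", {
  a <- strrep("ACGTACGTAC", 10)
  b <- paste0(strrep("T", 10), substr(a, 11, 100))   # 10% divergent
  dr <- dereplicate(read_df(c(rep(a, 5), rep(b, 4)), samples = "s1"))
  expect_equal(nrow(greedy_cluster(dr, 95)$counts), 2L)
  expect_equal(nrow(greedy_cluster(dr, 85)$counts), 1L)
})

test_that("lulu merges co-occurring low-abundance daughters into parents", {
  a <- strrep("ACGT", 25)
  daughter <- paste0("TTT", substr(a, 4, 100))       # 97% similar to a
  b <- strrep("GGCA", 25)
  counts <- c(rep(a, 50), rep(daughter, 5), rep(b, 30))
  samples <- c(rep("s1", 25), rep("s2", 25), rep("s1", 3), rep("s2", 2),
               rep("s3", 30))
  mt <- greedy_cluster(dereplicate(read_df(counts, samples = samples)), 99)
  expect_equal(nrow(mt$counts), 3L)
  cur <- lulu_curate(mt)
  expect_equal(nrow(cur$counts), 2L)
  expect_equal(sum(cur$counts), sum(mt$counts))      # reads conserved
  expect_equal(nrow(cur$merge_map), 1L)
  # idempotent
  again <- lulu_curate(cur)
  expect_equal(again$counts, cur$counts)
})

test_that("a daughter with low co-occurrence is retained", {
  a <- strrep("ACGT", 25)
  daughter <- paste0("TTT", substr(a, 4, 100))
  seqs <- c(rep(a, 40), rep(daughter, 4))
  # daughter present in s3/s4 where the parent is absent
  samples <- c(rep(c("s1", "s2"), 20), "s1", "s3", "s4", "s4")
  mt <- greedy_cluster(dereplicate(read_df(seqs, samples = samples)), 99)
  cur <- lulu_curate(mt)
  expect_equal(nrow(cur$counts), nrow(mt$counts))
})

test_that("curation shrinks error clouds toward the true species count", {
  p <- tiny_params(substitution_error_rate = 0.01, n_sites = 6L,
                   reads_per_site = c(COI = 300L, `18S` = 100L), seed = 31)
  db <- simulate_reference_db(p, "COI")
  comm <- simulate_communities(p)
  rr <- simulate_reads(comm, db, p, "COI")
  dr <- dereplicate(rr$reads)
  dr <- drop_chimeras(dr, detect_chimeras(dr))
  mt <- greedy_cluster(dr, 97)
  cur <- lulu_curate(mt)
  n_true <- sum(rowSums(comm$abundance) > 0)
  expect_lte(nrow(cur$counts), nrow(mt$counts))
  expect_lte(abs(nrow(cur$counts) - n_true) / n_true, 0.1)
  expect_gt(nrow(mt$counts) - n_true, 0)   # uncurated overestimates
  expect_equal(sum(cur$counts), sum(dr$uniques$size))
})
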