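test_that("percent identity matches hand alignments", {
  expect_equal(percent_identity("ACGT", "ACGT"), 1.0)
  expect_equal(percent_identity("ACGT", "ACGA"), 0.75)
  # one terminal gap column: 3 matches / 4 columns
  expect_equal(percent_identity("ACGT", "ACG"), 0.75)
  expect_equal(percent_identity("ACG", "ACGT"), 0.75)
  expect_error(percent_identity("", "ACGT"), "empty")
})

test_that("identity is symmetric on random sequence pairs", {
  set.seed(1)
  for (i in 1:10) {
    a <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(25:30, 1), TRUE),
               collapse = "")
    expect_equal(percent_identity(a, b), percent_identity(b, a))
  }
})

test_that("hit search returns references above the threshold", {
  db <- hand_refdb()
  hits <- search_hits(db$sequences[["A1"]], db, 0.97)
  expect_equal(hits$accession, "A1")
  expect_equal(hits$identity, 1.0)
  none <- search_hits(db$sequences[["A1"]], db, 0.95)
  expect_equal(none$accession, "A1")     # A2 at 0.90 excluded
  all4 <- search_hits(db$sequences[["A1"]], db, 0.5)
  expect_setequal(all4$accession, c("A1", "A2", "B1", "B2"))
})

test_that("accelerated k-mer search equals the brute-force full scan", {
  p <- tiny_params(substitution_error_rate = 0.02, seed = 13)
  db <- simulate_reference_db(p, "COI")
  comm <- simulate_communities(p)
  rr <- simulate_reads(comm, db, p, "COI")
  reads <- rr$reads$sequence[1:40]
  for (t in c(0.99, 0.95, 0.90)) {
    for (s in reads[seq(1, 40, by = 8)]) {
      expect_identical(search_hits(s, db, t, method = "kmer"),
                       search_hits(s, db, t, method = "full"))
    }
  }
})

test_that("naive LCA descends to the deepest shared rank", {
  db <- hand_refdb()
  tax <- db$taxonomy
  one <- naive_lca(data.frame(accession = "A1"), tax)
  expect_equal(one$name, "GenA sp1")
  expect_equal(one$rank, "species")
  genus <- naive_lca(data.frame(accession = c("A1", "A2")), tax)
  expect_equal(genus$name, "GenA")
  expect_equal(genus$rank, "genus")
  expect_false(genus$conflict)
  cross <- naive_lca(data.frame(accession = c("A1", "B1")), tax)
  expect_equal(cross$name, "Metazoa")
  expect_equal(cross$rank, "kingdom")
  expect_true(cross$conflict)
  expect_equal(naive_lca(data.frame(accession = character()), tax)$n_hits, 0L)
  expect_error(naive_lca(data.frame(accession = "nope"), tax),
               "without lineage")
})

test_that("zero-error reads are assigned to their true species", {
  p <- tiny_params(seed = 21)
  db <- simulate_reference_db(p, "COI")
  comm <- simulate_communities(p)
  rr <- simulate_reads(comm, db, p, "COI")
  asg <- assign_dataset(rr$reads, db, 95)
  tr <- merge(asg$assignments, rr$truth, by = "id")
  expect_equal(asg$n_unassigned, 0L)
  expect_true(all(tr$taxon.x == tr$taxon.y))
  expect_equal(sum(asg$matrix), nrow(rr$reads))
})

test_that("threshold 100 leaves reads with errors unassigned", {
  db <- hand_refdb()
  seqs <- vapply(db$sequences[db$taxonomy$metazoan], function(s) {
    v <- strsplit(s, "")[[1]]
    v[5] <- setdiff(c("A", "C", "G", "T"), v[5])[1]
    paste(v, collapse = "")
  }, character(1))
  asg <- assign_dataset(read_df(unname(seqs)), db, 100)
  expect_equal(asg$n_unassigned, length(seqs))
})

test_that("assignments nest: higher threshold gives descendant-or-equal node", {
  p <- tiny_params(substitution_error_rate = 0.03, seed = 8)
  db <- simulate_reference_db(p, "COI")
  comm <- simulate_communities(p)
  rr <- simulate_reads(comm, db, p, "COI")
  a90 <- assign_dataset(rr$reads, db, 90)$assignments
  a97 <- assign_dataset(rr$reads, db, 97)$assignments
  both <- !is.na(a90$taxon) & !is.na(a97$taxon)
  depth <- function(r) match(r, TAX_RANKS)
  expect_true(all(depth(a97$rank[both]) >= depth(a90$rank[both])))
})

test_that("sweep counts are monotone and conflict-free at high thresholds", {
  p <- tiny_params(seed = 5)
  db <- simulate_reference_db(p, "COI")
  comm <- simulate_communities(p)
  rr <- simulate_reads(comm, db, p, "COI")
  sw <- threshold_sweep(rr$reads, db, t_max = 100, t_min = 60)
  expect_true(all(diff(sw$cumulative_assigned) >= 0))   # decreasing thresholds
  expect_equal(sw$cumulative_assigned[sw$threshold == 100], nrow(rr$reads))
  # zero-error reads on a 30%-diverged DB: no conflicts until deep thresholds
  expect_true(all(sw$phylum_conflicts[sw$threshold >= 75] == 0))
  expect_error(threshold_sweep(rr$reads, db, t_max = 90, t_min = 95), "below")
})

test_that("phylum cutoff is the lowest conflict-free threshold", {
  sw <- data.frame(threshold = seq(100, 80),
                   cumulative_assigned = seq(10, 210, by = 10),
                   newly_assigned = 10,
                   phylum_conflicts = ifelse(seq(100, 80) <= 85, 3L, 0L))
  class(sw) <- c("sweep_result", "data.frame")
  expect_equal(phylum_cutoff(sw), 86)
  sw$phylum_conflicts <- 0L
  expect_equal(phylum_cutoff(sw), 80)     # no conflicts anywhere -> t_min
  sw$phylum_conflicts <- 1L
  expect_error(phylum_cutoff(sw), "t_max")
})

test_that("metazoan filter removes contaminants and partitions the input", {
  p <- tiny_params(contaminant_fraction = 0.2, seed = 17)
  db <- simulate_reference_db(p, "COI")
  comm <- simulate_communities(p)
  rr <- simulate_reads(comm, db, p, "COI")
  mz <- metazoan_filter(rr$reads, db, 80)
  expect_equal(nrow(mz$retained) + nrow(mz$removed), nrow(rr$reads))
  tr <- rr$truth
  cont <- tr$id[tr$is_contaminant]
  expect_true(all(cont %in% mz$removed$id))
  expect_true(all(tr$id[!tr$is_contaminant] %in% mz$retained$id))
})

test_that("assignment categories follow checklist, NIS and congener rules", {
  cl <- data.frame(taxon = c("Calanus helgolandicus", "Acartia clausi",
                             "Pseudodiaptomus marinus"),
                   status = c("indigenous", "indigenous", "NIS"),
                   key = tolower(c("Calanus helgolandicus", "Acartia clausi",
                                   "Pseudodiaptomus marinus")),
                   stringsAsFactors = FALSE)
  cats <- categorize_assignments(
    c("Calanus helgolandicus",      # on checklist
      "Pseudodiaptomus marinus",    # NIS beats PRESENT
      "Calanus finmarchicus",       # congener present
      "Diaixis hibernica"),         # nothing related
    cl)
  expect_equal(unname(cats),
               c("PRESENT", "NIS", "PLAUSIBLE_MISID", "ERRONEOUS"))
  expect_warning(categorize_assignments("", cl), "unparsable")
})

test_that("erroneous and singleton rows are removed", {
  m <- matrix(c(1L, 0L,  2L, 0L,  500L, 0L,  3L, 4L), nrow = 4, byrow = TRUE,
              dimnames = list(c("single", "pair", "bad", "good"),
                              c("s1", "s2")))
  cats <- c(single = "PRESENT", pair = "PRESENT", bad = "ERRONEOUS",
            good = "PRESENT")
  out <- remove_singletons_and_erroneous(m, cats)
  expect_setequal(rownames(out), c("pair", "good"))
  expect_error(remove_singletons_and_erroneous(m, cats[-1]), "missing")
})
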