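test_that("reference database has the constructed species and phylum counts", {
  p <- tiny_params()
  db <- simulate_reference_db(p, "COI")
  met <- db$taxonomy[db$taxonomy$metazoan, ]
  expect_equal(length(unique(met$species)), 6L)
  expect_equal(length(unique(met$phylum)), 2L)
  expect_equal(nrow(met), 6L * p$refs_per_species)
  expect_true(all(nchar(db$sequences) == p$marker_lengths[["COI"]]))
  # complete lineages at every rank
  expect_false(any(db$taxonomy[TAX_RANKS] == "" | is.na(db$taxonomy[TAX_RANKS])))
  # outgroup present and non-metazoan
  expect_true(any(!db$taxonomy$metazoan))
})

test_that("realized pairwise divergences match the requested rates", {
  p <- sim_params(n_phyla = 3, species_per_phylum = 4,
                  marker_lengths = c(COI = 300L, `18S` = 138L), seed = 42)
  db <- simulate_reference_db(p, "COI")
  met <- db$taxonomy$accession[db$taxonomy$metazoan]
  im <- zoopipe:::identity_matrix(db$sequences[met], db$sequences[met])
  ph <- db$taxonomy$phylum[match(met, db$taxonomy$accession)]
  sp <- db$taxonomy$species[match(met, db$taxonomy$accession)]
  d_cross_ph <- mean(1 - im[outer(ph, ph, "!=")])
  d_cross_sp <- mean(1 - im[outer(ph, ph, "==") & outer(sp, sp, "!=")])
  d_intra <- mean(1 - im[outer(sp, sp, "==") & !diag(length(met))])
  expect_lt(abs(d_cross_ph - p$inter_phylum_divergence), 0.05)
  expect_lt(abs(d_cross_sp - p$inter_species_divergence), 0.05)
  expect_lt(abs(d_intra - p$intra_species_divergence), 0.05)
})

test_that("generator outputs are deterministic in the seed", {
  p <- tiny_params(seed = 9)
  expect_identical(simulate_reference_db(p, "COI"),
                   simulate_reference_db(p, "COI"))
  expect_identical(simulate_communities(p), simulate_communities(p))
  db <- simulate_reference_db(p, "COI")
  comm <- simulate_communities(p)
  expect_identical(simulate_reads(comm, db, p, "COI"),
                   simulate_reads(comm, db, p, "COI"))
  p2 <- tiny_params(seed = 10)
  expect_false(identical(simulate_reference_db(p2, "COI"), db))
})

test_that("length too short to realize divergences is a parameter error", {
  p <- tiny_params()
  p$marker_lengths <- c(COI = 50L, `18S` = 50L)
  p$n_phyla <- 10L
  expect_error(simulate_reference_db(p, "COI"), "too short")
})

test_that("gradient strength 1 yields disjoint class compositions", {
  p <- tiny_params(gradient_strength = 1)
  comm <- simulate_communities(p)
  coastal <- names(comm$site_class)[comm$site_class == "coastal"]
  offshore <- names(comm$site_class)[comm$site_class == "offshore"]
  d <- bray_curtis(comm$abundance[, c(coastal[1], offshore[1])],
                   sqrt_standardize = TRUE)
  expect_equal(as.numeric(d), 1.0)
})

test_that("zero gradient leaves no systematic class difference", {
  p <- tiny_params(gradient_strength = 0, n_sites = 200L, seed = 3)
  comm <- simulate_communities(p)
  cls <- comm$site_class
  mu_c <- rowMeans(comm$abundance[, cls == "coastal"])
  mu_o <- rowMeans(comm$abundance[, cls == "offshore"])
  # aggregate composition indistinguishable; per-taxon ratios only noisy
  expect_lt(abs(log(mean(mu_c) / mean(mu_o))), 0.2)
  expect_lt(max(abs(log((mu_c + 1) / (mu_o + 1)))), 1.0)
})

test_that("n_sites below 2 is a parameter error", {
  expect_error(simulate_communities(tiny_params(n_sites = 1L)), "2 sites")
})

test_that("error-free reads match references exactly and respect totals", {
  p <- tiny_params(seed = 4)
  db <- simulate_reference_db(p, "COI")
  comm <- simulate_communities(p)
  rr <- simulate_reads(comm, db, p, "COI")
  expect_true(all(rr$reads$sequence %in% db$sequences))
  expect_equal(unname(table(rr$reads$sample)[colnames(comm$abundance)]),
               rep(p$reads_per_site[["COI"]], p$n_sites),
               ignore_attr = TRUE)
  # truth covers every read with consistent taxa
  expect_setequal(rr$reads$id, rr$truth$id)
  normal <- rr$truth[!rr$truth$is_chimera & !rr$truth$is_contaminant, ]
  expect_true(all(normal$taxon %in% db$taxonomy$species))
})

test_that("chimera fraction is honored within binomial tolerance", {
  p <- tiny_params(chimera_fraction = 0.1, n_sites = 4L,
                   reads_per_site = c(COI = 250L, `18S` = 100L), seed = 6)
  db <- simulate_reference_db(p, "COI")
  comm <- simulate_communities(p)
  rr <- simulate_reads(comm, db, p, "COI")
  n <- nrow(rr$truth)
  n_chim <- sum(rr$truth$is_chimera)
  expect_gt(n_chim, 0.1 * n - 3 * sqrt(0.1 * 0.9 * n))
  expect_lt(n_chim, 0.1 * n + 3 * sqrt(0.1 * 0.9 * n))
})

test_that("marker dropouts produce zero reads for that marker only", {
  p <- tiny_params(dropout_samples = list(COI = character(), `18S` = "st03"))
  db18 <- simulate_reference_db(p, "18S")
  dbco <- simulate_reference_db(p, "COI")
  comm <- simulate_communities(p)
  r18 <- simulate_reads(comm, db18, p, "18S")
  rco <- simulate_reads(comm, dbco, p, "COI")
  expect_false("st03" %in% r18$reads$sample)
  expect_gt(sum(rco$reads$sample == "st03"), 0)
})

test_that("morphological records follow the detection probabilities", {
  p <- tiny_params(n_sites = 40L, seed = 2)
  comm <- simulate_communities(p)
  support <- sum(comm$abundance > 0)
  all_seen <- simulate_morph_records(comm, 1, seed = 1)
  expect_equal(nrow(all_seen), support)
  expect_equal(nrow(simulate_morph_records(comm, 0, seed = 1)), 0L)
  half <- simulate_morph_records(comm, 0.5, seed = 1)
  expect_gt(nrow(half), 0.5 * support - 3 * sqrt(0.25 * support))
  expect_lt(nrow(half), 0.5 * support + 3 * sqrt(0.25 * support))
  expect_error(simulate_morph_records(comm, 1.5, seed = 1), "\\[0, 1\\]")
})

test_that("multiplexed reads carry tag plus primer prefixes", {
  p <- tiny_params()
  db <- simulate_reference_db(p, "COI")
  comm <- simulate_communities(p)
  rr <- simulate_reads(comm, db, p, "COI")
  tags <- setNames(c("AAAAAAAAAA", "CCCCCCCCCC", "GGGGGGGGGG", "TTTTTTTTTT"),
                   sort(unique(rr$reads$sample)))
  pooled <- multiplex_reads(rr$reads, tags, "ACGTACGT")
  expect_equal(nchar(pooled$sequence),
               nchar(rr$reads$sequence) + 10L + 8L)
  expect_equal(nchar(pooled$quality), nchar(pooled$sequence))
  expect_true(all(substr(pooled$sequence, 1L, 10L) ==
                    tags[rr$reads$sample]))
})
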