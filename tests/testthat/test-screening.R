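mk_mat <- function(rows, samples, vals) {
  matrix(as.integer(vals), nrow = length(rows), byrow = TRUE,
         dimnames = list(rows, samples))
}

test_that("NIS screening reports the highest supported stringency", {
  taxa <- c("Common sp", "Pseudodiaptomus marinus")
  m90 <- mk_mat(taxa, c("s1", "s2", "s3"), c(50, 60, 70, 5, 3, 0))
  m95 <- mk_mat(taxa, c("s1", "s2", "s3"), c(40, 50, 60, 4, 2, 0))
  m97 <- mk_mat(taxa, c("s1", "s2", "s3"), c(30, 40, 50, 2, 1, 0))
  mats <- list("90" = m90, "95" = m95, "97" = m97)
  out <- nis_screen(mats, "Pseudodiaptomus marinus")
  expect_equal(nrow(out), 1L)
  expect_equal(out$highest_threshold, 97)
  expect_equal(out$n_samples, 2L)
  expect_equal(out$samples, "s1,s2")
  # taxa not on the NIS list are never reported
  expect_equal(nrow(nis_screen(mats, "Common other")), 0L)
})

test_that("detection at a high threshold implies detection below it", {
  taxa <- c("Nis sp")
  mats <- list("90" = mk_mat(taxa, "s1", 8),
               "95" = mk_mat(taxa, "s1", 5),
               "97" = mk_mat(taxa, "s1", 2))
  out <- nis_screen(mats, "Nis sp")
  expect_equal(out$highest_threshold, 97)
  for (t in c("90", "95")) {
    expect_gt(sum(mats[[t]]["Nis sp", ]), 0)
  }
})

test_that("planted NIS signal is recovered from simulated assignments", {
  p <- tiny_params(seed = 23)
  db <- simulate_reference_db(p, "COI")
  comm <- simulate_communities(p)
  rr <- simulate_reads(comm, db, p, "COI")
  nis_taxon <- rownames(comm$abundance)[1]
  mats <- lapply(c("90" = 90, "95" = 95, "97" = 97), function(t)
    assign_dataset(rr$reads, db, t)$matrix)
  out <- nis_screen(mats, nis_taxon)
  expect_equal(out$highest_threshold, 97)
  truth_sites <- colnames(comm$abundance)[comm$abundance[nis_taxon, ] > 0]
  got_sites <- strsplit(out$samples, ",")[[1]]
  expect_true(all(got_sites %in% truth_sites))
})

test_that("relative abundances divide by sample totals and sum to one", {
  m <- mk_mat(c("a", "b"), c("s1", "s2"), c(5, 15, 45, 285))
  expect_equal(site_relative_abundance(m, "a"),
               c(s1 = 0.10, s2 = 0.05))
  expect_equal(site_relative_abundance(m, "a") +
                 site_relative_abundance(m, "b"),
               c(s1 = 1, s2 = 1))
  solo <- mk_mat("a", c("s1", "s2"), c(9, 0))
  expect_equal(site_relative_abundance(solo, "a"), c(s1 = 1, s2 = NA_real_))
  expect_error(site_relative_abundance(m, "zz"), "not in matrix")
})

test_that("reconciliation classifies and percentages records", {
  morph <- data.frame(sample = c("s1", "s1", "s2"),
                      taxon = c("Alpha sp", "Beta sp", "Alpha sp"),
                      stringsAsFactors = FALSE)
  mol <- data.frame(sample = c("s1", "s1", "s2"),
                    taxon = c("Alpha sp", "Gamma sp", "Alpha sp"),
                    method = c("COI", "18S", "COI"), stringsAsFactors = FALSE)
  out <- reconcile(morph, mol)
  expect_equal(out$total, 4L)
  s <- setNames(out$summary$pct, out$summary$category)
  expect_equal(unname(s["both"]), 50)
  expect_equal(unname(s["morph_only"]), 25)
  expect_equal(unname(s["molecular_only"]), 25)
  expect_equal(sum(out$summary$n[1:3]), out$total)

  # identical / disjoint record sets
  same <- reconcile(morph, cbind(morph, method = "COI"))
  expect_equal(same$summary$pct[same$summary$category == "both"], 100)
  disj <- reconcile(morph, data.frame(sample = "s9", taxon = "Zeta sp",
                                      method = "COI"))
  expect_equal(disj$summary$n[disj$summary$category == "both"], 0L)
  bad <- data.frame(sample = "s1", taxon = "A b", method = "microscope")
  expect_error(reconcile(morph, bad), "unknown method")
})

test_that("reconciliation sub-splits follow the expert flags", {
  morph <- data.frame(sample = "s1", taxon = c("Alpha sp", "Beta sp"))
  mol <- data.frame(sample = "s1", taxon = c("Alpha sp", "Gamma sp"),
                    method = "COI")
  flags <- data.frame(taxon = c("Alpha sp", "Beta sp", "Gamma sp"),
                      reference_available = c(TRUE, TRUE, FALSE),
                      morph_recognizable = c(TRUE, FALSE, TRUE))
  out <- reconcile(morph, mol, flags)
  s <- setNames(out$summary$n, out$summary$category)
  expect_equal(unname(s["morph_only_reference_available"]), 1L)
  expect_equal(unname(s["molecular_only_morph_recognizable"]), 1L)
})

test_that("individuals per cubic metre follow the volume arithmetic", {
  md <- list(net_area = 0.25, haul_depth = 20)
  expect_equal(abundance_per_m3(100, 5 / 200, md), 800)
  expect_equal(abundance_per_m3(0, 0.5, md), 0)
  expect_equal(abundance_per_m3(10, 1, md), 10 / (0.25 * 20))
  expect_error(abundance_per_m3(10, 0, md), "subsample_fraction")
  expect_error(abundance_per_m3(10, 0.5, list(net_area = 0, haul_depth = 20)),
               "volume")
})
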