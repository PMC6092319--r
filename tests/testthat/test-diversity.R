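test_that("Chao1 matches hand-computed values and dominates S_obs", {
  expect_equal(chao1_richness(c(5, 5, 5)), 3)
  expect_equal(chao1_richness(c(1, 1, 2, 2)), 5)     # 4 + 4/4
  expect_equal(chao1_richness(c(1, 1, 3)), 3 + 2 * 1 / 2)  # bias-corrected
  set.seed(1)
  for (i in 1:20) {
    x <- rpois(30, 2)
    if (sum(x) == 0) next
    expect_gte(chao1_richness(x), sum(x > 0))
  }
  expect_error(chao1_richness(c(0, 0)), "empty")
})

test_that("Gini-Simpson estimator matches closed forms and bounds", {
  expect_equal(gini_simpson(c(7)), 0)
  expect_equal(gini_simpson(c(2, 2)), 1 - 4 / 12)
  expect_error(gini_simpson(c(1)), "at least 2")
  set.seed(2)
  for (i in 1:20) {
    x <- rpois(20, 3) + 1
    g <- gini_simpson(x)
    expect_gte(g, 0); expect_lt(g, 1)
  }
  # perfectly even large community: -> 1 - 1/S
  x <- rep(20000, 5)
  expect_lt(abs(gini_simpson(x) - (1 - 1 / 5)), 1e-3)
})

test_that("rarefaction interpolation matches exhaustive enumeration", {
  counts <- c(4, 2, 1, 1)
  n <- sum(counts)
  reads <- rep(seq_along(counts), counts)
  subsets <- utils::combn(n, 4)
  brute <- mean(apply(subsets, 2, function(ix) length(unique(reads[ix]))))
  expect_equal(rarefy_extrapolate(counts, 4), brute)
})

test_that("rarefaction endpoints, monotonicity and concavity hold", {
  counts <- c(10, 5, 3, 1, 1)
  n <- sum(counts)
  expect_equal(rarefy_extrapolate(counts, n), sum(counts > 0))
  expect_equal(rarefy_extrapolate(counts, 1), 1)
  curve <- rarefy_extrapolate(counts, seq_len(2 * n))
  expect_true(all(diff(curve) > -1e-12))
  interp <- curve[seq_len(n)]
  expect_true(all(diff(diff(interp)) < 1e-12))   # concave on the interpolated arm
  expect_error(rarefy_extrapolate(counts, 0), ">= 1")
})

test_that("bootstrap intervals are reproducible and degenerate correctly", {
  one <- bootstrap_ci(c(50), chao1_richness, n_boot = 50, seed = 7)
  expect_equal(one$se, 0)
  a <- bootstrap_ci(c(4, 3, 2, 1, 1), chao1_richness, n_boot = 100, seed = 3)
  b <- bootstrap_ci(c(4, 3, 2, 1, 1), chao1_richness, n_boot = 100, seed = 3)
  expect_identical(a, b)
  expect_true(a$lower <= a$estimate && a$estimate <= a$upper)
})

test_that("bootstrap CI width shrinks with sample size", {
  set.seed(11)
  p <- rep(1 / 20, 20)
  small <- rmultinom(1, 100, p)[, 1]
  big <- rmultinom(1, 10000, p)[, 1]
  ci_s <- bootstrap_ci(small, gini_simpson, n_boot = 100, seed = 5)
  ci_b <- bootstrap_ci(big, gini_simpson, n_boot = 100, seed = 5)
  expect_lt(ci_b$se, ci_s$se)
})

test_that("Bray-Curtis on sqrt counts has the expected extremes", {
  m <- matrix(c(4L, 4L, 0L,
                0L, 4L, 4L), nrow = 2, byrow = TRUE,
              dimnames = list(c("t1", "t2"), c("a", "b", "c")))
  d <- as.matrix(bray_curtis(m))
  expect_equal(d["b", "b"], 0)
  expect_equal(d["a", "c"], 1)      # disjoint samples
  expect_equal(d, t(d))
  m0 <- cbind(m, d = c(0L, 0L))
  expect_error(bray_curtis(m0), "all-zero")
})

test_that("NMDS reaches near-zero stress on embeddable distances", {
  d3 <- stats::as.dist(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3))
  fit <- suppressWarnings(nmds(d3, k = 2, n_starts = 5, seed = 2))
  expect_lt(fit$stress, 1e-6)
  set.seed(4)
  xy <- matrix(rnorm(16), ncol = 2)
  fit2 <- suppressWarnings(nmds(stats::dist(xy), k = 2, n_starts = 10, seed = 2))
  expect_lt(fit2$stress, 0.01)
  expect_error(nmds(d3, k = 3), "below the number")
})

test_that("Ward clustering separates constructed groups deterministically", {
  m <- cbind(matrix(c(50L, 45L, 55L, 0L, 0L, 0L), 6, 3),
             matrix(c(0L, 0L, 0L, 50L, 52L, 48L), 6, 3))
  rownames(m) <- paste0("t", 1:6)
  colnames(m) <- c(paste0("g1_", 1:3), paste0("g2_", 1:3))
  h <- ward_cluster(bray_curtis(m))
  expect_true(all(diff(h$height) >= -1e-12))
  top <- stats::cutree(h, 2)
  expect_equal(length(unique(top[1:3])), 1L)
  expect_equal(length(unique(top[4:6])), 1L)
  expect_false(top[1] == top[4])
  h2 <- ward_cluster(stats::as.dist(matrix(c(0, 1, 1, 0), 2)))
  expect_equal(nrow(h2$merge), 1L)
})

test_that("node support is high for designed splits and exact at the root", {
  set.seed(9)
  m <- rbind(matrix(rpois(6 * 4, 60), 6, 4), matrix(0L, 6, 4))
  m <- cbind(m, rbind(matrix(0L, 6, 4), matrix(rpois(6 * 4, 60), 6, 4)))
  rownames(m) <- paste0("t", 1:12)
  colnames(m) <- c(paste0("a", 1:4), paste0("b", 1:4))
  ns <- node_support(m, n_boot = 100, seed = 5)
  root <- ns$support[ns$support$members == paste(sort(colnames(m)),
                                                 collapse = ","), ]
  expect_equal(root$bp, 1)
  ga <- ns$support[ns$support$members == paste(sort(paste0("a", 1:4)),
                                               collapse = ","), ]
  expect_gte(ga$bp, 0.95)
  expect_true(all(ns$support$bp >= 0 & ns$support$bp <= 1))
  expect_true(all(ns$support$au >= 0 & ns$support$au <= 1))
  ns2 <- node_support(m, n_boot = 100, seed = 5)
  expect_identical(ns$support, ns2$support)
})

test_that("SIMPER contributions decompose the mean between-group distance", {
  m1 <- matrix(c(4L, 0L, 0L, 4L), 2, dimnames = list(c("t1", "t2"),
                                                     c("x", "y")))
  sr <- simper(m1, c(x = "g1", y = "g2"))
  expect_equal(sr[[1]]$overall, 1.0)
  expect_equal(sort(sr[[1]]$contrib$average), c(0.5, 0.5))
  expect_equal(max(sr[[1]]$contrib$cum_pct), 100)

  # identical groups: zero everywhere
  m2 <- cbind(m1, x2 = m1[, "x"], y2 = m1[, "y"])
  sr2 <- simper(m2[, c("x", "x2")], c(x = "g1", x2 = "g2"))
  expect_equal(sr2[[1]]$overall, 0)

  # random matrices: sum of contributions == mean pairwise Bray-Curtis
  set.seed(6)
  for (i in 1:5) {
    m <- matrix(rpois(8 * 6, 5), 8, 6,
                dimnames = list(paste0("t", 1:8), paste0("s", 1:6)))
    m[1, ] <- m[1, ] + 1         # avoid all-zero samples
    g <- rep(c("g1", "g2"), each = 3)
    sr <- simper(m, setNames(g, colnames(m)))
    d <- as.matrix(bray_curtis(m))
    expect_equal(sr[[1]]$overall, mean(d[1:3, 4:6]), tolerance = 1e-12)
  }
})

test_that("SIMPER agrees with the vegan reference implementation", {
  set.seed(8)
  m <- matrix(rpois(10 * 8, 4) + 1, 10, 8,
              dimnames = list(paste0("t", 1:10), paste0("s", 1:8)))
  g <- rep(c("g1", "g2"), each = 4)
  mine <- simper(m, setNames(g, colnames(m)))
  ref <- vegan::simper(t(sqrt(m)), g, permutations = 0)
  ref_avg <- ref[[1]]$average
  expect_equal(mine[[1]]$contrib$average[match(names(ref_avg),
                                               mine[[1]]$contrib$taxon)],
               unname(ref_avg), tolerance = 1e-10)
})
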