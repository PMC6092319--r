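# Alpha diversity: Hill numbers q = 0 (richness, Chao1 asymptote with
# size-based rarefaction/extrapolation) and q = 2 (Gini-Simpson, minimum-
# variance unbiased estimator), with bootstrap standard errors from the
# bootstrap-augmented community. Beta diversity: Bray-Curtis on square-root
# transformed counts, NMDS, Ward clustering with multiscale-bootstrap node
# support (BP and AU), and a SIMPER decomposition whose per-taxon
# contributions sum exactly to the mean between-group dissimilarity.

# Frequency summaries of one sample's count vector.
count_summary <- function(counts) {
  counts <- counts[counts > 0]
  list(n = sum(counts), S_obs = length(counts),
       f1 = sum(counts == 1), f2 = sum(counts == 2))
}

#' Chao1 asymptotic richness
#'
#' `S_obs + f1^2 / (2 f2)` when doubletons exist, else the bias-corrected
#' form `S_obs + f1 (f1 - 1) / 2`.
#'
#' @param counts non-negative integer abundance vector for one sample.
#' @return asymptotic richness estimate (>= observed richness).
#' @export
chao1_richness <- function(counts) {
  cs <- count_summary(counts)
  if (cs$n < 1) stop("empty sample")
  if (cs$f2 > 0) cs$S_obs + cs$f1^2 / (2 * cs$f2)
  else cs$S_obs + cs$f1 * (cs$f1 - 1) / 2
}

#' Gini-Simpson diversity (minimum-variance unbiased estimator)
#'
#' `1 - sum x_i (x_i - 1) / (n (n - 1))`, the unbiased estimator of
#' `1 - sum p_i^2`.
#'
#' @param counts non-negative integer abundance vector, total >= 2.
#' @return estimate in [0, 1).
#' @export
gini_simpson <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop("Gini-Simpson needs at least 2 individuals")
  1 - sum(counts * (counts - 1)) / (n * (n - 1))
}

#' Expected richness under rarefaction and extrapolation
#'
#' For `m <= n` the exact hypergeometric interpolation
#' `S(m) = S_obs - sum_i C(n - x_i, m) / C(n, m)`; for `m > n` the Chao1-
#' based extrapolation
#' `S(n + m*) = S_obs + f0 [1 - (1 - f1 / (n f0 + f1))^{m*}]` with
#' `f0 = chao1 - S_obs`. The curve passes through `S(n) = S_obs`.
#'
#' @param counts abundance vector for one sample.
#' @param sizes vector of target sample sizes (>= 1).
#' @return numeric vector of expected richness values, one per size.
#' @export
rarefy_extrapolate <- function(counts, sizes) {
  if (any(sizes < 1)) stop("sizes must be >= 1")
  x <- counts[counts > 0]
  n <- sum(x)
  S <- length(x)
  f1 <- sum(x == 1)
  f0 <- chao1_richness(counts) - S
  vapply(sizes, function(m) {
    if (m <= n) {
      S - sum(exp(lchoose(n - x, m) - lchoose(n, m)))
    } else if (f1 == 0 || f0 == 0) {
      S
    } else {
      S + f0 * (1 - (1 - f1 / (n * f0 + f1))^(m - n))
    }
  }, numeric(1))
}

#' Bootstrap standard error and 95% CI for an alpha-diversity estimator
#'
#' Resamples `n` reads multinomially from the bootstrap-augmented community:
#' observed taxa keep their frequencies scaled by the Turing coverage
#' estimate `1 - f1/n`, and `ceiling(f0)` unseen taxa share the remaining
#' probability mass equally. CI = estimate +/- 1.96 SE.
#'
#' @param counts abundance vector for one sample.
#' @param estimator function of a count vector (e.g. [chao1_richness()]).
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @return list: `estimate`, `se`, `lower`, `upper`.
#' @export
bootstrap_ci <- function(counts, estimator, n_boot = 200, seed = 1) {
  x <- counts[counts > 0]
  n <- sum(x)
  est <- estimator(x)
  f1 <- sum(x == 1)
  f0 <- max(0, ceiling(chao1_richness(x) - length(x)))
  unseen_mass <- if (f0 > 0) f1 / n else 0
  p <- c(x / n * (1 - unseen_mass), rep(unseen_mass / max(f0, 1), f0))
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      estimator(stats::rmultinom(1L, n, p)[, 1L])
    }, numeric(1))
  })
  se <- stats::sd(boots)
  list(estimate = est, se = se,
       lower = est - 1.96 * se, upper = est + 1.96 * se)
}

#' Hill-number diversity estimate for one sample
#'
#' Order q = 0 (richness: observed, Chao1 asymptote, extrapolation to a
#' reference size) or q = 2 (Gini-Simpson: observed plug-in and unbiased
#' asymptotic estimate, which also serves as the extrapolated value).
#'
#' @param counts abundance vector for one sample.
#' @param q Hill order, 0 or 2.
#' @param m_ref reference size for extrapolation (default: sample total).
#' @param n_boot,seed bootstrap settings for the SE/CI.
#' @return data.frame with q, observed, asymptote, extrapolated, se, lower,
#'   upper.
#' @export
hill_estimate <- function(counts, q, m_ref = NULL, n_boot = 200, seed = 1) {
  x <- counts[counts > 0]
  if (is.null(m_ref)) m_ref <- sum(x)
  if (q == 0) {
    obs <- length(x)
    bc <- bootstrap_ci(x, chao1_richness, n_boot, seed)
    extr <- rarefy_extrapolate(x, m_ref)
  } else if (q == 2) {
    obs <- 1 - sum((x / sum(x))^2)
    bc <- bootstrap_ci(x, gini_simpson, n_boot, seed)
    extr <- bc$estimate
  } else {
    stop("q must be 0 or 2")
  }
  data.frame(q = q, observed = obs, asymptote = bc$estimate,
             extrapolated = extr, se = bc$se, lower = bc$lower,
             upper = bc$upper)
}

#' Bray-Curtis dissimilarities with square-root standardization
#'
#' Applies a per-cell square root (no row/column renormalization), then
#' Bray-Curtis between samples.
#'
#' @param m taxa x samples count matrix (>= 2 samples, no all-zero sample).
#' @param sqrt_standardize apply the square-root transform first.
#' @return `dist` object over samples.
#' @export
bray_curtis <- function(m, sqrt_standardize = TRUE) {
  if (ncol(m) < 2L) stop("need at least 2 samples")
  zero <- colSums(m) == 0
  if (any(zero)) {
    stop("all-zero sample(s): ", paste(colnames(m)[zero], collapse = ", "))
  }
  x <- if (sqrt_standardize) sqrt(m) else m
  vegan::vegdist(t(x), method = "bray")
}

#' Non-metric multidimensional scaling of a distance matrix
#'
#' Kruskal stress-1 minimization (vegan's monoMDS engine) with multiple
#' random starts; the best solution and its stress are returned.
#'
#' @param d `dist` object (>= 3 samples).
#' @param k embedding dimension (< number of samples).
#' @param n_starts random starts.
#' @param seed integer seed.
#' @return list: `points` (samples x k coordinates), `stress` (0-1 scale).
#' @export
nmds <- function(d, k = 2, n_starts = 20, seed = 1) {
  n <- attr(d, "Size")
  if (is.null(n) || n < 3L) stop("need at least 3 samples")
  if (k >= n) stop("k must be below the number of samples")
  fit <- with_seed(seed, {
    vegan::metaMDS(d, k = k, try = n_starts, trymax = n_starts,
                   autotransform = FALSE, wascores = FALSE, trace = 0)
  })
  list(points = fit$points, stress = fit$stress)
}

#' Ward hierarchical clustering of samples
#'
#' Agglomerative Ward linkage on squared dissimilarities (Lance-Williams
#' update; `hclust` method `ward.D2`).
#'
#' @param d `dist` object.
#' @return `hclust` tree.
#' @export
ward_cluster <- function(d) {
  stats::hclust(d, method = "ward.D2")
}

# Sample-membership set of every internal node of an hclust tree, as a
# sorted comma-joined label string.
node_sets <- function(h) {
  n <- length(h$labels)
  members <- vector("list", nrow(h$merge))
  for (i in seq_len(nrow(h$merge))) {
    pick <- function(j) if (j < 0) h$labels[-j] else members[[j]]
    members[[i]] <- sort(c(pick(h$merge[i, 1L]), pick(h$merge[i, 2L])))
  }
  vapply(members, paste, character(1), collapse = ",")
}

#' Bootstrap node support for the Ward tree (BP and AU)
#'
#' Taxa (rows) are resampled with replacement at relative scales 0.5-1.4;
#' per node, BP is the fraction of scale-1 replicate trees containing the
#' node's sample set, and the approximately-unbiased (AU) value comes from
#' the multiscale z-regression `qnorm(1 - BP_r) = v*sqrt(r) + c/sqrt(r)`
#' (signal v, curvature c), AU = `1 - pnorm(v - c)`. Nodes with degenerate replicate frequencies
#' across scales fall back to BP with a warning.
#'
#' @param m taxa x samples count matrix (>= 3 samples, >= 2 taxa).
#' @param n_boot replicates per scale.
#' @param seed integer seed.
#' @param scales relative resampling sizes.
#' @return list: `tree` (hclust on the full data), `support` (data.frame
#'   node, members, bp, au).
#' @export
node_support <- function(m, n_boot = 1000, seed = 1,
                         scales = seq(0.5, 1.4, by = 0.1)) {
  if (nrow(m) < 2L) stop("need at least 2 taxa for bootstrap support")
  if (ncol(m) < 3L) stop("need at least 3 samples")
  tree <- ward_cluster(bray_curtis(m))
  sets <- node_sets(tree)
  nt <- nrow(m)
  count <- matrix(0L, length(sets), length(scales))
  with_seed(seed, {
    for (si in seq_along(scales)) {
      nr <- max(2L, round(scales[si] * nt))
      for (b in seq_len(n_boot)) {
        for (try in 1:100) {
          idx <- sample.int(nt, nr, replace = TRUE)
          if (all(colSums(m[idx, , drop = FALSE]) > 0)) break
        }
        bt <- ward_cluster(bray_curtis(m[idx, , drop = FALSE]))
        count[, si] <- count[, si] + (sets %in% node_sets(bt))
      }
    }
  })
  bp_all <- count / n_boot
  r1 <- which.min(abs(scales - 1))
  au <- numeric(length(sets))
  fell_back <- FALSE
  for (i in seq_along(sets)) {
    nd <- which(count[i, ] > 0L & count[i, ] < n_boot)  # non-degenerate scales
    if (length(nd) < 3L || length(unique(round(bp_all[i, nd], 6))) < 2L) {
      au[i] <- bp_all[i, r1]
      if (bp_all[i, r1] > 0 && bp_all[i, r1] < 1 && length(nd) >= 1L) {
        fell_back <- TRUE
      }
      next
    }
    bp <- bp_all[i, nd]
    psi <- stats::qnorm(1 - bp)
    X <- cbind(sqrt(scales[nd]), 1 / sqrt(scales[nd]))
    w <- n_boot * stats::dnorm(psi)^2 / (bp * (1 - bp))
    fit <- tryCatch(stats::lm.wfit(X, psi, w), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) {
      au[i] <- bp_all[i, r1]
      fell_back <- TRUE
    } else {
      au[i] <- 1 - stats::pnorm(fit$coefficients[1L] - fit$coefficients[2L])
    }
  }
  if (fell_back) {
    warning("AU z-regression ill-conditioned for some node(s); using BP")
  }
  list(tree = tree,
       support = data.frame(node = seq_along(sets), members = sets,
                            bp = bp_all[, r1], au = au,
                            stringsAsFactors = FALSE))
}

#' SIMPER: per-taxon contributions to between-group dissimilarity
#'
#' For every between-group sample pair, the per-taxon Bray-Curtis term
#' `|x_i - y_i| / sum_k (x_k + y_k)` (on square-root transformed counts when
#' `sqrt_standardize`); a taxon's contribution is its mean term over pairs,
#' and contributions sum exactly to the mean between-group Bray-Curtis
#' dissimilarity.
#'
#' @param m taxa x samples count matrix.
#' @param groups named character vector sample -> group label (or vector
#'   aligned with `colnames(m)`), exactly two groups per comparison.
#' @param sqrt_standardize apply the square-root transform (same convention
#'   as [bray_curtis()]).
#' @return list of class `simper_result`, one element per group pair:
#'   `contrib` (data.frame taxon, average, contrib_pct, cum_pct, ranked by
#'   contribution) and `overall` (mean between-group dissimilarity).
#' @export
simper <- function(m, groups, sqrt_standardize = TRUE) {
  if (is.null(names(groups))) {
    stopifnot(length(groups) == ncol(m))
    groups <- stats::setNames(as.character(groups), colnames(m))
  }
  groups <- groups[colnames(m)]
  if (anyNA(groups)) stop("group label missing for some sample(s)")
  gl <- unique(groups)
  if (any(table(groups) == 0L)) stop("empty group")
  x <- if (sqrt_standardize) sqrt(m) else m
  pairs <- utils::combn(gl, 2L, simplify = FALSE)
  out <- lapply(pairs, function(pr) {
    s1 <- which(groups == pr[1L]); s2 <- which(groups == pr[2L])
    acc <- numeric(nrow(m))
    npair <- 0L
    for (i in s1) for (j in s2) {
      denom <- sum(x[, i] + x[, j])
      if (denom == 0) stop("pair of all-zero samples")
      acc <- acc + abs(x[, i] - x[, j]) / denom
      npair <- npair + 1L
    }
    avg <- acc / npair
    overall <- sum(avg)
    ord <- order(-avg, rownames(m))
    contrib <- data.frame(taxon = rownames(m)[ord], average = avg[ord],
                          contrib_pct = if (overall > 0) 100 * avg[ord] / overall
                                        else 0,
                          stringsAsFactors = FALSE)
    contrib$cum_pct <- cumsum(contrib$contrib_pct)
    list(groups = pr, contrib = contrib, overall = overall)
  })
  names(out) <- vapply(pairs, paste, character(1), collapse = "_vs_")
  structure(out, class = "simper_result")
}
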