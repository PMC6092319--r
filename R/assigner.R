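# Similarity-search + naive-LCA taxonomic assignment. Identity is defined by
# global alignment (match +1, mismatch -1, gap -2) as matches / alignment
# columns; under this scoring the optimal alignment of two equal-length
# sequences is gap-free, so equal-length pairs take an exact Hamming fast
# path. A read's assignment at threshold t is the lowest common ancestor of
# all references with identity >= t ("naive" LCA, no top-percent window by
# default). The stepwise threshold sweep records, per 1% step, cumulative
# assigned reads and reads whose hit set spans more than one phylum; the
# phylum-conflict cutoff is the lowest threshold at which no read does.

#' Percent identity between two DNA sequences
#'
#' Global (Needleman-Wunsch) alignment with match +1, mismatch -1, gap -2;
#' identity = matching columns / total alignment columns (gaps count against
#' identity). Symmetric. Equal-length sequences are scored by direct
#' position-wise comparison, which is the optimal alignment under this
#' scoring.
#'
#' @param a,b non-empty DNA strings (A/C/G/T).
#' @return identity fraction in [0, 1].
#' @export
percent_identity <- function(a, b) {
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty sequence")
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) == nchar(b)) {
    av <- utf8ToInt(a); bv <- utf8ToInt(b)
    return(sum(av == bv) / length(av))
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 0, gapExtension = 2)
  gapped <- as.character(Biostrings::alignedPattern(aln))
  Biostrings::nmatch(aln) / nchar(gapped)
}

# Identity of every query against every reference, as a queries x refs
# matrix. Equal-length blocks use a one-hot matrix-product match count;
# mixed lengths fall back to pairwise alignment.
identity_matrix <- function(queries, refs) {
  out <- matrix(NA_real_, length(queries), length(refs),
                dimnames = list(names(queries), names(refs)))
  qlen <- nchar(queries); rlen <- nchar(refs)
  for (L in unique(qlen)) {
    qi <- which(qlen == L); ri <- which(rlen == L)
    if (length(ri)) {
      qm <- matrix(unlist(lapply(queries[qi], utf8ToInt), use.names = FALSE),
                   nrow = length(qi), byrow = TRUE)
      rm_ <- matrix(unlist(lapply(refs[ri], utf8ToInt), use.names = FALSE),
                    nrow = length(ri), byrow = TRUE)
      matches <- matrix(0, length(qi), length(ri))
      for (b in utf8ToInt("ACGT")) {
        matches <- matches + (qm == b) %*% t(rm_ == b)
      }
      out[qi, ri] <- matches / L
    }
    ri_diff <- which(rlen != L)
    for (i in qi) for (j in ri_diff) {
      out[i, j] <- percent_identity(queries[[i]], refs[[j]])
    }
  }
  out
}

# Lossless k-mer prefilter: identity >= t implies at most
# floor((1-t)*(la+lb)) edit operations, each of which can destroy at most k
# of the la-k+1 query k-mers; references sharing fewer k-mers than the bound
# cannot reach the threshold.
kmer_candidates <- function(read, refs, min_identity, k = 8L) {
  la <- nchar(read)
  if (la < k) return(seq_along(refs))
  qk <- substring(read, 1:(la - k + 1L), k:la)   # every k-mer position
  which(vapply(seq_along(refs), function(j) {
    lb <- nchar(refs[[j]])
    bound <- (la - k + 1L) - k * floor((1 - min_identity) * (la + lb))
    if (bound <= 0L) return(TRUE)
    rk <- unique(substring(refs[[j]], 1:(lb - k + 1L), k:lb))
    sum(qk %in% rk) >= bound
  }, logical(1)))
}

#' Find all references above an identity threshold for one read
#'
#' @param read DNA string.
#' @param db a [refdb()].
#' @param min_identity identity threshold in [0, 1].
#' @param method `"kmer"` (lossless k-mer prefilter, then exact identity on
#'   candidates) or `"full"` (exact identity against every reference). Both
#'   return identical hit sets; the prefilter is an optimization contract.
#' @return data.frame (accession, identity), identity descending.
#' @export
search_hits <- function(read, db, min_identity, method = c("kmer", "full")) {
  method <- match.arg(method)
  stopifnot(inherits(db, "refdb"))
  refs <- db$sequences
  cand <- if (method == "kmer") kmer_candidates(read, refs, min_identity)
          else seq_along(refs)
  if (length(cand) == 0L) {
    return(data.frame(accession = character(), identity = numeric(),
                      stringsAsFactors = FALSE))
  }
  ident <- vapply(cand, function(j) percent_identity(read, refs[[j]]),
                  numeric(1))
  keep <- ident >= min_identity
  out <- data.frame(accession = names(refs)[cand][keep],
                    identity = ident[keep], stringsAsFactors = FALSE)
  out[order(-out$identity, out$accession), , drop = FALSE]
}

#' Naive lowest-common-ancestor assignment
#'
#' The LCA of the full lineages of all hits: the deepest rank at which every
#' hit agrees. Hits spanning more than one phylum are flagged as a phylum
#' conflict (their LCA lies above phylum).
#'
#' @param hits data.frame with an `accession` column (e.g. [search_hits()]).
#' @param taxonomy reference taxonomy data.frame (`refdb$taxonomy`).
#' @return list: `name`, `rank` (NA when unassigned or no shared rank),
#'   `lineage` (named character up to the LCA rank), `conflict` (logical),
#'   `n_hits`.
#' @export
naive_lca <- function(hits, taxonomy) {
  if (nrow(hits) == 0L) {
    return(list(name = NA_character_, rank = NA_character_,
                lineage = character(0), conflict = FALSE, n_hits = 0L))
  }
  idx <- match(hits$accession, taxonomy$accession)
  if (anyNA(idx)) {
    stop("accession without lineage: ", hits$accession[which(is.na(idx))[1L]])
  }
  lin <- taxonomy[idx, TAX_RANKS, drop = FALSE]
  depth <- 0L
  for (r in TAX_RANKS) {
    if (length(unique(lin[[r]])) == 1L) depth <- depth + 1L else break
  }
  conflict <- length(unique(lin$phylum)) > 1L
  if (depth == 0L) {
    return(list(name = "Root", rank = NA_character_, lineage = character(0),
                conflict = conflict, n_hits = nrow(hits)))
  }
  ranks <- TAX_RANKS[seq_len(depth)]
  lineage <- stats::setNames(as.character(lin[1L, ranks]), ranks)
  list(name = unname(lineage[depth]), rank = ranks[depth], lineage = lineage,
       conflict = conflict, n_hits = nrow(hits))
}

#' Precompute read-to-reference identities
#'
#' Identities of the deduplicated read sequences against every reference,
#' plus each read's best identity per phylum. Pass the result to
#' [assign_dataset()]'s `precomputed` argument to assign one read set at
#' several thresholds without re-aligning.
#'
#' @param reads data.frame with a `sequence` column.
#' @param db a [refdb()].
#' @return opaque list consumed by [assign_dataset()].
#' @export
read_ref_identities <- function(reads, db) {
  uniq <- unique(reads$sequence)
  ident <- identity_matrix(stats::setNames(uniq, uniq), db$sequences)
  phyla <- db$taxonomy$phylum
  phy_max <- do.call(cbind, lapply(unique(phyla), function(p) {
    apply(ident[, phyla == p, drop = FALSE], 1L, max)
  }))
  colnames(phy_max) <- unique(phyla)
  list(ident = ident, phy_max = phy_max,
       row_of = match(reads$sequence, uniq))
}

#' Assign a read set at a fixed similarity threshold
#'
#' Per-read naive LCA over all references with identity >= threshold, plus
#' the taxon-by-sample abundance matrix of assigned reads.
#'
#' @param reads data.frame with `id`, `sequence`, `sample`.
#' @param db a [refdb()].
#' @param threshold similarity threshold in percent (e.g. 95).
#' @param precomputed optional result of internal identity precomputation
#'   (reused across thresholds by callers that assign at several).
#' @return list: `assignments` (per-read taxon, rank, best identity, number
#'   of hits, conflict flag; unassigned reads have NA taxon), `matrix`
#'   (taxa x samples integer counts over assigned reads), `n_unassigned`.
#' @export
assign_dataset <- function(reads, db, threshold, precomputed = NULL) {
  stopifnot(inherits(db, "refdb"))
  pc <- if (is.null(precomputed)) read_ref_identities(reads, db) else precomputed
  t <- threshold / 100
  tax <- db$taxonomy
  n_u <- nrow(pc$ident)
  # one LCA per unique sequence, then broadcast to reads
  lca_u <- vector("list", n_u)
  for (i in seq_len(n_u)) {
    sel <- pc$ident[i, ] >= t
    if (!any(sel)) {
      lca_u[[i]] <- list(name = NA_character_, rank = NA_character_,
                         conflict = FALSE, n_hits = 0L, best = max(pc$ident[i, ]))
    } else {
      l <- naive_lca(data.frame(accession = colnames(pc$ident)[sel],
                                stringsAsFactors = FALSE), tax)
      l$best <- max(pc$ident[i, sel])
      lca_u[[i]] <- l
    }
  }
  pull <- function(f, mode) vapply(lca_u, function(l) l[[f]], mode)
  asg <- data.frame(
    id = reads$id, sample = reads$sample,
    taxon = pull("name", character(1))[pc$row_of],
    rank = pull("rank", character(1))[pc$row_of],
    identity = pull("best", numeric(1))[pc$row_of],
    n_hits = pull("n_hits", integer(1))[pc$row_of],
    conflict = pull("conflict", logical(1))[pc$row_of],
    stringsAsFactors = FALSE)
  ok <- !is.na(asg$taxon)
  samples <- sort(unique(reads$sample))
  taxa <- sort(unique(asg$taxon[ok]))
  m <- matrix(0L, length(taxa), length(samples), dimnames = list(taxa, samples))
  if (any(ok)) {
    tb <- table(asg$taxon[ok], asg$sample[ok])
    m[rownames(tb), colnames(tb)] <- as.integer(tb)
  }
  list(assignments = asg, matrix = m, n_unassigned = sum(!ok))
}

#' Stepwise similarity-threshold sweep
#'
#' Assigns the read set at every threshold from `t_max` down to `t_min`
#' (step 1%), recording cumulative and newly assigned read counts and the
#' number of reads whose hit set spans more than one phylum.
#'
#' @param reads data.frame with `id`, `sequence`, `sample`.
#' @param db a [refdb()].
#' @param t_max,t_min sweep bounds in percent (`t_min < t_max`).
#' @param step grid step in percent.
#' @return data.frame of class `sweep_result`: threshold,
#'   cumulative_assigned, newly_assigned, phylum_conflicts.
#' @export
threshold_sweep <- function(reads, db, t_max = 100, t_min, step = 1) {
  if (t_min >= t_max) stop("t_min must be below t_max")
  pc <- read_ref_identities(reads, db)
  best <- apply(pc$ident, 1L, max)[pc$row_of]
  second_phy <- apply(pc$phy_max, 1L, function(v) {
    if (length(v) < 2L) -Inf else sort(v, decreasing = TRUE)[2L]
  })[pc$row_of]
  thresholds <- seq(t_max, t_min, by = -step)
  cum <- vapply(thresholds, function(t) sum(best >= t / 100), integer(1))
  conf <- vapply(thresholds, function(t) sum(second_phy >= t / 100), integer(1))
  out <- data.frame(threshold = thresholds,
                    cumulative_assigned = cum,
                    newly_assigned = c(cum[1L], diff(cum)),
                    phylum_conflicts = conf)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Phylum-conflict cutoff of a threshold sweep
#'
#' The lowest threshold in the sweep at which no read's hit set spans more
#' than one phylum — the marker's operational barcoding-gap limit for
#' phylum-level discrimination.
#'
#' @param sweep a [threshold_sweep()] result.
#' @return cutoff threshold in percent.
#' @export
phylum_cutoff <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_result"))
  if (sweep$phylum_conflicts[1L] > 0L) {
    stop("no conflict-free threshold: conflicts present at t_max")
  }
  free <- sweep$threshold[sweep$phylum_conflicts == 0L]
  if (length(free) == 0L) stop("no conflict-free threshold in sweep range")
  min(free)
}

#' Retain reads assigned inside Metazoa at the cutoff threshold
#'
#' @param reads data.frame with `id`, `sequence`, `sample`.
#' @param db a [refdb()].
#' @param cutoff threshold in percent (from [phylum_cutoff()]).
#' @return list `retained` / `removed`, a partition of `reads`.
#' @export
metazoan_filter <- function(reads, db, cutoff) {
  asg <- assign_dataset(reads, db, cutoff)
  a <- asg$assignments
  tax <- db$taxonomy
  # inside Metazoa: assigned, kingdoms of all hits agree on Metazoa
  kingdom_of <- function(name, rank) {
    if (is.na(name) || name == "Root") return(NA_character_)
    if (rank == "kingdom") return(name)
    hit <- tax$kingdom[tax[[rank]] == name]
    if (length(unique(hit)) == 1L) unique(hit) else NA_character_
  }
  kg <- mapply(kingdom_of, a$taxon, a$rank)
  keep <- !is.na(kg) & kg == "Metazoa"
  list(retained = reads[keep, , drop = FALSE],
       removed = reads[!keep, , drop = FALSE])
}

#' Categorize assigned taxa against a regional checklist
#'
#' PRESENT when on the regional checklist; NIS when on the non-indigenous
#' list (which wins over PRESENT); PLAUSIBLE_MISID when absent but a
#' congener is on the checklist; ERRONEOUS otherwise.
#'
#' @param taxa character vector of assigned taxon names.
#' @param checklist data.frame from [load_checklist()].
#' @param nis_list optional character vector of NIS names; defaults to
#'   checklist entries with status "NIS".
#' @return named character vector of categories, one per taxon.
#' @export
categorize_assignments <- function(taxa, checklist, nis_list = NULL) {
  if (is.null(nis_list)) nis_list <- checklist$taxon[checklist$status == "NIS"]
  nis_key <- tolower(trimws(nis_list))
  check_key <- checklist$key
  check_genus <- vapply(strsplit(checklist$taxon, "\\s+"), `[[`, character(1), 1L)
  check_genus <- unique(tolower(check_genus))
  out <- vapply(taxa, function(tx) {
    key <- tolower(trimws(tx))
    if (is.na(key) || key == "") {
      warning("taxon unparsable to genus: ", tx)
      return("ERRONEOUS")
    }
    if (key %in% nis_key) return("NIS")
    if (key %in% check_key) return("PRESENT")
    genus <- tolower(strsplit(trimws(tx), "\\s+")[[1]][1L])
    if (genus %in% check_genus) return("PLAUSIBLE_MISID")
    "ERRONEOUS"
  }, character(1))
  stats::setNames(out, taxa)
}

#' Drop erroneous and singleton rows from an abundance matrix
#'
#' Removes rows categorized ERRONEOUS and rows whose total count across all
#' samples is exactly one (singletons).
#'
#' @param m taxa x samples integer matrix.
#' @param categories named character vector covering all rows of `m`.
#' @return filtered matrix.
#' @export
remove_singletons_and_erroneous <- function(m, categories) {
  miss <- setdiff(rownames(m), names(categories))
  if (length(miss)) stop("categories missing for row(s): ",
                         paste(miss, collapse = ", "))
  keep <- categories[rownames(m)] != "ERRONEOUS" & rowSums(m) > 1L
  m[keep, , drop = FALSE]
}
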