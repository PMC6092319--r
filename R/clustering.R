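# Taxonomy-free MOTU inference: global dereplication, de-novo two-parent
# chimera removal, greedy centroid clustering in decreasing-abundance order,
# and LULU post-clustering curation. Everything is deterministic: ordering is
# by decreasing abundance with lexicographic sequence tie-breaks.

#' Dereplicate reads into unique sequences
#'
#' Exact-sequence grouping pooled over all samples, keeping per-sample
#' counts. Output is ordered by decreasing size, ties broken by sequence.
#'
#' @param reads data.frame with `sequence` and `sample` columns.
#' @return list of class `derep`: `uniques` (data.frame uid, sequence, size)
#'   and `counts` (uniques x samples integer matrix).
#' @export
dereplicate <- function(reads) {
  stopifnot(all(c("sequence", "sample") %in% names(reads)))
  samples <- sort(unique(reads$sample))
  tb <- table(reads$sequence, reads$sample)
  size <- rowSums(tb)
  ord <- order(-size, rownames(tb))
  counts <- matrix(as.integer(tb[ord, , drop = FALSE]), nrow = nrow(tb),
                   dimnames = list(NULL, colnames(tb)))
  uid <- sprintf("U%05d", seq_len(nrow(tb)))
  rownames(counts) <- uid
  counts <- counts[, samples, drop = FALSE]
  structure(list(uniques = data.frame(uid = uid,
                                      sequence = rownames(tb)[ord],
                                      size = as.integer(size[ord]),
                                      stringsAsFactors = FALSE),
                 counts = counts),
            class = "derep")
}

#' Flag chimeric unique sequences (de-novo, two-parent model)
#'
#' A query is chimeric when two candidate parents — unique sequences at
#' least twice as abundant as the query — explain it under a single-
#' breakpoint prefix/suffix model strictly better (fewer mismatches) than
#' the best single parent does, with both segments at >= `segment_identity`
#' identity to their parent. A simplified uchime-de-novo: no three-way
#' alignment or skew score.
#'
#' @param derep a [dereplicate()] result (or any data.frame with
#'   `sequence` and `size`, sorted by decreasing size).
#' @param min_size_ratio parent/query abundance ratio required of candidate
#'   parents (default 2).
#' @param segment_identity per-segment identity floor (default 0.99).
#' @return logical vector, one flag per unique sequence.
#' @export
detect_chimeras <- function(derep, min_size_ratio = 2, segment_identity = 0.99) {
  un <- if (inherits(derep, "derep")) derep$uniques else derep
  n <- nrow(un)
  flags <- rep(FALSE, n)
  if (n < 3L) return(flags)
  seq_int <- lapply(un$sequence, utf8ToInt)
  lens <- nchar(un$sequence)
  for (q in seq_len(n)) {
    parents <- which(un$size >= min_size_ratio * un$size[q] & lens == lens[q])
    parents <- setdiff(parents, q)
    if (length(parents) < 2L) next
    L <- lens[q]
    qv <- seq_int[[q]]
    mism <- vapply(parents, function(p) cumsum(seq_int[[p]] != qv),
                   numeric(L))                       # L x nparents prefix mismatches
    tot <- mism[L, ]
    best_single <- min(tot)
    if (best_single == 0) next                       # identical to a parent
    suf <- sweep(-mism, 2L, tot, `+`)                # mismatches in (b+1)..L
    b <- seq_len(L - 1L)
    okp <- mism[b, , drop = FALSE] <= (1 - segment_identity) * b
    oks <- suf[b, , drop = FALSE] <= (1 - segment_identity) * (L - b)
    pref_best <- suppressWarnings(
      apply(ifelse(okp, mism[b, , drop = FALSE], Inf), 1L, min))
    suf_best <- suppressWarnings(
      apply(ifelse(oks, suf[b, , drop = FALSE], Inf), 1L, min))
    if (min(pref_best + suf_best) < best_single) flags[q] <- TRUE
  }
  flags
}

#' Remove flagged uniques from a dereplicated set
#'
#' @param derep a [dereplicate()] result.
#' @param flags logical vector from [detect_chimeras()].
#' @return a `derep` with flagged uniques removed; the removed read count is
#'   reported in attribute `removed_reads`.
#' @export
drop_chimeras <- function(derep, flags) {
  out <- structure(list(uniques = derep$uniques[!flags, , drop = FALSE],
                        counts = derep$counts[!flags, , drop = FALSE]),
                   class = "derep")
  rownames(out$uniques) <- NULL
  attr(out, "removed_reads") <- sum(derep$uniques$size[flags])
  out
}

#' Greedy centroid clustering into MOTUs
#'
#' One pass over unique sequences in decreasing-abundance order: a unique
#' joins the first (earliest-founded) centroid with identity at or above the
#' clustering level, otherwise it founds a new MOTU.
#'
#' @param derep a [dereplicate()] result (chimeras removed).
#' @param level clustering level in percent (e.g. 97 joins at identity >=
#'   0.97).
#' @return list of class `motu_table`: `motus` (data.frame motu_id,
#'   centroid, total), `counts` (MOTU x samples matrix), `members` (list of
#'   member uids per MOTU).
#' @export
greedy_cluster <- function(derep, level) {
  stopifnot(inherits(derep, "derep"))
  thr <- level / 100
  un <- derep$uniques
  n <- nrow(un)
  assign_to <- integer(n)
  cent_idx <- integer(0)
  seq_int <- lapply(un$sequence, utf8ToInt)
  for (i in seq_len(n)) {
    joined <- 0L
    L <- length(seq_int[[i]])
    hit_id <- rep(-Inf, length(cent_idx))
    same_len <- which(lengths(seq_int[cent_idx]) == L)
    if (length(same_len)) {
      cm <- matrix(unlist(seq_int[cent_idx[same_len]]), nrow = L)
      hit_id[same_len] <- 1 - colSums(cm != seq_int[[i]]) / L
    }
    diff_len <- setdiff(seq_along(cent_idx), same_len)
    for (j in diff_len) {
      hit_id[j] <- percent_identity(un$sequence[i], un$sequence[cent_idx[j]])
    }
    ok <- which(hit_id >= thr)
    if (length(ok)) {
      joined <- ok[1L]
    } else {
      cent_idx <- c(cent_idx, i)
      joined <- length(cent_idx)
    }
    assign_to[i] <- joined
  }
  ids <- sprintf("MOTU%04d", seq_along(cent_idx))
  counts <- do.call(rbind, lapply(seq_along(cent_idx), function(k) {
    colSums(derep$counts[assign_to == k, , drop = FALSE])
  }))
  storage.mode(counts) <- "integer"
  rownames(counts) <- ids
  members <- split(un$uid, ids[assign_to])[ids]
  structure(list(motus = data.frame(motu_id = ids,
                                    centroid = un$sequence[cent_idx],
                                    total = as.integer(rowSums(counts)),
                                    stringsAsFactors = FALSE),
                 counts = counts, members = members),
            class = "motu_table")
}

#' LULU curation parameters
#'
#' Defaults are the published LULU defaults: minimum centroid match 84%,
#' minimum relative co-occurrence 0.95, minimum parent/daughter abundance
#' ratio 1 computed as the minimum over daughter-positive samples.
#'
#' @param min_match minimum parent-daughter centroid identity, percent.
#' @param min_rel_cooccurrence minimum fraction of daughter-positive samples
#'   where the parent is also present.
#' @param min_ratio minimum per-sample parent/daughter abundance ratio.
#' @param ratio_type `"min"` or `"avg"` over daughter-positive samples.
#' @return list of class `lulu_params`.
#' @export
lulu_params <- function(min_match = 84, min_rel_cooccurrence = 0.95,
                        min_ratio = 1, ratio_type = c("min", "avg")) {
  ratio_type <- match.arg(ratio_type)
  if (min_match <= 0 || min_match > 100) stop("min_match must be in (0, 100]")
  if (min_rel_cooccurrence <= 0 || min_rel_cooccurrence > 1) {
    stop("min_rel_cooccurrence must be in (0, 1]")
  }
  structure(list(min_match = min_match,
                 min_rel_cooccurrence = min_rel_cooccurrence,
                 min_ratio = min_ratio, ratio_type = ratio_type),
            class = "lulu_params")
}

#' Curate a MOTU table with the LULU algorithm
#'
#' Candidate daughters are visited in ascending abundance; a daughter is
#' merged into the best potential parent (highest co-occurrence, then
#' highest abundance ratio) among MOTUs with centroid identity >=
#' `min_match`, strictly higher total abundance, relative co-occurrence >=
#' `min_rel_cooccurrence` and abundance ratio >= `min_ratio`. Passes repeat
#' until a fixpoint. Read counts are conserved.
#'
#' @param motus a [greedy_cluster()] result.
#' @param params a [lulu_params()] object.
#' @return list of class `motu_table` (curated, with `merge_map` data.frame
#'   of daughter -> parent merges as attribute and element).
#' @export
lulu_curate <- function(motus, params = lulu_params()) {
  stopifnot(inherits(motus, "motu_table"), inherits(params, "lulu_params"))
  counts <- motus$counts
  cents <- stats::setNames(motus$motus$centroid, motus$motus$motu_id)
  ident <- identity_matrix(cents, cents)
  thr <- params$min_match / 100
  merge_map <- list()
  alive <- rownames(counts)
  repeat {
    merged_this_pass <- FALSE
    totals <- rowSums(counts[alive, , drop = FALSE])
    for (d in alive[order(totals, alive)]) {
      dvec <- counts[d, ]
      dpos <- dvec > 0L
      if (!any(dpos)) next
      cand <- alive[alive != d &
                      ident[alive, d] >= thr &
                      rowSums(counts[alive, , drop = FALSE]) > sum(dvec)]
      if (length(cand) == 0L) next
      co <- vapply(cand, function(p) mean(counts[p, dpos] > 0L), numeric(1))
      ratio <- vapply(cand, function(p) {
        r <- counts[p, dpos] / dvec[dpos]
        if (params$ratio_type == "min") min(r) else mean(r)
      }, numeric(1))
      ok <- co >= params$min_rel_cooccurrence & ratio >= params$min_ratio
      if (!any(ok)) next
      cand <- cand[ok]; co <- co[ok]; ratio <- ratio[ok]
      best <- cand[order(-co, -ratio, cand)][1L]
      counts[best, ] <- counts[best, ] + dvec
      alive <- setdiff(alive, d)
      merge_map[[length(merge_map) + 1L]] <-
        data.frame(daughter = d, parent = best, stringsAsFactors = FALSE)
      merged_this_pass <- TRUE
    }
    if (!merged_this_pass) break
  }
  keep <- rownames(counts) %in% alive
  mm <- if (length(merge_map)) do.call(rbind, merge_map) else
    data.frame(daughter = character(), parent = character(),
               stringsAsFactors = FALSE)
  out <- structure(list(motus = data.frame(
    motu_id = motus$motus$motu_id[keep],
    centroid = motus$motus$centroid[keep],
    total = as.integer(rowSums(counts[keep, , drop = FALSE])),
    stringsAsFactors = FALSE),
    counts = counts[keep, , drop = FALSE],
    members = motus$members[keep],
    merge_map = mm),
    class = "motu_table")
  attr(out, "merge_map") <- mm
  out
}
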