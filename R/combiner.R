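# Combining the COI and 18S taxonomically assigned matrices: a one-decimal
# sequencing-depth weight, explicit sample drops plus sample-set
# intersection, per-cell ceiling of the weighted 18S counts, COI priority on
# double entries, and an auditable manual-curation hook.

#' Sequencing-depth adjustment weight
#'
#' The ratio of post-QC read totals, rounded to one decimal. With the
#' study's totals (824,148 COI and 223,273 18S reads) this is 3.7.
#'
#' @param total_coi_reads,total_18s_reads positive post-QC read totals.
#' @return one-decimal ratio.
#' @export
depth_weight <- function(total_coi_reads, total_18s_reads) {
  if (total_18s_reads <= 0 || total_coi_reads <= 0) {
    stop("read totals must be positive")
  }
  round(total_coi_reads / total_18s_reads, 1)
}

#' Parameters for combining the two marker matrices
#'
#' @param coi_threshold,s18_threshold assignment thresholds the two input
#'   matrices were built at (recorded for provenance).
#' @param weight depth-adjustment weight applied to 18S counts; compute with
#'   [depth_weight()] or inject a known value.
#' @param drop_samples sample ids removed before merging (amplification
#'   failures).
#' @return list of class `combine_params`.
#' @export
combine_params <- function(coi_threshold = 95, s18_threshold = 97,
                           weight, drop_samples = character()) {
  if (weight <= 0) stop("weight must be positive")
  structure(list(coi_threshold = coi_threshold, s18_threshold = s18_threshold,
                 weight = weight, drop_samples = as.character(drop_samples)),
            class = "combine_params")
}

#' Merge COI and 18S abundance matrices into a combined dataset
#'
#' Samples: the intersection of the two matrices' sample sets minus the
#' explicit drop list. 18S counts are multiplied by the depth weight and
#' non-zero products rounded up to the next integer (zeros stay zero). Taxa
#' rows are unioned; for taxa retrieved by both markers the COI row is kept
#' verbatim and the 18S row discarded. Row provenance is recorded in
#' attribute `provenance` ("COI" or "18S").
#'
#' @param coi,s18 taxa x samples integer matrices.
#' @param params a [combine_params()] object.
#' @return combined integer matrix with a `provenance` attribute.
#' @export
combine_matrices <- function(coi, s18, params) {
  stopifnot(inherits(params, "combine_params"))
  samples <- setdiff(intersect(colnames(coi), colnames(s18)),
                     params$drop_samples)
  if (length(samples) == 0L) stop("no common samples after drops")
  coi <- coi[, samples, drop = FALSE]
  s18 <- s18[, samples, drop = FALSE]
  s18w <- ceiling(s18 * params$weight)
  s18w[s18 == 0L] <- 0L
  storage.mode(s18w) <- "integer"
  s18_only <- setdiff(rownames(s18), rownames(coi))
  out <- rbind(coi, s18w[s18_only, , drop = FALSE])
  prov <- stats::setNames(rep(c("COI", "18S"), c(nrow(coi), length(s18_only))),
                          rownames(out))
  ord <- order(rownames(out))
  out <- out[ord, , drop = FALSE]
  attr(out, "provenance") <- prov[rownames(out)]
  out
}

#' Apply a manual-curation decisions table to a combined matrix
#'
#' Decisions are `keep` (no-op), `drop` (remove row) or `rename` (relabel
#' row to `new_name`). Every applied change is returned in an audit log.
#'
#' @param combined taxa x samples matrix.
#' @param decisions data.frame with columns `taxon`, `action` and (for
#'   renames) `new_name`.
#' @return list: `matrix` (curated) and `log` (data.frame of changes).
#' @export
apply_curation <- function(combined, decisions) {
  if (is.null(decisions) || nrow(decisions) == 0L) {
    return(list(matrix = combined,
                log = data.frame(taxon = character(), action = character(),
                                 detail = character(), stringsAsFactors = FALSE)))
  }
  stopifnot(all(c("taxon", "action") %in% names(decisions)))
  bad <- setdiff(decisions$action, c("keep", "drop", "rename"))
  if (length(bad)) stop("unknown curation action: ", bad[1L])
  m <- combined
  log <- list()
  for (i in seq_len(nrow(decisions))) {
    tx <- decisions$taxon[i]; act <- decisions$action[i]
    if (!tx %in% rownames(m)) next
    if (act == "drop") {
      m <- m[rownames(m) != tx, , drop = FALSE]
      log[[length(log) + 1L]] <- data.frame(taxon = tx, action = "drop",
                                            detail = "", stringsAsFactors = FALSE)
    } else if (act == "rename") {
      new <- decisions$new_name[i]
      if (is.na(new) || new == "") stop("rename without new_name for ", tx)
      if (new %in% rownames(m)) stop("rename collision: ", new)
      rownames(m)[rownames(m) == tx] <- new
      log[[length(log) + 1L]] <- data.frame(taxon = tx, action = "rename",
                                            detail = new, stringsAsFactors = FALSE)
    }
  }
  list(matrix = m,
       log = if (length(log)) do.call(rbind, log) else
         data.frame(taxon = character(), action = character(),
                    detail = character(), stringsAsFactors = FALSE))
}
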