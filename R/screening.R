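# Non-indigenous-species screening across assignment stringencies, per-site
# relative-abundance profiles, reconciliation of morphological and molecular
# identification records, and the individuals-per-cubic-metre conversion.

# Name normalization used when matching records and checklists: case-fold,
# collapse whitespace, strip trailing authorship in parentheses. Binomials
# match on genus+species; higher-rank names match only identically.
normalize_taxon <- function(x) {
  x <- gsub("\\s*\\([^)]*\\)\\s*$", "", trimws(x))
  tolower(gsub("\\s+", " ", x))
}

#' Screen assignments for non-indigenous species across stringency levels
#'
#' Given taxon-by-sample matrices built at increasing similarity thresholds,
#' reports each NIS taxon at the highest stringency at which it is detected,
#' with its supporting samples and read counts at that level.
#'
#' @param matrices named list of taxa x samples matrices, names = threshold
#'   percents (e.g. `list("90" = ..., "95" = ..., "97" = ...)`).
#' @param nis_list character vector of NIS taxon names.
#' @return data.frame: taxon, highest_threshold, n_samples, total_reads,
#'   samples (comma-joined); one row per detected NIS taxon.
#' @export
nis_screen <- function(matrices, nis_list) {
  stopifnot(is.list(matrices), !is.null(names(matrices)))
  thr <- sort(as.numeric(names(matrices)))
  nis_key <- normalize_taxon(nis_list)
  rows <- list()
  for (i in seq_along(nis_list)) {
    best <- NULL
    for (t in thr) {                      # ascending: keep the highest with signal
      m <- matrices[[as.character(t)]]
      hit <- which(normalize_taxon(rownames(m)) == nis_key[i])
      if (length(hit) && sum(m[hit[1L], ]) > 0) {
        smp <- colnames(m)[m[hit[1L], ] > 0]
        best <- data.frame(taxon = nis_list[i], highest_threshold = t,
                           n_samples = length(smp),
                           total_reads = sum(m[hit[1L], ]),
                           samples = paste(smp, collapse = ","),
                           stringsAsFactors = FALSE)
      }
    }
    if (!is.null(best)) rows[[length(rows) + 1L]] <- best
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(taxon = character(), highest_threshold = numeric(),
               n_samples = integer(), total_reads = numeric(),
               samples = character(), stringsAsFactors = FALSE)
}

#' Per-sample relative abundance of one taxon
#'
#' @param m taxa x samples count matrix.
#' @param taxon row label.
#' @return named numeric vector of fractions in [0, 1]; NA where a sample
#'   has zero total reads.
#' @export
site_relative_abundance <- function(m, taxon) {
  if (!taxon %in% rownames(m)) stop("taxon not in matrix: ", taxon)
  tot <- colSums(m)
  out <- ifelse(tot > 0, m[taxon, ] / tot, NA_real_)
  stats::setNames(out, colnames(m))
}

#' Reconcile morphological and molecular identification records
#'
#' Records are keyed by (sample, normalized taxon). Each key is classified
#' `both`, `morph_only` or `molecular_only`; morphology-only records are
#' sub-split by whether a reference sequence exists for the taxon, and
#' molecular-only records by whether the taxon is morphologically
#' recognizable — both are input flags encoding expert/database knowledge.
#'
#' @param morph data.frame (sample, taxon) of morphological records.
#' @param molecular data.frame (sample, taxon, method in COI/18S) of
#'   molecular records.
#' @param flags optional data.frame (taxon, reference_available,
#'   morph_recognizable) of per-taxon logical flags.
#' @return list: `records` (per-key classification), `summary` (data.frame
#'   category, n, pct; sub-splits included), `total`.
#' @export
reconcile <- function(morph, molecular, flags = NULL) {
  if (nrow(molecular) && !all(molecular$method %in% c("COI", "18S", "MOL"))) {
    stop("unknown method label in molecular records")
  }
  key <- function(df) paste(df$sample, normalize_taxon(df$taxon), sep = "\r")
  mk <- unique(key(morph))
  lk <- unique(key(molecular))
  all_keys <- union(mk, lk)
  cls <- ifelse(all_keys %in% mk & all_keys %in% lk, "both",
                ifelse(all_keys %in% mk, "morph_only", "molecular_only"))
  parts <- do.call(rbind, strsplit(all_keys, "\r", fixed = TRUE))
  rec <- data.frame(sample = parts[, 1L], taxon = parts[, 2L],
                    category = cls, stringsAsFactors = FALSE)
  if (!is.null(flags)) {
    fk <- normalize_taxon(flags$taxon)
    rec$reference_available <- flags$reference_available[match(rec$taxon, fk)]
    rec$morph_recognizable <- flags$morph_recognizable[match(rec$taxon, fk)]
  }
  total <- nrow(rec)
  pct <- function(n) if (total > 0) 100 * n / total else 0
  summ <- data.frame(
    category = c("both", "morph_only", "molecular_only"),
    n = c(sum(cls == "both"), sum(cls == "morph_only"),
          sum(cls == "molecular_only")),
    stringsAsFactors = FALSE)
  summ$pct <- pct(summ$n)
  if (!is.null(flags)) {
    sub <- data.frame(
      category = c("morph_only_reference_available",
                   "molecular_only_morph_recognizable"),
      n = c(sum(cls == "morph_only" & rec$reference_available %in% TRUE),
            sum(cls == "molecular_only" & rec$morph_recognizable %in% TRUE)),
      stringsAsFactors = FALSE)
    sub$pct <- pct(sub$n)
    summ <- rbind(summ, sub)
  }
  list(records = rec, summary = summ, total = total)
}

#' Convert counted individuals to individuals per cubic metre
#'
#' The filtered volume is net mouth area times haul depth; the count is
#' scaled up by the examined subsample fraction first.
#'
#' @param counted individuals counted in the subsample.
#' @param subsample_fraction fraction of the sample examined, in (0, 1].
#' @param metadata one row of a [read_metadata()] table (uses `net_area`
#'   and `haul_depth`), or a list with those fields.
#' @return abundance in ind m^-3.
#' @export
abundance_per_m3 <- function(counted, subsample_fraction, metadata) {
  if (subsample_fraction <= 0 || subsample_fraction > 1) {
    stop("subsample_fraction must lie in (0, 1]")
  }
  vol <- metadata$net_area * metadata$haul_depth
  if (any(vol <= 0)) stop("filtered volume must be positive")
  (counted / subsample_fraction) / vol
}
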