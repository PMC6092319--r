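# Demultiplexing, tag/primer trimming, and quality filtering.
# Contract: tags match exactly; primers tolerate up to `max_primer_mismatches`
# (default 3) with IUPAC degeneracy counted as a match; reads are kept when
# mean Phred is strictly above the minimum (default 20) and length is at
# least the marker minimum (COI 200, 18S 100).

IUPAC_SETS <- c(A = "A", C = "C", G = "G", T = "T",
                R = "AG", Y = "CT", S = "GC", W = "AT", K = "GT", M = "AC",
                B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

#' Quality-control parameters
#'
#' @param tags named character vector sample -> tag (10-12 bases, unique).
#' @param fwd_primer forward primer (IUPAC allowed).
#' @param max_primer_mismatches maximum primer mismatches tolerated.
#' @param min_mean_phred mean-quality threshold (strict: mean must exceed it).
#' @param min_length named vector marker -> minimum retained read length.
#' @return list of class `qc_params`.
#' @export
qc_params <- function(tags, fwd_primer,
                      max_primer_mismatches = 3L,
                      min_mean_phred = 20,
                      min_length = c(COI = 200L, `18S` = 100L)) {
  stopifnot(is.character(tags), !is.null(names(tags)))
  if (anyDuplicated(tags)) stop("sample tags must be unique within a run")
  if (any(min_length < 1L)) stop("minimum lengths must be >= 1")
  structure(list(tags = toupper(tags), fwd_primer = toupper(fwd_primer),
                 max_primer_mismatches = as.integer(max_primer_mismatches),
                 min_mean_phred = min_mean_phred,
                 min_length = min_length),
            class = "qc_params")
}

#' Reverse-complement DNA strings (IUPAC-aware)
#' @param x character vector of sequences.
#' @return reverse-complemented character vector.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(x))
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# Mismatch count between an IUPAC primer and an ACGT read segment of equal
# length; a read base contained in the primer code's base set is a match.
primer_mismatches <- function(segment, primer) {
  if (nchar(segment) != nchar(primer)) return(NA_integer_)
  p <- strsplit(primer, "", fixed = TRUE)[[1]]
  s <- strsplit(segment, "", fixed = TRUE)[[1]]
  sum(!mapply(function(pc, sc) {
    !is.na(IUPAC_SETS[pc]) && grepl(sc, IUPAC_SETS[pc], fixed = TRUE)
  }, p, s))
}

#' Demultiplex and trim a pooled read library
#'
#' Assigns each read to the sample whose tag is an exact prefix (trying the
#' reverse complement when the forward orientation has no tag), then requires
#' the forward primer immediately after the tag with at most
#' `max_primer_mismatches` IUPAC-aware mismatches. The tag+primer prefix is
#' removed; reads are reoriented to forward. Reads failing either check go
#' to the unassigned bin (not an error).
#'
#' @param reads data.frame with `id`, `sequence`, `quality` columns.
#' @param params a [qc_params()] object.
#' @return list with `assigned` (reads plus `sample` column, trimmed) and
#'   `unassigned` (untouched reads).
#' @export
demultiplex_trim <- function(reads, params) {
  stopifnot(inherits(params, "qc_params"))
  stopifnot(all(c("id", "sequence", "quality") %in% names(reads)))
  tags <- params$tags
  plen <- nchar(params$fwd_primer)
  n <- nrow(reads)
  sample_of <- rep(NA_character_, n)
  trimmed_seq <- reads$sequence
  trimmed_qual <- reads$quality

  match_orientation <- function(seqs) {
    hit <- rep(NA_character_, length(seqs))
    for (len in unique(nchar(tags))) {
      pre <- substr(seqs, 1L, len)
      idx <- match(pre, tags[nchar(tags) == len])
      found <- !is.na(idx) & is.na(hit)
      hit[found] <- names(tags[nchar(tags) == len])[idx[found]]
    }
    hit
  }

  fwd_hit <- match_orientation(reads$sequence)
  rc_seq <- revcomp(reads$sequence)
  rev_hit <- match_orientation(rc_seq)

  for (i in seq_len(n)) {
    if (!is.na(fwd_hit[i])) {
      smp <- fwd_hit[i]; s <- reads$sequence[i]; q <- reads$quality[i]
    } else if (!is.na(rev_hit[i])) {
      smp <- rev_hit[i]; s <- rc_seq[i]
      q <- paste(rev(strsplit(reads$quality[i], "", fixed = TRUE)[[1]]),
                 collapse = "")
    } else next
    tlen <- nchar(tags[smp])
    if (nchar(s) < tlen + plen) next
    mm <- primer_mismatches(substr(s, tlen + 1L, tlen + plen),
                            params$fwd_primer)
    if (is.na(mm) || mm > params$max_primer_mismatches) next
    sample_of[i] <- smp
    trimmed_seq[i] <- substr(s, tlen + plen + 1L, nchar(s))
    trimmed_qual[i] <- substr(q, tlen + plen + 1L, nchar(q))
  }

  ok <- !is.na(sample_of)
  assigned <- data.frame(id = reads$id[ok], sequence = trimmed_seq[ok],
                         quality = trimmed_qual[ok], sample = sample_of[ok],
                         stringsAsFactors = FALSE)
  list(assigned = assigned, unassigned = reads[!ok, , drop = FALSE])
}

#' Quality-filter demultiplexed reads
#'
#' Retains a read iff its mean Phred score strictly exceeds
#' `min_mean_phred` and its length is at least the marker minimum
#' (a read of exactly the minimum length is retained).
#'
#' @param reads data.frame with `sequence` and `quality`.
#' @param params a [qc_params()] object.
#' @param marker marker label indexing `params$min_length`.
#' @return the retained subset of `reads`.
#' @export
quality_filter <- function(reads, params, marker) {
  stopifnot(inherits(params, "qc_params"))
  if (!marker %in% names(params$min_length)) stop("unknown marker: ", marker)
  if (nrow(reads) == 0L) return(reads)
  meanq <- vapply(phred_scores(reads$quality), mean, numeric(1))
  keep <- meanq > params$min_mean_phred &
    nchar(reads$sequence) >= params$min_length[[marker]]
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize retained read counts
#'
#' @param counts per-sample retained read counts (non-negative).
#' @param n_samples divisor for the mean. Defaults to `length(counts)`;
#'   exposed because the divisor convention (all collected samples vs.
#'   successfully amplified samples) is a reporting choice.
#' @return list with `total`, `mean` (rounded to nearest integer), `min`,
#'   `max`.
#' @export
summarize_counts <- function(counts, n_samples = length(counts)) {
  if (n_samples == 0L) stop("n_samples must be positive")
  if (any(counts < 0)) stop("counts must be non-negative")
  list(total = sum(counts),
       mean = round(sum(counts) / n_samples),
       min = if (length(counts)) min(counts) else 0L,
       max = if (length(counts)) max(counts) else 0L)
}
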