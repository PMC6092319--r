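# Readers and writers for the plain-text formats exchanged between pipeline
# stages: FASTQ reads, reference FASTA with embedded lineages, TSV abundance
# matrices, sample metadata and regional checklists. All readers validate and
# reject malformed input; every writer round-trips through its paired reader.

#' Taxonomic ranks used throughout the pipeline, kingdom to species.
#' @export
TAX_RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")

#' Convert a Phred+33 quality string to integer scores
#'
#' @param qual character vector of Sanger-encoded quality strings.
#' @return list of integer vectors, one per input string.
#' @export
phred_scores <- function(qual) {
  lapply(qual, function(q) as.integer(utf8ToInt(q)) - 33L)
}

#' Convert integer Phred scores to a Phred+33 string
#' @param scores integer vector of per-base scores (0-93).
#' @return single character string.
#' @export
phred_string <- function(scores) {
  stopifnot(all(scores >= 0L), all(scores <= 93L))
  intToUtf8(as.integer(scores) + 33L)
}

#' Read a FASTQ file into a read table
#'
#' Parses Sanger (Phred+33) FASTQ. Each record must be a well-formed 4-line
#' block; malformed blocks raise an error naming the offending line.
#'
#' @param path file path.
#' @param marker optional marker label ("COI" or "18S") attached to all reads.
#' @return data.frame with columns `id`, `sequence`, `quality` (and `marker`
#'   when given). Record order is preserved.
#' @export
read_fastq <- function(path, marker = NA_character_) {
  lines <- readLines(path)
  if (length(lines) == 0L) {
    out <- data.frame(id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE)
    if (!is.na(marker)) out$marker <- character()
    return(out)
  }
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ: truncated record starting at line ",
         4L * (length(lines) %/% 4L) + 1L)
  }
  idx <- seq(1L, length(lines), by = 4L)
  hdr <- lines[idx]
  seqs <- lines[idx + 1L]
  plus <- lines[idx + 2L]
  qual <- lines[idx + 3L]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) {
    stop("malformed FASTQ: expected '@' header at line ", idx[bad[1L]])
  }
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) {
    stop("malformed FASTQ: expected '+' separator at line ", idx[bad[1L]] + 2L)
  }
  bad <- which(nchar(qual) != nchar(seqs))
  if (length(bad)) {
    stop("malformed FASTQ: quality length differs from sequence length at line ",
         idx[bad[1L]] + 3L)
  }
  out <- data.frame(id = sub("^@", "", sub("\\s.*$", "", hdr)),
                    sequence = toupper(seqs), quality = qual,
                    stringsAsFactors = FALSE)
  if (!is.na(marker)) out$marker <- marker
  out
}

#' Write a read table to FASTQ (Phred+33)
#'
#' @param reads data.frame with `id`, `sequence`, `quality` columns.
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "sequence", "quality") %in% names(reads)))
  stopifnot(all(nchar(reads$quality) == nchar(reads$sequence)))
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads)) {
    writeLines(paste0("@", reads$id, "\n", reads$sequence, "\n+\n", reads$quality),
               con, sep = "\n")
  }
  invisible(path)
}

#' Write a reference database to FASTA with embedded lineages
#'
#' Headers carry the full ranked lineage as semicolon-separated `rank:name`
#' pairs after the accession: `>ACC|kingdom:Metazoa;phylum:Arthropoda;...`.
#'
#' @param refdb a `refdb` object (see [refdb()]).
#' @param path output path.
#' @export
write_refdb_fasta <- function(refdb, path) {
  tax <- refdb$taxonomy
  lin <- vapply(seq_len(nrow(tax)), function(i) {
    paste(paste0(TAX_RANKS, ":", unlist(tax[i, TAX_RANKS])), collapse = ";")
  }, character(1))
  hdr <- paste0(tax$accession, "|", lin)
  writeLines(paste0(">", hdr, "\n", refdb$sequences[tax$accession]), path)
  invisible(path)
}

#' Read a reference database from a lineage-annotated FASTA
#'
#' @param path FASTA path written by [write_refdb_fasta()] (or any FASTA whose
#'   headers are `accession|rank:name;rank:name;...`).
#' @return a `refdb` object.
#' @export
read_refdb_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  hdr <- names(ss)
  parts <- strsplit(hdr, "|", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) stop("malformed reference header (no '|' lineage): ", hdr[bad[1L]])
  acc <- vapply(parts, `[[`, character(1), 1L)
  lin <- vapply(parts, `[[`, character(1), 2L)
  ranks <- lapply(strsplit(lin, ";", fixed = TRUE), function(pairs) {
    kv <- strsplit(pairs, ":", fixed = TRUE)
    stats::setNames(vapply(kv, `[[`, character(1), 2L),
                    vapply(kv, `[[`, character(1), 1L))
  })
  tax <- do.call(rbind, lapply(seq_along(ranks), function(i) {
    r <- ranks[[i]]
    miss <- setdiff(TAX_RANKS, names(r))
    if (length(miss)) stop("lineage for ", acc[i], " missing rank(s): ",
                           paste(miss, collapse = ", "))
    as.data.frame(as.list(r[TAX_RANKS]), stringsAsFactors = FALSE)
  }))
  tax$accession <- acc
  tax$metazoan <- tax$kingdom == "Metazoa"
  seqs <- stats::setNames(as.character(ss), acc)
  refdb(seqs, tax)
}

#' Construct a reference database object
#'
#' @param sequences named character vector, accession -> uppercase DNA.
#' @param taxonomy data.frame with `accession` plus the seven [TAX_RANKS]
#'   columns; a logical `metazoan` column is derived from the kingdom if
#'   absent.
#' @return object of class `refdb`.
#' @export
refdb <- function(sequences, taxonomy) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  stopifnot(all(c("accession", TAX_RANKS) %in% names(taxonomy)))
  if (anyDuplicated(taxonomy$accession)) stop("duplicate accessions in taxonomy")
  if (!setequal(names(sequences), taxonomy$accession)) {
    stop("sequence accessions and taxonomy accessions differ")
  }
  if (is.null(taxonomy$metazoan)) taxonomy$metazoan <- taxonomy$kingdom == "Metazoa"
  structure(list(sequences = toupper(sequences),
                 taxonomy = taxonomy[match(names(sequences), taxonomy$accession), ]),
            class = "refdb")
}

#' @export
print.refdb <- function(x, ...) {
  cat("<refdb> ", length(x$sequences), " reference sequences, ",
      length(unique(x$taxonomy$species)), " species, ",
      length(unique(x$taxonomy$phylum)), " phyla\n", sep = "")
  invisible(x)
}

#' Read an abundance matrix from TSV
#'
#' Expects a header row of sample ids and a first column of row labels
#' (taxa or MOTU ids). Counts must be non-negative integers.
#'
#' @param path TSV path.
#' @return integer matrix, rows = taxa/MOTUs, columns = samples.
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("abundance matrix needs a label column and >=1 sample")
  labels <- as.character(df[[1L]])
  if (anyDuplicated(labels)) {
    stop("duplicate row labels: ", labels[duplicated(labels)][1L])
  }
  samples <- colnames(df)[-1L]
  if (anyDuplicated(samples)) {
    stop("duplicate sample ids: ", samples[duplicated(samples)][1L])
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric count cell in abundance matrix")
  if (any(m < 0)) stop("negative count in abundance matrix")
  if (any(m != round(m))) stop("non-integer count in abundance matrix")
  storage.mode(m) <- "integer"
  rownames(m) <- labels
  m
}

#' Write an abundance matrix to TSV
#'
#' @param m integer matrix with row and column names.
#' @param path output path.
#' @export
write_matrix <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  df <- data.frame(taxon = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a regional species checklist
#'
#' A two-column TSV (`taxon`, `status`) where status is `indigenous` or `NIS`
#' (case-insensitive). Lookups downstream are case-insensitive on the taxon
#' name.
#'
#' @param path TSV path.
#' @return data.frame with columns `taxon`, `status` and a normalized `key`.
#' @export
load_checklist <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    return(data.frame(taxon = character(), status = character(),
                      key = character(), stringsAsFactors = FALSE))
  }
  if (!all(c("taxon", "status") %in% names(df))) {
    stop("checklist needs 'taxon' and 'status' columns")
  }
  status <- toupper(trimws(df$status))
  status <- ifelse(status == "NIS", "NIS",
                   ifelse(status == "INDIGENOUS", "indigenous", NA))
  if (anyNA(status)) {
    stop("unknown checklist status label: ", df$status[which(is.na(status))[1L]])
  }
  key <- tolower(trimws(df$taxon))
  conflict <- tapply(status, key, function(s) length(unique(s)) > 1L)
  if (any(conflict)) {
    stop("conflicting status for taxon: ", names(conflict)[conflict][1L])
  }
  keep <- !duplicated(key)
  data.frame(taxon = trimws(df$taxon)[keep], status = status[keep],
             key = key[keep], stringsAsFactors = FALSE)
}

#' Read a sample metadata table
#'
#' Columns: `sample`, `latitude`, `longitude`, `bottom_depth` (m),
#' `net_area` (m^2), `haul_depth` (m), `subsample_fraction` (0, 1].
#'
#' @param path TSV path.
#' @return validated data.frame.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "latitude", "longitude", "bottom_depth", "net_area",
            "haul_depth", "subsample_fraction")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  df$sample <- as.character(df$sample)
  if (any(df$haul_depth <= 0) || any(df$net_area <= 0)) {
    stop("haul depth and net mouth area must be positive")
  }
  if (any(df$subsample_fraction <= 0 | df$subsample_fraction > 1)) {
    stop("subsample_fraction must lie in (0, 1]")
  }
  df
}
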