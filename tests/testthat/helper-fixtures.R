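# Shared fixture builders: tiny parameter sets and a hand-built reference
# database small enough to reason about by eye.

tiny_params <- function(seed = 1, ...) {
  args <- list(n_phyla = 2L, species_per_phylum = 3L, refs_per_species = 2L,
               n_sites = 4L, offshore_fraction = 0.5,
               reads_per_site = c(COI = 60L, `18S` = 40L),
               substitution_error_rate = 0, chimera_fraction = 0,
               contaminant_fraction = 0,
               dropout_samples = list(COI = character(), `18S` = character()),
               seed = seed)
  do.call(sim_params, utils::modifyList(args, list(...)))
}

# Two phyla, two species each, one reference per species; sequences chosen
# so identities are simple fractions of 20.
hand_refdb <- function() {
  base <- strrep("ACGT", 5L)                       # 20 bp
  mut <- function(s, pos, to) {
    v <- strsplit(s, "")[[1]]; v[pos] <- to; paste(v, collapse = "")
  }
  seqs <- c(
    A1 = base,
    A2 = mut(base, 1:2, c("T", "G")),              # 0.90 to A1
    B1 = mut(base, 1:8, c("T","G","A","C","T","G","A","C")),  # 0.60 to A1
    B2 = mut(mut(base, 1:8, c("T","G","A","C","T","G","A","C")), 9:10,
             c("T", "G"))
  )
  tax <- data.frame(
    accession = names(seqs),
    kingdom = "Metazoa",
    phylum = c("Arthropoda", "Arthropoda", "Chordata", "Chordata"),
    class = c("Cl1", "Cl1", "Cl2", "Cl2"),
    order = c("Or1", "Or1", "Or2", "Or2"),
    family = c("Fa1", "Fa1", "Fa2", "Fa2"),
    genus = c("GenA", "GenA", "GenB", "GenB"),
    species = c("GenA sp1", "GenA sp2", "GenB sp1", "GenB sp2"),
    stringsAsFactors = FALSE)
  refdb(seqs, tax)
}

read_df <- function(seqs, samples = "s1", ids = NULL) {
  n <- max(length(seqs), length(samples))
  seqs <- rep_len(seqs, n); samples <- rep_len(samples, n)
  data.frame(id = if (is.null(ids)) sprintf("r%03d", seq_len(n)) else ids,
             sequence = seqs,
             quality = vapply(nchar(seqs), function(l) phred_string(rep(35L, l)),
                              character(1)),
             sample = samples, stringsAsFactors = FALSE)
}
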