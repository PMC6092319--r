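# Synthetic dual-marker communities: reference databases with controlled
# hierarchical divergences, log-normal site communities on a coastal-offshore
# gradient, amplicon reads with substitution errors, chimeras and a
# non-metazoan contaminant fraction, and morphological identification records.
#
# Divergences are realized by construction rather than by a stochastic
# substitution process: each lineage at each level mutates a fixed number of
# positions drawn from blocks disjoint from every other lineage's at that
# level (phylum blocks disjoint globally; species sets disjoint within their
# phylum and sampled outside all phylum blocks; per-reference sets disjoint
# from each other and from their phylum's species sets). Pairwise distances
# are then deterministic sums of layer contributions: intra-species 2*k_ref,
# cross-species 2*(k_sp + k_ref), cross-phylum 2*(k_phy + k_sp + k_ref),
# with the k's solved from the requested pairwise divergences. The only
# residual randomness is the (rare, tiny) overlap of species sets belonging
# to different phyla.

DNA_BASES <- c("A", "C", "G", "T")

#' Derive a reproducible child seed from a base seed and a stage tag
#'
#' @param seed integer base seed.
#' @param tag character stage label.
#' @return integer below 2^31, deterministic in (seed, tag).
#' @export
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag))) %% 99991L
  as.integer((as.numeric(seed) * 10007 + h * 7919 + 12345) %% .Machine$integer.max)
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv())
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Parameters of the synthetic community generator
#'
#' Defaults emulate the study conditions: a 46-station coastal-offshore
#' transect (12 offshore), ~313 bp COI and ~138 bp 18S V9 amplicons,
#' inter-phylum / inter-species / intra-species pairwise divergences of
#' 0.30 / 0.10 / 0.01, a ~5% non-metazoan contaminant fraction, and
#' marker-specific amplification dropouts (COI: station 16; 18S: 43 and 46).
#'
#' @param n_phyla number of metazoan phyla.
#' @param species_per_phylum species per phylum.
#' @param refs_per_species reference sequences per species.
#' @param inter_phylum_divergence expected pairwise difference between
#'   sequences of different phyla.
#' @param inter_species_divergence expected pairwise difference between
#'   congeneric-or-confamilial species within a phylum.
#' @param intra_species_divergence expected pairwise difference between
#'   conspecific references.
#' @param marker_lengths named vector of amplicon lengths (bases).
#' @param n_sites number of sampling stations.
#' @param offshore_fraction fraction of stations in the offshore class.
#' @param lognormal_mu,lognormal_sigma log-scale mean and sd of per-taxon
#'   per-site abundances.
#' @param gradient_strength in [0,1]; 0 = identical expected composition in
#'   both site classes, 1 = class-associated taxa absent from the other class.
#' @param reads_per_site named vector, reads generated per station per marker.
#' @param substitution_error_rate per-base read error probability.
#' @param chimera_fraction fraction of reads built from two parent templates.
#' @param contaminant_fraction fraction of reads drawn from the non-metazoan
#'   outgroup.
#' @param dropout_samples named list marker -> station ids with no reads.
#' @param seed integer; all generator randomness derives from it.
#' @return validated list of class `sim_params`.
#' @export
sim_params <- function(n_phyla = 4L,
                       species_per_phylum = 6L,
                       refs_per_species = 2L,
                       inter_phylum_divergence = 0.30,
                       inter_species_divergence = 0.10,
                       intra_species_divergence = 0.01,
                       marker_lengths = c(COI = 313L, `18S` = 138L),
                       n_sites = 46L,
                       offshore_fraction = 12 / 46,
                       lognormal_mu = 3,
                       lognormal_sigma = 1.2,
                       gradient_strength = 0.6,
                       reads_per_site = c(COI = 400L, `18S` = 150L),
                       substitution_error_rate = 0.01,
                       chimera_fraction = 0.02,
                       contaminant_fraction = 0.05,
                       dropout_samples = list(COI = "st16", `18S` = c("st43", "st46")),
                       seed = 1L) {
  p <- list(n_phyla = as.integer(n_phyla),
            species_per_phylum = as.integer(species_per_phylum),
            refs_per_species = as.integer(refs_per_species),
            inter_phylum_divergence = inter_phylum_divergence,
            inter_species_divergence = inter_species_divergence,
            intra_species_divergence = intra_species_divergence,
            marker_lengths = marker_lengths,
            n_sites = as.integer(n_sites),
            offshore_fraction = offshore_fraction,
            lognormal_mu = lognormal_mu,
            lognormal_sigma = lognormal_sigma,
            gradient_strength = gradient_strength,
            reads_per_site = reads_per_site,
            substitution_error_rate = substitution_error_rate,
            chimera_fraction = chimera_fraction,
            contaminant_fraction = contaminant_fraction,
            dropout_samples = dropout_samples,
            seed = as.integer(seed))
  fr <- c(p$inter_phylum_divergence, p$inter_species_divergence,
          p$intra_species_divergence, p$gradient_strength,
          p$substitution_error_rate, p$chimera_fraction,
          p$contaminant_fraction, p$offshore_fraction)
  if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0, 1]")
  if (!(p$inter_phylum_divergence > p$inter_species_divergence &&
        p$inter_species_divergence > p$intra_species_divergence)) {
    stop("divergences must satisfy inter-phylum > inter-species > intra-species")
  }
  if (any(p$marker_lengths < 50L)) stop("marker lengths must be >= 50 bases")
  if (p$n_phyla < 1L || p$species_per_phylum < 1L || p$refs_per_species < 1L) {
    stop("counts must be positive")
  }
  structure(p, class = "sim_params")
}

# Site ids and class labels for a parameter set (offshore sites last).
site_classes <- function(params) {
  ids <- sprintf("st%02d", seq_len(params$n_sites))
  n_off <- max(1L, round(params$n_sites * params$offshore_fraction))
  cls <- rep("coastal", params$n_sites)
  cls[seq.int(params$n_sites - n_off + 1L, params$n_sites)] <- "offshore"
  stats::setNames(cls, ids)
}

# Skeleton taxonomy shared by the two markers: genera of two species, one
# class/order/family per phylum, kingdom Metazoa.
species_table <- function(params) {
  out <- do.call(rbind, lapply(seq_len(params$n_phyla), function(p) {
    sp <- seq_len(params$species_per_phylum)
    genus <- sprintf("Genus%02d%s", p, LETTERS[(sp - 1L) %/% 2L + 1L])
    data.frame(kingdom = "Metazoa",
               phylum = sprintf("Phylum%02d", p),
               class = sprintf("Class%02d", p),
               order = sprintf("Order%02d", p),
               family = sprintf("Family%02d", p),
               genus = genus,
               species = sprintf("%s sp%d", genus, (sp - 1L) %% 2L + 1L),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# Mutate exactly k positions (uniform replacement among the other 3 bases).
mutate_fixed <- function(base_int, k) {
  L <- length(base_int)
  if (k == 0L) return(base_int)
  pos <- sample.int(L, k)
  shift <- sample.int(3L, k, replace = TRUE)
  base_int[pos] <- (base_int[pos] + shift - 1L) %% 4L + 1L
  base_int
}

int_to_dna <- function(x) paste(DNA_BASES[x], collapse = "")
dna_to_int <- function(s) match(strsplit(s, "", fixed = TRUE)[[1]], DNA_BASES)

# Mutate the given positions to a (uniform) different base.
mutate_at <- function(base_int, pos) {
  if (length(pos) == 0L) return(base_int)
  shift <- sample.int(3L, length(pos), replace = TRUE)
  base_int[pos] <- (base_int[pos] + shift - 1L) %% 4L + 1L
  base_int
}

#' Simulate a reference database for one marker
#'
#' Builds one ancestral sequence per phylum from a common root, species
#' ancestors within each phylum, and per-species reference variants.
#' Per-layer mutation counts are `k_phy = (D_p - D_s) L / 2`,
#' `k_sp = (D_s - D_i) L / 2` and `k_ref = D_i L / 2` on mutually disjoint
#' position sets, so realized pairwise divergences equal the requested
#' inter-phylum / inter-species / intra-species rates by construction. A
#' divergent non-metazoan outgroup (two species, independent random
#' sequences) is appended so contaminant reads have references to hit and
#' the metazoan filter has work to do.
#'
#' @param params a [sim_params()] object.
#' @param marker marker label, a name of `params$marker_lengths`.
#' @return a [refdb()] object; deterministic given `params$seed`.
#' @export
simulate_reference_db <- function(params, marker) {
  stopifnot(inherits(params, "sim_params"))
  if (!marker %in% names(params$marker_lengths)) {
    stop("unknown marker: ", marker)
  }
  L <- as.integer(params$marker_lengths[[marker]])
  k_p <- round((params$inter_phylum_divergence -
                  params$inter_species_divergence) * L / 2)
  k_s <- round((params$inter_species_divergence -
                  params$intra_species_divergence) * L / 2)
  k_r <- round(params$intra_species_divergence * L / 2)
  if (k_p == 0L || k_s == 0L) {
    stop("marker length too short to realize the requested divergences")
  }
  if (params$n_phyla * k_p >= L) {
    stop("marker length too short to realize the requested divergences")
  }
  spt <- species_table(params)
  with_seed(derive_seed(params$seed, paste0("refdb_", marker)), {
    root <- sample.int(4L, L, replace = TRUE)
    phy_block <- matrix(sample.int(L, params$n_phyla * k_p), nrow = k_p)
    free <- setdiff(seq_len(L), as.integer(phy_block))
    if (params$species_per_phylum * k_s > length(free)) {
      stop("marker length too short to realize the requested divergences")
    }
    # When the full species + reference mutation budget fits in the free
    # region, draw all sets globally disjoint: every pairwise distance is
    # then exact. Otherwise sets are disjoint within their phylum only and
    # rare cross-phylum overlaps perturb distances by a fraction of a
    # percent.
    per_phylum_budget <- params$species_per_phylum *
      (k_s + params$refs_per_species * k_r)
    exact_mode <- params$n_phyla * per_phylum_budget <= length(free)
    pool <- free
    draw <- function(from, n) from[sample.int(length(from), n)]
    take <- function(n) {
      got <- if (exact_mode) draw(pool, n) else draw(free, n)
      if (exact_mode) pool <<- setdiff(pool, got)
      got
    }
    seqs <- character(0)
    tax <- list()
    for (pi in seq_along(unique(spt$phylum))) {
      p <- unique(spt$phylum)[pi]
      anc_p <- mutate_at(root, phy_block[, pi])
      rows <- spt[spt$phylum == p, ]
      sp_pos <- matrix(take(nrow(rows) * k_s), nrow = k_s)
      ref_free <- setdiff(if (exact_mode) pool else free, as.integer(sp_pos))
      if (params$refs_per_species * k_r > length(ref_free)) {
        stop("marker length too short to realize the requested divergences")
      }
      for (i in seq_len(nrow(rows))) {
        anc_s <- mutate_at(anc_p, sp_pos[, i])
        ref_pos <- if (k_r > 0L) {
          got <- if (exact_mode) draw(pool, params$refs_per_species * k_r)
                 else draw(ref_free, params$refs_per_species * k_r)
          if (exact_mode) pool <- setdiff(pool, got)
          matrix(got, nrow = k_r)
        } else NULL
        for (j in seq_len(params$refs_per_species)) {
          acc <- sprintf("%s_%s_R%02d", marker,
                         gsub("[^A-Za-z0-9]", "", rows$species[i]), j)
          seqs[acc] <- int_to_dna(
            if (k_r > 0L) mutate_at(anc_s, ref_pos[, j]) else anc_s)
          tax[[acc]] <- cbind(rows[i, ], accession = acc)
        }
      }
    }
    for (j in 1:2) {
      acc <- sprintf("%s_OUTG_R%02d", marker, j)
      seqs[acc] <- int_to_dna(sample.int(4L, L, replace = TRUE))
      tax[[acc]] <- data.frame(kingdom = "Chromista", phylum = "Ochrophyta",
                               class = "OutClass", order = "OutOrder",
                               family = "OutFamily", genus = "Outgenus",
                               species = sprintf("Outgenus sp%d", j),
                               accession = acc, stringsAsFactors = FALSE)
    }
    taxonomy <- do.call(rbind, tax)
    rownames(taxonomy) <- NULL
    refdb(seqs, taxonomy)
  })
}

#' Simulate site communities on a coastal-offshore gradient
#'
#' Per-taxon per-site abundances are log-normal; taxa are alternately
#' associated with the coastal or offshore class and scaled by
#' `1 + gradient_strength` in their home class and `1 - gradient_strength`
#' elsewhere, so `gradient_strength = 1` yields fully disjoint class
#' compositions and 0 yields none.
#'
#' @param params a [sim_params()] object (`n_sites >= 2`).
#' @return list with `abundance` (integer taxa x sites matrix), `site_class`
#'   (named character vector) and `taxon_class` (home class per taxon).
#' @export
simulate_communities <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  if (params$n_sites < 2L) stop("need at least 2 sites")
  spt <- species_table(params)
  taxa <- spt$species
  cls <- site_classes(params)
  taxon_class <- rep(c("coastal", "offshore"), length.out = length(taxa))
  with_seed(derive_seed(params$seed, "communities"), {
    base <- matrix(stats::rlnorm(length(taxa) * params$n_sites,
                                 params$lognormal_mu, params$lognormal_sigma),
                   nrow = length(taxa))
    mult <- outer(taxon_class, unname(cls), function(tc, sc) {
      ifelse(tc == sc, 1 + params$gradient_strength,
             1 - params$gradient_strength)
    })
    ab <- round(base * mult)
    storage.mode(ab) <- "integer"
    dimnames(ab) <- list(taxa, names(cls))
    list(abundance = ab, site_class = cls,
         taxon_class = stats::setNames(taxon_class, taxa))
  })
}

# Per-base qualities: high-quality Ion-Torrent-like profile, mean ~32.
sim_quality <- function(n, L) {
  q <- matrix(pmin(40L, pmax(2L, round(stats::rnorm(n * L, 32, 4)))), nrow = n)
  apply(q, 1L, phred_string)
}

#' Simulate amplicon reads for one marker
#'
#' Per station, read counts per taxon are multinomial in abundance; reads are
#' copies of a uniformly chosen conspecific reference with i.i.d. per-base
#' substitution errors. A `chimera_fraction` of reads is built from a prefix
#' of one parent and a suffix of another (breakpoint uniform in the middle
#' 50% of the amplicon; parents are references of the station's two most
#' abundant taxa), and a `contaminant_fraction` from the non-metazoan
#' outgroup. Stations listed in `dropout_samples[[marker]]` get no reads.
#'
#' @param community output of [simulate_communities()].
#' @param db a [refdb()] containing every community taxon.
#' @param params a [sim_params()] object.
#' @param marker marker label.
#' @return list with `reads` (data.frame: id, sequence, quality, sample,
#'   marker) and `truth` (per-read true taxon and chimera/contaminant flags).
#' @export
simulate_reads <- function(community, db, params, marker) {
  stopifnot(inherits(params, "sim_params"), inherits(db, "refdb"))
  ab <- community$abundance
  if (!all(rownames(ab) %in% db$taxonomy$species)) {
    stop("community contains taxa absent from the reference database")
  }
  L <- as.integer(params$marker_lengths[[marker]])
  n_per_site <- as.integer(params$reads_per_site[[marker]])
  dropouts <- params$dropout_samples[[marker]]
  refs_by_sp <- split(db$taxonomy$accession, db$taxonomy$species)
  out_accs <- db$taxonomy$accession[!db$taxonomy$metazoan]
  ref_int <- lapply(db$sequences, dna_to_int)

  with_seed(derive_seed(params$seed, paste0("reads_", marker)), {
    reads <- list(); truth <- list()
    for (site in colnames(ab)) {
      n_tot <- if (site %in% dropouts) 0L else n_per_site
      if (n_tot == 0L || sum(ab[, site]) == 0L) next
      n_cont <- stats::rbinom(1L, n_tot, params$contaminant_fraction)
      n_chim <- stats::rbinom(1L, n_tot - n_cont, params$chimera_fraction)
      top2 <- rownames(ab)[order(-ab[, site])][1:2]
      if (nrow(ab) < 2L || is.na(top2[2L]) || ab[top2[2L], site] == 0L) n_chim <- 0L
      n_norm <- n_tot - n_cont - n_chim

      taxa_draw <- sample(rownames(ab), n_norm, replace = TRUE,
                          prob = ab[, site])
      seq_int <- vector("list", n_tot)
      tru <- data.frame(taxon = c(taxa_draw, rep(NA_character_, n_chim),
                                  rep(NA_character_, n_cont)),
                        is_chimera = rep(c(FALSE, TRUE, FALSE),
                                         c(n_norm, n_chim, n_cont)),
                        is_contaminant = rep(c(FALSE, FALSE, TRUE),
                                             c(n_norm, n_chim, n_cont)),
                        stringsAsFactors = FALSE)
      for (i in seq_len(n_norm)) {
        acc <- sample(refs_by_sp[[taxa_draw[i]]], 1L)
        seq_int[[i]] <- ref_int[[acc]]
      }
      if (n_chim > 0L) {
        pa <- ref_int[[refs_by_sp[[top2[1L]]][1L]]]
        pb <- ref_int[[refs_by_sp[[top2[2L]]][1L]]]
        for (i in seq_len(n_chim)) {
          bp <- sample(seq.int(floor(L * 0.25), ceiling(L * 0.75)), 1L)
          seq_int[[n_norm + i]] <- c(pa[seq_len(bp)], pb[seq.int(bp + 1L, L)])
        }
        tru$taxon[n_norm + seq_len(n_chim)] <-
          paste(top2, collapse = "+")
      }
      for (i in seq_len(n_cont)) {
        acc <- sample(out_accs, 1L)
        seq_int[[n_norm + n_chim + i]] <- ref_int[[acc]]
        tru$taxon[n_norm + n_chim + i] <-
          db$taxonomy$species[db$taxonomy$accession == acc]
      }
      # i.i.d. substitution errors on every read
      if (params$substitution_error_rate > 0) {
        for (i in seq_len(n_tot)) {
          k <- stats::rbinom(1L, L, params$substitution_error_rate)
          if (k > 0L) seq_int[[i]] <- mutate_fixed(seq_int[[i]], k)
        }
      }
      ids <- sprintf("%s_%s_r%05d", marker, site, seq_len(n_tot))
      reads[[site]] <- data.frame(
        id = ids,
        sequence = vapply(seq_int, int_to_dna, character(1)),
        quality = sim_quality(n_tot, L),
        sample = site, marker = marker, stringsAsFactors = FALSE)
      truth[[site]] <- cbind(data.frame(id = ids, sample = site,
                                        stringsAsFactors = FALSE), tru)
    }
    empty <- data.frame(id = character(), sequence = character(),
                        quality = character(), sample = character(),
                        marker = character(), stringsAsFactors = FALSE)
    list(reads = if (length(reads)) do.call(rbind, c(reads, make.row.names = FALSE)) else empty,
         truth = if (length(truth)) do.call(rbind, c(truth, make.row.names = FALSE)) else
           data.frame(id = character(), sample = character(),
                      taxon = character(), is_chimera = logical(),
                      is_contaminant = logical(), stringsAsFactors = FALSE))
  })
}

#' Pool per-sample reads into one multiplexed library
#'
#' Prepends the per-sample tag and the forward primer to every read (with
#' matching high-quality bases), emulating the undemultiplexed library that
#' the QC stage consumes.
#'
#' @param reads read table from [simulate_reads()].
#' @param tags named character vector sample -> tag sequence (10-12 bases).
#' @param primer forward primer sequence (IUPAC; attached as its literal
#'   ACGT realization here).
#' @return pooled read table (id, sequence, quality).
#' @export
multiplex_reads <- function(reads, tags, primer) {
  miss <- setdiff(unique(reads$sample), names(tags))
  if (length(miss)) stop("no tag for sample(s): ", paste(miss, collapse = ", "))
  pre <- paste0(tags[reads$sample], primer)
  data.frame(id = reads$id,
             sequence = paste0(pre, reads$sequence),
             quality = paste0(vapply(nchar(pre), function(n)
               phred_string(rep(38L, n)), character(1)), reads$quality),
             stringsAsFactors = FALSE)
}

#' Simulate morphological identification records
#'
#' One record per (station, taxon) pair with non-zero abundance, retained
#' with the taxon's detection probability.
#'
#' @param community output of [simulate_communities()].
#' @param detectability single probability or named vector taxon -> prob.
#' @param seed integer seed.
#' @return data.frame (sample, taxon, method = "MORPH").
#' @export
simulate_morph_records <- function(community, detectability, seed) {
  ab <- community$abundance
  taxa <- rownames(ab)
  if (length(detectability) == 1L && is.null(names(detectability))) {
    detectability <- stats::setNames(rep(detectability, length(taxa)), taxa)
  }
  if (any(detectability < 0 | detectability > 1)) {
    stop("detectability probabilities must lie in [0, 1]")
  }
  present <- which(ab > 0, arr.ind = TRUE)
  if (nrow(present) == 0L) {
    return(data.frame(sample = character(), taxon = character(),
                      method = character(), stringsAsFactors = FALSE))
  }
  tx <- taxa[present[, 1L]]
  smp <- colnames(ab)[present[, 2L]]
  with_seed(seed, {
    keep <- stats::runif(length(tx)) < detectability[tx]
    out <- data.frame(sample = smp[keep], taxon = tx[keep],
                      method = rep("MORPH", sum(keep)),
                      stringsAsFactors = FALSE)
    out <- out[order(out$sample, out$taxon), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}
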