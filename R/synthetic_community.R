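# Synthetic SAG community generator.
#
# Generates reference taxa (phylum, genetic code, coding density, marker and
# gene complements, a divergent 16S gene) and partial single-cell assemblies
# from them, including planted two-cell co-sorts, so that every downstream
# stage of the pipeline can be exercised against known truth.

.sagcensus_cache <- new.env(parent = emptyenv())

#' The 25 COG functional category letters
#'
#' Single-letter functional categories of the Clusters of Orthologous Groups
#' scheme, in the fixed column order used by [build_cog_matrix()].
#'
#' @return Character vector of 25 category letters.
#' @export
cog_categories <- function() {
  c("J", "A", "K", "L", "B", "D", "Y", "V", "T", "M", "N", "Z", "W",
    "U", "O", "C", "G", "E", "F", "H", "I", "P", "Q", "R", "S")
}

#' The 56-gene universal single-copy marker set
#'
#' Labels for the 56 universal single-copy marker proteins used for
#' completeness and contamination estimation (ribosomal proteins plus a set
#' of universally conserved information-processing genes).
#'
#' @return Character vector of 56 marker labels.
#' @export
marker_universe <- function() {
  c(paste0("rpl", c(1:6, 10, 11, 13:16, 18:24, 27, 29, 30)),
    paste0("rps", c(2:13, 15:17, 19)),
    "secY", "secE", "ffh", "ftsY", "infB", "infC", "tsf", "frr",
    "rpoA", "rpoB", "rpoC", "nusA", "nusG", "smpB",
    "pheS", "pheT", "serS", "pyrG")
}

#' Default electron-transport-chain complex map
#'
#' A small KO-to-complex map covering respiratory complexes I-IV (NADH
#' dehydrogenase, succinate dehydrogenase, cytochrome c reductase, and
#' terminal reductase subunits). The membership is configuration, not ground
#' truth: swap in a curated map for real data. Thresholds emulate per-family
#' curated HMM score cutoffs and are a deterministic function of the KO id.
#'
#' @return Data frame with columns `ko`, `complex`, `threshold`.
#' @export
default_complex_map <- function() {
  kos <- list(
    I   = c("K00330", "K00331", "K00332", "K00333", "K00334", "K00335"),
    II  = c("K00234", "K00235", "K00236", "K00237"),
    III = c("K00410", "K00411", "K00412"),
    IV  = c("K02274", "K02275", "K02276")
  )
  df <- data.frame(
    ko      = unlist(kos, use.names = FALSE),
    complex = rep(names(kos), lengths(kos)),
    stringsAsFactors = FALSE
  )
  df$threshold <- 100 + vapply(df$ko, hash_key, numeric(1)) %% 200
  df
}

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_peptide <- function(n) paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")

mutate_peptide <- function(pep, rate) {
  aa <- strsplit(pep, "")[[1]]
  hit <- stats::runif(length(aa)) < rate
  if (any(hit)) {
    aa[hit] <- vapply(aa[hit], function(x) sample(setdiff(AA_ALPHABET, x), 1), "")
  }
  paste(aa, collapse = "")
}

#' Packaged oxygen-reductase reference peptides (synthetic)
#'
#' A small synthetic stand-in for a curated oxygen-reductase subunit database:
#' heme-copper oxidase subunit I (family `HCO_A`, low affinity for oxygen) and
#' bd-ubiquinol oxidase subunit A (family `bd`, high affinity). Affinity is a
#' property of the family carried as reference metadata. Sequences are
#' deterministic random peptides, not biological sequences.
#'
#' @return Data frame with columns `id`, `family`, `affinity`, `seq`.
#' @export
o2red_reference <- function() {
  if (!is.null(.sagcensus_cache$o2red_ref)) return(.sagcensus_cache$o2red_ref)
  ref <- with_seed(615234, {
    data.frame(
      id       = c("HCOA_ref1", "HCOA_ref2", "BD_ref1", "BD_ref2"),
      family   = c("HCO_A", "HCO_A", "bd", "bd"),
      affinity = c("low", "low", "high", "high"),
      seq      = c(random_peptide(550), random_peptide(520),
                   random_peptide(430), random_peptide(450)),
      stringsAsFactors = FALSE
    )
  })
  .sagcensus_cache$o2red_ref <- ref
  ref
}

#' Default phylum set of the generator
#'
#' Superphylum-level grouping with generator styles, domains and the default
#' cohort mixture weights (the fraction of cells drawn from each group).
#'
#' @return Data frame with columns `phylum`, `style`, `domain`, `weight`.
#' @export
default_phyla <- function() {
  data.frame(
    phylum = c("Patescibacteria", "DPANN", "Other-Bacteria", "Other-Archaea"),
    style  = c("patesci_like", "dpann_like", "standard", "standard"),
    domain = c("Bacteria", "Archaea", "Bacteria", "Archaea"),
    weight = c(0.16, 0.02, 0.62, 0.20),
    stringsAsFactors = FALSE
  )
}

ssu_ancestor <- function() {
  if (is.null(.sagcensus_cache$ssu_ancestor)) {
    .sagcensus_cache$ssu_ancestor <- with_seed(424243, random_dna(1542))
  }
  .sagcensus_cache$ssu_ancestor
}

#' Phylum-level 16S reference sequence
#'
#' Deterministic per-phylum 16S reference, derived from a fixed common
#' ancestor by ~10% divergence so distinct phyla sit at ~19% pairwise
#' divergence (ample signal for an 8-mer classifier).
#'
#' @param phylum Phylum label.
#' @return Nucleotide sequence (character scalar).
#' @export
phylum_reference_ssu <- function(phylum) {
  key <- paste0("phyref_", phylum)
  if (is.null(.sagcensus_cache[[key]])) {
    .sagcensus_cache[[key]] <- evolve_ssu(ssu_ancestor(), 0.10,
                                          seed = split_seed(7919, "phylum-ref", phylum))
  }
  .sagcensus_cache[[key]]
}

#' Labeled 16S reference database
#'
#' Builds the packaged reference database for the naive-Bayes classifier:
#' `n_per_phylum` sequences per phylum, each at ~2% divergence from the
#' phylum reference.
#'
#' @param phyla Character vector of phylum labels.
#' @param n_per_phylum Sequences per phylum.
#' @param seed Integer seed (the default gives the packaged reference set).
#' @return Data frame with columns `id`, `phylum`, `seq`.
#' @export
ssu_refdb <- function(phyla = default_phyla()$phylum, n_per_phylum = 3, seed = 1903) {
  rows <- lapply(phyla, function(ph) {
    data.frame(
      id = sprintf("%s_ref%d", gsub("[^A-Za-z0-9]", "", ph), seq_len(n_per_phylum)),
      phylum = ph,
      seq = vapply(seq_len(n_per_phylum), function(i) {
        evolve_ssu(phylum_reference_ssu(ph), 0.02,
                   seed = split_seed(seed, "refdb", ph, i))
      }, ""),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

# style presets: the generative study conditions (see the methods vignette)
style_presets <- function() {
  list(
    standard = list(
      code25_prob = 0, density_mean = 0.90, density_sd = 0.02,
      genome_length = 100000, ec1_rate = 0.05,
      etc_complement = c("I", "II", "III", "IV"),
      o2red = c("HCO_A", "bd"), diameter_um_mean = 0.8,
      cog_depletion = character(0), ssu_divergence = 0.02
    ),
    patesci_like = list(
      code25_prob = 0.3, density_mean = 0.91, density_sd = 0.02,
      genome_length = 75000, ec1_rate = 0.01,
      etc_complement = character(0),
      o2red = character(0), diameter_um_mean = 0.35,
      cog_depletion = c("C", "E", "H", "P"), ssu_divergence = 0.02
    ),
    dpann_like = list(
      code25_prob = 0, density_mean = 0.90, density_sd = 0.02,
      genome_length = 75000, ec1_rate = 0.01,
      etc_complement = character(0),
      o2red = character(0), diameter_um_mean = 0.35,
      cog_depletion = c("C", "E", "H", "P"), ssu_divergence = 0.02
    ),
    symbiont_like = list(
      code25_prob = 0, density_mean = 0.85, density_sd = 0.02,
      genome_length = 85000, ec1_rate = 0.03,
      etc_complement = c("IV"),
      o2red = character(0), diameter_um_mean = 0.5,
      cog_depletion = c("C", "H"), ssu_divergence = 0.02
    )
  )
}

base_cog_weights <- function() {
  w <- c(J = 0.060, A = 0.002, K = 0.070, L = 0.060, B = 0.002, D = 0.010,
         Y = 0.001, V = 0.015, T = 0.040, M = 0.050, N = 0.015, Z = 0.002,
         W = 0.002, U = 0.020, O = 0.040, C = 0.060, G = 0.070, E = 0.080,
         F = 0.020, H = 0.045, I = 0.030, P = 0.050, Q = 0.020, R = 0.120,
         S = 0.100)
  w[cog_categories()] / sum(w)
}

#' Generate a reference taxon profile
#'
#' Draws the generative truth for one taxon: domain, genetic code, target
#' coding density, marker/COG/ETC/oxygen-reductase complements, and a
#' taxon-specific 16S sequence. Profiles are deterministic for a given
#' `(phylum, style, seed)`.
#'
#' Styles encode the cohort contrasts: `patesci_like`/`dpann_like` deplete
#' COG categories C/E/H/P, carry no electron-transport complexes or oxygen
#' reductases and a low oxidoreductase (EC1) rate; `patesci_like` taxa may
#' use genetic code 25 (TGA read-through); `symbiont_like` lowers coding
#' density.
#'
#' @param phylum Phylum label.
#' @param style One of `"standard"`, `"patesci_like"`, `"dpann_like"`,
#'   `"symbiont_like"`.
#' @param seed Integer seed.
#' @param taxon_id Optional taxon label; defaults to `phylum_style_seed`.
#' @param domain `"Bacteria"` or `"Archaea"`.
#' @param overrides Named list of preset fields to override (e.g.,
#'   `genome_length`, `genetic_code`, `marker_complement`, `ec1_rate`).
#' @return An object of class `taxon_profile`.
#' @export
make_taxon_profile <- function(phylum, style = c("standard", "patesci_like",
                                                 "dpann_like", "symbiont_like"),
                               seed, taxon_id = NULL, domain = "Bacteria",
                               overrides = list()) {
  style <- match.arg(style)
  preset <- style_presets()[[style]]
  preset_keys <- intersect(names(overrides), names(preset))
  preset[preset_keys] <- overrides[preset_keys]

  if (is.null(taxon_id)) taxon_id <- paste(phylum, style, seed, sep = "_")

  prof <- with_seed(split_seed(seed, "taxon", phylum, style), {
    genetic_code <- if (!is.null(overrides$genetic_code)) {
      as.integer(overrides$genetic_code)
    } else if (stats::runif(1) < preset$code25_prob) 25L else 11L

    density <- stats::rnorm(1, preset$density_mean, preset$density_sd)
    # cap so the (non-coding) 16S gene and some intergenic room always fit
    cap <- (as.numeric(preset$genome_length) - 2600) / as.numeric(preset$genome_length)
    density <- min(max(density, 0.5), 0.98, cap)

    w <- base_cog_weights()
    if (length(preset$cog_depletion)) w[preset$cog_depletion] <- w[preset$cog_depletion] * 0.2
    w <- w * exp(stats::rnorm(length(w), 0, 0.10))
    w <- w / sum(w)

    markers <- if (!is.null(overrides$marker_complement)) {
      overrides$marker_complement
    } else {
      marker_universe()
    }

    o2red_genes <- if (length(preset$o2red)) {
      lapply(preset$o2red, function(fam) {
        list(family = fam, affinity = if (fam == "bd") "high" else "low")
      })
    } else list()

    structure(list(
      taxon_id = taxon_id,
      domain = domain,
      phylum = phylum,
      style = style,
      genetic_code = genetic_code,
      target_coding_density = density,
      genome_length = as.integer(preset$genome_length),
      marker_complement = markers,
      ssu_ref = evolve_ssu(phylum_reference_ssu(phylum), preset$ssu_divergence,
                           seed = split_seed(seed, "ssu", taxon_id)),
      cog_distribution = w,
      ec1_rate = preset$ec1_rate,
      etc_complement = preset$etc_complement,
      o2red_genes = o2red_genes,
      diameter_um_mean = preset$diameter_um_mean
    ), class = "taxon_profile")
  })
  validate_taxon_profile(prof)
  prof
}

validate_taxon_profile <- function(p) {
  stopifnot(inherits(p, "taxon_profile"))
  if (abs(sum(p$cog_distribution) - 1) > 1e-9) stop("cog_distribution must sum to 1")
  if (nchar(p$ssu_ref) < 1200) stop("ssu_ref must be >= 1,200 nt")
  if (!p$genetic_code %in% c(11L, 25L)) stop("genetic_code must be 11 or 25")
  if (p$ec1_rate < 0 || p$ec1_rate > 1) stop("ec1_rate must lie in [0, 1]")
  if (p$target_coding_density < 0.5 || p$target_coding_density > 1) {
    stop("target_coding_density must lie in [0.5, 1]")
  }
  invisible(p)
}

#' @export
print.taxon_profile <- function(x, ...) {
  cat(sprintf("<taxon_profile> %s (%s, %s)\n", x$taxon_id, x$phylum, x$style))
  cat(sprintf("  code %d | density %.3f | genome %d nt | markers %d | ETC {%s}\n",
              x$genetic_code, x$target_coding_density, x$genome_length,
              length(x$marker_complement), paste(x$etc_complement, collapse = ",")))
  invisible(x)
}

#' Evolve a 16S sequence by random substitution
#'
#' Single-hit substitution model: every site is substituted independently
#' with probability `divergence`, to one of the three other bases, so the
#' expected observed difference fraction equals `divergence` (no multiple-hit
#' correction). Length is preserved.
#'
#' @param ref Nucleotide sequence.
#' @param divergence Substitutions per site, in `[0, 0.3]`.
#' @param seed Integer seed.
#' @return Nucleotide sequence of the same length.
#' @export
evolve_ssu <- function(ref, divergence, seed) {
  if (divergence < 0 || divergence > 0.3) {
    stop("divergence must lie in [0, 0.3]", call. = FALSE)
  }
  if (divergence == 0) return(ref)
  with_seed(seed, {
    nt <- strsplit(ref, "")[[1]]
    hit <- stats::runif(length(nt)) < divergence
    if (any(hit)) {
      nt[hit] <- vapply(nt[hit], function(x) sample(setdiff(DNA_BASES, x), 1), "")
    }
    paste(nt, collapse = "")
  })
}

sense_codons <- function(table) {
  setdiff(names(Biostrings::GENETIC_CODE), stop_codons(table))
}

# aa -> representative sense codons (valid under both code 11 and 25)
codon_choices <- function() {
  if (is.null(.sagcensus_cache$codon_choices)) {
    gc <- Biostrings::GENETIC_CODE
    gc <- gc[!names(gc) %in% c("TAA", "TAG", "TGA")]
    .sagcensus_cache$codon_choices <- split(names(gc), unname(gc))
  }
  .sagcensus_cache$codon_choices
}

reverse_translate <- function(pep) {
  ch <- codon_choices()
  aa <- strsplit(pep, "")[[1]]
  paste(vapply(aa, function(a) {
    cs <- ch[[a]]
    cs[sample.int(length(cs), 1)]
  }, ""), collapse = "")
}

make_cds <- function(n_codons, table) {
  body <- sample(sense_codons(table), n_codons - 2L, replace = TRUE)
  paste(c("ATG", body, sample(stop_codons(table), 1)), collapse = "")
}

#' Synthesize a genome from a taxon profile
#'
#' Lays out marker, electron-transport, oxygen-reductase and filler genes on
#' both strands with i.i.d. uniform intergenic sequence, embeds the taxon's
#' 16S gene, and returns the genome together with its gene map and truth
#' annotation table. Genes are ATG-initiated and terminated by the stop set
#' of the profile's genetic code; code-25 genes freely use TGA as a sense
#' codon, so essentially every code-25 CDS carries in-frame TGA.
#'
#' @param profile A `taxon_profile`.
#' @param seed Integer seed.
#' @return An object of class `synthetic_genome`: a list with `taxon_id`,
#'   `phylum`, `domain`, `genetic_code`, `sequence`, `gene_map` (0-based
#'   half-open intervals), `annotations`, and `ssu` (interval + strand).
#' @export
synthesize_genome <- function(profile, seed) {
  validate_taxon_profile(profile)
  with_seed(split_seed(seed, "genome", profile$taxon_id), {
    code <- profile$genetic_code
    L <- profile$genome_length
    target_coding <- round(profile$target_coding_density * L)

    genes <- list()
    add_gene <- function(type, n_codons = NULL, cds = NULL, marker_id = NA,
                         ko_id = NA, family = NA, affinity = NA) {
      if (is.null(cds)) cds <- make_cds(n_codons, code)
      genes[[length(genes) + 1L]] <<- list(
        type = type, cds = cds, marker_id = marker_id, ko_id = ko_id,
        family = family, affinity = affinity
      )
    }

    for (m in profile$marker_complement) {
      add_gene("marker", n_codons = sample(220:300, 1), marker_id = m)
    }
    cmap <- default_complex_map()
    for (cx in profile$etc_complement) {
      for (ko in cmap$ko[cmap$complex == cx]) {
        add_gene("etc", n_codons = sample(300:460, 1), ko_id = ko)
      }
    }
    if (length(profile$o2red_genes)) {
      refs <- o2red_reference()
      for (g in profile$o2red_genes) {
        fam_refs <- refs[refs$family == g$family, , drop = FALSE]
        pep <- mutate_peptide(fam_refs$seq[sample.int(nrow(fam_refs), 1)], 0.03)
        pep <- paste0("M", substring(pep, 2))
        cds <- paste0(reverse_translate(pep), sample(stop_codons(code), 1))
        add_gene("o2red", cds = cds, family = g$family, affinity = g$affinity)
      }
    }

    coding_now <- function() sum(vapply(genes, function(g) nchar(g$cds), 0))
    acc <- coding_now()
    if (acc > target_coding) {
      stop("genome_length too small to fit the requested gene complements",
           call. = FALSE)
    }
    while (target_coding - acc > 1380) {
      n <- sample(250:450, 1)
      add_gene("filler", n_codons = n)
      acc <- acc + 3 * n
    }
    rem_codons <- floor((target_coding - acc) / 3)
    if (rem_codons >= 100) {
      add_gene("filler", n_codons = rem_codons)
      acc <- acc + 3 * rem_codons
    }

    ssu_seq <- profile$ssu_ref
    non_coding <- L - acc - nchar(ssu_seq)
    if (non_coding < 0) {
      stop("genome_length too small to fit the requested gene complements",
           call. = FALSE)
    }

    # treat the 16S as one more (non-coding) piece in a random gene order
    n_genes <- length(genes)
    piece_order <- sample(n_genes + 1L)
    ssu_slot <- which(piece_order == n_genes + 1L)
    gaps <- as.integer(stats::rmultinom(1, non_coding, rep(1, n_genes + 2L)))

    pieces <- character(2 * (n_genes + 1L) + 1L)
    pieces[1] <- random_dna(gaps[1])
    map_rows <- vector("list", n_genes + 1L)
    pos <- gaps[1]
    prot_i <- 0L
    for (j in seq_len(n_genes + 1L)) {
      idx <- piece_order[j]
      strand <- sample(c("+", "-"), 1)
      if (idx <= n_genes) {
        g <- genes[[idx]]
        cds <- g$cds
        len <- nchar(cds)
        emitted <- if (strand == "+") cds else revcomp(cds)
        prot_i <- prot_i + 1L
        map_rows[[j]] <- data.frame(
          gene_id = sprintf("%s_g%03d", profile$taxon_id, idx),
          protein_id = sprintf("%s_p%03d", profile$taxon_id, prot_i),
          type = g$type, marker_id = g$marker_id, ko_id = g$ko_id,
          family = g$family, affinity = g$affinity,
          start = pos, end = pos + len, strand = strand, length_nt = len,
          stringsAsFactors = FALSE
        )
      } else {
        len <- nchar(ssu_seq)
        emitted <- if (strand == "+") ssu_seq else revcomp(ssu_seq)
        map_rows[[j]] <- data.frame(
          gene_id = sprintf("%s_ssu", profile$taxon_id),
          protein_id = NA_character_, type = "ssu", marker_id = NA_character_,
          ko_id = NA_character_, family = NA_character_,
          affinity = NA_character_,
          start = pos, end = pos + len, strand = strand, length_nt = len,
          stringsAsFactors = FALSE
        )
      }
      pieces[2 * j] <- emitted
      pieces[2 * j + 1L] <- random_dna(gaps[j + 1L])
      pos <- pos + len + gaps[j + 1L]
    }
    genome_seq <- paste(pieces, collapse = "")
    gene_map <- do.call(rbind, map_rows)

    cds_map <- gene_map[gene_map$type != "ssu", , drop = FALSE]
    ann <- annotate_proteins(cds_map, profile)

    ssu_row <- gene_map[gene_map$type == "ssu", , drop = FALSE]
    structure(list(
      taxon_id = profile$taxon_id,
      phylum = profile$phylum,
      domain = profile$domain,
      genetic_code = code,
      sequence = genome_seq,
      gene_map = gene_map,
      annotations = ann,
      ssu = list(start = ssu_row$start, end = ssu_row$end, strand = ssu_row$strand)
    ), class = "synthetic_genome")
  })
}

# truth annotation rows (COG / EC / KO / marker) for one genome's proteins
annotate_proteins <- function(cds_map, profile) {
  n <- nrow(cds_map)
  cmap <- default_complex_map()
  cat_letters <- cog_categories()

  cog <- ifelse(stats::runif(n) < 0.85,
                sample(cat_letters, n, replace = TRUE, prob = profile$cog_distribution),
                NA_character_)
  u <- stats::runif(n)
  ec <- ifelse(u < profile$ec1_rate, 1L,
               ifelse(stats::runif(n) < 0.35, sample(2:7, n, replace = TRUE),
                      NA_integer_))

  ko_id <- cds_map$ko_id
  ko_thr <- cmap$threshold[match(ko_id, cmap$ko)]
  ko_score <- ifelse(is.na(ko_id), NA_real_,
                     round(ko_thr * stats::runif(n, 0.6, 1.4), 2))

  ann <- data.frame(
    genome_id = profile$taxon_id,
    protein_id = cds_map$protein_id,
    marker_id = cds_map$marker_id,
    cog_category = cog,
    ec_top_class = as.integer(ec),
    ko_id = ko_id,
    ko_score = ko_score,
    ko_threshold = ko_thr,
    stringsAsFactors = FALSE
  )

  # sub-threshold decoy KO rows on a few filler proteins, so the KO
  # acceptance rule has rejections to exercise
  filler <- which(cds_map$type == "filler")
  decoy <- filler[stats::runif(length(filler)) < 0.08]
  if (length(decoy)) {
    dk <- sample(cmap$ko, length(decoy), replace = TRUE)
    thr <- cmap$threshold[match(dk, cmap$ko)]
    ann2 <- data.frame(
      genome_id = profile$taxon_id,
      protein_id = cds_map$protein_id[decoy],
      marker_id = NA_character_,
      cog_category = NA_character_,
      ec_top_class = NA_integer_,
      ko_id = dk,
      ko_score = round(thr * stats::runif(length(decoy), 0.05, 0.45), 2),
      ko_threshold = thr,
      stringsAsFactors = FALSE
    )
    ann <- rbind(ann, ann2)
  }
  rownames(ann) <- NULL
  ann
}

#' Extract protein sequences from a synthetic genome
#'
#' Translates every protein-coding gene in the genome's gene map under the
#' genome's genetic code (table 25 reads TGA as glycine). The terminal stop
#' codon is dropped.
#'
#' @param genome A `synthetic_genome`.
#' @return Named character vector of peptides (names = protein ids).
#' @export
genome_proteins <- function(genome) {
  gm <- genome$gene_map
  gm <- gm[gm$type != "ssu", , drop = FALSE]
  code <- genetic_code_table(genome$genetic_code)
  peps <- vapply(seq_len(nrow(gm)), function(i) {
    cds <- substr(genome$sequence, gm$start[i] + 1L, gm$end[i])
    if (gm$strand[i] == "-") cds <- revcomp(cds)
    cds <- substr(cds, 1L, nchar(cds) - 3L)  # drop stop
    n <- nchar(cds)
    paste(code[substring(cds, seq(1, n, 3), seq(3, n, 3))], collapse = "")
  }, "")
  stats::setNames(peps, gm$protein_id)
}

#' Sample a partial single-cell assembly from one or two genomes
#'
#' Draws non-overlapping genomic fragments covering approximately the
#' requested completeness fraction of each source genome, emulating the
#' partial genome recovery of single-cell sequencing. Two sources model a
#' co-sorted pair of cells (`admixture = TRUE`). Truth annotation rows are
#' subset to proteins fully contained in retained fragments.
#'
#' @param genomes A `synthetic_genome` or list of one or two.
#' @param completeness Fraction(s) in `(0, 1]`, recycled per source.
#' @param n_fragments Total number of contigs to aim for (>= 1).
#' @param plate_id Plate label.
#' @param sag_id SAG label.
#' @param diameter_um Cell diameter in micrometers (metadata, may be `NA`).
#' @param seed Integer seed.
#' @param min_contig_len Minimum retained contig length in nt (assembly
#'   filter; fragments shorter than this are never emitted).
#' @return An object of class `sag_assembly`: `sag_id`, `plate_id`, `contigs`
#'   (named character), `diameter_um`, `truth` (sources, realized per-source
#'   completeness, admixture flag, fragment count), `annotations`, and
#'   `gene_map` (retained genes in contig-local 0-based coordinates).
#' @export
sample_sag <- function(genomes, completeness, n_fragments = 8,
                       plate_id = "plate1", sag_id = "sag1",
                       diameter_um = NA_real_, seed = 1,
                       min_contig_len = 2000) {
  if (inherits(genomes, "synthetic_genome")) genomes <- list(genomes)
  stopifnot(length(genomes) %in% 1:2, n_fragments >= 1)
  completeness <- rep_len(completeness, length(genomes))
  if (any(completeness <= 0) || any(completeness > 1)) {
    stop("completeness must lie in (0, 1]", call. = FALSE)
  }

  with_seed(split_seed(seed, "sag", sag_id), {
    lens_L <- vapply(genomes, function(g) nchar(g$sequence), 0)
    R <- pmin(round(completeness * lens_L), lens_L)
    # retained fragments can never be shorter than the assembly length filter
    R <- pmax(R, pmin(min_contig_len, lens_L))
    k <- pmax(1L, round(n_fragments * R / sum(R)))
    k <- pmin(k, pmax(1L, floor(R / min_contig_len)))

    contigs <- character(0)
    ann_list <- list()
    map_list <- list()
    realized <- numeric(length(genomes))
    ci <- 0L
    for (s in seq_along(genomes)) {
      g <- genomes[[s]]
      L <- lens_L[s]
      ks <- k[s]
      Rs <- min(R[s], L)
      if (Rs >= L) {
        ks <- 1L
        starts <- 0L
        lens <- L
      } else {
        extra <- max(Rs - ks * min_contig_len, 0)
        lens <- min(min_contig_len, Rs) + as.integer(stats::rmultinom(1, extra, rep(1, ks)))
        gaps <- as.integer(stats::rmultinom(1, L - sum(lens), rep(1, ks + 1L)))
        starts <- if (ks == 1L) gaps[1] else cumsum(c(gaps[1], lens[-ks] + gaps[2:ks]))
      }
      realized[s] <- sum(lens) / L
      gm <- g$gene_map
      for (j in seq_len(ks)) {
        ci <- ci + 1L
        cid <- sprintf("%s_c%02d", sag_id, ci)
        fs <- starts[j]
        fe <- fs + lens[j]
        contigs[cid] <- substr(g$sequence, fs + 1L, fe)
        keep <- gm$start >= fs & gm$end <= fe
        if (any(keep)) {
          sub <- gm[keep, , drop = FALSE]
          sub$contig_id <- cid
          sub$start <- sub$start - fs
          sub$end <- sub$end - fs
          sub$source_taxon <- g$taxon_id
          map_list[[length(map_list) + 1L]] <- sub
          prot <- sub$protein_id[!is.na(sub$protein_id)]
          ann <- g$annotations[g$annotations$protein_id %in% prot, , drop = FALSE]
          if (nrow(ann)) {
            ann$contig_id <- cid
            ann_list[[length(ann_list) + 1L]] <- ann
          }
        }
      }
    }
    annotations <- if (length(ann_list)) do.call(rbind, ann_list) else NULL
    gene_map <- if (length(map_list)) do.call(rbind, map_list) else NULL
    if (!is.null(annotations)) {
      annotations <- cbind(sag_id = sag_id, annotations)
      rownames(annotations) <- NULL
    }
    if (!is.null(gene_map)) rownames(gene_map) <- NULL

    structure(list(
      sag_id = sag_id,
      plate_id = plate_id,
      contigs = contigs,
      diameter_um = diameter_um,
      truth = list(
        source_taxa = vapply(genomes, `[[`, "", "taxon_id"),
        source_phyla = vapply(genomes, `[[`, "", "phylum"),
        completeness = stats::setNames(realized, vapply(genomes, `[[`, "", "taxon_id")),
        admixture = length(genomes) == 2L,
        fragments = length(contigs)
      ),
      annotations = annotations,
      gene_map = gene_map
    ), class = "sag_assembly")
  })
}

#' @export
print.sag_assembly <- function(x, ...) {
  cat(sprintf("<sag_assembly> %s (%s): %d contigs, %d nt, sources {%s}%s\n",
              x$sag_id, x$plate_id, length(x$contigs),
              sum(nchar(x$contigs)),
              paste(x$truth$source_taxa, collapse = ","),
              if (x$truth$admixture) " [co-sort]" else ""))
  invisible(x)
}

#' Simulate a SAG community
#'
#' Generates reference taxa across the configured phyla, synthesizes one
#' genome per taxon, then draws a cohort of SAGs with partial genome
#' recovery. A fraction `cosort_rate` of SAGs are planted two-cell co-sorts
#' (two distinct taxa in one well). Cohort group labels follow the phylum of
#' the first (sorted) cell.
#'
#' @param n_taxa Number of reference taxa (>= number of phyla).
#' @param n_sags Number of SAGs.
#' @param cosort_rate Probability a SAG is a two-cell co-sort.
#' @param completeness_range Per-source completeness, drawn uniformly.
#' @param n_fragments_range Range of fragment counts per SAG.
#' @param n_plates Number of sort plates (SAGs assigned round-robin).
#' @param phyla Data frame as in [default_phyla()].
#' @param seed Integer seed.
#' @param outdir Optional directory; if given, FASTA/TSV outputs are written
#'   via [write_community()].
#' @return An object of class `sag_community`: `profiles`, `genomes`, `sags`,
#'   `truth` (one row per SAG), `annotations` (all truth annotation rows),
#'   `refdb` (the 16S reference database), `config`.
#' @export
simulate_community <- function(n_taxa = 8, n_sags = 40, cosort_rate = 0.02,
                               completeness_range = c(0.06, 0.60),
                               n_fragments_range = c(4, 12),
                               n_plates = 5, phyla = default_phyla(),
                               seed = 1, outdir = NULL) {
  stopifnot(n_taxa >= nrow(phyla), n_sags >= 1)

  counts <- pmax(1L, round(phyla$weight / sum(phyla$weight) * n_taxa))
  while (sum(counts) > n_taxa) counts[which.max(counts)] <- counts[which.max(counts)] - 1L
  while (sum(counts) < n_taxa) counts[which.max(phyla$weight)] <- counts[which.max(phyla$weight)] + 1L

  profiles <- list()
  i <- 0L
  for (p in seq_len(nrow(phyla))) {
    for (r in seq_len(counts[p])) {
      i <- i + 1L
      tid <- sprintf("t%02d", i)
      profiles[[tid]] <- make_taxon_profile(
        phyla$phylum[p], phyla$style[p],
        seed = split_seed(seed, "profile", tid),
        taxon_id = tid, domain = phyla$domain[p]
      )
    }
  }
  genomes <- lapply(profiles, function(pr) {
    synthesize_genome(pr, seed = split_seed(seed, "synth", pr$taxon_id))
  })
  taxon_phyla <- vapply(profiles, `[[`, "", "phylum")

  sags <- vector("list", n_sags)
  truth_rows <- vector("list", n_sags)
  ann_rows <- vector("list", n_sags)
  for (j in seq_len(n_sags)) {
    sid <- sprintf("sag%03d", j)
    pick <- with_seed(split_seed(seed, "pick", sid), {
      admix <- stats::runif(1) < cosort_rate
      pick_taxon <- function() {
        ph <- sample(phyla$phylum, 1, prob = phyla$weight)
        cand <- names(taxon_phyla)[taxon_phyla == ph]
        cand[sample.int(length(cand), 1)]
      }
      t1 <- pick_taxon()
      taxa <- t1
      if (admix) {
        repeat {
          t2 <- pick_taxon()
          if (t2 != t1) break
        }
        taxa <- c(t1, t2)
      }
      comp <- stats::runif(length(taxa), completeness_range[1], completeness_range[2])
      nf <- sample(n_fragments_range[1]:n_fragments_range[2], 1)
      d1 <- stats::rlnorm(1, log(profiles[[t1]]$diameter_um_mean), 0.25)
      if (admix) d1 <- d1 + stats::rlnorm(1, log(profiles[[taxa[2]]]$diameter_um_mean), 0.25)
      list(taxa = taxa, comp = comp, nf = nf, diameter = round(d1, 3))
    })
    sag <- sample_sag(genomes[pick$taxa], pick$comp, n_fragments = pick$nf,
                      plate_id = sprintf("plate%d", 1L + (j - 1L) %% n_plates),
                      sag_id = sid, diameter_um = pick$diameter,
                      seed = split_seed(seed, "frag", sid))
    sags[[j]] <- sag
    truth_rows[[j]] <- data.frame(
      sag_id = sid,
      plate_id = sag$plate_id,
      group = taxon_phyla[[pick$taxa[1]]],
      taxon_ids = paste(sag$truth$source_taxa, collapse = ","),
      phyla = paste(sag$truth$source_phyla, collapse = ","),
      completeness = paste(sprintf("%.4f", sag$truth$completeness), collapse = ","),
      admixture = sag$truth$admixture,
      fragments = sag$truth$fragments,
      diameter_um = sag$diameter_um,
      stringsAsFactors = FALSE
    )
    ann_rows[[j]] <- sag$annotations
  }
  names(sags) <- vapply(sags, `[[`, "", "sag_id")

  comm <- structure(list(
    profiles = profiles,
    genomes = genomes,
    sags = sags,
    truth = do.call(rbind, truth_rows),
    annotations = do.call(rbind, ann_rows),
    refdb = ssu_refdb(phyla$phylum),
    config = list(
      n_taxa = n_taxa, n_sags = n_sags, cosort_rate = cosort_rate,
      completeness_range = completeness_range,
      n_fragments_range = n_fragments_range, n_plates = n_plates,
      phyla = paste(phyla$phylum, collapse = ","), seed = seed
    )
  ), class = "sag_community")
  if (!is.null(outdir)) write_community(comm, outdir)
  comm
}

#' Write a simulated community to disk
#'
#' Emits contigs as 60-column wrapped FASTA, truth and annotation tables as
#' TSV, the 16S reference database as FASTA with header-embedded taxonomy
#' (`>id;phylum=X`), and the run configuration as `key=value` lines. Every
#' truth field is recoverable from these files.
#'
#' @param community A `sag_community`.
#' @param outdir Output directory (created if needed).
#' @return The output directory, invisibly.
#' @export
write_community <- function(community, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  contigs <- unlist(lapply(community$sags, `[[`, "contigs"))
  names(contigs) <- unlist(lapply(community$sags, function(s) names(s$contigs)))
  dna <- Biostrings::DNAStringSet(contigs)
  Biostrings::writeXStringSet(dna, file.path(outdir, "contigs.fasta"), width = 60)
  write_tsv(community$truth, file.path(outdir, "truth.tsv"))
  write_tsv(community$annotations, file.path(outdir, "annotations.tsv"))
  write_ssu_refdb(community$refdb, file.path(outdir, "ssu_refdb.fasta"))
  cfg <- community$config
  writeLines(sprintf("%s=%s", names(cfg),
                     vapply(cfg, function(x) paste(x, collapse = ","), "")),
             file.path(outdir, "config.txt"))
  invisible(outdir)
}
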