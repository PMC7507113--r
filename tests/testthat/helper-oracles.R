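# Independent oracles used across the suite. These deliberately use different
# algorithms (or different packages) than the implementation they check.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

rand_pep <- function(n) {
  paste(sample(rownames(sagcensus::blosum62())[1:20], n, TRUE), collapse = "")
}

# Brute-force ORF oracle: codon-by-codon scan of all 6 frames.
orf_oracle <- function(seq, table, min_orf_len) {
  stops <- if (table == 11) c("TAA", "TAG", "TGA") else c("TAA", "TAG")
  n <- nchar(seq)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc
    for (f in 0:2) {
      i <- f + 1L
      cur <- NA
      while (i + 2L <= n) {
        cod <- substr(s, i, i + 2L)
        if (is.na(cur) && cod == "ATG") cur <- i
        if (cod %in% stops) {
          if (!is.na(cur)) {
            len <- i + 3L - cur
            if (len >= min_orf_len) {
              st <- cur - 1L
              en <- i + 2L
              if (strand == "-") {
                tmp <- st
                st <- n - en
                en <- n - tmp
              }
              rows[[length(rows) + 1L]] <- data.frame(
                start = st, end = en, strand = strand, length_nt = len)
            }
          }
          cur <- NA
        }
        i <- i + 3L
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), length_nt = integer(0)))
  }
  df <- do.call(rbind, rows)
  df[order(df$start, df$end, df$strand), , drop = FALSE]
}

orf_call_set <- function(df) {
  df <- df[order(df$start, df$end, df$strand), c("start", "end", "strand", "length_nt")]
  rownames(df) <- NULL
  df
}

# Exhaustive local-alignment oracle: enumerate every monotone matching of
# query/subject positions; between consecutive aligned pairs the skipped
# residues form one affine gap per sequence. Score of the empty matching is 0.
sw_enum_oracle <- function(q, s, mat, gap_open = 11, gap_extend = 1) {
  qa <- strsplit(q, "")[[1]]
  sa <- strsplit(s, "")[[1]]
  n <- length(qa)
  m <- length(sa)
  gapcost <- function(d) if (d > 0) gap_open + gap_extend * d else 0
  best <- 0
  rec <- function(i, j, score) {
    if (score > best) best <<- score
    if (i > n || j > m) return(invisible())
    for (ii in i:n) for (jj in j:m) {
      pair <- mat[qa[ii], sa[jj]]
      pen <- if (i == 1 && j == 1) 0 else gapcost(ii - i) + gapcost(jj - j)
      # i,j == 1 marks the first aligned pair: local alignments are free to
      # start anywhere, so no leading gap cost
      rec(ii + 1L, jj + 1L, score + pair - pen)
    }
  }
  # choose every possible first aligned pair explicitly
  for (i0 in seq_len(n)) for (j0 in seq_len(m)) {
    rec(i0 + 1L, j0 + 1L, mat[qa[i0], sa[j0]])
  }
  best
}

# Biostrings local alignment score (independent C implementation)
sw_biostrings <- function(q, s, gap_open = 11, gap_extend = 1) {
  Biostrings::pairwiseAlignment(q, s, type = "local",
                                substitutionMatrix = sagcensus::blosum62(),
                                gapOpening = gap_open, gapExtension = gap_extend,
                                scoreOnly = TRUE)
}

# small standard-style profile/genome for fast tests
small_profile <- function(seed, code = NULL, taxon_id = paste0("sp", seed),
                          phylum = "Other-Bacteria", style = "standard",
                          genome_length = 30000, n_markers = 10) {
  ov <- list(genome_length = genome_length,
             marker_complement = sagcensus::marker_universe()[seq_len(n_markers)],
             etc_complement = character(0), o2red = character(0))
  if (!is.null(code)) ov$genetic_code <- code
  make_taxon_profile(phylum, style, seed = seed, taxon_id = taxon_id,
                     overrides = ov)
}
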