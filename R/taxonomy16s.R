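# 16S rRNA gene detection (k-mer panel matching) and phylum-level
# classification (naive-Bayes word classifier with bootstrap confidence).

#' Detect 16S rRNA genes in an assembly by k-mer panel matching
#'
#' Slides fixed windows along every contig and scores the fraction of window
#' k-mers shared with a panel of reference 16S sequences; windows above the
#' detection threshold are merged (within a gap tolerance) into candidate
#' regions, trimmed to the outermost matching k-mers. Both strands are
#' searched; for minus-strand hits the reported sequence is the reverse
#' complement of the contig slice.
#'
#' @param assembly A `sag_assembly` or named character vector of contigs.
#' @param ref_panel Character vector of reference 16S sequences (e.g.,
#'   `ssu_refdb()$seq`).
#' @param min_len Minimum reported hit length in nt (>= 0).
#' @param k Word size for panel matching.
#' @param window,step Window length and stride in nt.
#' @param threshold Minimum shared-k-mer fraction for a window to qualify.
#' @param gap_tol Maximum gap in nt between qualifying windows to merge.
#' @return Data frame of hits: `sag_id`, `contig_id`, `start`, `end` (0-based
#'   half-open), `strand`, `length_nt`, `sequence`.
#' @export
detect_ssu <- function(assembly, ref_panel, min_len = 1000, k = 16,
                       window = 200, step = 100, threshold = 0.35,
                       gap_tol = 300) {
  if (!length(ref_panel)) stop("ref_panel must be nonempty", call. = FALSE)
  if (min_len < 0) stop("min_len must be >= 0", call. = FALSE)
  contigs <- as_contigs(assembly)
  sag_id <- assembly_id(assembly)

  panel_f <- unique(unlist(lapply(ref_panel, kmers, k = k)))
  panel_r <- unique(unlist(lapply(vapply(ref_panel, revcomp, ""), kmers, k = k)))

  hits <- list()
  for (ci in seq_along(contigs)) {
    seq <- contigs[[ci]]
    cid <- names(contigs)[ci] %||% sprintf("contig%d", ci)
    n <- nchar(seq)
    if (n < max(window, k)) next
    words <- kmers(seq, k)
    for (strand in c("+", "-")) {
      panel <- if (strand == "+") panel_f else panel_r
      m <- words %in% panel
      cm <- cumsum(c(0L, m))
      w_starts <- seq.int(1L, max(n - window + 1L, 1L), by = step)
      w_nk <- pmin(w_starts + window - k, length(m))
      frac <- (cm[w_nk + 1L] - cm[w_starts]) / (w_nk - w_starts + 1L)
      qual <- which(frac >= threshold)
      if (!length(qual)) next
      # merge qualifying windows within gap_tol
      grp <- cumsum(c(1L, diff(w_starts[qual]) > window + gap_tol))
      for (g in unique(grp)) {
        idx <- qual[grp == g]
        lo <- w_starts[idx[1]]
        hi <- min(w_starts[idx[length(idx)]] + window - 1L, n)
        # trim to outermost matching k-mers within the merged region
        span <- lo:min(hi - k + 1L, length(m))
        mm <- span[m[span]]
        if (!length(mm)) next
        s0 <- mm[1] - 1L                  # 0-based
        e0 <- mm[length(mm)] + k - 1L
        if (e0 - s0 < min_len) next
        sl <- substr(seq, s0 + 1L, e0)
        hits[[length(hits) + 1L]] <- data.frame(
          sag_id = sag_id, contig_id = cid, start = s0, end = e0,
          strand = strand, length_nt = e0 - s0,
          sequence = if (strand == "+") sl else revcomp(sl),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(sag_id = character(0), contig_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), length_nt = integer(0),
                      sequence = character(0)))
  }
  do.call(rbind, hits)
}

# word-presence model: list per phylum of (counts of refs containing word,
# number of refs)
train_word_model <- function(refdb, k) {
  refdb <- as_refdb(refdb)
  phyla <- sort(unique(refdb$phylum))
  if (length(phyla) < 2) stop("refdb must contain >= 2 phyla", call. = FALSE)
  model <- lapply(phyla, function(ph) {
    seqs <- refdb$seq[refdb$phylum == ph]
    tabs <- lapply(seqs, function(s) unique(kmers(s, k)))
    counts <- table(unlist(tabs))
    list(counts = counts, n_refs = length(seqs))
  })
  stats::setNames(model, phyla)
}

#' Classify a 16S sequence with a naive-Bayes word classifier
#'
#' Phylum is the argmax over phyla of the summed log word-likelihoods of the
#' query's distinct k-mers, with add-half smoothing:
#' `P(w | phylum) = (n_refs_containing_w + 0.5) / (n_refs + 1)`. Confidence
#' is the percentage of `n_boot` bootstrap subsamples (each of `ceiling(W/8)`
#' of the `W` distinct query words, drawn with replacement) that agree with
#' the full-set winner.
#'
#' @param seq Query nucleotide sequence (length >= `k`).
#' @param refdb Reference database: data frame with `id`, `phylum`, `seq`
#'   (as from [ssu_refdb()]), or a named character vector with
#'   `"id;phylum=X"` names.
#' @param k Word size.
#' @param n_boot Number of bootstrap subsamples.
#' @param seed Integer seed for the bootstrap.
#' @return One-row data frame: `phylum`, `confidence` (0-100).
#' @export
classify_ssu <- function(seq, refdb, k = 8, n_boot = 100, seed = 1) {
  refdb <- as_refdb(refdb)
  if (!nrow(refdb)) stop("refdb must be nonempty", call. = FALSE)
  if (nchar(seq) < k) stop("query shorter than word size", call. = FALSE)
  model <- train_word_model(refdb, k)
  words <- unique(kmers(toupper(seq), k))
  W <- length(words)
  # log-likelihood matrix: words x phyla
  ll <- vapply(model, function(m) {
    cnt <- as.integer(m$counts[words])
    cnt[is.na(cnt)] <- 0L
    log((cnt + 0.5) / (m$n_refs + 1))
  }, numeric(W))
  if (W == 1) ll <- matrix(ll, nrow = 1, dimnames = list(NULL, names(model)))
  full_scores <- colSums(ll)
  winner <- which.max(full_scores)

  m_boot <- ceiling(W / 8)
  agree <- with_seed(split_seed(seed, "boot", substr(seq, 1, 50)), {
    draws <- matrix(sample.int(W, m_boot * n_boot, replace = TRUE),
                    nrow = n_boot)
    sum(apply(draws, 1, function(ix) {
      which.max(colSums(ll[ix, , drop = FALSE])) == winner
    }))
  })
  data.frame(phylum = names(model)[winner],
             confidence = 100 * agree / n_boot,
             stringsAsFactors = FALSE)
}

#' Detect and classify 16S genes across an assembly
#'
#' Convenience wrapper: [detect_ssu()] then [classify_ssu()] per hit.
#'
#' @inheritParams detect_ssu
#' @inheritParams classify_ssu
#' @return Data frame: hit columns plus `phylum`, `confidence`.
#' @export
classify_assembly_ssu <- function(assembly, refdb, min_len = 1000, k = 8,
                                  n_boot = 100, seed = 1) {
  refdb <- as_refdb(refdb)
  hits <- detect_ssu(assembly, refdb$seq, min_len = min_len)
  if (!nrow(hits)) {
    hits$phylum <- character(0)
    hits$confidence <- numeric(0)
    return(hits)
  }
  cls <- do.call(rbind, lapply(seq_len(nrow(hits)), function(i) {
    classify_ssu(hits$sequence[i], refdb, k = k, n_boot = n_boot,
                 seed = split_seed(seed, hits$contig_id[i], hits$start[i]))
  }))
  cbind(hits, cls)
}

#' Remove exactly identical sequences
#'
#' Keeps the first occurrence of each sequence; order otherwise preserved.
#'
#' @param seqs Character vector (possibly named).
#' @return `seqs` without exact duplicates.
#' @export
dedupe_identical <- function(seqs) {
  seqs[!duplicated(unname(seqs))]
}

as_refdb <- function(refdb) {
  if (is.data.frame(refdb)) {
    stopifnot(all(c("phylum", "seq") %in% names(refdb)))
    if (is.null(refdb$id)) refdb$id <- sprintf("ref%d", seq_len(nrow(refdb)))
    return(refdb[, c("id", "phylum", "seq")])
  }
  if (is.character(refdb) && !is.null(names(refdb))) {
    hdr <- names(refdb)
    phylum <- sub(".*;phylum=([^;]+).*", "\\1", hdr)
    id <- sub(";.*", "", hdr)
    return(data.frame(id = id, phylum = phylum, seq = unname(refdb),
                      stringsAsFactors = FALSE))
  }
  stop("refdb must be a data frame or a named character vector", call. = FALSE)
}

#' Read / write a 16S reference database as FASTA
#'
#' Headers embed the taxonomy as `>id;phylum=X`.
#'
#' @param refdb Data frame with `id`, `phylum`, `seq`.
#' @param path File path.
#' @return For the reader, a refdb data frame; for the writer, `path`.
#' @export
write_ssu_refdb <- function(refdb, path) {
  x <- Biostrings::DNAStringSet(refdb$seq)
  names(x) <- sprintf("%s;phylum=%s", refdb$id, refdb$phylum)
  Biostrings::writeXStringSet(x, path, width = 60)
  invisible(path)
}

#' @rdname write_ssu_refdb
#' @export
read_ssu_refdb <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  as_refdb(stats::setNames(as.character(x), names(x)))
}
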